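# Shared domain containers and readers/writers for the standard formats:
# genetic map TSV, RFMix v2 .msp.tsv, VCF genotypes, phenotype tables, and
# TSV scan results. Physical positions are 1-based (VCF convention), genetic
# positions are in centimorgans; internal distance arithmetic is in Morgans.

#' Construct a genetic map
#'
#' A genetic map relates physical coordinates (bp) to genetic coordinates
#' (cM) on each chromosome. Genetic positions must be non-decreasing within
#' a chromosome.
#'
#' @param chrom chromosome labels (coercible to character).
#' @param pos_bp 1-based physical positions.
#' @param pos_cM genetic positions in centimorgans.
#' @param build genome build label carried as metadata (default "GRCh37").
#' @return A `genetic_map` data.frame with columns `chrom`, `pos_bp`,
#'   `pos_cM` and attribute `build`.
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM, build = "GRCh37") {
  map <- data.frame(chrom = as.character(chrom),
                    pos_bp = as.integer(pos_bp),
                    pos_cM = as.numeric(pos_cM),
                    stringsAsFactors = FALSE)
  if (nrow(map) == 0L) stop("genetic map is empty")
  for (ch in unique(map$chrom)) {
    cm <- map$pos_cM[map$chrom == ch]
    bad <- which(diff(cm) < 0)
    if (length(bad))
      stop(sprintf("genetic map: pos_cM decreases on chromosome %s at row %d",
                   ch, bad[1] + 1L))
  }
  attr(map, "build") <- build
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read a genetic map from a delimited file
#'
#' Expects at least three columns: chromosome, physical position (bp), and
#' genetic position (cM), with a header line.
#'
#' @param path file path.
#' @inheritParams genetic_map
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path, build = "GRCh37") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(d) < 3L) stop("genetic map must have >= 3 columns (chrom, pos_bp, pos_cM)")
  genetic_map(d[[1]], d[[2]], d[[3]], build = build)
}

#' Construct a local-ancestry matrix
#'
#' Stores haploid ancestry codes for every individual at every locus of a
#' genetic map. Codes are integers in `0..K-1`; each individual contributes
#' exactly two haplotype rows (stored consecutively).
#'
#' @param codes integer matrix of dimension `2n x L` (haplotypes x loci);
#'   rows ordered `id1.0, id1.1, id2.0, ...`. `NA` marks a missing call.
#' @param individuals character vector of `n` unique individual ids.
#' @param map a [genetic_map()] with `L` rows, aligned to the columns.
#' @param ancestries character vector of `K` ancestry labels (code `k`
#'   means `ancestries[k + 1]`).
#' @return A `local_ancestry` object.
#' @export
local_ancestry <- function(codes, individuals, map, ancestries) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  n <- length(individuals)
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  if (nrow(codes) != 2L * n)
    stop("codes must have two haplotype rows per individual")
  if (ncol(codes) != nrow(map))
    stop("codes columns must align to map loci")
  K <- length(ancestries)
  rng <- range(codes, na.rm = TRUE)
  if (rng[1] < 0L || rng[2] >= K)
    stop("ancestry code outside declared K = ", K)
  structure(list(codes = codes,
                 individuals = as.character(individuals),
                 map = map,
                 ancestries = as.character(ancestries)),
            class = "local_ancestry")
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat(sprintf("local_ancestry: %d individuals x %d loci, K = %d (%s)\n",
              length(x$individuals), ncol(x$codes), length(x$ancestries),
              paste(x$ancestries, collapse = "/")))
  invisible(x)
}

#' Number of individuals / loci in a local-ancestry matrix
#' @param la a `local_ancestry` object.
#' @return integer count.
#' @export
n_individuals <- function(la) length(la$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(la) ncol(la$codes)

#' Read an RFMix v2 msp.tsv file
#'
#' Parses the `.msp.tsv` dialect: a first line `#Subpopulation order/codes:
#' EUR=0 AFR=1 ...`, then a header `#chm spos epos sgpos egpos n snps` plus
#' two columns per individual (`id.0`, `id.1`), and one row per ancestry
#' window. Windows are expanded to the loci of `map` that fall inside them
#' (by physical position); loci not covered by any window get `NA`.
#'
#' @param path path to the msp file.
#' @param map a [genetic_map()] giving the loci to expand the windows onto.
#'   If `NULL`, one locus per window is created at the window midpoint using
#'   the window's genetic coordinates.
#' @return A [local_ancestry()] object.
#' @export
read_msp <- function(path, map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1], "#Subpopulation order/codes"))
    stop("malformed msp header at line 1: expected '#Subpopulation order/codes'")
  codes_part <- sub("^#Subpopulation order/codes:\\s*", "", lines[1])
  toks <- strsplit(trimws(codes_part), "[[:space:],]+")[[1]]
  anc <- vapply(strsplit(toks, "="), `[`, "", 1L)
  code_of <- as.integer(vapply(strsplit(toks, "="), `[`, "", 2L))
  ancestries <- anc[order(code_of)]

  hdr <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  if (length(hdr) < 8L || hdr[1] != "chm")
    stop("malformed msp header at line 2: expected '#chm spos epos ...'")
  hap_cols <- hdr[-(1:6)]
  ind <- unique(sub("\\.[01]$", "", hap_cols))
  if (length(hap_cols) != 2L * length(ind))
    stop("msp: expected two haplotype columns per individual")

  d <- data.table::fread(path, skip = 1L, header = TRUE, data.table = FALSE)
  names(d)[1] <- sub("^#", "", names(d)[1])
  win_codes <- as.matrix(d[, -(1:6), drop = FALSE])
  storage.mode(win_codes) <- "integer"
  if (max(win_codes, na.rm = TRUE) >= length(ancestries))
    stop("ancestry code outside declared K = ", length(ancestries))

  if (is.null(map)) {
    map <- genetic_map(d$chm, floor((d$spos + d$epos) / 2),
                       (d$sgpos + d$egpos) / 2)
    codes <- t(win_codes)
    return(local_ancestry(codes, ind, map, ancestries))
  }

  # expand windows onto the supplied loci (windows are [spos, epos))
  L <- nrow(map)
  codes <- matrix(NA_integer_, nrow = 2L * length(ind), ncol = L)
  for (ch in unique(map$chrom)) {
    li <- which(map$chrom == ch)
    wi <- which(as.character(d$chm) == ch)
    if (!length(wi)) next
    idx <- findInterval(map$pos_bp[li], d$spos[wi])
    inside <- idx >= 1L & map$pos_bp[li] < d$epos[wi][pmax(idx, 1L)]
    codes[, li[inside]] <- t(win_codes[wi[idx[inside]], , drop = FALSE])
  }
  local_ancestry(codes, ind, map, ancestries)
}

#' Construct a genotype matrix
#'
#' @param dosage numeric matrix `n x V` of alt-allele dosages in `[0, 2]`,
#'   rownames = individual ids.
#' @param variants data.frame with columns `chrom`, `pos_bp`, `id`, `ref`,
#'   `alt` (one row per column of `dosage`).
#' @return A `genotype_matrix` with per-variant minor-allele frequency in
#'   `$maf`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns must match variants rows")
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  variants <- as.data.frame(variants)
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  names(maf) <- variants$id
  structure(list(dosage = dosage, variants = variants, maf = maf),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Read genotypes from a VCF
#'
#' Uses `GT` calls when present (missing calls imputed to twice the allele
#' frequency and flagged), else the `DS` dosage field.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()]; attribute `n_imputed_missing` counts
#'   GT-missing entries filled with `2 x` allele frequency.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos_bp = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"],
                         alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  fmt <- v@gt[, 1]
  has_gt <- any(grepl("(^|:)GT(:|$)", fmt))
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles != "0")
    })
  } else {
    ds <- vcfR::extract.gt(v, element = "DS")
    dos <- apply(ds, c(1, 2), as.numeric)
  }
  dos <- t(dos)  # individuals x variants
  n_miss <- sum(is.na(dos))
  if (n_miss > 0) {
    af2 <- colMeans(dos, na.rm = TRUE)
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- af2[j]
  }
  g <- genotype_matrix(dos, variants)
  attr(g, "n_imputed_missing") <- n_miss
  g
}

#' Read a phenotype/covariate table
#'
#' Delimited text with a header; must contain an id column (first column or
#' one named `id`) and a binary case-status column `pad_status` with values
#' in `{0, 1}`.
#'
#' @param path file path.
#' @return data.frame with unique ids.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"id" %in% names(d)) names(d)[1] <- "id"
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stop("phenotype table: duplicate ids")
  if ("pad_status" %in% names(d) &&
      !all(d$pad_status %in% c(0L, 1L, NA)))
    stop("pad_status must be 0/1")
  d
}

#' Intersect individuals across inputs
#'
#' Restricts a local-ancestry matrix, genotype matrix and phenotype table to
#' their common individuals (in the phenotype table's order) and reports the
#' drops. Errors if the overlap falls below `min_overlap` of the smallest
#' input.
#'
#' @param la,geno,pheno the three inputs; `geno` may be `NULL`.
#' @param min_overlap minimum tolerated fraction of the smallest input
#'   retained (default 0.5).
#' @return list with the aligned `la`, `geno`, `pheno` and a `dropped`
#'   report.
#' @export
align_individuals <- function(la, pheno, geno = NULL, min_overlap = 0.5) {
  sets <- list(la = la$individuals, pheno = pheno$id)
  if (!is.null(geno)) sets$geno <- rownames(geno$dosage)
  common <- Reduce(intersect, sets)
  smallest <- min(lengths(sets))
  if (length(common) < min_overlap * smallest)
    stop(sprintf("individual overlap %d below %.0f%% of smallest input (%d)",
                 length(common), 100 * min_overlap, smallest))
  common <- pheno$id[pheno$id %in% common]  # stable order
  hi <- match(common, la$individuals)
  hap_rows <- as.vector(rbind(2L * hi - 1L, 2L * hi))
  la2 <- local_ancestry(la$codes[hap_rows, , drop = FALSE], common,
                        la$map, la$ancestries)
  out <- list(la = la2,
              pheno = pheno[match(common, pheno$id), , drop = FALSE],
              dropped = lapply(sets, function(s) setdiff(s, common)))
  if (!is.null(geno)) {
    out$geno <- genotype_matrix(geno$dosage[match(common, rownames(geno$dosage)),
                                            , drop = FALSE],
                                geno$variants)
  }
  out
}

#' Write a scan result (or any table) to TSV
#'
#' Deterministic column order as given; floats written with full precision
#' so the table round-trips through [read_scan_result()].
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_scan_result
#' @export
read_scan_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
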