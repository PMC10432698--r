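# Fixtures built in code. The shared Dominican-like cohort (three-way
# EUR/AFR/NAT admixture, g = 9.73, n = 1813 on a reduced two-chromosome
# map) is memoised because several files summarise it.

tiny_map <- function(n_loci = 4, chrom = "1", spacing_cM = 1) {
  genetic_map(rep(chrom, n_loci),
              seq(1e6, by = 1e6, length.out = n_loci),
              seq(0, by = spacing_cM, length.out = n_loci))
}

# hand-specified 2-individual, 4-locus, K=3 matrix
tiny_la <- function() {
  codes <- rbind(c(0L, 0L, 1L, 1L),   # ind1 hap1: EUR EUR AFR AFR
                 c(1L, 1L, 1L, 0L),   # ind1 hap2: AFR AFR AFR EUR
                 c(2L, 2L, 2L, 2L),   # ind2 hap1: all NAT
                 c(2L, 2L, 2L, 2L))   # ind2 hap2: all NAT
  local_ancestry(codes, c("A", "B"), tiny_map(),
                 c("EUR", "AFR", "NAT"))
}

shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- admixture_config(map = default_map(chrom_cM = c("1" = 150,
                                                             "2" = 150)),
                              seed = 42)
      la <- simulate_local_ancestry(cfg)
      pheno <- simulate_phenotypes(la, model = phenotype_model(), seed = 42)
      cache <<- list(cfg = cfg, la = la, pheno = pheno)
    }
    cache
  }
})

write_msp_fixture <- function(path) {
  lines <- c(
    "#Subpopulation order/codes: EUR=0\tAFR=1\tNAT=2",
    paste("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
          "A.0", "A.1", "B.0", "B.1", sep = "\t"),
    paste("1", "1", "1000000", "0.0", "1.0", "10", "0", "1", "2", "2", sep = "\t"),
    paste("1", "1000000", "2000000", "1.0", "2.0", "10", "0", "1", "2", "1", sep = "\t"),
    paste("1", "2000000", "3000000", "2.0", "3.0", "10", "1", "1", "2", "0", sep = "\t"))
  writeLines(lines, path)
  path
}

write_vcf_fixture <- function(path, gts) {
  ids <- sprintf("S%02d", seq_along(gts))
  lines <- c(
    "##fileformat=VCFv4.1",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    paste(c("1", "12345", "rs1", "A", "C", ".", "PASS", ".", "GT", gts),
          collapse = "\t"))
  writeLines(lines, path)
  path
}
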