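# shared small panels, built once per test run
shared_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_panel(sim_config(
        n_X = 100, n_G = 100, n_chrom = 3, snps_per_chrom = 300, seed = 42))
    }
    cache
  }
})

identity_kinship <- function(n, ids = NULL) {
  k <- diag(n)
  if (!is.null(ids)) dimnames(k) <- list(ids, ids)
  k
}

# minimal hand-written VCF for parser tests
write_toy_vcf <- function(path, records,
                          samples = c("S1", "S2", "S3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# build a gmc_geno directly from a dosage matrix on one chromosome
toy_geno <- function(dosage, chrom = "1", pos = NULL, subset = "X",
                     ref = NULL, alt = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  gmc_geno(dosage,
           data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      id = paste0("s", seq_len(m)),
                      stringsAsFactors = FALSE),
           sprintf("acc%03d", seq_len(nrow(dosage))), subset)
}
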