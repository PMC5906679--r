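gene1 <- function(end = 1e4) {
  data.frame(gene_id = "g1", chrom = "1", start = 1, end = end,
             stringsAsFactors = FALSE)
}

test_that("haplotypes rank by carrier count with exclusion reasons", {
  d <- matrix(c(rep(0, 30), rep(2, 10)), ncol = 1)
  g <- toy_geno(d)
  h <- build_haplotypes(g, gene1(), subset = "X", min_count = 5)
  expect_equal(h$haplotypes$name, c("Hap1", "Hap2"))
  expect_equal(h$haplotypes$n, c(30L, 10L))
  expect_equal(h$haplotypes$string, c("A", "G"))  # REF then ALT

  # heterozygous accessions are excluded with the policy reason
  d2 <- d; d2[c(2, 5, 9), 1] <- 1
  h2 <- build_haplotypes(toy_geno(d2), gene1(), subset = "X", min_count = 5)
  expect_equal(unname(h2$excluded[c("acc002", "acc005", "acc009")]),
               rep("heterozygous", 3))
  expect_equal(sum(h2$haplotypes$n), 37L)

  # missing calls exclude too
  d3 <- d; d3[c(1, 4), 1] <- NA
  h3 <- build_haplotypes(toy_geno(d3), gene1(), subset = "X", min_count = 5)
  expect_equal(unname(h3$excluded[c("acc001", "acc004")]),
               rep("missing", 2))

  # rare haplotypes drop below min_count
  d4 <- matrix(c(rep(0, 30), rep(2, 3)), ncol = 1)
  h4 <- build_haplotypes(toy_geno(d4), gene1(), subset = "X", min_count = 5)
  expect_equal(nrow(h4$haplotypes), 1L)
  expect_equal(sum(h4$excluded == "rare"), 3L)

  # monomorphic span is flagged
  h5 <- build_haplotypes(toy_geno(matrix(0, 20, 1)), gene1(), subset = "X")
  expect_equal(h5$flag, "no_polymorphic_snp")
  expect_equal(nrow(h5$haplotypes), 0L)
})

test_that("the haplotype partition equals brute-force string grouping", {
  set.seed(77)
  for (rep in 1:10) {
    d <- matrix(sample(c(0, 2), 40 * 6, replace = TRUE,
                       prob = c(0.6, 0.4)), 40, 6)
    g <- toy_geno(d)
    h <- build_haplotypes(g, gene1(), subset = "X", min_count = 1)
    strs <- apply(d, 1, paste, collapse = "")
    # same partition: two accessions share a haplotype iff strings equal
    assig <- h$assignment
    for (i in 1:39) for (j in (i + 1):40) {
      expect_equal(assig[[i]] == assig[[j]], strs[i] == strs[j])
    }
    # with min_count 1 and clean calls, carriers sum to the subset size
    expect_equal(sum(h$haplotypes$n), 40L)
    # frequency-rank invariant: Hap1 is (one of) the most frequent
    expect_equal(h$haplotypes$n, sort(h$haplotypes$n, decreasing = TRUE))
  }
})

test_that("identical gene-span strings always share a haplotype", {
  sim <- shared_panel()
  gene <- data.frame(gene_id = "gg", chrom = "2", start = 5e6, end = 9e6)
  h <- build_haplotypes(sim$geno, gene, subset = "G", min_count = 1)
  idx <- which(sim$geno$subset == "G")
  span <- which(sim$geno$snps$chrom == "2" &
                  sim$geno$snps$pos >= 5e6 & sim$geno$snps$pos <= 9e6)
  poly <- span[apply(sim$geno$dosage[idx, span], 2, var) > 0]
  strs <- apply(sim$geno$dosage[idx, poly, drop = FALSE], 1, paste,
                collapse = "")
  expect_equal(length(unique(strs)), nrow(h$haplotypes))
  grouping <- split(names(h$assignment), h$assignment)
  brute <- split(sim$geno$accession_ids[idx], strs)
  expect_setequal(unname(lapply(grouping, function(v) sort(unname(v)))),
                  unname(lapply(brute, function(v) sort(unname(v)))))
})

test_that("favorable classification reproduces the narrative archetypes", {
  # three haplotypes, 30 carriers each, planted trait patterns:
  #   HapA: high Fe, mid Zn (lower than C)   -> conditional (trade-off)
  #   HapB: low Fe, low Zn, no gain          -> unfavorable
  #   HapC: high Fe, high Zn, Cd flat        -> favorable
  d <- matrix(rep(c(0, 2), c(60, 30)), ncol = 1)
  d <- cbind(d, rep(c(0, 2, 0), c(30, 30, 30)))
  g <- toy_geno(d)
  hap <- rep(c("A", "B", "C"), each = 30)
  set.seed(99)
  mk <- function(means, sd = 0.1) {
    vals <- means[hap] + rnorm(90, 0, sd)
    data.frame(accession = g$accession_ids, subset = "X",
               Fe = 2.4, Zn = 16, Cd = 0.01, Mn = 9.7, Cu = 3.2,
               Se = 0.04, vals = vals)
  }
  haps <- build_haplotypes(g, gene1(), subset = "X", min_count = 5)
  expect_equal(nrow(haps$haplotypes), 3L)
  fe_ph <- mk(c(A = 3.2, B = 2.0, C = 3.2)); fe_ph$Fe <- fe_ph$vals
  zn_ph <- mk(c(A = 14, B = 11, C = 18));    zn_ph$Zn <- zn_ph$vals
  cd_ph <- mk(c(A = 0.01, B = 0.01, C = 0.01), sd = 0)
  cd_ph$Cd <- cd_ph$vals
  fe <- star_level(haps, fe_ph, "Fe")
  zn <- star_level(haps, zn_ph, "Zn")
  cd <- star_level(haps, cd_ph, "Cd")
  expect_equal(cd$star, "ns")
  fav <- classify_favorable(fe, zn, cd)
  # map haplotype names back to the planted groups via carrier strings
  hmap <- setNames(c(AA = "A", AG = "B", GA = "C")[haps$haplotypes$string],
                   haps$haplotypes$name)
  verdict <- setNames(fav$verdict, hmap[fav$haplotype])
  expect_equal(unname(verdict["C"]), "favorable")
  expect_equal(unname(verdict["A"]), "conditional")
  expect_equal(unname(verdict["B"]), "unfavorable")

  # all-ns screens are neutral
  fe0 <- star_level(haps, mk(c(A = 2.4, B = 2.4, C = 2.4), sd = 0), "Fe")
  zn0 <- star_level(haps, mk(c(A = 16, B = 16, C = 16), sd = 0), "Zn")
  fav0 <- classify_favorable(fe0, zn0, cd)
  expect_equal(unique(fav0$verdict), "neutral")

  # a missing trait result skips classification
  expect_message(out <- classify_favorable(fe, NULL, cd), "skipped")
  expect_null(out)
})

test_that("haplotype-effect plots render deterministically", {
  d <- matrix(rep(c(0, 2), c(25, 15)), ncol = 1)
  g <- toy_geno(d)
  haps <- build_haplotypes(g, gene1(), subset = "X", min_count = 5)
  set.seed(6)
  ph <- data.frame(accession = g$accession_ids, subset = "X",
                   Fe = 2.4, Zn = 16 + d[, 1] + rnorm(40, 0, 0.3),
                   Cd = 0.01, Mn = 9.7, Cu = 3.2, Se = 0.04)
  st <- star_level(haps, ph, "Zn")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_haplotype_traits(st, ph, haps, file = f1)
  plot_haplotype_traits(st, ph, haps, file = f2)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
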