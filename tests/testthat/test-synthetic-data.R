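test_that("the same configuration and seed reproduce the panel exactly", {
  cfg <- sim_config(n_X = 20, n_G = 20, n_chrom = 2, snps_per_chrom = 50,
                    seed = 11)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth, s2$truth)
})

test_that("with no causal effects and equal baselines, trait means match", {
  mu <- c(Fe = 2.4, Zn = 16.4, Cd = 0.02, Mn = 9.7, Cu = 3.2, Se = 0.04)
  sd <- c(Fe = 0.4, Zn = 2.0, Cd = 0.004, Mn = 1.5, Cu = 0.5, Se = 0.01)
  cfg <- sim_config(n_X = 200, n_G = 200, n_chrom = 1, snps_per_chrom = 50,
                    means = list(X = mu, G = mu), sds = list(X = sd, G = sd),
                    seed = 21)
  sim <- simulate_panel(cfg)
  for (tr in gmc_traits()) {
    se <- sd[[tr]] / sqrt(400)
    expect_lt(abs(mean(sim$pheno[[tr]]) - mu[[tr]]), 3 * se)
  }
  expect_equal(unname(sim$truth$heritability), rep(0, 6))
})

test_that("the pooled Cd distribution is bimodal with the G mode lower", {
  sim <- simulate_panel(sim_config(seed = 1))
  cd <- sim$pheno$Cd
  d <- density(cd)
  # modes = local maxima of the kernel density
  ys <- d$y
  peaks <- which(diff(sign(diff(ys))) == -2) + 1L
  big <- peaks[ys[peaks] > 0.1 * max(ys)]
  expect_gte(length(big), 2L)
  mode_g <- d$x[big[1]]; mode_x <- d$x[big[length(big)]]
  expect_lt(mode_g, mode_x)
  # and the subset means are ordered accordingly
  expect_lt(mean(cd[sim$pheno$subset == "G"]),
            mean(cd[sim$pheno$subset == "X"]))
  # G runs higher for Zn and Cu
  expect_gt(mean(sim$pheno$Zn[sim$pheno$subset == "G"]),
            mean(sim$pheno$Zn[sim$pheno$subset == "X"]))
  expect_gt(mean(sim$pheno$Cu[sim$pheno$subset == "G"]),
            mean(sim$pheno$Cu[sim$pheno$subset == "X"]))
})

test_that("subset allele-frequency divergence grows with the divergence parameter", {
  msd <- vapply(c(0.02, 0.1, 0.3), function(f) {
    sim <- simulate_panel(sim_config(n_X = 120, n_G = 120, n_chrom = 2,
                                     snps_per_chrom = 250, fst = f,
                                     seed = 33))
    px <- colMeans(sim$geno$dosage[sim$geno$subset == "X", ]) / 2
    pg <- colMeans(sim$geno$dosage[sim$geno$subset == "G", ]) / 2
    mean((px - pg)^2)
  }, numeric(1))
  expect_true(all(diff(msd) > 0))
})

test_that("plant_haplotype_effect assigns identical increments to identical strings", {
  # 2-SNP gene, effects (0, +2): increments only 0 or 2
  set.seed(4)
  d <- matrix(sample(c(0, 2), 60 * 2, replace = TRUE), 60, 2)
  g <- toy_geno(d, pos = c(150L, 250L))
  gene <- data.frame(gene_id = "g", chrom = "1", start = 100, end = 300)
  ph <- plant_haplotype_effect(g, gene, c(0, 2))
  expect_true(all(ph$increment %in% c(0, 2)))
  strs <- apply(d, 1, paste, collapse = "")
  for (s in unique(strs)) {
    expect_equal(length(unique(ph$increment[strs == s])), 1L)
  }
  # monomorphic span -> one haplotype, all increments equal
  gmono <- toy_geno(matrix(0, 30, 1))
  ph2 <- plant_haplotype_effect(gmono,
                                data.frame(gene_id = "m", chrom = "1",
                                           start = 1, end = 1000),
                                c(0.5))
  expect_equal(unique(ph2$increment), 0.5)
  expect_equal(ph2$n_haplotypes, 1L)
  # more effects than realized haplotypes is a configuration error
  expect_error(plant_haplotype_effect(gmono,
                                      data.frame(gene_id = "m", chrom = "1",
                                                 start = 1, end = 1000),
                                      c(0, 1)),
               "more effect entries")
})

test_that("causal genes outside the simulated coordinates are rejected", {
  expect_error(sim_config(n_chrom = 2, causal_genes = list(
    list(gene_id = "bad", chrom = 5, start = 1e6, end = 2e6, trait = "Fe",
         effects = c(0, 1)))), "outside simulated coordinates")
})

test_that("planted haplotype effects are recovered in rank order", {
  # effects spread 2 ppm, noise half the spread
  taus <- vapply(1:20, function(r) {
    cfg <- sim_config(n_X = 300, n_G = 0 + 1, n_chrom = 1,
                      snps_per_chrom = 60,
                      causal_genes = list(list(
                        gene_id = "g", chrom = 1, start = 1e6, end = 8e6,
                        trait = "Zn", effects = c(0, 0.7, 1.4, 2.0))),
                      means = list(
                        X = c(Fe = 2.4, Zn = 16, Cd = 0.01, Mn = 9.7,
                              Cu = 3.2, Se = 0.04),
                        G = c(Fe = 2.4, Zn = 16, Cd = 0.01, Mn = 9.7,
                              Cu = 3.2, Se = 0.04)),
                      sds = list(
                        X = c(Fe = 0.5, Zn = 1.0, Cd = 0.003, Mn = 1.5,
                              Cu = 0.5, Se = 0.01),
                        G = c(Fe = 0.5, Zn = 1.0, Cd = 0.003, Mn = 1.5,
                              Cu = 0.5, Se = 0.01)),
                      seed = 100 + r)
    sim <- simulate_panel(cfg)
    tg <- sim$truth$causal_genes$g
    hap <- tg$haplotype
    planted <- tg$effects
    nh <- min(length(planted), max(hap))
    obs <- vapply(seq_len(nh), function(h) {
      mean(sim$pheno$Zn[hap == h])
    }, numeric(1))
    cor(planted[seq_len(nh)], obs, method = "kendall")
  }, numeric(1))
  expect_gte(mean(taus), 0.8)
})

test_that("null panels yield no genome-wide significant loci", {
  # type-I control smoke test at the stringent threshold
  hits <- vapply(1:10, function(r) {
    sim <- simulate_panel(sim_config(n_X = 250, n_G = 250, n_chrom = 5,
                                     snps_per_chrom = 1000,
                                     seed = 500 + r))
    k <- vanraden_kinship(sim$geno)
    x <- genotype_pca(sim$geno, 2)
    assoc <- scan_mlm(sim$pheno$Fe, x, k, sim$geno, trait = "Fe")
    nrow(call_loci(assoc, "Fe", strict = 6, loose = 3))
  }, numeric(1))
  expect_equal(sum(hits), 0)
})
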