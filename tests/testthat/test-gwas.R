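test_that("VanRaden kinship matches the direct formula on a hand matrix", {
  d <- matrix(c(0, 1, 2,
                2, 2, 0,
                0, 0, 2,
                1, 0, 1), nrow = 3)
  g <- toy_geno(d)
  p <- colMeans(d) / 2
  z <- sweep(d, 2, 2 * p)
  k_hand <- z %*% t(z) / (2 * sum(p * (1 - p)))
  expect_equal(unname(vanraden_kinship(g)), k_hand, tolerance = 1e-12)
})

test_that("kinship treats duplicates and monomorphic columns correctly", {
  set.seed(9)
  d <- matrix(sample(0:2, 100 * 4, replace = TRUE, prob = c(.4, .2, .4)),
              ncol = 100, nrow = 4)
  d[2, ] <- d[1, ]  # duplicate accessions
  k <- vanraden_kinship(toy_geno(d))
  expect_equal(k[1, 2], k[1, 1], tolerance = 1e-12)
  # appending a monomorphic SNP leaves K unchanged
  d2 <- cbind(d, 0)
  expect_equal(unname(vanraden_kinship(toy_geno(d2))), unname(k),
               tolerance = 1e-12)
  # all-monomorphic input is degenerate
  expect_error(vanraden_kinship(toy_geno(matrix(2, 4, 5))), "monomorphic")
})

test_that("PCA separates simulated subsets and returns orthogonal scores", {
  sim <- simulate_panel(sim_config(n_X = 100, n_G = 100, n_chrom = 2,
                                   snps_per_chrom = 1000, fst = 0.15,
                                   seed = 13))
  x <- genotype_pca(sim$geno, 3)
  r <- cor(x[, "PC1"], as.numeric(sim$geno$subset == "X"))
  expect_gt(abs(r), 0.9)
  gram <- crossprod(x[, c("PC2", "PC3")], x[, c("PC2", "PC3")])
  expect_lt(abs(gram[1, 2]), 1e-8)
  # k = 0 gives intercept-only covariates
  expect_equal(colnames(genotype_pca(sim$geno, 0)), "intercept")
})

test_that("REML with identity kinship recovers the OLS residual variance", {
  set.seed(5)
  n <- 80
  y <- rnorm(n, 10, 2)
  x <- cbind(intercept = rep(1, n))
  fit <- fit_null_reml(y, x, identity_kinship(n))
  ols_s2 <- sum(lm(y ~ 1)$residuals^2) / (n - 1)
  expect_equal(fit$sigma2_g + fit$sigma2_e, ols_s2, tolerance = 1e-6)
  expect_true("delta_unidentifiable" %in% fit$flags)
})

test_that("REML matches a direct-formula grid-search oracle", {
  sim <- shared_panel()
  k <- vanraden_kinship(sim$geno)
  x <- genotype_pca(sim$geno, 1)
  y <- sim$pheno$Zn
  fit <- fit_null_reml(y, x, k)
  n <- length(y); q <- ncol(x)
  reml_direct <- function(delta) {
    h <- k + delta * diag(n)
    hi <- solve(h)
    xthx <- t(x) %*% hi %*% x
    p <- hi - hi %*% x %*% solve(xthx) %*% t(x) %*% hi
    s2 <- drop(t(y) %*% p %*% y) / (n - q)
    -0.5 * ((n - q) * log(2 * pi * s2) +
              as.numeric(determinant(h)$modulus) +
              as.numeric(determinant(xthx)$modulus) -
              as.numeric(determinant(crossprod(x))$modulus) + (n - q))
  }
  grid <- 10^seq(-5, 5, length.out = 50)
  ll_grid <- vapply(grid, reml_direct, numeric(1))
  # the eigen-shortcut likelihood equals the direct formula at the optimum
  expect_equal(reml_direct(fit$delta), fit$loglik, tolerance = 1e-4)
  # and the optimizer is at least as good as every grid point
  expect_gte(fit$loglik, max(ll_grid) - 1e-4)
})

test_that("REML recovers simulated heritability on average", {
  sim <- simulate_panel(sim_config(n_X = 250, n_G = 250, n_chrom = 3,
                                   snps_per_chrom = 400, seed = 77))
  k <- vanraden_kinship(sim$geno)
  n <- nrow(k)
  ek <- eigen(k, symmetric = TRUE)
  l <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)))
  x <- cbind(intercept = rep(1, n))
  md <- mean(diag(k))  # VanRaden diagonal is ~2 under strong structure
  set.seed(123)
  h2_hat <- vapply(1:20, function(r) {
    g <- drop(l %*% rnorm(n))          # genetic value, Var = K
    e <- rnorm(n, 0, sd(g))            # equal variance split: h2 = 0.5
    fit <- fit_null_reml(g + e, x, k)
    # express the genetic variance on the trait scale (sigma2_g K_ii)
    fit$sigma2_g * md / (fit$sigma2_g * md + fit$sigma2_e)
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
})

test_that("with identity kinship and no PCs the scan reduces to OLS", {
  sim <- shared_panel()
  n <- nrow(sim$geno$dosage)
  x <- genotype_pca(sim$geno, 0)
  a <- scan_mlm(sim$pheno$Fe, x, identity_kinship(n), sim$geno,
                trait = "Fe")
  y <- sim$pheno$Fe
  d <- sim$geno$dosage
  for (j in which(!is.na(a$minus_log10_p))[seq(1, 700, by = 23)]) {
    sm <- summary(lm(y ~ d[, j]))
    p_ols <- pf(sm$fstatistic[1], 1, sm$fstatistic[3], lower.tail = FALSE)
    expect_equal(10^(-a$minus_log10_p[j]), unname(p_ols), tolerance = 1e-8)
    expect_equal(a$beta[j], unname(coef(sm)[2, 1]), tolerance = 1e-8)
  }
})

test_that("-log10 p is invariant to affine rescaling of the phenotype", {
  sim <- shared_panel()
  k <- vanraden_kinship(sim$geno)
  x <- genotype_pca(sim$geno, 1)
  a1 <- scan_mlm(sim$pheno$Cu, x, k, sim$geno)
  a2 <- scan_mlm(100 * sim$pheno$Cu - 7, x, k, sim$geno)
  ok <- !is.na(a1$minus_log10_p)
  expect_equal(a1$minus_log10_p[ok], a2$minus_log10_p[ok],
               tolerance = 1e-6)
})

test_that("low-MAF SNPs are flagged and left untested", {
  d <- cbind(matrix(sample(0:2, 200 * 5, replace = TRUE), 200, 5),
             c(2, rep(0, 199)))  # MAF 0.005
  g <- toy_geno(d)
  y <- rnorm(200)
  a <- scan_mlm(y, cbind(intercept = rep(1, 200)), identity_kinship(200), g)
  expect_equal(a$flag[6], "low_maf")
  expect_true(is.na(a$minus_log10_p[6]))
  expect_false(any(is.na(a$minus_log10_p[1:5])))
})

test_that("per-SNP case-wise deletion matches a scan on the complete subset", {
  sim <- simulate_panel(sim_config(n_X = 40, n_G = 40, n_chrom = 1,
                                   snps_per_chrom = 30, seed = 19))
  g <- sim$geno
  miss <- c(3, 17, 50)
  g$dosage[miss, 5] <- NA
  y <- sim$pheno$Mn
  k <- vanraden_kinship(sim$geno)  # kinship from complete data
  x <- cbind(intercept = rep(1, 80))
  a <- scan_mlm(y, x, k, g, p3d = TRUE)
  # oracle: direct GLS dropping those accessions at the null delta
  keep <- setdiff(1:80, miss)
  delta <- attr(a, "vc")$delta
  kk <- k[keep, keep]
  ch <- chol(kk + delta * diag(length(keep)))
  yw <- backsolve(ch, y[keep], transpose = TRUE)
  mw <- backsolve(ch, cbind(1, g$dosage[keep, 5]), transpose = TRUE)
  fit <- lm(yw ~ mw - 1)
  p_or <- coef(summary(fit))[2, 4]
  expect_equal(10^(-a$minus_log10_p[5]), p_or, tolerance = 1e-6)
  expect_equal(a$n_used[5], 77L)
})

test_that("favorable allele effects follow the major-allele-zero convention", {
  # constructed data: minor-allele carriers sit ~0.3 ppm higher
  set.seed(31)
  n <- 200
  dos <- rbinom(n, 2, 0.2)            # ALT is minor
  y <- 2.4 + 0.15 * dos + rnorm(n, 0, 0.05)
  g <- toy_geno(cbind(dos, matrix(sample(0:2, n * 3, replace = TRUE), n, 3)))
  a <- scan_mlm(y, cbind(intercept = rep(1, n)), identity_kinship(n), g)
  expect_equal(a$fae[1], 0.15, tolerance = 0.02)
  # swapping ref/alt coding leaves the FAE unchanged
  g2 <- g
  g2$dosage[, 1] <- 2 - g2$dosage[, 1]
  a2 <- scan_mlm(y, cbind(intercept = rep(1, n)), identity_kinship(n), g2)
  expect_equal(a2$fae[1], a$fae[1], tolerance = 1e-8)
  # vectorized convention helper
  fa <- estimate_fae(c(0.5, 0.5, 0.5), c(0.2, 0.8, 0.5))
  expect_equal(fa$fae, c(0.5, -0.5, 0.5))
  expect_equal(fa$tie, c(FALSE, FALSE, TRUE))
})

test_that("parsed FAE values feed summaries unchanged", {
  tab <- gmc_table1()
  expect_equal(tab$fae[tab$locus == "qFe1"], 0.300)
  s <- summarize_qtl_table(tab)
  # qFe1 counts once among the increasing, favorable loci
  dir <- annotate_direction(tab$fae, tab$trait)
  expect_equal(sum(dir$direction == "increasing"), s$n_increasing)
  expect_equal(sum(dir$health == "favorable"), s$n_favorable)
})

test_that("BIC selects PCs exactly when structure drives the phenotype", {
  sim <- shared_panel()
  k <- vanraden_kinship(sim$geno)
  n <- nrow(k)
  set.seed(55)
  # pure subset effect
  y <- 2 * (sim$geno$subset == "G") + rnorm(n)
  expect_gte(select_pcs_bic(y, sim$geno, k, 3), 1L)
  # structure-independent phenotype: selects 0 in >= 80% of replicates
  sel <- vapply(1:50, function(r) {
    select_pcs_bic(rnorm(n), sim$geno, k, 3)
  }, integer(1))
  expect_gte(mean(sel == 0L), 0.8)
  expect_equal(select_pcs_bic(y, sim$geno, k, 0), 0L)
})
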