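#' VanRaden genomic relationship matrix
#'
#' Computes the kinship matrix K = Z Z' / (2 * sum p(1-p)) where Z is the
#' allele-frequency-centered dosage matrix.  Monomorphic SNPs are excluded
#' and missing dosages are mean-imputed per SNP before centering, so K is
#' always well defined on polymorphic data.
#'
#' @param geno a [gmc_geno()] panel (or a plain dosage matrix, accessions
#'   in rows).
#' @return symmetric accessions x accessions matrix.
#' @export
vanraden_kinship <- function(geno) {
  d <- if (inherits(geno, "gmc_geno")) geno$dosage else as.matrix(geno)
  if (nrow(d) < 2L) stop("kinship needs at least 2 accessions")
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(keep)) stop("all SNPs monomorphic; kinship undefined")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  # mean-impute missing dosages per SNP
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0L)) {
      d[is.na(d[, j]), j] <- 2 * p[j]
    }
  }
  z <- sweep(d, 2L, 2 * p)
  k <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(k) <- list(rownames(d), rownames(d))
  k
}

#' Principal-component covariates from genotypes
#'
#' Top-k principal component scores of the centered (optionally unit-scaled)
#' mean-imputed dosage matrix, returned together with an intercept column.
#' A deterministic sign convention is applied: each component is flipped so
#' that its largest-magnitude SNP loading is positive.
#'
#' @param geno a [gmc_geno()] panel or dosage matrix.
#' @param k number of components; `k <= 0` yields intercept-only covariates.
#' @param scale logical; unit-scale SNP columns before the decomposition.
#' @return numeric matrix with columns `intercept`, `PC1`, ..., `PCk`.
#' @export
genotype_pca <- function(geno, k, scale = FALSE) {
  d <- if (inherits(geno, "gmc_geno")) geno$dosage else as.matrix(geno)
  n <- nrow(d)
  ic <- matrix(1, n, 1, dimnames = list(rownames(d), "intercept"))
  if (k <= 0) return(ic)
  if (k >= n) stop("k must be smaller than the number of accessions")
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  d <- d[, keep, drop = FALSE]
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0L)) {
      d[is.na(d[, j]), j] <- 2 * p[keep][j]
    }
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = scale, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  cbind(ic, scores)
}

# REML log-likelihood profile in delta = sigma2_e / sigma2_g, via a single
# eigendecomposition of S K S (S the projection off the fixed effects).
.reml_setup <- function(y, x, k) {
  n <- length(y)
  q <- qr(x)$rank
  s <- diag(n) - x %*% solve(crossprod(x), t(x))
  sks <- s %*% k %*% s
  sks <- (sks + t(sks)) / 2
  e <- eigen(sks, symmetric = TRUE)
  keep <- seq_len(n - q)
  list(xi = e$values[keep], eta = drop(crossprod(e$vectors[, keep], y)),
       n = n, q = q)
}

.reml_loglik <- function(delta, su) {
  nq <- su$n - su$q
  denom <- su$xi + delta
  if (any(denom <= 0)) return(-Inf)
  ss <- sum(su$eta^2 / denom)
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(ss) - sum(log(denom)))
}

#' Fit the null mixed model by REML
#'
#' Restricted maximum likelihood estimation of the variance components of
#' y = X beta + u + e, u ~ N(0, sigma2_g K), e ~ N(0, sigma2_e I), via a
#' single eigendecomposition of the projected kinship and one-dimensional
#' optimization of the REML likelihood over log10(delta),
#' delta = sigma2_e / sigma2_g, on [-5, 5] (Brent, tolerance 1e-8).
#'
#' @param y numeric response (one trait, ppm).
#' @param x covariate matrix including the intercept (see
#'   [genotype_pca()]).
#' @param k kinship matrix (positive semi-definite within -1e-8).
#' @return object of class `gmc_reml` with `sigma2_g`, `sigma2_e`, `delta`,
#'   `loglik`, and a `flags` field (e.g. `delta_unidentifiable` when the
#'   REML surface is flat, as with K = I).
#' @export
fit_null_reml <- function(y, x, k) {
  stopifnot(length(y) == nrow(x), nrow(k) == length(y))
  ok <- which(!is.na(y))
  y <- y[ok]; x <- x[ok, , drop = FALSE]; k <- k[ok, ok, drop = FALSE]
  ev_min <- min(eigen((k + t(k)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("kinship matrix is not positive semi-definite")
  su <- .reml_setup(y, x, k)
  f <- function(l) .reml_loglik(10^l, su)
  opt <- stats::optimize(f, c(-5, 5), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(-5, f(-5)), c(5, f(5)))
  best <- cand[which.max(cand[, 2]), ]
  delta <- 10^best[1]
  flags <- character()
  grid <- vapply(seq(-5, 5, length.out = 21), f, numeric(1))
  if (max(grid) - min(grid) < 1e-6) flags <- c(flags, "delta_unidentifiable")
  nq <- su$n - su$q
  sigma2_g <- sum(su$eta^2 / (su$xi + delta)) / nq
  structure(list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
                 delta = delta, loglik = best[2], n = su$n, q = su$q,
                 flags = flags),
            class = "gmc_reml")
}

#' @export
print.gmc_reml <- function(x, ...) {
  cat("Null mixed model (REML):\n")
  cat(sprintf("  sigma2_g = %.6g  sigma2_e = %.6g  delta = %.6g\n",
              x$sigma2_g, x$sigma2_e, x$delta))
  h2 <- x$sigma2_g / (x$sigma2_g + x$sigma2_e)
  cat(sprintf("  pseudo-heritability = %.3f   logLik = %.4f   n = %d\n",
              h2, x$loglik, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# ML log-likelihood (for BIC model selection), profiled over beta and
# sigma2_g at fixed delta using the full eigendecomposition of K.
.ml_loglik_opt <- function(y, x, ek) {
  n <- length(y)
  f <- function(l) {
    delta <- 10^l
    w <- 1 / (ek$values + delta)
    sw <- sqrt(w)
    xw <- x * sw
    yw <- drop(crossprod(ek$vectors, y)) * sw
    fit <- stats::lm.fit(xw, yw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(ek$values + delta)) + n)
  }
  opt <- stats::optimize(f, c(-5, 5), maximum = TRUE, tol = 1e-8)
  max(opt$objective, f(-5), f(5))
}

#' Select the number of PC covariates by BIC
#'
#' Fits the null mixed model by maximum likelihood for each number of
#' principal-component covariates k = 0..k_max and returns the k minimizing
#' BIC = -2 logLik + (k + 3) log n (intercept plus two variance
#' components).  Ties resolve to the smaller k.
#'
#' @param y trait vector.
#' @param geno a [gmc_geno()] panel.
#' @param k kinship matrix.
#' @param k_max maximum number of components considered.
#' @return integer in `0:k_max`.
#' @export
select_pcs_bic <- function(y, geno, k, k_max = 3) {
  stopifnot(k_max >= 0)
  if (k_max == 0) return(0L)
  pcs <- genotype_pca(geno, k_max)
  ok <- which(!is.na(y))
  yy <- y[ok]; kk <- k[ok, ok, drop = FALSE]
  ek <- eigen((kk + t(kk)) / 2, symmetric = TRUE)
  ek$vectors <- ek$vectors
  n <- length(yy)
  ek$values <- pmax(ek$values, 0)
  bic <- vapply(0:k_max, function(kc) {
    x <- pcs[ok, seq_len(kc + 1L), drop = FALSE]
    xr <- crossprod(ek$vectors, x)
    ll <- .ml_loglik_opt(yy, xr, ek)
    -2 * ll + (kc + 3) * log(n)
  }, numeric(1))
  best <- which(bic <= min(bic) + 1e-9)[1] - 1L
  as.integer(best)
}

#' Favorable allele effect from a tested SNP
#'
#' Re-expresses the ALT-dosage regression coefficient with the major allele
#' as the zero reference, so the reported effect is that of the minor
#' (germplasm) allele: positive values mean the minor allele raises the
#' trait.  At an exact 50/50 frequency tie the REF allele is taken as
#' reference and the effect is reported for ALT (flagged `maf_tie`).
#'
#' @param beta ALT-allele dosage effect(s) from the scan.
#' @param alt_freq ALT allele frequency(ies) among tested accessions.
#' @return list with `fae` and logical `tie` flags, vectorized.
#' @export
estimate_fae <- function(beta, alt_freq) {
  tie <- !is.na(alt_freq) & alt_freq == 0.5
  fae <- ifelse(!is.na(alt_freq) & alt_freq > 0.5, -beta, beta)
  list(fae = fae, tie = tie)
}

#' Mixed linear model association scan
#'
#' Per-SNP generalized least squares Wald/F test of the ALT-dosage effect
#' under covariance sigma2_g K + sigma2_e I.  With `p3d = TRUE` (the
#' default) the null variance components are estimated once and reused for
#' every SNP; `p3d = FALSE` re-estimates them per SNP.  Accessions missing
#' the phenotype are dropped globally; accessions missing a dosage are
#' dropped for that SNP only (case-wise deletion, via an exact GLS on the
#' reduced kinship).  SNPs below the minor-allele-frequency threshold are
#' emitted untested with flag `low_maf`.
#'
#' @param y trait vector aligned to the panel.
#' @param x covariate matrix including intercept.
#' @param k kinship matrix.
#' @param geno a [gmc_geno()] panel.
#' @param p3d reuse null variance components for all SNPs.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param trait optional trait name carried in the result.
#' @return data.frame of class `gmc_assoc` with columns `id`, `chrom`,
#'   `pos`, `maf`, `n_used`, `beta`, `se`, `fae`, `minus_log10_p`, `flag`;
#'   the null `gmc_reml` fit is attached as attribute `vc`.
#' @export
scan_mlm <- function(y, x, k, geno, p3d = TRUE, maf_min = 0.01,
                     trait = NA_character_) {
  stopifnot(inherits(geno, "gmc_geno"))
  n_all <- length(geno$accession_ids)
  stopifnot(length(y) == n_all, nrow(x) == n_all, nrow(k) == n_all)
  ok <- which(!is.na(y))
  y0 <- y[ok]; x0 <- x[ok, , drop = FALSE]
  k0 <- k[ok, ok, drop = FALSE]
  d0 <- geno$dosage[ok, , drop = FALSE]
  null_fit <- fit_null_reml(y0, x0, k0)
  delta <- null_fit$delta
  n <- length(y0); q <- ncol(x0)
  ek <- eigen((k0 + t(k0)) / 2, symmetric = TRUE)
  ev <- pmax(ek$values, 0)
  w <- 1 / (ev + delta)
  sw <- sqrt(w)
  ys <- drop(crossprod(ek$vectors, y0)) * sw
  xs <- crossprod(ek$vectors, x0) * sw
  qx <- qr(xs)
  ey <- qr.resid(qx, ys)
  rss0 <- sum(ey^2)

  m <- ncol(d0)
  alt_freq <- colMeans(d0, na.rm = TRUE) / 2
  n_used <- colSums(!is.na(d0))
  maf <- pmin(alt_freq, 1 - alt_freq)
  beta <- se <- mlp <- rep(NA_real_, m)
  flag <- rep("", m)
  testable <- which(!is.na(maf) & maf >= maf_min & n_used > q + 1)
  flag[setdiff(seq_len(m), testable)] <- "low_maf"

  complete <- testable[colSums(is.na(d0[, testable, drop = FALSE])) == 0L]
  partial <- setdiff(testable, complete)

  if (length(complete) && p3d) {
    gs <- crossprod(ek$vectors, d0[, complete, drop = FALSE]) * sw
    egs <- qr.resid(qx, gs)
    gg <- colSums(egs^2)
    gy <- colSums(egs * ey)
    b <- gy / gg
    rss <- rss0 - b^2 * gg
    df2 <- n - q - 1
    s2 <- rss / df2
    fstat <- b^2 * gg / s2
    lp <- stats::pf(fstat, 1, df2, lower.tail = FALSE, log.p = TRUE)
    beta[complete] <- b
    se[complete] <- sqrt(s2 / gg)
    mlp[complete] <- -lp / log(10)
  }
  slow <- c(partial, if (!p3d) complete)
  for (j in slow) {
    rows <- which(!is.na(d0[, j]))
    yy <- y0[rows]; xx <- x0[rows, , drop = FALSE]
    kk <- k0[rows, rows, drop = FALSE]
    g <- d0[rows, j]
    dj <- if (p3d) delta else fit_null_reml(yy, cbind(xx, g), kk)$delta
    ej <- eigen((kk + t(kk)) / 2, symmetric = TRUE)
    wj <- sqrt(1 / (pmax(ej$values, 0) + dj))
    ysj <- drop(crossprod(ej$vectors, yy)) * wj
    msj <- crossprod(ej$vectors, cbind(xx, g)) * wj
    xtxinv <- tryCatch(solve(crossprod(msj)), error = function(e) NULL)
    if (is.null(xtxinv)) next
    bvec <- drop(xtxinv %*% crossprod(msj, ysj))
    rdf <- length(yy) - ncol(msj)
    if (rdf < 1) next
    s2j <- sum((ysj - drop(msj %*% bvec))^2) / rdf
    sej <- sqrt(s2j * xtxinv[ncol(msj), ncol(msj)])
    bj <- bvec[ncol(msj)]
    fj <- (bj / sej)^2
    lp <- stats::pf(fj, 1, rdf, lower.tail = FALSE, log.p = TRUE)
    beta[j] <- bj; se[j] <- sej; mlp[j] <- -lp / log(10)
  }
  fa <- estimate_fae(beta, alt_freq)
  flag[fa$tie & flag == ""] <- "maf_tie"
  out <- data.frame(id = geno$snps$id, chrom = geno$snps$chrom,
                    pos = geno$snps$pos, maf = maf, n_used = n_used,
                    beta = beta, se = se, fae = fa$fae,
                    minus_log10_p = mlp, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "vc") <- null_fit
  attr(out, "trait") <- trait
  class(out) <- c("gmc_assoc", "data.frame")
  out
}

#' @export
print.gmc_assoc <- function(x, ...) {
  tr <- attr(x, "trait")
  cat("Association scan", if (!is.na(tr)) paste0("(", tr, ")"), ":",
      nrow(x), "SNPs,", sum(!is.na(x$minus_log10_p)), "tested\n")
  top <- x[order(-x$minus_log10_p), ][1:min(5, nrow(x)), ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.gmc_assoc <- function(object, ...) {
  list(n_snps = nrow(object),
       n_tested = sum(!is.na(object$minus_log10_p)),
       lambda = gc_lambda(object),
       max_minus_log10_p = max(object$minus_log10_p, na.rm = TRUE),
       vc = attr(object, "vc"))
}

#' Genomic-control inflation factor
#'
#' Lambda = median of the per-SNP 1-df chi-square statistics divided by its
#' null median; values near 1 indicate a well-calibrated scan.
#'
#' @param assoc a `gmc_assoc` result (or a numeric vector of -log10 p).
#' @return numeric lambda.
#' @export
gc_lambda <- function(assoc) {
  mlp <- if (is.numeric(assoc)) assoc else assoc$minus_log10_p
  mlp <- mlp[!is.na(mlp)]
  chi <- stats::qchisq(-mlp * log(10), df = 1, lower.tail = FALSE,
                       log.p = TRUE)
  stats::median(chi) / stats::qchisq(0.5, 1)
}

#' Write an association scan as TSV
#' @param assoc `gmc_assoc` result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(assoc, path) .write_tsv(as.data.frame(assoc), path)
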