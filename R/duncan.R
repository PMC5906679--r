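#' Duncan's multiple range test
#'
#' Step-down range procedure on the ranked group means of a one-way layout.
#' The critical range for a stretch of p ranked means is
#' `q(1 - alpha_p, p, df) * sqrt(MSE / n_h)`, where `q` is the studentized
#' range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's
#' protection level, MSE and df come from the one-way ANOVA, and `n_h` is
#' the harmonic mean of the sizes of the groups spanned by the comparison.
#' A stretch is declared non-significant whenever a containing stretch is,
#' and the resulting relation is rendered as a compact letter display: two
#' groups share a letter exactly when their means are not separated.
#'
#' The range procedure runs protected behind the one-way ANOVA F test
#' (`protect_f = TRUE`, the default): when the F test is not significant at
#' `alpha`, no pair separates.  Unprotected, Duncan's procedure lets its
#' family-wise error grow with the group count (the widest stretch is
#' tested at level `1 - (1-alpha)^(k-1)`); the ANOVA gate keeps the null
#' any-separation rate near `alpha` while leaving the liberal stepwise
#' behaviour untouched once a real signal is present.
#'
#' With two groups the procedure (protected or not) reduces exactly to the
#' pooled two-sample t-test at level alpha: the F gate is the squared t
#' test and q(2, df) = sqrt(2) t.
#'
#' @param groups named list of numeric vectors (one per group); groups with
#'   no observations are dropped with a warning.
#' @param alpha significance level.
#' @param protect_f gate the range procedure behind the one-way ANOVA F
#'   test at `alpha`.
#' @return object of class `gmc_duncan`: `table` (group, n, mean, sd,
#'   letters, in descending-mean order), `mse`, `df`, `alpha`, `any_sig`
#'   (whether at least one pair separates), `f_pvalue`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, protect_f = TRUE) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  if (k < 2L) {
    tab <- data.frame(group = names(groups), n = as.integer(ns),
                      mean = unname(means), sd = unname(sds),
                      letters = rep("a", k), stringsAsFactors = FALSE)
    return(structure(list(table = tab, mse = NA_real_, df = NA_integer_,
                          alpha = alpha, any_sig = FALSE,
                          f_pvalue = NA_real_),
                     class = "gmc_duncan"))
  }
  total_n <- sum(ns)
  df <- total_n - k
  if (df < 1L) stop("error degrees of freedom < 1; need more observations")
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) / df
  gm <- sum(ns * means) / total_n
  ms_between <- sum(ns * (means - gm)^2) / (k - 1)
  f_pvalue <- if (mse > 0) {
    stats::pf(ms_between / mse, k - 1, df, lower.tail = FALSE)
  } else if (ms_between > 0) 0 else 1
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nn <- ns[ord]
  # nonsig[i, j]: ranked means i..j not separated
  nonsig <- diag(k) > 0
  if (protect_f && f_pvalue >= alpha) {
    nonsig[] <- TRUE
  } else if (mse <= 0) {
    # all observations identical within groups; separate any unequal means
    for (span in k:2) for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      nonsig[i, j] <- nonsig[j, i] <- (m[i] - m[j]) == 0
    }
  } else {
    for (span in k:2) {
      alpha_p <- 1 - (1 - alpha)^(span - 1)
      qcrit <- stats::qtukey(1 - alpha_p, span, df)
      for (i in seq_len(k - span + 1L)) {
        j <- i + span - 1L
        n_h <- span / sum(1 / nn[i:j])
        rng <- qcrit * sqrt(mse / n_h)
        ns_ij <- (m[i] - m[j]) < rng
        # protection: contained in a non-significant stretch
        if (i > 1L && nonsig[i - 1L, j]) ns_ij <- TRUE
        if (j < k && nonsig[i, j + 1L]) ns_ij <- TRUE
        nonsig[i, j] <- nonsig[j, i] <- ns_ij
      }
    }
  }
  # maximal non-significant stretches -> letters
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    j
  }, integer(1))
  intervals <- list()
  for (i in seq_len(k)) {
    if (i == 1L || reach[i] > reach[i - 1L]) {
      intervals[[length(intervals) + 1L]] <- c(i, reach[i])
    }
  }
  lets <- c(letters, paste0(rep(letters, each = 26), letters))
  disp <- character(k)
  for (t in seq_along(intervals)) {
    iv <- intervals[[t]]
    disp[iv[1]:iv[2]] <- paste0(disp[iv[1]:iv[2]], lets[t])
  }
  tab <- data.frame(group = names(groups)[ord], n = as.integer(nn),
                    mean = unname(m), sd = unname(sds[ord]),
                    letters = disp, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  any_sig <- any(!nonsig[upper.tri(nonsig)])
  structure(list(table = tab, mse = mse, df = df, alpha = alpha,
                 any_sig = any_sig, nonsig = nonsig,
                 f_pvalue = f_pvalue),
            class = "gmc_duncan")
}

#' @export
print.gmc_duncan <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g)\n", x$alpha))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  if (!is.na(x$df)) {
    cat(sprintf("  MSE = %.5g on %d df; %s\n", x$mse, x$df,
                if (x$any_sig) "at least one pair separated" else
                  "no pair separated"))
  }
  invisible(x)
}

#' Are two groups significantly different in a Duncan result?
#'
#' @param x a `gmc_duncan` object.
#' @param a,b group names.
#' @return `TRUE` when `a` and `b` share no letter.
#' @export
duncan_separated <- function(x, a, b) {
  la <- x$table$letters[x$table$group == a]
  lb <- x$table$letters[x$table$group == b]
  if (!length(la) || !length(lb)) stop("unknown group name")
  !any(strsplit(la, "")[[1]] %in% strsplit(lb, "")[[1]])
}

GMC_ALPHAS <- c(0.05, 0.01, 0.001, 0.0001)
GMC_STARS <- c("*", "**", "***", "****")

#' Star-level Duncan screen of one gene/trait/subset cell
#'
#' Runs [duncan_mrt()] on per-haplotype trait values at each of the four
#' reporting levels (0.05, 0.01, 0.001, 0.0001); the star level is the most
#' stringent level at which at least one pair of haplotypes separates
#' (`ns` when none separates at 0.05).
#'
#' @param assignment a [build_haplotypes()] result.
#' @param pheno phenotype data.frame (`accession` + trait columns).
#' @param trait trait name.
#' @return object of class `gmc_duncan_star`: the 0.05-level `gmc_duncan`
#'   plus `star` (`"ns"`, `"*"`, ..., `"****"`), `level`, `gene_id`,
#'   `trait`, `subset`, and `by_alpha` (the `gmc_duncan` fit per level).
#' @export
star_level <- function(assignment, pheno, trait) {
  stopifnot(inherits(assignment, "gmc_haps"))
  pheno <- as.data.frame(pheno)
  y <- stats::setNames(pheno[[trait]], pheno$accession)
  hap <- assignment$assignment
  hap <- hap[!is.na(hap)]
  groups <- split(unname(y[names(hap)]), hap)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[order(as.integer(sub("^Hap", "", names(groups))))]
  res <- list(gene_id = assignment$gene_id, trait = trait,
              subset = assignment$subset)
  if (length(groups) < 2L) {
    res <- c(res, list(star = "ns", level = NA_real_, by_alpha = list(),
                       duncan = NULL, reason = "fewer than 2 haplotypes"))
    class(res) <- "gmc_duncan_star"
    return(res)
  }
  by_alpha <- lapply(GMC_ALPHAS, function(a) duncan_mrt(groups, a))
  names(by_alpha) <- as.character(GMC_ALPHAS)
  sig <- vapply(by_alpha, `[[`, logical(1), "any_sig")
  star <- "ns"; level <- NA_real_
  if (any(sig)) {
    idx <- max(which(sig))
    star <- GMC_STARS[idx]
    level <- GMC_ALPHAS[idx]
  }
  res <- c(res, list(star = star, level = level, by_alpha = by_alpha,
                     duncan = by_alpha[["0.05"]]))
  class(res) <- "gmc_duncan_star"
  res
}

#' @export
print.gmc_duncan_star <- function(x, ...) {
  cat(sprintf("%s / %s / %s-set: %s\n", x$gene_id, x$trait,
              x$subset %||% "all", x$star))
  if (!is.null(x$duncan)) print(x$duncan)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a
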