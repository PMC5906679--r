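.open_png <- function(file, width, height) {
  grDevices::png(file, width = width, height = height, res = 96)
}

#' Manhattan plot of an association scan
#'
#' Per-chromosome alternating palette with horizontal reference lines at
#' the loose and stringent calling thresholds (3.0 and 6.0 by default).
#'
#' @param assoc `gmc_assoc` scan result.
#' @param thresholds -log10 P reference lines.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return invisibly, a list with the plotted data frame and the threshold
#'   values drawn.
#' @export
plot_manhattan <- function(assoc, thresholds = c(3, 6), file = NULL,
                           main = attr(assoc, "trait") %||% "") {
  a <- assoc[!is.na(assoc$minus_log10_p), , drop = FALSE]
  if (nrow(a) == 0L) stop("no tested SNPs to plot")
  chroms <- unique(a$chrom)
  offset <- 0
  xs <- numeric(nrow(a))
  ticks <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    ii <- a$chrom == chroms[i]
    xs[ii] <- a$pos[ii] + offset
    ticks[i] <- offset + mean(range(a$pos[ii]))
    offset <- offset + max(a$pos[ii]) + 1e6
  }
  cols <- c("#3B6BA5", "#E08F41")[(match(a$chrom, chroms) - 1L) %% 2L + 1L]
  draw <- function() {
    graphics::plot(xs, a$minus_log10_p, col = cols, pch = 16, cex = 0.5,
                   xaxt = "n", xlab = "Chromosome",
                   ylab = expression(-log[10](italic(P))), main = main,
                   ylim = c(0, max(a$minus_log10_p, thresholds) * 1.05))
    graphics::axis(1, at = ticks, labels = chroms)
    graphics::abline(h = thresholds, lty = c(3, 2), col = "grey30")
  }
  if (!is.null(file)) {
    .open_png(file, 1200, 400)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(list(data = data.frame(x = xs, minus_log10_p = a$minus_log10_p,
                                   chrom = a$chrom),
                 thresholds = thresholds))
}

#' Trait distribution histograms by subset
#'
#' One histogram per trait with the X and G subsets overlaid in distinct
#' colors, mirroring panel-wide concentration distribution figures.
#'
#' @param pheno phenotype data.frame.
#' @param file optional PNG path.
#' @return invisibly, the list of per-trait histogram break/count data.
#' @export
plot_distributions <- function(pheno, file = NULL) {
  pheno <- as.data.frame(pheno)
  if (nrow(pheno) == 0L) stop("no phenotypes to plot")
  draw <- function() {
    op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    out <- list()
    for (tr in GMC_TRAITS) {
      v <- pheno[[tr]]
      ok <- !is.na(v)
      brk <- pretty(v[ok], 30)
      hx <- graphics::hist(v[ok & pheno$subset == "X"], breaks = brk,
                           plot = FALSE)
      hg <- graphics::hist(v[ok & pheno$subset == "G"], breaks = brk,
                           plot = FALSE)
      ymax <- max(hx$counts, hg$counts)
      graphics::plot(hx, col = grDevices::adjustcolor("#3B6BA5", 0.6),
                     border = NA, main = tr, xlab = "ppm",
                     ylim = c(0, ymax))
      graphics::plot(hg, col = grDevices::adjustcolor("#E08F41", 0.6),
                     border = NA, add = TRUE)
      out[[tr]] <- list(breaks = brk, x = hx$counts, g = hg$counts)
    }
    out
  }
  if (!is.null(file)) {
    .open_png(file, 1200, 700)
    on.exit(grDevices::dev.off())
    res <- draw()
  } else {
    res <- draw()
  }
  invisible(res)
}

#' Haplotype-effect plot for one gene/trait/subset cell
#'
#' Box plot of trait values per haplotype (Hap1..HapN order) annotated with
#' the compact letter display at the 0.05 level and the cell's star level.
#'
#' @param star a [star_level()] result.
#' @param pheno phenotype data.frame (to recover the raw values).
#' @param assignment the [build_haplotypes()] assignment used.
#' @param file optional PNG path.
#' @return invisibly, the per-haplotype summary table.
#' @export
plot_haplotype_traits <- function(star, pheno, assignment, file = NULL) {
  stopifnot(inherits(star, "gmc_duncan_star"))
  pheno <- as.data.frame(pheno)
  y <- stats::setNames(pheno[[star$trait]], pheno$accession)
  hap <- assignment$assignment
  hap <- hap[!is.na(hap)]
  groups <- split(unname(y[names(hap)]), hap)
  groups <- groups[order(as.integer(sub("^Hap", "", names(groups))))]
  tab <- if (!is.null(star$duncan)) star$duncan$table else NULL
  draw <- function() {
    bp <- graphics::boxplot(groups, col = "#9CC3E4",
                            ylab = paste(star$trait, "(ppm)"),
                            main = sprintf("%s  %s (%s-set)  %s",
                                           star$gene_id, star$trait,
                                           star$subset, star$star))
    if (!is.null(tab)) {
      lets <- tab$letters[match(names(groups), tab$group)]
      graphics::text(seq_along(groups), bp$stats[5, ], lets, pos = 3,
                     col = "red")
    }
  }
  if (!is.null(file)) {
    .open_png(file, 600, 400)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(tab)
}
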