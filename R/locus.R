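#' Health polarity of the six grain mineral traits
#'
#' Raising Fe, Zn, Mn, Cu and Se in milled grain is beneficial for the
#' consumer; raising Cd is harmful.  An allele is "favorable" when its
#' effect sign matches this polarity.
#'
#' @return named character vector mapping trait to `"+"` or `"-"`.
#' @export
trait_polarity <- function() {
  c(Fe = "+", Zn = "+", Cd = "-", Mn = "+", Cu = "+", Se = "+")
}

#' Call QTL loci from an association scan
#'
#' Dual-threshold locus calling: SNPs at or above the stringent threshold
#' always seed loci; SNPs between the loose and stringent thresholds seed
#' loci only when they fall inside a supporting interval (same-trait
#' linkage or literature QTL).  Qualifying SNPs within `merge_gap` bp of
#' each other on a chromosome merge into one locus spanning them; the peak
#' marker is the SNP with the largest -log10 P.  Loci are named
#' `q<Trait><chrom>` with a positional `-k` suffix when a trait has more
#' than one locus on a chromosome.
#'
#' @param assoc `gmc_assoc` scan result (one trait).
#' @param trait trait name (Fe, Zn, Cd, Mn, Cu or Se).
#' @param strict,loose -log10 P thresholds (defaults 6.0 and 3.0).
#' @param support optional support-interval data.frame (see
#'   [read_support_intervals()]).
#' @param merge_gap SNP-to-locus merge distance in bp (default 300 kb).
#' @return data.frame of class `gmc_loci`, zero rows when nothing
#'   qualifies.
#' @export
call_loci <- function(assoc, trait, strict = 6, loose = 3, support = NULL,
                      merge_gap = 3e5) {
  stopifnot(strict >= loose)
  empty <- data.frame(name = character(), trait = character(),
                      chrom = character(), start = integer(),
                      end = integer(), peak_pos = integer(),
                      peak_log10p = numeric(), fae = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("gmc_loci", "data.frame")
  if (is.null(assoc) || nrow(assoc) == 0L) return(empty)
  a <- assoc[!is.na(assoc$minus_log10_p), , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  in_support <- rep(FALSE, nrow(a))
  if (!is.null(support) && nrow(support) > 0L) {
    sup <- support[is.na(support$trait) | support$trait == trait, ,
                   drop = FALSE]
    for (i in seq_len(nrow(sup))) {
      in_support <- in_support |
        (a$chrom == sup$chrom[i] & a$pos >= sup$start[i] &
           a$pos <= sup$end[i])
    }
  }
  qual <- a$minus_log10_p >= strict |
    (a$minus_log10_p >= loose & in_support)
  a <- a[qual, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  a <- a[order(a$chrom, a$pos), , drop = FALSE]
  grp <- integer(nrow(a))
  g <- 0L
  for (i in seq_len(nrow(a))) {
    if (i == 1L || a$chrom[i] != a$chrom[i - 1L] ||
        a$pos[i] - a$pos[i - 1L] > merge_gap) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  loci <- do.call(rbind, lapply(split(seq_len(nrow(a)), grp), function(ii) {
    b <- a[ii, , drop = FALSE]
    pk <- which.max(b$minus_log10_p)
    data.frame(name = NA_character_, trait = trait, chrom = b$chrom[1],
               start = min(b$pos), end = max(b$pos),
               peak_pos = b$pos[pk], peak_log10p = b$minus_log10_p[pk],
               fae = b$fae[pk], n_snps = nrow(b),
               stringsAsFactors = FALSE)
  }))
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  for (ch in unique(loci$chrom)) {
    ii <- which(loci$chrom == ch)
    base <- paste0("q", trait, ch)
    loci$name[ii] <- if (length(ii) == 1L) base else
      paste0(base, "-", seq_along(ii))
  }
  rownames(loci) <- NULL
  class(loci) <- c("gmc_loci", "data.frame")
  loci
}

#' Group cadmium loci into physical QTL clusters
#'
#' Single-linkage chaining of same-chromosome loci: consecutive loci join a
#' cluster when the gap between them (next start minus previous end) is at
#' most `max_gap`.  Clusters are labelled `Clst<chrom><a, b, c...>` in
#' positional order; a singleton locus forms its own labelled cluster.
#'
#' @param loci data.frame of Cd loci with columns `name` (or `locus`),
#'   `chrom`, `start`, `end`.
#' @param max_gap chaining distance in bp (default 3 Mb).
#' @return list of class `gmc_clusters`: `clusters` (one row per cluster:
#'   label, chrom, start, end, n_loci, members) and `loci` (the input with
#'   a filled `cluster` column).
#' @export
cluster_cd_loci <- function(loci, max_gap = 3e6) {
  loci <- as.data.frame(loci)
  if (is.null(loci$name) && !is.null(loci$locus)) loci$name <- loci$locus
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  n <- nrow(loci)
  lab <- character(n)
  if (n > 0L) {
    grp <- integer(n)
    g <- 0L
    for (i in seq_len(n)) {
      if (i == 1L || loci$chrom[i] != loci$chrom[i - 1L] ||
          loci$start[i] - loci$end[i - 1L] > max_gap) {
        g <- g + 1L
      }
      grp[i] <- g
    }
    for (ch in unique(loci$chrom)) {
      gs <- unique(grp[loci$chrom == ch])
      suff <- c(letters, paste0(rep(letters, each = 26), letters))
      for (j in seq_along(gs)) {
        lab[grp == gs[j]] <- paste0("Clst", ch, suff[j])
      }
    }
    loci$cluster <- lab
    clusters <- do.call(rbind, lapply(split(seq_len(n), grp), function(ii) {
      data.frame(label = lab[ii[1]], chrom = loci$chrom[ii[1]],
                 start = min(loci$start[ii]), end = max(loci$end[ii]),
                 n_loci = length(ii),
                 members = paste(loci$name[ii], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(clusters) <- NULL
  } else {
    loci$cluster <- character(0)
    clusters <- data.frame(label = character(), chrom = character(),
                           start = integer(), end = integer(),
                           n_loci = integer(), members = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(loci) <- NULL
  structure(list(clusters = clusters, loci = loci), class = "gmc_clusters")
}

#' @export
print.gmc_clusters <- function(x, ...) {
  cat("QTL clusters:", nrow(x$clusters), "clusters over",
      nrow(x$loci), "loci\n")
  print.data.frame(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Direction and health classification of a locus allele
#'
#' The minor-allele effect is `increasing` when positive; it is
#' `favorable` when its sign matches the trait's health polarity
#' (positive for the nutrient traits, negative for Cd).
#'
#' @param fae favorable-allele effect(s), nonzero.
#' @param trait trait name(s), recycled.
#' @param polarity polarity map (default [trait_polarity()]).
#' @return data.frame with columns `direction` and `health`.
#' @export
annotate_direction <- function(fae, trait, polarity = trait_polarity()) {
  if (any(fae == 0, na.rm = TRUE)) {
    stop("direction undefined for a zero allele effect")
  }
  trait <- rep_len(trait, length(fae))
  pol <- polarity[trait]
  direction <- ifelse(fae > 0, "increasing", "decreasing")
  health <- ifelse((fae > 0) == (pol == "+"), "favorable", "unfavorable")
  data.frame(direction = direction, health = health,
             stringsAsFactors = FALSE)
}

#' Summary accounting of a QTL table
#'
#' Computes the headline statistics of a locus table: total loci and loci
#' per trait; QTL regions (non-Cd loci plus distinct Cd cluster labels);
#' mean and range of the peak -log10 P overall and per trait; counts of
#' loci whose minor allele increases/decreases the trait, overall and for
#' Cd; health-favorable allele counts under [trait_polarity()]; Cd cluster
#' size distribution; and linkage/literature support counts.  Loci with an
#' exactly zero effect are counted in neither direction and reported in
#' `n_fae_zero`.
#'
#' @param tab a `gmc_qtl_table` (see [read_qtl_table()]) or any data.frame
#'   with columns `trait`, `cluster`, `log10p`, `fae`, `linkage_support`,
#'   `literature_support`.
#' @return list of class `gmc_qtl_summary`.
#' @export
summarize_qtl_table <- function(tab) {
  tab <- as.data.frame(tab)
  n <- nrow(tab)
  is_cd <- tab$trait == "Cd"
  cd_labels <- tab$cluster[is_cd]
  n_unclustered_cd <- sum(is.na(cd_labels))
  n_clusters <- length(unique(cd_labels[!is.na(cd_labels)]))
  n_regions <- sum(!is_cd) + n_clusters + n_unclustered_cd
  per_trait <- function(f) {
    vapply(GMC_TRAITS, function(tr) {
      v <- tab$log10p[tab$trait == tr]
      if (!length(v)) return(NA_real_)
      f(v)
    }, numeric(1))
  }
  pos <- !is.na(tab$fae) & tab$fae > 0
  neg <- !is.na(tab$fae) & tab$fae < 0
  zero <- !is.na(tab$fae) & tab$fae == 0
  pol <- trait_polarity()[tab$trait]
  favorable <- (pos & pol == "+") | (neg & pol == "-")
  sizes <- if (n_clusters > 0) {
    as.integer(table(cd_labels[!is.na(cd_labels)]))
  } else integer(0)
  has_link <- !is.na(tab$linkage_support) & tab$linkage_support != ""
  has_lit <- !is.na(tab$literature_support) & tab$literature_support != ""
  out <- list(
    n_loci = n,
    loci_per_trait = vapply(GMC_TRAITS, function(tr) sum(tab$trait == tr),
                            integer(1)),
    n_cd_loci = sum(is_cd),
    n_clusters = n_clusters,
    n_regions = n_regions,
    mean_log10p = mean(tab$log10p),
    range_log10p = if (n) range(tab$log10p) else c(NA_real_, NA_real_),
    mean_log10p_trait = per_trait(mean),
    min_log10p_trait = per_trait(min),
    max_log10p_trait = per_trait(max),
    n_increasing = sum(pos),
    n_decreasing = sum(neg),
    n_fae_zero = sum(zero),
    n_increasing_cd = sum(pos & is_cd),
    n_decreasing_cd = sum(neg & is_cd),
    n_favorable = sum(favorable),
    cluster_sizes = sizes,
    max_cluster_size = if (length(sizes)) max(sizes) else 0L,
    n_singleton_clusters = sum(sizes == 1L),
    n_multi_clusters = sum(sizes > 1L),
    n_linkage_supported = sum(has_link),
    n_literature_supported = sum(has_lit),
    n_multi_supported = sum(has_link & has_lit),
    pct_linkage_supported = if (n) 100 * sum(has_link) / n else NA_real_,
    pct_literature_supported = if (n) 100 * sum(has_lit) / n else NA_real_
  )
  class(out) <- "gmc_qtl_summary"
  out
}

#' @export
print.gmc_qtl_summary <- function(x, ...) {
  cat("QTL table summary\n")
  cat(sprintf("  loci: %d (%s)\n", x$n_loci,
              paste(names(x$loci_per_trait), x$loci_per_trait,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  regions: %d (%d non-Cd loci + %d Cd clusters)\n",
              x$n_regions, x$n_loci - x$n_cd_loci, x$n_clusters))
  cat(sprintf("  -log10 P: mean %.1f (range %.1f-%.1f)\n",
              x$mean_log10p, x$range_log10p[1], x$range_log10p[2]))
  cat(sprintf("  allele direction: %d increasing (%d Cd), %d decreasing (%d Cd)\n",
              x$n_increasing, x$n_increasing_cd, x$n_decreasing,
              x$n_decreasing_cd))
  cat(sprintf("  health-favorable alleles: %d (%.1f%%)\n", x$n_favorable,
              100 * x$n_favorable / max(x$n_loci, 1)))
  cat(sprintf("  Cd clusters: %d (max size %d, %d singleton, %d multi-locus)\n",
              x$n_clusters, x$max_cluster_size, x$n_singleton_clusters,
              x$n_multi_clusters))
  cat(sprintf("  support: %d linkage (%.1f%%), %d literature (%.1f%%), %d both\n",
              x$n_linkage_supported, x$pct_linkage_supported,
              x$n_literature_supported, x$pct_literature_supported,
              x$n_multi_supported))
  invisible(x)
}

#' Convert called loci to the published table layout
#'
#' @param loci annotated `gmc_loci` (with optional `cluster`,
#'   `linkage_support`, `literature_support` columns).
#' @return data.frame with the `gmc_qtl_table` columns, suitable for
#'   [summarize_qtl_table()] and [write_qtl_table()].
#' @export
loci_as_qtl_table <- function(loci) {
  loci <- as.data.frame(loci)
  out <- data.frame(
    trait = loci$trait,
    cluster = if (is.null(loci$cluster)) NA_character_ else loci$cluster,
    locus = loci$name, chrom = loci$chrom,
    start = loci$start, end = loci$end,
    log10p = loci$peak_log10p, fae = loci$fae,
    linkage_support = if (is.null(loci$linkage_support)) NA_character_
    else loci$linkage_support,
    literature_support = if (is.null(loci$literature_support)) NA_character_
    else loci$literature_support,
    stringsAsFactors = FALSE)
  class(out) <- c("gmc_qtl_table", "data.frame")
  out
}

#' Write a QTL table as TSV (published-table layout)
#' @param tab `gmc_qtl_table` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(tab, path) {
  tab <- as.data.frame(tab)
  out <- data.frame(trait = tab$trait, clst = tab$cluster,
                    locus = tab$locus, chrom = tab$chrom,
                    range = paste0(tab$start, "~", tab$end),
                    log10p = tab$log10p, fae = tab$fae,
                    linkage_support = tab$linkage_support,
                    literature_support = tab$literature_support,
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}
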