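#' Annotate loci with linkage and literature support
#'
#' A locus is supported by an interval when their 1-based inclusive ranges
#' share at least one bp on the same chromosome and (by default) the same
#' trait.  Names of matching linkage intervals fill `linkage_support`,
#' literature intervals fill `literature_support` (semicolon-separated when
#' several match).
#'
#' @param loci data.frame with columns `trait`, `chrom`, `start`, `end`
#'   (a `gmc_loci` or `gmc_qtl_table`).
#' @param support support intervals (see [read_support_intervals()]).
#' @param match_trait require equal trait for a match (intervals with
#'   missing trait match any).
#' @return `loci` with `linkage_support` and `literature_support` filled.
#' @export
overlap_support <- function(loci, support, match_trait = TRUE) {
  loci <- as.data.frame(loci)
  n <- nrow(loci)
  lnk <- lit <- rep(NA_character_, n)
  if (!is.null(support) && nrow(support) > 0L && n > 0L) {
    for (i in seq_len(n)) {
      hit <- support$chrom == loci$chrom[i] &
        support$start <= loci$end[i] & support$end >= loci$start[i]
      if (match_trait) {
        hit <- hit & (is.na(support$trait) | support$trait == loci$trait[i])
      }
      ln <- support$name[hit & support$source == "linkage"]
      li <- support$name[hit & support$source == "literature"]
      if (length(ln)) lnk[i] <- paste(ln, collapse = ";")
      if (length(li)) lit[i] <- paste(li, collapse = ";")
    }
  }
  loci$linkage_support <- lnk
  loci$literature_support <- lit
  loci
}

#' Count joint-evidence support over annotated loci
#'
#' @param loci output of [overlap_support()] (or any table with
#'   `linkage_support` / `literature_support` columns).
#' @return named integer vector: `n_linkage`, `n_literature`, `n_multi`
#'   (loci with both kinds of evidence).
#' @export
count_joint_support <- function(loci) {
  loci <- as.data.frame(loci)
  has_link <- !is.na(loci$linkage_support) & loci$linkage_support != ""
  has_lit <- !is.na(loci$literature_support) & loci$literature_support != ""
  c(n_linkage = sum(has_link), n_literature = sum(has_lit),
    n_multi = sum(has_link & has_lit))
}
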