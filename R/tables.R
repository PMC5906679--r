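GMC_TRAITS <- c("Fe", "Zn", "Cd", "Mn", "Cu", "Se")

# strip thousands separators/whitespace and normalize the typographic
# minus sign (U+2212) before numeric conversion
.num <- function(x) {
  x <- gsub("−", "-", x)
  suppressWarnings(as.numeric(gsub("[ ,]", "", x)))
}

#' Read a phenotype table
#'
#' Tab-delimited file with header columns `accession`, `subset` and the six
#' grain mineral concentration traits (`Fe`, `Zn`, `Cd`, `Mn`, `Cu`, `Se`,
#' in ppm).  `"."` and empty cells are treated as missing.
#'
#' @param path TSV file.
#' @return data.frame of class `gmc_pheno`.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ".", ""))
  need <- c("accession", "subset", GMC_TRAITS)
  if (!all(need %in% names(d))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[, need]
  for (tr in GMC_TRAITS) {
    d[[tr]] <- as.numeric(d[[tr]])
    if (any(d[[tr]] < 0, na.rm = TRUE)) {
      stop("negative ", tr, " concentration in ", path)
    }
  }
  class(d) <- c("gmc_pheno", "data.frame")
  d
}

#' Write a phenotype table
#' @param x phenotype data.frame (columns accession, subset, six traits).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  out <- as.data.frame(x)[, c("accession", "subset", GMC_TRAITS)]
  .write_tsv(out, path)
}

.write_tsv <- function(d, path) {
  d2 <- d
  for (j in seq_along(d2)) {
    v <- d2[[j]]
    if (is.numeric(v)) v <- formatC(v, format = "g", digits = 15)
    v[is.na(d[[j]])] <- "."
    d2[[j]] <- v
  }
  utils::write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene models
#'
#' Tab-delimited table of annotated genes with columns `gene_id`, `chrom`,
#' `start`, `end` (1-based inclusive), `strand` and optional `annotation`.
#'
#' @param path TSV file.
#' @return data.frame with one row per gene.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ".", ""))
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(d))) {
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$gene_id)) stop("gene_id must be unique")
  d$start <- as.integer(.num(d$start)); d$end <- as.integer(.num(d$end))
  if (any(d$start > d$end)) stop("gene start > end")
  if (is.null(d$strand)) d$strand <- "+"
  if (is.null(d$annotation)) d$annotation <- NA_character_
  d$chrom <- as.character(d$chrom)
  d[, c("gene_id", "chrom", "start", "end", "strand", "annotation")]
}

#' Write gene models
#' @param x gene model data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) .write_tsv(x, path)

#' Read QTL support intervals
#'
#' Intervals from linkage mapping or the literature used as supporting
#' evidence in dual-threshold locus calling and comparative annotation.
#' Columns: `name`, `trait`, `chrom`, `start`, `end`, `source` (`"linkage"`
#' or `"literature"`).  Duplicate names are allowed (names are labels, not
#' keys).
#'
#' @param path TSV file.
#' @return data.frame of intervals; zero rows for an empty file.
#' @export
read_support_intervals <- function(path) {
  empty <- data.frame(name = character(), trait = character(),
                      chrom = character(), start = integer(),
                      end = integer(), source = character(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("support interval file not found: ", path)
  if (file.size(path) == 0L) return(empty)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ".", ""))
  if (nrow(d) == 0L) return(empty)
  need <- c("name", "chrom", "start", "end", "source")
  if (!all(need %in% names(d))) {
    stop("support table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(d$trait)) d$trait <- NA_character_
  d$start <- as.integer(.num(d$start)); d$end <- as.integer(.num(d$end))
  bad <- which(d$start > d$end)
  if (length(bad)) {
    stop("support interval start > end in row ", bad[1], " (", d$name[bad[1]], ")")
  }
  d$chrom <- as.character(d$chrom)
  d[, c("name", "trait", "chrom", "start", "end", "source")]
}

#' Write support intervals
#' @param x support interval data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_support_intervals <- function(x, path) .write_tsv(x, path)

#' Read a QTL locus table
#'
#' Parses a published-table-style TSV of GWAS QTL with columns `trait`,
#' `clst` (cluster label, printed only on the first locus of each cluster),
#' `locus`, `chrom`, `range` (`start~end`, thousands separators allowed),
#' `log10p` (peak -log10 P), `fae` (favorable allele effect of the peak
#' marker), `linkage_support` and `literature_support` (semicolon-separated
#' codes).  Cluster labels are forward-filled within each contiguous
#' cadmium block, matching the printed layout where a label appears once
#' per cluster.
#'
#' @param path TSV file; an empty file yields a zero-row table.
#' @return data.frame of class `gmc_qtl_table` with numeric `start`, `end`,
#'   `log10p`, `fae` and filled `cluster` labels.
#' @export
read_qtl_table <- function(path) {
  cols <- c("trait", "cluster", "locus", "chrom", "start", "end",
            "log10p", "fae", "linkage_support", "literature_support")
  empty <- as.data.frame(stats::setNames(
    list(character(), character(), character(), character(), integer(),
         integer(), numeric(), numeric(), character(), character()), cols),
    stringsAsFactors = FALSE)
  class(empty) <- c("gmc_qtl_table", "data.frame")
  if (!file.exists(path)) stop("QTL table not found: ", path)
  if (file.size(path) == 0L) return(empty)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), colClasses = "character")
  if (nrow(d) == 0L) return(empty)
  need <- c("trait", "clst", "locus", "chrom", "range", "log10p", "fae")
  if (!all(need %in% names(d))) {
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  }
  rng <- strsplit(d$range, "~", fixed = TRUE)
  bad <- which(lengths(rng) != 2L)
  if (length(bad)) stop("malformed range in row ", bad[1], " (", d$locus[bad[1]], ")")
  start <- .num(vapply(rng, `[`, character(1), 1L))
  end <- .num(vapply(rng, `[`, character(1), 2L))
  log10p <- .num(d$log10p)
  fae <- .num(d$fae)
  chk <- list(start = start, end = end, log10p = log10p, fae = fae)
  for (nm in names(chk)) {
    bad <- which(is.na(chk[[nm]]))
    if (length(bad)) {
      stop("non-numeric ", nm, " in row ", bad[1], " (", d$locus[bad[1]], ")")
    }
  }
  if (any(start > end)) stop("range start > end in QTL table")
  # forward-fill cluster labels within contiguous Cd blocks
  cluster <- d$clst
  cluster[!is.na(cluster) & cluster == "."] <- NA_character_
  for (i in seq_along(cluster)) {
    if (d$trait[i] == "Cd" && is.na(cluster[i]) && i > 1L &&
        d$trait[i - 1L] == "Cd") {
      cluster[i] <- cluster[i - 1L]
    }
  }
  dotna <- function(v) {
    if (is.null(v)) return(NA_character_)
    v[!is.na(v) & v == "."] <- NA_character_
    v
  }
  lit <- dotna(d$literature_support)
  lnk <- dotna(d$linkage_support)
  out <- data.frame(trait = d$trait, cluster = cluster, locus = d$locus,
                    chrom = d$chrom, start = as.integer(start),
                    end = as.integer(end), log10p = log10p, fae = fae,
                    linkage_support = lnk, literature_support = lit,
                    stringsAsFactors = FALSE)
  class(out) <- c("gmc_qtl_table", "data.frame")
  out
}

#' The packaged GWAS QTL reference table
#'
#' Returns the 80-locus QTL table for the six grain mineral concentration
#' traits (18 single-trait loci plus 62 cadmium loci in 29 clusters) that
#' ships with the package, parsed via [read_qtl_table()].
#'
#' @return A `gmc_qtl_table` data.frame with 80 rows.
#' @export
gmc_table1 <- function() {
  read_qtl_table(system.file("extdata", "gmc_qtl_table.tsv",
                             package = "gmcqtl", mustWork = TRUE))
}

#' The packaged synthetic support-interval table
#'
#' Linkage and literature support intervals reconstructed from the support
#' columns of the packaged QTL table.  The original linkage-mapping interval
#' coordinates are not published, so these are synthetic stand-ins spanning
#' the supported loci; they reproduce the printed support pattern exactly.
#'
#' @return Support-interval data.frame (see [read_support_intervals()]).
#' @export
gmc_support_intervals <- function() {
  read_support_intervals(system.file(
    "extdata", "support_intervals_synthetic.tsv",
    package = "gmcqtl", mustWork = TRUE))
}
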