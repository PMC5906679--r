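#' Build candidate-gene haplotypes for a panel subset
#'
#' Forms, for every accession of the chosen subset, the string of alleles
#' at all polymorphic SNPs inside the gene span (1-based inclusive).
#' Accessions with any missing call over the span are excluded with reason
#' `missing`; heterozygous accessions with reason `heterozygous`
#' (rice germplasm panels are inbred and near-homozygous, so exclusion is
#' conservative); haplotypes carried by fewer than `min_count` accessions
#' are excluded with reason `rare`.  Retained haplotypes are named
#' `Hap1..HapN` by descending carrier count (ties by first occurrence).
#'
#' @param geno a [gmc_geno()] panel.
#' @param gene one-row data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param subset `"X"`, `"G"` or `NULL` for the whole panel.
#' @param min_count minimum carrier count for a retained haplotype
#'   (default 5).
#' @return object of class `gmc_haps`: `gene_id`, `subset`, `snp_pos`,
#'   `snp_id`, `haplotypes` (name, string, n), `assignment` (named
#'   accession -> haplotype name, `NA` when excluded), `excluded` (named
#'   reason vector), `flag` (`"no_polymorphic_snp"` when the span is
#'   monomorphic).
#' @export
build_haplotypes <- function(geno, gene, subset = NULL, min_count = 5) {
  stopifnot(inherits(geno, "gmc_geno"))
  rows <- if (is.null(subset)) seq_along(geno$accession_ids) else
    which(geno$subset == subset)
  if (!length(rows)) stop("no accessions in subset ", subset)
  acc <- geno$accession_ids[rows]
  span <- which(geno$snps$chrom == as.character(gene$chrom) &
                  geno$snps$pos >= gene$start & geno$snps$pos <= gene$end)
  base <- list(gene_id = gene$gene_id, subset = subset %||% "all",
               snp_pos = integer(0), snp_id = character(0),
               haplotypes = data.frame(name = character(),
                                       string = character(), n = integer(),
                                       stringsAsFactors = FALSE),
               assignment = stats::setNames(rep(NA_character_, length(acc)),
                                            acc),
               excluded = stats::setNames(character(0), character(0)),
               flag = NA_character_)
  d <- geno$dosage[rows, span, drop = FALSE]
  poly <- which(apply(d, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1L
  }))
  if (!length(poly)) {
    base$flag <- "no_polymorphic_snp"
    class(base) <- "gmc_haps"
    return(base)
  }
  span <- span[poly]
  d <- d[, poly, drop = FALSE]
  excl <- stats::setNames(rep(NA_character_, length(acc)), acc)
  excl[rowSums(is.na(d)) > 0L] <- "missing"
  excl[is.na(excl) & rowSums(d == 1, na.rm = TRUE) > 0L] <- "heterozygous"
  usable <- which(is.na(excl))
  assignment <- stats::setNames(rep(NA_character_, length(acc)), acc)
  haplo <- base$haplotypes
  if (length(usable)) {
    ref <- geno$snps$ref[span]; alt <- geno$snps$alt[span]
    strs <- vapply(usable, function(i) {
      paste(ifelse(d[i, ] == 0, ref, alt), collapse = "")
    }, character(1))
    counts <- table(strs)
    first <- tapply(seq_along(strs), strs, min)
    ord <- order(-as.integer(counts[names(counts)]),
                 as.integer(first[names(counts)]))
    ranked <- names(counts)[ord]
    keep <- ranked[as.integer(counts[ranked]) >= min_count]
    rare <- !(strs %in% keep)
    excl[usable[rare]] <- "rare"
    if (length(keep)) {
      nm <- stats::setNames(paste0("Hap", seq_along(keep)), keep)
      assignment[usable[!rare]] <- unname(nm[strs[!rare]])
      haplo <- data.frame(name = unname(nm), string = keep,
                          n = as.integer(counts[keep]),
                          stringsAsFactors = FALSE)
    }
  }
  out <- list(gene_id = gene$gene_id, subset = subset %||% "all",
              snp_pos = geno$snps$pos[span], snp_id = geno$snps$id[span],
              haplotypes = haplo, assignment = assignment,
              excluded = excl[!is.na(excl)], flag = NA_character_)
  class(out) <- "gmc_haps"
  out
}

#' @export
print.gmc_haps <- function(x, ...) {
  cat(sprintf("Haplotypes of %s (%s-set): %d SNPs, %d haplotypes\n",
              x$gene_id, x$subset, length(x$snp_pos), nrow(x$haplotypes)))
  if (nrow(x$haplotypes)) print.data.frame(x$haplotypes, row.names = FALSE)
  if (length(x$excluded)) {
    cat("  excluded:", paste(names(table(x$excluded)), table(x$excluded),
                             sep = "=", collapse = ", "), "\n")
  }
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Classify haplotypes as favorable, conditional, unfavorable or neutral
#'
#' Codifies the breeding-oriented reading of the haplotype screen for the
#' three major traits.  At the 0.05 level, for each haplotype: a *gain* is
#' being significantly higher than at least one other haplotype in Fe or
#' Zn; a *nutrient loss* is being significantly lower than another
#' haplotype in Fe or Zn; a *Cd increase* is being significantly higher in
#' Cd.  Then: favorable = gain without nutrient loss or Cd increase;
#' conditional = gain accompanied by a nutrient loss or a Cd increase
#' (trade-off); unfavorable = nutrient loss or Cd increase without any
#' gain; neutral otherwise.
#'
#' @param fe,zn,cd [star_level()] results for Fe, Zn and Cd sharing one
#'   haplotype assignment.
#' @return data.frame of class `gmc_favorable`: haplotype, verdict and the
#'   per-trait gain/loss indicators; `NULL` (with a message) when a trait
#'   result is missing.
#' @export
classify_favorable <- function(fe, zn, cd) {
  res <- list(Fe = fe, Zn = zn, Cd = cd)
  missing <- vapply(res, function(r) {
    is.null(r) || is.null(r$duncan)
  }, logical(1))
  if (any(missing)) {
    message("classification skipped: missing result for ",
            paste(names(res)[missing], collapse = ", "))
    return(NULL)
  }
  haps <- res$Fe$duncan$table$group
  sig_dir <- function(r, h, higher = TRUE) {
    tab <- r$duncan$table
    others <- setdiff(tab$group, h)
    any(vapply(others, function(o) {
      sep <- duncan_separated(r$duncan, h, o)
      mh <- tab$mean[tab$group == h]; mo <- tab$mean[tab$group == o]
      sep && if (higher) mh > mo else mh < mo
    }, logical(1)))
  }
  out <- do.call(rbind, lapply(haps, function(h) {
    gain_fe <- sig_dir(res$Fe, h, TRUE)
    gain_zn <- sig_dir(res$Zn, h, TRUE)
    loss_fe <- sig_dir(res$Fe, h, FALSE)
    loss_zn <- sig_dir(res$Zn, h, FALSE)
    cd_up <- sig_dir(res$Cd, h, TRUE)
    cd_down <- sig_dir(res$Cd, h, FALSE)
    gain <- gain_fe || gain_zn
    harm <- loss_fe || loss_zn || cd_up
    verdict <- if (gain && !harm) "favorable"
    else if (gain && harm) "conditional"
    else if (!gain && harm) "unfavorable"
    else "neutral"
    data.frame(haplotype = h, verdict = verdict,
               gain_fe = gain_fe, gain_zn = gain_zn,
               loss_fe = loss_fe, loss_zn = loss_zn,
               cd_up = cd_up, cd_down = cd_down,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(as.integer(sub("^Hap", "", out$haplotype))), ]
  rownames(out) <- NULL
  class(out) <- c("gmc_favorable", "data.frame")
  out
}

#' Screen candidate genes by haplotype-trait association
#'
#' For every gene and subset, builds haplotypes over the gene span and runs
#' the Duncan star-level screen for each requested trait, yielding a wide
#' report (one row per gene, star columns per subset x trait) mirroring a
#' published candidate-gene screen, plus the per-cell results.
#'
#' @param geno a [gmc_geno()] panel.
#' @param pheno phenotype data.frame.
#' @param genes gene model data.frame (see [read_gene_models()]).
#' @param subsets subset labels to screen (default X and G).
#' @param traits traits to test (default Fe, Zn, Cd).
#' @param min_count minimum haplotype carrier count.
#' @return list of class `gmc_screen`: `report` (wide data.frame) and
#'   `cells` (named list of `gmc_duncan_star`).
#' @export
screen_genes <- function(geno, pheno, genes, subsets = c("X", "G"),
                         traits = c("Fe", "Zn", "Cd"), min_count = 5) {
  genes <- as.data.frame(genes)
  cells <- list()
  rows <- lapply(seq_len(nrow(genes)), function(gi) {
    gene <- genes[gi, , drop = FALSE]
    row <- list(gene_id = gene$gene_id,
                region = sprintf("Chr%s:%d-%d", gene$chrom, gene$start,
                                 gene$end))
    for (ss in subsets) {
      haps <- build_haplotypes(geno, gene, ss, min_count = min_count)
      for (tr in traits) {
        st <- star_level(haps, pheno, tr)
        cells[[paste(gene$gene_id, ss, tr, sep = ".")]] <<- st
        row[[paste0(ss, "_", tr)]] <- st$star
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(report = report, cells = cells), class = "gmc_screen")
}

#' @export
print.gmc_screen <- function(x, ...) {
  star_cols <- setdiff(names(x$report), c("gene_id", "region"))
  n_sig <- sum(apply(x$report[, star_cols, drop = FALSE], 1,
                     function(r) any(r != "ns")))
  cat(sprintf("Candidate-gene screen: %d genes, %d with at least one starred cell\n",
              nrow(x$report), n_sig))
  print.data.frame(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a gene screen report as TSV
#' @param screen `gmc_screen` result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) .write_tsv(screen$report, path)

#' Write a haplotype assignment as TSV
#' @param haps `gmc_haps` result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  acc <- names(haps$assignment)
  status <- haps$assignment
  status[is.na(status)] <- paste0("EXCLUDED:",
                                  haps$excluded[acc[is.na(status)]])
  .write_tsv(data.frame(accession = acc, gene = haps$gene_id,
                        subset = haps$subset, haplotype = unname(status),
                        stringsAsFactors = FALSE), path)
}
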