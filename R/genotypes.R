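#' Biallelic SNP dosage matrix for a germplasm panel
#'
#' `gmc_geno()` builds the canonical genotype container used throughout the
#' package: a dosage matrix (accessions in rows, SNPs in columns) counting
#' copies of the ALT allele (0, 1, 2 or `NA` for missing), a per-accession
#' subset label (`"X"` for indica/Xian, `"G"` for japonica/Geng, `"UNKNOWN"`
#' when unlabelled) and a SNP map with 1-based physical coordinates.
#'
#' Positions must be strictly increasing within each chromosome and all sites
#' must be biallelic SNPs; the constructor validates both.
#'
#' @param dosage numeric matrix, accessions x SNPs, entries in
#'   `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @param accession_ids character vector of unique accession names.
#' @param subset per-accession labels in `{"X", "G", "UNKNOWN"}`; recycled if
#'   length 1.
#' @return An object of class `gmc_geno`.
#' @export
gmc_geno <- function(dosage, snps, accession_ids, subset = "UNKNOWN") {
  dosage <- as.matrix(dosage)
  accession_ids <- as.character(accession_ids)
  if (length(subset) == 1L) subset <- rep(subset, length(accession_ids))
  subset <- as.character(subset)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns: ", paste(need, collapse = ", "))
  }
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(accession_ids)) stop("accession_ids must be unique")
  if (nrow(dosage) != length(accession_ids)) {
    stop("dosage rows (", nrow(dosage), ") != accessions (",
         length(accession_ids), ")")
  }
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage columns (", ncol(dosage), ") != SNPs (", nrow(snps), ")")
  }
  if (length(subset) != length(accession_ids)) {
    stop("subset labels must match accessions")
  }
  bad <- !(subset %in% c("X", "G", "UNKNOWN"))
  if (any(bad)) stop("subset labels must be in {X, G, UNKNOWN}")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  ok_base <- function(x) all(nchar(x) == 1L & x %in% c("A", "C", "G", "T"))
  if (!ok_base(snps$ref) || !ok_base(snps$alt)) {
    stop("only biallelic SNPs (single-base ref/alt) are allowed")
  }
  rownames(dosage) <- accession_ids
  colnames(dosage) <- snps$id
  structure(
    list(accession_ids = accession_ids, subset = subset,
         snps = snps, dosage = dosage),
    class = "gmc_geno"
  )
}

#' @export
print.gmc_geno <- function(x, ...) {
  cat("Genotype panel:", length(x$accession_ids), "accessions x",
      nrow(x$snps), "SNPs\n")
  tab <- table(factor(x$subset, levels = c("X", "G", "UNKNOWN")))
  cat("  subsets: X =", tab[["X"]], " G =", tab[["G"]],
      " UNKNOWN =", tab[["UNKNOWN"]], "\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.gmc_geno <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param x a [gmc_geno()] object.
#' @param accessions accession ids or logical/integer index to keep.
#' @param snp_idx SNP column index (logical or integer) to keep.
#' @return A `gmc_geno` restricted to the selection.
#' @export
subset_geno <- function(x, accessions = NULL, snp_idx = NULL) {
  stopifnot(inherits(x, "gmc_geno"))
  ai <- seq_along(x$accession_ids)
  if (!is.null(accessions)) {
    ai <- if (is.character(accessions)) {
      match(accessions, x$accession_ids)
    } else {
      ai[accessions]
    }
    if (anyNA(ai)) stop("unknown accession id")
  }
  si <- seq_len(nrow(x$snps))
  if (!is.null(snp_idx)) si <- si[snp_idx]
  gmc_geno(x$dosage[ai, si, drop = FALSE], x$snps[si, , drop = FALSE],
           x$accession_ids[ai], x$subset[ai])
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file, keeps only biallelic SNP records, codes genotypes
#' as ALT-allele dosages (heterozygous calls as 1, missing calls as `NA`) and
#' sorts sites by (chromosome, position).  Accessions absent from
#' `subset_map` are labelled `"UNKNOWN"` with a warning.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param subset_map named character vector mapping accession id to
#'   `"X"`/`"G"`; `NULL` labels everyone `UNKNOWN` silently.
#' @return A [gmc_geno()] object.
#' @export
read_genotypes <- function(path, subset_map = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNPs in VCF: ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- v@gt[keep, -1L, drop = FALSE]
  samples <- colnames(v@gt)[-1L]
  # strip FORMAT extras, keep the GT field
  fmt <- v@gt[keep, 1L]
  gt_field <- function(cell, k) {
    if (is.na(cell)) return(NA_character_)
    strsplit(cell, ":", fixed = TRUE)[[1]][k]
  }
  kgt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                function(f) match("GT", f), integer(1))
  dos <- matrix(NA_real_, nrow = length(samples), ncol = nrow(fix))
  for (j in seq_len(nrow(fix))) {
    cells <- vapply(gt[j, ], gt_field, character(1), k = kgt[j])
    al <- strsplit(gsub("\\|", "/", cells), "/", fixed = FALSE)
    dos[, j] <- vapply(al, function(a) {
      if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  ord <- order(fix$CHROM, as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  subset <- rep("UNKNOWN", length(samples))
  if (!is.null(subset_map)) {
    hit <- match(samples, names(subset_map))
    subset <- ifelse(is.na(hit), "UNKNOWN", unname(subset_map[hit]))
    if (anyNA(hit)) {
      warning("accessions not in subset_map labelled UNKNOWN: ",
              paste(samples[is.na(hit)], collapse = ", "))
    }
  }
  gmc_geno(dos,
           data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, id = ids,
                      stringsAsFactors = FALSE),
           samples, subset)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 text file with GT-only genotype columns.  Dosage 0
#' is written `0/0`, 1 as `0/1`, 2 as `1/1`, missing as `./.`; the subset
#' label of each accession is recorded in a `##SAMPLE` header line so a
#' write/read round trip restores the full object.
#'
#' @param x a [gmc_geno()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "gmc_geno"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gmcqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##SAMPLE=<ID=", x$accession_ids, ",Subset=", x$subset, ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$accession_ids), collapse = "\t")
  ), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(x$snps))) {
    d <- x$dosage[, j]
    g <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(x$snps$chrom[j], x$snps$pos[j], x$snps$id[j],
                       x$snps$ref[j], x$snps$alt[j], ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Recover subset labels stored in a gmcqtl-written VCF
#'
#' @param path VCF written by [write_genotypes()].
#' @return Named character vector accession -> subset, or `NULL` when the
#'   file carries no `##SAMPLE` lines.
#' @export
read_vcf_subset_map <- function(path) {
  hdr <- grep("^##SAMPLE=", readLines(path, n = 10000L), value = TRUE)
  if (!length(hdr)) return(NULL)
  id <- sub('.*ID=([^,>]+).*', "\\1", hdr)
  ss <- sub('.*Subset=([^,>]+).*', "\\1", hdr)
  stats::setNames(ss, id)
}

#' Extract markers shared by two panels
#'
#' Matches SNPs by chromosome, position and (unordered) allele pair, the
#' natural join key when two panels were called against the same reference
#' genome.  Used to build the common marker set for pooled analyses of
#' separately genotyped subsets.
#'
#' @param a,b [gmc_geno()] objects.
#' @return list with `a_idx`, `b_idx`: matching SNP column indices.
#' @export
shared_markers <- function(a, b) {
  key <- function(g) {
    al <- ifelse(g$snps$ref < g$snps$alt,
                 paste0(g$snps$ref, g$snps$alt),
                 paste0(g$snps$alt, g$snps$ref))
    paste(g$snps$chrom, g$snps$pos, al, sep = ":")
  }
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  list(a_idx = match(common, ka), b_idx = match(common, kb))
}

#' Combine two genotype panels on their shared markers
#'
#' @param a,b [gmc_geno()] objects with disjoint accession ids.
#' @return A `gmc_geno` over the union of accessions and the shared SNPs,
#'   with `b`'s dosages flipped where its REF/ALT coding is swapped
#'   relative to `a`.
#' @export
merge_panels <- function(a, b) {
  sm <- shared_markers(a, b)
  if (!length(sm$a_idx)) stop("no shared markers between panels")
  sa <- subset_geno(a, snp_idx = sm$a_idx)
  sb <- subset_geno(b, snp_idx = sm$b_idx)
  flip <- sa$snps$ref != sb$snps$ref
  if (any(flip)) sb$dosage[, flip] <- 2 - sb$dosage[, flip]
  gmc_geno(rbind(sa$dosage, sb$dosage), sa$snps,
           c(sa$accession_ids, sb$accession_ids),
           c(sa$subset, sb$subset))
}
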