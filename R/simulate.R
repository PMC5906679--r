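#' Simulation configuration for a two-subset germplasm panel
#'
#' Builds the configuration consumed by [simulate_panel()].  Defaults emulate
#' the structured 698-accession panel the package targets: 265 indica/Xian
#' (X) and 433 japonica/Geng (G) accessions, Balding-Nichols allele-frequency
#' divergence between the subsets, grain mineral concentration baselines
#' whose pooled means match the observed trait distributions (Fe 2.4, Zn
#' 16.4, Cd 0.009, Mn 9.7, Cu 3.2, Se 0.04 ppm), a lower cadmium baseline in
#' the G subset (so the pooled Cd distribution is bimodal) and marked
#' between-subset overlap for Se.
#'
#' Genotypes are drawn in linkage-disequilibrium blocks: each block carries a
#' small number of founder haplotypes per subset and every (inbred,
#' homozygous) accession copies one founder per block, so gene spans harbor
#' few distinct haplotypes, as candidate-gene haplotype analysis requires.
#'
#' @param n_X,n_G accessions per subset.
#' @param n_chrom,snps_per_chrom genome dimensions.
#' @param chrom_length chromosome length in bp.
#' @param fst Balding-Nichols divergence parameter between subsets.
#' @param block_size SNPs per LD block.
#' @param n_founders founder haplotypes per block per subset.
#' @param means,sds named lists (`X`, `G`) of per-trait baseline means and
#'   residual standard deviations (ppm).
#' @param causal_genes list of `list(gene_id, chrom, start, end, trait,
#'   effects)`; `effects` are ppm increments for frequency-ranked haplotypes
#'   of the gene span.
#' @param het_rate,missing_rate per-call rates of residual heterozygosity
#'   and missingness.
#' @param seed integer seed that fully determines the output.
#' @return list of class `gmc_sim_config`.
#' @export
sim_config <- function(n_X = 265, n_G = 433,
                       n_chrom = 12, snps_per_chrom = 400,
                       chrom_length = 30e6,
                       fst = 0.1, block_size = 10, n_founders = 4,
                       means = NULL, sds = NULL,
                       causal_genes = list(),
                       het_rate = 0, missing_rate = 0,
                       seed = 1) {
  if (is.null(means)) {
    means <- list(
      X = c(Fe = 2.4, Zn = 15.0, Cd = 0.014, Mn = 9.7, Cu = 2.9, Se = 0.04),
      G = c(Fe = 2.4, Zn = 17.3, Cd = 0.005, Mn = 9.7, Cu = 3.4, Se = 0.04))
  }
  if (is.null(sds)) {
    sds <- list(
      X = c(Fe = 0.8, Zn = 3.0, Cd = 0.005, Mn = 2.2, Cu = 0.8, Se = 0.012),
      G = c(Fe = 0.8, Zn = 3.0, Cd = 0.0015, Mn = 2.2, Cu = 0.8, Se = 0.012))
  }
  stopifnot(n_X > 0, n_G > 0, n_chrom > 0, snps_per_chrom > 1,
            fst >= 0, fst < 1, block_size >= 1, n_founders >= 2,
            het_rate >= 0, missing_rate >= 0)
  for (s in c("X", "G")) {
    if (!all(GMC_TRAITS %in% names(means[[s]])) ||
        !all(GMC_TRAITS %in% names(sds[[s]]))) {
      stop("means/sds must cover the six traits for subset ", s)
    }
  }
  for (cg in causal_genes) {
    need <- c("gene_id", "chrom", "start", "end", "trait", "effects")
    if (!all(need %in% names(cg))) {
      stop("causal gene entries need fields: ", paste(need, collapse = ", "))
    }
    if (!all(is.finite(cg$effects))) stop("causal effects must be finite")
    if (!(cg$trait %in% GMC_TRAITS)) stop("unknown causal trait ", cg$trait)
    if (cg$chrom > n_chrom || cg$start < 1 || cg$end > chrom_length) {
      stop("causal gene ", cg$gene_id, " outside simulated coordinates")
    }
  }
  structure(list(n_X = n_X, n_G = n_G, n_chrom = n_chrom,
                 snps_per_chrom = snps_per_chrom,
                 chrom_length = chrom_length, fst = fst,
                 block_size = block_size, n_founders = n_founders,
                 means = means, sds = sds, causal_genes = causal_genes,
                 het_rate = het_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "gmc_sim_config")
}

#' Simulate a structured two-subset panel with planted causal haplotypes
#'
#' Draws ancestral allele frequencies Uniform(0.05, 0.95), derives
#' subset-specific frequencies under the Balding-Nichols model
#' (Beta(p(1-F)/F, (1-p)(1-F)/F)), generates homozygous dosages by founder-
#' haplotype copying within LD blocks, and builds phenotypes as subset
#' baseline + planted causal-haplotype increments + Gaussian noise
#' (truncated at a small positive floor, concentrations being non-negative).
#'
#' @param config a [sim_config()] object.
#' @return list with elements `geno` ([gmc_geno()]), `pheno` (phenotype
#'   data.frame) and `truth` (causal gene ids and effect vectors, subset
#'   baselines, realized heritability per trait).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "gmc_sim_config"))
  set.seed(config$seed)
  n <- config$n_X + config$n_G
  acc <- c(sprintf("X%03d", seq_len(config$n_X)),
           sprintf("G%03d", seq_len(config$n_G)))
  subset <- c(rep("X", config$n_X), rep("G", config$n_G))
  m_chr <- config$snps_per_chrom
  m <- config$n_chrom * m_chr
  snps <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ch) {
    pos <- sort(sample.int(config$chrom_length, m_chr))
    data.frame(chrom = as.character(ch), pos = pos,
               ref = "A", alt = "G",
               id = sprintf("snp%02d_%09d", ch, pos),
               stringsAsFactors = FALSE)
  }))
  p_anc <- stats::runif(m, 0.05, 0.95)
  bn_freq <- function(p, f) {
    if (f <= 0) return(p)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p_sub <- list(X = bn_freq(p_anc, config$fst),
                G = bn_freq(p_anc, config$fst))
  dos <- matrix(0, n, m, dimnames = list(acc, snps$id))
  blocks <- split(seq_len(m),
                  ceiling(seq_len(m) / config$block_size))
  for (b in blocks) {
    for (s in c("X", "G")) {
      rows <- which(subset == s)
      founders <- matrix(
        stats::rbinom(config$n_founders * length(b), 1,
                      rep(p_sub[[s]][b], each = config$n_founders)),
        nrow = config$n_founders)
      pick <- sample.int(config$n_founders, length(rows), replace = TRUE)
      dos[rows, b] <- 2 * founders[pick, , drop = FALSE]
    }
  }
  if (config$het_rate > 0) {
    flip <- which(stats::runif(length(dos)) < config$het_rate)
    dos[flip] <- 1
  }
  if (config$missing_rate > 0) {
    drop <- which(stats::runif(length(dos)) < config$missing_rate)
    dos[drop] <- NA
  }
  geno <- gmc_geno(dos, snps, acc, subset)

  pheno <- data.frame(accession = acc, subset = subset,
                      stringsAsFactors = FALSE)
  genetic <- matrix(0, n, length(GMC_TRAITS),
                    dimnames = list(acc, GMC_TRAITS))
  truth_genes <- list()
  for (cg in config$causal_genes) {
    gene <- data.frame(gene_id = cg$gene_id, chrom = as.character(cg$chrom),
                       start = cg$start, end = cg$end,
                       stringsAsFactors = FALSE)
    ph <- plant_haplotype_effect(geno, gene, cg$effects)
    genetic[, cg$trait] <- genetic[, cg$trait] + ph$increment
    truth_genes[[cg$gene_id]] <- list(gene_id = cg$gene_id, trait = cg$trait,
                                      chrom = as.character(cg$chrom),
                                      start = cg$start, end = cg$end,
                                      effects = cg$effects,
                                      haplotype = ph$haplotype)
  }
  h2 <- stats::setNames(numeric(length(GMC_TRAITS)), GMC_TRAITS)
  for (tr in GMC_TRAITS) {
    mu <- ifelse(subset == "X", config$means$X[[tr]], config$means$G[[tr]])
    sd <- ifelse(subset == "X", config$sds$X[[tr]], config$sds$G[[tr]])
    e <- stats::rnorm(n, 0, sd)
    y <- pmax(mu + genetic[, tr] + e, 1e-4)
    pheno[[tr]] <- y
    vg <- stats::var(genetic[, tr])
    h2[tr] <- if (vg > 0) vg / stats::var(y) else 0
  }
  class(pheno) <- c("gmc_pheno", "data.frame")
  truth <- list(causal_genes = truth_genes,
                subset_means = config$means,
                heritability = h2, seed = config$seed)
  list(geno = geno, pheno = pheno, truth = truth)
}

#' Plant a per-haplotype effect over a gene span
#'
#' Partitions accessions by their exact SNP string across the gene span and
#' assigns the supplied ppm increments to frequency-ranked haplotypes
#' (`effects[1]` to the most common haplotype, and so on; haplotypes beyond
#' the vector receive 0).
#'
#' @param geno a [gmc_geno()] panel.
#' @param gene one-row data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param effects numeric vector of per-haplotype increments (ppm).
#' @return list with `increment` (per-accession numeric vector),
#'   `haplotype` (per-accession partition index, frequency-ranked) and
#'   `n_haplotypes`.
#' @export
plant_haplotype_effect <- function(geno, gene, effects) {
  stopifnot(inherits(geno, "gmc_geno"))
  idx <- which(geno$snps$chrom == as.character(gene$chrom) &
                 geno$snps$pos >= gene$start & geno$snps$pos <= gene$end)
  if (!length(idx)) {
    stop("gene span of ", gene$gene_id, " contains no simulated SNP")
  }
  d <- geno$dosage[, idx, drop = FALSE]
  str <- apply(d, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  counts <- table(str)
  first <- tapply(seq_along(str), str, min)
  ord <- order(-as.integer(counts[names(counts)]),
               as.integer(first[names(counts)]))
  ranked <- names(counts)[ord]
  if (length(effects) > length(ranked)) {
    stop("more effect entries (", length(effects), ") than realized haplotypes (",
         length(ranked), ") for ", gene$gene_id)
  }
  eff <- stats::setNames(rep(0, length(ranked)), ranked)
  eff[ranked[seq_along(effects)]] <- effects
  list(increment = unname(eff[str]),
       haplotype = match(str, ranked),
       n_haplotypes = length(ranked))
}
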