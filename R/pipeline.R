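#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' tunable threshold surfaced: the stringent/loose -log10 P calling
#' thresholds (6.0 and 3.0), SNP-to-locus merge gap (300 kb), Cd cluster
#' gap (3 Mb), minimum haplotype carrier count (5), the four Duncan
#' reporting levels, MAF threshold (0.01) and PC selection cap.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_X = 150, n_G = 150, n_chrom = 5,
                    snps_per_chrom = 1000, fst = 0.1, causal = "demo"),
    inputs = list(vcf = NULL, phenotypes = NULL, genes = NULL,
                  support = NULL, qtl_table = NULL),
    gwas = list(traits = c("Fe", "Zn", "Cd", "Mn", "Cu", "Se"),
                pcs = "auto", pc_max = 3, p3d = TRUE, maf_min = 0.01),
    loci = list(strict = 6, loose = 3, merge_gap = 3e5),
    cluster = list(max_gap = 3e6),
    haplotypes = list(min_count = 5, traits = c("Fe", "Zn", "Cd"),
                      subsets = c("X", "G")),
    plots = list(enabled = TRUE)
  )
}

#' Read a pipeline configuration file
#'
#' YAML (key: value) file merged over [default_config()]; unknown keys are
#' kept so stage code can consume extensions.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_lists(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_lists(default_config(), user)
}

# three demo genes with planted per-haplotype effects, placed on distinct
# chromosomes well inside the simulated coordinate range
.demo_causal <- function(config) {
  len <- 30e6
  list(
    list(gene_id = "GeneFe1", chrom = 1, start = 10e6, end = 10.3e6,
         trait = "Fe", effects = c(0, 0.8)),
    list(gene_id = "GeneZn2", chrom = 2, start = 15e6, end = 15.3e6,
         trait = "Zn", effects = c(0, 2.0)),
    list(gene_id = "GeneCd3", chrom = 3, start = 20e6, end = 20.3e6,
         trait = "Cd", effects = c(0, 0.006))
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> kinship/PCA -> mixed-model GWAS per
#' trait -> dual-threshold locus calling -> Cd-locus clustering ->
#' comparative support annotation -> QTL table summary -> candidate-gene
#' haplotype screen -> figures, writing every table as TSV plus a run
#' manifest (config hash, seed, package version, stage counts).  Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config configuration list ([default_config()]), or the path of a
#'   YAML file ([read_pipeline_config()]).
#' @param out_dir output directory (created if absent).
#' @return object of class `gmc_run`: paths of all outputs plus the key
#'   in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  genes <- NULL
  support <- NULL
  # table-only mode: summarize an existing QTL table, no genotypes needed
  if (!isTRUE(config$simulate$enabled) &&
      !is.null(config$inputs$qtl_table)) {
    tab <- read_qtl_table(config$inputs$qtl_table)
    say("table mode: %d loci loaded", nrow(tab))
    if (!is.null(config$inputs$support)) {
      support <- read_support_intervals(config$inputs$support)
      ann <- overlap_support(tab, support)
      tab$linkage_support <- ann$linkage_support
      tab$literature_support <- ann$literature_support
    }
    summ <- summarize_qtl_table(tab)
    write_qtl_table(tab, file.path(out_dir, "loci.tsv"))
    .write_tsv(data.frame(
      key = c("n_loci", "n_cd_loci", "n_clusters", "n_regions",
              "mean_log10p", "n_increasing", "n_decreasing", "n_favorable",
              "n_linkage_supported", "n_literature_supported"),
      value = c(summ$n_loci, summ$n_cd_loci, summ$n_clusters,
                summ$n_regions, round(summ$mean_log10p, 4),
                summ$n_increasing, summ$n_decreasing, summ$n_favorable,
                summ$n_linkage_supported, summ$n_literature_supported),
      stringsAsFactors = FALSE), file.path(out_dir, "summary.tsv"))
    writeLines(c(paste0("package_version\t",
                        as.character(utils::packageVersion("gmcqtl"))),
                 paste0("seed\t", config$seed),
                 paste0("log\t", log)),
               file.path(out_dir, "manifest.tsv"))
    res <- list(out_dir = out_dir, config = config, loci = tab,
                clusters = NULL, summary = summ, screen = NULL,
                assoc = list(),
                support_counts = count_joint_support(tab))
    class(res) <- "gmc_run"
    return(res)
  }
  if (isTRUE(config$simulate$enabled)) {
    causal <- config$simulate$causal
    if (identical(causal, "demo")) causal <- .demo_causal(config)
    if (is.null(causal)) causal <- list()
    sc <- sim_config(n_X = config$simulate$n_X, n_G = config$simulate$n_G,
                     n_chrom = config$simulate$n_chrom,
                     snps_per_chrom = config$simulate$snps_per_chrom,
                     fst = config$simulate$fst,
                     causal_genes = causal, seed = config$seed)
    sim <- simulate_panel(sc)
    geno <- sim$geno; pheno <- sim$pheno
    say("simulate: %d accessions x %d SNPs, %d causal genes",
        nrow(geno$dosage), ncol(geno$dosage), length(causal))
    write_genotypes(geno, file.path(out_dir, "panel.vcf"))
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
    if (length(causal)) {
      genes <- do.call(rbind, lapply(causal, function(cg) {
        data.frame(gene_id = cg$gene_id, chrom = as.character(cg$chrom),
                   start = cg$start, end = cg$end, strand = "+",
                   annotation = paste0("planted:", cg$trait),
                   stringsAsFactors = FALSE)
      }))
      write_gene_models(genes, file.path(out_dir, "genes.tsv"))
      truth <- do.call(rbind, lapply(sim$truth$causal_genes, function(tg) {
        data.frame(gene_id = tg$gene_id, trait = tg$trait,
                   effects = paste(tg$effects, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      .write_tsv(truth, file.path(out_dir, "truth.tsv"))
    }
  } else {
    sm <- NULL
    if (!is.null(config$inputs$vcf) && file.exists(config$inputs$vcf)) {
      sm <- read_vcf_subset_map(config$inputs$vcf)
    }
    for (nm in c("vcf", "phenotypes")) {
      p <- config$inputs[[nm]]
      if (is.null(p) || !file.exists(p)) stop("missing input: ", nm)
    }
    geno <- read_genotypes(config$inputs$vcf, sm)
    pheno <- read_phenotypes(config$inputs$phenotypes)
    pheno <- pheno[match(geno$accession_ids, pheno$accession), ]
    names(pheno)[1] <- "accession"
    if (!is.null(config$inputs$genes)) {
      genes <- read_gene_models(config$inputs$genes)
    }
    say("load: %d accessions x %d SNPs", nrow(geno$dosage),
        ncol(geno$dosage))
  }
  if (!is.null(config$inputs$support)) {
    support <- read_support_intervals(config$inputs$support)
    say("support: %d intervals", nrow(support))
  }
  stopifnot(identical(pheno$accession, geno$accession_ids))

  kin <- vanraden_kinship(geno)
  say("kinship: %d x %d VanRaden matrix", nrow(kin), ncol(kin))
  all_loci <- list()
  assoc_list <- list()
  for (tr in config$gwas$traits) {
    y <- pheno[[tr]]
    kpc <- config$gwas$pcs
    if (identical(kpc, "auto")) {
      kpc <- select_pcs_bic(y, geno, kin, config$gwas$pc_max)
    }
    x <- genotype_pca(geno, as.integer(kpc))
    assoc <- scan_mlm(y, x, kin, geno, p3d = isTRUE(config$gwas$p3d),
                      maf_min = config$gwas$maf_min, trait = tr)
    assoc_list[[tr]] <- assoc
    write_assoc(assoc, file.path(out_dir, paste0("assoc_", tr, ".tsv")))
    loci <- call_loci(assoc, tr, strict = config$loci$strict,
                      loose = config$loci$loose, support = support,
                      merge_gap = config$loci$merge_gap)
    say("gwas %s: %d PCs, lambda %.3f, %d loci", tr, as.integer(kpc),
        gc_lambda(assoc), nrow(loci))
    all_loci[[tr]] <- loci
  }
  loci <- do.call(rbind, all_loci)
  rownames(loci) <- NULL
  cd <- loci[loci$trait == "Cd", , drop = FALSE]
  loci$cluster <- NA_character_
  clusters <- NULL
  if (nrow(cd)) {
    cl <- cluster_cd_loci(cd, max_gap = config$cluster$max_gap)
    clusters <- cl$clusters
    loci$cluster[match(cl$loci$name, loci$name)] <- cl$loci$cluster
    .write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    say("cluster: %d Cd loci -> %d clusters", nrow(cd), nrow(clusters))
  }
  loci <- overlap_support(loci, support)
  sup_counts <- count_joint_support(loci)
  say("comparative: %d linkage, %d literature, %d multi-evidence",
      sup_counts["n_linkage"], sup_counts["n_literature"],
      sup_counts["n_multi"])
  tab <- loci_as_qtl_table(loci)
  write_qtl_table(tab, file.path(out_dir, "loci.tsv"))
  summ <- summarize_qtl_table(tab)
  .write_tsv(data.frame(key = c("n_loci", "n_cd_loci", "n_clusters",
                                "n_regions", "mean_log10p", "n_increasing",
                                "n_decreasing", "n_favorable",
                                "n_linkage_supported",
                                "n_literature_supported"),
                        value = c(summ$n_loci, summ$n_cd_loci,
                                  summ$n_clusters, summ$n_regions,
                                  round(summ$mean_log10p, 4),
                                  summ$n_increasing, summ$n_decreasing,
                                  summ$n_favorable,
                                  summ$n_linkage_supported,
                                  summ$n_literature_supported),
                        stringsAsFactors = FALSE),
             file.path(out_dir, "summary.tsv"))
  screen <- NULL
  if (!is.null(genes) && nrow(genes)) {
    screen <- screen_genes(geno, pheno, genes,
                           subsets = config$haplotypes$subsets,
                           traits = config$haplotypes$traits,
                           min_count = config$haplotypes$min_count)
    write_screen(screen, file.path(out_dir, "gene_screen.tsv"))
    say("haplotypes: screened %d genes", nrow(genes))
  }
  if (isTRUE(config$plots$enabled)) {
    for (tr in names(assoc_list)) {
      plot_manhattan(assoc_list[[tr]],
                     thresholds = c(config$loci$loose, config$loci$strict),
                     file = file.path(out_dir,
                                      paste0("manhattan_", tr, ".png")))
    }
    plot_distributions(pheno, file.path(out_dir, "distributions.png"))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("gmcqtl"))),
    paste0("seed\t", config$seed),
    paste0("config_md5\t", unname(tools::md5sum(cfg_path))),
    paste0("log\t", log)
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  res <- list(out_dir = out_dir, config = config, loci = loci,
              clusters = clusters, summary = summ, screen = screen,
              assoc = assoc_list, support_counts = sup_counts)
  class(res) <- "gmc_run"
  res
}

#' @export
print.gmc_run <- function(x, ...) {
  cat("Pipeline run ->", x$out_dir, "\n")
  cat("  traits scanned:", paste(names(x$assoc), collapse = ", "), "\n")
  cat("  loci called:", nrow(x$loci),
      "(", sum(x$loci$trait == "Cd"), "Cd )\n")
  if (!is.null(x$clusters)) cat("  Cd clusters:", nrow(x$clusters), "\n")
  if (!is.null(x$screen)) {
    cat("  genes screened:", nrow(x$screen$report), "\n")
  }
  invisible(x)
}
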