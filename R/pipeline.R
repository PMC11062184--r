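#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset from `config`, writes it out, calls DEGs for every
#' condition against the reference, computes hormone-set enrichment per
#' contrast, selects and clusters strongly varying genes (writing
#' Cluster 3.0 CDT/GTR files when at least two genes pass the filter),
#' simulates and summarizes a phenotype table, and writes every result as
#' TSV. All randomness derives from `config$seed`; two runs with the same
#' config produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_perm permutations per enrichment record.
#' @param min_set_size smallest tested set size.
#' @param lfc_threshold,alpha DEG filter thresholds.
#' @param cut_corr correlation threshold for cluster cutting.
#' @param phenotype_probs per-internode rooting probabilities for the
#'   phenotype simulation; the default mimics a cohort rooting mostly on
#'   the two lowest internodes and around internodes 9-13 below the
#'   compressed zone.
#' @param n_plants plants in the phenotype simulation.
#' @param digits decimals for floating-point serialization.
#' @return invisibly, a list with the in-memory results (`sim`, `de`,
#'   `enrichment`, `model`, `phenotype`) and `files`, the paths written.
#' @export
run_pipeline <- function(config, out_dir, n_perm = 2000L,
                         min_set_size = 8L, lfc_threshold = 1, alpha = 0.05,
                         cut_corr = 0.7,
                         phenotype_probs = c(0.33, 0.56, 0.02, 0.02, 0.02,
                                             0.02, 0.02, 0.02, 0.11, 0.22,
                                             0.33, 0.11, 0.11),
                         n_plants = 9L, digits = 6) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))
  files <- character()

  sim <- simulate_dataset(config)
  write_counts(sim$counts, path("counts.tsv"), path("samples.tsv"))
  write_gmt(sim$sets, path("sets.gmt"))
  truth_out <- sim$truth$de
  truth_out$true_log2fc <- formatC(truth_out$true_log2fc, format = "f",
                                   digits = digits)
  utils::write.table(truth_out, path("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, path("counts.tsv"), path("samples.tsv"),
             path("sets.gmt"), path("truth.tsv"))

  universe <- rownames(sim$counts$counts)
  test_conds <- setdiff(config$conditions, config$reference)
  de_list <- list()
  enr_list <- list()
  for (cond in test_conds) {
    de <- call_degs(sim$counts, c(cond, config$reference),
                    lfc_threshold = lfc_threshold, alpha = alpha)
    de_list[[cond]] <- de
    f <- path("de_", gsub("[^A-Za-z0-9]+", "_", cond), "_vs_",
              gsub("[^A-Za-z0-9]+", "_", config$reference), ".tsv")
    write_de(de, f, digits = digits)
    files <- c(files, f)
    enr_list[[cond]] <- enrich_all(de, sim$sets, universe = universe,
                                   min_set_size = min_set_size,
                                   n_perm = n_perm, seed = config$seed)
  }
  enrichment <- do.call(rbind, enr_list)
  rownames(enrichment) <- NULL
  write_enrichment(enrichment, path("enrichment.tsv"), digits = digits)
  files <- c(files, path("enrichment.tsv"))

  expr <- condition_means(sim$counts)
  selected <- select_clustering_genes(expr)
  model <- NULL
  if (length(selected) >= 2L) {
    model <- cluster_genes(expr, selected, cut_corr = cut_corr)
    files <- c(files, write_cdt_gtr(model, path("heatmap"), digits = digits))
    utils::write.table(
      data.frame(gene = names(model$clusters), cluster = model$clusters,
                 row.names = NULL),
      path("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- data.frame(cluster = rownames(model$mean_profiles),
                     formatC(model$mean_profiles, format = "f",
                             digits = digits),
                     check.names = FALSE)
    utils::write.table(mp, path("mean_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, path("clusters.tsv"), path("mean_profiles.tsv"))
  }

  pheno <- simulate_phenotype(n_plants, phenotype_probs,
                              seed = config$seed + 1L)
  utils::write.table(pheno, path("phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  per_int <- percent_per_internode(pheno, unique(pheno$treatment)[1])
  per_int$percent <- format_percent(per_int$percent)
  utils::write.table(per_int, path("phenotype_per_internode.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, path("phenotype.tsv"), path("phenotype_per_internode.tsv"))

  invisible(list(sim = sim, de = de_list, enrichment = enrichment,
                 model = model, phenotype = pheno, files = files))
}
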