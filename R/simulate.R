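#' Default hormone gene-set specification for simulation
#'
#' One entry per "response to <hormone>" GO term (see
#' [hormone_go_terms()]), each with a target membership size and an
#' optional planted enrichment. The default size of 200 genes is in the
#' range of hormone-response GO terms in crucifer genome annotations.
#'
#' @param size membership size used for every set.
#' @return list of lists with elements `name`, `go`, `size`, `enrich`
#'   (`NULL`, or a data.frame with columns `contrast`, `direction`,
#'   `factor` describing planted enrichment of the set among DEGs of that
#'   direction in that contrast).
#' @export
default_hormone_sets <- function(size = 200L) {
  terms <- hormone_go_terms()
  lapply(seq_len(nrow(terms)), function(i) {
    list(name = terms$set_name[i], go = terms$go_id[i],
         size = as.integer(size), enrich = NULL)
  })
}

#' Simulation configuration for the vernalization time-course design
#'
#' Encodes the study conditions the generator emulates: nine conditions
#' (six cold durations at 0 weeks in long days plus three returned to long
#' days for 5 days), three biological replicates, negative-binomial counts
#' with lognormal baseline means and lognormal per-gene dispersions, a
#' fixed fraction of genes differentially expressed per contrast against
#' the pre-cold reference, and hormone gene sets whose membership can be
#' planted to be enriched among directional DEGs.
#'
#' @param n_genes number of genes (default 2000; the full catalogue of
#'   30510 genes is supported).
#' @param conditions ordered condition labels.
#' @param reference reference condition for all contrasts.
#' @param n_replicates biological replicates per condition.
#' @param baseline_log_mean,baseline_log_sd lognormal parameters (natural
#'   log scale) of per-gene baseline mean counts.
#' @param dispersion_log_mean,dispersion_log_sd lognormal parameters of
#'   the per-gene NB dispersion alpha in Var = mu + alpha * mu^2.
#' @param deg_fraction fraction of genes differentially expressed in each
#'   contrast versus `reference`, in \[0, 1\].
#' @param lfc_mean,lfc_sd normal parameters of the planted |log2
#'   fold-change| magnitude (draws are taken in absolute value).
#' @param lfc_up_share probability a planted DEG is up-regulated.
#' @param size_factor_sd lognormal sigma of per-sample library-size
#'   factors, so normalization is non-trivially exercised.
#' @param hormone_sets list as produced by [default_hormone_sets()].
#' @param seed integer seed; identical configs with identical seeds give
#'   bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       conditions = c("0w", "4w", "8w", "12w", "16w", "21w",
                                      "12w+5dLD", "16w+5dLD", "21w+5dLD"),
                       reference = "0w",
                       n_replicates = 3L,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.5,
                       dispersion_log_mean = log(0.05),
                       dispersion_log_sd = 0.5,
                       deg_fraction = 0.1,
                       lfc_mean = 2,
                       lfc_sd = 0.5,
                       lfc_up_share = 0.5,
                       size_factor_sd = 0.1,
                       hormone_sets = default_hormone_sets(),
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 2L, n_replicates >= 1L,
            length(conditions) >= 2L, !anyDuplicated(conditions),
            reference %in% conditions,
            baseline_log_sd >= 0, dispersion_log_sd >= 0,
            lfc_sd >= 0, size_factor_sd >= 0)
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("deg_fraction must be in [0, 1]")
  if (lfc_up_share < 0 || lfc_up_share > 1)
    stop("lfc_up_share must be in [0, 1]")
  for (hs in hormone_sets) {
    if (is.null(hs$name) || is.null(hs$size))
      stop("each hormone set needs a name and a size")
    if (hs$size > n_genes)
      stop("set '", hs$name, "' larger than n_genes")
    if (!is.null(hs$enrich) && any(hs$enrich$factor <= 0))
      stop("planted enrichment factors must be > 0")
  }
  if (anyDuplicated(vapply(hormone_sets, `[[`, "", "name")))
    stop("duplicate hormone set name")
  structure(list(n_genes = n_genes, conditions = conditions,
                 reference = reference, n_replicates = as.integer(n_replicates),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion_log_mean = dispersion_log_mean,
                 dispersion_log_sd = dispersion_log_sd,
                 deg_fraction = deg_fraction,
                 lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 lfc_up_share = lfc_up_share,
                 size_factor_sd = size_factor_sd,
                 hormone_sets = hormone_sets,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a complete dataset with ground truth
#'
#' Draws per-gene baseline means and NB dispersions, plants DEGs per
#' contrast (each non-reference condition versus the reference), samples
#' hormone-set membership — uniformly for factor-1 sets, stratified so
#' that planted sets overlap directional DEGs by the requested factor —
#' applies lognormal library-size factors and draws NB counts.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]), `sets`
#'   (a [gene_sets()] collection), and `truth` (class `sim_truth`: `de`
#'   data.frame with gene/contrast/is_de/true_log2fc, `planted`
#'   data.frame of planted factors, `size_factors`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("AaG%05d", seq_len(n))
  baseline <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  alpha <- stats::rlnorm(n, config$dispersion_log_mean,
                         config$dispersion_log_sd)

  test_conds <- setdiff(config$conditions, config$reference)
  lfc <- matrix(0, n, length(config$conditions),
                dimnames = list(genes, config$conditions))
  n_de <- round(config$deg_fraction * n)
  for (cond in test_conds) {
    if (n_de == 0L) next
    idx <- sample.int(n, n_de)
    sgn <- ifelse(stats::runif(n_de) < config$lfc_up_share, 1, -1)
    mag <- abs(stats::rnorm(n_de, config$lfc_mean, config$lfc_sd))
    lfc[idx, cond] <- sgn * mag
  }

  members <- lapply(config$hormone_sets, function(hs) {
    .sample_set_members(hs, genes, lfc, n)
  })
  names(members) <- vapply(config$hormone_sets, `[[`, "", "name")
  sets <- gene_sets(members,
                    source_ids = vapply(config$hormone_sets,
                                        function(h) h$go %||% "", ""))

  planted <- do.call(rbind, lapply(config$hormone_sets, function(hs) {
    if (is.null(hs$enrich)) return(NULL)
    data.frame(set_name = hs$name, hs$enrich, stringsAsFactors = FALSE)
  }))
  if (is.null(planted))
    planted <- data.frame(set_name = character(), contrast = character(),
                          direction = character(), factor = numeric())

  cond_of <- rep(config$conditions, each = config$n_replicates)
  sample_ids <- paste0(cond_of, "_r",
                       rep(seq_len(config$n_replicates),
                           times = length(config$conditions)))
  sf <- stats::rlnorm(length(sample_ids), 0, config$size_factor_sd)
  counts <- matrix(0L, n, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- baseline * 2^lfc[, cond_of[j]] * sf[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
  samples <- data.frame(sample_id = sample_ids, condition = cond_of,
                        replicate = rep(seq_len(config$n_replicates),
                                        times = length(config$conditions)),
                        stringsAsFactors = FALSE)

  de <- data.frame(
    gene = rep(genes, times = length(test_conds)),
    contrast = rep(test_conds, each = n),
    is_de = as.vector(lfc[, test_conds, drop = FALSE] != 0),
    true_log2fc = as.vector(lfc[, test_conds, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(de = de, planted = planted,
                          size_factors = stats::setNames(sf, sample_ids)),
                     class = "sim_truth")
  list(counts = count_matrix(counts, samples), sets = sets, truth = truth)
}

# Stratified membership sampling. For a planted (contrast, direction,
# factor) the target overlap is round(factor * n_dir * K / M), the
# factor-weighted null expectation; factor-1 sets are drawn uniformly so
# the null calibration is exact.
.sample_set_members <- function(hs, genes, lfc, n) {
  K <- as.integer(hs$size)
  enr <- hs$enrich
  if (!is.null(enr)) enr <- enr[enr$factor != 1, , drop = FALSE]
  if (is.null(enr) || nrow(enr) == 0L)
    return(sample(genes, K))
  strata <- lapply(seq_len(nrow(enr)), function(i) {
    cond <- enr$contrast[i]
    if (!cond %in% colnames(lfc))
      stop("planted contrast '", cond, "' is not a simulated condition")
    s <- if (enr$direction[i] == "up") lfc[, cond] > 0 else lfc[, cond] < 0
    genes[s]
  })
  if (nrow(enr) > 1L &&
      any(duplicated(unlist(strata))))
    stop("planted strata overlap; plant at most one constraint per ",
         "direction-specific DEG pool")
  need <- integer(nrow(enr))
  for (i in seq_len(nrow(enr))) {
    n_dir <- length(strata[[i]])
    need[i] <- round(enr$factor[i] * n_dir * K / n)
    if (need[i] > K)
      stop(sprintf(
        "infeasible enrichment for set '%s': %d members needed but set size is %d",
        hs$name, need[i], K))
    if (need[i] > n_dir)
      stop(sprintf(
        "infeasible enrichment for set '%s': %d members needed but only %d %s-regulated DEGs exist in contrast %s",
        hs$name, need[i], n_dir, enr$direction[i], enr$contrast[i]))
  }
  picked <- unlist(lapply(seq_len(nrow(enr)),
                          function(i) sample(strata[[i]], need[i])))
  pool <- setdiff(genes, unlist(strata))
  rest <- K - length(picked)
  if (rest > length(pool))
    stop(sprintf(
      "infeasible enrichment for set '%s': only %d genes left outside planted strata but %d needed",
      hs$name, length(pool), rest))
  sort(c(picked, sample(pool, rest)))
}

#' Enrichment index realized in the simulation truth
#'
#' Computes the index directly from the ground-truth DEG labels (not from
#' any DE calling), for checking that planted factors are realized.
#'
#' @param truth `sim_truth` from [simulate_dataset()].
#' @param sets the matching [gene_sets()] collection.
#' @param set_name,contrast,direction which record to evaluate.
#' @param universe gene universe (default: all genes in `truth`).
#' @return the realized index (k/K)/(n/M).
#' @export
truth_enrichment <- function(truth, sets, set_name, contrast, direction,
                             universe = unique(truth$de$gene)) {
  d <- truth$de[truth$de$contrast == contrast & truth$de$is_de, , drop = FALSE]
  deg <- if (direction == "up") d$gene[d$true_log2fc > 0]
         else d$gene[d$true_log2fc < 0]
  members <- intersect(sets[[set_name]], universe)
  enrichment_index(k = length(intersect(deg, members)),
                   K = length(members), n = length(deg),
                   M = length(universe))
}

#' Simulate a per-internode adventitious-root presence table
#'
#' Bernoulli presence per plant and internode, emulating the
#' column-per-plant scoring of AR presence along the main stem.
#'
#' @param n_plants number of plants.
#' @param internode_probs vector of presence probabilities, one per
#'   internode position (1 = bottom of the stem).
#' @param seed integer seed.
#' @param treatment treatment label attached to all records.
#' @param branch_prob optional probability that a plant has at least one
#'   rooted axillary branch; adds one `branch` record per plant.
#' @return a `phenotype_table` data.frame (see [phenotype_table()]).
#' @export
simulate_phenotype <- function(n_plants, internode_probs, seed = 1L,
                               treatment = "21w+2wLD", branch_prob = NULL) {
  if (any(internode_probs < 0 | internode_probs > 1))
    stop("internode_probs must lie in [0, 1]")
  if (!is.null(branch_prob) && (branch_prob < 0 || branch_prob > 1))
    stop("branch_prob must lie in [0, 1]")
  set.seed(seed)
  n_int <- length(internode_probs)
  plants <- sprintf("plant%04d", seq_len(n_plants))
  df <- data.frame(
    plant_id = rep(plants, each = n_int),
    treatment = treatment,
    organ = "main_stem_internode",
    internode_index = rep(seq_len(n_int), times = n_plants),
    presence = as.integer(stats::rbinom(n_plants * n_int, 1,
                                        rep(internode_probs, times = n_plants))),
    zone = "unknown",
    stringsAsFactors = FALSE
  )
  if (!is.null(branch_prob)) {
    df <- rbind(df, data.frame(
      plant_id = plants, treatment = treatment, organ = "branch",
      internode_index = NA_integer_,
      presence = as.integer(stats::rbinom(n_plants, 1, branch_prob)),
      zone = "unknown", stringsAsFactors = FALSE))
  }
  phenotype_table(df)
}
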