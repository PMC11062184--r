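#' Replicate-averaged log2 normalized expression per condition
#'
#' Divides counts by size factors, takes `log2(normalized + 1)` per
#' sample, and averages replicates within each condition. Columns are
#' ordered along the time course (by cold weeks, then days after return
#' to long days).
#'
#' @param cm a [count_matrix()].
#' @param sf optional size factors (default: [size_factors()] of `cm`).
#' @return numeric matrix genes x conditions (class `expr_matrix`).
#' @export
condition_means <- function(cm, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(sf)) sf <- size_factors(cm)
  logexpr <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  conds <- condition_order(unique(cm$samples$condition))
  out <- vapply(conds, function(cond) {
    rowMeans(logexpr[, cm$samples$condition == cond, drop = FALSE])
  }, numeric(nrow(cm$counts)))
  out <- matrix(out, nrow = nrow(cm$counts),
                dimnames = list(rownames(cm$counts), conds))
  structure(out, class = c("expr_matrix", class(out)))
}

#' Select strongly varying genes for clustering
#'
#' Keeps genes satisfying both selection criteria of the heat-map stage:
#' the log2 fold change between the highest- and lowest-expression
#' condition at least `lfc_min`, and the spread (max minus min) of the
#' values entering clustering at least `range_min`; both comparisons are
#' inclusive. On the default log2 scale both criteria reduce to the
#' row-wise max minus min; `range_scale = "linear"` applies `range_min`
#' to the de-logged normalized values instead.
#'
#' @param expr an [condition_means()] matrix.
#' @param lfc_min minimum log2 fold change (default 2).
#' @param range_min minimum max-minus-min spread (default 3).
#' @param range_scale scale on which `range_min` is applied.
#' @return character vector of selected gene ids, in input order.
#' @export
select_clustering_genes <- function(expr, lfc_min = 2, range_min = 3,
                                    range_scale = c("log2", "linear")) {
  if (lfc_min < 0 || range_min < 0)
    stop("lfc_min and range_min must be non-negative")
  range_scale <- match.arg(range_scale)
  if (ncol(expr) < 2L) stop("need >= 2 conditions")
  spread_log <- apply(expr, 1, max) - apply(expr, 1, min)
  spread_rng <- if (range_scale == "log2") spread_log
                else apply(2^expr - 1, 1, max) - apply(2^expr - 1, 1, min)
  rownames(expr)[spread_log >= lfc_min & spread_rng >= range_min]
}

#' Hierarchically cluster gene expression profiles
#'
#' Cluster 3.0 style: each selected gene's profile is centered to mean 0
#' and scaled to unit sum of squares; similarity is the Pearson
#' correlation; genes are joined by average-linkage agglomeration; flat
#' clusters come from cutting the tree where the join similarity drops
#' below a correlation threshold (default 0.7), or at a requested number
#' of clusters. Genes are processed in lexicographic id order so the
#' result does not depend on input order; zero-variance genes are
#' excluded with a warning (their correlation is undefined).
#'
#' @param expr an [condition_means()] matrix.
#' @param genes gene ids to cluster (>= 2 after exclusions).
#' @param cut_corr correlation threshold for cutting the tree.
#' @param k if given, cut into exactly `k` clusters instead.
#' @return object of class `cluster_model`: list with `genes` (clustered,
#'   lexicographic order), `normalized` (matrix), `tree` (`hclust`, with
#'   heights `1 - similarity`), `clusters` (named integer vector),
#'   `mean_profiles` (cluster x condition matrix), `excluded`
#'   (zero-variance gene ids), `cut` (the rule used).
#' @export
cluster_genes <- function(expr, genes, cut_corr = 0.7, k = NULL) {
  genes <- sort(unique(as.character(genes)))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  v <- apply(x, 1, stats::var)
  excluded <- genes[v == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " zero-variance gene(s) from clustering: ",
            paste(utils::head(excluded, 5), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("tree requires >= 2 genes")

  ctr <- x - rowMeans(x)
  normalized <- ctr / sqrt(rowSums(ctr^2))
  sim <- stats::cor(t(ctr))
  tree <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  tree$labels <- rownames(x)
  clusters <- if (!is.null(k)) stats::cutree(tree, k = k)
              else stats::cutree(tree, h = 1 - cut_corr)
  mp <- .cluster_means(normalized, clusters)
  structure(list(genes = rownames(x), normalized = normalized, tree = tree,
                 clusters = clusters, mean_profiles = mp,
                 excluded = excluded,
                 cut = if (is.null(k)) list(type = "corr", value = cut_corr)
                       else list(type = "k", value = k)),
            class = "cluster_model")
}

.cluster_means <- function(normalized, clusters) {
  ids <- sort(unique(clusters))
  mp <- t(vapply(ids, function(cl) {
    colMeans(normalized[clusters == cl, , drop = FALSE])
  }, numeric(ncol(normalized))))
  rownames(mp) <- as.character(ids)
  mp
}

#' Average normalized expression profile of each cluster
#'
#' @param model a [cluster_genes()] result.
#' @return cluster x condition matrix of member means.
#' @export
cluster_mean_profiles <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  .cluster_means(model$normalized, model$clusters)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d genes, %d clusters (cut: %s %.2g)\n",
              length(x$genes), length(unique(x$clusters)),
              x$cut$type, x$cut$value))
  if (length(x$excluded))
    cat("excluded (zero variance):", length(x$excluded), "gene(s)\n")
  invisible(x)
}
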