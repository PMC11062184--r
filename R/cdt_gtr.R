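#' Write a clustering result in Cluster 3.0 CDT/GTR format
#'
#' Emits `<basename>.cdt` (clustered data table: GID, gene id, name,
#' GWEIGHT, then one column per condition, rows in dendrogram order) and
#' `<basename>.gtr` (gene tree: one join per line with node id, the two
#' child ids and the join similarity), the file pair TreeView uses to
#' render reorderable heatmaps. Values are serialized with a fixed number
#' of decimals so that [read_cdt()] reproduces them bit-exactly at that
#' precision.
#'
#' Leaf ids follow the Cluster 3.0 convention `GENE<i>X` with `i` the
#' 0-based row index in the input order; internal nodes are `NODE<j>X`
#' with `j` the 1-based join index.
#'
#' @param model a [cluster_genes()] result (class `cluster_model`).
#' @param basename output path without extension.
#' @param digits number of decimals used for all floating-point fields.
#' @return invisibly, a character vector with the two paths written.
#' @export
write_cdt_gtr <- function(model, basename, digits = 6) {
  stopifnot(inherits(model, "cluster_model"))
  tree <- model$tree
  if (is.null(tree)) stop("cluster model has no tree")
  n <- length(model$genes)
  if (n < 2L) stop("tree requires >= 2 genes")
  fmt <- function(x) formatC(x, format = "f", digits = digits)

  node_id <- function(i) {
    if (i < 0L) sprintf("GENE%dX", -i - 1L) else sprintf("NODE%dX", i)
  }
  gtr <- vapply(seq_len(nrow(tree$merge)), function(j) {
    paste(sprintf("NODE%dX", j),
          node_id(tree$merge[j, 1]), node_id(tree$merge[j, 2]),
          fmt(1 - tree$height[j]), sep = "\t")
  }, "")
  gtr_path <- paste0(basename, ".gtr")
  writeLines(gtr, gtr_path)

  conds <- colnames(model$normalized)
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", conds), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "",
                     rep(fmt(1), length(conds))), collapse = "\t")
  ord <- tree$order
  rows <- vapply(ord, function(i) {
    paste(c(sprintf("GENE%dX", i - 1L), model$genes[i], model$genes[i],
            fmt(1), fmt(model$normalized[i, ])), collapse = "\t")
  }, "")
  cdt_path <- paste0(basename, ".cdt")
  writeLines(c(header, eweight, rows), cdt_path)
  invisible(c(cdt = cdt_path, gtr = gtr_path))
}

#' Read the value matrix back from a CDT file
#'
#' @param path path to a `.cdt` file as written by [write_cdt_gtr()].
#' @return numeric matrix (genes x conditions) in the file's row order,
#'   rownames = gene ids.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("not a CDT file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  conds <- header[-(1:4)]
  body <- lines[-1]
  body <- body[!startsWith(body, "EWEIGHT")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(fields, `[[`, "", 2L)
  vals <- t(vapply(fields,
                   function(f) as.numeric(f[-(1:4)]),
                   numeric(length(conds))))
  dimnames(vals) <- list(genes, conds)
  vals
}
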