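#' Construct a validated count matrix with sample metadata
#'
#' The central container of the pipeline: an integer gene-by-sample count
#' matrix together with a per-sample metadata table describing the
#' vernalization time-course design (cold duration, days after return to
#' long days, replicate).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All cells must be finite,
#'   non-negative whole numbers.
#' @param samples data.frame with one row per sample and columns
#'   `sample_id`, `condition`, `replicate`; optional `cold_weeks` and
#'   `post_cold_days` (derived from `condition` labels such as `"12w"` or
#'   `"12w+5dLD"` when absent).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `samples` (data.frame, one row per
#'   column of `counts`, in column order).
#' @examples
#' m <- matrix(c(1L, 0L, 10L, 2L, 5L, 10L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' s <- data.frame(sample_id = c("s1", "s2"),
#'                 condition = c("0w", "21w"), replicate = c(1L, 1L))
#' cm <- count_matrix(m, s)
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (nrow(counts) == 0L)
    stop("no genes parsed: count matrix has zero rows")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id in sample sheet")
  absent <- setdiff(colnames(counts), samples$sample_id)
  if (length(absent))
    stop("sample in matrix missing from metadata: ",
         paste(absent, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  parsed <- parse_condition(samples$condition)
  if (is.null(samples$cold_weeks)) samples$cold_weeks <- parsed$cold_weeks
  if (is.null(samples$post_cold_days))
    samples$post_cold_days <- parsed$post_cold_days
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop("replicate must be an integer >= 1")

  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Parse vernalization condition labels
#'
#' Labels follow the `"<weeks>w"` / `"<weeks>w+<days>dLD"` convention of the
#' time-course design (e.g. `"0w"`, `"21w"`, `"12w+5dLD"`). Labels that do
#' not match yield `NA` for both components; such conditions keep their
#' order of appearance instead of a numeric ordering.
#'
#' @param labels character vector of condition labels.
#' @return data.frame with integer columns `cold_weeks` and `post_cold_days`.
#' @export
parse_condition <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)w(?:\\+([0-9]+)dLD)?$", labels))
  cw <- vapply(m, function(x) if (length(x)) as.integer(x[2]) else NA_integer_,
               integer(1))
  pd <- vapply(m, function(x) {
    if (length(x) < 3L || x[3] == "") 0L else as.integer(x[3])
  }, integer(1))
  pd[is.na(cw)] <- NA_integer_
  data.frame(cold_weeks = cw, post_cold_days = pd)
}

#' Order condition labels along the time course
#'
#' @param labels character vector of unique condition labels.
#' @return `labels` sorted by (cold_weeks, post_cold_days); unparseable
#'   labels keep their input order and sort last.
#' @export
condition_order <- function(labels) {
  p <- parse_condition(labels)
  key1 <- ifelse(is.na(p$cold_weeks), .Machine$integer.max, p$cold_weeks)
  key2 <- ifelse(is.na(p$post_cold_days), .Machine$integer.max, p$post_cold_days)
  labels[order(key1, key2, seq_along(labels))]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a count matrix and sample sheet from tab-separated files
#'
#' The matrix is a TSV with the gene id in the first column and one column
#' per sample (header row holds sample ids). The sample sheet is a TSV with
#' columns `sample_id`, `condition`, `replicate`. gzip-compressed files are
#' accepted transparently.
#'
#' @param path path to the count matrix TSV.
#' @param meta_path path to the sample sheet TSV.
#' @return A [count_matrix()] with gene order as in the file.
#' @export
read_counts <- function(path, meta_path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("no genes parsed from ", path, call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("no genes parsed from ", path)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-integer or negative count: non-numeric cell in ", path)
  rownames(mat) <- genes
  samples <- utils::read.delim(meta_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  count_matrix(mat, samples)
}

#' Write a count matrix and its sample sheet to TSV files
#'
#' Inverse of [read_counts()]: `read_counts(path, meta_path)` on the files
#' written here reproduces the object.
#'
#' @param cm a [count_matrix()].
#' @param path output path for the counts TSV.
#' @param meta_path output path for the sample sheet TSV.
#' @return invisibly, `cm`.
#' @export
write_counts <- function(cm, path, meta_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}
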