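#' Validate a per-plant adventitious-root presence table
#'
#' Long-format scoring table: one record per plant, treatment, organ and
#' (for main-stem records) internode position, with binary presence.
#' Internodes are numbered 1-based from the bottom of the stem. Only
#' presence, not root number, is recorded.
#'
#' @param df data.frame with columns `plant_id`, `treatment`, `organ`
#'   (`main_stem_internode` or `branch`), `internode_index` (integer >= 1
#'   for internode records, `NA` for branch records), `presence` (0/1),
#'   optional `zone` (`compressed`/`non_compressed`/`unknown`).
#' @return the validated data.frame, class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("plant_id", "treatment", "organ", "internode_index", "presence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$organ %in% c("main_stem_internode", "branch")))
    stop("organ must be 'main_stem_internode' or 'branch'")
  is_int <- df$organ == "main_stem_internode"
  if (any(is.na(df$internode_index[is_int])) ||
      any(df$internode_index[is_int] < 1))
    stop("internode records need internode_index >= 1")
  if (any(!is.na(df$internode_index[!is_int])))
    stop("branch records must not carry an internode_index")
  if (!all(df$presence %in% c(0L, 1L)))
    stop("presence must be 0 or 1")
  if (is.null(df$zone)) df$zone <- "unknown"
  if (!all(df$zone %in% c("compressed", "non_compressed", "unknown")))
    stop("zone must be compressed/non_compressed/unknown")
  key <- paste(df$plant_id, df$treatment, df$organ, df$internode_index)
  if (anyDuplicated(key))
    stop("duplicate (plant, treatment, organ, internode) record")
  df$presence <- as.integer(df$presence)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a phenotype table from TSV
#'
#' @param path long-format TSV as described in [phenotype_table()].
#' @return a `phenotype_table`.
#' @export
read_phenotype <- function(path) {
  phenotype_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Percentage of plants with adventitious roots, per treatment
#'
#' For each treatment, the share of scored plants that have at least one
#' presence record in the requested organ class (any internode for the
#' main stem).
#'
#' @param table a [phenotype_table()].
#' @param organ `"main_stem_internode"` or `"branch"`.
#' @param treatments treatments to report (default: all in the table);
#'   requesting a treatment with no scored plant is an error.
#' @return data.frame with columns `treatment`, `n_plants`, `percent`
#'   (full precision; see [format_percent()] for reporting).
#' @export
percent_plants_with_ar <- function(table, organ = "main_stem_internode",
                                   treatments = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  sub <- table[table$organ == organ, , drop = FALSE]
  if (is.null(treatments)) treatments <- unique(sub$treatment)
  out <- lapply(treatments, function(tr) {
    rec <- sub[sub$treatment == tr, , drop = FALSE]
    if (nrow(rec) == 0L)
      stop("no plants scored for treatment '", tr, "'")
    rooted <- tapply(rec$presence, rec$plant_id, function(p) any(p == 1L))
    data.frame(treatment = tr, n_plants = length(rooted),
               percent = 100 * mean(rooted), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentage of plants with adventitious roots per internode position
#'
#' For one treatment, the share of plants with a root at each internode,
#' reported bottom-to-top. Internodes never scored are omitted (they are
#' missing, not 0%); plants missing a score for an internode are excluded
#' from that internode's denominator.
#'
#' @param table a [phenotype_table()].
#' @param treatment treatment label to summarize.
#' @return data.frame with columns `internode_index`, `n_plants`,
#'   `percent`, ordered by internode index.
#' @export
percent_per_internode <- function(table, treatment) {
  stopifnot(inherits(table, "phenotype_table"))
  rec <- table[table$organ == "main_stem_internode" &
               table$treatment == treatment, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no internode records for treatment '", treatment, "'")
  idx <- sort(unique(rec$internode_index))
  out <- lapply(idx, function(i) {
    at <- rec[rec$internode_index == i, , drop = FALSE]
    data.frame(internode_index = i, n_plants = nrow(at),
               percent = 100 * mean(at$presence), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Format percentages for reports
#'
#' One decimal place, the granularity used for small cohorts (e.g. 5 of 9
#' plants prints as 55.6).
#'
#' @param x numeric percentages.
#' @return character vector.
#' @export
format_percent <- function(x) formatC(x, format = "f", digits = 1)
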