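#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members); names are set
#'   names and must be unique, member vectors non-empty (duplicates within
#'   a set are collapsed).
#' @param source_ids optional character vector parallel to `sets` giving a
#'   source accession per set (e.g. a GO id); empty string when unknown.
#' @return An object of class `gene_sets`: the named list of member
#'   vectors, with a `source_ids` attribute.
#' @export
gene_sets <- function(sets, source_ids = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(m) unique(as.character(m[m != ""])))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set: ", paste(empty, collapse = ", "))
  if (is.null(source_ids)) source_ids <- rep("", length(sets))
  names(source_ids) <- names(sets)
  structure(sets, source_ids = source_ids, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line; tab-separated fields are the set name,
#' a description (here used to carry the GO accession), then the member
#' gene ids. Blank member fields (including trailing tabs) are dropped.
#'
#' @param path path to the GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets parsed from ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(stats::setNames(members, nm), source_ids = desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets a [gene_sets()] collection.
#' @param path output path.
#' @return invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  src <- attr(sets, "source_ids")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, src[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' The eight hormone-response GO terms of the study
#'
#' Names and GO accessions of the "response to <hormone>" Gene Ontology
#' terms used for the enrichment analysis. Membership is annotation- and
#' genome-specific and is not shipped; pair these ids with your own
#' annotation, or use [simulate_dataset()] for synthetic membership.
#'
#' @return data.frame with columns `set_name` and `go_id`.
#' @export
hormone_go_terms <- function() {
  data.frame(
    set_name = c("response to abscisic acid", "response to auxin",
                 "response to brassinosteroid", "response to cytokinin",
                 "response to ethylene", "response to gibberellin",
                 "response to jasmonic acid", "response to salicylic acid"),
    go_id = c("GO:0009737", "GO:0009733", "GO:0009741", "GO:0009735",
              "GO:0009723", "GO:0009739", "GO:0009753", "GO:0009751"),
    stringsAsFactors = FALSE
  )
}
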