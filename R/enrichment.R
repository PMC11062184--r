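#' Hormone gene-set enrichment index
#'
#' The index compares the share of a hormone-responsive set among the
#' directional DEGs with its genome-wide share:
#' `E = (k / K) / (n / M)` where `k` is the overlap between the direction's
#' DEGs and the set, `K` the set size, `n` the number of DEGs of that
#' direction and `M` the universe (genome) size. `E > 1` indicates
#' over-representation, `E < 1` depletion.
#'
#' Computed as `(k * M) / (K * n)` — a single final division of exact
#' integer products — so representable results are exact.
#'
#' @param k overlap count.
#' @param K set size within the universe.
#' @param n number of up- (or down-) regulated genes.
#' @param M universe size.
#' @return the index, a plain number; when `K == 0` or `n == 0` the index
#'   is undefined and `NA_real_` is returned carrying a `reason`
#'   attribute (never 0).
#' @examples
#' enrichment_index(k = 4, K = 10, n = 20, M = 100)  # 2
#' @export
enrichment_index <- function(k, K, n, M) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(M) == 1)
  if (M < K || M < n || k > min(K, n) || k < 0 || K < 0 || n < 0)
    stop("invalid counts: need M >= K >= 0, M >= n >= 0, 0 <= k <= min(K, n)")
  if (K == 0)
    return(structure(NA_real_, reason = "K = 0"))
  if (n == 0)
    return(structure(NA_real_, reason = "n = 0"))
  (as.numeric(k) * as.numeric(M)) / (as.numeric(K) * as.numeric(n))
}

#' Monte Carlo test of the DEG / gene-set overlap
#'
#' Null hypothesis: the DEG list is a uniform draw from the universe.
#' The test draws `|deg_genes|` genes from the universe without
#' replacement `n_perm` times and counts how often the intersection with
#' the (effective) hormone set is equal to or higher than the observed
#' one; `p_mc` is that count divided by `n_perm`. The hormone set is first
#' intersected with the universe.
#'
#' @param deg_genes character vector of directional DEGs; must be a
#'   subset of `universe`.
#' @param hormone_set character vector of set members.
#' @param universe character vector: the full gene catalogue resampled
#'   from.
#' @param n_perm number of random draws (default 10000).
#' @param seed integer seed; fixed seed gives identical results.
#' @param add_one if `TRUE`, report the add-one-corrected
#'   `(count + 1) / (n_perm + 1)` instead of the plain `count / n_perm`.
#' @param return_null if `TRUE`, include the `n_perm` null overlap counts
#'   in the result (used for calibration checks).
#' @return list with `k_obs`, `p_mc`, `n_perm`, `seed` and (optionally)
#'   `null_overlap`.
#' @export
mc_overlap_test <- function(deg_genes, hormone_set, universe,
                            n_perm = 10000L, seed = 1L,
                            add_one = FALSE, return_null = FALSE) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  universe <- unique(as.character(universe))
  deg_genes <- unique(as.character(deg_genes))
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(deg_genes, universe)
  if (length(outside))
    stop("deg_genes not in universe: ", paste(utils::head(outside, 5),
                                              collapse = ", "),
         if (length(outside) > 5) sprintf(" (and %d more)", length(outside) - 5))
  memb <- universe %in% hormone_set
  M <- length(universe)
  n <- length(deg_genes)
  k_obs <- sum(deg_genes %in% universe[memb])

  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(memb[sample.int(M, n)]), integer(1))
  })
  hits <- sum(null >= k_obs)
  p_mc <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  out <- list(k_obs = k_obs, p_mc = p_mc, n_perm = n_perm, seed = seed)
  if (return_null) out$null_overlap <- null
  out
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-record sub-seed below 2^31, derived from the master
# seed and the record key.
record_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Enrichment of every gene set among up- and down-regulated genes
#'
#' For each set with at least `min_set_size` members inside the universe,
#' computes one record per direction: the observed overlap `k`, the
#' enrichment index `E` and the Monte Carlo p-value. Sets below the size
#' threshold are reported with an `excluded` flag rather than dropped
#' (the study excluded a 7-gene strigolactone term on this ground).
#' Depletion (`E < 1`) is reported but not tested; the test is one-sided
#' for enrichment. No multiple-testing correction is applied across sets
#' by default (`adjust = TRUE` adds a BH column).
#'
#' @param de a `de_table` from [call_degs()] or [import_de()].
#' @param sets a [gene_sets()] collection.
#' @param universe the gene catalogue to resample from (default: the
#'   genes of `de`).
#' @param min_set_size smallest effective set size that is tested
#'   (default 8).
#' @param n_perm,seed passed to [mc_overlap_test()]; each record gets a
#'   deterministic sub-seed derived from `seed` and the record key.
#' @param star_alpha records with `p_mc` strictly below this are flagged
#'   `significant` (default 0.05).
#' @param adjust add a `padj_sets` BH column across tested records.
#' @return data.frame of class `enrichment_table`, one row per set and
#'   direction, columns `set_name, direction, contrast, M, K, n, k, E,
#'   p_mc, n_perm, seed, excluded, reason, significant`.
#' @export
enrich_all <- function(de, sets, universe = de$gene, min_set_size = 8L,
                       n_perm = 10000L, seed = 1L, star_alpha = 0.05,
                       adjust = FALSE) {
  stopifnot(inherits(de, "de_table"), inherits(sets, "gene_sets"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  contrast <- attr(de, "contrast")
  contrast_label <- if (all(is.na(contrast))) NA_character_
                    else paste(contrast, collapse = "_vs_")
  deg <- list(up = intersect(de$gene[de$direction == "up"], universe),
              down = intersect(de$gene[de$direction == "down"], universe))
  M <- length(universe)

  rows <- list()
  for (nm in names(sets)) {
    eff <- intersect(sets[[nm]], universe)
    K <- length(eff)
    for (dir in c("up", "down")) {
      n <- length(deg[[dir]])
      row <- data.frame(set_name = nm, direction = dir,
                        contrast = contrast_label, M = M, K = K, n = n,
                        k = NA_integer_, E = NA_real_, p_mc = NA_real_,
                        n_perm = as.integer(n_perm), seed = NA_integer_,
                        excluded = FALSE, reason = "",
                        significant = FALSE, stringsAsFactors = FALSE)
      if (K < min_set_size) {
        row$excluded <- TRUE
        row$reason <- "excluded: set below minimum size"
      } else if (n == 0L) {
        row$reason <- "undefined: n = 0"
      } else {
        sub_seed <- record_seed(seed, paste(nm, dir, contrast_label, sep = "|"))
        mc <- mc_overlap_test(deg[[dir]], eff, universe,
                              n_perm = n_perm, seed = sub_seed)
        row$k <- mc$k_obs
        row$E <- as.numeric(enrichment_index(mc$k_obs, K, n, M))
        row$p_mc <- mc$p_mc
        row$seed <- sub_seed
        row$significant <- mc$p_mc < star_alpha
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj_sets <- NA_real_
    tested <- !is.na(out$p_mc)
    out$padj_sets[tested] <- stats::p.adjust(out$p_mc[tested], method = "BH")
  }
  structure(out, class = c("enrichment_table", "data.frame"),
            star_alpha = star_alpha)
}

#' Write an enrichment table to TSV
#'
#' @param enr an `enrichment_table`.
#' @param path output path.
#' @param digits decimals for the `E` and `p_mc` columns.
#' @return invisibly, `enr`.
#' @export
write_enrichment <- function(enr, path, digits = 6) {
  out <- enr
  for (col in c("E", "p_mc", "padj_sets"))
    if (col %in% names(out))
      out[[col]] <- formatC(out[[col]], format = "f", digits = digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(enr)
}
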