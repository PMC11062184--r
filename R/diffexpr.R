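#' Median-of-ratios size factors
#'
#' Library-size normalization factors: each gene's counts are divided by
#' the gene's geometric mean across samples (genes with any zero count are
#' excluded from the reference) and the per-sample median of those ratios
#' is taken, then factors are rescaled to geometric mean 1. When no gene
#' is nonzero in every sample the function falls back to total-count
#' factors with a warning.
#'
#' @param cm a [count_matrix()], or a bare counts matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    if (any(tot == 0))
      stop("total-count fallback undefined: sample(s) with zero total: ",
           paste(colnames(counts)[tot == 0], collapse = ", "))
    sf <- tot
  } else {
    ref <- counts[pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    sf <- apply(ref / geo, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Call differentially expressed genes for one contrast
#'
#' Per-gene negative-binomial Wald test between two conditions, with the
#' study's DEG filter: a gene is called `up` (or `down`) when its raw
#' |log2 fold change| exceeds `lfc_threshold` (strict, i.e. more than
#' 2-fold at the default) AND its Benjamini-Hochberg adjusted p-value is
#' strictly below `alpha`.
#'
#' The test is a documented stand-in for a full NB GLM framework:
#' normalized group means with a 0.5 pseudocount give the fold change;
#' per-gene dispersions come from a method-of-moments estimate floored at
#' 1e-8 and shrunk toward the mean dispersion of genes of similar
#' expression (simple binned trend); the Wald statistic uses a normal
#' approximation for the two-sided p-value. Genes with zero counts in
#' every sample of the contrast are excluded from testing and from the BH
#' family.
#'
#' @param cm a [count_matrix()].
#' @param contrast length-2 character vector `c(condition, reference)`:
#'   fold changes are condition over reference.
#' @param lfc_threshold log2 fold-change threshold (default 1, i.e.
#'   2-fold).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param shrink_weight weight of the binned trend in the dispersion
#'   shrinkage, in \[0, 1\].
#' @return data.frame of class `de_table` with columns `gene`, `mean_a`,
#'   `mean_b` (normalized means of condition and reference), `log2fc`,
#'   `pvalue`, `padj`, `direction` (`up`/`down`/`ns`); attributes
#'   `contrast`, `lfc_threshold`, `alpha`.
#' @export
call_degs <- function(cm, contrast, lfc_threshold = 1, alpha = 0.05,
                      shrink_weight = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2L)
  cond_a <- contrast[1]
  cond_b <- contrast[2]
  if (cond_a == cond_b)
    stop("contrast of a condition with itself: ", cond_a)
  for (cond in c(cond_a, cond_b))
    if (!cond %in% cm$samples$condition)
      stop("unknown condition label: ", cond)
  sel <- cm$samples$condition %in% c(cond_a, cond_b)
  counts <- cm$counts[, sel, drop = FALSE]
  grp <- cm$samples$condition[sel]
  if (min(table(grp)) < 2L)
    warning("fewer than 2 replicates in a group; p-values are unreliable")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- grp == cond_a
  b <- grp == cond_b
  qa <- rowMeans(norm[, a, drop = FALSE])
  qb <- rowMeans(norm[, b, drop = FALSE])
  log2fc <- log2((qa + 0.5) / (qb + 0.5))

  tested <- rowSums(counts) > 0
  disp <- .shrunk_dispersion(norm, counts, grp, sf, tested, shrink_weight)

  var_q <- function(q, idx) {
    s <- sf[idx]
    rowSums(outer(q, 1 / s) + disp * q^2) / sum(idx)^2
  }
  ln2sq <- log(2)^2
  se2 <- var_q(qa, a) / ((qa + 0.5)^2 * ln2sq) +
         var_q(qb, b) / ((qb + 0.5)^2 * ln2sq)
  z <- log2fc / sqrt(se2)
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue[!tested] <- NA_real_
  padj <- rep(NA_real_, length(pvalue))
  padj[tested] <- stats::p.adjust(pvalue[tested], method = "BH")

  direction <- rep("ns", nrow(counts))
  direction[tested & log2fc > lfc_threshold & padj < alpha] <- "up"
  direction[tested & log2fc < -lfc_threshold & padj < alpha] <- "down"

  structure(
    data.frame(gene = rownames(counts), mean_a = qa, mean_b = qb,
               log2fc = log2fc, pvalue = pvalue, padj = padj,
               direction = direction,
               row.names = NULL, stringsAsFactors = FALSE),
    contrast = c(cond_a, cond_b), lfc_threshold = lfc_threshold,
    alpha = alpha, class = c("de_table", "data.frame"))
}

# Method-of-moments NB dispersion per gene, pooled over the two groups,
# floored at 1e-8 and shrunk toward a 20-bin mean-expression trend.
.shrunk_dispersion <- function(norm, counts, grp, sf, tested, shrink_weight) {
  groups <- unique(grp)
  num <- 0
  den <- 0
  base <- rowMeans(norm)
  for (g in groups) {
    idx <- grp == g
    ni <- sum(idx)
    if (ni < 2L) next
    q <- rowMeans(norm[, idx, drop = FALSE])
    s2 <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    shot <- q * mean(1 / sf[idx])
    a_hat <- (s2 - shot) / pmax(q^2, 1e-12)
    num <- num + (ni - 1) * a_hat
    den <- den + (ni - 1)
  }
  raw <- if (den > 0) pmax(num / den, 1e-8) else rep(0.1, nrow(norm))
  n_bins <- max(1L, min(20L, floor(sum(tested) / 50)))
  bin <- rep(1L, length(raw))
  if (n_bins > 1L)
    bin[tested] <- as.integer(cut(rank(base[tested], ties.method = "first"),
                                  breaks = n_bins, labels = FALSE))
  trend <- stats::ave(raw, bin, FUN = mean)
  pmax((1 - shrink_weight) * raw + shrink_weight * trend, 1e-8)
}

#' Import an externally produced differential-expression table
#'
#' Accepts a pre-made per-gene table (e.g. from another DE tool) with
#' columns `gene`, `log2fc`, `padj` and applies the same direction filter
#' as [call_degs()].
#'
#' @param path TSV file with columns `gene`, `log2fc`, `padj` (extra
#'   columns are kept).
#' @param contrast length-2 character vector recorded on the result.
#' @param lfc_threshold,alpha the DEG filter thresholds.
#' @return a `de_table` data.frame.
#' @export
import_de <- function(path, contrast = c(NA_character_, NA_character_),
                      lfc_threshold = 1, alpha = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("imported DE table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("duplicate gene id in imported DE table")
  df$direction <- "ns"
  ok <- !is.na(df$padj)
  df$direction[ok & df$log2fc > lfc_threshold & df$padj < alpha] <- "up"
  df$direction[ok & df$log2fc < -lfc_threshold & df$padj < alpha] <- "down"
  structure(df, contrast = contrast, lfc_threshold = lfc_threshold,
            alpha = alpha, class = c("de_table", "data.frame"))
}

#' Write a DE table to TSV
#'
#' @param de a `de_table`.
#' @param path output path.
#' @param digits decimals for floating-point columns.
#' @return invisibly, `de`.
#' @export
write_de <- function(de, path, digits = 6) {
  out <- de
  for (col in c("mean_a", "mean_b", "log2fc", "pvalue", "padj"))
    if (col %in% names(out))
      out[[col]] <- formatC(out[[col]], format = "g", digits = digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}
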