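# Shared fixtures and independent oracles used across test files.

make_counts <- function(counts, conditions, replicates = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (is.null(replicates))
    replicates <- stats::ave(seq_along(conditions), conditions,
                             FUN = seq_along)
  count_matrix(counts,
               data.frame(sample_id = colnames(counts),
                          condition = conditions,
                          replicate = replicates))
}

# Brute-force Benjamini-Hochberg step-up, written independently of
# stats::p.adjust: find the largest i with p_(i) <= i*q/m by scanning,
# then report the monotone adjusted values.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Brute-force O(n^3) average-linkage agglomeration returning the
# cophenetic distance matrix, which identifies the tree uniquely when
# merge heights are distinct.
bf_average_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  D <- d
  diag(D) <- Inf
  while (length(groups) > 1L) {
    idx <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    h <- D[i, j]
    coph[groups[[i]], groups[[j]]] <- h
    coph[groups[[j]], groups[[i]]] <- h
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- D[, i] <- newrow
    D[i, i] <- Inf
    groups[[i]] <- c(groups[[i]], groups[[j]])
    D <- D[-j, -j, drop = FALSE]
    groups[[j]] <- NULL
  }
  coph
}

# Exact hypergeometric upper tail P(X >= k).
hyper_upper_tail <- function(k, K, M, n) {
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

# Expression matrix with three planted anti-correlated template profiles.
planted_templates_expr <- function(n_per = 10, noise_sd = 0.1, seed = 5) {
  templates <- rbind(c(3, 3, 0, 0, 0, 0),
                     c(0, 0, 3, 3, 0, 0),
                     c(0, 0, 0, 0, 3, 3))
  set.seed(seed)
  x <- templates[rep(1:3, each = n_per), ] +
    matrix(stats::rnorm(3 * n_per * 6, 0, noise_sd), 3 * n_per, 6)
  dimnames(x) <- list(sprintf("g%02d", seq_len(3 * n_per)),
                      c("0w", "4w", "8w", "12w", "16w", "21w"))
  list(expr = x, membership = rep(1:3, each = n_per))
}
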