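test_that("condition means apply normalization, pseudocount and replicate averaging", {
  m <- matrix(c(3L, 3L, 3L), 1, 3, dimnames = list("g1", c("s1", "s2", "s3")))
  cm <- make_counts(m, rep("0w", 3))
  expr <- condition_means(cm, sf = c(1, 1, 1))
  expect_equal(unname(expr["g1", "0w"]), log2(4))

  m2 <- matrix(c(0L, 0L), 1, 2, dimnames = list("g1", c("s1", "s2")))
  cm2 <- make_counts(m2, rep("0w", 2))
  expect_equal(unname(condition_means(cm2, sf = c(1, 1))["g1", "0w"]), 0)

  cfg <- sim_config(n_genes = 100, conditions = c("0w", "4w", "21w"),
                    seed = 3, hormone_sets = default_hormone_sets(10))
  cm3 <- simulate_dataset(cfg)$counts
  sf <- size_factors(cm3)
  e1 <- condition_means(cm3, sf = sf)
  cm4 <- cm3
  cm4$counts <- cm4$counts * 2L
  e2 <- condition_means(cm4, sf = 2 * sf)
  expect_equal(e1, e2)
  expect_equal(colnames(e1), c("0w", "4w", "21w"))
})

test_that("gene selection applies both spread criteria conjunctively", {
  x <- rbind(flat = c(1, 1, 1),
             strong = c(0, 1, 3.5),
             partial = c(0, 1, 2.5))
  colnames(x) <- c("0w", "4w", "21w")
  expect_equal(select_clustering_genes(x), "strong")
  # lowering range_min admits the gene passing only the fold-change rule
  expect_setequal(select_clustering_genes(x, range_min = 2),
                  c("strong", "partial"))
  expect_error(select_clustering_genes(x, lfc_min = -1), "non-negative")
})

test_that("gene selection is monotone in both thresholds", {
  set.seed(15)
  x <- matrix(rnorm(300 * 6, sd = 2), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300),
                              c("0w", "4w", "8w", "12w", "16w", "21w")))
  for (l in c(0, 1, 2, 3))
    expect_true(all(select_clustering_genes(x, l + 0.5, 0) %in%
                    select_clustering_genes(x, l, 0)))
  for (r in c(0, 1.5, 3))
    expect_true(all(select_clustering_genes(x, 0, r + 0.5) %in%
                    select_clustering_genes(x, 0, r)))
})

test_that("perfectly correlated and anti-correlated pairs cluster as expected", {
  x <- rbind(g1 = c(0, 1, 2, 3), g2 = c(1, 2, 3, 4))
  colnames(x) <- c("0w", "4w", "8w", "12w")
  model <- cluster_genes(x, c("g1", "g2"))
  expect_equal(1 - model$tree$height, 1)
  expect_equal(unname(model$clusters), c(1L, 1L))

  y <- rbind(g1 = c(0, 1, 2, 3), g2 = c(3, 2, 1, 0))
  colnames(y) <- colnames(x)
  model2 <- cluster_genes(y, c("g1", "g2"))
  expect_equal(1 - model2$tree$height, -1)
  expect_equal(length(unique(model2$clusters)), 2L)
})

test_that("a planted three-template partition is recovered exactly at cut 0.7", {
  pl <- planted_templates_expr(n_per = 10, noise_sd = 0.1, seed = 5)
  model <- cluster_genes(pl$expr, rownames(pl$expr), cut_corr = 0.7)
  cl <- model$clusters[rownames(pl$expr)]
  expect_equal(length(unique(cl)), 3L)
  # identical partition up to label permutation
  expect_equal(length(unique(paste(cl, pl$membership))), 3L)
})

test_that("clustering is invariant to gene input order", {
  pl <- planted_templates_expr(n_per = 5, seed = 8)
  g <- rownames(pl$expr)
  a <- cluster_genes(pl$expr, g)
  set.seed(2)
  b <- cluster_genes(pl$expr, sample(g))
  expect_identical(a$genes, b$genes)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$tree$merge, b$tree$merge)
  expect_identical(a$tree$height, b$tree$height)
})

test_that("the average-linkage tree matches a brute-force agglomeration oracle", {
  set.seed(23)
  for (rep in 1:3) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 7), n, 7,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("c%d", 1:7)))
    model <- cluster_genes(x, rownames(x))
    d <- 1 - stats::cor(t(x))
    coph_oracle <- bf_average_cophenetic(d)
    coph_impl <- as.matrix(stats::cophenetic(model$tree))
    expect_equal(unname(coph_impl), unname(coph_oracle), tolerance = 1e-10)
  }
})

test_that("normalized rows are centered with unit sum of squares", {
  pl <- planted_templates_expr(n_per = 6, seed = 12)
  model <- cluster_genes(pl$expr, rownames(pl$expr))
  expect_lt(max(abs(rowMeans(model$normalized))), 1e-10)
  expect_equal(unname(rowSums(model$normalized^2)),
               rep(1, nrow(model$normalized)))
})

test_that("zero-variance genes are excluded with a warning, never silently", {
  x <- rbind(g1 = c(0, 1, 2, 3), g2 = c(1, 2, 3, 4), g3 = c(2, 2, 2, 2))
  colnames(x) <- c("0w", "4w", "8w", "12w")
  expect_warning(model <- cluster_genes(x, rownames(x)), "zero-variance")
  expect_equal(model$excluded, "g3")
  expect_setequal(model$genes, c("g1", "g2"))
})

test_that("cluster mean profiles are member means of centered profiles", {
  pl <- planted_templates_expr(n_per = 4, seed = 3)
  model <- cluster_genes(pl$expr, rownames(pl$expr))
  mp <- cluster_mean_profiles(model)
  expect_identical(mp, model$mean_profiles)
  # means of centered members are centered
  expect_lt(max(abs(rowMeans(mp))), 1e-10)
  for (cl in unique(model$clusters)) {
    members <- names(model$clusters)[model$clusters == cl]
    expect_equal(unname(mp[as.character(cl), ]),
                 unname(colMeans(model$normalized[members, , drop = FALSE])))
  }

  # a singleton cluster's profile is the gene's own normalized profile
  y <- rbind(g1 = c(0, 1, 2, 3), g2 = c(0, 1.1, 2, 3.2), g3 = c(3, 2, 1, 0))
  colnames(y) <- colnames(pl$expr)[1:4]
  m2 <- cluster_genes(y, rownames(y), cut_corr = 0.9)
  singleton <- names(which(table(m2$clusters) == 1))
  gene <- names(m2$clusters)[m2$clusters == singleton]
  expect_equal(unname(m2$mean_profiles[singleton, ]),
               unname(m2$normalized[gene, ]))

  # mirror-image profiles average to the zero profile
  z <- rbind(g1 = c(0, 1, 2, 3), g2 = c(3, 2, 1, 0))
  colnames(z) <- colnames(y)
  m3 <- cluster_genes(z, rownames(z), k = 1)
  expect_equal(unname(m3$mean_profiles["1", ]), rep(0, 4))
})
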