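test_that("the enrichment index obeys its closed-form identities", {
  expect_identical(enrichment_index(k = 4, K = 10, n = 20, M = 100), 2)
  # DEG list equal to the universe forces E = 1
  expect_identical(enrichment_index(k = 10, K = 10, n = 100, M = 100), 1)
  expect_identical(enrichment_index(k = 0, K = 10, n = 20, M = 100), 0)

  e <- enrichment_index(k = 0, K = 0, n = 20, M = 100)
  expect_true(is.na(e))
  expect_equal(attr(e, "reason"), "K = 0")
  e <- enrichment_index(k = 0, K = 10, n = 0, M = 100)
  expect_true(is.na(e))
  expect_equal(attr(e, "reason"), "n = 0")
  expect_error(enrichment_index(k = 11, K = 10, n = 20, M = 100),
               "invalid counts")
})

test_that("degenerate overlaps force the Monte Carlo p-value to 1", {
  uni <- sprintf("g%02d", 1:30)
  # empty observed overlap: every draw has intersection >= 0
  r <- mc_overlap_test(uni[21:25], uni[1:5], uni, n_perm = 50, seed = 1)
  expect_equal(r$k_obs, 0L)
  expect_equal(r$p_mc, 1)
  # DEG list = universe: intersection always equals the set size
  r <- mc_overlap_test(uni, uni[1:7], uni, n_perm = 50, seed = 1)
  expect_equal(r$k_obs, 7L)
  expect_equal(r$p_mc, 1)
})

test_that("the Monte Carlo p matches the exact hypergeometric tail", {
  uni <- sprintf("g%02d", 1:50)
  set <- uni[1:10]
  deg <- c(uni[1:7], uni[31:43])  # overlap 7 of 20 DEGs
  r <- mc_overlap_test(deg, set, uni, n_perm = 2e5, seed = 17)
  expect_equal(r$k_obs, 7L)
  p_exact <- hyper_upper_tail(7, K = 10, M = 50, n = 20)
  expect_lte(abs(r$p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2e5))
})

test_that("identical inputs and seed give bit-identical results", {
  uni <- sprintf("g%03d", 1:200)
  a <- mc_overlap_test(uni[1:40], uni[30:60], uni, n_perm = 500, seed = 5,
                       return_null = TRUE)
  b <- mc_overlap_test(uni[1:40], uni[30:60], uni, n_perm = 500, seed = 5,
                       return_null = TRUE)
  expect_identical(a, b)
  c <- mc_overlap_test(uni[1:40], uni[30:60], uni, n_perm = 500, seed = 6)
  expect_false(identical(a$p_mc, c$p_mc) && identical(a, c))
})

test_that("input validation names offenders and rejects bad n_perm", {
  uni <- sprintf("g%02d", 1:20)
  expect_error(mc_overlap_test(c(uni[1], "nope"), uni[1:5], uni, seed = 1),
               "nope")
  expect_error(mc_overlap_test(uni[1], uni[1:5], uni, n_perm = 0, seed = 1),
               "n_perm")
  expect_error(mc_overlap_test(uni[1], uni[1:5], character(0), seed = 1),
               "empty universe")
})

test_that("the index of a uniformly random DEG list has expectation 1", {
  set.seed(30)
  uni <- sprintf("g%04d", 1:2000)
  memb <- sample(uni, 200)
  E <- replicate(400, {
    deg <- sample(uni, 150)
    (length(intersect(deg, memb)) / 200) / (150 / 2000)
  })
  expect_lte(abs(mean(E) - 1), 3 * stats::sd(E) / sqrt(length(E)))
})

test_that("enrich_all excludes small sets, flags degenerate directions, and recovers a planted set", {
  hs <- default_hormone_sets(200)
  hs[[2]]$enrich <- data.frame(contrast = "21w", direction = "up",
                               factor = 2.0)
  hs[[9]] <- list(name = "strigolactone-like", go = "GO:0000000",
                  size = 7L, enrich = NULL)
  cfg <- sim_config(n_genes = 2000, conditions = c("0w", "21w"),
                    hormone_sets = hs, seed = 77)
  sim <- simulate_dataset(cfg)
  de <- call_degs(sim$counts, c("21w", "0w"))
  enr <- enrich_all(de, sim$sets, universe = de$gene, min_set_size = 8,
                    n_perm = 2000, seed = 77)

  # a 7-member set is reported excluded, not tested, not dropped
  small <- enr[enr$set_name == "strigolactone-like", ]
  expect_equal(nrow(small), 2L)
  expect_true(all(small$excluded))
  expect_true(all(is.na(small$p_mc)))
  expect_match(small$reason[1], "below minimum size")

  tested <- enr[!enr$excluded & !is.na(enr$E), ]
  # every record satisfies the index identity exactly
  expect_equal(tested$E, (tested$k * tested$M) / (tested$K * tested$n))
  up <- tested[tested$direction == "up", ]
  planted <- up[up$set_name == "response to auxin", ]
  expect_equal(planted$E, max(up$E))
  expect_lt(planted$p_mc, 0.05)
  expect_true(planted$significant)

  # reruns are bit-identical
  enr2 <- enrich_all(de, sim$sets, universe = de$gene, min_set_size = 8,
                     n_perm = 2000, seed = 77)
  expect_identical(enr, enr2)
})

test_that("a direction with zero DEGs yields an undefined record, not a zero", {
  m <- cbind(a1 = c(5L, 9L), a2 = c(6L, 8L), b1 = c(5L, 9L), b2 = c(6L, 8L))
  rownames(m) <- c("g1", "g2")
  cm <- make_counts(m, c("0w", "0w", "21w", "21w"))
  de <- call_degs(cm, c("21w", "0w"))
  sets <- gene_sets(list(s = c("g1", "g2")))
  enr <- enrich_all(de, sets, universe = c(de$gene, sprintf("x%d", 1:20)),
                    min_set_size = 2, n_perm = 100, seed = 1)
  expect_true(all(is.na(enr$E)))
  expect_true(all(grepl("n = 0", enr$reason)))
})
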