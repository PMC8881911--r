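test_that("estimator returns the generating bias exactly on noiseless data", {
  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(10)
  for (i in 1:5) {
    B <- rand_bias(design$taxon)
    counts <- noiseless_counts(expd, B, n_samples = 8)
    est <- estimate_bias(counts, toy_meta(8), design)
    expect_equal(est$efficiency, recenter(B)[names(est$efficiency)],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # observed = expected gives the all-ones vector
  ones <- estimate_bias(noiseless_counts(expd, setNames(rep(1, 16),
                                                        design$taxon), 4),
                        toy_meta(4), design)
  expect_equal(unname(ones$efficiency), rep(1, 16), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("point estimate is the per-taxon geometric mean of sample errors", {
  design <- tibble::tibble(taxon = c("a", "b", "c"), pool_1 = c(1L, 1L, 1L))
  expd <- expected_composition(design, 1)
  counts <- cbind(
    s1 = close_composition(expd * c(2, 1, 0.5)) * 1000,
    s2 = close_composition(expd * c(8, 1, 0.125)) * 1000
  )
  rownames(counts) <- design$taxon
  est <- estimate_bias(counts, toy_meta(2), design)
  # gm of (2,8), (1,1), (0.5,0.125) = (4, 1, 0.25); already centered
  expect_equal(unname(est$efficiency), c(4, 1, 0.25), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("estimates are invariant to per-sample depth and global bias scale", {
  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(11)
  B <- rand_bias(design$taxon)
  counts <- noisy_counts(expd, B, n_samples = 6, depth = 50000)
  meta <- toy_meta(6)
  est <- estimate_bias(counts, meta, design)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7.3
  expect_equal(estimate_bias(scaled, meta, design)$efficiency,
               est$efficiency, tolerance = 1e-12)
  # multiplying every taxon's true bias by a constant changes nothing
  counts2 <- noiseless_counts(expd, B, 4)
  counts3 <- noiseless_counts(expd, B * 3, 4)
  expect_equal(estimate_bias(counts2, toy_meta(4), design)$efficiency,
               estimate_bias(counts3, toy_meta(4), design)$efficiency,
               tolerance = 1e-9)
})

test_that("taxa observed nowhere are excluded with a warning and registered", {
  design <- toy_design(4)
  expd <- expected_composition(design, 1)
  counts <- noiseless_counts(expd, setNames(rep(1, 4), design$taxon), 3)
  counts["t2", ] <- 0
  expect_warning(est <- estimate_bias(counts, toy_meta(3), design),
                 "observed in no sample")
  expect_false("t2" %in% names(est$efficiency))
  expect_equal(sort(unique(est$dropouts$taxon)), "t2")
  expect_equal(nrow(est$dropouts), 3)
  expect_true(is_centered(est$efficiency))
})

test_that("bootstrap is deterministic and degrades gracefully", {
  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(12)
  counts <- noisy_counts(expd, rand_bias(design$taxon), 8, 20000)
  meta <- toy_meta(8)
  b1 <- bootstrap_bias(counts, meta, design, n_boot = 50, seed = 42)
  b2 <- bootstrap_bias(counts, meta, design, n_boot = 50, seed = 42)
  expect_identical(b1$log_replicates, b2$log_replicates)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_bias(counts, meta, design, n_boot = 50, seed = 43)
  expect_false(identical(b3$log_replicates, b1$log_replicates))

  expect_equal(unname(bootstrap_bias(counts, meta, design, n_boot = 1,
                                     seed = 1)$se_log),
               rep(0, 16))
  one <- counts[, 1, drop = FALSE]
  expect_warning(
    s1 <- bootstrap_bias(one, meta[1, ], design, n_boot = 20, seed = 1),
    "single sample")
  expect_equal(unname(s1$se_log), rep(0, 16))
})

test_that("bootstrap intervals cover the true bias at roughly nominal rate", {
  # percentile bootstrap with 24 samples: coverage close to, but a little
  # under, the nominal 95%
  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(13)
  inside <- total <- 0
  for (s in 1:60) {
    B <- rand_bias(design$taxon)
    counts <- noisy_counts(expd, B, 24, 20000)
    est <- bootstrap_bias(counts, toy_meta(24), design, n_boot = 200,
                          seed = s)
    tr <- recenter(B)[rownames(est$ci)]
    inside <- inside + sum(tr >= est$ci[, "lo95"] & tr <= est$ci[, "hi95"])
    total <- total + nrow(est$ci)
  }
  expect_gt(inside / total, 0.87)
  expect_lt(inside / total, 0.99)
})

test_that("estimation error shrinks with sequencing depth", {
  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(14)
  rmse_at <- function(depth) {
    mean(vapply(1:30, function(i) {
      B <- rand_bias(design$taxon)
      counts <- noisy_counts(expd, B, 8, depth)
      est <- estimate_bias(counts, toy_meta(8), design)
      sqrt(mean((log(est$efficiency) -
                   log(recenter(B)[names(est$efficiency)]))^2))
    }, numeric(1)))
  }
  expect_lt(rmse_at(2e5), rmse_at(2e3))
})

test_that("predicted compositions close the loop with the estimator", {
  expect_equal(predict_composition(c(a = 0.5, b = 0.5), c(a = 1, b = 1)),
               c(a = 0.5, b = 0.5))
  expect_equal(predict_composition(c(a = 0.5, b = 0.5), c(a = 3, b = 1)),
               c(a = 0.75, b = 0.25))
  expect_error(predict_composition(c(a = 0.5, b = 0.5), c(a = 1, z = 1)),
               "same taxa")

  design <- toy_design()
  expd <- expected_composition(design, 1)
  set.seed(15)
  B <- rand_bias(design$taxon)
  counts <- noiseless_counts(expd, B, 4)
  est <- estimate_bias(counts, toy_meta(4), design)
  pred <- predict_composition(expd, est$efficiency)
  observed <- close_composition(counts[, 1])
  expect_equal(rmse_composition(pred, observed), 0, tolerance = 1e-8)
})
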