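test_that("trait design matrix reproduces the packaged trait values", {
  traits <- insect_traits_fixture()
  design <- mock_design_fixture()
  X <- build_trait_design(traits, design$taxon, "fwhF2-fwhR2n")
  expect_equal(dim(X), c(16, 6))
  expect_equal(colnames(X), c("soft", "intermediate", "hard", "log_volume",
                              "mismatch", "gc"))
  # spot checks against the packaged table
  cd <- X["Carpophilus davidsoni", ]
  expect_equal(unname(cd[c("soft", "intermediate", "hard")]), c(0, 0, 1))
  expect_equal(unname(cd["mismatch"]), 0.12 + 0.09)
  expect_equal(unname(cd["gc"]), 0.37)
  expect_equal(unname(cd["log_volume"]), log(3.80))
  expect_equal(unname(X["Rhopalosiphum padi", "soft"]), 1)
  # every taxon sits in exactly one hardness level
  expect_equal(unname(rowSums(X[, 1:3])), rep(1, 16))
  # hexCOIR4 reverse mismatches differ where the table says so
  X2 <- build_trait_design(traits, design$taxon, "fwhF2-HexCOIR4")
  expect_equal(unname(X2["Drosophila hydei", "mismatch"]), 0.04 + 0.06)
  expect_error(build_trait_design(traits, c(design$taxon, "nope"),
                                  "fwhF2-fwhR2n"), "missing")
})

test_that("design encodings behave: dummies, volume column, reference level", {
  tr <- tibble::tibble(
    taxon = paste0("t", 1:4), primer = "p",
    fwd_mismatch = c(0, 0.1, 0, 0), rev_mismatch = 0,
    gc = c(0.3, 0.3, 0.4, 0.3), volume_mm3 = c(1, 1, 1, 5),
    hardness = c(1L, 1L, 1L, 1L))
  X <- build_trait_design(tr, tr$taxon, "p")
  expect_equal(unname(X[, "hard"]), rep(0, 4))
  expect_equal(unname(X[, "intermediate"]), rep(0, 4))
  # volume-only difference shows up only in the volume column
  d <- X["t4", ] - X["t1", ]
  expect_equal(unname(d[names(d) != "log_volume"]), rep(0, 5))
  expect_equal(unname(d["log_volume"]), log(5))
  Xref <- build_trait_design(tr, tr$taxon, "p",
                             encoding = "intercept_reference")
  expect_false("hard" %in% colnames(Xref))
  Xraw <- build_trait_design(tr, tr$taxon, "p", log_volume = FALSE)
  expect_equal(unname(Xraw[, "volume"]), tr$volume_mm3)
})

test_that("the OLS fit recovers noiseless coefficients and matches the
           normal-equations oracle", {
  traits <- insect_traits_fixture()
  design <- mock_design_fixture()
  X <- build_trait_design(traits, design$taxon, "fwhF2-fwhR2n")
  beta <- c(soft = 0.5, intermediate = 0.2, hard = -0.7, log_volume = 0.3,
            mismatch = -2, gc = 1.5)
  y <- drop(X %*% beta)
  # a zero-residual fit: lm's perfect-fit advisory is expected here
  fit <- suppressWarnings(fit_trait_model(setNames(y, rownames(X)), X))
  expect_equal(setNames(fit$coefficients$estimate_log,
                        fit$coefficients$term), beta, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$coefficients$estimate, exp(fit$coefficients$estimate_log))

  set.seed(30)
  ynoisy <- y + stats::rnorm(16, 0, 0.3)
  fit2 <- fit_trait_model(setNames(ynoisy, rownames(X)), X)
  oracle <- drop(solve(crossprod(X), crossprod(X, ynoisy)))
  expect_equal(fit2$coefficients$estimate_log, unname(oracle),
               tolerance = 1e-8)
  # residuals orthogonal to every design column
  r <- ynoisy - drop(X %*% oracle)
  expect_lt(max(abs(crossprod(X, r))), 1e-8 * 16)
  expect_equal(fit2$n, 16)
  expect_equal(fit2$df1 + fit2$df2, 16)
})

test_that("the intercept/reference encoding reports 5 model df", {
  traits <- insect_traits_fixture()
  design <- mock_design_fixture()
  X <- build_trait_design(traits, design$taxon, "fwhF2-fwhR2n",
                          encoding = "intercept_reference")
  set.seed(31)
  y <- setNames(stats::rnorm(16), rownames(X))
  fit <- fit_trait_model(y, X)
  expect_equal(fit$df1, 5)
  expect_equal(fit$df2, 10)
  expect_true("(Intercept)" %in% fit$coefficients$term)
})

test_that("rank-deficient designs fail loudly, naming the culprit", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, 0, 1, 0))
  attr(X, "encoding") <- "hardness_levels"
  rownames(X) <- paste0("t", 1:4)
  expect_error(fit_trait_model(setNames(rnorm(4), rownames(X)), X), "b")
})

test_that("bootstrap CIs collapse on identical replicates and are
           deterministic", {
  traits <- insect_traits_fixture()
  design <- mock_design_fixture()
  X <- build_trait_design(traits, design$taxon, "fwhF2-fwhR2n")
  set.seed(32)
  eff <- rand_bias(design$taxon, 0.5)
  reps <- matrix(rep(log(recenter(eff)), 20), ncol = 20,
                 dimnames = list(design$taxon, NULL))
  est <- fake_estimate(eff, reps = reps)
  fit <- bootstrap_trait_cis(est, X)
  expect_equal(fit$coefficients$ci_lo, fit$coefficients$ci_hi,
               tolerance = 1e-12)
  expect_equal(fit$coefficients$ci_lo, fit$coefficients$estimate,
               tolerance = 1e-9)
  # same inputs, same intervals
  fit2 <- bootstrap_trait_cis(est, X)
  expect_identical(fit$coefficients, fit2$coefficients)
  one <- fake_estimate(eff, reps = reps[, 1, drop = FALSE])
  expect_error(bootstrap_trait_cis(one, X), "2 bootstrap replicates")
})

test_that("stacking estimates over primers concatenates observations", {
  traits <- insect_traits_fixture()
  design <- mock_design_fixture()
  X1 <- build_trait_design(traits, design$taxon, "fwhF2-fwhR2n")
  X2 <- build_trait_design(traits, design$taxon, "fwhF2-HexCOIR4")
  set.seed(33)
  y1 <- rand_bias(design$taxon); y2 <- rand_bias(design$taxon)
  fit <- fit_trait_model(list(log(y1), log(y2)), list(X1, X2))
  expect_equal(fit$n, 32)
  oracle <- drop(solve(crossprod(rbind(X1, X2)),
                       crossprod(rbind(X1, X2), c(log(y1), log(y2)))))
  expect_equal(fit$coefficients$estimate_log, unname(oracle),
               tolerance = 1e-8)
})

test_that("mismatch proportions honour IUPAC degeneracy", {
  expect_equal(mismatch_proportion("ACGT", "ACGT"), 0)
  expect_equal(mismatch_proportion("GGD", "GGA"), 0) # D covers A/G/T
  expect_equal(mismatch_proportion("GGD", "GGC"), round(1 / 3, 2))
  # 26-nt primer with 3 incompatible positions, as in the fwhF2 column
  primer <- "GGDACWGGWTGAACWGTWTAYCCHCC"
  template <- "GGAACTGGATGAACTGTTTACCCACC"
  # position-by-position oracle
  map <- Biostrings::IUPAC_CODE_MAP
  pc <- strsplit(primer, "")[[1]]; tc <- strsplit(template, "")[[1]]
  manual <- mean(vapply(seq_along(pc), function(i) {
    !grepl(tc[i], map[[pc[i]]], fixed = TRUE)
  }, logical(1)))
  expect_equal(mismatch_proportion(primer, template), round(manual, 2))
  expect_equal(mismatch_proportion(primer, template), 0)
  # force three mismatching positions
  template3 <- paste0("CCC", substr(template, 4, 26))
  expect_equal(mismatch_proportion(primer, template3), 0.12) # 3/26
  expect_error(mismatch_proportion("ACGT", "ACG"), "equal")
  expect_error(mismatch_proportion("ACXT", "ACGT"), "non-IUPAC")
})

test_that("amplicon lengths use the end-minus-start convention", {
  expect_equal(amplicon_length(346, 551), 205)
  expect_equal(amplicon_length(346, 560), 214)
  expect_equal(amplicon_length(0, 0), 0)
  expect_error(amplicon_length(551, 346), ">=")
})
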