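test_that("the simulation is a pure function of its parameters", {
  p <- test_sim_params(seed = 5)
  a <- simulate_experiment(p)
  b <- simulate_experiment(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$extraction, b$truth$extraction)
  c <- simulate_experiment(test_sim_params(seed = 6))
  expect_false(identical(a$counts, c$counts))
})

test_that("ground-truth vectors are centered and follow the trait model", {
  p0 <- test_sim_params(
    seed = 2,
    extraction_coefs = list(
      quickextract = c(soft = 0, intermediate = 0, hard = 0,
                       log_volume = 0),
      dneasy = c(soft = 0, intermediate = 0, hard = 0, log_volume = 0)),
    noise_sd = c(extraction = 0, pcr = 0, sequencing = 0))
  tr0 <- simulate_bias_vectors(p0)
  expect_equal(unname(tr0$extraction$dneasy), rep(1, 16), tolerance = 1e-12)

  # zero noise: truth is exactly the centered design-matrix product
  p <- test_sim_params(seed = 3,
                       noise_sd = c(extraction = 0, pcr = 0,
                                    sequencing = 0))
  tru <- simulate_bias_vectors(p)
  primer <- names(p$pcr_coefs)[1]
  X <- build_trait_design(p$traits, p$design$taxon, primer)
  beta <- p$pcr_coefs[[primer]]
  oracle <- drop(X[, names(beta)] %*% beta)
  oracle <- exp(oracle - mean(oracle))
  expect_equal(unname(tru$pcr[[primer]]), unname(oracle),
               tolerance = 1e-12)
  # every stage vector centered; totals reconstruct from the product
  for (v in c(tru$extraction, tru$pcr, tru$sequencing)) {
    expect_true(is_centered(v))
  }
  tot <- tru$total$quickextract[[primer]]
  expect_equal(tot,
               recenter(tru$extraction$quickextract * tru$pcr[[primer]] *
                          tru$sequencing[[primer]]),
               tolerance = 1e-12)
})

test_that("counts respect depth, metadata structure and factor sharing", {
  p <- sim_params(depth_mean = 5000, depth_sd = 0, seed = 9, runs = 2)
  sim <- simulate_experiment(p)
  # depth_sd = 0: every sample sums to exactly the mean depth
  expect_true(all(colSums(sim$counts) == 5000))
  expect_equal(ncol(sim$counts), nrow(sim$meta))
  # 2 protocols x 2 primers x 2 runs x 4 pools insect samples,
  # plus 2 stages x 2 primers x 2 runs x 8 pools shared dna/pcr samples
  expect_equal(sum(sim$meta$stage == "insect"), 32)
  expect_equal(sum(sim$meta$stage == "dna"), 32)
  expect_equal(sum(sim$meta$stage == "pcr"), 32)
  expect_true(all(sim$meta$extraction[sim$meta$stage != "insect"] ==
                    "none"))
  expect_true(all(sim$meta$pool[sim$meta$extraction == "quickextract"]
                  %in% 1:4))
  expect_true(all(sim$meta$pool[sim$meta$extraction == "dneasy"] %in% 5:8))
  # taxa absent from a pool receive no reads
  absent <- sim$meta$sample_id[sim$meta$pool == 1]
  expect_true(all(sim$counts["Bradysia nr. ocellaris", absent] == 0))
})

test_that("empirical proportions converge to the generating composition", {
  p <- sim_params(depth_mean = 1e7, depth_sd = 0, seed = 11, runs = 1)
  sim <- simulate_experiment(p)
  s <- sim$meta$sample_id[1]
  phat <- sim$counts[, s] / sum(sim$counts[, s])
  ptrue <- sim$truth$compositions[, s]
  ok <- !is.na(ptrue)
  expect_lt(max(abs(phat[ok] - ptrue[ok])), 0.005)
  expect_true(all(phat[!ok] == 0))
})

test_that("bias at one stage leaves upstream-entry samples untouched", {
  base <- test_sim_params(seed = 7)
  tweaked_ext <- test_sim_params(
    seed = 7,
    extraction_coefs = list(
      quickextract = c(soft = 2, intermediate = -1, hard = 0,
                       log_volume = 1),
      dneasy = c(soft = -2, intermediate = 1, hard = 0, log_volume = -1)))
  a <- simulate_experiment(base)
  b <- simulate_experiment(tweaked_ext)
  dna_pcr <- a$meta$sample_id[a$meta$stage != "insect"]
  insect <- a$meta$sample_id[a$meta$stage == "insect"]
  expect_identical(a$counts[, dna_pcr], b$counts[, dna_pcr])
  expect_false(identical(a$counts[, insect], b$counts[, insect]))

  # changing the PCR step leaves only the amplicon (pcr) pools unchanged
  tweaked_pcr <- test_sim_params(
    seed = 7,
    pcr_coefs = lapply(base$pcr_coefs, function(b) b + 1 * (names(b) == "gc")))
  d <- simulate_experiment(tweaked_pcr)
  pcr_ids <- a$meta$sample_id[a$meta$stage == "pcr"]
  dna_ids <- a$meta$sample_id[a$meta$stage == "dna"]
  expect_identical(a$counts[, pcr_ids], d$counts[, pcr_ids])
  expect_false(identical(a$counts[, dna_ids], d$counts[, dna_ids]))
})

test_that("dropout and overdispersion knobs act as documented", {
  p <- sim_params(depth_mean = 2000, depth_sd = 0, dropout = 0.3,
                  seed = 13, runs = 1)
  sim <- simulate_experiment(p)
  expd_cells <- !is.na(sim$truth$compositions)
  zero_frac <- mean(sim$counts[expd_cells] == 0)
  expect_gt(zero_frac, 0.2) # ~30% of expected cells zeroed
  expect_lt(zero_frac, 0.4)

  po <- sim_params(depth_mean = 2000, depth_sd = 0, overdispersion = 50,
                   seed = 14, runs = 1)
  simo <- simulate_experiment(po)
  expect_true(all(colSums(simo$counts) == 2000))
  expect_error(sim_params(dropout = 1), "\\[0, 1\\)")
  expect_error(sim_params(depth_mean = -1), "positive")
})

test_that("fixtures round-trip through the writer", {
  dir <- withr::local_tempdir()
  p <- sim_params(depth_mean = 3000, depth_sd = 0, seed = 17, runs = 1)
  files <- write_fixture(dir, p)
  d <- read_design(files["design"])
  expect_equal(unname(colSums(as.matrix(d[grep("^pool_", names(d))]))),
               c(100, 100, 100, 100, 101, 100, 101, 100))
  expect_identical(d, p$design)
  expect_identical(read_traits(files["traits"]), p$traits)
  counts <- read_count_table(files["counts"])
  sim <- simulate_experiment(p)
  expect_equal(counts, sim$counts)
  expect_equal(read_meta(files["meta"]), sim$meta)
  # stored truth respects the product invariant
  tru <- jsonlite::read_json(files["truth"], simplifyVector = TRUE)
  for (prot in names(tru$total)) {
    for (pr in names(tru$total[[prot]])) {
      prod <- unlist(tru$extraction[[prot]]) * unlist(tru$pcr[[pr]]) *
        unlist(tru$sequencing[[pr]])
      expect_equal(unlist(tru$total[[prot]][[pr]]), recenter(prod),
                   tolerance = 1e-9)
    }
  }
})
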