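# shared in-code fixtures: no data files, everything built at test time

# single-pool design with the abundance spread of a realistic mock pool
toy_design <- function(k = 16) {
  counts <- c(25, 1, 1, 1, 1, 5, 1, 1, 1, 10, 1, 1, 1, 1, 36, 14)[seq_len(k)]
  tibble::tibble(taxon = paste0("t", seq_len(k)), pool_1 = counts)
}

toy_meta <- function(n, pool = 1, stage = "insect", extraction = "dneasy",
                     primer = "p1", run = 1) {
  tibble::tibble(sample_id = paste0("s", seq_len(n)), pool = pool,
                 stage = stage, extraction = extraction, primer = primer,
                 run = run)
}

# noiseless counts: exact biased proportions at a fixed notional depth
noiseless_counts <- function(expected, bias, n_samples, depth = 1e6) {
  props <- close_composition(expected * bias[names(expected)])
  m <- matrix(rep(props * depth, n_samples), ncol = n_samples,
              dimnames = list(names(props), paste0("s", seq_len(n_samples))))
  m
}

# multinomial counts around the biased composition
noisy_counts <- function(expected, bias, n_samples, depth) {
  props <- close_composition(expected * bias[names(expected)])
  m <- vapply(seq_len(n_samples), function(i) {
    drop(stats::rmultinom(1, depth, props))
  }, numeric(length(props)))
  dimnames(m) <- list(names(props), paste0("s", seq_len(n_samples)))
  m
}

rand_bias <- function(taxa, sd = 0.5) {
  b <- exp(stats::rnorm(length(taxa), 0, sd))
  names(b) <- taxa
  b
}

recenter <- function(e) exp(log(e) - mean(log(e)))

# minimal bias_estimate wrapper for partition-level unit tests
fake_estimate <- function(eff, reps = NULL) {
  eff <- recenter(eff)
  structure(
    list(efficiency = eff,
         se_log = stats::setNames(rep(0, length(eff)), names(eff)),
         ci = NULL, group = "synthetic", n_samples = NA_integer_,
         n_boot = if (is.null(reps)) 0L else ncol(reps),
         dropouts = tibble::tibble(sample_id = character(0),
                                   taxon = character(0)),
         log_errors = NULL, log_replicates = reps),
    class = "bias_estimate"
  )
}

# small, fast simulation profile used across tests
test_sim_params <- function(seed = 1, ...) {
  sim_params(depth_mean = 20000, depth_sd = 500, seed = seed, ...)
}
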