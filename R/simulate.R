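#' Parameters for a simulated mock-community experiment
#'
#' Defines the full three-stage design that the generator emulates: eight
#' mock pools entering the workflow as whole insects (extraction + PCR +
#' sequencing), as pooled genomic DNA (PCR + sequencing) or as pooled
#' amplicons (sequencing only), each amplified with two primer sets and
#' sequenced on replicate runs. Per-step taxon bias is trait-driven on the
#' log scale with lognormal taxon noise; counts are multinomial at a
#' normally distributed depth, optionally Dirichlet-overdispersed, with
#' optional per-cell dropout.
#'
#' Default depths mirror the per-sample scale of a MiSeq mock-community run
#' (mean 272,600 reads, sd 3,762). Default coefficients give extraction bias
#' favouring soft-bodied and (weakly) larger insects, and PCR bias driven by
#' primer mismatch (negative) and amplicon GC (positive), with a small
#' residual sequencing/bioinformatics step.
#'
#' @param design Mock design tibble (default: the packaged eight-pool
#'   design, [mock_design_fixture()]).
#' @param traits Trait table (default: [insect_traits_fixture()]).
#' @param extraction_coefs Named list per extraction protocol of log-scale
#'   coefficients over the morphological design columns
#'   (`soft`, `intermediate`, `hard`, `log_volume`).
#' @param pcr_coefs,seq_coefs Named lists per primer set of log-scale
#'   coefficients over the full design columns (additionally `mismatch`,
#'   `gc`).
#' @param noise_sd Lognormal taxon-noise standard deviation per step
#'   (named: `extraction`, `pcr`, `sequencing`).
#' @param depth_mean,depth_sd Normal sequencing-depth distribution (reads).
#' @param overdispersion Dirichlet precision for overdispersed counts
#'   (`Inf` = plain multinomial, the default).
#' @param dropout Per taxon-sample probability of post-draw zeroing,
#'   in \[0, 1).
#' @param runs Replicate sequencing runs per pool (default 2).
#' @param protocol_pools Named list mapping each extraction protocol to the
#'   pool ids processed with it.
#' @param seed Master seed; the whole simulation is a pure function of the
#'   parameter object.
#' @return A `sim_params` list.
#' @export
sim_params <- function(design = mock_design_fixture(),
                       traits = insect_traits_fixture(),
                       extraction_coefs = list(
                         quickextract = c(soft = 0.8, intermediate = 0.4,
                                          hard = -0.6, log_volume = 0.35),
                         dneasy = c(soft = 0.7, intermediate = 0.4,
                                    hard = -0.5, log_volume = 0.3)
                       ),
                       pcr_coefs = NULL,
                       seq_coefs = NULL,
                       noise_sd = c(extraction = 0.2, pcr = 0.2,
                                    sequencing = 0.2),
                       depth_mean = 272600,
                       depth_sd = 3762,
                       overdispersion = Inf,
                       dropout = 0,
                       runs = 2,
                       protocol_pools = list(quickextract = 1:4,
                                             dneasy = 5:8),
                       seed = 1) {
  primers <- unique(traits$primer)
  default_pcr <- c(soft = 0, intermediate = 0, hard = 0, log_volume = -0.1,
                   mismatch = -3, gc = 3)
  default_seq <- c(soft = 0, intermediate = 0, hard = 0, log_volume = 0,
                   mismatch = -0.5, gc = 0.5)
  if (is.null(pcr_coefs)) {
    pcr_coefs <- setNames(rep(list(default_pcr), length(primers)), primers)
  }
  if (is.null(seq_coefs)) {
    seq_coefs <- setNames(rep(list(default_seq), length(primers)), primers)
  }
  check_traits(traits)
  if (depth_mean <= 0) abort("`depth_mean` must be positive.")
  if (depth_sd < 0) abort("`depth_sd` must be non-negative.")
  if (any(noise_sd < 0)) abort("`noise_sd` entries must be non-negative.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  runs <- check_scalar_count(runs, "runs")
  if (!setequal(names(pcr_coefs), primers) ||
      !setequal(names(seq_coefs), primers)) {
    abort("`pcr_coefs` and `seq_coefs` must be named by the trait-table primers.")
  }
  structure(
    list(design = design, traits = traits,
         extraction_coefs = extraction_coefs,
         pcr_coefs = pcr_coefs, seq_coefs = seq_coefs,
         noise_sd = noise_sd, depth_mean = depth_mean, depth_sd = depth_sd,
         overdispersion = overdispersion, dropout = dropout, runs = runs,
         protocol_pools = protocol_pools, seed = check_seed(seed)),
    class = "sim_params"
  )
}

#' Draw the ground-truth bias vectors
#'
#' For each workflow step the true log bias is the trait design matrix times
#' that step's coefficient vector plus lognormal taxon noise, geometrically
#' centered. Extraction truth is per protocol (morphological traits only);
#' PCR and sequencing truths are per primer set. The RNG stream order is:
#' protocols in list order (extraction noise), then primers in trait-table
#' order (PCR noise, then sequencing noise).
#'
#' @param params A [sim_params()] object.
#' @param seed Seed for the noise draws; defaults to the master seed.
#' @return A `ground_truth` list: centered `extraction` (per protocol),
#'   `pcr` and `sequencing` (per primer) efficiency vectors, and `total`
#'   (per protocol x primer) equal to the re-centered product.
#' @export
simulate_bias_vectors <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(check_seed(seed), draw_bias_vectors(params))
}

draw_bias_vectors <- function(params) {
  taxa <- params$design$taxon
  primers <- names(params$pcr_coefs)
  Xs <- lapply(primers, function(pr) {
    build_trait_design(params$traits, taxa, pr, encoding = "hardness_levels")
  })
  names(Xs) <- primers

  step_truth <- function(X, coefs, sd) {
    missing <- setdiff(names(coefs), colnames(X))
    if (length(missing)) {
      abort(paste0("unknown coefficient name(s): ",
                   paste(missing, collapse = ", ")))
    }
    lb <- drop(X[, names(coefs), drop = FALSE] %*% coefs) +
      rnorm(nrow(X), 0, sd)
    center_log(setNames(lb, rownames(X)))
  }

  extraction <- lapply(params$extraction_coefs, function(b) {
    step_truth(Xs[[1]], b, params$noise_sd[["extraction"]])
  })
  pcr <- lapply(primers, function(pr) {
    step_truth(Xs[[pr]], params$pcr_coefs[[pr]], params$noise_sd[["pcr"]])
  })
  names(pcr) <- primers
  sequencing <- lapply(primers, function(pr) {
    step_truth(Xs[[pr]], params$seq_coefs[[pr]],
               params$noise_sd[["sequencing"]])
  })
  names(sequencing) <- primers

  total <- lapply(names(extraction), function(prot) {
    out <- lapply(primers, function(pr) {
      exp(center_log(extraction[[prot]] + pcr[[pr]] + sequencing[[pr]]))
    })
    names(out) <- primers
    out
  })
  names(total) <- names(extraction)

  structure(
    list(
      extraction = lapply(extraction, exp),
      pcr = lapply(pcr, exp),
      sequencing = lapply(sequencing, exp),
      total = total,
      taxa = taxa
    ),
    class = "ground_truth"
  )
}

#' Simulate read counts for every pool, stage, protocol, primer and run
#'
#' Each sample's generating composition is the closure of its pool's
#' expected composition times the cumulative true bias through its entry
#' stage (whole-insect pools: extraction x PCR x sequencing; DNA pools: PCR
#' x sequencing; PCR pools: sequencing only). Counts are multinomial at a
#' depth drawn from the configured normal distribution, optionally with
#' symmetric Dirichlet overdispersion, then subjected to per-cell dropout.
#' DNA and PCR pools are shared across extraction protocols (they were built
#' by destructive extraction), so they carry `extraction = "none"`.
#'
#' Samples are enumerated in a fixed order — stage (insect, dna, pcr),
#' protocol, primer, run, pool — and sample j draws from its own RNG
#' substream seeded at `seed + j`, so that changing the bias entering one
#' stage leaves the draws of upstream-entry samples bit-identical.
#'
#' @param design Mock design tibble.
#' @param truth `ground_truth` from [simulate_bias_vectors()].
#' @param params A [sim_params()] object.
#' @param seed Seed for the count draws; defaults to master seed + 1.
#' @return List with `counts` (taxa x samples integer matrix), `meta`
#'   (sample metadata tibble) and `compositions` (taxa x samples matrix of
#'   the generating proportions, NA where a taxon is absent from the pool).
#' @export
simulate_counts <- function(design, truth, params, seed = params$seed + 1) {
  stopifnot(inherits(params, "sim_params"), inherits(truth, "ground_truth"))
  draw_counts(design, truth, params, check_seed(seed))
}

draw_counts <- function(design, truth, params, base_seed) {
  taxa <- design$taxon
  primers <- names(truth$pcr)
  protocols <- names(truth$extraction)

  plan <- list()
  for (prot in protocols) {
    for (pr in primers) {
      for (run in seq_len(params$runs)) {
        for (pool in params$protocol_pools[[prot]]) {
          lb <- log(truth$extraction[[prot]]) + log(truth$pcr[[pr]]) +
            log(truth$sequencing[[pr]])
          plan[[length(plan) + 1]] <- list(
            stage = "insect", extraction = prot, primer = pr, run = run,
            pool = pool, log_bias = lb)
        }
      }
    }
  }
  for (stage in c("dna", "pcr")) {
    for (pr in primers) {
      for (run in seq_len(params$runs)) {
        for (pool in seq_along(pool_columns(design))) {
          lb <- if (stage == "dna") {
            log(truth$pcr[[pr]]) + log(truth$sequencing[[pr]])
          } else {
            log(truth$sequencing[[pr]])
          }
          plan[[length(plan) + 1]] <- list(
            stage = stage, extraction = "none", primer = pr, run = run,
            pool = pool, log_bias = lb)
        }
      }
    }
  }

  n <- length(plan)
  counts <- matrix(0L, nrow = length(taxa), ncol = n,
                   dimnames = list(taxa, NULL))
  comps <- matrix(NA_real_, nrow = length(taxa), ncol = n,
                  dimnames = list(taxa, NULL))
  meta <- vector("list", n)
  for (j in seq_len(n)) {
    s <- plan[[j]]
    expd <- expected_composition(design, s$pool)
    props <- close_composition(expd * exp(s$log_bias[names(expd)]))
    x <- withr::with_seed(base_seed + j, {
      depth <- max(1L, as.integer(round(rnorm(1, params$depth_mean,
                                              params$depth_sd))))
      draw_p <- props
      if (is.finite(params$overdispersion)) {
        g <- rgamma(length(props), shape = params$overdispersion * props)
        if (sum(g) == 0) g[] <- props
        draw_p <- g / sum(g)
      }
      x <- drop(rmultinom(1, depth, draw_p))
      if (params$dropout > 0) {
        x[runif(length(x)) < params$dropout] <- 0L
      }
      x
    })
    id <- sprintf("%s_%s_%s_p%d_r%d", s$stage, s$extraction, s$primer,
                  s$pool, s$run)
    counts[names(props), j] <- as.integer(x)
    comps[names(props), j] <- props
    meta[[j]] <- tibble::tibble(
      sample_id = id, pool = s$pool, stage = s$stage,
      extraction = s$extraction, primer = s$primer, run = s$run)
  }
  meta <- dplyr::bind_rows(meta)
  colnames(counts) <- meta$sample_id
  colnames(comps) <- meta$sample_id
  list(counts = counts, meta = meta, compositions = comps)
}

#' Simulate a complete experiment
#'
#' Draws the ground-truth bias vectors and then the read counts, both from
#' seeds derived deterministically from the master seed (truth: `seed`;
#' counts: `seed + 1`).
#'
#' @param params A [sim_params()] object.
#' @return List with `counts`, `meta`, `truth` (including the per-sample
#'   generating `compositions`) and `params`.
#' @export
simulate_experiment <- function(params = sim_params()) {
  truth <- simulate_bias_vectors(params, seed = params$seed)
  sim <- simulate_counts(params$design, truth, params,
                         seed = params$seed + 1)
  truth$compositions <- sim$compositions
  list(counts = sim$counts, meta = sim$meta, truth = truth, params = params)
}

#' Write a seeded simulated experiment (plus the design and trait tables)
#'
#' Writes `mock_design.tsv`, `insect_traits.tsv`, `counts.tsv`,
#' `sample_meta.tsv` and `truth.json` under `path`.
#'
#' @param path Output directory (created if needed).
#' @param params A [sim_params()] object.
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(path, params = sim_params()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(params)
  files <- c(
    design = file.path(path, "mock_design.tsv"),
    traits = file.path(path, "insect_traits.tsv"),
    counts = file.path(path, "counts.tsv"),
    meta = file.path(path, "sample_meta.tsv"),
    truth = file.path(path, "truth.json")
  )
  readr::write_tsv(params$design, files["design"])
  readr::write_tsv(params$traits, files["traits"])
  write_count_table(sim$counts, files["counts"])
  readr::write_tsv(sim$meta, files["meta"])
  truth <- sim$truth
  jsonlite::write_json(
    list(extraction = lapply(truth$extraction, as.list),
         pcr = lapply(truth$pcr, as.list),
         sequencing = lapply(truth$sequencing, as.list),
         total = lapply(truth$total, function(pp) lapply(pp, as.list)),
         seed = params$seed),
    files["truth"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
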