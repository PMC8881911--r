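#' Configuration for the end-to-end pipeline
#'
#' Collects inputs and options for [run_pipeline()]. Every input can be a
#' path to the documented TSV dialect or an already-loaded object.
#'
#' @param counts Count table: path or taxa x samples matrix.
#' @param meta Sample metadata: path or tibble.
#' @param design Mock design: path or tibble (default: packaged design).
#' @param traits Trait table: path or tibble (default: packaged traits).
#' @param zero_policy,pseudocount Zero handling for compositional errors
#'   (see [compositional_error()]).
#' @param n_boot Bootstrap replicates per group (default 1000; must be
#'   at least 1).
#' @param seed Integer seed governing every bootstrap in the run.
#' @param rmse_mode RMSE aggregation: `"pooled"` cells (default) or
#'   `"per_sample"`.
#' @param trait_encoding Hardness encoding for the trait model (see
#'   [build_trait_design()]).
#' @param rarefy_depth Rarefaction depth for the richness comparison, or
#'   `NULL` to skip it (default 100000 reads).
#' @param out_dir Directory for result files, or `NULL` to return the
#'   bundle without writing.
#' @return A validated `run_config` list.
#' @export
run_config <- function(counts, meta,
                       design = mock_design_fixture(),
                       traits = insect_traits_fixture(),
                       zero_policy = c("exclude", "pseudocount"),
                       pseudocount = 0.5,
                       n_boot = 1000,
                       seed = NULL,
                       rmse_mode = c("pooled", "per_sample"),
                       trait_encoding = c("hardness_levels",
                                          "intercept_reference"),
                       rarefy_depth = 100000,
                       out_dir = NULL) {
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(meta)) meta <- read_meta(meta)
  if (is.character(design)) design <- read_design(design)
  if (is.character(traits)) traits <- read_traits(traits)
  check_counts(counts)
  check_meta(meta)
  check_traits(traits)
  n_boot <- check_scalar_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  if (!is.null(rarefy_depth)) {
    rarefy_depth <- check_scalar_count(rarefy_depth, "rarefy_depth")
  }
  structure(
    list(counts = counts, meta = meta, design = design, traits = traits,
         zero_policy = match.arg(zero_policy), pseudocount = pseudocount,
         n_boot = n_boot, seed = seed, rmse_mode = match.arg(rmse_mode),
         trait_encoding = match.arg(trait_encoding),
         rarefy_depth = rarefy_depth, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full bias analysis
#'
#' For every primer set present, estimates per-taxon bias (with bootstrap
#' uncertainty) for the DNA pools, the PCR pools and, per extraction
#' protocol, the whole-insect pools; partitions total protocol bias into
#' extraction, PCR and sequencing components; computes per-step abundance
#' trajectories; reports raw and bias-corrected RMSE per group; fits the
#' trait regression (total bias and each partitioned component, stacking
#' primer sets, with per-run estimates stacked for the total); and compares
#' rarefied richness between treatments. Reruns with the same configuration
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return A `mockbias_result` list: `estimates`, `partitions`,
#'   `trajectories`, `trait_fits`, `rmse`, `richness`, `config`. If
#'   `config$out_dir` is set, result tables, a JSON summary and a run log
#'   are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- config$counts
  meta <- config$meta
  design <- config$design
  primers <- sort(unique(meta$primer))
  protocols <- intersect(c("quickextract", "dneasy"),
                         unique(meta$extraction))
  runs <- sort(unique(meta$run))
  for (st in c("dna", "pcr")) {
    if (!st %in% meta$stage) {
      abort(sprintf(
        "stage group(s) missing from metadata: %s (need insect, dna, pcr).",
        paste(setdiff(c("insect", "dna", "pcr"), unique(meta$stage)),
              collapse = ", ")))
    }
  }

  k <- 0L
  boot <- function(group) {
    k <<- k + 1L
    bootstrap_bias(counts, meta, design, group,
                   n_boot = config$n_boot, seed = config$seed + k,
                   zero_policy = config$zero_policy,
                   pseudocount = config$pseudocount)
  }

  estimates <- list()
  partitions <- list()
  trajectories <- list()
  rmse_rows <- list()

  for (pr in primers) {
    dna_est <- boot(list(stage = "dna", primer = pr))
    pcr_est <- boot(list(stage = "pcr", primer = pr))
    estimates[[paste("dna", pr, sep = ".")]] <- dna_est
    estimates[[paste("pcr", pr, sep = ".")]] <- pcr_est
    rmse_rows[[paste("dna", pr)]] <-
      rmse_row(config, list(stage = "dna", primer = pr), "dna", "none", pr,
               dna_est)
    rmse_rows[[paste("pcr", pr)]] <-
      rmse_row(config, list(stage = "pcr", primer = pr), "pcr", "none", pr,
               pcr_est)
    for (prot in protocols) {
      grp <- list(stage = "insect", extraction = prot, primer = pr)
      total_est <- boot(grp)
      key <- paste("insect", prot, pr, sep = ".")
      estimates[[key]] <- total_est
      part <- partition_bias(total_est, dna_est, pcr_est,
                             protocol = prot, primer = pr)
      partitions[[paste(prot, pr, sep = ".")]] <- part
      trajectories[[paste(prot, pr, sep = ".")]] <- bias_trajectory(part)
      rmse_rows[[paste("insect", prot, pr)]] <-
        rmse_row(config, grp, "insect", prot, pr, total_est)
    }
  }

  # per-run total-bias estimates: the observations of the trait regression
  run_estimates <- list()
  for (prot in protocols) {
    for (pr in primers) {
      for (rn in runs) {
        grp <- list(stage = "insect", extraction = prot, primer = pr,
                    run = rn)
        if (length(select_samples(meta, grp)) == 0) next
        run_estimates[[paste(prot, pr, rn, sep = ".")]] <- boot(grp)
      }
    }
  }

  designs_by_primer <- lapply(setNames(primers, primers), function(pr) {
    build_trait_design(config$traits, design$taxon, pr,
                       encoding = config$trait_encoding)
  })
  trait_fits <- lapply(setNames(protocols, protocols), function(prot) {
    keys <- grep(paste0("^", prot, "\\."), names(run_estimates),
                 value = TRUE)
    resp <- run_estimates[keys]
    dsgn <- lapply(keys, function(kk) {
      designs_by_primer[[strsplit(kk, ".", fixed = TRUE)[[1]][2]]]
    })
    fits <- list(total = bootstrap_trait_cis(resp, dsgn))
    for (comp in c("extraction", "pcr", "sequencing")) {
      cresp <- lapply(primers, function(p2) {
        component_as_estimate(partitions[[paste(prot, p2, sep = ".")]],
                              comp)
      })
      cdsgn <- lapply(primers, function(p2) designs_by_primer[[p2]])
      fits[[comp]] <- bootstrap_trait_cis(cresp, cdsgn)
    }
    fits
  })

  richness <- NULL
  if (!is.null(config$rarefy_depth)) {
    richness <- tryCatch(
      richness_comparison(counts, meta, config$rarefy_depth,
                          config$seed + k + 1L),
      error = function(e) {
        warn(paste0("richness comparison skipped: ", conditionMessage(e)))
        NULL
      })
  }

  result <- structure(
    list(estimates = estimates, partitions = partitions,
         trajectories = trajectories, trait_fits = trait_fits,
         rmse = dplyr::bind_rows(rmse_rows), richness = richness,
         config = config),
    class = "mockbias_result"
  )
  if (!is.null(config$out_dir)) write_result_bundle(result, config$out_dir)
  result
}

# one row of the RMSE report: raw accuracy of the group's samples, and
# accuracy after predicting observations with the group's fitted bias
rmse_row <- function(config, group, stage, protocol, primer, est) {
  raw <- group_rmse(config, group, bias = NULL)
  corrected <- group_rmse(config, group, bias = est$efficiency)
  tibble::tibble(stage = stage, protocol = protocol, primer = primer,
                 n_samples = est$n_samples,
                 rmse_raw = raw, rmse_corrected = corrected)
}

group_rmse <- function(config, group, bias = NULL) {
  meta <- config$meta
  ids <- select_samples(meta, group)
  obs_list <- list()
  exp_list <- list()
  for (s in ids) {
    pool <- meta$pool[meta$sample_id == s]
    expd <- expected_composition(config$design, pool)
    obs <- config$counts[names(expd), s]
    keep <- if (config$zero_policy == "exclude") obs > 0 else
      rep(TRUE, length(obs))
    if (!is.null(bias)) keep <- keep & names(expd) %in% names(bias)
    if (!any(keep)) next
    o <- close_composition(obs[keep] +
                             if (config$zero_policy == "pseudocount")
                               config$pseudocount else 0)
    e <- close_composition(expd[keep])
    if (!is.null(bias)) e <- predict_composition(e, bias[names(e)])
    obs_list[[s]] <- o
    exp_list[[s]] <- e
  }
  rmse_composition(obs_list, exp_list, aggregate = config$rmse_mode)
}

# wrap one partition component as a minimal bias_estimate so the trait
# model can consume its point estimate and paired replicates
component_as_estimate <- function(part, component) {
  comp <- part$components[[component]]
  structure(
    list(efficiency = comp$efficiency,
         log_replicates = comp$log_replicates,
         se_log = comp$se_log, ci = comp$ci,
         group = paste(component, part$protocol, part$primer),
         n_samples = NA_integer_,
         n_boot = if (is.null(comp$log_replicates)) 0L else
           ncol(comp$log_replicates),
         dropouts = tibble::tibble(sample_id = character(0),
                                   taxon = character(0))),
    class = "bias_estimate"
  )
}

richness_comparison <- function(counts, meta, depth, seed) {
  rare <- rarefy_counts(counts, depth = depth, seed = seed)
  meta_sub <- meta[match(colnames(rare), meta$sample_id), ]
  rich <- observed_richness(rare)
  treatment <- ifelse(meta_sub$stage == "insect",
                      paste("insect", meta_sub$extraction, sep = "_"),
                      meta_sub$stage)
  table <- tibble::tibble(sample_id = colnames(rare),
                          treatment = treatment,
                          primer = meta_sub$primer,
                          richness = as.integer(rich))
  an <- richness_anova(table$richness, table$treatment)
  list(table = table,
       anova = an[c("f", "df1", "df2", "p")],
       tukey = tukey_hsd(table$richness, table$treatment))
}

write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est_tab <- purrr::imap_dfr(result$estimates, function(e, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    dplyr::mutate(tibble::as_tibble(e),
                  stage = parts[1],
                  group = e$group, .before = 1)
  })
  readr::write_tsv(est_tab, file.path(out_dir, "bias_estimates.tsv"))
  part_tab <- purrr::imap_dfr(result$partitions, function(p, key) {
    dplyr::mutate(tibble::as_tibble(p), protocol = p$protocol,
                  primer = p$primer, .before = 1)
  })
  readr::write_tsv(part_tab, file.path(out_dir, "partitioned_bias.tsv"))
  traj_tab <- purrr::imap_dfr(result$trajectories, function(tr, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    dplyr::mutate(tr, protocol = parts[1], primer = parts[2], .before = 1)
  })
  readr::write_tsv(traj_tab, file.path(out_dir, "trajectories.tsv"))
  trait_tab <- purrr::imap_dfr(result$trait_fits, function(fits, prot) {
    purrr::imap_dfr(fits, function(f, resp) {
      dplyr::mutate(f$coefficients, protocol = prot, response = resp,
                    adj_r_squared = f$adj_r_squared,
                    f_statistic = f$f_statistic, df1 = f$df1, df2 = f$df2,
                    .before = 1)
    })
  })
  readr::write_tsv(trait_tab, file.path(out_dir, "trait_coefficients.tsv"))
  readr::write_tsv(result$rmse, file.path(out_dir, "rmse.tsv"))
  if (!is.null(result$richness)) {
    readr::write_tsv(result$richness$table,
                     file.path(out_dir, "richness.tsv"))
    readr::write_tsv(result$richness$tukey,
                     file.path(out_dir, "richness_tukey.tsv"))
  }
  cfg <- result$config
  summary <- list(
    primers = sort(unique(cfg$meta$primer)),
    protocols = intersect(c("quickextract", "dneasy"),
                          unique(cfg$meta$extraction)),
    n_samples = ncol(cfg$counts),
    n_boot = cfg$n_boot,
    seed = cfg$seed,
    zero_policy = cfg$zero_policy,
    rmse_mode = cfg$rmse_mode,
    trait_encoding = cfg$trait_encoding,
    rmse = result$rmse,
    richness_anova = if (is.null(result$richness)) NULL else
      result$richness$anova
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  log_lines <- c(
    paste0("mockbias ", as.character(utils::packageVersion("mockbias"))),
    R.version.string,
    paste0("seed: ", cfg$seed),
    paste0("n_boot: ", cfg$n_boot),
    paste0("zero_policy: ", cfg$zero_policy),
    paste0("rmse_mode: ", cfg$rmse_mode),
    paste0("trait_encoding: ", cfg$trait_encoding),
    paste0("rarefy_depth: ",
           if (is.null(cfg$rarefy_depth)) "none" else cfg$rarefy_depth),
    paste0("samples: ", ncol(cfg$counts)),
    paste0("taxa: ", nrow(cfg$counts))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.mockbias_result <- function(x, ...) {
  cat("<mockbias_result>\n")
  cat(sprintf("  %d bias estimates, %d partitions\n",
              length(x$estimates), length(x$partitions)))
  print(x$rmse)
  invisible(x)
}
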