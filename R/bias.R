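#' Estimate per-taxon detection efficiency for a group of samples
#'
#' For every sample in the group, the sample's compositional error (observed
#' vs the expected composition of its pool) is computed; the point estimate
#' for each taxon is the geometric mean of those errors over the samples in
#' which the taxon was both expected and observed, re-centered at the end.
#' This geometric-mean estimator is the closed form of a least-squares fit of
#' taxon indicators to centered log-ratio errors.
#'
#' Taxa never expected in any of the group's pools are absent from the
#' result; taxa expected somewhere but observed in no sample are excluded
#' with a warning and recorded in the dropout registry.
#'
#' @param counts Numeric matrix of reads, taxa x samples, with dimnames.
#' @param meta Sample metadata tibble (see [read_meta()]): `sample_id`,
#'   `pool`, `stage`, `extraction`, `primer`, `run`.
#' @param design Mock design tibble (see [read_design()]).
#' @param group Named list selecting samples by metadata columns, e.g.
#'   `list(stage = "insect", extraction = "dneasy", primer = "fwhF2-fwhR2n")`.
#'   Several values per field are allowed; omitted fields are unrestricted.
#' @param zero_policy,pseudocount Passed to [compositional_error()].
#' @return A `bias_estimate` object: centered efficiency vector, dropout
#'   registry, sample count and group label. [bootstrap_bias()] adds
#'   uncertainty. Use [as_tibble()] for a tabular view.
#' @seealso [bootstrap_bias()], [partition_bias()]
#' @export
estimate_bias <- function(counts, meta, design, group = list(),
                          zero_policy = c("exclude", "pseudocount"),
                          pseudocount = 0.5) {
  zero_policy <- match.arg(zero_policy)
  le <- group_log_errors(counts, meta, design, group, zero_policy, pseudocount)
  log_eff <- estimate_from_log_errors(le$log_errors)
  lost <- names(log_eff)[is.na(log_eff) & le$expected_somewhere]
  if (length(lost)) {
    warn(paste0("taxa expected but observed in no sample of the group, ",
                "excluded: ", paste(lost, collapse = ", ")))
  }
  eff <- exp(log_eff[!is.na(log_eff)])
  attr(eff, "centered") <- TRUE
  new_bias_estimate(
    efficiency = eff,
    group = le$group_label,
    n_samples = ncol(le$log_errors),
    dropouts = le$dropouts,
    log_errors = le$log_errors,
    zero_policy = zero_policy
  )
}

#' Bootstrap uncertainty for a bias estimate
#'
#' Resamples the group's samples with replacement, re-runs the estimator on
#' each replicate, and summarises the replicates into per-taxon log-scale
#' standard errors and percentile confidence intervals (95% and 50%). The
#' replicate matrix is retained so that downstream partitioning and trait
#' models can propagate uncertainty by pairing replicates.
#'
#' @inheritParams estimate_bias
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `bias_estimate` with `se_log`, `ci` (columns `lo95`, `hi95`,
#'   `lo50`, `hi50`) and the `n_boot`-column matrix `log_replicates`.
#' @export
bootstrap_bias <- function(counts, meta, design, group = list(),
                           n_boot = 1000, seed = NULL,
                           zero_policy = c("exclude", "pseudocount"),
                           pseudocount = 0.5) {
  zero_policy <- match.arg(zero_policy)
  n_boot <- check_scalar_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  est <- estimate_bias(counts, meta, design, group,
                       zero_policy = zero_policy, pseudocount = pseudocount)
  L <- est$log_errors[names(est$efficiency), , drop = FALSE]
  n <- ncol(L)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      estimate_from_log_errors(L[, idx, drop = FALSE])
    }, numeric(nrow(L)))
  })
  reps <- matrix(reps, nrow = nrow(L),
                 dimnames = list(rownames(L), NULL))
  if (n == 1) {
    warn("group contains a single sample; bootstrap standard errors are 0.")
  }
  se <- apply(reps, 1, sd, na.rm = TRUE)
  se[is.na(se)] <- 0
  if (n == 1 || n_boot == 1) se[] <- 0
  qs <- t(apply(reps, 1, quantile,
                probs = c(0.025, 0.975, 0.25, 0.75), na.rm = TRUE))
  ci <- exp(qs)
  colnames(ci) <- c("lo95", "hi95", "lo50", "hi50")
  est$se_log <- se
  est$ci <- ci
  est$log_replicates <- reps
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Predict the observed composition implied by a bias vector
#'
#' The multiplicative bias model: perturb the expected composition by the
#' per-taxon efficiencies and re-close. With efficiencies estimated from mock
#' communities this predicts what sequencing will report; inverting the bias
#' (dividing instead) calibrates an observed composition.
#'
#' @param expected Expected composition vector, named by taxon.
#' @param bias Positive efficiency vector over the same taxa.
#' @return Predicted composition (sums to 1).
#' @examples
#' predict_composition(c(a = 0.5, b = 0.5), c(a = 3, b = 1)) # 0.75, 0.25
#' @export
predict_composition <- function(expected, bias) {
  check_named_numeric(expected, "expected")
  check_named_numeric(bias, "bias")
  check_same_taxa(expected, bias, "expected", "bias")
  bias <- align_taxa(bias, expected)
  close_composition(expected * bias)
}

# shared machinery ---------------------------------------------------------

# per-sample centered log errors for one group: matrix over the union of
# expected taxa (NA where a taxon was not expected in, or dropped from, a
# sample), plus the dropout registry
group_log_errors <- function(counts, meta, design, group,
                             zero_policy, pseudocount) {
  check_counts(counts)
  check_meta(meta)
  ids <- select_samples(meta, group)
  if (length(ids) == 0) {
    abort("no samples match the requested group.")
  }
  missing <- setdiff(ids, colnames(counts))
  if (length(missing)) {
    abort(paste0("samples in metadata but not in counts: ",
                 paste(missing, collapse = ", ")))
  }
  meta_sub <- meta[match(ids, meta$sample_id), ]
  taxa <- design$taxon
  L <- matrix(NA_real_, nrow = length(taxa), ncol = length(ids),
              dimnames = list(taxa, ids))
  expected_somewhere <- setNames(rep(FALSE, length(taxa)), taxa)
  drops <- list()
  for (j in seq_along(ids)) {
    expd <- expected_composition(design, meta_sub$pool[j])
    expected_somewhere[names(expd)] <- TRUE
    obs <- counts[names(expd), ids[j]]
    err <- compositional_error(obs, expd, zero_policy = zero_policy,
                               pseudocount = pseudocount)
    L[names(err), j] <- log(err)
    d <- attr(err, "dropout")
    if (length(d)) drops[[ids[j]]] <- d
  }
  dropouts <- if (length(drops)) {
    tibble::tibble(
      sample_id = rep(names(drops), lengths(drops)),
      taxon = unlist(drops, use.names = FALSE)
    )
  } else {
    tibble::tibble(sample_id = character(0), taxon = character(0))
  }
  list(log_errors = L, dropouts = dropouts,
       expected_somewhere = expected_somewhere,
       group_label = group_label(group))
}

# geometric-mean-of-errors estimator on the log scale: per-taxon mean over
# available samples, then re-centered over the taxa with any observation
estimate_from_log_errors <- function(L) {
  m <- rowMeans(L, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  ok <- !is.na(m)
  m[ok] <- m[ok] - mean(m[ok])
  m
}

select_samples <- function(meta, group) {
  if (length(group) == 0) return(meta$sample_id)
  if (is.null(names(group)) || any(names(group) == "")) {
    abort("`group` must be a named list of metadata fields.")
  }
  bad <- setdiff(names(group), names(meta))
  if (length(bad)) {
    abort(paste0("unknown group field(s): ", paste(bad, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(meta))
  for (field in names(group)) {
    keep <- keep & meta[[field]] %in% group[[field]]
  }
  meta$sample_id[keep]
}

group_label <- function(group) {
  if (length(group) == 0) return("all samples")
  paste(names(group), vapply(group, function(v)
    paste(v, collapse = "|"), character(1)), sep = "=", collapse = ", ")
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (taxa x samples).")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have taxon rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("`counts` dimnames must be unique.")
  }
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  invisible(counts)
}

check_meta <- function(meta) {
  required <- c("sample_id", "pool", "stage", "extraction", "primer", "run")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("`sample_id` values must be unique.")
  }
  invisible(meta)
}

# bias_estimate class ------------------------------------------------------

new_bias_estimate <- function(efficiency, group, n_samples, dropouts,
                              log_errors, zero_policy) {
  structure(
    list(
      efficiency = efficiency,
      se_log = setNames(rep(NA_real_, length(efficiency)), names(efficiency)),
      ci = NULL,
      group = group,
      n_samples = n_samples,
      n_boot = 0L,
      dropouts = dropouts,
      log_errors = log_errors,
      log_replicates = NULL,
      zero_policy = zero_policy
    ),
    class = "bias_estimate"
  )
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat("<bias_estimate>", x$group, "\n")
  cat(sprintf("  %d taxa, %d samples, %d bootstrap replicates, %d dropouts\n",
              length(x$efficiency), x$n_samples, x$n_boot, nrow(x$dropouts)))
  print(tibble::as_tibble(x), n = 6)
  invisible(x)
}

#' Tabular view of a bias estimate
#'
#' @param x A `bias_estimate`.
#' @param ... Unused.
#' @return Tibble with columns `taxon`, `efficiency`, `se_log`, `ci_lo`,
#'   `ci_hi`, `ci50_lo`, `ci50_hi`, `n_dropout`.
#' @method as_tibble bias_estimate
#' @export
as_tibble.bias_estimate <- function(x, ...) {
  nd <- table(factor(x$dropouts$taxon, levels = names(x$efficiency)))
  tibble::tibble(
    taxon = names(x$efficiency),
    efficiency = unname(x$efficiency),
    se_log = unname(x$se_log),
    ci_lo = if (is.null(x$ci)) NA_real_ else unname(x$ci[, "lo95"]),
    ci_hi = if (is.null(x$ci)) NA_real_ else unname(x$ci[, "hi95"]),
    ci50_lo = if (is.null(x$ci)) NA_real_ else unname(x$ci[, "lo50"]),
    ci50_hi = if (is.null(x$ci)) NA_real_ else unname(x$ci[, "hi50"]),
    n_dropout = as.integer(nd)
  )
}
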