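#' Build the trait design matrix for the bias regression
#'
#' Assembles, per taxon, the covariates used to explain log detection
#' efficiency: exoskeleton-hardness indicators, (log) body volume, combined
#' primer mismatch (forward + reverse proportions) and amplicon GC fraction.
#'
#' Two encodings of hardness are available. The default,
#' `"hardness_levels"`, carries all three level indicators and no intercept,
#' so each hardness coefficient is that level's own baseline. The
#' alternative, `"intercept_reference"`, drops the hard level and lets
#' [fit_trait_model()] add an intercept, so hardness coefficients are
#' contrasts against hard-bodied taxa.
#'
#' @param traits Trait table (see [read_traits()] /
#'   [insect_traits_fixture()]): one row per taxon x primer set.
#' @param taxa Character vector of taxa, defining the row order.
#' @param primer Primer-set label to select trait rows.
#' @param log_volume Enter body volume as its natural log (default `TRUE`;
#'   volumes span two orders of magnitude and effects are multiplicative).
#' @param encoding `"hardness_levels"` or `"intercept_reference"`.
#' @return Numeric matrix, one row per taxon, with attributes `encoding` and
#'   `primer`.
#' @export
build_trait_design <- function(traits, taxa, primer,
                               log_volume = TRUE,
                               encoding = c("hardness_levels",
                                            "intercept_reference")) {
  encoding <- match.arg(encoding)
  check_traits(traits)
  tr <- traits[traits$primer == primer, ]
  if (nrow(tr) == 0) {
    abort(sprintf("no trait rows for primer `%s`.", primer))
  }
  idx <- match(taxa, tr$taxon)
  if (anyNA(idx)) {
    abort(paste0("taxa missing from trait table: ",
                 paste(taxa[is.na(idx)], collapse = ", ")))
  }
  tr <- tr[idx, ]
  vol <- if (log_volume) log(tr$volume_mm3) else tr$volume_mm3
  X <- cbind(
    soft = as.numeric(tr$hardness == 1),
    intermediate = as.numeric(tr$hardness == 2),
    hard = as.numeric(tr$hardness == 3),
    log_volume = vol,
    mismatch = tr$fwd_mismatch + tr$rev_mismatch,
    gc = tr$gc
  )
  if (!log_volume) colnames(X)[4] <- "volume"
  if (encoding == "intercept_reference") {
    X <- X[, colnames(X) != "hard", drop = FALSE]
  }
  rownames(X) <- taxa
  attr(X, "encoding") <- encoding
  attr(X, "primer") <- primer
  X
}

#' Regress log detection efficiency on insect traits
#'
#' Ordinary least squares of log efficiency on the trait design matrix.
#' Coefficients are reported both on the log scale and exponentiated (the
#' multiplicative change in detection efficiency per unit trait). Under the
#' default no-intercept encoding the model has one coefficient per hardness
#' level plus the three continuous traits.
#'
#' Observations can be stacked over several estimates (e.g. two primer sets
#' x two runs) by passing lists: responses are concatenated and design
#' matrices row-bound in the same order.
#'
#' @param response A `bias_estimate` (its log efficiencies are the
#'   response), a named numeric vector of log efficiencies, or a list of
#'   either to stack.
#' @param design Trait design matrix from [build_trait_design()], or a list
#'   matching `response`.
#' @return A `trait_model_fit`: coefficient tibble (`term`, `estimate_log`,
#'   `estimate`, CI columns filled by [bootstrap_trait_cis()]), adjusted
#'   R-squared, F statistic with degrees of freedom, p-value and `n`.
#' @export
fit_trait_model <- function(response, design) {
  stacked <- stack_response_design(response, design)
  y <- stacked$y
  X <- stacked$X
  encoding <- stacked$encoding

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  form <- if (encoding == "hardness_levels") .y ~ 0 + . else .y ~ .
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  est <- coef(fit)
  new_trait_model_fit(
    coefficients = tibble::tibble(
      term = names(est),
      estimate_log = unname(est),
      estimate = exp(unname(est)),
      ci_lo = NA_real_,
      ci_hi = NA_real_
    ),
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat["value"]),
    df1 = unname(fstat["numdf"]),
    df2 = unname(fstat["dendf"]),
    p_value = unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                        lower.tail = FALSE)),
    n = length(y),
    encoding = encoding,
    fit = fit
  )
}

#' Bootstrap confidence intervals for trait-model coefficients
#'
#' Refits the trait regression to every bootstrap replicate of the bias
#' estimate(s) and attaches percentile confidence intervals (95%) to the
#' exponentiated coefficients of the point-estimate fit. Given the same
#' replicates the result is fully deterministic; `seed` is accepted for
#' interface symmetry with the other bootstrap functions.
#'
#' @param response A `bias_estimate` carrying `log_replicates` (from
#'   [bootstrap_bias()]), or a list of them to stack. All stacked estimates
#'   must share the same number of replicates.
#' @param design Design matrix or matching list, as in [fit_trait_model()].
#' @param seed Ignored (kept for call-signature consistency).
#' @return A `trait_model_fit` with `ci_lo` / `ci_hi` filled (exponentiated
#'   scale) and `n_boot` set.
#' @export
bootstrap_trait_cis <- function(response, design, seed = NULL) {
  point <- fit_trait_model(response, design)
  reps <- stack_replicates(response, design)
  if (ncol(reps$Y) < 2) {
    abort("at least 2 bootstrap replicates are required.")
  }
  X <- reps$X
  Y <- reps$Y
  # refit per replicate on the rows available in that replicate (a taxon can
  # be missing from a resample, e.g. one expected in few pools)
  complete <- stats::complete.cases(Y)
  B <- if (all(complete)) {
    solve(crossprod(X), crossprod(X, Y))
  } else {
    vapply(seq_len(ncol(Y)), function(r) {
      ok <- !is.na(Y[, r])
      qr.coef(qr(X[ok, , drop = FALSE]), Y[ok, r])
    }, numeric(ncol(X)))
  }
  qs <- t(apply(B, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  point$coefficients$ci_lo <- unname(exp(qs[, 1]))
  point$coefficients$ci_hi <- unname(exp(qs[, 2]))
  point$n_boot <- ncol(Y)
  point
}

# stacking helpers ---------------------------------------------------------

response_log <- function(r) {
  if (inherits(r, "bias_estimate")) return(log(r$efficiency))
  check_named_numeric(r, "response")
  r
}

stack_response_design <- function(response, design) {
  if (!is.list(response) || inherits(response, "bias_estimate")) {
    response <- list(response)
  }
  if (is.matrix(design)) design <- list(design)
  if (length(design) == 1 && length(response) > 1) {
    design <- rep(design, length(response))
  }
  if (length(design) != length(response)) {
    abort("`response` and `design` lists must have matching lengths.")
  }
  parts <- Map(function(r, X) {
    y <- response_log(r)
    if (!is.null(names(y)) && !is.null(rownames(X))) {
      common <- intersect(names(y), rownames(X))
      if (length(common) == 0) abort("no taxa shared by response and design.")
      y <- y[common]
      X <- X[common, , drop = FALSE]
    }
    if (length(y) != nrow(X)) {
      abort("response length does not match design rows.")
    }
    list(y = y, X = X)
  }, response, design)
  enc <- unique(vapply(design, function(X) {
    e <- attr(X, "encoding")
    if (is.null(e)) "hardness_levels" else e
  }, character(1)))
  if (length(enc) != 1) abort("stacked designs use different encodings.")
  list(
    y = unlist(lapply(parts, `[[`, "y")),
    X = do.call(rbind, lapply(parts, `[[`, "X")),
    encoding = enc
  )
}

stack_replicates <- function(response, design) {
  if (!is.list(response) || inherits(response, "bias_estimate")) {
    response <- list(response)
  }
  if (is.matrix(design)) design <- list(design)
  if (length(design) == 1 && length(response) > 1) {
    design <- rep(design, length(response))
  }
  parts <- Map(function(r, X) {
    if (!inherits(r, "bias_estimate") || is.null(r$log_replicates)) {
      abort("each response must be a bias_estimate from bootstrap_bias().")
    }
    common <- intersect(names(r$efficiency), rownames(X))
    list(Y = r$log_replicates[common, , drop = FALSE],
         X = X[common, , drop = FALSE])
  }, response, design)
  nb <- unique(vapply(parts, function(p) ncol(p$Y), integer(1)))
  if (length(nb) != 1) {
    abort("stacked estimates must share the same number of replicates.")
  }
  list(Y = do.call(rbind, lapply(parts, `[[`, "Y")),
       X = do.call(rbind, lapply(parts, `[[`, "X")))
}

# trait_model_fit class ----------------------------------------------------

new_trait_model_fit <- function(coefficients, adj_r_squared, f_statistic,
                                df1, df2, p_value, n, encoding, fit) {
  structure(
    list(coefficients = coefficients, adj_r_squared = adj_r_squared,
         f_statistic = f_statistic, df1 = df1, df2 = df2, p_value = p_value,
         n = n, n_boot = 0L, encoding = encoding, fit = fit),
    class = "trait_model_fit"
  )
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat("<trait_model_fit>", x$encoding, "\n")
  cat(sprintf("  n = %d, F(%d, %d) = %.2f, adj. R^2 = %.2f, p = %.3g\n",
              x$n, x$df1, x$df2, x$f_statistic, x$adj_r_squared, x$p_value))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @method as_tibble trait_model_fit
#' @export
as_tibble.trait_model_fit <- function(x, ...) x$coefficients

#' Primer-template mismatch proportion
#'
#' Fraction of primer positions whose (possibly degenerate) IUPAC base set
#' excludes the template base at the aligned binding site. Degenerate primer
#' bases match any template base in their set (e.g. D covers A, G and T).
#' The result is rounded to two decimals, matching the granularity of the
#' packaged trait table.
#'
#' @param primer Primer sequence (IUPAC nucleotide codes allowed).
#' @param template Template binding-site sequence of the same length.
#' @return Mismatch proportion in \[0, 1\].
#' @examples
#' mismatch_proportion("GGD", "GGA") # 0: D covers A
#' @export
mismatch_proportion <- function(primer, template) {
  p <- toupper(chartr("U", "T", primer))
  t <- toupper(chartr("U", "T", template))
  pc <- strsplit(p, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  if (length(pc) != length(tc)) {
    abort("`primer` and `template` must have equal (aligned) lengths.")
  }
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(unique(c(pc, tc)), names(map))
  if (length(bad)) {
    abort(paste0("non-IUPAC character(s): ", paste(bad, collapse = ", ")))
  }
  mis <- vapply(seq_along(pc), function(i) {
    pset <- strsplit(map[[pc[i]]], "")[[1]]
    tset <- strsplit(map[[tc[i]]], "")[[1]]
    length(intersect(pset, tset)) == 0
  }, logical(1))
  round(mean(mis), 2)
}

#' Amplicon length from barcode coordinates
#'
#' Length of the amplified fragment (excluding primers) between two
#' coordinates of the barcode region, using the end-minus-start convention
#' that reproduces the conventional printed COI amplicon lengths (e.g.
#' 346–551 is a 205 bp amplicon).
#'
#' @param start,end Coordinates in bp, `end >= start`.
#' @return Length in bp.
#' @examples
#' amplicon_length(346, 551) # 205
#' @export
amplicon_length <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) ||
      length(start) != 1 || length(end) != 1 || is.na(start) || is.na(end)) {
    abort("`start` and `end` must be single numbers.")
  }
  if (end < start) abort("`end` must be >= `start`.")
  end - start
}

check_traits <- function(traits) {
  required <- c("taxon", "primer", "fwd_mismatch", "rev_mismatch", "gc",
                "volume_mm3", "hardness")
  missing <- setdiff(required, names(traits))
  if (length(missing)) {
    abort(paste0("trait table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  with(traits, {
    if (any(fwd_mismatch < 0 | fwd_mismatch > 1) ||
        any(rev_mismatch < 0 | rev_mismatch > 1)) {
      abort("mismatch proportions must lie in [0, 1].")
    }
    if (any(gc < 0 | gc > 1)) abort("GC fractions must lie in [0, 1].")
    if (any(volume_mm3 <= 0)) abort("volumes must be positive.")
    if (!all(hardness %in% 1:3)) abort("hardness must be 1, 2 or 3.")
  })
  invisible(traits)
}
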