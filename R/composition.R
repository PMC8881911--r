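#' Close a vector of abundances to a composition
#'
#' Divides a non-negative vector by its total so that it sums to one. This is
#' the closure operation of compositional data analysis and underlies every
#' "relative abundance" in the package.
#'
#' @param v Non-negative numeric vector with at least one positive entry,
#'   optionally named by taxon.
#' @return A numeric vector of proportions summing to 1, names preserved.
#' @examples
#' close_composition(c(a = 25, b = 75))
#' @export
close_composition <- function(v) {
  check_named_numeric(v, "v")
  if (any(v < 0)) abort("`v` must be non-negative.")
  total <- sum(v)
  if (total <= 0) abort("`v` must contain at least one positive entry.")
  v / total
}

#' Geometrically center a vector of efficiencies
#'
#' Divides a strictly positive vector by its geometric mean, so that the
#' result has geometric mean 1 and each entry reads as an efficiency relative
#' to the "average" taxon. Centering is idempotent.
#'
#' Zeros are rejected rather than imputed: apply a zero policy (exclusion or
#' a pseudocount) before centering. See [compositional_error()].
#'
#' @param e Strictly positive numeric vector, optionally named by taxon.
#' @return The centered vector, carrying attribute `centered = TRUE`.
#' @examples
#' center_efficiency(c(4, 1)) # c(2, 0.5)
#' @export
center_efficiency <- function(e) {
  check_named_numeric(e, "e")
  if (any(e <= 0)) {
    abort("`e` must be strictly positive; apply a zero policy first.")
  }
  out <- e / geometric_mean(e)
  attr(out, "centered") <- TRUE
  out
}

#' Is an efficiency vector geometrically centered?
#'
#' @param e Positive numeric vector.
#' @param tol Tolerance on |log geometric mean|.
#' @return `TRUE` if the geometric mean of `e` is 1 within `tol`.
#' @export
is_centered <- function(e, tol = 1e-9) {
  abs(mean(log(e))) < tol
}

#' Compositional error of one sample
#'
#' The per-taxon ratio of observed to expected relative abundance,
#' geometrically centered. Because compositions carry no absolute scale, the
#' ratio is only meaningful relative to the average taxon, which the
#' centering makes explicit.
#'
#' Observed zeros for taxa that were expected cannot enter a multiplicative
#' error (log 0 is undefined). Two policies are available:
#' \describe{
#'   \item{`"exclude"` (default)}{zero cells are dropped from the sample's
#'     error vector and recorded in the `"dropout"` attribute; both vectors
#'     are re-closed over the retained taxa.}
#'   \item{`"pseudocount"`}{`pseudocount` is added to every observed entry
#'     before closure, retaining all taxa.}
#' }
#'
#' @param observed Non-negative vector of observed reads or proportions,
#'   named by taxon.
#' @param expected Strictly positive vector of expected proportions over the
#'   same taxa.
#' @param zero_policy `"exclude"` or `"pseudocount"`.
#' @param pseudocount Value added to `observed` under the pseudocount policy
#'   (default 0.5 reads).
#' @return Centered efficiency vector over the retained taxa, with attribute
#'   `"dropout"` naming excluded taxa (empty under the pseudocount policy).
#' @examples
#' compositional_error(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.75))
#' @export
compositional_error <- function(observed, expected,
                                zero_policy = c("exclude", "pseudocount"),
                                pseudocount = 0.5) {
  zero_policy <- match.arg(zero_policy)
  check_named_numeric(observed, "observed")
  check_named_numeric(expected, "expected")
  check_same_taxa(observed, expected, "observed", "expected")
  expected <- align_taxa(expected, observed)
  if (any(expected <= 0)) {
    abort("`expected` must be strictly positive; drop absent taxa first.")
  }
  if (any(observed < 0)) abort("`observed` must be non-negative.")

  dropout <- character(0)
  if (zero_policy == "pseudocount") {
    observed <- observed + pseudocount
  } else if (any(observed == 0)) {
    dropout <- names(observed)[observed == 0]
    if (is.null(dropout)) dropout <- character(0)
    keep <- observed > 0
    if (!any(keep)) abort("all observed entries are zero.")
    observed <- observed[keep]
    expected <- expected[keep]
  }
  err <- center_efficiency(close_composition(observed) /
                             close_composition(expected))
  attr(err, "dropout") <- dropout
  err
}

#' Expected composition of a mock-community pool
#'
#' Closes the pool's individual counts over the taxa actually present
#' (nonzero count), giving the relative abundances the protocol would report
#' in the absence of any bias.
#'
#' @param design Mock design tibble: a `taxon` column plus one
#'   `pool_<id>` count column per pool (see [read_design()]).
#' @param pool Pool identifier: either an integer id or a full pool column
#'   name such as `"pool_5"`.
#' @return Named proportion vector over the pool's nonzero taxa.
#' @examples
#' expected_composition(mock_design_fixture(), 1)
#' @export
expected_composition <- function(design, pool) {
  cols <- pool_columns(design)
  col <- if (is.character(pool) && pool %in% cols) {
    pool
  } else {
    paste0("pool_", pool)
  }
  if (!col %in% cols) {
    abort(sprintf("pool `%s` not found in design (pools: %s).",
                  as.character(pool), paste(cols, collapse = ", ")))
  }
  counts <- setNames(design[[col]], design$taxon)
  close_composition(counts[counts > 0])
}

pool_columns <- function(design) {
  if (!"taxon" %in% names(design)) {
    abort("`design` must contain a `taxon` column.")
  }
  grep("^pool_", names(design), value = TRUE)
}

#' Root mean square error between observed and expected compositions
#'
#' An accuracy metric for quantitative performance: the root mean square
#' difference between observed and expected relative abundances across
#' sample-taxon cells, reported in percentage points (smaller is less
#' biased).
#'
#' With `aggregate = "pooled"` (default) all cells of all pairs enter one
#' root mean square; with `"per_sample"` each pair yields its own RMSE and
#' the mean of those is returned.
#'
#' @param observed,expected A pair of composition vectors, or paired lists of
#'   them; within each pair the taxon sets must match.
#' @param aggregate `"pooled"` or `"per_sample"`.
#' @return RMSE in percentage points.
#' @examples
#' rmse_composition(c(0.6, 0.4), c(0.5, 0.5)) # 10
#' @export
rmse_composition <- function(observed, expected,
                             aggregate = c("pooled", "per_sample")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(observed)) observed <- list(observed)
  if (!is.list(expected)) expected <- list(expected)
  if (length(observed) != length(expected) || length(observed) == 0) {
    abort("`observed` and `expected` must be non-empty paired lists.")
  }
  sq <- Map(function(o, e) {
    check_named_numeric(o, "observed")
    check_named_numeric(e, "expected")
    check_same_taxa(o, e, "observed", "expected")
    e <- align_taxa(e, o)
    (o - e)^2
  }, observed, expected)
  if (aggregate == "pooled") {
    sqrt(mean(unlist(sq))) * 100
  } else {
    mean(vapply(sq, function(s) sqrt(mean(s)), numeric(1))) * 100
  }
}
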