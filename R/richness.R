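#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw, one per sample) to exactly `depth` reads, removing
#' the confounding effect of differing sequencing depths before richness
#' comparisons. Samples with fewer than `depth` total reads are dropped with
#' a warning.
#'
#' @param counts Integer matrix of reads, taxa x samples.
#' @param depth Target depth (default 100000 reads).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Rarefied count matrix (every retained column sums to `depth`).
#' @export
rarefy_counts <- function(counts, depth = 100000, seed = NULL) {
  check_counts(counts)
  depth <- check_scalar_count(depth, "depth")
  seed <- check_seed(seed)
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) {
    abort(sprintf("no sample reaches the rarefaction depth of %d reads.",
                  depth))
  }
  if (any(!keep)) {
    warn(sprintf("%d sample(s) below %d reads dropped: %s",
                 sum(!keep), depth,
                 paste(colnames(counts)[!keep], collapse = ", ")))
  }
  sub <- counts[, keep, drop = FALSE]
  rare <- withr::with_seed(seed, {
    # vegan advises when the smallest nonzero count exceeds 1; harmless here
    withCallingHandlers(
      t(vegan::rrarefy(t(sub), sample = depth)),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  storage.mode(rare) <- "integer"
  rare
}

#' Observed richness per sample
#'
#' @param counts Count matrix, taxa x samples.
#' @return Named integer vector: number of taxa (or ASVs) with nonzero
#'   counts in each sample.
#' @export
observed_richness <- function(counts) {
  check_counts(counts)
  colSums(counts > 0)
}

#' One-way analysis of variance for richness
#'
#' Standard one-way decomposition (between / within group mean squares) of
#' per-sample richness, as used to compare ASV counts between extraction
#' protocols, primer sets and workflow stages.
#'
#' @param values Numeric vector of per-sample richness.
#' @param groups Group labels, same length as `values`.
#' @return List with elements `f`, `df1`, `df2`, `p` and the `aov` fit.
#'   If all values are identical (both sums of squares zero) `f` is
#'   reported as 0 with a warning.
#' @export
richness_anova <- function(values, groups) {
  g <- validate_groups(values, groups, min_groups = 2)
  if (length(values) <= nlevels(g)) {
    abort("need more observations than groups.")
  }
  if (sum((values - mean(values))^2) < 1e-12 * max(1, mean(values)^2)) {
    warn("zero between- and within-group variation; F reported as 0.")
    return(list(f = 0, df1 = nlevels(g) - 1,
                df2 = length(values) - nlevels(g), p = 1, fit = NULL))
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  df1 <- tab$Df[1]
  df2 <- tab$Df[2]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) {
    warn("zero between- and within-group variation; F reported as 0.")
    f <- 0
    p <- 1
  }
  list(f = f, df1 = df1, df2 = df2, p = p, fit = fit)
}

#' Tukey's honest significant difference test
#'
#' Post-hoc pairwise comparisons after a one-way ANOVA, with p-values
#' adjusted via the studentized-range distribution.
#'
#' @inheritParams richness_anova
#' @param alpha Familywise significance level for the `significant` flag.
#' @return Tibble with one row per group pair: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- validate_groups(values, groups, min_groups = 2)
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group1 = vapply(pairs, `[`, character(1), 1),
    group2 = vapply(pairs, `[`, character(1), 2),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
}

validate_groups <- function(values, groups, min_groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  if (anyNA(values)) abort("`values` contains missing entries.")
  g <- factor(groups)
  if (any(table(g) == 0)) abort("every group must have observations.")
  if (nlevels(g) < min_groups) {
    abort(sprintf("need at least %d groups.", min_groups))
  }
  g
}
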