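#' Partition total protocol bias into workflow components
#'
#' Mock communities entering the workflow at different stages see different
#' subsets of the protocol: whole-insect pools accumulate extraction, PCR
#' and sequencing bias; DNA pools skip extraction; PCR (amplicon) pools skip
#' extraction and PCR. Under the multiplicative bias model the stage
#' components are recovered by element-wise division:
#' \deqn{extraction = center(total / dna), \quad
#'       pcr = center(dna / pcr\_pools), \quad
#'       sequencing = center(pcr\_pools)}
#' so that the re-centered product of the three components reconstructs the
#' centered total bias exactly.
#'
#' When all three estimates carry bootstrap replicate matrices with the same
#' number of replicates, uncertainty is propagated by combining replicate r
#' of each stage (a joint bootstrap, since the stage groups are disjoint);
#' otherwise log-scale variances are added independently.
#'
#' @param total `bias_estimate` from whole-insect pools (one extraction
#'   protocol, one primer set).
#' @param dna_stage `bias_estimate` from the DNA pools (same primer).
#' @param pcr_stage `bias_estimate` from the PCR pools (same primer).
#' @param protocol,primer Optional labels stored in the result.
#' @return A `partitioned_bias` object with components `extraction`, `pcr`
#'   and `sequencing`, each a list of centered `efficiency`, `se_log` and
#'   percentile `ci`. Taxa missing from any stage are excluded from all
#'   components with a warning.
#' @seealso [bias_trajectory()]
#' @export
partition_bias <- function(total, dna_stage, pcr_stage,
                           protocol = NULL, primer = NULL) {
  for (x in list(total, dna_stage, pcr_stage)) {
    if (!inherits(x, "bias_estimate")) {
      abort("`total`, `dna_stage` and `pcr_stage` must be bias_estimate objects.")
    }
  }
  taxa <- Reduce(intersect, list(names(total$efficiency),
                                 names(dna_stage$efficiency),
                                 names(pcr_stage$efficiency)))
  if (length(taxa) == 0) abort("no taxa shared by all three stages.")
  lost <- setdiff(union(names(total$efficiency),
                        union(names(dna_stage$efficiency),
                              names(pcr_stage$efficiency))), taxa)
  if (length(lost)) {
    warn(paste0("taxa missing from at least one stage, excluded from all ",
                "components: ", paste(lost, collapse = ", ")))
  }

  lt <- log(total$efficiency[taxa])
  ld <- log(dna_stage$efficiency[taxa])
  lp <- log(pcr_stage$efficiency[taxa])
  comp_log <- list(
    extraction = center_log(lt - ld),
    pcr        = center_log(ld - lp),
    sequencing = center_log(lp)
  )

  reps <- paired_component_replicates(total, dna_stage, pcr_stage, taxa)
  components <- lapply(names(comp_log), function(nm) {
    se <- ci <- NULL
    if (!is.null(reps)) {
      R <- reps[[nm]]
      se <- apply(R, 1, sd, na.rm = TRUE)
      se[is.na(se)] <- 0
      qs <- t(apply(R, 1, quantile,
                    probs = c(0.025, 0.975, 0.25, 0.75), na.rm = TRUE))
      ci <- exp(qs)
      colnames(ci) <- c("lo95", "hi95", "lo50", "hi50")
    } else {
      se <- independent_se(nm, total, dna_stage, pcr_stage, taxa)
    }
    eff <- exp(comp_log[[nm]])
    attr(eff, "centered") <- TRUE
    list(efficiency = eff, se_log = se, ci = ci,
         log_replicates = if (is.null(reps)) NULL else reps[[nm]])
  })
  names(components) <- names(comp_log)

  total_eff <- exp(center_log(lt))
  attr(total_eff, "centered") <- TRUE
  structure(
    list(
      components = components,
      total = total_eff,
      taxa = taxa,
      protocol = protocol,
      primer = primer,
      se_propagation = if (is.null(reps)) "independent" else "paired"
    ),
    class = "partitioned_bias"
  )
}

center_log <- function(l) l - mean(l)

paired_component_replicates <- function(total, dna_stage, pcr_stage, taxa) {
  Rs <- list(total$log_replicates, dna_stage$log_replicates,
             pcr_stage$log_replicates)
  if (any(vapply(Rs, is.null, logical(1)))) return(NULL)
  nb <- vapply(Rs, ncol, integer(1))
  if (length(unique(nb)) != 1) return(NULL)
  rt <- total$log_replicates[taxa, , drop = FALSE]
  rd <- dna_stage$log_replicates[taxa, , drop = FALSE]
  rp <- pcr_stage$log_replicates[taxa, , drop = FALSE]
  list(
    extraction = apply(rt - rd, 2, center_log_na) |>
      matrix(nrow = length(taxa), dimnames = list(taxa, NULL)),
    pcr = apply(rd - rp, 2, center_log_na) |>
      matrix(nrow = length(taxa), dimnames = list(taxa, NULL)),
    sequencing = apply(rp, 2, center_log_na) |>
      matrix(nrow = length(taxa), dimnames = list(taxa, NULL))
  )
}

center_log_na <- function(l) {
  ok <- !is.na(l)
  l[ok] <- l[ok] - mean(l[ok])
  l
}

independent_se <- function(nm, total, dna_stage, pcr_stage, taxa) {
  g <- function(x) {
    s <- x$se_log[taxa]
    s[is.na(s)] <- 0
    s
  }
  switch(nm,
    extraction = sqrt(g(total)^2 + g(dna_stage)^2),
    pcr = sqrt(g(dna_stage)^2 + g(pcr_stage)^2),
    sequencing = g(pcr_stage)
  )
}

#' @export
print.partitioned_bias <- function(x, ...) {
  cat("<partitioned_bias>",
      if (!is.null(x$protocol)) paste0("protocol=", x$protocol),
      if (!is.null(x$primer)) paste0("primer=", x$primer), "\n")
  cat(sprintf("  %d taxa; SE propagation: %s\n",
              length(x$taxa), x$se_propagation))
  print(tibble::as_tibble(x), n = 6)
  invisible(x)
}

#' Tabular view of a partitioned bias
#'
#' @param x A `partitioned_bias`.
#' @param ... Unused.
#' @return Tibble with one row per taxon x component.
#' @method as_tibble partitioned_bias
#' @export
as_tibble.partitioned_bias <- function(x, ...) {
  purrr::imap_dfr(x$components, function(comp, nm) {
    tibble::tibble(
      taxon = x$taxa,
      component = nm,
      efficiency = unname(comp$efficiency),
      se_log = unname(comp$se_log),
      ci_lo = if (is.null(comp$ci)) NA_real_ else unname(comp$ci[, "lo95"]),
      ci_hi = if (is.null(comp$ci)) NA_real_ else unname(comp$ci[, "hi95"])
    )
  })
}

#' Per-taxon abundance trajectory through the workflow
#'
#' Starting from a relative abundance of one, each taxon's abundance is
#' multiplied sequentially by the partitioned bias components (extraction,
#' then PCR, then sequencing/bioinformatics); every cumulative step is
#' re-centered to the geometric-mean taxon. The final step therefore equals
#' the centered total protocol bias.
#'
#' @param p A `partitioned_bias`.
#' @return Tibble with columns `taxon`, `start`, `extraction`, `pcr`,
#'   `sequencing` (relative abundance after each step).
#' @export
bias_trajectory <- function(p) {
  if (!inherits(p, "partitioned_bias")) {
    abort("`p` must be a partitioned_bias object.")
  }
  le <- log(p$components$extraction$efficiency)
  lp <- log(p$components$pcr$efficiency)
  ls <- log(p$components$sequencing$efficiency)
  tibble::tibble(
    taxon = p$taxa,
    start = 1,
    extraction = unname(exp(center_log(le))),
    pcr = unname(exp(center_log(le + lp))),
    sequencing = unname(exp(center_log(le + lp + ls)))
  )
}
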