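# TSV dialect used throughout: tab-separated, header row, UTF-8, '.' decimal.

#' Read a mock-community design table
#'
#' Expects a `taxon` column (unique names), an optional `order` column, and
#' one non-negative integer count column per pool named `pool_<id>`.
#'
#' @param path Path to a TSV file.
#' @return Design tibble.
#' @export
read_design <- function(path) {
  design <- read_tsv_checked(path)
  if (!"taxon" %in% names(design)) {
    abort(sprintf("%s: missing `taxon` column.", path))
  }
  if (anyDuplicated(design$taxon)) {
    abort(sprintf("%s: duplicate taxon names.", path))
  }
  cols <- pool_columns(design)
  if (length(cols) == 0) {
    abort(sprintf("%s: no `pool_<id>` columns found.", path))
  }
  for (cl in cols) {
    v <- design[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      abort(sprintf("%s: column `%s` must hold non-negative integers.",
                    path, cl))
    }
    design[[cl]] <- as.integer(v)
  }
  design
}

#' Read a taxa x samples count table
#'
#' First column `taxon`, remaining columns one per sample, non-negative
#' numeric entries.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with taxon rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  tab <- read_tsv_checked(path)
  if (names(tab)[1] != "taxon") {
    abort(sprintf("%s: first column must be `taxon`.", path))
  }
  if (ncol(tab) < 2) abort(sprintf("%s: no sample columns.", path))
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$taxon
  if (!is.numeric(m) || anyNA(m)) {
    abort(sprintf("%s: counts must be numeric and complete.", path))
  }
  check_counts(m)
  m
}

#' Write a count table
#'
#' @param counts Count matrix, taxa x samples.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  check_counts(counts)
  tab <- tibble::as_tibble(counts, rownames = "taxon")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a per-taxon trait table
#'
#' One row per taxon x primer set with columns `taxon`, `primer`,
#' `fwd_mismatch`, `rev_mismatch`, `gc`, `volume_mm3`, `hardness` (and
#' optionally `order`). Ranges are validated: mismatch and GC in \[0, 1\],
#' positive volumes, hardness in 1–3 (1 = soft, 2 = intermediate, 3 = hard).
#'
#' @param path Path to a TSV file.
#' @return Trait tibble.
#' @export
read_traits <- function(path) {
  traits <- read_tsv_checked(path)
  check_traits(traits)
  if (anyDuplicated(traits[, c("taxon", "primer")])) {
    abort(sprintf("%s: duplicate taxon x primer rows.", path))
  }
  traits$hardness <- as.integer(traits$hardness)
  traits
}

#' Read sample metadata
#'
#' Columns `sample_id` (unique), `pool`, `stage` (insect, dna or pcr),
#' `extraction` (quickextract, dneasy or none), `primer`, `run`.
#'
#' @param path Path to a TSV file.
#' @return Metadata tibble.
#' @export
read_meta <- function(path) {
  meta <- read_tsv_checked(path)
  check_meta(meta)
  bad_stage <- setdiff(unique(meta$stage), c("insect", "dna", "pcr"))
  if (length(bad_stage)) {
    abort(sprintf("%s: unknown stage value(s): %s", path,
                  paste(bad_stage, collapse = ", ")))
  }
  bad_ext <- setdiff(unique(meta$extraction),
                     c("quickextract", "dneasy", "none"))
  if (length(bad_ext)) {
    abort(sprintf("%s: unknown extraction value(s): %s", path,
                  paste(bad_ext, collapse = ", ")))
  }
  meta
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)))
  )
  if (nrow(tab) == 0 || ncol(tab) == 0) {
    abort(sprintf("%s: empty table.", path))
  }
  tab
}

#' Packaged eight-pool mock-community design
#'
#' The design table shipped with the package: individuals per taxon for the
#' eight insect pools (16 species; six pools of 100 individuals, two of 101
#' that additionally contain a single Bradysia nr. ocellaris).
#'
#' @return Design tibble (see [read_design()]).
#' @export
mock_design_fixture <- function() {
  read_design(system.file("extdata", "mock_design.tsv",
                          package = "mockbias", mustWork = TRUE))
}

#' Packaged insect trait table
#'
#' Per-taxon molecular traits (forward/reverse primer-mismatch proportions
#' and amplicon GC fraction, per primer set) and morphological traits (body
#' volume in mm^3 averaged over 10 specimens; exoskeleton hardness 1 = soft,
#' 2 = intermediate, 3 = hard).
#'
#' @return Trait tibble (see [read_traits()]).
#' @export
insect_traits_fixture <- function() {
  read_traits(system.file("extdata", "insect_traits.tsv",
                          package = "mockbias", mustWork = TRUE))
}

#' Serialize a bias estimate
#'
#' @param x A `bias_estimate`.
#' @param path Output path; `.json` extension selects JSON, anything else
#'   TSV.
#' @return Invisibly, `path`.
#' @export
write_bias_estimate <- function(x, path) {
  stopifnot(inherits(x, "bias_estimate"))
  tab <- tibble::as_tibble(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(group = x$group, n_samples = x$n_samples, n_boot = x$n_boot,
           estimate = tab),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}
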