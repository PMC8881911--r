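# internal helpers shared across modules

geometric_mean <- function(x) exp(mean(log(x)))

# named-numeric checks -----------------------------------------------------

check_named_numeric <- function(x, arg) {
  if (!is.numeric(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", arg))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", arg))
  invisible(x)
}

check_same_taxa <- function(x, y, arg_x, arg_y) {
  if (is.null(names(x)) || is.null(names(y))) {
    if (length(x) != length(y)) {
      abort(sprintf("`%s` and `%s` must cover the same taxa.", arg_x, arg_y))
    }
    return(invisible(NULL))
  }
  if (!setequal(names(x), names(y))) {
    abort(sprintf(
      "`%s` and `%s` must cover the same taxa (mismatch: %s).",
      arg_x, arg_y,
      paste(union(setdiff(names(x), names(y)), setdiff(names(y), names(x))),
            collapse = ", ")
    ))
  }
  invisible(NULL)
}

# align y to the name order of x (no-op for unnamed vectors)
align_taxa <- function(y, x) {
  if (is.null(names(x)) || is.null(names(y))) return(y)
  y[names(x)]
}

check_scalar_count <- function(x, arg, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) abort("a `seed` is required for reproducibility.")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}
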