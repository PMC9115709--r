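#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats coef lm median pf pt qt rnorm runif rlnorm sd setNames t.test var
#' @importFrom utils head modifyList
NULL

# classed condition helpers so callers can distinguish failure modes
stop_spq <- function(message, class, ...) {
  abort(message, class = c(paste0("spq_error_", class), "spq_error"), ...)
}

warn_spq <- function(message, class, ...) {
  warn(message, class = c(paste0("spq_warning_", class), "spq_warning"), ...)
}

#' Run code with a reproducible, locally scoped RNG seed
#'
#' If `seed` is `NULL` the expression runs against the current RNG stream.
#' @noRd
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# deterministic per-stage sub-seeds fanned out from one top-level seed;
# kept below 2^31 so they remain valid R integers
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 48271 + stage * 10007) %% 2147483647)
}

is_count_like <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol & x >= 0
}

assert_columns <- function(data, cols, what, class = "missing_data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_spq(
      sprintf("%s: missing required column(s): %s", what, paste(missing, collapse = ", ")),
      class = class, columns = missing
    )
  }
  invisible(data)
}

assert_no_na <- function(data, cols, what) {
  for (col in cols) {
    if (anyNA(data[[col]])) {
      rows <- which(is.na(data[[col]]))
      stop_spq(
        sprintf("%s: missing values in '%s' (rows %s)", what, col,
                paste(head(rows, 5), collapse = ", ")),
        class = "missing_data", column = col, rows = rows
      )
    }
  }
  invisible(data)
}
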