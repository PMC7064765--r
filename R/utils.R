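#' @keywords internal
"_PACKAGE"

# internal assertion helpers ------------------------------------------------

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, finite = TRUE, positive = FALSE,
                         nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_("`%s` must be a single non-missing number", name)
  if (finite && !is.finite(x))
    stop_("`%s` must be finite (got %s)", name, format(x))
  if (positive && x <= 0)
    stop_("`%s` must be > 0 (got %s)", name, format(x))
  if (nonneg && x < 0)
    stop_("`%s` must be >= 0 (got %s)", name, format(x))
  invisible(x)
}

check_numeric_vec <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop_("`%s` must be numeric with no missing values", name)
  if (nonneg && any(x < 0))
    stop_("`%s` must be non-negative (entry %d is %s)",
          name, which(x < 0)[1L], format(x[which(x < 0)[1L]]))
  invisible(x)
}
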