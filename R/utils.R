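`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_stage <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Two-sided p-value of a Pearson correlation via the t transform with
# n - 2 degrees of freedom.  r is clamped away from +/-1 to keep the
# statistic finite; p is floored downstream where -log10 is taken.
#' @noRd
cor_pvalue <- function(r, n) {
  assert_that(n >= 3, "need at least 3 samples for a correlation p-value")
  r <- pmin(pmax(r, -1), 1)
  r2 <- pmin(r^2, 1 - 1e-15)
  tval <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
}

# Column standardization that errors informatively on zero variance.
#' @noRd
standardize_columns <- function(x, what = "column") {
  sds <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance ", what, ": ", paste(colnames(x)[bad], collapse = ", "),
         call. = FALSE)
  }
  scale(x)
}

#' @noRd
is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x > 0
}
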