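#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a treatment comparison
#'
#' `tidy()` returns the ANOVA table (default), the Tukey HSD pairs
#' (`which = "tukey"`), or the compact letter display (`which = "letters"`)
#' as a tibble; `glance()` returns a one-row summary of the fit and the
#' assumption checks.
#'
#' @param x A `rhizo_comparison` from [compare_groups()].
#' @param which One of `"anova"`, `"tukey"`, `"letters"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rhizo_comparison <- function(x, which = c("anova", "tukey", "letters"),
                                  ...) {
  which <- match.arg(which)
  switch(which, anova = x$anova, tukey = x$tukey, letters = x$letters)
}

#' @rdname tidy.rhizo_comparison
#' @export
glance.rhizo_comparison <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    factors = paste(x$factors, collapse = "*"),
    transform = x$transform_applied,
    fligner_p = x$assumptions$fligner_p,
    shapiro_p = x$assumptions$shapiro_p,
    alpha = x$alpha,
    n = length(stats::residuals(x$fit)))
}

#' Tidy an instrument correction model
#'
#' @param x A `csia_correction` from [fit_instrument_correction()].
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row fit
#'   summary (residual sd before and after correction).
#' @export
tidy.csia_correction <- function(x, ...) {
  tibble::tibble(
    term = c("offset", "drift_slope", "amount_slope"),
    estimate = c(x$offset, x$drift_slope, x$amount_slope))
}

#' @rdname tidy.csia_correction
#' @export
glance.csia_correction <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(n = 0L, sd_uncorrected = NA_real_,
                          sd_corrected = NA_real_))
  }
  err <- x$fit$model$err
  tibble::tibble(n = x$n,
                 sd_uncorrected = stats::sd(err),
                 sd_corrected = stats::sd(stats::residuals(x$fit)))
}
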