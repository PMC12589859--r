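#' Summary of residual normality for a mixed-model fit
#'
#' Reports skewness, excess kurtosis and a Kolmogorov-Smirnov distance of
#' the conditional residuals against a normal with matching mean and SD. A
#' log10-transformed richness response typically shows some residual
#' skew because richness is a small positive integer.
#'
#' @param fit A `troph_fit`.
#' @return Tibble with `skewness`, `excess_kurtosis`, `ks_distance`, `n`.
#' @export
residual_normality_summary <- function(fit) {
  stopifnot(inherits(fit, "troph_fit"))
  r <- stats::residuals(fit$model)
  n <- length(r)
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12) {
    warning("residuals are (near-)constant: degenerate distribution",
            call. = FALSE)
    return(tibble::tibble(skewness = NA_real_, excess_kurtosis = NA_real_,
                          ks_distance = NA_real_, n = n))
  }
  m <- mean(r)
  z <- (r - m) / s
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  ks <- suppressWarnings(ks.test(r, "pnorm", m, s))$statistic
  tibble::tibble(skewness = skew, excess_kurtosis = kurt,
                 ks_distance = unname(ks), n = n)
}
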