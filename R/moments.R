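#' Moment statistics of a sample
#'
#' Mean, standard deviation, coefficient of variation, skewness and excess
#' kurtosis. Skewness and kurtosis use the bias-corrected sample estimators
#' (e1071 type 2, the SAS/SPSS convention); kurtosis is reported as excess
#' (0 for a normal distribution). For constant samples the shape moments are
#' undefined and returned as `NA`.
#'
#' @param x numeric vector, length >= 2 for sd.
#' @return One-row data.frame: n, mean, sd, cv, skewness, kurtosis.
#' @export
moment_summary <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n >= 2) sd(x) else NA_real_
  constant <- is.na(s) || s == 0
  data.frame(
    n = n, mean = m, sd = s,
    cv = if (constant || m == 0) NA_real_ else s / m,
    skewness = if (constant || n < 3) NA_real_ else
      e1071::skewness(x, type = 2),
    kurtosis = if (constant || n < 4) NA_real_ else
      e1071::kurtosis(x, type = 2))
}
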