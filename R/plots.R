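# Optional figures (ggplot2 is suggested, not required).

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("plotting requires the 'ggplot2' package")
  }
}

#' Q-Q plot of observed counts against simulated specific energies
#'
#' @param qq A [qq_compare()] result.
#' @return A ggplot object.
#' @export
plot_qq <- function(qq) {
  stopifnot(inherits(qq, "qq_result"))
  require_ggplot()
  ggplot2::ggplot(qq$pairs, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_abline(slope = qq$slope, intercept = qq$intercept,
                         linewidth = 0.4) +
    ggplot2::labs(x = "Specific energy quantile (Gy)",
                  y = "RIF count quantile",
                  subtitle = sprintf("slope %.2f RIF/Gy, R² = %.4f",
                                     qq$slope, qq$r_squared)) +
    ggplot2::theme_minimal()
}

#' Dose-response plot with replicate error bars
#'
#' @param fit A [fit_dose_response()] result.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  require_ggplot()
  pd <- fit$per_dose
  ggplot2::ggplot(pd, ggplot2::aes(x = dose_Gy, y = mean_rif)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_rif - sd_replicate_means,
                                        ymax = mean_rif + sd_replicate_means),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linewidth = 0.4) +
    ggplot2::labs(x = "Dose (Gy)", y = "Mean RIF per nucleus",
                  subtitle = sprintf("%.2f RIF/Gy, R² = %.4f",
                                     fit$slope, fit$r_squared)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("x", "y", "dose_Gy", "mean_rif", "sd_replicate_means"))
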