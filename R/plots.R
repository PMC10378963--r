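#' Plots
#'
#' Presentation helpers; every number they draw comes from the tabular
#' outputs, never the other way around.
#'
#' @name plots
NULL

#' Kaplan-Meier curves by volume quartile
#' @param km A [km_by_quartile()] result.
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  stopifnot(inherits(km, "km_quartiles"))
  d <- km$curves
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  color = .data$quartile,
                                  fill = .data$quartile)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15, linetype = 0) +
    ggplot2::labs(x = "Years since accelerometer measurement",
                  y = "Survival", color = "PA volume", fill = "PA volume") +
    ggplot2::theme_minimal()
}

#' Fitted volume smooth
#' @param curve A [volume_curve()] data frame.
#' @export
plot_volume_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$volume,
                                      y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "PA volume (mg)", y = "log hazard") +
    ggplot2::theme_minimal()
}

#' Fitted intensity weight function
#' @param curve An [intensity_weight_curve()] data frame.
#' @export
plot_intensity_weight <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$z, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Intensity (mg)", y = "weight (log hazard)") +
    ggplot2::theme_minimal()
}

#' Profile hazard-ratio curves by volume quartile
#' @param curves A [profile_hr_by_volume()] data frame.
#' @export
plot_profile_hr <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$s, y = .data$hr,
                                       color = .data$stratum,
                                       fill = .data$stratum)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.12, linetype = 0) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::scale_x_continuous(
      breaks = c(0, 0.5, 1), labels = c("low risk", "average", "high risk")) +
    ggplot2::labs(x = "Intensity risk profile", y = "Hazard ratio",
                  color = "PA volume", fill = "PA volume") +
    ggplot2::theme_minimal()
}
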