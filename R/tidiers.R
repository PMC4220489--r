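# broom-style tidiers and ggplot2 autoplot methods for fitted objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.ab_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = vapply(x$params, as.numeric, numeric(1)))
}

#' @export
glance.ab_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data),
         sigma = sqrt(x$rss / max(1, nrow(x$data) - length(x$params))))
}

#' @export
tidy.ab_qc_panel <- function(x, ...) x$classes

#' @export
glance.ab_qc_panel <- function(x, ...) {
  tibble(n = x$n, n_unique = x$n_unique,
         fraction_defective = x$fraction_defective)
}

#' @export
tidy.ab_interface <- function(x, ...) x$residues

#' @export
glance.ab_interface <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary[, c("side", "buried_area", "n_interface_residues")],
    names_from = "side",
    values_from = c("buried_area", "n_interface_residues")
  ) |>
    mutate(n_hbonds = nrow(x$hbonds), n_salt_bridges = nrow(x$salt_bridges))
}

#' @export
tidy.ab_kih <- function(x, ...) x$knobs

#' Plot a kinetic ELISA fit
#'
#' Observed OD against analyte concentration (log scale), one colour per
#' incubation time, with the fitted model overlaid.
#'
#' @param object `ab_kinelisa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ab_kinelisa_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  d$hours <- factor(round(d$time_s / 3600, 2))
  ggplot2::ggplot(d[d$conc_M > 0, ],
                  ggplot2::aes(x = .data$conc_M, y = .data$od,
                               colour = .data$hours)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "analyte concentration (M)", y = "OD",
                  colour = "incubation (h)")
}

#' Plot a sensorgram fit
#'
#' @param object `ab_spr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ab_spr_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  d$conc_nM <- factor(signif(d$conc_M * 1e9, 2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$ru,
                                  group = .data$conc_nM,
                                  colour = .data$conc_nM)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (s)", y = "response (RU)", colour = "conc (nM)")
}

#' Plot an ITC fit
#'
#' Per-injection heats against molar ratio with the fitted one-site
#' isotherm.
#'
#' @param object `ab_itc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ab_itc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  if (!"molar_ratio" %in% names(d)) d$molar_ratio <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molar_ratio, y = .data$heat_J)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "molar ratio (syringe/cell)", y = "injection heat (J)")
}

#' Plot a thermal melt fit
#'
#' @param object `ab_melt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ab_melt_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_vline(xintercept = object$params$Tm, linetype = 2) +
    ggplot2::labs(x = "temperature", y = "signal")
}

#' Plot melting temperatures against denaturant concentration
#'
#' Scatter of Tm against GuHCl with the least-squares extrapolation line
#' back to 0 M.
#'
#' @param T_m Melting temperatures.
#' @param guhcl_M GuHCl concentrations, M.
#' @return A ggplot object.
#' @export
plot_tm_extrapolation <- function(T_m, guhcl_M) {
  ex <- extrapolate_tm(T_m, guhcl_M)
  d <- tibble(guhcl_M = guhcl_M, T_m = T_m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$guhcl_M, y = .data$T_m)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = ex$tm_at_zero, slope = ex$slope,
                         linetype = 2) +
    ggplot2::expand_limits(x = 0, y = ex$tm_at_zero) +
    ggplot2::labs(x = "GuHCl (M)", y = "Tm")
}
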