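# ggplot2 figure helpers.

#' Stacked single-cone expression profile
#'
#' Per-sample stacked bars of proportional expression, by default for the
#' single-cone group (SWS1 paralogues and SWS2B) — the standard way of
#' displaying variable single-cone opsin usage across species.
#'
#' @param proportions Output of [proportional_expression()].
#' @param group Gene group to display; default `"single_cone"`.
#' @return A ggplot object.
#' @export
plot_expression_profile <- function(proportions, group = "single_cone") {
  dat <- filter(proportions, .data$group == !!group, !is.na(.data$proportion))
  if (nrow(dat) == 0) abort("no defined proportions to plot for this group")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                    fill = .data$gene)) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1), expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "Proportion of group expression",
                  fill = "Opsin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pigment absorbance curves, optionally with a co-expression mixture
#'
#' Draws A1 absorbance templates for the given peak wavelengths and, when
#' two or more are supplied and `mixture = TRUE`, overlays their
#' equal-weight co-expression mixture as a dashed curve.
#'
#' @param lambda_max_nm Numeric vector of peak wavelengths (nm).
#' @param wavelength_nm Wavelength grid; default 300-550 nm.
#' @param mixture Overlay the equal-weight mixture? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_absorbance_curves <- function(lambda_max_nm, wavelength_nm = 300:550,
                                   mixture = TRUE) {
  curves <- map(lambda_max_nm, pigment_template,
                wavelength_nm = wavelength_nm)
  dat <- bind_rows(map2(curves, lambda_max_nm,
                        ~ mutate(.x, pigment = sprintf("%g nm", .y))))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$wavelength_nm,
                                         y = .data$value,
                                         colour = .data$pigment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Normalised absorbance",
                  colour = expression(lambda[max])) +
    ggplot2::theme_minimal()
  if (mixture && length(curves) >= 2) {
    mix <- coexpression_mixture(curves)
    p <- p + ggplot2::geom_line(data = mutate(mix, pigment = "mixture"),
                                linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a spectrum with its classification annotation
#'
#' Line plot of a transmission or reflectance spectrum; for transmission
#' spectra the T50 and the 400 nm UV boundary are marked.
#'
#' @param spectrum Tibble `wavelength_nm`, `value`.
#' @param kind `"transmission"` or `"reflectance"`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, kind = c("transmission", "reflectance")) {
  kind <- match.arg(kind)
  spectrum <- check_spectrum(spectrum)
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$wavelength_nm,
                                              y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = if (kind == "transmission") "Transmission (%)"
                      else "Reflectance (%)") +
    ggplot2::theme_minimal()
  if (kind == "transmission") {
    t50 <- compute_t50(spectrum)
    p <- p +
      ggplot2::geom_vline(xintercept = t50$t50_nm, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = 400, linetype = "dotted") +
      ggplot2::annotate("text", x = t50$t50_nm, y = max(spectrum$value),
                        label = sprintf("T50 = %.1f nm (%s)", t50$t50_nm,
                                        t50$classification),
                        hjust = -0.05, vjust = 1, size = 3)
  }
  p
}
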