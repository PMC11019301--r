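# Spectra: ocular-media T50 classification, UV reflectance calls, replicate
# averaging, and A1 visual-pigment absorbance templates.

check_spectrum <- function(spectrum) {
  need <- c("wavelength_nm", "value")
  if (!all(need %in% names(spectrum))) {
    abort("a spectrum needs columns wavelength_nm and value")
  }
  w <- spectrum$wavelength_nm
  if (any(diff(w) <= 0)) abort("wavelengths must be strictly increasing")
  if (any(!is.finite(spectrum$value))) abort("spectrum values must be finite")
  spectrum
}

#' Read a two-column spectrum file
#'
#' CSV or TSV with wavelength in the first column and one or more value
#' columns; additional columns are treated as replicate measurements and
#' returned in long form (`replicate` column).
#'
#' @param path Path to the file; delimiter guessed from the extension.
#' @return A tibble `wavelength_nm`, `replicate`, `value` (single-replicate
#'   files get `replicate = 1`).
#' @export
read_spectrum <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#")
  if (ncol(raw) < 2) abort("spectrum file needs at least two columns")
  names(raw)[1] <- "wavelength_nm"
  raw |>
    tidyr::pivot_longer(-"wavelength_nm", names_to = "replicate",
                        values_to = "value") |>
    mutate(replicate = as.integer(factor(.data$replicate,
                                         levels = unique(.data$replicate)))) |>
    arrange(.data$replicate, .data$wavelength_nm)
}

#' Ocular-media T50 and UV-transmission class
#'
#' Finds the wavelength at which a transmission spectrum reaches 50% of its
#' maximal transmittance, by linear interpolation between the samples
#' bracketing the longest-wavelength upward crossing (ocular media are
#' long-pass, so the biologically meaningful cutoff is the final rise; with
#' noise, earlier spurious crossings are ignored). Lenses are classified
#' UV-transmitting when T50 < 400 nm and UV-blocking when T50 >= 400 nm
#' (strict inequality for transmitting).
#'
#' @param spectrum Tibble `wavelength_nm`, `value` (percent transmission),
#'   covering at least 300-700 nm.
#' @return A one-row tibble `t50_nm`, `classification`, `note`.
#' @examples
#' s <- simulate_spectrum(midpoint_nm = 380, noise_sd = 0, seed = 1)
#' compute_t50(s)
#' @export
compute_t50 <- function(spectrum) {
  spectrum <- check_spectrum(spectrum)
  w <- spectrum$wavelength_nm
  if (min(w) > 300 || max(w) < 700) {
    abort("transmission spectrum must cover at least 300-700 nm")
  }
  # light 5-point moving average: damps measurement noise in the maximum
  # and the crossing region; exact for symmetric sigmoids on even grids
  raw <- spectrum$value
  v <- if (length(raw) >= 7) {
    vapply(seq_along(raw), function(i) {
      mean(raw[max(1, i - 2):min(length(raw), i + 2)])
    }, numeric(1))
  } else raw
  half <- max(v) / 2
  note <- NA_character_
  if (all(v >= half)) {
    # e.g. flat 100% transmission: no crossing exists
    t50 <- w[1]
    note <- "degenerate: spectrum never falls below half-maximum; T50 set to first sample"
  } else {
    up <- which(v[-length(v)] < half & v[-1] >= half)
    if (length(up) == 0) abort("spectrum never rises through 50% of its maximum")
    i <- max(up)  # longest-wavelength upward crossing
    t50 <- w[i] + (half - v[i]) * (w[i + 1] - w[i]) / (v[i + 1] - v[i])
    note <- "linear interpolation at the longest-wavelength upward crossing"
  }
  tibble(
    t50_nm = t50,
    classification = if_else(t50 < 400, "UV-transmitting", "UV-blocking"),
    note = note
  )
}

#' Classify a reflectance spectrum for UV colouration
#'
#' UV colouration is defined as spectral reflection below 400 nm. Because a
#' binary call needs a magnitude criterion, the flag is `TRUE` when the peak
#' reflectance inside the UV band reaches at least `criterion_fraction` of
#' the spectrum's overall peak (default 0.2); the criterion is echoed in the
#' output.
#'
#' @param spectrum Tibble `wavelength_nm`, `value` (percent reflectance).
#' @param band UV band, default `c(300, 400)` nm; must be covered.
#' @param criterion_fraction Fraction of overall peak required in-band.
#' @return A one-row tibble `uv_reflective`, `band_peak`, `overall_peak`,
#'   `criterion_fraction`.
#' @export
classify_uv_reflectance <- function(spectrum, band = c(300, 400),
                                    criterion_fraction = 0.2) {
  spectrum <- check_spectrum(spectrum)
  if (any(spectrum$value < 0)) abort("reflectance must be >= 0")
  w <- spectrum$wavelength_nm
  if (min(w) > band[1] || max(w) < band[2]) {
    abort("spectrum does not cover the UV band")
  }
  in_band <- w >= band[1] & w <= band[2]
  band_peak <- max(spectrum$value[in_band])
  overall_peak <- max(spectrum$value)
  tibble(
    uv_reflective = band_peak >= criterion_fraction * overall_peak,
    band_peak = band_peak,
    overall_peak = overall_peak,
    criterion_fraction = criterion_fraction
  )
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean. Spectra on different wavelength grids are
#' first resampled by linear interpolation onto the shared (intersection)
#' range of the densest grid; no extrapolation beyond measured ranges. The
#' resampling applied is recorded in attribute `"resampled"`.
#'
#' @param spectra A list of spectrum tibbles, or a long tibble with a
#'   `replicate` column (as from [read_spectrum()]).
#' @return A spectrum tibble `wavelength_nm`, `value`.
#' @export
average_replicates <- function(spectra) {
  if (is.data.frame(spectra)) {
    if (!"replicate" %in% names(spectra)) {
      return(check_spectrum(spectra))
    }
    spectra <- spectra |>
      group_by(.data$replicate) |>
      dplyr::group_split() |>
      map(~ select(.x, "wavelength_nm", "value"))
  }
  if (length(spectra) == 0) abort("no spectra to average")
  spectra <- map(spectra, check_spectrum)
  grids <- map(spectra, "wavelength_nm")
  common <- all(map_dbl(grids, length) == length(grids[[1]])) &&
    all(map_chr(grids, ~ paste(.x, collapse = ",")) ==
          paste(grids[[1]], collapse = ","))
  if (common) {
    out <- tibble(
      wavelength_nm = grids[[1]],
      value = Reduce(`+`, map(spectra, "value")) / length(spectra)
    )
    attr(out, "resampled") <- FALSE
    return(out)
  }
  lo <- max(map_dbl(grids, min))
  hi <- min(map_dbl(grids, max))
  if (lo >= hi) abort("spectra have no overlapping wavelength range")
  target <- grids[[which.max(map_dbl(grids, length))]]
  target <- target[target >= lo & target <= hi]
  vals <- map(spectra, ~ approx(.x$wavelength_nm, .x$value, xout = target)$y)
  out <- tibble(wavelength_nm = target,
                value = Reduce(`+`, vals) / length(vals))
  attr(out, "resampled") <- TRUE
  out
}

#' A1 visual-pigment absorbance template
#'
#' Normalised absorbance curve of an A1 (11-cis retinal) visual pigment
#' with the given peak wavelength, using the Govardovskii et al. (2000)
#' rhodopsin nomogram (alpha band plus beta band), normalised to a maximum
#' of 1 on the grid. Suitable for rendering pigment absorbance curves and
#' co-expression mixtures.
#'
#' @param lambda_max_nm Peak absorbance, 330-600 nm.
#' @param wavelength_nm Wavelength grid (nm), strictly increasing; must
#'   span `lambda_max_nm`. Default 300-800 at 1 nm.
#' @return A spectrum tibble `wavelength_nm`, `value` in `[0, 1]`.
#' @examples
#' tpl <- pigment_template(360)
#' tpl$wavelength_nm[which.max(tpl$value)]
#' @export
pigment_template <- function(lambda_max_nm, wavelength_nm = 300:800) {
  if (lambda_max_nm < 330 || lambda_max_nm > 600) {
    abort("lambda_max_nm must be within 330-600 nm")
  }
  if (any(diff(wavelength_nm) <= 0)) abort("wavelength grid must be strictly increasing")
  if (min(wavelength_nm) > lambda_max_nm || max(wavelength_nm) < lambda_max_nm) {
    abort("wavelength grid does not span lambda_max_nm")
  }
  x <- lambda_max_nm / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max_nm
  bwb <- -40.5 + 0.195 * lambda_max_nm
  beta <- 0.26 * exp(-((wavelength_nm - lmb) / bwb)^2)
  v <- alpha + beta
  tibble(wavelength_nm = as.numeric(wavelength_nm), value = v / max(v))
}

#' Co-expression absorbance mixture
#'
#' Weighted mean of pigment absorbance curves on a common grid,
#' renormalised to peak 1 — the intermediate absorbance produced when two
#' opsins are co-expressed within the same photoreceptor. The mixture peak
#' lies between the component peaks.
#'
#' @param curves List of spectrum tibbles on a common wavelength grid.
#' @param weights Non-negative weights, one per curve, summing > 0.
#' @return A spectrum tibble `wavelength_nm`, `value`.
#' @examples
#' mix <- coexpression_mixture(
#'   list(pigment_template(360), pigment_template(407)), c(1, 1))
#' @export
coexpression_mixture <- function(curves, weights = rep(1, length(curves))) {
  if (length(curves) == 0) abort("no curves supplied")
  if (length(weights) != length(curves)) abort("one weight per curve required")
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative and sum > 0")
  }
  curves <- map(curves, check_spectrum)
  grid <- curves[[1]]$wavelength_nm
  same <- map_chr(curves, ~ paste(.x$wavelength_nm, collapse = ","))
  if (!all(same == same[[1]])) abort("curves must share a common wavelength grid")
  v <- Reduce(`+`, map2(curves, weights, ~ .x$value * .y)) / sum(weights)
  tibble(wavelength_nm = grid, value = v / max(v))
}
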