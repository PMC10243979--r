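#' Element amounts for spectrum simulation
#'
#' A validated mapping of element symbols to non-negative amounts.  Amounts
#' are in arbitrary linear units proportional to the expected principal-line
#' peak area (quantification physics is out of scope; fitted outputs are
#' relative counts).
#'
#' @param ... Either named numeric arguments (`Fe = 100, Zn = 20`) or a
#'   single named numeric vector.
#' @return Named numeric vector of class `element_amounts`.
#' @export
element_amounts <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    x <- args[[1]]
  else
    x <- unlist(args)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("amounts must be named by element symbol", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("amounts must be finite and >= 0", call. = FALSE)
  check_element(names(x))
  structure(as.numeric(x), names = names(x), class = "element_amounts")
}

#' Uniform energy grid for a beam
#'
#' @param beam An [xrf_beam()].
#' @param step_keV Grid step in keV (default 10 eV).
#' @return Ascending numeric vector from 0 to the excitation energy.
#' @export
energy_grid <- function(beam, step_keV = 0.010) {
  stopifnot(inherits(beam, "xrf_beam"), step_keV > 0)
  seq(0, beam$excitation_keV, by = step_keV)
}

#' Simulated XRF spectrum container
#'
#' @param energy_keV Strictly ascending, uniformly spaced energies (keV).
#' @param counts Non-negative counts per grid point (counts per keV; peak
#'   areas integrate to the element amount times line intensity).
#' @return Object of class `xrf_spectrum` with fields `energy_keV`,
#'   `counts`, `gain` (keV per channel) and `offset` (keV of channel 0).
#' @export
xrf_spectrum <- function(energy_keV, counts) {
  if (length(energy_keV) < 2L || length(energy_keV) != length(counts))
    stop("`energy_keV` and `counts` must have equal length >= 2",
         call. = FALSE)
  d <- diff(energy_keV)
  if (any(d <= 0) || diff(range(d)) > 1e-9 * max(d))
    stop("`energy_keV` must be strictly ascending and uniform",
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and >= 0", call. = FALSE)
  structure(list(energy_keV = as.numeric(energy_keV),
                 counts = as.numeric(counts),
                 gain = d[1], offset = energy_keV[1]),
            class = "xrf_spectrum")
}

#' @export
print.xrf_spectrum <- function(x, ...) {
  cat(sprintf(
    "<xrf_spectrum> %d channels, %.4f-%.4f keV (gain %.4g keV/ch), total %.4g\n",
    length(x$counts), min(x$energy_keV), max(x$energy_keV), x$gain,
    sum(x$counts) * x$gain))
  invisible(x)
}

#' Forward-simulate an emission-only XRF spectrum
#'
#' Each excitable line of each element with positive amount contributes a
#' Gaussian peak centred at the line energy with the detector FWHM at that
#' energy, of integrated area `amount * rel_intensity`.  The model contains
#' emission only: no background and no pile-up, escape or scatter peaks.
#' An element whose every edge lies above the excitation energy contributes
#' nothing (excitation gating).
#'
#' @param amounts An [element_amounts()] (or named numeric vector).
#' @param beam An [xrf_beam()].
#' @param detector An [xrf_detector()].
#' @param grid Energy grid (keV); default [energy_grid()] of the beam.  The
#'   grid must cover every contributing line energy, otherwise an error
#'   names the uncovered line.
#' @return An [xrf_spectrum()].
#' @examples
#' sp <- simulate_spectrum(element_amounts(Fe = 100, Ca = 50), xrf_beam(7.7),
#'                         xrf_detector())
#' @export
simulate_spectrum <- function(amounts, beam, detector = xrf_detector(),
                              grid = NULL) {
  if (!inherits(amounts, "element_amounts")) amounts <- element_amounts(amounts)
  stopifnot(inherits(beam, "xrf_beam"), inherits(detector, "xrf_detector"))
  if (is.null(grid)) grid <- energy_grid(beam)
  counts <- numeric(length(grid))
  for (el in names(amounts)) {
    a <- amounts[[el]]
    if (a == 0) next
    lines <- get_lines(el, beam)
    if (!nrow(lines)) next
    uncovered <- lines$energy_keV < min(grid) | lines$energy_keV > max(grid)
    if (any(uncovered))
      stop(sprintf("grid does not cover line %s %s at %.4f keV",
                   el, lines$transition[uncovered][1],
                   lines$energy_keV[uncovered][1]), call. = FALSE)
    for (i in seq_len(nrow(lines))) {
      sigma <- fwhm_at(detector, lines$energy_keV[i]) / 1000 / 2.3548
      counts <- counts + a * lines$rel_intensity[i] *
        dnorm(grid, mean = lines$energy_keV[i], sd = sigma)
    }
  }
  xrf_spectrum(grid, counts)
}

#' Apply Poisson counting noise to a spectrum
#'
#' Replaces every grid value by a Poisson draw with that mean, emulating
#' counting statistics.  Reproducible given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param spectrum An [xrf_spectrum()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return An [xrf_spectrum()] with integer-valued counts.
#' @export
add_poisson_noise <- function(spectrum, seed) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  noisy <- with_seed(seed, rpois(length(spectrum$counts), spectrum$counts))
  xrf_spectrum(spectrum$energy_keV, noisy)
}
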