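#' X-ray emission-line catalogue
#'
#' Returns the embedded table of radiative X-ray transitions used throughout
#' the package.  The catalogue covers the K series of the light elements
#' commonly seen in soft-tissue XRF (P--Zn) and the full L series of the
#' lanthanides La--Lu.  It was generated once from a physics-constants
#' library and is shipped as a static, versioned CSV so the package has no
#' run-time dependency on external databases.
#'
#' Relative intensities are expressed within an (element, series) group,
#' normalized so the principal line (Ka1 for the K series, La1/L3M5 for the
#' L series) equals 1.  They fold in the relative subshell excitation and
#' fluorescence yields at a 20 keV reference excitation; absolute
#' cross-sections are deliberately out of scope.
#'
#' @return A data frame with columns `element`, `transition` (IUPAC code,
#'   e.g. `"KL3"`, `"L3M5"`), `energy_keV`, `rel_intensity`, `edge_keV`
#'   (binding energy of the ionized shell) and `series` (`"K"` or `"L"`).
#' @examples
#' cat <- xrf_catalogue()
#' subset(cat, element == "Fe")
#' @export
xrf_catalogue <- function() {
  if (is.null(.xrftag_env$catalogue)) {
    path <- system.file("extdata", "xray_lines.csv", package = "xrftag",
                        mustWork = TRUE)
    cat <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(
      all(c("element", "transition", "energy_keV", "rel_intensity",
            "edge_keV", "series") %in% names(cat)),
      all(cat$energy_keV > 0),
      all(cat$energy_keV < cat$edge_keV),
      all(cat$rel_intensity > 0 & cat$rel_intensity <= 1)
    )
    .xrftag_env$catalogue <- cat
  }
  .xrftag_env$catalogue
}

# Atomic numbers for every catalogue element (used for deterministic
# orderings and pile-up reasoning; not exported).
atomic_number <- function(element) {
  z <- c(P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Ti = 22, V = 23, Cr = 24,
         Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
         La = 57, Ce = 58, Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63,
         Gd = 64, Tb = 65, Dy = 66, Ho = 67, Er = 68, Tm = 69, Yb = 70,
         Lu = 71)
  out <- z[element]
  if (anyNA(out))
    stop("unknown element symbol(s): ",
         paste(element[is.na(out)], collapse = ", "), call. = FALSE)
  unname(out)
}

check_element <- function(element) {
  known <- unique(xrf_catalogue()$element)
  bad <- setdiff(element, known)
  if (length(bad))
    stop("element(s) not in catalogue: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(element)
}

#' The 14 stable lanthanides
#'
#' Default candidate labels for panel design: La--Lu excluding promethium,
#' which has no stable isotope and is not used as an antibody tag.
#'
#' @return Character vector of element symbols.
#' @export
stable_lanthanides <- function() {
  c("La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
    "Tm", "Yb", "Lu")
}

#' Incident beam configuration
#'
#' @param excitation_keV Monochromatic incident energy in keV.  Only shells
#'   whose absorption edge lies below this energy can fluoresce.  Imaging
#'   energies used in practice are around 5.7--7.7 keV; panel design uses a
#'   higher survey energy so every candidate L shell is excitable (see
#'   [select_labels()]).
#' @return An object of class `xrf_beam`.
#' @export
xrf_beam <- function(excitation_keV) {
  if (!is.numeric(excitation_keV) || length(excitation_keV) != 1L ||
      !is.finite(excitation_keV) || excitation_keV <= 0)
    stop("`excitation_keV` must be a single positive number", call. = FALSE)
  structure(list(excitation_keV = excitation_keV), class = "xrf_beam")
}

#' @export
print.xrf_beam <- function(x, ...) {
  cat(sprintf("<xrf_beam> excitation %.3f keV\n", x$excitation_keV))
  invisible(x)
}

#' Silicon drift detector resolution model
#'
#' Energy-dependent resolution of an energy-dispersive silicon detector:
#' \deqn{FWHM(E) = \sqrt{noise^2 + 2.3548^2\, F\, \epsilon\, E}}
#' with `noise` the electronic noise contribution (eV), `F` the Fano factor
#' and `epsilon` the electron-hole pair-creation energy (eV).  The default
#' parameters give 140 eV FWHM at Mn Ka (5.895 keV), typical of the silicon
#' drift detectors used at microfocus beamlines.
#'
#' @param electronic_noise_eV Constant electronic noise term in eV.
#' @param fano Fano factor (dimensionless).
#' @param pair_creation_eV Energy per electron-hole pair in eV (3.85 for Si).
#' @return An object of class `xrf_detector`.
#' @examples
#' fwhm_at(xrf_detector(), 5.895)  # ~140 eV
#' @export
xrf_detector <- function(electronic_noise_eV = 72.5, fano = 0.114,
                         pair_creation_eV = 3.85) {
  stopifnot(electronic_noise_eV >= 0, fano >= 0, pair_creation_eV > 0)
  structure(list(electronic_noise_eV = electronic_noise_eV, fano = fano,
                 pair_creation_eV = pair_creation_eV),
            class = "xrf_detector")
}

#' @export
print.xrf_detector <- function(x, ...) {
  cat(sprintf(
    "<xrf_detector> noise %.1f eV, Fano %.3f, pair creation %.2f eV (FWHM %.0f eV at Mn Ka)\n",
    x$electronic_noise_eV, x$fano, x$pair_creation_eV, fwhm_at(x, 5.895)))
  invisible(x)
}

#' Detector resolution at a given energy
#'
#' @param detector An [xrf_detector()].
#' @param energy_keV Photon energy (keV); may be a vector.
#' @return FWHM in eV at each energy.
#' @export
fwhm_at <- function(detector, energy_keV) {
  stopifnot(inherits(detector, "xrf_detector"))
  if (!is.numeric(energy_keV) || any(!is.finite(energy_keV)) ||
      any(energy_keV <= 0))
    stop("`energy_keV` must be positive and finite", call. = FALSE)
  sqrt(detector$electronic_noise_eV^2 +
         2.3548^2 * detector$fano * detector$pair_creation_eV *
         energy_keV * 1000)
}

#' Excitable emission lines of an element
#'
#' Returns catalogue lines of `element` whose shell edge lies below the
#' beam's excitation energy and whose relative intensity passes the cutoff,
#' sorted by descending relative intensity.  An element with no excitable
#' shell yields an empty (zero-row) data frame, not an error.
#'
#' @param element Chemical symbol present in the catalogue.
#' @param beam An [xrf_beam()].
#' @param min_rel_intensity Minimum relative intensity (within-series,
#'   principal line = 1) for a line to be returned.  Default 0 returns every
#'   radiative transition; a lanthanide L shell then has well over 20 lines,
#'   most with relative intensities far below the detectable range.
#' @return Data frame with the catalogue columns, possibly zero rows.
#' @examples
#' nrow(get_lines("Sm", xrf_beam(7.7)))          # > 20 L lines
#' get_lines("Zn", xrf_beam(5.7))                # empty: K edge above beam
#' @export
get_lines <- function(element, beam, min_rel_intensity = 0) {
  stopifnot(inherits(beam, "xrf_beam"))
  if (length(element) != 1L) stop("`element` must be a single symbol",
                                  call. = FALSE)
  if (!is.numeric(min_rel_intensity) || min_rel_intensity < 0 ||
      min_rel_intensity > 1)
    stop("`min_rel_intensity` must be in [0, 1]", call. = FALSE)
  check_element(element)
  cat <- xrf_catalogue()
  out <- cat[cat$element == element &
               cat$edge_keV < beam$excitation_keV &
               cat$rel_intensity >= min_rel_intensity, , drop = FALSE]
  out <- out[order(-out$rel_intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Principal emission line of a series
#'
#' The line with maximal relative intensity of an element within one series:
#' Ka1 (KL3) for the K series and La1 (L3M5) for the lanthanide L series.
#' These are the peaks that matter most for convolution-free detection.
#'
#' @param element Chemical symbol.
#' @param series `"K"` or `"L"`.
#' @return One-row data frame (an emission line record).
#' @examples
#' principal_line("Nd", "L")$transition  # "L3M5"
#' @export
principal_line <- function(element, series = c("K", "L")) {
  series <- match.arg(series)
  check_element(element)
  cat <- xrf_catalogue()
  sub <- cat[cat$element == element & cat$series == series, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("element %s has no %s-series lines in the catalogue",
                 element, series), call. = FALSE)
  out <- sub[which.max(sub$rel_intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
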