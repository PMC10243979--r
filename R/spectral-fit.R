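#' Linear energy calibration from known peaks
#'
#' Least-squares straight line `energy = gain * channel + offset` through
#' observed (channel, energy) pairs.
#'
#' @param observed_peak_channels Channel positions of identified peaks.
#' @param known_energies_keV Their known line energies (keV).
#' @return Object of class `xrf_calibration`: `gain` (keV/channel),
#'   `offset` (keV), `residuals_keV`, and standard errors of both
#'   coefficients (`NA` with exactly two points).
#' @export
calibrate_energy <- function(observed_peak_channels, known_energies_keV) {
  ch <- as.numeric(observed_peak_channels)
  en <- as.numeric(known_energies_keV)
  if (length(ch) < 2L || length(ch) != length(en))
    stop("need >= 2 (channel, energy) pairs of equal length", call. = FALSE)
  if (anyDuplicated(ch) || diff(range(ch)) == 0)
    stop("channels must be distinct (zero channel spread is degenerate)",
         call. = FALSE)
  fit <- lm(en ~ ch)
  se <- if (length(ch) > 2L)
    tryCatch(
      suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
      error = function(e) c(NA_real_, NA_real_))
  else c(NA_real_, NA_real_)
  structure(list(gain = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
                 residuals_keV = unname(residuals(fit)),
                 se_offset = unname(se[1]), se_gain = unname(se[2]),
                 n = length(ch)),
            class = "xrf_calibration")
}

#' @export
print.xrf_calibration <- function(x, ...) {
  cat(sprintf("<xrf_calibration> gain %.6g keV/ch, offset %.6g keV (n = %d, rms residual %.3g keV)\n",
              x$gain, x$offset, x$n, sqrt(mean(x$residuals_keV^2))))
  invisible(x)
}

#' Spectrum cube container
#'
#' @param counts 3-D array `[row, col, channel]` of non-negative counts.
#' @param gain,offset Linear channel-to-energy calibration (keV/channel,
#'   keV); channel indices are 0-based in the calibration convention.
#' @param pixel_size_um Spatial sampling in micrometres.
#' @return Object of class `xrf_cube`.
#' @export
xrf_cube <- function(counts, gain, offset = 0, pixel_size_um = 1) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-D array [row, col, channel]", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("cube counts must be finite and >= 0", call. = FALSE)
  stopifnot(gain > 0, pixel_size_um > 0)
  structure(list(counts = counts, gain = gain, offset = offset,
                 pixel_size_um = pixel_size_um),
            class = "xrf_cube")
}

#' @export
print.xrf_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<xrf_cube> %d x %d pixels, %d channels (gain %.4g keV/ch, offset %.4g keV, %.3g um/px)\n",
              d[1], d[2], d[3], x$gain, x$offset, x$pixel_size_um))
  invisible(x)
}

cube_energy_grid <- function(gain, offset, n_channels)
  offset + gain * (seq_len(n_channels) - 1)

#' Fixed-shape design matrix for linear spectral fitting
#'
#' One column per element equal to its unit-amount simulated spectrum on the
#' calibrated energy grid, plus optional constant and linear baseline
#' columns.  Channels in the scatter region above
#' `excitation - 3 FWHM(excitation)` are masked from fitting by default,
#' since elastic/Compton scatter is not part of the emission-only model.
#'
#' @param elements Element symbols to fit; every element must have at least
#'   one excitable line, otherwise an error names the offender.
#' @param calibration An [calibrate_energy()] result, or a list with `gain`
#'   and `offset`.
#' @param detector An [xrf_detector()].
#' @param beam An [xrf_beam()].
#' @param n_channels Number of channels (rows of the design).
#' @param include_baseline Add constant + linear baseline columns
#'   (default `TRUE`; recommended for noisy data).
#' @param mask_scatter Mask channels in the scatter region (default `TRUE`).
#' @return Matrix of class `xrf_design` (channels x components) with
#'   attributes `elements`, `energy_keV`, `mask` (logical: channels used)
#'   and `baseline` columns flag.
#' @export
build_design_matrix <- function(elements, calibration, detector, beam,
                                n_channels, include_baseline = TRUE,
                                mask_scatter = TRUE) {
  stopifnot(length(elements) >= 1L, n_channels >= 2L)
  gain <- calibration$gain; offset <- calibration$offset
  grid <- cube_energy_grid(gain, offset, n_channels)
  cols <- list()
  for (el in elements) {
    lines <- get_lines(el, beam)
    if (!nrow(lines))
      stop(sprintf("element %s has no excitable line below %.3f keV",
                   el, beam$excitation_keV), call. = FALSE)
    amt <- structure(1, names = el, class = "element_amounts")
    cols[[el]] <- simulate_spectrum(amt, beam, detector, grid)$counts
  }
  X <- do.call(cbind, cols)
  colnames(X) <- elements
  if (include_baseline) {
    ramp <- seq(0, 1, length.out = n_channels)
    X <- cbind(X, .const = 1, .slope = ramp)
  }
  mask <- rep(TRUE, n_channels)
  if (mask_scatter) {
    cutoff <- beam$excitation_keV - 3 * fwhm_at(detector, beam$excitation_keV) / 1000
    mask <- grid <= cutoff
  }
  structure(X, class = c("xrf_design", "matrix"), elements = elements,
            energy_keV = grid, mask = mask, baseline = include_baseline)
}

# Lawson-Hanson non-negative least squares: min ||A x - y||, x >= 0.
# Deterministic active-set method; exact least-squares solution on the
# final passive set.
nnls_solve <- function(A, y) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, y))
  tol <- 1e-10 * max(abs(w), 1e-300)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), y)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / pmax(x[neg] - z[neg], .Machine$double.xmin))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x
}

#' Fit one pixel spectrum against a design matrix
#'
#' Solves `min || design %*% a - spectrum ||^2` subject to `a >= 0`
#' (non-negative least squares).  A fast path accepts the unconstrained
#' least-squares solution when it is already non-negative; otherwise the
#' deterministic Lawson-Hanson active-set method is used.  Masked channels
#' (see [build_design_matrix()]) are excluded from the fit.
#'
#' @param spectrum Numeric counts vector, length equal to the design rows.
#' @param design An `xrf_design` matrix.
#' @return List with `amplitudes` (named by element), `baseline`
#'   (named coefficients or `NULL`) and `residual_norm` (Euclidean norm over
#'   fitted channels).
#' @export
fit_pixel <- function(spectrum, design) {
  if (!inherits(design, "xrf_design"))
    stop("`design` must come from build_design_matrix()", call. = FALSE)
  if (length(spectrum) != nrow(design))
    stop(sprintf("spectrum length %d != design rows %d", length(spectrum),
                 nrow(design)), call. = FALSE)
  mask <- attr(design, "mask")
  A <- design[mask, , drop = FALSE]
  y <- as.numeric(spectrum)[mask]
  qrA <- attr(design, "qr")
  if (is.null(qrA)) qrA <- qr(A)
  ls <- qr.coef(qrA, y)
  ls[is.na(ls)] <- 0
  x <- if (all(ls >= 0)) ls else nnls_solve(A, y)
  names(x) <- colnames(design)
  elements <- attr(design, "elements")
  resid <- y - drop(A %*% x)
  list(amplitudes = x[elements],
       baseline = if (attr(design, "baseline"))
         x[c(".const", ".slope")] else NULL,
       residual_norm = sqrt(sum(resid^2)))
}

#' Batch-fit a spectrum cube into elemental maps
#'
#' Applies [fit_pixel()] to every pixel of the cube and assembles
#' per-element amplitude maps plus a per-pixel residual-norm map.
#'
#' @param cube An [xrf_cube()].
#' @param elements Elements to fit.
#' @param detector An [xrf_detector()].
#' @param beam An [xrf_beam()].
#' @param include_baseline,mask_scatter Passed to [build_design_matrix()].
#' @param verbose Log progress every few rows.
#' @return Object of class `element_map_set`: named list `maps` of 2-D
#'   matrices, `residual_norm` map, `elements`, `pixel_size_um`.
#' @export
batch_fit <- function(cube, elements, detector = xrf_detector(), beam,
                      include_baseline = TRUE, mask_scatter = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(cube, "xrf_cube"))
  d <- dim(cube$counts)
  design <- build_design_matrix(elements, cube, detector, beam,
                                n_channels = d[3],
                                include_baseline = include_baseline,
                                mask_scatter = mask_scatter)
  attr(design, "qr") <- qr(design[attr(design, "mask"), , drop = FALSE])
  maps <- lapply(elements, function(e) matrix(0, d[1], d[2]))
  names(maps) <- elements
  resid <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      fit <- tryCatch(
        fit_pixel(cube$counts[i, j, ], design),
        error = function(e)
          stop(sprintf("pixel (%d, %d): %s", i, j, conditionMessage(e)),
               call. = FALSE))
      for (e in elements) maps[[e]][i, j] <- fit$amplitudes[[e]]
      resid[i, j] <- fit$residual_norm
    }
    if (verbose && i %% 16L == 0L)
      message(sprintf("batch_fit: row %d / %d", i, d[1]))
  }
  structure(list(maps = maps, residual_norm = resid, elements = elements,
                 pixel_size_um = cube$pixel_size_um),
            class = "element_map_set")
}

#' @export
print.element_map_set <- function(x, ...) {
  d <- dim(x$residual_norm)
  cat(sprintf("<element_map_set> %d x %d pixels, elements: %s\n",
              d[1], d[2], paste(x$elements, collapse = ", ")))
  invisible(x)
}
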