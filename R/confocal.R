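#' Confocal XRF depth stack
#'
#' An ordered list of per-depth 2-D elemental maps acquired by translating
#' the sample towards the beam between planes.  Because the sample surface
#' sits at an angle to the beam (45 degrees in the reference geometry), each
#' successive plane is laterally displaced by `depth_step_um * tan(angle)`
#' until corrected with [shift_correct()].
#'
#' @param planes List of equally sized numeric matrices (or a 3-D array
#'   `[row, col, plane]`), shallowest plane first.  `NA` marks invalid
#'   pixels.
#' @param depth_step_um Sample translation between planes (um); 15 in the
#'   reference setup.
#' @param geometry_angle_deg Beam-sample angle in degrees, strictly between
#'   0 and 90 (default 45).
#' @param pixel_size_um Lateral pixel size (um).
#' @param probe_depth_um Confocal acceptance depth (um), metadata only
#'   (default 30).
#' @return Object of class `confocal_stack`.
#' @export
confocal_stack <- function(planes, depth_step_um, geometry_angle_deg = 45,
                           pixel_size_um = 1, probe_depth_um = 30) {
  if (is.array(planes) && length(dim(planes)) == 3L)
    planes <- lapply(seq_len(dim(planes)[3]), function(k) planes[, , k])
  if (!is.list(planes) || !length(planes) ||
      !all(vapply(planes, is.matrix, logical(1))))
    stop("`planes` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all planes must share the same shape", call. = FALSE)
  stopifnot(depth_step_um >= 0, geometry_angle_deg > 0,
            geometry_angle_deg < 90, pixel_size_um > 0, probe_depth_um > 0)
  structure(list(planes = planes, depth_step_um = depth_step_um,
                 geometry_angle_deg = geometry_angle_deg,
                 pixel_size_um = pixel_size_um,
                 probe_depth_um = probe_depth_um),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf(
    "<confocal_stack> %d plane(s) of %d x %d px, %.3g um depth step, %g deg geometry\n",
    length(x$planes), d[1], d[2], x$depth_step_um, x$geometry_angle_deg))
  invisible(x)
}

# Translate a matrix along rows by a (possibly fractional) pixel shift.
# out[r, ] = in[r + shift, ], linear interpolation; vacated margins -> NA.
translate_rows <- function(m, shift) {
  nr <- nrow(m)
  out <- matrix(NA_real_, nr, ncol(m))
  src <- seq_len(nr) + shift
  r0 <- floor(src)
  f <- src - r0
  ok0 <- r0 >= 1 & r0 <= nr
  ok1 <- (r0 + 1) >= 1 & (r0 + 1) <= nr
  for (r in seq_len(nr)) {
    if (f[r] < 1e-12) {
      if (ok0[r]) out[r, ] <- m[r0[r], ]
    } else if (ok0[r] && ok1[r]) {
      out[r, ] <- (1 - f[r]) * m[r0[r], ] + f[r] * m[r0[r] + 1, ]
    }
  }
  out
}

#' Correct the geometric inter-plane shift of a confocal stack
#'
#' Plane `k` (0-based) is displaced laterally by
#' `k * depth_step_um * tan(geometry_angle_deg)` relative to the first
#' plane; for the 45-degree reference geometry the displacement equals the
#' depth step.  This translates each plane back so that features are coaxial
#' across depth.  Sub-pixel shifts use linear interpolation; vacated margins
#' are marked `NA` (invalid), never zero-filled.
#'
#' @param stack A [confocal_stack()].
#' @param direction `+1` (default) when acquisition displaced features
#'   towards larger row indices, `-1` otherwise.  The shift axis is the row
#'   axis by convention; transpose planes for column-axis scans.
#' @return A corrected [confocal_stack()].
#' @export
shift_correct <- function(stack, direction = 1) {
  stopifnot(inherits(stack, "confocal_stack"), direction %in% c(-1, 1))
  shift_px <- stack$depth_step_um *
    tan(stack$geometry_angle_deg * pi / 180) / stack$pixel_size_um
  n <- length(stack$planes)
  max_shift <- (n - 1) * shift_px
  if (max_shift >= nrow(stack$planes[[1]]))
    stop(sprintf("total shift %.1f px exceeds image extent %d px",
                 max_shift, nrow(stack$planes[[1]])), call. = FALSE)
  planes <- lapply(seq_len(n), function(k) {
    s <- direction * (k - 1) * shift_px
    if (s == 0) stack$planes[[k]] else translate_rows(stack$planes[[k]], s)
  })
  out <- stack
  out$planes <- planes
  out
}

#' Estimate the background level of a map
#'
#' Median of the off-tissue pixels when a tissue mask is supplied; otherwise
#' the median of the lowest-intensity quartile, a robust stand-in when no
#' mask is available.
#'
#' @param map Numeric matrix (`NA` allowed, ignored).
#' @param tissue_mask Optional logical matrix, `TRUE` on tissue.
#' @return Scalar background level.
#' @export
estimate_background <- function(map, tissue_mask = NULL) {
  stopifnot(is.matrix(map), length(map) > 0)
  vals <- map[!is.na(map)]
  if (!length(vals)) stop("map has no valid pixels", call. = FALSE)
  if (!is.null(tissue_mask)) {
    stopifnot(is.logical(tissue_mask), all(dim(tissue_mask) == dim(map)))
    off <- map[!tissue_mask & !is.na(map)]
    if (!length(off)) stop("empty off-tissue region", call. = FALSE)
    return(median(off))
  }
  q <- quantile(vals, 0.25, names = FALSE)
  median(vals[vals <= q])
}

#' Threshold a map at a multiple of background
#'
#' Pixels below `factor * background` are zeroed; surviving pixels are
#' retained unchanged.  With the conventional factor 10 this isolates
#' high-intensity exogenous particles from tissue signal.  Idempotent.
#'
#' @param map Numeric matrix.
#' @param background Scalar background level, `>= 0`.
#' @param factor Threshold multiple (default 10).
#' @return Filtered matrix (invalid `NA` pixels stay `NA`).
#' @export
threshold_map <- function(map, background, factor = 10) {
  stopifnot(is.matrix(map))
  if (!is.numeric(factor) || factor <= 0)
    stop("`factor` must be > 0", call. = FALSE)
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("`background` must be a single value >= 0", call. = FALSE)
  map[!is.na(map) & map < factor * background] <- 0
  map
}

#' Logarithmic display scaling
#'
#' `log10(1 + value)`: a monotone, order-preserving transform that lets low
#' and high intensity features be visualized in a single image.  Invalid
#' (`NA`) pixels stay invalid.
#'
#' @param map Numeric matrix with values `>= 0`.
#' @return Transformed matrix.
#' @export
log_display <- function(map) {
  stopifnot(is.matrix(map))
  if (any(map < 0, na.rm = TRUE))
    stop("log display requires values >= 0", call. = FALSE)
  log10(1 + map)
}

# 26-connected (3-D) or 8-connected (2-D) component labelling via flood
# fill on the voxel list.  `on` is a logical array; returns an integer
# array of labels (0 = off).
label_components <- function(on) {
  dims <- dim(on)
  nd <- length(dims)
  labels <- array(0L, dims)
  idx <- which(on)
  if (!length(idx)) return(labels)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(offsets != 0) > 0, , drop = FALSE]
  coord <- arrayInd(idx, dims)
  key <- function(co) as.vector((co - 1) %*% cumprod(c(1, dims[-nd]))) + 1
  lookup <- new.env(parent = emptyenv(), size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, lookup)
  seen <- logical(length(idx))
  lab <- 0L
  for (i in seq_along(idx)) {
    if (seen[i]) next
    lab <- lab + 1L
    queue <- i
    seen[i] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      labels[idx[cur]] <- lab
      co <- coord[cur, , drop = FALSE]
      nb <- offsets + matrix(co, nrow(offsets), nd, byrow = TRUE)
      ok <- rowSums(nb >= 1 & nb <= matrix(dims, nrow(nb), nd,
                                           byrow = TRUE)) == nd
      if (!any(ok)) next
      nb_lin <- key(nb[ok, , drop = FALSE])
      for (l in nb_lin) {
        j <- lookup[[as.character(l)]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Extract 3-D particle features from a thresholded stack
#'
#' Labels 26-connected components of strictly positive voxels in a
#' shift-corrected, thresholded stack and summarizes each feature.
#'
#' @param stack A [confocal_stack()] (thresholded: background zeroed).
#' @return Data frame with one row per feature: `id`, `volume_voxels`,
#'   `extent_um` (maximum in-plane bounding-box extent), `depth_span`
#'   (planes from first to last occurrence), `centroid_row`, `centroid_col`,
#'   `centroid_plane`.  The voxel coordinates of each feature are attached
#'   as the `voxels` attribute (list of matrices `[plane, row, col]`).
#' @export
particle_features <- function(stack) {
  stopifnot(inherits(stack, "confocal_stack"))
  d <- dim(stack$planes[[1]])
  n <- length(stack$planes)
  on <- array(FALSE, c(d[1], d[2], n))
  for (k in seq_len(n)) {
    p <- stack$planes[[k]]
    on[, , k] <- !is.na(p) & p > 0
  }
  labels <- label_components(on)
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- data.frame(id = integer(), volume_voxels = integer(),
                      extent_um = numeric(), depth_span = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_plane = numeric())
    attr(out, "voxels") <- list()
    return(out)
  }
  vox <- vector("list", nlab)
  rows <- vector("list", nlab)
  for (f in seq_len(nlab)) {
    ind <- arrayInd(which(labels == f), dim(labels))  # row, col, plane
    vox[[f]] <- cbind(plane = ind[, 3], row = ind[, 1], col = ind[, 2])
    ext_px <- max(vapply(split.data.frame(ind, ind[, 3]), function(m)
      max(diff(range(m[, 1])), diff(range(m[, 2]))) + 1, numeric(1)))
    rows[[f]] <- data.frame(
      id = f, volume_voxels = nrow(ind),
      extent_um = ext_px * stack$pixel_size_um,
      depth_span = diff(range(ind[, 3])) + 1L,
      centroid_row = mean(ind[, 1]), centroid_col = mean(ind[, 2]),
      centroid_plane = mean(ind[, 3]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "voxels") <- vox
  out
}
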