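# Between-class-variance (Otsu) threshold selection on a histogram.
# Returns one threshold (k = 1) or two (k = 2, exhaustive search), as
# bin-centre values; errors on a uniform input.
otsu_threshold <- function(x, k = 1, nbins = 256) {
  v <- x[is.finite(x)]
  if (!length(v) || diff(range(v)) == 0)
    stop("cannot threshold a uniform map (no between-class variance)",
         call. = FALSE)
  br <- seq(min(v), max(v), length.out = nbins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  centre <- (br[-1] + br[-(nbins + 1)]) / 2
  if (k == 1) {
    w <- cumsum(p)
    mu <- cumsum(p * centre)
    mu_t <- mu[nbins]
    sb <- (mu_t * w - mu)^2 / (w * (1 - w))
    sb[!is.finite(sb)] <- 0
    return(centre[which.max(sb)])
  }
  # two thresholds: maximize sum of class w * mean^2 over the 3 classes
  cw <- cumsum(p); cm <- cumsum(p * centre)
  classstat <- function(i, j) {  # bins (i, j]
    w <- cw[j] - if (i >= 1) cw[i] else 0
    if (w <= 0) return(0)
    m <- (cm[j] - if (i >= 1) cm[i] else 0) / w
    w * m^2
  }
  best <- -Inf; t12 <- c(1L, 2L)
  for (i in seq_len(nbins - 2)) {
    si <- classstat(0L, i)
    for (j in seq.int(i + 1L, nbins - 1L)) {
      s <- si + classstat(i, j) + classstat(j, nbins)
      if (s > best) { best <- s; t12 <- c(i, j) }
    }
  }
  centre[t12]
}

#' Segment cells from an elemental intensity map
#'
#' Automatic global thresholding by the between-class-variance (Otsu)
#' criterion, followed by 8-connected component labelling and an area
#' filter.  With `classify_ecm = TRUE` a two-threshold variant separates
#' three classes - background, extracellular matrix (ECM) and cells - as
#' seen in P-intensity maps of soft tissue, where cells are the brightest
#' class and the ECM carries intermediate signal.
#'
#' Touching cells merge into one component under 8-connectivity; this is a
#' documented property of the operator, not an error.
#'
#' @param map Numeric intensity matrix.
#' @param min_area_um2,max_area_um2 Area filter for accepted cells.
#' @param pixel_size_um Pixel size (um).
#' @param classify_ecm Add the intermediate ECM class (default `TRUE`).
#' @return Object of class `xrf_segmentation`: `labels` matrix (0 =
#'   background, 1 = ECM, ids >= 2 = cells, contiguous), `cells` data frame
#'   (`id`, `area_um2`, `equiv_diameter_um`, `centroid_row`,
#'   `centroid_col`), `thresholds`, `pixel_size_um`.
#' @export
segment_cells <- function(map, min_area_um2 = 10, max_area_um2 = 1000,
                          pixel_size_um = 1, classify_ecm = TRUE) {
  stopifnot(is.matrix(map), length(map) > 0, min_area_um2 < max_area_um2,
            pixel_size_um > 0)
  if (classify_ecm) {
    th <- otsu_threshold(map, k = 2)
    cell_mask <- !is.na(map) & map > th[2]
    ecm_mask <- !is.na(map) & map > th[1] & !cell_mask
  } else {
    th <- otsu_threshold(map, k = 1)
    cell_mask <- !is.na(map) & map > th
    ecm_mask <- matrix(FALSE, nrow(map), ncol(map))
  }
  comp <- label_components(cell_mask)  # 8-connectivity in 2-D
  px_area <- pixel_size_um^2
  labels <- matrix(0L, nrow(map), ncol(map))
  labels[ecm_mask] <- 1L
  cells <- list()
  next_id <- 2L
  if (max(comp) > 0) {
    for (f in seq_len(max(comp))) {
      ind <- which(comp == f)
      area <- length(ind) * px_area
      if (area < min_area_um2 || area > max_area_um2) {
        # rejected by the area filter: falls back into the surrounding class
        labels[ind] <- if (classify_ecm) 1L else 0L
        next
      }
      rc <- arrayInd(ind, dim(map))
      labels[ind] <- next_id
      cells[[length(cells) + 1L]] <- data.frame(
        id = next_id, area_um2 = area,
        equiv_diameter_um = 2 * sqrt(area / pi),
        centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]))
      next_id <- next_id + 1L
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(id = integer(), area_um2 = numeric(),
               equiv_diameter_um = numeric(), centroid_row = numeric(),
               centroid_col = numeric())
  rownames(cells) <- NULL
  structure(list(labels = labels, cells = cells, thresholds = th,
                 pixel_size_um = pixel_size_um),
            class = "xrf_segmentation")
}

#' @export
print.xrf_segmentation <- function(x, ...) {
  cat(sprintf("<xrf_segmentation> %d cell(s), thresholds %s\n",
              nrow(x$cells), paste(signif(x$thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Label-positivity statistics over a segmentation
#'
#' A pixel is label-positive iff its value in `label_map` is strictly
#' greater than `k * background_level`.  Sensitivity is the positive
#' fraction of cell pixels; the false-positive rate is the positive
#' fraction of background-class pixels.  ECM pixels are excluded from both
#' denominators.  With `per_region = TRUE` the cell-side statistic is
#' computed per cell region (a cell counts as positive when more than half
#' its pixels are positive); the background side is always per-pixel.
#'
#' The statistics are invariant to any monotone rescaling applied jointly
#' to `label_map` and `background_level`.
#'
#' @param seg An [segment_cells()] result.
#' @param label_map Label-element intensity matrix, same shape.
#' @param background_level Scalar background level of the label channel.
#' @param k Positivity multiplier (default 1).
#' @param per_region Per-region sensitivity variant (default `FALSE`,
#'   per-pixel).
#' @return Object of class `positivity_stats`: `sensitivity`,
#'   `false_positive_rate`, and the underlying counts.
#' @export
positivity <- function(seg, label_map, background_level, k = 1,
                       per_region = FALSE) {
  stopifnot(inherits(seg, "xrf_segmentation"), is.matrix(label_map))
  if (!all(dim(label_map) == dim(seg$labels)))
    stop("label map shape does not match segmentation", call. = FALSE)
  if (!is.numeric(background_level) || background_level < 0)
    stop("`background_level` must be >= 0", call. = FALSE)
  pos <- !is.na(label_map) & label_map > k * background_level
  cell <- seg$labels >= 2L
  bg <- seg$labels == 0L
  n_cell <- sum(cell)
  if (n_cell == 0L) stop("segmentation contains no cell pixels",
                         call. = FALSE)
  n_bg <- sum(bg)
  if (per_region) {
    ids <- seg$cells$id
    hit <- vapply(ids, function(i) mean(pos[seg$labels == i]) > 0.5,
                  logical(1))
    sens <- mean(hit)
    n_cell_units <- length(ids); n_cell_pos <- sum(hit)
  } else {
    n_cell_units <- n_cell
    n_cell_pos <- sum(pos & cell)
    sens <- n_cell_pos / n_cell
  }
  n_bg_pos <- sum(pos & bg)
  structure(list(sensitivity = sens,
                 false_positive_rate = if (n_bg) n_bg_pos / n_bg else NA_real_,
                 n_cell = n_cell_units, n_cell_positive = n_cell_pos,
                 n_background = n_bg, n_background_positive = n_bg_pos,
                 k = k, background_level = background_level,
                 per_region = per_region),
            class = "positivity_stats")
}

#' @export
print.positivity_stats <- function(x, ...) {
  cat(sprintf(
    "<positivity_stats> sensitivity %.1f%% (%d/%d), background positivity %.1f%% (%d/%d)\n",
    100 * x$sensitivity, x$n_cell_positive, x$n_cell,
    100 * x$false_positive_rate, x$n_background_positive, x$n_background))
  invisible(x)
}

#' Pearson correlation with two-sided t test
#'
#' Product-moment correlation between paired size measurements (e.g. cell
#' diameters from two imaging modalities), with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param sizes_a,sizes_b Equal-length numeric vectors, `n >= 3`, both with
#'   nonzero variance.
#' @return Object of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_correlation <- function(sizes_a, sizes_b) {
  a <- as.numeric(sizes_a); b <- as.numeric(sizes_b)
  n <- length(a)
  if (n != length(b) || n < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in input", call. = FALSE)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, P %s (n = %d)\n", x$r,
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3g", x$p), x$n))
  invisible(x)
}
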