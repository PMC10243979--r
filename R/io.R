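# File formats: element maps, confocal stacks and spectrum cubes are
# multi-page TIFF with JSON metadata in the per-page ImageDescription;
# spectra and tables are CSV; configs, truth and stats reports are JSON.

meta_json <- function(meta) {
  as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

parse_meta <- function(desc, path) {
  tryCatch(jsonlite::fromJSON(desc),
           error = function(e)
             stop(sprintf("malformed metadata in %s: %s", path,
                          conditionMessage(e)), call. = FALSE))
}

#' Write / read per-element maps as multi-page TIFF
#'
#' One 32-bit float page per element; page names (element symbols) and the
#' pixel size travel in the per-page JSON ImageDescription.
#'
#' @param maps Named list of matrices.
#' @param path File path.
#' @param pixel_size_um Pixel size metadata.
#' @return `write_element_maps()` returns `path` invisibly;
#'   `read_element_maps()` returns a list with `maps` (named list) and
#'   `pixel_size_um`.
#' @export
write_element_maps <- function(maps, path, pixel_size_um = 1) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  desc <- vapply(names(maps), function(nm)
    meta_json(list(name = nm, pixel_size_um = pixel_size_um)),
    character(1))
  write_tiff(maps, path, desc, type = "float32")
}

#' @rdname write_element_maps
#' @export
read_element_maps <- function(path) {
  tf <- read_tiff(path)
  meta <- lapply(tf$descriptions, parse_meta, path = path)
  nms <- vapply(meta, function(m) m$name %||% "", character(1))
  if (any(!nzchar(nms)))
    stop(sprintf("malformed map file %s: missing page name", path),
         call. = FALSE)
  maps <- tf$pages
  names(maps) <- nms
  list(maps = maps,
       pixel_size_um = meta[[1]]$pixel_size_um %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a confocal stack as multi-page TIFF
#'
#' One float page per depth plane, shallowest first; depth step, geometry
#' angle, pixel size and probe depth travel in the page metadata.
#'
#' @param stack A [confocal_stack()].
#' @param path File path.
#' @return `write_confocal_stack()` returns `path` invisibly;
#'   `read_confocal_stack()` returns a [confocal_stack()].
#' @export
write_confocal_stack <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  desc <- vapply(seq_along(stack$planes), function(k)
    meta_json(list(plane = k - 1, depth_um = (k - 1) * stack$depth_step_um,
                   depth_step_um = stack$depth_step_um,
                   geometry_angle_deg = stack$geometry_angle_deg,
                   pixel_size_um = stack$pixel_size_um,
                   probe_depth_um = stack$probe_depth_um)),
    character(1))
  planes <- lapply(stack$planes, function(p) {
    p[is.na(p)] <- -1  # invalid marker; restored as NA on read
    p
  })
  write_tiff(planes, path, desc, type = "float32")
}

#' @rdname write_confocal_stack
#' @export
read_confocal_stack <- function(path) {
  tf <- read_tiff(path)
  meta <- parse_meta(tf$descriptions[[1]], path)
  for (f in c("depth_step_um", "geometry_angle_deg", "pixel_size_um"))
    if (is.null(meta[[f]]))
      stop(sprintf("malformed stack file %s: missing field %s", path, f),
           call. = FALSE)
  planes <- lapply(tf$pages, function(p) { p[p < 0] <- NA_real_; p })
  confocal_stack(planes, meta$depth_step_um, meta$geometry_angle_deg,
                 meta$pixel_size_um, meta$probe_depth_um %||% 30)
}

#' Write / read a spectrum cube as multi-page TIFF
#'
#' One float page per energy channel; the linear calibration (gain,
#' offset) and pixel size travel in the page metadata.
#'
#' @param cube An [xrf_cube()].
#' @param path File path.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` an
#'   [xrf_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "xrf_cube"))
  d <- dim(cube$counts)
  meta <- meta_json(list(gain = cube$gain, offset = cube$offset,
                         pixel_size_um = cube$pixel_size_um,
                         n_channels = d[3]))
  pages <- lapply(seq_len(d[3]), function(k) cube$counts[, , k])
  write_tiff(pages, path, meta, type = "float32")
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  tf <- read_tiff(path)
  meta <- parse_meta(tf$descriptions[[1]], path)
  for (f in c("gain", "offset", "pixel_size_um"))
    if (is.null(meta[[f]]))
      stop(sprintf("malformed cube file %s: missing field %s", path, f),
           call. = FALSE)
  d <- dim(tf$pages[[1]])
  counts <- array(0, c(d[1], d[2], length(tf$pages)))
  for (k in seq_along(tf$pages)) counts[, , k] <- tf$pages[[k]]
  xrf_cube(counts, meta$gain, meta$offset, meta$pixel_size_um)
}

#' Write / read a spectrum as two-column CSV
#'
#' @param spectrum An [xrf_spectrum()].
#' @param path File path.
#' @return `write_spectrum_csv()` returns `path` invisibly;
#'   `read_spectrum_csv()` an [xrf_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  write.csv(data.frame(energy_keV = spectrum$energy_keV,
                       counts = spectrum$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("energy_keV", "counts") %in% names(df)))
    stop(sprintf("malformed spectrum CSV %s: need energy_keV, counts",
                 path), call. = FALSE)
  xrf_spectrum(df$energy_keV, df$counts)
}

#' Read a panel configuration from JSON
#'
#' Accepts an object with optional keys `endogenous`, `exogenous`,
#' `candidates` (element symbol arrays), plus optional `excitation_keV`.
#' Unknown keys and unknown element symbols are rejected.
#'
#' @param path JSON file.
#' @return Named list of validated fields.
#' @export
read_panel_config <- function(path) {
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    stop(sprintf("malformed config %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  allowed <- c("endogenous", "exogenous", "candidates", "excitation_keV")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s) in %s: %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  for (f in c("endogenous", "exogenous", "candidates"))
    if (!is.null(cfg[[f]])) check_element(cfg[[f]])
  cfg
}

#' Machine-readable provenance block for a pipeline run
#'
#' @param config List of parameters that determined the run.
#' @param seed Seed used, if any.
#' @return List with package version, an md5 hash of the canonicalized
#'   configuration, the seed and a timestamp.
#' @export
provenance <- function(config = list(), seed = NULL) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(meta_json(config), tf)
  list(package = "xrftag",
       version = as.character(utils::packageVersion("xrftag")),
       config_hash = unname(tools::md5sum(tf)),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
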