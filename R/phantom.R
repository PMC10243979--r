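#' Default per-class element means for tissue phantoms
#'
#' Mean counts per pixel (at a counts budget of 1000) for the three tissue
#' classes.  True tissue concentrations are not published for this system;
#' these are order-of-magnitude defaults chosen so that soft-tissue pixels
#' are dominated by Cl/K/P with strong Fe in cells, the ECM carries
#' intermediate signal, and the off-tissue background is nearly empty.
#'
#' @return Matrix with rows `cell`, `ecm`, `background` and columns
#'   `Cl, K, P, Ca, Fe, Zn`.
#' @export
default_element_means <- function() {
  m <- rbind(cell       = c(Cl = 400, K = 600, P = 1000, Ca = 80, Fe = 300, Zn = 60),
             ecm        = c(Cl = 300, K = 250, P = 200,  Ca = 120, Fe = 40, Zn = 25),
             background = c(Cl = 20,  K = 10,  P = 10,   Ca = 5,  Fe = 5,  Zn = 2))
  m
}

#' Configuration of a synthetic tissue phantom
#'
#' Describes a 2-D tissue phantom: an elliptical tissue region (ECM) on an
#' empty substrate, non-overlapping disk-shaped cells (a diffuse lymphocyte
#' infiltrate), a CD45-positive subset carrying a Sm label with imperfect
#' binding, sparse high-intensity exogenous Ti particles, and Poisson
#' counting noise.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size (um); 1.5 matches a focused beam
#'   footprint.
#' @param n_cells Number of cells to place.
#' @param cell_diameter_logmean,cell_diameter_logsd Lognormal cell diameter
#'   parameters, in log-um (defaults give a ~9 um median lymphocyte).
#' @param cd45_fraction Fraction of cells that are CD45 positive.
#' @param binding_efficiency Per-pixel Bernoulli probability `beta` that a
#'   CD45-positive cell pixel carries the Sm label (default 0.98, the
#'   operating point of a well-stained section).
#' @param nonspecific_rate Per-pixel Bernoulli probability `gamma` of
#'   nonspecific Sm deposition on background pixels (default 0.01).
#' @param element_means Per-class mean table, see [default_element_means()].
#' @param sm_counts Mean Sm counts on a labelled pixel (at budget 1000).
#' @param ti_background Mean Ti counts on an unlabelled pixel (at budget
#'   1000).
#' @param n_ti_particles Number of Ti particles.
#' @param ti_diameter_logmean,ti_diameter_logsd Lognormal Ti particle
#'   diameter parameters (log-um).
#' @param ti_intensity_multiple Particle intensity as a multiple of the Ti
#'   background (default 50, comfortably above the conventional 10x
#'   detection threshold).
#' @param counts_budget Approximate total counts per pixel scale; all means
#'   are multiplied by `counts_budget / 1000`.
#' @param noise Apply Poisson noise (default `TRUE`).
#' @param seed Mandatory integer seed.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(256, 256), pixel_size_um = 1.5,
                           n_cells = 50,
                           cell_diameter_logmean = log(9),
                           cell_diameter_logsd = 0.25,
                           cd45_fraction = 0.6,
                           binding_efficiency = 0.98,
                           nonspecific_rate = 0.01,
                           element_means = default_element_means(),
                           sm_counts = 25, ti_background = 2,
                           n_ti_particles = 8,
                           ti_diameter_logmean = log(4),
                           ti_diameter_logsd = 0.5,
                           ti_intensity_multiple = 50,
                           counts_budget = 1000, noise = TRUE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            pixel_size_um > 0, n_cells >= 0,
            cell_diameter_logsd > 0, ti_diameter_logsd > 0,
            cd45_fraction >= 0, cd45_fraction <= 1,
            binding_efficiency >= 0, binding_efficiency <= 1,
            nonspecific_rate >= 0, nonspecific_rate <= 1,
            is.matrix(element_means),
            all(rownames(element_means) == c("cell", "ecm", "background")),
            sm_counts > 0, ti_background >= 0, n_ti_particles >= 0,
            ti_intensity_multiple > 0, counts_budget > 0)
  check_element(colnames(element_means))
  structure(as.list(environment()), class = "phantom_config")
}

# Rasterize a disk: TRUE where (r, c) within radius of centre.
disk_mask <- function(nr, nc, centre_r, centre_c, radius_px) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - centre_r)^2 + (cc - centre_c)^2 <= radius_px^2
}

place_disks <- function(n, radii_px, domain_mask, min_gap_px = 1,
                        max_tries = 200) {
  nr <- nrow(domain_mask); nc <- ncol(domain_mask)
  centres <- matrix(numeric(0), 0, 2)
  placed_r <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- runif(1, 1 + radii_px[i], nr - radii_px[i])
      c <- runif(1, 1 + radii_px[i], nc - radii_px[i])
      if (!domain_mask[round(r), round(c)]) next
      if (nrow(centres)) {
        d <- sqrt((centres[, 1] - r)^2 + (centres[, 2] - c)^2)
        if (any(d < placed_r + radii_px[i] + min_gap_px)) next
      }
      centres <- rbind(centres, c(r, c))
      placed_r <- c(placed_r, radii_px[i])
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not place disk %d of %d without overlap (packing too dense)",
                   i, n), call. = FALSE)
  }
  centres
}

#' Generate a 2-D tissue phantom with ground truth
#'
#' Builds per-element maps (the configured endogenous elements plus `Sm`
#' and `Ti`) together with the ground truth needed to score every analysis
#' stage: the class mask, per-cell identities and true diameters, the CD45+
#' subset, the true Sm-positive pixel mask, the Ti particle list and the
#' true per-element background levels.  Fully reproducible from the
#' configuration seed.
#'
#' @param config A [phantom_config()].
#' @return List with `maps` (named list of matrices) and `truth` (class
#'   `phantom_truth`).
#' @export
make_map_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    nr <- config$image_size[1]; nc <- config$image_size[2]
    scale <- config$counts_budget / 1000
    # elliptical tissue region on bare substrate
    rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc,
                                                    byrow = TRUE)
    tissue <- ((rr - (nr + 1) / 2) / (0.42 * nr))^2 +
      ((cc - (nc + 1) / 2) / (0.42 * nc))^2 <= 1
    # cells: non-overlapping disks inside the tissue
    diam_um <- rlnorm(config$n_cells, config$cell_diameter_logmean,
                      config$cell_diameter_logsd)
    radii_px <- diam_um / 2 / config$pixel_size_um
    centres <- place_disks(config$n_cells, radii_px, tissue)
    class_mask <- matrix(0L, nr, nc)
    class_mask[tissue] <- 1L
    for (i in seq_len(config$n_cells)) {
      m <- disk_mask(nr, nc, centres[i, 1], centres[i, 2], radii_px[i])
      class_mask[m] <- i + 1L
    }
    n_cd45 <- round(config$cd45_fraction * config$n_cells)
    cd45_ids <- if (n_cd45 > 0) 1L + sort(sample(config$n_cells, n_cd45))
                else integer()
    # Sm deposition: Bernoulli(beta) on CD45+ cell pixels,
    # Bernoulli(gamma) on background pixels
    sm_mask <- matrix(FALSE, nr, nc)
    cd45_px <- class_mask %in% cd45_ids
    sm_mask[cd45_px] <- runif(sum(cd45_px)) < config$binding_efficiency
    bg_px <- class_mask == 0L
    sm_mask[bg_px] <- runif(sum(bg_px)) < config$nonspecific_rate
    # Ti particles
    ti_map <- matrix(config$ti_background * scale, nr, nc)
    ti_particles <- NULL
    if (config$n_ti_particles > 0) {
      ti_diam_um <- rlnorm(config$n_ti_particles, config$ti_diameter_logmean,
                           config$ti_diameter_logsd)
      ti_r_px <- pmax(ti_diam_um / 2 / config$pixel_size_um, 0.6)
      ti_centres <- place_disks(config$n_ti_particles, ti_r_px, tissue)
      ti_level <- config$ti_intensity_multiple * config$ti_background * scale
      for (i in seq_len(config$n_ti_particles)) {
        m <- disk_mask(nr, nc, ti_centres[i, 1], ti_centres[i, 2], ti_r_px[i])
        ti_map[m] <- ti_level
      }
      ti_particles <- data.frame(
        id = seq_len(config$n_ti_particles),
        centre_row = ti_centres[, 1], centre_col = ti_centres[, 2],
        diameter_um = ti_diam_um, radius_px = ti_r_px)
    }
    # endogenous maps from per-class means
    class_idx <- ifelse(class_mask >= 2L, 1L, ifelse(class_mask == 1L, 2L, 3L))
    maps <- list()
    for (el in colnames(config$element_means)) {
      mu <- config$element_means[, el][class_idx] * scale
      maps[[el]] <- matrix(mu, nr, nc)
    }
    maps$Sm <- matrix(0, nr, nc)
    maps$Sm[sm_mask] <- config$sm_counts * scale
    maps$Ti <- ti_map
    if (config$noise)
      maps <- lapply(maps, function(m)
        matrix(rpois(length(m), m), nrow(m), ncol(m)))
    cells <- data.frame(id = seq_len(config$n_cells) + 1L,
                        centre_row = centres[, 1], centre_col = centres[, 2],
                        diameter_um = diam_um,
                        cd45 = (seq_len(config$n_cells) + 1L) %in% cd45_ids)
    bg_levels <- c(config$element_means["background", ] * scale,
                   Sm = 0, Ti = config$ti_background * scale)
    truth <- structure(list(class_mask = class_mask, cells = cells,
                            cd45_ids = cd45_ids, sm_mask = sm_mask,
                            ti_particles = ti_particles,
                            background_levels = bg_levels,
                            config = config),
                       class = "phantom_truth")
    list(maps = maps, truth = truth)
  })
}

#' Forward-simulate a spectrum cube from phantom element maps
#'
#' Converts noiseless per-element amount maps into a full spectrum cube by
#' summing unit-amount line spectra, optionally applying Poisson noise to
#' the cube.  This gives [batch_fit()] a phantom with exactly known
#' per-pixel amounts.
#'
#' @param maps Named list of amount matrices (elements must be in the
#'   catalogue).
#' @param beam An [xrf_beam()].
#' @param detector An [xrf_detector()].
#' @param step_keV Channel width (default 10 eV).
#' @param pixel_size_um Pixel size for the cube metadata.
#' @param noise Apply Poisson noise to the cube.
#' @param seed Seed for the noise (mandatory when `noise = TRUE`).
#' @return An [xrf_cube()].
#' @export
phantom_cube <- function(maps, beam, detector = xrf_detector(),
                         step_keV = 0.010, pixel_size_um = 1.5,
                         noise = TRUE, seed = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  elements <- names(maps)
  check_element(elements)
  d <- dim(maps[[1]])
  grid <- energy_grid(beam, step_keV)
  unit <- vapply(elements, function(el) {
    amt <- structure(1, names = el, class = "element_amounts")
    simulate_spectrum(amt, beam, detector, grid)$counts
  }, numeric(length(grid)))
  A <- vapply(maps, as.numeric, numeric(prod(d)))  # pixels x elements
  flat <- A %*% t(unit)                            # pixels x channels
  if (noise) {
    if (is.null(seed)) stop("`seed` is required when noise = TRUE",
                            call. = FALSE)
    flat <- with_seed(seed,
                      matrix(rpois(length(flat), flat), nrow(flat)))
  }
  cube <- array(flat, c(d[1], d[2], length(grid)))
  xrf_cube(cube, gain = step_keV, offset = 0, pixel_size_um = pixel_size_um)
}

#' Generate a confocal depth-stack phantom with ground truth
#'
#' Simulates the 3-D Ti-particle scene: particles with lognormal sizes
#' whose depth persistence increases with their lateral extent (large
#' agglomerates persist through many planes, small isolated particles
#' appear in few), imaged as a confocal stack with the geometric inter-plane
#' skew of the angled beam-sample geometry already applied, so that
#' [shift_correct()] has a known truth to recover.
#'
#' The persistence rule is `span = clamp(round(diameter_px * persistence) +
#' jitter, 1, n_planes)` with a +/-1 stochastic jitter, guaranteeing a
#' positive size-persistence association by construction.
#'
#' @param n_planes Number of depth planes (>= 2).
#' @param image_size `c(rows, cols)` pixels.
#' @param n_particles Number of particles.
#' @param depth_step_um,geometry_angle_deg,pixel_size_um Stack geometry
#'   (defaults 15 um, 45 deg, 5 um: the reference confocal setup, giving an
#'   integral 3 px skew per plane).
#' @param diameter_logmean,diameter_logsd Lognormal particle diameter
#'   parameters (log-um).
#' @param background Mean background counts per pixel.
#' @param intensity_multiple Particle intensity as multiple of background.
#' @param persistence Span per pixel of diameter (default 0.8).
#' @param noise Apply Poisson noise.
#' @param seed Mandatory seed.
#' @return List with `stack` (a skewed [confocal_stack()]) and `truth`
#'   (particle table with assigned spans, background level, skew per plane
#'   in px).
#' @export
make_confocal_phantom <- function(n_planes = 5, image_size = c(96, 96),
                                  n_particles = 10, depth_step_um = 15,
                                  geometry_angle_deg = 45, pixel_size_um = 5,
                                  diameter_logmean = log(20),
                                  diameter_logsd = 0.5,
                                  background = 2, intensity_multiple = 50,
                                  persistence = 0.8, noise = TRUE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_planes >= 2, n_particles >= 0, background >= 0,
            intensity_multiple > 0, persistence > 0)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    skew_px <- depth_step_um * tan(geometry_angle_deg * pi / 180) /
      pixel_size_um
    margin <- ceiling((n_planes - 1) * skew_px)
    diam_um <- rlnorm(n_particles, diameter_logmean, diameter_logsd)
    r_px <- pmax(diam_um / 2 / pixel_size_um, 0.6)
    span <- as.integer(pmin(pmax(round(2 * r_px * persistence) +
                                   sample(-1:1, n_particles, replace = TRUE),
                                 1L), n_planes))
    first <- vapply(span, function(s)
      if (s >= n_planes) 1L else sample.int(n_planes - s + 1L, 1L),
      integer(1))
    # keep skewed disks fully inside the frame on every plane
    domain <- matrix(FALSE, nr, nc)
    keep_rows <- max(1, nr - margin - ceiling(max(r_px, 0)))
    domain[seq_len(keep_rows), ] <- TRUE
    centres <- place_disks(n_particles, r_px, domain)
    # a zero-background phantom still needs visible particles
    level <- intensity_multiple * if (background > 0) background else 1
    planes <- lapply(seq_len(n_planes), function(k) {
      m <- matrix(background, nr, nc)
      for (i in seq_len(n_particles)) {
        if (k >= first[i] && k < first[i] + span[i]) {
          # acquisition skew: plane k displaced towards larger rows
          mask <- disk_mask(nr, nc, centres[i, 1] + (k - 1) * skew_px,
                            centres[i, 2], r_px[i])
          m[mask] <- level
        }
      }
      if (noise) m <- matrix(rpois(length(m), m), nr, nc)
      m
    })
    stack <- confocal_stack(planes, depth_step_um, geometry_angle_deg,
                            pixel_size_um)
    truth <- list(
      particles = data.frame(
        id = seq_len(n_particles), centre_row = centres[, 1],
        centre_col = centres[, 2], diameter_um = diam_um,
        radius_px = r_px, extent_um = 2 * r_px * pixel_size_um,
        first_plane = first, depth_span = span),
      background = background, level = level, skew_px_per_plane = skew_px)
    list(stack = stack, truth = truth)
  })
}
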