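beam <- xrf_beam(7.7)
det <- xrf_detector()

test_that("energy calibration recovers exact and noisy lines", {
  cal <- calibrate_energy(c(100, 200), c(1.0, 2.0))
  expect_equal(cal$gain, 0.01)
  expect_equal(cal$offset, 0, tolerance = 1e-12)
  # collinear points leave zero residuals
  cal3 <- calibrate_energy(c(0, 100, 300), 0.05 + 0.01 * c(0, 100, 300))
  expect_equal(max(abs(cal3$residuals_keV)), 0, tolerance = 1e-12)
  # noisy pairs: recovered gain within 3 standard errors
  set.seed(31)
  ch <- seq(50, 950, length.out = 10)
  en <- 0.05 + 0.01 * ch + rnorm(10, 0, 0.002)
  cal10 <- calibrate_energy(ch, en)
  expect_lt(abs(cal10$gain - 0.01), 3 * cal10$se_gain)
  expect_error(calibrate_energy(100, 1.0), ">= 2")
  expect_error(calibrate_energy(c(5, 5), c(1, 2)), "distinct")
})

test_that("design matrix columns are unit-amount spectra in element order", {
  cal <- list(gain = 0.01, offset = 0)
  n <- 771
  X <- build_design_matrix(c("Fe", "Ca"), cal, det, beam, n,
                           include_baseline = FALSE, mask_scatter = FALSE)
  expect_identical(colnames(X), c("Fe", "Ca"))
  grid <- attr(X, "energy_keV")
  unit <- simulate_spectrum(element_amounts(Fe = 1), beam, det, grid)
  expect_equal(unname(X[, "Fe"]), unit$counts, tolerance = 1e-12)
  # baseline adds constant + ramp columns
  Xb <- build_design_matrix("Fe", cal, det, beam, n)
  expect_identical(colnames(Xb), c("Fe", ".const", ".slope"))
  # scatter mask removes the channels near the excitation energy
  expect_false(all(attr(Xb, "mask")))
  expect_true(all(grid[!attr(Xb, "mask")] >
                    beam$excitation_keV - 3 * fwhm_at(det, 7.7) / 1000))
  expect_error(build_design_matrix("Zn", cal, det, beam, n),
               "Zn has no excitable line")
})

test_that("overlapped panels are worse conditioned than separated ones", {
  cal <- list(gain = 0.01, offset = 0)
  b12 <- xrf_beam(12)
  sep <- build_design_matrix(c("Fe", "Zn"), cal, det, b12, 1150,
                             include_baseline = FALSE)
  ovl <- build_design_matrix(c("Fe", "Dy"), cal, det, b12, 1150,
                             include_baseline = FALSE)
  expect_lt(kappa(sep[attr(sep, "mask"), ]),
            kappa(ovl[attr(ovl, "mask"), ]))
})

test_that("fit_pixel solves constrained recovery exactly and safely", {
  cal <- list(gain = 0.01, offset = 0)
  X <- build_design_matrix(c("Cl", "Fe", "Sm"), cal, det, beam, 771)
  truth <- c(Cl = 120, Fe = 35.5, Sm = 8.25)
  y <- as.numeric(X[, 1:3] %*% truth)
  fit <- fit_pixel(y, X)
  expect_equal(fit$amplitudes, truth, tolerance = 1e-10)
  expect_lt(fit$residual_norm, 1e-8)
  # zero spectrum -> zero amplitudes
  f0 <- fit_pixel(numeric(nrow(X)), X)
  expect_true(all(f0$amplitudes == 0))
  # non-negativity under a spectrum that pulls a coefficient negative
  y_neg <- as.numeric(X[, "Fe"]) - 0.5 * as.numeric(X[, "Sm"])
  fneg <- fit_pixel(pmax(y_neg, 0), X)
  expect_true(all(fneg$amplitudes >= 0))
  expect_error(fit_pixel(numeric(10), X), "length")
})

test_that("noisy single-pixel amplitudes recover within 5%", {
  # tolerance established by a 100-seed Monte Carlo during development:
  # worst observed relative error 1.7% at >= 1e4 total counts
  cal <- list(gain = 0.01, offset = 0)
  els <- c("Cl", "K", "P", "Ca", "Fe", "Sm", "Ti")
  X <- build_design_matrix(els, cal, det, beam, 771)
  truth <- c(Cl = 4000, K = 6000, P = 10000, Ca = 800, Fe = 3000,
             Sm = 250, Ti = 1000)
  sp <- simulate_spectrum(element_amounts(truth), beam, det,
                          attr(X, "energy_keV"))
  for (s in c(1, 17, 303)) {
    y <- add_poisson_noise(sp, s)$counts
    fit <- fit_pixel(y, X)
    expect_true(all(abs(fit$amplitudes - truth) / truth < 0.05),
                label = sprintf("seed %d relative errors < 5%%", s))
  }
})

test_that("batch_fit assembles maps and respects element permutations", {
  amounts <- c(Cl = 200, Fe = 80, Sm = 15)
  maps <- lapply(amounts, function(a) matrix(a, 2, 2))
  cube <- phantom_cube(maps, beam, det, noise = FALSE)
  fit <- batch_fit(cube, names(amounts), det, beam)
  # identical pixels give identical amplitude sets
  for (el in names(amounts)) {
    expect_equal(max(abs(fit$maps[[el]] - amounts[[el]])), 0,
                 tolerance = 1e-8)
  }
  expect_lt(max(fit$residual_norm), 1e-6)
  # permuting the element list permutes the maps correspondingly
  fit2 <- batch_fit(cube, rev(names(amounts)), det, beam)
  expect_identical(names(fit2$maps), rev(names(fit$maps)))
  expect_equal(fit2$maps$Fe, fit$maps$Fe, tolerance = 1e-10)
})

test_that("phantom cube round-trip correlates with ground truth maps", {
  cfg <- tiny_phantom_config(seed = 8, image_size = c(24, 24), n_cells = 3,
                             n_ti_particles = 1, counts_budget = 5000)
  ph <- make_map_phantom(cfg)
  els <- c("Cl", "K", "P", "Ca", "Fe", "Sm", "Ti")
  cube <- phantom_cube(ph$maps[els], beam, det, noise = TRUE, seed = 9)
  fit <- batch_fit(cube, els, det, beam)
  for (el in c("Cl", "K", "P", "Fe", "Ti")) {
    r <- cor(as.vector(fit$maps[[el]]), as.vector(ph$maps[[el]]))
    expect_gt(r, 0.95)
  }
  expect_true(all(vapply(fit$maps, function(m) all(m >= 0), logical(1))))
})
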