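make_disk_map <- function(nr = 40, nc = 40, centres, radius = 4,
                          value = 100, bg = 1) {
  m <- matrix(bg, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centres)))
    m[(rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= radius^2] <- value
  m
}

test_that("segmentation recovers disjoint synthetic cells and their sizes", {
  cfg <- phantom_config(image_size = c(128, 128), n_cells = 8,
                        n_ti_particles = 0, noise = TRUE, seed = 61)
  ph <- make_map_phantom(cfg)
  seg <- segment_cells(ph$maps$P, min_area_um2 = 15, max_area_um2 = 2000,
                       pixel_size_um = cfg$pixel_size_um)
  expect_identical(nrow(seg$cells), 8L)
  # match each segmented cell to the nearest truth cell; diameters agree
  # within one pixel
  truth <- ph$truth$cells
  for (i in seq_len(nrow(seg$cells))) {
    d <- sqrt((truth$centre_row - seg$cells$centroid_row[i])^2 +
                (truth$centre_col - seg$cells$centroid_col[i])^2)
    j <- which.min(d)
    expect_lt(abs(seg$cells$equiv_diameter_um[i] - truth$diameter_um[j]),
              cfg$pixel_size_um)
  }
  # label image invariants: 0/1 background/ECM plus contiguous cell ids
  ids <- sort(unique(seg$labels[seg$labels >= 2]))
  expect_identical(ids, seq.int(2L, length.out = nrow(seg$cells)))
})

test_that("segmentation edge cases behave as documented", {
  expect_error(segment_cells(matrix(0, 8, 8)), "uniform")
  # two touching disks merge under 8-connectivity
  m <- make_disk_map(centres = rbind(c(15, 15), c(15, 22)), radius = 4)
  seg <- segment_cells(m, min_area_um2 = 5, max_area_um2 = 1e5,
                       classify_ecm = FALSE)
  expect_identical(nrow(seg$cells), 1L)
  # the area filter drops small and oversized components
  m2 <- make_disk_map(centres = rbind(c(10, 10), c(30, 30)), radius = 4)
  m2[20, 20] <- 100  # single hot pixel
  seg2 <- segment_cells(m2, min_area_um2 = 4, max_area_um2 = 1e5,
                        classify_ecm = FALSE)
  expect_identical(nrow(seg2$cells), 2L)
})

test_that("positivity handles its trivial contracts", {
  m <- make_disk_map(centres = rbind(c(10, 10), c(30, 28)), radius = 4)
  seg <- segment_cells(m, min_area_um2 = 5, max_area_um2 = 1e5,
                       classify_ecm = FALSE)
  # label equal to k * background everywhere: strict inequality, all zero
  lab <- matrix(5, 40, 40)
  p0 <- positivity(seg, lab, background_level = 5)
  expect_equal(p0$sensitivity, 0)
  expect_equal(p0$false_positive_rate, 0)
  # every cell pixel labelled, no background labelled
  lab2 <- matrix(0, 40, 40); lab2[seg$labels >= 2] <- 10
  p1 <- positivity(seg, lab2, background_level = 0)
  expect_equal(p1$sensitivity, 1)
  expect_equal(p1$false_positive_rate, 0)
  expect_error(positivity(seg, matrix(0, 3, 3), 0), "shape")
})

test_that("positivity is invariant to joint monotone rescaling", {
  cfg <- tiny_phantom_config(seed = 77, cd45_fraction = 1)
  ph <- make_map_phantom(cfg)
  seg <- segment_cells(ph$maps$P, min_area_um2 = 15, max_area_um2 = 2000,
                       pixel_size_um = cfg$pixel_size_um)
  base <- positivity(seg, ph$maps$Sm, background_level = 2)
  scaled <- positivity(seg, ph$maps$Sm * 13.7, background_level = 2 * 13.7)
  expect_equal(scaled$sensitivity, base$sensitivity)
  expect_equal(scaled$false_positive_rate, base$false_positive_rate)
  mono <- positivity(seg, sqrt(ph$maps$Sm), background_level = sqrt(2))
  expect_equal(mono$sensitivity, base$sensitivity)
  expect_equal(mono$false_positive_rate, base$false_positive_rate)
})

test_that("phantom binding rates are recovered within binomial intervals", {
  cfg <- phantom_config(image_size = c(192, 192), n_cells = 30,
                        cd45_fraction = 1, binding_efficiency = 0.95,
                        nonspecific_rate = 0.02, n_ti_particles = 0,
                        seed = 99)
  ph <- make_map_phantom(cfg)
  seg <- segment_cells(ph$maps$P, min_area_um2 = 15, max_area_um2 = 2000,
                       pixel_size_um = cfg$pixel_size_um)
  pos <- positivity(seg, ph$maps$Sm, background_level = 0)
  expect_binomial_ci(pos$sensitivity, pos$n_cell, 0.95)
  expect_binomial_ci(pos$false_positive_rate, pos$n_background, 0.02)
  # per-region variant: every cell should be majority-positive here
  posr <- positivity(seg, ph$maps$Sm, background_level = 0,
                     per_region = TRUE)
  expect_equal(posr$sensitivity, 1)
})

test_that("pearson correlation matches its formula and stats oracle", {
  x <- c(4.2, 5.1, 6.3, 7.7, 9.0, 10.4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(20); b <- 0.6 * a + rnorm(20)
    got <- pearson_correlation(a, b)
    ref <- cor.test(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    # affine invariance, sign flip under negative slope
    expect_equal(pearson_correlation(2 * a + 3, 0.5 * b - 1)$r, got$r,
                 tolerance = 1e-12)
    expect_equal(pearson_correlation(-2 * a, b)$r, -got$r,
                 tolerance = 1e-12)
  }
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})

test_that("bivariate simulation at rho = 0.97 behaves like the field case", {
  # 300-rep check here; the full 1000-rep version runs in the acceptance
  # suite
  set.seed(50)
  rs <- replicate(300, {
    z <- matrix(rnorm(100), 50)
    b <- 0.97 * z[, 1] + sqrt(1 - 0.97^2) * z[, 2]
    res <- pearson_correlation(z[, 1], b)
    c(res$r, res$p)
  })
  expect_lt(abs(mean(rs[1, ]) - 0.97), 0.003)
  expect_gt(mean(rs[2, ] < 0.001), 0.99)
})
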