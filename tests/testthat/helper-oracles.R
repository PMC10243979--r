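# Independent brute-force clash oracle: straight double loop over raw
# catalogue rows, no shared code with find_clashes().
brute_force_clashes <- function(panel_a, panel_b, detector, beam,
                                window_multiplier, cutoff_a, cutoff_b) {
  cat <- xrf_catalogue()
  rows_for <- function(els, cutoff)
    cat[cat$element %in% els & cat$edge_keV < beam$excitation_keV &
          cat$rel_intensity >= cutoff, , drop = FALSE]
  a <- rows_for(panel_a, cutoff_a)
  b <- rows_for(panel_b, cutoff_b)
  pairs <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      mid <- (a$energy_keV[i] + b$energy_keV[j]) / 2
      w <- window_multiplier *
        sqrt(detector$electronic_noise_eV^2 +
               2.3548^2 * detector$fano * detector$pair_creation_eV *
               mid * 1000)
      if (abs(a$energy_keV[i] - b$energy_keV[j]) * 1000 < w)
        pairs <- c(pairs, paste(a$element[i], a$transition[i],
                                b$element[j], b$transition[j]))
    }
  }
  sort(pairs)
}

clash_pairs <- function(tab)
  sort(paste(tab$element_a, tab$transition_a, tab$element_b,
             tab$transition_b))

# Small, quickly solvable phantom configuration for unit tests.
tiny_phantom_config <- function(seed, ...) {
  defaults <- list(image_size = c(64, 64), n_cells = 6, n_ti_particles = 2,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}

expect_binomial_ci <- function(p_hat, n, p_true) {
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  expect_gte(p_true, p_hat - half)
  expect_lte(p_true, p_hat + half)
}
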