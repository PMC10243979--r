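#' Peak-convolution criterion for label selection
#'
#' Two emission lines are considered convolved when their energy separation
#' is smaller than a multiple of the detector FWHM evaluated at the midpoint
#' energy.  The defaults are tuned so that, with the default detector and
#' soft-tissue panel, the selection reproduces the known operating point of
#' lanthanide-tag XRF panel design: 12 of the 14 stable lanthanides usable
#' against {Cl, K, Ca, Fe, Zn}, and Cr flagging exactly {Nd, Sm, Eu, Gd}.
#'
#' The endogenous (disqualifying) test compares each candidate's principal
#' line only (`label_line_cutoff = 0.999`; the within-series normalization
#' makes the principal line the unique line at 1) against the endogenous
#' Ka lines (`endo_line_cutoff = 0.2` admits Ka1/Ka2 but not Kb), with a
#' 1 FWHM window.  The exogenous (advisory) test uses a wider ~250 eV
#' window (1.8 FWHM near 5.5 keV) against Ka and Kb lines
#' (`exo_line_cutoff = 0.1`).
#'
#' @param endogenous_window_multiplier Clash window for the endogenous test,
#'   as a multiple of FWHM at the pair midpoint.
#' @param exogenous_window_multiplier Likewise for the advisory exogenous
#'   test.
#' @param endo_line_cutoff Minimum relative intensity for an endogenous line
#'   to participate.
#' @param exo_line_cutoff Likewise for exogenous lines.
#' @param label_line_cutoff Likewise for candidate-label lines.
#' @return Object of class `convolution_criterion`.
#' @export
convolution_criterion <- function(endogenous_window_multiplier = 1.0,
                                  exogenous_window_multiplier = 1.8,
                                  endo_line_cutoff = 0.2,
                                  exo_line_cutoff = 0.1,
                                  label_line_cutoff = 0.999) {
  stopifnot(endogenous_window_multiplier > 0, exogenous_window_multiplier > 0,
            endo_line_cutoff >= 0, endo_line_cutoff <= 1,
            exo_line_cutoff >= 0, exo_line_cutoff <= 1,
            label_line_cutoff >= 0, label_line_cutoff <= 1)
  structure(list(endogenous_window_multiplier = endogenous_window_multiplier,
                 exogenous_window_multiplier = exogenous_window_multiplier,
                 endo_line_cutoff = endo_line_cutoff,
                 exo_line_cutoff = exo_line_cutoff,
                 label_line_cutoff = label_line_cutoff),
            class = "convolution_criterion")
}

#' Find convolving line pairs between two element panels
#'
#' Exhaustive pairwise comparison of every excitable line of panel A
#' (passing `cutoff_a`) against every excitable line of panel B (passing
#' `cutoff_b`).  A pair clashes when its separation is below
#' `window_multiplier` times the detector FWHM at the midpoint energy.
#' Symmetric in panel order when the cutoffs are equal.
#'
#' @param panel_a,panel_b Disjoint, non-empty element symbol vectors.
#' @param detector An [xrf_detector()].
#' @param beam An [xrf_beam()]; only lines with edge below the excitation
#'   energy participate.
#' @param window_multiplier Clash window as a multiple of FWHM at the pair
#'   midpoint.
#' @param cutoff_a,cutoff_b Per-panel relative-intensity cutoffs.
#' @return Data frame with one row per clashing pair: `element_a`,
#'   `transition_a`, `energy_a_keV`, `element_b`, `transition_b`,
#'   `energy_b_keV`, `delta_eV`, `window_eV`.
#' @export
find_clashes <- function(panel_a, panel_b, detector = xrf_detector(),
                         beam = xrf_beam(12), window_multiplier = 1.8,
                         cutoff_a = 0.1, cutoff_b = 0.1) {
  if (!length(panel_a) || !length(panel_b))
    stop("panels must be non-empty", call. = FALSE)
  if (length(intersect(panel_a, panel_b)))
    stop("panels overlap: ",
         paste(intersect(panel_a, panel_b), collapse = ", "), call. = FALSE)
  check_element(c(panel_a, panel_b))
  out <- list()
  for (ea in panel_a) {
    la <- get_lines(ea, beam, cutoff_a)
    if (!nrow(la)) next
    for (eb in panel_b) {
      lb <- get_lines(eb, beam, cutoff_b)
      if (!nrow(lb)) next
      for (i in seq_len(nrow(la))) {
        mid <- (la$energy_keV[i] + lb$energy_keV) / 2
        window <- window_multiplier * fwhm_at(detector, mid)
        delta <- abs(la$energy_keV[i] - lb$energy_keV) * 1000
        hit <- which(delta < window)
        for (j in hit) {
          out[[length(out) + 1L]] <- data.frame(
            element_a = ea, transition_a = la$transition[i],
            energy_a_keV = la$energy_keV[i],
            element_b = eb, transition_b = lb$transition[j],
            energy_b_keV = lb$energy_keV[j],
            delta_eV = delta[j], window_eV = window[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_clash_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_clash_table <- function() {
  data.frame(element_a = character(), transition_a = character(),
             energy_a_keV = numeric(), element_b = character(),
             transition_b = character(), energy_b_keV = numeric(),
             delta_eV = numeric(), window_eV = numeric(),
             stringsAsFactors = FALSE)
}

#' Select usable lanthanide labels for a panel
#'
#' Determines which candidate label elements can be detected free of
#' fluorescence-peak convolution with the endogenous tissue elements, and
#' reports advisory convolution warnings against expected exogenous
#' elements.  Endogenous clashes disqualify a candidate; exogenous clashes
#' are advisory only (conditional on that element actually being present)
#' and do not remove candidates from the usable set.
#'
#' The default beam is a 12 keV survey excitation, above every candidate
#' L edge and every endogenous K edge, so that panel design considers all
#' lines that could be excited in practice regardless of the imaging energy
#' eventually chosen.
#'
#' A free-text warning is added when the pile-up (doubled) Ka energy of a
#' high-concentration low-Z panel element lands within a window of a
#' candidate's principal line: pile-up peaks may be a source of convolution
#' even though they are outside the emission-only model.
#'
#' @param endogenous Elements expected in the tissue; default
#'   `{Cl, K, Ca, Fe, Zn}`.
#' @param exogenous Elements that may be present as exposures (advisory).
#' @param candidates Candidate labels; default the 14 stable lanthanides.
#'   An empty candidate list yields an empty report.
#' @param detector,beam,criterion See [convolution_criterion()].
#' @return Object of class `convolution_report` with fields `candidates`,
#'   `usable`, `endogenous_clashes`, `exogenous_clashes` (clash tables as in
#'   [find_clashes()]), `warnings`, plus the configuration used.
#' @examples
#' rep <- select_labels()
#' length(rep$usable)  # 12
#' @export
select_labels <- function(endogenous = c("Cl", "K", "Ca", "Fe", "Zn"),
                          exogenous = character(),
                          candidates = stable_lanthanides(),
                          detector = xrf_detector(), beam = xrf_beam(12),
                          criterion = convolution_criterion()) {
  stopifnot(inherits(criterion, "convolution_criterion"))
  if (length(intersect(candidates, endogenous)))
    stop("candidate label(s) also listed as endogenous: ",
         paste(intersect(candidates, endogenous), collapse = ", "),
         call. = FALSE)
  check_element(c(endogenous, exogenous, candidates))
  if (length(candidates)) {
    endo <- find_clashes(candidates, endogenous, detector, beam,
                         criterion$endogenous_window_multiplier,
                         cutoff_a = criterion$label_line_cutoff,
                         cutoff_b = criterion$endo_line_cutoff)
    exo <- if (length(exogenous))
      find_clashes(candidates, exogenous, detector, beam,
                   criterion$exogenous_window_multiplier,
                   cutoff_a = criterion$label_line_cutoff,
                   cutoff_b = criterion$exo_line_cutoff)
    else empty_clash_table()
    usable <- setdiff(candidates, unique(endo$element_a))
  } else {
    endo <- exo <- empty_clash_table()
    usable <- character()
  }
  warnings <- pileup_warnings(candidates, c(endogenous, exogenous),
                              detector, beam, criterion)
  structure(list(candidates = candidates, usable = usable,
                 endogenous = endogenous, exogenous = exogenous,
                 endogenous_clashes = endo, exogenous_clashes = exo,
                 warnings = warnings, criterion = criterion,
                 detector = detector, beam = beam),
            class = "convolution_report")
}

# Advisory pile-up check: doubled Ka1 energy of a lower-Z panel element
# falling within the exogenous window of a candidate's principal line.
pileup_warnings <- function(candidates, panel, detector, beam, criterion) {
  out <- character()
  for (el in unique(panel)) {
    pk <- tryCatch(principal_line(el, "K"), error = function(e) NULL)
    if (is.null(pk) || pk$edge_keV >= beam$excitation_keV) next
    e2 <- 2 * pk$energy_keV
    for (cand in candidates) {
      if (atomic_number(el) >= atomic_number(cand)) next
      sr <- if (atomic_number(cand) >= 57) "L" else "K"
      pl <- principal_line(cand, sr)
      if (pl$edge_keV >= beam$excitation_keV) next
      window <- criterion$exogenous_window_multiplier *
        fwhm_at(detector, (e2 + pl$energy_keV) / 2)
      if (abs(e2 - pl$energy_keV) * 1000 < window)
        out <- c(out, sprintf(
          paste0("Pile-up peaks may be a source of convolution: doubled ",
                 "%s Ka (%.3f keV) lies within %.0f eV of %s %s ",
                 "(%.3f keV) if %s is highly concentrated."),
          el, e2, window, cand, pl$transition, pl$energy_keV, el))
    }
  }
  out
}

#' @export
print.convolution_report <- function(x, ...) {
  cat(sprintf("<convolution_report> %d candidate(s), %d usable\n",
              length(x$candidates), length(x$usable)))
  cat("  usable: ", paste(x$usable, collapse = ", "), "\n", sep = "")
  excl <- setdiff(x$candidates, x$usable)
  if (length(excl))
    cat("  excluded (endogenous clash): ", paste(excl, collapse = ", "),
        "\n", sep = "")
  if (nrow(x$exogenous_clashes)) {
    adv <- unique(x$exogenous_clashes$element_a)
    cat("  advisory (exogenous clash): ", paste(adv, collapse = ", "),
        "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tabulate a convolution report
#'
#' One row per clashing (label, interferer) line pair with the separation
#' and applicable window, ordered by label atomic number then interferer,
#' followed by a single `usable` summary row.
#'
#' @param report A `convolution_report` from [select_labels()].
#' @return Data frame with columns `kind` (`"endogenous"`, `"exogenous"`,
#'   `"usable"`), `label`, `interferer`, `label_transition`,
#'   `interferer_transition`, `delta_eV`, `window_eV`.
#' @export
report_to_table <- function(report) {
  stopifnot(inherits(report, "convolution_report"))
  row_of <- function(tab, kind) {
    if (!nrow(tab)) return(NULL)
    data.frame(kind = kind, label = tab$element_a,
               interferer = tab$element_b,
               label_transition = tab$transition_a,
               interferer_transition = tab$transition_b,
               delta_eV = tab$delta_eV, window_eV = tab$window_eV,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(row_of(report$endogenous_clashes, "endogenous"),
                row_of(report$exogenous_clashes, "exogenous"))
  if (!is.null(rows) && nrow(rows))
    rows <- rows[order(atomic_number(rows$label), rows$interferer,
                       rows$label_transition, rows$interferer_transition), ,
                 drop = FALSE]
  usable_row <- if (length(report$usable)) data.frame(
    kind = "usable", label = paste(report$usable, collapse = ";"),
    interferer = "", label_transition = "", interferer_transition = "",
    delta_eV = NA_real_, window_eV = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(rows, usable_row)
  if (is.null(out))
    out <- data.frame(kind = character(), label = character(),
                      interferer = character(), label_transition = character(),
                      interferer_transition = character(),
                      delta_eV = numeric(), window_eV = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
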