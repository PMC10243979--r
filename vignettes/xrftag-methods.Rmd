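---
title: "Methods: lanthanide-tag panel design and synchronous XRF image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lanthanide-tag panel design and synchronous XRF image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrftag)
```

## The problem

Synchrotron X-ray fluorescence (XRF) microscopy images endogenous elements
(Cl, K, P, Ca, Fe, Zn in soft tissue) and exogenous metal particles (e.g.
TiO~2~) simultaneously and non-destructively. Antibodies conjugated to
lanthanide tags extend this to biological epitopes: the lanthanide L-shell
fluorescence falls in the same energy window as the tissue K lines, so one
scan yields cells, matrix, endogenous chemistry and the exposure at once.
The price is spectral crowding: an energy-dispersive detector has a finite
resolution, and an L line landing within roughly one resolution width of a
tissue K line cannot be quantified independently. `xrftag` implements the
planning and analysis chain for this kind of experiment: emission-line
physics, forward spectrum simulation, convolution-aware tag selection,
per-pixel spectral fitting, confocal depth-stack processing, label/cell
colocalization statistics, and a synthetic phantom generator that makes every
stage testable against known ground truth.

## Line physics

The embedded catalogue (`xrf_catalogue()`) holds every radiative K transition
for P--Zn and every L transition for La--Lu: IUPAC transition code, photon
energy, edge (binding) energy of the ionized shell, and a relative intensity.
Intensities are normalized per (element, series) so the principal line --
K$\alpha_1$ (KL3) or L$\alpha_1$ (L3M5) -- equals 1; they fold in relative
subshell excitation and fluorescence yields at a 20 keV reference
excitation. Absolute cross sections are deliberately out of scope: fitted
outputs are relative counts.

A practical note on multiplicity: a lanthanide L shell emits well over 20
distinct lines (the catalogue holds 42--46 per element), but only 4--6 are
detectable in real spectra. The conventional statement that the rest have
"emission probabilities below 1%" refers to *absolute* probabilities; on the
catalogue's normalized scale (principal line = 1, L-shell yield ~0.1--0.2)
the equivalent detectability cutoff is about 0.12, and the package's
property tests use that value.

The detector model is the standard energy-dispersive silicon response

$$\mathrm{FWHM}(E) = \sqrt{n^2 + 2.3548^2\, F\, \epsilon\, E},$$

with electronic noise $n$ (eV), Fano factor $F$ and pair-creation energy
$\epsilon$ (3.85 eV for Si). The defaults ($n = 72.5$ eV, $F = 0.114$) give
140 eV FWHM at Mn K$\alpha$ (5.895 keV), typical of the silicon drift
detectors used at microfocus beamlines; no resolution figure is published
for the reference experiments, so this is a package default, stated once
and used everywhere.

## Spectrum simulation

`simulate_spectrum()` is an emission-only forward model: each excitable line
(edge below the beam energy) contributes a Gaussian at its line energy with
the detector FWHM, with integrated area `amount x rel_intensity`. There is no
background and there are no pile-up, escape or scatter peaks -- deliberately,
because tag selection reasons about fluorescence emission only, and scatter
artefacts are controlled experimentally (incident energy, detector choice).
Consequences worth knowing:

* the model is linear in the amounts (tested as an invariant), which is what
  makes fixed-shape linear fitting exact on simulated data;
* an element whose every edge lies above the beam contributes nothing -- at
  7.7 keV, Zn (K edge 9.66 keV) is invisible;
* closely spaced lines blend: Sm L$\alpha_1$ (5.636 keV) and Nd L$\beta_1$
  (5.722 keV) are 86 eV apart, under one FWHM, so in a multi-tag spectrum the
  apex of a blended ridge need not sit exactly on a line energy. Tests
  assert apex position only for isolated peaks.

The default grid is 10 eV per channel from 0 to the excitation energy.

## Tag selection

`select_labels()` answers: which of the 14 stable lanthanides can be detected
free of convolution over a given endogenous panel, and which become risky if
specific exogenous elements are present?

Two emission lines *clash* when their separation is below a multiple of the
detector FWHM at their midpoint. The default criterion, the one genuinely
open design decision in this package, is:

* **endogenous (disqualifying) test**: the candidate's *principal* L line
  only, against the endogenous K$\alpha$ lines (cutoff 0.2 admits
  K$\alpha_{1,2}$ but not K$\beta$), window $1.0 \times$ FWHM. The principal
  line is the one that must be clean for quantification; secondary L lines
  overlap something in almost any panel and are handled by the fit.
* **exogenous (advisory) test**: the candidate's principal line against
  K$\alpha$ and K$\beta$ of the exogenous element (cutoff 0.1), window
  $1.8 \times$ FWHM ($\approx 250$ eV near 5.5 keV). Advisory clashes are
  reported but do not disqualify: they matter only if that element is
  actually present.

With the default soft-tissue panel {Cl, K, Ca, Fe, Zn} this yields 12 usable
candidates; the two excluded are Tb and Dy, whose L$\alpha_1$ lines (6.273,
6.495 keV) bracket Fe K$\alpha$ (6.404 keV) within one FWHM. Adding Cr to
the exogenous panel flags exactly Nd, Sm, Eu (via Cr K$\alpha$) and Gd (via
Cr K$\beta$). A wider endogenous cutoff that admits secondary L lines would
additionally disqualify Lu (L$\beta_1$ 8.709 keV vs Zn K$\alpha$ 8.639 keV)
and is not consistent with the known 12-element operating point.

Two caveats are intentional. First, selection runs at a 12 keV survey
energy by default: the imaging energies actually used (5.7--7.7 keV) cannot
excite the heavier candidates at all (Lu L3 edge 9.24 keV), and panel design
must consider every line that could be excited. Second, the V example is
only partially decidable: V flags Pr and Nd under the default criterion, as
expected, but also Ce (L$\alpha_1$ 112 eV from V K$\alpha$) -- the exact
historical per-element windows are not recoverable, so the test suite
asserts only the Pr/Nd containment.

Pile-up is outside the emission model, but the report carries a free-text
warning when the doubled K$\alpha$ energy of a lighter panel element lands
within a window of a candidate's principal line (e.g. 2 x Cl K$\alpha$ =
5.245 keV sits 15 eV from Nd L$\alpha_1$): pile-up peaks may be a source of
convolution when the light element is highly concentrated.

## Spectral fitting

`batch_fit()` re-implements the "energy calibrate, batch fit, output
elemental images" stage as a fixed-shape linear model: one design column per
element equal to its unit-amount simulated spectrum on the calibrated grid,
optional constant + linear baseline columns (default on), and per-pixel
non-negative least squares (Lawson--Hanson active set, with a fast path that
accepts the unconstrained QR solution when it is already non-negative).
There is no per-pixel shape refinement: simulation and fitting share the
peak model, so noiseless round trips are exact to machine precision, which
is the point of the phantom-based validation. Channels above
$E_0 - 3\,\mathrm{FWHM}(E_0)$ are masked by default because scatter is not
modelled. Matrix-effect correction is out of scope: the configuration used
for it in the reference workflow is not reproducible from public
information.

Tolerances: a 100-seed Monte Carlo on a seven-element soft-tissue pixel with
$\ge 10^4$ total counts gave worst-case amplitude errors of 1.7%; the
acceptance suite asserts 5% per pixel for amplitudes with true amounts of at
least 500 counts. No percent tolerance can hold for near-zero amounts
(Poisson noise is unbounded relative to them), which is why the bound is
scoped.

## Confocal stacks

A confocal depth stack acquired at 45 degrees between sample and beam
carries a lateral displacement of `depth_step x tan(angle)` per plane (15 um
steps at 45 degrees = 15 um = 3 px at 5 um pixels). `shift_correct()`
translates each plane back, with linear interpolation for sub-pixel shifts;
vacated margins become `NA` (invalid), never zero. Integer shifts are exact
and invertible; fractional shifts conserve total intensity to 0.1% but are
low-pass, so the inverse-pair property is only exact for integer shifts.

Particle processing follows the reference recipe: threshold at 10 x
background, display as $\log_{10}(1 + x)$, then 26-connected 3-D components
with per-feature volume, maximal in-plane extent and depth span. Background
is the median of off-tissue pixels when a mask is available, else the median
of the lowest-intensity quartile. The unmasked estimator is biased low on
discrete low-count data (it estimates roughly the 12th percentile), which is
harmless for 10x thresholding but means the within-10% background-recovery
guarantee is only made for the masked route.

## Colocalization statistics

`segment_cells()` uses a global between-class-variance (Otsu) threshold --
two thresholds when the ECM class is enabled, separating background / ECM /
cells -- followed by 8-connected components and an area filter. Touching
cells merge; that is a documented property of the operator. Cell size is
reported as equivalent diameter.

`positivity()` counts a pixel as label-positive when its value strictly
exceeds `k x background` (k = 1 by default; no published value exists). The
sensitivity denominator is cell pixels, the false-positive denominator is
background pixels, and ECM pixels are excluded from both. A per-region
variant (cell positive if more than half its pixels are) is provided because
the published background statistic is phrased over "regions"; the default is
per-pixel. `pearson_correlation()` implements the product-moment formula
with the two-sided t test on n - 2 degrees of freedom.

## The phantom world

The generator emulates exactly the statistical structure the analysis
assumes, with every random element seeded:

* an elliptical tissue (ECM) region on a bare substrate;
* non-overlapping disk cells with lognormal diameters (median 9 um,
  log-sd 0.25 -- a lymphocyte-sized infiltrate), placed by rejection
  sampling (a packing failure is an error, not a silent shortfall);
* a CD45-positive subset (default 60%; set to 100% to emulate a segmented
  CD45+ population as in the spleen scenario) carrying the Sm label as
  per-pixel Bernoulli($\beta$) with default $\beta = 0.98$, plus
  Bernoulli($\gamma$) nonspecific deposition on background, default
  $\gamma = 0.01$ -- the reported operating point of a well-stained section;
* per-class element means (order-of-magnitude defaults; true tissue
  concentrations are not published for this system) scaled by a counts
  budget, with Poisson noise;
* sparse Ti disks at 50 x background, comfortably above the 10x threshold;
* optionally, a full spectrum cube via the forward model, so the fitting
  stage has exactly known per-pixel amounts;
* a confocal variant whose particles persist through a number of planes
  proportional to their lateral extent (positive size-persistence
  association by construction) and whose planes carry the geometric skew,
  so the correction has a known truth.

What a green phantom test does *not* establish: recovery of the published
in-vivo percentages (those maps are not deposited), robustness to detector
tailing, scatter or pile-up (excluded from the emission model), absorption
with depth (no self-absorption correction is made, matching the reference
treatment), or segmentation of textured, touching, anisotropic real cells.
The phantom's crisp class means make Otsu segmentation nearly exact;
sensitivity/specificity recovery therefore validates the statistics
pipeline, not the difficulty of real segmentation.

## Numerical and interface choices

* NNLS tolerance is relative (`1e-10` of the largest gradient entry);
  ties in the active-set selection resolve deterministically by column
  order, so fits are reproducible.
* All randomness is funnelled through one seeded helper that restores the
  caller's RNG state; phantom outputs are bit-identical across runs for a
  fixed seed.
* With no HDF5 or TIFF binding available in the target environment, the
  package carries a minimal baseline TIFF reader/writer (uncompressed,
  grayscale, float32/uint16, multi-page, JSON metadata in the per-page
  description), interoperable with standard readers; cubes, maps and stacks
  use it, spectra and tables are CSV, reports and configs JSON.
* The CLI (`xrftag_cli()`, wrapped by `inst/cli/xrftag`) returns status 0 /
  1 / 2 (success / validation failure / usage error) and prints a
  provenance block (package version, config hash, seed) on every run.

## Known limitations

Amounts are relative; no attenuation, pile-up, escape or scatter modelling;
no per-pixel peak-shape refinement; selection windows are a tuned default,
not a measured instrument property; the unmasked background estimator is
biased at low counts; segmentation is global-threshold based and merges
touching cells.
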