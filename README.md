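# xrftag

Lanthanide-tag panel design and synchronous X-ray fluorescence (XRF)
imaging analysis.

## The problem

Synchrotron micro-XRF images endogenous tissue elements (Cl, K, P, Ca, Fe,
Zn), exogenous metal particles (e.g. TiO2 exposures) and — when sections are
stained with lanthanide-conjugated antibodies — biological epitopes, all in
one non-destructive scan. This removes the serial-section uncertainty that
plagues correlative imaging: everything is measured on the same pixels.
The catch is spectral: lanthanide L-shell emission falls in the same energy
window as the tissue K lines, and two lines closer than about one detector
resolution width (FWHM) cannot be quantified independently.

`xrftag` implements the full planning and analysis chain:

- **line physics** — embedded emission-line catalogue (K series P–Zn,
  L series La–Lu) and a silicon-drift-detector resolution model
  `FWHM(E) = sqrt(noise^2 + 2.3548^2 * Fano * pair * E)` (140 eV at Mn Ka
  by default);
- **spectrum simulation** — emission-only forward model (Gaussian peaks,
  no background/pile-up/escape/scatter), linear in element amounts;
- **tag selection** — convolution analysis of candidate lanthanide labels
  against endogenous and exogenous panels; a candidate is usable when its
  principal L3M5 line is at least one FWHM away from every endogenous
  Ka line, and exogenous clashes (within ~250 eV) are advisory;
- **spectral fitting** — energy calibration and per-pixel non-negative
  least squares on fixed simulated peak shapes, producing elemental maps;
- **confocal stacks** — 45°-geometry lateral shift correction,
  10×-background thresholding, log display scaling, 3-D 26-connected
  particle statistics (volume, extent, depth persistence);
- **colocalization** — Otsu cell segmentation, label-positivity
  sensitivity / false-positive rate, Pearson size correlation;
- **synthetic phantoms** — seeded tissue and confocal phantoms with full
  ground truth, so every stage is validated end-to-end without external
  data;
- **CLI** — `inst/cli/xrftag` with `simulate`, `select-labels`, `fit`,
  `confocal`, `coloc`, `phantom` subcommands.

## Worked example

Which lanthanide tags survive a soft-tissue panel, and what happens if a
Cr-bearing exposure is expected?

```r
library(xrftag)
rep <- select_labels(exogenous = "Cr")
print(rep)
#> <convolution_report> 14 candidate(s), 12 usable
#>   usable: La, Ce, Pr, Nd, Sm, Eu, Gd, Ho, Er, Tm, Yb, Lu
#>   excluded (endogenous clash): Tb, Dy
#>   advisory (exogenous clash): Nd, Sm, Eu, Gd
#>   warning: Pile-up peaks may be a source of convolution: doubled Cl Ka
#>   (5.245 keV) lies within 242 eV of Nd L3M5 (5.230 keV) if Cl is highly
#>   concentrated.  [...]
```

12 of the 14 stable lanthanides are usable; Tb and Dy fall within one FWHM
of Fe Ka (6.404 keV) and are excluded; if Cr is present, Nd, Sm, Eu and Gd
are additionally not recommended.

End-to-end label/cell statistics on a seeded phantom (cells as disks on an
ECM field, Sm deposited on CD45+ cell pixels with binding efficiency
β = 0.98 and nonspecific background rate γ = 0.01, Poisson noise):

```r
cfg <- phantom_config(image_size = c(256, 256), cd45_fraction = 1, seed = 42)
ph  <- make_map_phantom(cfg)
seg <- segment_cells(ph$maps$P, min_area_um2 = 20, max_area_um2 = 2000,
                     pixel_size_um = 1.5)
positivity(seg, ph$maps$Sm, background_level = 0)
#> <positivity_stats> sensitivity 98.1% (1588/1618),
#>                    background positivity 1.1% (315/29228)
```

The segment → positivity pipeline recovers the generator's operating point:
98.1% of segmented cell pixels carry the label, 1.1% of background pixels
do — i.e. high sensitivity and high specificity of epitope detection.

Forward-simulate the spectrum such a panel produces at 7.7 keV excitation:

```r
sp <- simulate_spectrum(element_amounts(Cl = 300, K = 500, Ca = 150,
                                        Fe = 400, Nd = 40, Sm = 40,
                                        Eu = 40), xrf_beam(7.7))
print(sp)
#> <xrf_spectrum> 771 channels, 0.0000-7.7000 keV (gain 0.01 keV/ch), total 2547
```

## Documentation

The methods vignette (`vignettes/xrftag-methods.Rmd`) documents the models,
the tuned selection criterion and its rationale, numerical tolerances, what
the phantom world does and does not establish, and known limitations.
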