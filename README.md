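# gbcaPET

Quantifying the effect of gadolinium-based MR contrast agents (GBCA) on PET
attenuation and image-based activity concentration, at phantom scale.

## The problem

In simultaneous cardiac PET-MR perfusion imaging, a contrast bolus and the
PET tracer can occupy the left ventricle at the same time. A 20 ml bolus of
a 0.5 mmol/ml agent mixed into a 150 ml end-diastolic volume reaches
~70 mM of gadolinium — and Gd is a heavy element, so the question is
whether that much of it measurably changes the 511 keV linear attenuation
coefficient (LAC) of the blood/tracer mixture, and whether
attenuation-correction (AC) strategies that assume a contrast-free
attenuation map then bias PET quantification.

`gbcaPET` answers both questions computationally for a cylindrical phantom
(5 cm diameter, 120 ml water + 40 MBq [18F]-NaF, DOTAREM added in steps to
66 mM):

* **Mixture model.** Hubbell's weighted-average rule for the solution MAC,
  μ_M(soln) = μ_M(wa)·w_wa + μ_M(Gd)·w_Gd, with LAC = MAC × density and an
  additive-volume density model for the dilution series.
* **Synthetic CT chain.** Single-effective-energy Hounsfield numbers
  (150 keV surrogate for a 140 kVp beam) and the standard bilinear HU →
  511 keV LAC conversion.
* **Phantom simulation.** Voxelised cylinder, 2-D parallel-beam projection,
  attenuation factors exp(+∫μ dl), optional seeded Poisson noise, ramp-filtered
  back-projection, absolute calibration.
* **Quantification.** Three AC strategies — AC1 (matched CT map per step),
  AC2 (fixed 0 mM CT map), AC3 (uniform 0.1 cm⁻¹) — reduced to VOI bias
  against decay- and volume-corrected ground truth.

## Worked example

```r
library(gbcaPET)

## worst-case left-ventricle concentration
maxChamberConcentration(20, 0.5, 150)
#> [1] 66.66667

## the dilution series and its 511 keV LAC rise
series <- buildDilutionSeries()          # 0, 3, ..., 30, 34, ..., 66 mM
lacIncreasePercent(series, energy = 511)
#> [1] 2.496417

## full simulated experiment: 20 steps x {AC1, AC2, AC3}, noise-free
study <- runPhantomStudy()               # ~3 min on one CPU
study
#> PhantomStudy: 20 steps x 3 methods (none noise)
#>   AC1     max |bias| 1.65%
#>   AC2     max |bias| 1.22%
#>   AC3     max |bias| 2.06%

summarizeStudy(study)$ac1_vs_ac2_mean_difference_percent
#> [1] 1.671613
```

Reading the numbers: the mixture rule puts the solution's 511 keV LAC rise
at ≈2.5% over 0–66 mM (0.0969 → 0.0993 cm⁻¹), and every AC strategy stays
within 5% of the true activity concentration at every step, with no bias
trend against concentration — contrast at worst-case cardiac
concentrations is a minimal effect on corrected PET quantification. AC2
under-corrects progressively (to ≈ −1.2% at 66 mM), AC3 over-corrects most
at 0 mM (0.1 cm⁻¹ vs 0.0969) and less as concentration rises.

The methods vignette (`vignettes/gbca-pet-quantification.Rmd`) documents
the models, the density assumption behind the 2.5%, the deliberate
limitations of the synthetic CT chain, and the closed-form ACF ratios that
predict the entire bias structure.

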