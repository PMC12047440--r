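# rnpquant

Quantitative analysis of LINE-1 ORF1p ribonucleoprotein (RNP)
condensate experiments.

LINE-1 (L1) is the only autonomously active human retrotransposon. Its
RNA-binding protein ORF1p forms homotrimers that oligomerize and coat L1
mRNA into RNP condensates; when ORF1p stoichiometry exceeds the RNA's
direct binding capacity ("super-saturation"), the condensate acquires
DNA-binding activity. Characterising this behaviour takes four
quantitative pipelines that usually live in scattered scripts:

* **Mass photometry** — contrast-to-mass calibration against protein
  standards, fixed 100-bin / 8-kDa mass histograms, Gaussian
  deconvolution of oligomeric species (monomer / trimer / hexamer /
  higher-order), and the cooperative Hill model of RNA-induced hexamer
  dissociation,
  p₃(c) = f_min + (f_max − f_min) · cʰ / (K½ʰ + cʰ).
* **Equilibrium binding** — anisotropy blank subtraction and min–max
  normalization, Hill fits θ(P) = Pʰ/(K_dʰ + Pʰ) (with free affine
  amplitude absorbing normalization distortion), and an exact
  coupled-equilibrium solver for two nucleic acids competing for one
  shared site.
* **Footprint stoichiometry** — each trimer needs a 30-nt footprint at a
  45-nt periodicity, so an RNA of L nt holds
  N(L) = ⌊(L − 30)/45⌋ + 1 trimers (L ≥ 30); a 2-kb RNA holds 44
  trimers = 132 monomers ≈ 130-fold molar excess at saturation.
* **DNA curtains** — binding events per DNA with per-nM normalization
  and weighted averaging, two-colour condensate colocalization, 24 × 2-kbp
  position histograms against TTTTTAA motif and A/T-content genome
  tracks with a permutation enrichment test, Kaplan–Meier dwell-time
  survival with bootstrap bands, amplitudes and kymograms.
* **3D cell imaging** — multiscale Laplacian-of-Gaussian spot detection
  in 3D, ROI assignment, nuclear/cytoplasmic classification,
  count-matched randomized-spot nulls, per-ROI median-normalized
  cross-channel intensities, Mann–Whitney colocalization statistics and
  puncta–chromatin fractions.

Every modality has a synthetic-data generator with recorded ground truth
(`simMassEvents`, `simAnisotropyCurve`, `simDissociationSeries`,
`simGenome`/`simCurtainEvents`, `simSpotImages`), so the full stack is
testable end to end without any external data. The package is aimed at
single-molecule and imaging labs that want these estimators as tested,
reusable components rather than per-figure scripts.

## Worked example

Deconvolve a synthetic 30/70 trimer/hexamer mixture (20,000 landing
events, 12 kDa mass noise, monomer 40 kDa), then check the footprint
model and a binding fit:

```r
library(rnpquant)

sim <- simMassEvents(data.frame(mass = c(120, 240), fraction = c(0.3, 0.7)),
                     n_events = 20000, mass_noise_sd = 12, seed = 1)
cal <- calibrateMass(sim$standards, massStandards())
fitOligomerPeaks(buildMassHistogram(applyCalibration(sim$events, cal)))
#> OligomerFit (sse = 12800 )
#>   species    mu sigma      area fraction
#> 1       1    NA    NA     0.000    0.000
#> 2       3 119.6  12.0  6087.074    0.304
#> 3       6 239.5  12.3 13938.771    0.696
#> 4      >6    NA    NA     0.000    0.000
```

The fitted trimer peak sits at 119.6 kDa (monomer 39.9 kDa) and the
recovered fractions 0.304/0.696 match the generating 0.3/0.7.

```r
maxTrimers(c(30, 60, 90, 120, 1970))
#> [1]  1  1  2  3 44
saturationExcess(1970)$rounded
#> [1] 130
```

One trimer binds from 30 nt, a second from 90 nt; a 2-kb RNA offers 44
trimer sites, saturated at a ~130-fold monomer excess.

```r
bc <- simAnisotropyCurve(kd = 3.9, h = 1, noise_sd = 0,
                         protein_concs = 10^seq(-1, 3, length.out = 12))
coef(fitHillBinding(normalizeAnisotropy(bc)))["kd"]
#>  kd
#> 3.9
```

A noise-free RNA-affinity titration returns the generating
K_d = 3.9 nM exactly. Dwell-time survival of 300 exponential lifetimes
(mean 750 s) censored at movie end (600 s):

```r
set.seed(1); d <- rexp(300, 1/750); cen <- d > 600
km <- kaplanMeier(pmin(d, 600), cen, n_bootstrap = 1000, seed = 1)
survivalAt(km, 300)
#> [1] 0.7133333
```

about 71% of condensates survive past 300 s, consistent with the
closed-form exp(−300/750) ≈ 0.67 and well above 60% five-minute
persistence.

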