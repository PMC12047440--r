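---
title: "Models and methods for ORF1p RNP condensate quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ORF1p RNP condensate quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpquant)
```

# Scope

LINE-1 ORF1p is an RNA-binding protein that assembles as homotrimers,
oligomerizes, and coats L1 mRNA into ribonucleoprotein (RNP) condensates.
`rnpquant` implements the quantitative stack used to characterise such
condensates across four experimental modalities — single-molecule mass
photometry, fluorescence-anisotropy binding assays, DNA-curtains
single-molecule imaging, and 3D cell imaging of RNA/protein puncta —
together with synthetic-data generators that emulate each modality with a
recorded ground truth. All statements below about estimator behaviour are
the ones the package's test suite and `scripts/acceptance.R` actually
compute.

# Mass photometry

Landing-event contrasts are converted to masses through a linear
calibration fitted to the median contrasts of standard proteins (defaults
BSA 66.4, ovalbumin 43, aldolase 158 kDa; these are configuration values,
`massStandards()`, because standard preparations vary). Masses are
histogrammed with the fixed deconvolution binning of the field: 100
uniform bins of exactly 8 kDa, lower edge configurable (default 0 kDa,
masses being nonnegative with a device floor near 40 kDa); out-of-range
events are counted and excluded. A quadratic Savitzky–Golay filter with a
nine-bin span (`smoothMassHistogram`) is provided for visualising
low-abundance higher-order species; peak fitting always operates on raw
counts, since smoothing correlates neighbouring bins and would bias the
least-squares areas.

`fitOligomerPeaks` fits a sum of four Gaussians on the species grid
monomer / trimer / hexamer / higher-order (">6"), initialized at 1×, 3×,
6× the monomer mass (default 40 kDa) with peak means constrained to ±25%
of their initialization and one unconstrained high-mass component. The
±25% window is what absorbs RNA-induced mass shifts of trimer and hexamer
peaks without modelling nucleic-acid mass explicitly. Bounded L-BFGS-B
least squares is used; species whose fitted area falls below 2% of the
total are reported absent (their peak position is then meaningless and
returned as `NA`). Relative abundances are fitted areas divided by the
summed area and sum to one by construction. On 20,000-event synthetic
trimer/hexamer mixtures with 12 kDa mass noise the recovered fractions
agree with nearest-mean hard assignment within ±0.05 and the trimer peak
mass over three is within ±3 kDa of the monomer mass.

## Cooperative hexamer dissociation

The trimer fraction along an RNA titration is modelled with the
four-parameter Hill form

$$p_3(c) = f_{\min} + (f_{\max} - f_{\min})\,
   \frac{c^h}{K_{1/2}^h + c^h},$$

with free baseline and plateau because the assay never reaches exactly 0
or 1. Cooperativity $h > 1$ captures the mechanism in which RNA binding
to one trimer of a hexamer promotes dissociation and frees the second
trimer's binding site. The generator's defaults for this titration are
$h = 2.1$ (the fitted cooperativity of the RNA-dissociation experiment),
$K_{1/2} = 50$ nM, $f_{\min} = 0.1$, $f_{\max} = 0.9$ on a 0–200 nM,
8-point grid with Gaussian noise of sd 0.05 on the fraction; $K_{1/2}$
and the plateau values are not published quantities, so they were fixed
once at values consistent with the titration range and the low trimer
fraction of the RNA-free sample. Noise-free titrations return all four
parameters to at least six significant digits; across 200 noisy
replicates the median fitted $h$ stays within ±0.15 of truth.

## Footprint occupancy model

Each ORF1p trimer occupies a 30-nt RNA footprint, and successive trimers
require a 45-nt periodicity (a 15-nt linker between footprints). The
maximal trimer count on an RNA of length $L$ nt is

$$N(L) = \Big\lfloor \frac{L - 30}{45} \Big\rfloor + 1 \quad (L \ge 30),
\qquad N(L) = 0 \ \text{otherwise},$$

so $N$ increases by exactly one at $L = 30 + 45k$: one trimer from 30 nt,
two from 90 nt, three from 120 nt, and 44 on a 1970-nt (2-kb) RNA.
`saturationExcess` multiplies by three monomers per trimer: 132 monomers
per 2-kb RNA exactly, 130 at two significant figures — the molar excess
at which every direct binding site is occupied and beyond which
additional protein must join the condensate through protein–protein
contacts (super-saturation). Both the exact and the rounded value are
reported because the published figure is the rounded one.

# Equilibrium binding and competition

Anisotropy titrations are normalized exactly as the assay software does:
subtract the protein-free blank, then min–max scale so the smallest value
is 0 and the largest 1. This pins two noisy points, so on a finite
titration range the normalized curve is an affine distortion of the true
bound fraction. `fitHillBinding` therefore fits

$$y(P) = s_0 + (s_1 - s_0)\,\frac{P^h}{K_d^h + P^h},$$

with narrow bounds on the affine terms ($s_0 \in [-0.2, 0.2]$,
$s_1 \in [0.8, 1.5]$) that cover the distortion any plausible titration
range produces while keeping $K_d$ identifiable under noise. With the
bare two-parameter isotherm the pinning biases $K_d$ by several percent
even without noise; with the affine terms the noise-free fit is exact.
The sum-of-squares surface has corner local minima in which $h$ runs to
its bounds, so the fit is multi-started over $K_d$ and $h$ and the
lowest-SSE solution kept. Hill $h$ is fitted freely throughout. Protein
is treated as total concentration (1 nM labelled oligo makes depletion
negligible above ~10 nM protein); `depletionIsotherm` provides the exact
quadratic single-site solution where that assumption is not wanted.

Noise conventions: simulated recovery experiments add Gaussian noise of
sd 0.05 *on the normalized (unit-span) signal* — the same convention as
noise on a fraction. The generator's realistic raw-anisotropy defaults
(r_free 0.05, r_bound 0.20) are kept for ordinary use; applying sd 0.05
to that 0.15-wide raw span would mean 33% relative noise, under which no
estimator resolves $K_d$ to 10% from 12 points.

## Shared-site competition

`solveCompetition` solves the coupled equilibria $P + L \rightleftharpoons
PL$ and $P + C \rightleftharpoons PC$ (one shared site per binding unit)
exactly, by bracketed root finding on free protein (relative tolerance
1e-12), conserving all three totals to 1e-10. Two regimes matter for a
*protein titration* against a trace labelled species:

* **Negligible-depletion limit** (weak competitor in excess,
  $K_{d,C} \gg K_{d,L}$, free protein $\ll K_{d,C}$ across the fitted
  range): the competitor consumes free protein proportionally, the total
  axis is rescaled, and the apparent $K_d$ is the classical
  $K_{d,L}(1 + C_T/K_{d,C})$. The package reproduces this within 2%.
* **Strong competitor** ($K_{d,C} \ll C_T$, the experimental regime of a
  tight RNA competitor): the competitor is stoichiometrically saturated
  by the titrated protein and the exact half-saturation shift is
  *additive*, $K_{d,L} + C_T K_{d,L}/(K_{d,C}+K_{d,L}) + L_T/2$. The
  multiplicative formula does not apply in this direction of titration —
  a point worth emphasising because it is easy to transplant the
  Cheng–Prusoff result into the wrong geometry. Consequently the ideal
  shared-site model does not predict the experimentally observed
  ~33-fold affinity drop of dsDNA binding after RNA saturation, and the
  package documents that fold change as an empirical quantity rather
  than a model output.

# DNA-curtains analysis

Binding-event tables carry positions in kbp from the barrier, times in
seconds, a censoring flag, colour channel and amplitude; columns are
unit-named to prevent unit drift. Events per DNA divide condensate counts
(a dual-colour pair counts once) by the DNA strands per experiment, then
average across experiments with a SEM; per-nM normalization divides by
the RNA concentration, and weighted averages weight experiments by their
DNA-strand counts — the weighting is not specified by the assay
description, and observation count is the natural precision proxy.
Two-colour colocalization greedily pairs nearest cross-channel events on
the same DNA within 1 kbp and one frame (0.5 s) by default; both
thresholds are configurable since the assay description does not state
them.

Positions are histogrammed into the standard 24 × 2-kbp bins (half-open,
bin 0 at the barrier). Sequence context comes from `genomeTrack`: exact
motif occurrences (default the L1 endonuclease target TTTTTAA, scanned on
both strands by default because curtains cannot distinguish strands) and
a sliding-window A/T-content track. `positionEnrichmentTest` turns the
qualitative "binding aligns with A/T-rich regions" statement into a
permutation test: observed mean window-A/T at binding positions against
uniformly resampled positions. Note that i.i.d. uniform-GC synthetic
sequences carry almost no window-scale A/T variance, so power against
A/T-biased binding requires substrates with domain-scale composition
structure (`simGenome` accepts block-wise GC for this reason; real
genomes have such structure).

Dwell times are right-censored at movie end. `kaplanMeier` wraps the
product-limit estimator with a percentile bootstrap (default 1000
resamples, seeded); the band is clipped to cover the point estimate so
that the reported envelope always contains the curve. With no censoring
the estimator equals the empirical survival function exactly, which the
suite asserts as an oracle identity. For exponential dwells of mean 750 s
censored at 600 s, $\hat S(300\,\mathrm{s})$ concentrates near
$e^{-0.4} \approx 0.67$ — comfortably above the 60% five-minute
persistence the assay reports. The dwell generator starts events at
$t = 0$ by default (so lifetimes are censored at the movie length,
matching that arithmetic); a uniform-start mode exists for kymogram-like
visualisations. Kymograms paint per-event amplitudes into position ×
frame matrices, with uncovered frames flagged.

# 3D spot colocalization

RNA puncta are detected with multiscale Laplacian-of-Gaussian filtering
in full 3D (separable Gaussian convolution and 26-connected local maxima
implemented in compiled code; scales default to 0.75×, 1×, 1.5× the
nominal PSF sigma). The detection threshold is expressed in units of the
median-absolute-deviation noise of the LoG response (default 6), making
it transferable across intensity scales; the MAD is estimated on a
~260k-voxel stride subsample, which is accurate to well under a percent
on these smooth responses. Duplicate detections across scales or within a
blob radius are merged greedily (strongest response first, minimum
separation $2\sigma$): two rendered spots 2 voxels apart at
$\sigma = 2$ merge into one detection by design. Sub-voxel localization
is not attempted; the downstream statistics use a 2-voxel-radius
spherical aperture and do not benefit from it.

Spots take the ROI label under their (y, x) position; background spots
are dropped. Nuclear/cytoplasmic classification thresholds per-spot mean
nuclear-channel intensity with Otsu's method computed over the spots of
the image (the criterion is stated by the protocol, the threshold is
not); it presupposes a mixed population — applied to an all-cytoplasmic
set it will still split the noise, so the pipeline only classifies when
asked to. The randomized null draws, per ROI, exactly the detected count
of pixel positions uniformly from that ROI, with z sampled from the
image-wide multiset of detected z values (the protocol words the z
distribution at image level). Intensities are measured in the target
channel over the aperture and divided by the median of the random spots
of the same ROI; detected and random distributions are compared with a
two-sided Mann–Whitney test on the pooled normalized intensities.

The acceptance-scale calibration runs the full
detect→randomize→normalize→test chain 200 times on null images
(64×256×256 voxels, 10 cells, 15 puncta per cell, colocalized fraction
0) and requires the rejection rate at $\alpha = 0.05$ to sit in
5% ± 3%; on 80%-colocalized images a single run rejects with
$p < 10^{-4}$. These sizes keep the whole calibration under ten minutes
on one CPU and were chosen as the package's standard benchmark problem.

# What the generators do and do not emulate

The generators reproduce the *statistical structure* the estimators rely
on: mixture-of-Gaussians mass spectra with a linear contrast calibration;
Hill/competition-shaped titrations with Gaussian noise; Poisson event
counts with sequence-biased positions, exponential censored dwells and
Bernoulli dual-labelling; Gaussian-PSF puncta on Gaussian background with
disjoint elliptical cells and ellipsoidal nuclei. They deliberately omit
photophysics (bleaching, drift), cotranslational-assembly kinetics,
non-Gaussian camera noise, segmentation errors and cell-shape
irregularity. Green tests therefore certify estimator correctness under
known ground truth, not robustness to every artefact of real data; the
absolute event counts, two-colour fractions, fusion fractions and
per-cell statistics of real experiments require the raw recordings and
are covered only by these generator-truth recovery properties.

# Numerical choices and degenerate inputs

Sub-seeds are derived per DNA molecule / cell / channel from one master
seed, so enlarging a dataset never perturbs earlier units, and every
stage is byte-reproducible under a fixed seed. Root finding uses
`uniroot` on a guaranteed bracket $[0, P_T]$; nonlinear fits use
Levenberg–Marquardt with bounds and multi-starts, erroring (never
silently degrading) on non-convergence. Degenerate inputs error early
with named messages: empty event sets, flat titrations after blank
subtraction, all-censored dwell sets, overlapping cell ROIs, histograms
narrower than the smoothing span. Histogram bins and position bins are
half-open `[lo, hi)`; sequence coordinates are 1-based inclusive in
reports.

# Known limitations

The competition model is single-shared-site; multivalent trimer binding
is out of scope, which is one reason measured competition fold-changes
can exceed the ideal additive prediction. The Otsu-based compartment
classifier needs both populations present. The LoG detector reports
integer-voxel positions. The bootstrap band is percentile-based and
clipped to the estimate; it is not a simultaneous band. The motif-count
check against the real λ genome requires the NC_001416 FASTA, which is
not redistributed with the package; place it at
`inst/extdata/lambda_NC001416.fa` to run that check on the true
sequence.
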