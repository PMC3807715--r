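---
title: "neuroband: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroband: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroband)
```

## The problem

In elderly and cognitively impaired subjects the canonical fixed EEG bands
(e.g. alpha = 8-12 Hz) misrepresent individual oscillatory structure,
because both ageing and disease shift the alpha peak.  `neuroband`
implements an *individually anchored* band analysis of resting,
eyes-closed EEG: each subject's bands are laid out relative to two anchor
frequencies estimated from their own channel-collapsed power spectrum.
The biomarker of interest is the ratio of relative power in the upper
alpha band (alpha3) to the upper-low alpha band (alpha2), a quantity that
has been associated with risk of progression from mild cognitive
impairment to Alzheimer-type dementia.  Around this core the package
provides the companion analyses such a study needs: stratification of a
cohort by the ratio, white-matter hyperintensity (WMH) load estimation
from FLAIR-like volumes (used as a covariate), vertex-wise
cortical-thickness group comparisons, and thickness-memory correlation
maps — plus synthetic generators so the whole pipeline is testable
without any acquisition.

## Spectral estimation

Recordings (19 channels in the 10-20 layout, 250 Hz, about 5 minutes,
eyes closed) are cut into consecutive non-overlapping 2-s epochs; epochs
rejected by human artifact review enter as an *epoch mask*.  Power
spectral density is estimated per channel by the Welch method with one
Hanning-windowed segment per epoch (no overlap, no segment shift),
averaged over epochs, then averaged over channels.  The 2-s epoch gives
the analysis its 0.5 Hz resolution; the grid is the bin centers 2.0,
2.5, ..., 45.0 Hz (87 bins).  Channel collapsing is an arithmetic mean of
the per-channel densities; it suppresses channel-to-channel variability
and yields a smoother, single-peaked alpha region, which is exactly why
the anchor detection operates on the collapsed spectrum.

A stationarity control averages the spectra of the first ten and last ten
epochs and compares the per-epoch total 2-45 Hz power between the two
ends by one-way ANOVA.  The dependent variable for this ANOVA is not
fixed by the original description, which is ambiguous between a
per-subject and a pooled test; `stationarity_check()` implements the
per-subject form and `stationarity_check_pooled()` the pooled form, and
the report records the choice.  Two literally identical epoch sets are a
degenerate case; the p-value is then reported as 1 with a flag.

## Anchor frequencies and band construction

* **IAF** — the individual alpha frequency: the highest *interior local
  maximum* of the collapsed spectrum within the extended alpha range
  5-14 Hz.  A spectrum with no interior local maximum (pure 1/f decay)
  falls back to the range maximum and is flagged; ties break toward the
  lower frequency.  The local-maximum rule matters: on a decaying
  background the global range maximum is the left edge, not a peak.
* **TF** — the theta/alpha transition: the power minimum in the window
  `[max(4, IAF - 6), IAF - 1]`.  The source description ("minimum in the
  alpha frequency range") is under-specified; this window guarantees
  TF < IAF, keeps it above the delta range, and is consistent with the
  whole-sample mean TF = IAF - 4.  An IAF at or below 5 Hz leaves no
  usable window and raises an error.
* **IBF1, IBF2, IGF** — beta and gamma peaks: the three
  highest-prominence local maxima between the alpha3 upper edge and
  45 Hz (prominence at least 5% of the spectrum maximum).  The
  beta1/beta2 and beta2/gamma boundaries are the power minima between
  consecutive peaks.  When three peaks cannot be found the boundaries
  fall back to 19.0 and 32.5 Hz — the grid values nearest the
  whole-sample means (19.2, 32.4) — and the result is flagged.
* **ITF** — the theta peak inside `[TF - 2, TF)`; reported, not used
  downstream.

Bands are half-open intervals on bin centers: delta `[TF-4, TF-2)`,
theta `[TF-2, TF)`, alpha1 `[TF, mid)`, alpha2 `[mid, IAF)` with `mid`
the TF-IAF midpoint, alpha3 `[IAF, IAF+2)`, beta1/beta2 up to the
detected boundaries, gamma closed at 45 Hz.  With the whole-sample mean
anchors TF = 6.9 and IAF = 10.9 this reproduces the printed edges:

```{r}
build_bands(6.9, 10.9)
```

Relative power per bin is density divided by the mean density over all
87 bins; a band's relative power is the mean over its bins; the biomarker
is alpha3/alpha2.  Bins below `TF - 4` belong to no band but still enter
the normalisation denominator.  Two consequences are property-tested: the
mean per-bin relative power is identically 1, and the profile is
invariant under any positive rescaling of the spectrum.

## Stratification and demographics

Fixed cutoffs assign low (`r < 1`), middle (`1 <= r < 1.17`) and high
(`r >= 1.17`).  The published description leaves the boundary points and
the interval [1.16, 1.17) unassigned; boundaries here belong to the upper
group, which reproduces the printed group ranges ([0.77-0.98], [1-1.16],
[1.17-1.52]).  Because the published "tertiles" are 18/38/18 rather than
equal thirds, an empirical-tertile mode is provided as well; neither is
asserted to be "the" tertile rule.  Group comparisons use one-way ANOVA
(continuous), chi-squared (dichotomous), and Levene's mean-centered test
to choose Games-Howell (heteroscedastic) versus Bonferroni post hocs, the
SPSS-style decision path.

## WMH segmentation

The in-brain FLAIR intensity histogram is modelled as a single Gaussian;
voxels above `mu + 3.5 sigma` are classified as WMH, and lesion load is
voxel count times the voxel volume (1.44 mm^3 by default).  The robust
fit option anchors location/scale on median/MAD before excluding the
upper tail and re-fitting moments — a plain mean/SD-anchored re-fit is
not robust, because with a noticeable lesion load the first threshold
sits *above* the lesion intensities (and iterating it stalls on the
bimodal mixture).  T1 intensity correction replaces each 26-connected
lesion component by the mean of the non-lesion in-brain voxels in a
2-voxel Chebyshev shell around it; components with an empty shell are
left unchanged and flagged.  An optional large-kernel (sigma 25 mm)
low-pass bias division stands in for radio-frequency inhomogeneity
filtering; the original filter is unspecified, so this is off by default.
Skull-stripping and template warping are out of scope; the brain mask and
any cross-modality alignment are inputs.

## Cortical-thickness statistics

For a two-group contrast, each vertex gets an ordinary-least-squares fit
of thickness on a group indicator plus five covariates (age, sex 0/1,
education, MMSE, WMH load) and a two-sided t-test on the group
coefficient; one QR decomposition serves all vertices.  Supra-threshold
vertices (p < 0.001 uncorrected by default) with a consistent effect sign
are grouped into connected components under the surface adjacency;
components below the minimum extent (30 mm^2 for group contrasts,
15 mm^2 for correlation maps) are discarded; the total atrophy extent is
the sum of surviving cluster areas.  Thickness-memory association uses
within-group Pearson correlation per vertex with a t-based p-value and
the same clustering at 15 mm^2.  Zero-residual vertices (possible in
noise-free synthetic data) are decided from the coefficient directly
rather than the unstable t ratio.  Surface smoothing to a requested FWHM
is approximated by iterated self-plus-neighbor averaging with a
random-walk variance calibration; it is provided but off by default, and
exact FreeSurfer-style geodesic smoothing is out of scope.

## The synthetic world

The generators' defaults *are* the study's stated conditions; none of
them is tuned per test.

**EEG.**  Each channel is an independent realisation (frequency-domain
synthesis with random phases) of a shared subject-level spectral model:
a `bg/f` background (default scale 15 uV^2/Hz at 1 Hz), a flat noise
floor, a theta bump at TF - 1.5, a skewed alpha bump at the IAF (wide
low flank, sd 1.7 Hz; narrow high flank, sd 0.7 Hz), an upper-alpha bump
peaking exactly at the IAF with a steep low flank (sd 0.4 / 0.8 Hz), and
three beta/gamma bumps at 16/25/38 Hz.  Channels sharing parameters with
independent noise is what makes the channel collapse useful, mirroring
the rationale for collapsing in the first place.  Default geometry is
19 channels, 250 Hz, 300 s, matching the recording protocol; anchors are
snapped to the 0.5 Hz analysis grid, on which the anchor types live.

Ground-truth anchors are defined as what an ideal estimator would see:
the detector rules applied to the noiseless model spectrum convolved with
the Hanning leakage kernel (1/6, 2/3, 1/6 across neighbouring bins).
The default shape parameters were fixed once, at design time, such that
this model trough falls on the nominal TF across the IAF range 9-12.5 Hz;
they were not revisited afterwards.

**Ratio calibration.**  The upper-alpha amplitude is the only dial that
moves alpha3/alpha2, and the analytic amplitude-to-ratio map is strictly
monotone (a tested invariant), so it is inverted by interpolation for a
target ratio.  Because the realised Welch estimate is biased slightly
below the analytic expectation and carries per-seed noise, cohort
generation refines the amplitude by a few secant steps against the
subject's own seeded realisation — a deterministic monotone function of
amplitude once the seed is fixed — so that realised ratios land in the
target group ranges, which is the generator's stated contract.  Two
guard rails exist and are documented rather than hidden: (1) the lowest
ratios (below about 0.83) are unreachable at the highest IAFs, so targets
are truncated into the subject's feasible range, distorting the low-group
mean by well under 1%; (2) near zero amplitude a seed-specific half-bin
flip of the detected IAF occasionally defeats calibration, in which case
the subject's recording seed is re-drawn (bounded rejection, at most 5
attempts).

**Cohort.**  74 subjects in groups of 18/38/18 with target ratios from
truncated normals matching the published group statistics (0.90 +/- 0.10
on [0.77, 0.98]; 1.08 +/- 0.045 on [1.00, 1.16]; 1.29 +/- 0.10 on
[1.17, 1.52]; the middle SD is printed as "0.0" and was set to 0.045 so
the truncated distribution plausibly fills its printed range).  IAF is
N(10.9, 1) clipped to [9, 12.5] and TF = IAF - 4, reproducing the
whole-sample mean bands.  Covariates (age 70 +/- 7, education, MMSE
27 +/- 1.5, sex, lognormal WMH load) and memory scores are drawn with
identical distributions in all groups, mirroring the null demographic
comparisons of the source cohort.

**Volumes.**  Gaussian background (mean 100, SD 10) inside an ellipsoidal
brain mask with ellipsoidal lesions at a stated contrast in SD units;
the truth mask is returned for recovery tests.

**Thickness.**  `thickness = baseline + group offsets on planted
clusters + covariate effects + iid Gaussian vertex noise` on a
triangulated grid surface (unit vertex areas in the interior), with
per-cluster group means and noise SD at the scale of the published
per-cluster statistics (offsets ~0.25 mm, SD 0.17 mm).  Memory scores
are regenerated with a specified within-group correlation to the mean
thickness of a named vertex set.  A consequence of iid vertex noise,
stated here deliberately: the per-vertex correlation with a score planted
against a k-vertex region attenuates by about `1/sqrt(k)`, so
correlation-recovery tests target very small regions, and the default
end-to-end run does not reproduce broad correlation clusters.  Real
smoothed cortical data is spatially correlated; a green test here
establishes estimator correctness, not performance under spatial
correlation.  Likewise, the planted middle group equals the low group
exactly so that the middle-vs-low contrast is a true null, which means
the synthetic high-vs-middle and high-vs-low extents are comparable
rather than graded as in the source cohort.

## Numerical choices and degenerate inputs

* Grid membership uses a 1e-9 tolerance; frequencies are compared on bin
  centers only.
* All detector ties break toward the lower frequency and are flagged.
* The Welch density normalisation follows the standard
  `2 / (fs * sum(w^2))` one-sided convention; a flat unit-density noise
  input reproduces density 1 within a few percent (tested against an
  independently written periodogram oracle).
* Segmentation is monotone in the threshold multiplier `k` by
  construction; `k -> Inf` empties the mask.
* NIfTI-1 and EDF support is implemented in-package (no reader exists in
  the dependency stack): single-file NIfTI with common numeric datatypes
  and slope/intercept scaling (cross-validated against nibabel), and
  continuous one-rate EDF with int16 digitisation whose physical range is
  rounded outward to the ASCII precision actually stored, so write/read
  round-trips are exact to quantisation.
* Configuration files (YAML or JSON) may set only known keys; all
  defaults equal the published analysis parameters.

## Known limitations

* FreeSurfer-style surface reconstruction, registration and anatomical
  labelling are out of scope; surfaces, thickness matrices and region
  labels are inputs.
* The EEG generator produces stationary Gaussian spectra; it does not
  emulate artifacts, drowsiness drift, or inter-channel coherence
  structure, so the epoch-mask pathway is exercised only synthetically.
* The published total high-vs-middle atrophy extent (160 mm^2) differs
  from the sum of its printed cluster sizes (59 + 71 + 33 = 163 mm^2);
  the package reproduces the column sum and records the discrepancy
  rather than guessing the intent.
* The WMH group summaries printed with the cohort table (a few mm^3) are
  implausibly small for total lesion load; their unit is not resolvable
  from the source and they are not used as targets.
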