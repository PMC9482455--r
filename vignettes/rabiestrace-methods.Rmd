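---
title: "Methods: quantifying monosynaptic rabies tracing with rabiestrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying monosynaptic rabies tracing with rabiestrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabiestrace)
```

## The measurement problem

Monosynaptic rabies tracing labels the direct presynaptic partners of a
defined *starter* population: helper AAV supplies TVA and optimized rabies
glycoprotein to CA1 excitatory neurons (EGFP), and an EnvA-pseudotyped,
glycoprotein-deleted rabies virus (DsRed) then spreads exactly one synapse
retrogradely. Cells expressing both fluorophores are starters; DsRed-only
cells are presynaptic inputs. Connectivity is summarized per animal by

* the **connectivity strength index** for region $r$,
  $\mathrm{CSI}_r = N_r / S$, the number of input neurons in $r$ over the
  starter count $S$;
* the **proportion of input**, $\mathrm{PI}_r = N_r / N_\mathrm{tot}$, the
  fraction of all labeled inputs falling in $r$; and
* the **overall connectivity** $O = N_\mathrm{tot}/S = \sum_r \mathrm{CSI}_r$.

These satisfy $\mathrm{CSI}_r = \mathrm{PI}_r \cdot O$ and
$\sum_r \mathrm{PI}_r = 1$ identically; the package treats those identities
as invariants and tests them to $10^{-9}$ on every simulated animal. The
catch-all region `OTHER` pools every labeled input outside the named
regions, so PI normalizes over all inputs and $O$ includes the whole brain.

The study design the package emulates is four groups — wild-type (WT) and
APP knock-in (APP-KI, the APP^NL-G-F^ amyloid model) mice at young (3–4
months) and old (10–11 months) ages, n = 7/10/10/8 with recorded sex
composition — plus an amyloid-plaque imaging arm with two sections from
each of five brains per group.

## The synthetic cohort generator

Raw counts and images for the underlying experiment are not public, so the
package ships a generative stand-in whose defaults are calibrated to the
published group summaries. Per animal:

1. $S \sim$ round(lognormal), mean 150, `sdlog` 0.25, redrawing the
   never-observed $S = 0$. Starter counts were not published; only ratios
   matter downstream, so the scale is a design choice.
2. $N_r \mid S \sim \mathrm{NB}(\mu_r S, \theta_r)$, a negative binomial
   with mean $\mu_r S$ and dispersion $\theta_r$, giving
   $E[\mathrm{CSI}_r] = \mu_r$ exactly and biological overdispersion
   across animals.
3. Each input cell receives an anterior–posterior (AP) position from a
   truncated Gaussian occupancy profile per region, snapped to the mounted
   section grid (30 µm sections, one of three mounted, so 0.09 mm
   spacing), a position inside the region's atlas footprint, and channel
   amplitudes per its class. A configurable fraction of helper-only
   (GFP-only) cells is added for QC realism.

**Choosing the region means.** The published tables give group-mean CSI
for some regions, group-mean PI for others, and the overall index for all
four groups. Within a group those three sets are not exactly mutually
consistent (a group mean of per-animal ratios does not factor through the
group means of numerator and denominator), so a single mean table cannot
match all printed numbers simultaneously. The precedence rule, applied
once: printed CSI wins; where only PI is printed the mean is
$\mu_r = \mathrm{PI}_r \times O$; regions with no printed value carry
fixed anatomically plausible fill-ins; and `OTHER` absorbs the remainder
so that $\sum_r \mu_r$ equals the printed overall connectivity exactly.
`study_group_params()` records the provenance of every entry in its
`source` column.

**Dispersion calibration.** Since per-animal CSI has coefficient of
variation $\approx \sqrt{1/\theta_r + 1/(\mu_r S)}$, each $\theta_r$ is
solved from the published SE (converted to a per-animal CV) at a nominal
$S = 150$, capped at $10^4$ (near-Poisson) and defaulting to 8 — a CV of
about 0.36, the typical published magnitude — where no SE is printed.
With these dispersions the mean-of-ratios bias of group-mean PI relative
to $\mu_r / \sum \mu$ is far below the Monte-Carlo resolution of the
acceptance runs, so PI round-trips directly against its configured value.

**Sex effect.** The only published sex difference is a subiculum deficit
in old APP-KI females. It is planted as a female multiplier on the SUB
mean (default 0.55) with the male multiplier solved so the group mean is
preserved; group-level summaries are therefore unaffected while the
within-group male–female contrast carries a real effect.

**AP occupancy.** Profile means are ordered along the AP axis as in the
tracing data: MS-DB most anterior, then the hippocampal formation, SUB,
EC most posterior; the CA3 mean sits at −1.60 mm, anterior to the CA1
injection site at −1.94 mm, reproducing the anterior CA3 input peak. The
spreads are design choices (0.2–0.5 mm; 1.5 mm for `OTHER`).

## The schematic atlas

Assignment of cells to regions uses a packaged table of rectangular
footprints — one y-band per region code in the left hemisphere, mirrored
across the midline, each valid over an AP slab — rather than a volumetric
reference atlas. This keeps assignment deterministic, total (every cell
maps to exactly one region–side pair, with `OTHER` as fallback and a
warning for APs outside every slab) and exactly invertible against the
generator's planted labels, which is what the pipeline's round-trip tests
need. Polygon boundaries count as inside; cells inside the ±150 µm
midline band that do not match a midline structure resolve to the
injection side by convention. Slab bounds are multiples of the 0.09 mm
section spacing so snapped APs never leave their slab. MS-DB, MnR/PMnR
and ReN are midline structures; SUB and EC are carried as sided codes
with only the ipsilateral entry populated by default, since the published
tables report them unsided.

## Synthetic micrographs and quantification

Tracing sections are rendered as three-channel (DAPI/GFP/DsRed) 16-bit
images: each cell is a Gaussian spot (σ = 10 µm, truncated at 3σ) in the
channels its class dictates, over constant background plus optional
Gaussian noise. Plaque sections plant Poisson(density × area) disks with
lognormal diameters (mean 12 µm, CV 0.25 — no published age difference in
size) and uniform per-plaque intensity; centers are sampled inside the
field of view inset by each plaque's radius, with a minimum edge-to-edge
gap so plaques remain spatially distinct and counts are recoverable
exactly. The plaque-count distribution stays exactly Poisson by
construction. The default 250 × 200 µm field at 0.65 µm/px mirrors a 10×
slide-scanner scale; the density unit is plaques per mm² (the published
unit is unstated; the configuration records the normalization).

Detection thresholds each channel at background median + k·MAD (k = 6) —
a transparent, parameter-light stand-in for manual counting, invariant to
positive rescaling of the channel. On noise-free images the MAD is zero
and the threshold falls back to median + 1% of the dynamic range, which
separates truncated spots from constant background cleanly; a blank image
yields zero detections with a warning. Connected components below the
minimum area are dropped; two spots closer than the PSF merge into one
component (documented limitation — the generator's `min_spacing` placement
option guarantees the non-overlapping regime for equivalence tests).
Classification declares a DsRed detection a starter when its mask
overlaps a GFP mask by ≥ 0.5 of the smaller mask (robust to 1-px
registration jitter); GFP-only detections are helper-only cells, counted
in QC and excluded from both $S$ and $N_r$. Starters outside ipsilateral
CA1 are flagged and excluded from $S$; losing every starter is an error
because CSI is then undefined.

In the noise-free, non-overlapping regime the image pipeline (render →
detect → classify → assign) reproduces the planted $S$ and every $N_r$
exactly, so the count-level and image-level modes of `run_pipeline()`
agree bit for bit — the package's stage-equivalence guarantee.

## AP distribution curves

Per-animal curves bin a region's input cells on a grid anchored at bregma
with 0.09 mm bins (the effective section spacing; "registered to similar
AP numbers" is otherwise underdetermined), divided by $S$, so each curve
sums exactly to the region's CSI. Group curves average animal curves
bin-wise (mean ± SE). The area under a curve is trapezoidal; an isolated
single-bin spike contributes height × bin width. Group curves are
compared with the exact signed-rank test on AP-bin-matched group means,
dropping bins where both groups are zero — the package's reading of a
"paired rank-sum" comparison of registered curves, pairing by AP bin.

## Statistics

All tests are implemented from scratch and cross-checked against
independent references in the test suite.

* **Wilcoxon rank-sum**, two-sided, tie-aware: midranks; for
  $n + m \le 14$ the exact null distribution of the rank sum is built by
  a subset-sum recursion over all $\binom{n+m}{n}$ assignments of the
  observed (tied) values; above that, normal approximation with tie and
  continuity corrections. Two-sided p doubles the smaller tail, capped at
  1 — determinate under asymmetric tie distributions. All-equal data give
  p = 1.
* **Wilcoxon signed-rank** for paired values: zero differences dropped,
  midranks of |d|; exact via the $2^n$ sign-pattern generating function
  for $n \le 15$, else the corrected normal approximation.
* **Random-intercept LME** for section-level intensity (two sections per
  brain): $y_{ij} = \beta_0 + \beta_1\,\mathrm{group}_i + b_i +
  \varepsilon_{ij}$, fitted by maximum likelihood with the variance ratio
  $\lambda = \sigma_b^2/\sigma^2$ profiled (1-D optimization on the log
  scale, boundary $\lambda = 0$ always considered, GLS closed form for
  $\beta$ and $\sigma^2$ at each ratio), Wald z test on $\beta_1$. ML
  rather than REML because the fit is also used for likelihood
  comparisons on a grid; the choice is documented rather than published.
  Estimates are scale-equivariant and match `lme4::lmer(..., REML =
  FALSE)` to numerical precision.

The comparison driver runs the study's contrast structure — WT vs APP-KI
within age, young vs old within genotype, per region × {CSI, PI} plus the
overall index, and male vs female within group — with **no multiplicity
adjustment**, mirroring the original analysis; the output records the
number of tests and flags the absence of correction. Significance stars
follow the 0.05/0.01/0.001/0.0001 convention and group summaries are
mean ± SE. A cross-check mode (`cross_check_contrasts()`) re-runs untied
contrasts through `stats::wilcox.test()` and reports the largest p-value
discrepancy.

## Numerical choices and degenerate inputs

* Polygon containment is even-odd with inclusive boundaries (closed
  polygons), so assignment is deterministic on synthetic data.
* Snapped APs are normalized (`+ 0`) to avoid IEEE −0 section keys.
* `rank()` midranks make doubled ranks integers, so exact distributions
  use integer convolutions with no floating-point tail error.
* Degenerate statistics (all values equal, all differences zero, blank
  images, empty regions, zero plaque density) return defined results with
  flags rather than errors; undefined ratios ($S = 0$, $N_\mathrm{tot} =
  0$) raise errors because upstream exclusion is the only valid handling.
* The LME profile search spans $\lambda \in [10^{-8}, 10^4]$ on the log
  scale; a boundary estimate $\sigma_b^2 = 0$ is allowed.

## Problem sizes in the test and acceptance runs

Generator fidelity is assessed over 500 simulated cohorts per group
(count level), 200 plaque replicates of 2 sections × 5 brains, 200
random instances per exact-test oracle, 500 LME replicates, and 1000
null simulations for size calibration; image-mode equivalence runs on
reduced cohorts (region means scaled ×0.03, S ≈ 12, 80 µm minimum
spacing) where the non-overlap guarantee holds. These sizes give
Monte-Carlo standard errors comfortably below the differences of
scientific interest while keeping the default suite fast.

## What passing tests do and do not show

The generator reproduces count-level group structure (means, spread of
the published order, AP occupancy, sex composition) and idealized
micrographs. It does not model tissue texture, autofluorescence, uneven
illumination, overlapping somata, 3-D structure, viral-spread kinetics or
amyloid toxicity; detection on real slide-scanner images would need a
more robust segmenter than the median+MAD rule. Passing round trips
therefore validate the quantification pipeline's correctness —
bookkeeping, indices, statistics — not the biological fidelity of any
particular micrograph model. Per-animal values of the original study are
not reproducible (raw data unavailable); only group-level parameters are
matched. The old-group age label follows the 10–11 month usage; one
published passage says 8–11 months, and the configuration stores the
label only. EC is kept as a single code (no medial/lateral split), as the
published tables do not subdivide it.
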