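---
title: "Models and methods behind tbimarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tbimarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbimarkers)
```

`tbimarkers` implements the three quantitative layers used in rodent
repeated mild traumatic brain injury (RmTBI) biomarker studies: protein
quantification from reverse-phase protein microarray (RPPM) dilution
series, diffusion-MRI scalar and track-weighted maps with
region-of-interest summaries, and factorial group statistics. Each layer
ships with a synthetic-data generator carrying explicit ground truth, so
every stage can be validated end to end without animal data.

## 1. RPPM dilution-series quantification

### The measurement model

On an RPPM slide each plasma sample is printed as a 1:1 serial dilution
series (dilution step $k$ carries relative concentration $2^{-k}$; the
initial 1:10 plating dilution is a constant factor absorbed into the
sample's abundance). After local background subtraction, net
fluorescence versus concentration is analysed on a log–log scale:
$x = \log_2(\text{relative concentration})$,
$y = \log_{10}(\text{net fluorescence})$. The response is the
five-parameter logistic (5PL)

$$y(x) = D + \frac{A - D}{\bigl(1 + 2^{B (x - C)}\bigr)^{G}},$$

with lower/upper asymptotes $A$ and $D$ (log10 AU), position $C$ (log2
concentration), Hill slope $B > 0$ and asymmetry constant $G > 0$
($G = 1$ gives the symmetric 4PL). The asymmetric form is used because
the shape family is described by its asymptotic maximum and minimum,
Hill slope, *and* an asymmetry constant. Evaluation is done in log
space (`log1p` of the exponential term) so extreme arguments cannot
overflow.

### Pipeline

1. **Filtering.** Spots indiscernible from background are excluded by
   strict thresholds: SNR $< 2$ or net fluorescence $< 10$ AU. The SNR
   is taken from the input table (scanner-reported) when present.
   Surviving replicate depositions (the arrayer prints 2 per spot) are
   averaged on the linear net scale.
2. **Master curve.** A single 5PL is fitted by bounded least squares to
   all usable points on the slide, pooled on a common $-k$ axis.
   Bounds: $B, G \in (0.1, 10)$, $C$ within the data range $\pm 4$ log2
   units; max 500 iterations, tolerance $10^{-10}$; deterministic
   initialisation from data quantiles. The solver is `nls(port)` with a
   bounded quasi-Newton polish, so a near-singular `nls` step can never
   make the returned parameters worse than the start.
3. **FDR outlier rejection (ROUT-style).** Residual scale is estimated
   as the 68.27th percentile of absolute residuals (exactly one SD for
   Gaussian residuals), each point gets a two-sided t-statistic, and the
   Benjamini–Hochberg step-up at $Q = 0.01$ flags outliers. Flagging and
   refitting alternate until the outlier set is stable, at most 5
   rounds. All-zero residual sets return an empty mask; if the scale
   estimate collapses to zero with nonzero residuals, exactly the
   nonzero residuals are flagged.
4. **Local block fits.** Each printing block is refitted jointly with
   $A, D, B, G$ shared across its samples and one free position $C_i$
   per sample, initialised at the master values. A one-sample block
   degenerates to an ordinary per-sample fit.
5. **y-intercept readout.** The *linear portion* of a sample's curve is
   defined as the observed points whose fitted response lies within the
   central 25–75% band of the asymptote range $|A - D|$ (configurable).
   An ordinary least-squares line through those points, extrapolated
   back to dilution step 0, gives the y-intercept, which indexes the
   amount of protein; group tables report mean ± SEM of y-intercepts.

### The slide generator and its defaults

`slide_sim_config()` states the emulated world: 16 samples × 8 dilution
steps × 2 depositions; multiplicative log-normal noise
($\sigma = 0.02$ in log10 units, i.e. ≈ 4.7% CV, typical of fluorescence
replicates); background 50 AU with raw = net + background so background
correction is exact by construction; per-sample abundances log-normal
with SD 0.1 log10 (≈ 26% between-sample CV). The truth curve has
asymptotes 2 and 4.5 log10 AU and Hill slope
$B = 4\log_{10}2 / ((D-A)\ln 2) \approx 0.695$, chosen so the mid-curve
responds *proportionally* (slope $\log_{10}2$ per concentration
doubling) — the regime a well-designed dilution immunoassay operates in,
and the regime in which doubling a sample's abundance raises its
y-intercept by $\log_{10}2$. Planted artifacts: sub-threshold spots get
SNR drawn uniformly in $[0.5, 1.9]$; intensity outliers have net
multiplied by 10; planted counts are $\lfloor f \cdot n \rfloor$ with
assignment by a seeded shuffle. The number of dilution steps is a free
parameter (8 by default, ≥ 4 required).

What the generator does *not* emulate: spatial print artifacts,
antibody cross-reactivity, between-slide normalisation, or saturation
nonlinearity beyond the 5PL — a green test establishes correctness of
the estimation machinery under the stated noise model, not robustness
to those effects.

### Known limitations (measured, not hypothesised)

* **The 5PL asymmetry triple $(C, B, G)$ is weakly identified on an
  8-step series at realistic noise.** With $\sigma = 0.02$ and even with
  *equal* abundances, the least-squares surface has a flat ridge along
  which $G$ trades off against $C$ and $B$: initialising the optimizer
  at the true parameters still moves it to a distant point with lower
  residual sum of squares. Mean relative errors over 20 simulated
  slides are ≈ 4% ($A$), 1% ($D$), but ≈ 20% ($C$), ≈ 11% ($B$) and
  ≈ 30–50% ($G$). The asymptotes — the parameters that the local fits
  actually share downstream — are recovered well; the shape triple is
  not, and no least-squares estimator can do better on these data.
* **The pooled master curve's effective noise is the abundance
  spread**, because pooling aligns samples by dilution step while each
  sample's curve is shifted by its own $\log_2$ abundance. At the
  default spread the structured residual SD (~0.1 log10) is five times
  the measurement noise. The master fit is therefore treated as what it
  is downstream: an initialisation and outlier-screening device, with
  per-sample positions recovered by the local block fits.
* **The y-intercept readout carries ~0.025 log10 intrinsic noise** at
  the default design, dominated by which integer dilution steps happen
  to fall inside the 25–75% band (window discreteness) plus the
  extrapolation lever arm — verified by re-running the readout with
  oracle (true-parameter) band selection, which does not reduce the
  noise. Rank recovery of abundances is consequently excellent but not
  perfect at small between-sample spreads (Spearman ≈ 0.91 at 0.1 log10
  spread, ≈ 0.97 at 0.2).

## 2. Diffusion-tensor scalars and track-weighted imaging

### Tensor scalars

Per voxel, the symmetric diffusion tensor (6 unique elements, stored in
lower-triangular order dxx, dxy, dyy, dxz, dyz, dzz) is
eigen-decomposed into $\lambda_1 \ge \lambda_2 \ge \lambda_3$, giving
trace $TR = \sum_i \lambda_i$, axial diffusivity $AD = \lambda_1$,
radial diffusivity $RD = (\lambda_2 + \lambda_3)/2$ and fractional
anisotropy

$$FA = \sqrt{\tfrac32}\,
  \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},$$

defined as 0 for an all-zero tensor. Negative eigenvalues are *not*
clamped; the voxel keeps its computed values and is flagged in the
validity mask (visibility over silent correction).

### Track-weighted maps

A streamline is an ordered polyline in world mm. Coordinates follow the
NIfTI convention: 0-based voxel indices, voxel-centred, world mapping
through the affine, voxel $i$ owning the half-open interval
$[i - 0.5,\, i + 0.5)$ in voxel space. Rasterization is *exact*: each
segment's half-integer boundary-plane crossings are enumerated and each
sub-interval midpoint read off, so the result is precisely the set of
voxels the polyline intersects (equivalent to Amanatides–Woo traversal,
and strictly finer than any supersampling scheme; the test suite checks
it against a brute-force segment/box-clipping oracle). Each voxel counts
once per streamline regardless of re-entry.

On that raster set, three maps accumulate per-streamline scalars:
track density TDI($v$) = number of streamlines through $v$; average
pathlength APM($v$) = mean *total* length of those streamlines (not the
in-voxel chord); and mean curvature CURV($v$) = mean of their per-track
mean curvatures — track-level averaging, matching the definition of the
map as the average curvature of tracks passing through the voxel.
Per-track curvature is the Menger curvature (inverse circumradius of
each consecutive point triple) averaged over interior points; it is
exact on circular arcs at any sampling density and converges with
refinement on curves of varying torsion. APM/CURV are masked invalid
where no (curvature-bearing) track passes; two-point streamlines
contribute to TDI/APM but carry no curvature.

ROI means are whole-ROI means: zero voxels count, and invalid APM/CURV
voxels contribute 0 (a nonzero-only variant is available via
`valid_only = TRUE` but is not the default).

The bundle generator produces analytic phantoms — line (curvature 0),
circle ($\kappa = 1/R$) and helix ($\kappa = r/(r^2 + c^2)$) — sampled
at a configurable arc-length step, with optional rigid Gaussian offsets
of each streamline's whole centerline, which displace the bundle without
changing per-streamline length or curvature (so curvature acceptance is
tested at jitter 0 and rigid jitter alike).

## 3. Factorial group statistics

The between-subjects layer is a two-way ANOVA with injury and recovery
day as factors, computed with **Type III sums of squares under
sum-to-zero contrasts** — the convention of the SPSS default the field
reports — so unbalanced cohorts (e.g. 8 sham vs 10 injured) keep
meaningful main-effect tests. Each effect's SS is the residual-SS
increase when that effect's columns are dropped from the full model.
Post-hoc comparisons are protected Bonferroni t-tests on the pooled
ANOVA error term (single error df, as a single reported residual df
implies), with adjusted $p = \min(1, m\,p)$ and family size $m$
defaulting to the number of recovery days compared (5), configurable.
Significance is $p \le 0.05$, inclusive.

Acute injury measures (two injuries per animal) use a 2×2 mixed-design
ANOVA: with exactly two within-subject levels the strata reduce to
per-subject means (between-group effect, tested against
subjects-within-group) and per-subject differences (within effect and
interaction, tested against the subject×within residual); unbalanced
groups are handled with unweighted (Type III) means. An effect with
zero sum of squares reports $F = 0$. Observational units are whatever
the input rows are; the reported residual df makes the choice visible.

The factorial generator draws independent normal observations at
specified cell means and a common residual SD, with per-cell counts
that may be unbalanced; ground truth records cell means and the
standardised injury effect per day.

## 4. Numerical and design choices

* Fitting space is log10 intensity vs log2 concentration ("log–log");
  base choices only rescale $B$ and $C$.
* Strict `<` for exclusion thresholds; boundary spots (SNR = 2,
  net = 10) are kept.
* The FDR t-statistics use $n - 5$ degrees of freedom (the 5PL's
  parameter count).
* Refinement is capped at 5 alternations; an oscillating outlier set
  stops there and is flagged as non-converged rather than hidden.
* Quantifications with fewer than 2 linear-band points are returned as
  unusable (`NA` intercept), never silently extrapolated.
* Generators set their own seed and restore the caller's RNG state;
  the pipeline derives per-stage substream seeds deterministically from
  the master seed (all below $2^{31}$).
* All tabular interfaces are tibbles; fitted objects expose
  `tidy()`/`glance()` and `autoplot()`.

## 5. Reproducibility surface

`run_pipeline()` executes simulate → quantify/map → statistics, writes
every artifact (TSV/CSV, NIfTI-1, TCK, JSON sidecars) into one output
directory and records a JSON manifest with MD5 checksums; identical
config + seed reproduce identical checksums. A thin command-line
wrapper (`inst/scripts/rmtbi-markers`) exposes the same functions as
subcommands for shell use.
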