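---
title: "Quantitative surface traceology of carving techniques"
author: "sculptrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative surface traceology of carving techniques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sculptrace)
```

## The problem

Stone-carving techniques — pecking with a point or cobble, scraping with a
tool edge, polishing with hide, sand or a cobble, and engraving — leave
characteristic micro-topographic signatures on worked limestone. `sculptrace`
implements the quantitative side of discriminating those techniques, and the
expertise of the person wielding the tool, from 3D surface scans: areal
surface-texture parameters (ISO 25178), scale-sensitive fractal analysis
(SSFA), furrow and texture-direction analysis, elliptic Fourier morphometrics
of engraving cross-sections, and the statistical chain that turns parameter
tables into classification results.

Because physical scan sets are rarely shareable, the package carries a
first-class synthetic-surface generator that emulates worked coarse bioclastic
limestone patches. Every downstream stage is exercised and validated against
it; the generator is therefore documented here with the same care as the
analysis code.

## Surface model and pre-treatment

All texture computation operates on a `heightmap`: a regular grid of heights
z(x, y) in mm with a lateral spacing and a validity mask. Scans arrive either
as STL meshes (`read_mesh()`, rasterised onto the least-squares reference
plane by `rasterize_mesh()`) or as CSV grids with a YAML sidecar
(`read_heightmap()`).

Pre-treatment follows standard areal metrology: least-squares plane levelling
(`level_surface()`), polynomial form removal of total degree 3 — the
10-monomial F-operator — (`remove_form()`), and tiling into nine non-
overlapping 10 x 10 mm sub-areas in a centred 3 x 3 layout (`subdivide()`),
with an optional worked-area mask so unworked tiles can be excluded. Total
degree (rather than degree 3 per axis) is the conventional form operator; the
choice is recorded in the output metadata. Levelling and form removal are
applied per sub-area, since parameters are reported per sub-area; both
operators are idempotent and leave residuals orthogonal to the fitted basis.

## The 29 surface parameters

`collect_parameters()` assembles, per sub-area:

* **Height/functional/volume**: Sq (RMS height, mm), Smc (inverse areal
  material ratio at p = 10%, mm), Vvv (dale void volume below the 80%
  material-ratio plane, mm^3/mm^2). The material-ratio arguments are common
  metrology defaults and are configuration keys (`analysis_config()`), logged
  with the output.
* **Spatial**: Sal and Str from the FFT-based normalised areal
  autocorrelation, with the ISO decay threshold s = 0.2 (configurable). Sal is
  the fastest radial decay distance, Str the ratio of fastest to slowest.
  Directions whose ACF never decays inside the half-window are capped there
  and flagged; on a strongly lineated surface this drives Str towards 0.
* **Hybrid**: Sdr, from a two-triangles-per-cell triangulation.
* **Feature parameters**: watershed segmentation of hills and dales
  (`segment_features()`) with prominence ("Wolf") pruning at 5% of Sz.
  Spd/Svd are peak/pit densities; Spc is the arithmetic mean peak curvature
  from local 3 x 3 quadratic fits; hill/dale roundness (Shrn/Sdrn, with
  Shrnq/Sdrnq their standard deviations) is the isoperimetric ratio
  4&pi;A/P^2 of each feature's half-prominence contour, traced with
  sub-cell contour interpolation. The commercial roundness definition is
  proprietary, so this documented formula stands in; roundness values are
  validated against constructed geometry only.
* **SSFA**: relative-area curves by virtual triangulation over a ladder of 16
  logarithmically spaced scales from (2 x spacing)^2 to (extent/3)^2, with
  phase-offset averaging and an isotonic (running-minimum) projection —
  relative area is non-increasing in scale, and the projection removes
  estimator noise at the coarsest scales where few triangles remain.
  Asfc = -1000 x the steepest negative log-log slope; Smfc is the scale where
  it occurs; Das = 2 - 2 x (fine-scale regression slope); Ymax is the largest
  relative area. HAsfc and MedianAsfc summarise Asfc over a 3 x 3 block
  partition (median absolute deviation / median, and median). epLsar is the
  mean-vector length (angles doubled) of the normalised rose of transect
  relative lengths in 5-degree steps at the 40 um scale; NewEplsar is the
  same statistic on log relative lengths. When a grid is coarser than half
  the scale, the scale is raised to twice the spacing and the substitution
  logged.
* **Furrows**: valley-line cells (strict 1-D minima along a grid axis inside
  watershed dales), each with a depth below its local rim — the lower of the
  two height maxima within a 1 mm window on either side along the scan axis.
  Maximum and mean depth are reported in mm and density as cm/cm^2. The
  commercial furrow algorithm is unpublished; this stand-in is validated
  against constructed groove fields (k parallel grooves of known length,
  depth and spacing) and used only for orderings, never for comparison with
  externally reported absolute values.
* **Texture direction**: the angular power spectrum integrates 2-D FFT power
  per 1-degree orientation bin (DC excluded, per-bin mean so the uneven
  angular population of a square grid does not bias the diagonals), reported
  in the groove convention (structure direction = spectral normal), folded to
  [0, 180). Isotropy = 100 x mean/max of the spectrum smoothed over 5
  degrees (flat spectrum = 100%, single line -> 0%); First/Second/Third
  directions are the three highest non-adjacent local maxima. Std delegates
  to the same spectrum and is flagged unstable when no bin reaches three
  times the median power, as on isotropic noise.

Variable classes matter downstream: Str and Isotropy are bounded (logit
transform with boundary clipping at 1e-6 before testing and ordination);
Std and the three direction parameters are circular (axial, period 180
degrees).

## Engraving cross-sections

`detect_landmarks()` finds the apex (global minimum; on flat-bottomed U
profiles the midpoint of the minimal plateau), the shoulder crossings of the
reference surface level, and the left/right depth-convergent wall points at
90% depth. `measure_profile()` derives D (depth), WIS (width at the surface),
the opening angle theta at the apex between apex-to-shoulder vectors, and the
asymmetry score A: the left wall is reflected about the vertical through the
apex and A is the mean horizontal distance to the right wall over 20 evenly
spaced depth fractions (reported in mm; the aggregation is a documented
package choice, and A values are treated as arbitrary-unit scores). Profiles
whose secondary trough reaches half the main depth are flagged as lacking a
single dominant incision.

For shape analysis, `close_outline()` closes the wall polyline with the
straight shoulder-to-shoulder segment and resamples it to 256 points,
counter-clockwise from the left shoulder. `efa()` computes standard elliptic
Fourier coefficients (a, b, c, d per harmonic; power = (a^2+b^2+c^2+d^2)/2).
`normalize_efa()` standardises starting phase, rotation and size on the first
harmonic, leaving d1 plus four coefficients per higher harmonic: (4 x h) - 3
shape variables, 21 at the default h = 6. The starting point can land on
either end of the semi-major axis; both candidates are computed and a
canonical one chosen, so the normalization is exactly invariant to the input
starting point, rotation and scale. An outline parameterised by arc length is
the default; `timing = "vertex"` treats input vertices as equal parameter
steps, the parameterisation in which a parametric ellipse is exactly one
harmonic (the two coincide for resampled outlines). `allometry_check()`
regresses each shape variable on log centroid size (Holm-adjusted, alpha =
0.003) before shape-only analyses.

## Statistical layer

The study-wide significance threshold is alpha = 0.003. Univariate screening
routes on normality: Shapiro-Wilk per group at the same alpha, then one-way
ANOVA if every group is compatible with a Gaussian, otherwise Kruskal-Wallis
(`shapiro_route()`; the routing is recorded in each result). Circular
variables are compared with the Mardia-Watson-Wheeler uniform-scores test
(permutation fallback under heavy ties); Rayleigh, generalized
Watson-Williams (with the 1 + 3/(8 kappa) correction and a low-concentration
warning) and Fisher's common-median test cover the engraving angles. Robust
summaries use the median and the square root of the biweight midvariance
(tuning constant 9).

Variable selection (`select_variables()`) keeps univariately significant
variables, then computes the mixed correlation matrix — Pearson for linear
pairs, Jammalamadaka-Sarma for circular-circular, Johnson-Wehrly-Mardia for
linear-circular, with permutation p-values under the add-one rule — and
greedily drops, from every pair with R^2 >= 0.7, the member with the larger
univariate p (ties alphabetical), so exactly one variable per correlated pair
survives; every drop is logged with its partner.

For ordination, circular variables are linearised as cos(theta) + sin(theta)
(after doubling axial angles so 0 and 180 degrees coincide — a documented,
switchable deviation that respects the period of orientation data), bounded
variables are logit-transformed, and the PCA is computed on z-scored columns
(mixed units make correlation-PCA the defensible default; a toggle is
provided). The smallest k components whose cumulative explained variance
exceeds 0.95 feed a stratified 80/20 split with 10-fold cross-validation
inside the training set; the final LDA is evaluated on the held-out test set
and reported with exact (Clopper-Pearson) confidence limits, the
no-information rate, a one-sided exact binomial accuracy-vs-NIR p-value,
Cohen's kappa and per-class sensitivity/specificity/precision. CVA provides
the ordination view with leave-one-out (jackknifed) scores, ridge-regularised
when the within-class scatter is singular. Group differences in score space
use Wilks' lambda on the first two components with a 999-permutation p-value,
p = (1 + #{lambda_perm <= lambda_obs}) / (n_perm + 1), so a reported p is
never 0.

`run_technique_analysis()`, `run_expertise_analysis()` (per technique subset,
as skill contrasts are technique-dependent) and `run_engraving_analysis()`
chain these stages; all three share the same statistical code paths, carry
the configuration hash in their outputs, and are deterministic under a fixed
`analysis_config()`.

## What the synthetic generator emulates

`make_base_substrate()` builds a self-affine spectral-synthesis relief (Hurst
exponent 0.8, RMS 0.03 mm over a 10 x 10 mm patch), superposed spherical-cap
pore depressions (0.05 per mm^2, mean radius 0.3 mm) and a 1 um measurement
noise floor — a coarse bioclastic limestone patch as seen by a
structured-light scanner. Two spacings are in routine use: 25 um for
fine-scale unit tests and 100 um, matching the scanner resolution, for the
study-sized panels.

Technique operators share one conservation rule: apart from the additive
noise floor, material is only removed (every operator is pointwise
non-increasing). Working time is mapped to event counts through configurable
rates (pecking 16 impacts/min, scraping 18 strokes/min, polishing 250
strokes/min — calibration choices, since no physical rates are prescribed),
with five-minute default budgets per technique step.

* **Pecking** carves ellipsoidal-cap craters delivered in sweeps (rows of
  blows along the gesture direction). Crater orientation follows a von Mises
  distribution with the skill preset's concentration; elongation is the
  tool's imprint eccentricity (comet-shaped for a pick, round for a cobble).
  Craters clip against a floor referenced to the pre-impact centre height, so
  overlapping blows do not stack depth. Gesture control enters three ways:
  orientation concentration, crater-finish (novices leave sharp-rimmed
  spherical caps, experts smooth paraboloid depressions), and blow force
  (uncontrolled blows land harder and more variably).
* **Scraping** is superficial: shallow striations whose per-pass relief is
  the envelope of the strokes (re-cutting the same groove does not deepen
  it), alternating between two hand-position direction families whose
  separation shrinks with skill, while a moving reference plane truncates
  peaks before each pass — repeated passes homogenise the relief. Much of
  the substrate's isotropic micro-relief survives, which is what keeps
  scraped surfaces less directional (higher Str) than pecked ones under the
  ACF-threshold definition.
* **Polishing** planes contact peaks against a smoothed tool envelope and a
  descending quantile plateau, but conforms only ~10 um below the contact
  plane: deeper valleys and pores are preserved, as observed on real polished
  stone. Dense, very shallow multi-directional micro-scratches (1-4 um by
  tool: skin < sand < cobble) accumulate on the contact surfaces.
* **Engraving** subtracts a V-channel along a path; multiple strokes
  superpose laterally jittered V's with alternating wall asymmetry and
  progressive deepening, so repeated gestures widen, deepen and symmetrise
  the groove. `generate_profile()` produces the corresponding standalone
  V/U cross-sections with prescribed D, WIS and asymmetry.

`default_study_design()` enumerates the full experimental structure — twelve
single technique-tool modalities plus seven sequential combinations, five
participants (two novices, two intermediates, one expert), 95 trials — and
`generate_study()` materialises it with per-trial seeds and a label table.
`generate_technique_panel()` is the reference three-class recovery study
(pecking with a pick, scraping with an endscraper, skin polish of a
blade-scraped surface; 30 sub-areas per class at 100 um spacing, skill
mixture cycling through the five participants).

The generator's defaults were calibrated once so that the documented
qualitative structure of worked surfaces is designed in and recoverable:
median Sal, Spc and MedianAsfc strictly decrease from pecking through
scraping to polishing, Str and furrow density strictly increase, and expert
pecking yields lower Isotropy and MedianAsfc than novice pecking. These
orderings — not any absolute parameter values — are the tested contract; the
absolute knob values (crater radii, striation depths, von Mises
concentrations of 2/8/32 for novice/intermediate/expert) are fixed in
`default_tools()` and `skill_level()` and documented there.

What the generator does **not** emulate: petrographic heterogeneity (fossil
inclusions, grain plucking), fracture mechanics and conchoidal chips, tool
wear and participant fatigue, or photorealistic appearance. Passing the
recovery suite therefore shows that the analysis chain can separate textures
whose generative structure differs in the documented ways — it does not show
that real limestone scans will separate equally well, and absolute parameter
values from the generator should never be compared with values measured by
commercial metrology software, whose furrow, roundness and isotropy
conventions are proprietary.

## Numerical choices and degenerate inputs

* All generators and permutation procedures are seeded; RNG state is
  restored after use, so calls do not disturb the caller's stream.
* Flat surfaces: zero Sq/Sdr/Vvv/Asfc, empty furrow network, Isotropy 100%,
  Sal/Str missing-with-reason; constant vectors give zero biweight
  midvariance; all-masked sub-areas report every parameter as missing with a
  reason, and the pipeline continues.
* FFT-based operators fill masked cells with the valid mean after cropping
  fully masked borders; distribution parameters (Sq, Smc, Vvv) use unmasked
  cells only.
* Logit boundary values are clipped at 1e-6 and the clip counted; the apex
  tie-break on flat-bottomed profiles is the plateau midpoint; the EFA
  normalization resolves the semi-major-axis ambiguity canonically.
* Problem sizes in the test-suite: 10 x 10 mm patches at 100 um for the
  recovery panels (30 sub-areas per technique class, 20 per skill level),
  6 x 6 mm at 100 um for operator unit tests, 2 x 2 mm at 20-25 um for
  fine-scale SSFA/epLsar oracles, and 500 replicates per statistical
  calibration case. These sizes were chosen as the smallest at which the
  tested properties are stable.

## Known limitations

* The ACF-threshold Str of strongly lineated textures saturates near
  Sal/half-window; comparing Str across very different patch sizes is not
  meaningful.
* Furrow density saturates at the grid resolution (one valley line per two
  cells), so very fine polish scratches are only partially resolved at
  100 um.
* The Watson-Williams test assumes concentrated groups; the implementation
  warns (and should not be trusted) below kappa of about 1.
* NewEplsar is implemented as the log-domain variant of epLsar and is
  versioned as such; only orderings should be compared across toolchains.
* Expertise analysis with a single expert participant is exploratory by
  construction; the per-technique classifier reports inherit that caveat.
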