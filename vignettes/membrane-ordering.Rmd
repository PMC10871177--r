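---
title: "Methods: monolayer thermodynamics, bilayer order, and cell-robustness statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monolayer thermodynamics, bilayer order, and cell-robustness statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorder)
```

`memorder` quantifies how ordering lipids — cholesterol-like sterols and
diplopterol-like hopanoids — condense phospholipids as a function of
acyl-chain double-bond position.  This vignette is the package's own
account of the models it implements, the parameters that matter, the
numerical choices made where several readings were defensible, and what
the synthetic-data generators do and do not emulate.

## Monolayer thermodynamics

### The condensing effect

For a binary monolayer of a phospholipid (mole fraction $X_1$) and a
terpenoid ($X_2 = 1 - X_1$), the condensing effect at surface pressure
$\Pi$ is

$$c = 100\left(1 - \frac{A_0}{X_1 A_1 + X_2 A_2}\right)\ (\%)$$

where $A_0$ is the mixture's mean molecular area and $A_1, A_2$ the
pure-component areas at the same pressure (all in Å²/molecule).  $c > 0$
means tighter-than-ideal packing (an ordering interaction); $c < 0$ means
net area expansion.  The default reference pressure is 30 mN/m, a
conventional proxy for the lateral pressure of a bilayer leaflet.

Replicate isotherms are combined by `average_replicates()`: the union
pressure grid is clipped to the range common to all replicates, and each
replicate is evaluated at every grid pressure by **nearest-lower-recorded-
point lookup** — the area recorded at the largest pressure at or below the
request.  Recorded isotherm pressures rarely hit round values exactly, and
rounding *down* is the conservative convention for compression data (the
monolayer has certainly reached the recorded pressure).  Because the
phrasing "rounded down to the nearest neighbor" admits a second reading,
`area_at()` also offers plain linear interpolation (`mode =
"interpolate"`); the lookup mode is threaded through every downstream
computation.

Uncertainty on $c$ is first-order propagation of the replicate standard
deviations of $A_0, A_1, A_2$, treated as independent:
$\sigma_c^2 = \sum_i (\partial c/\partial A_i)^2 \sigma_i^2$.  The
gradient is evaluated analytically; a finite-difference oracle in the test
suite cross-checks it.  Averaged means are passed through a running
minimum so the averaged curve honours the non-increasing-area invariant
even with noisy replicates.

### Excess free energy of mixing

$$\Delta G_{exc} = N_A \int_0^{\Pi_{max}} \left[A_{mix}(\Pi) - X_1
A_1(\Pi) - X_2 A_2(\Pi)\right] d\Pi$$

evaluated by the trapezoidal rule over the node set $\{0^+, 5, 10, 15,
20, 25\}$ mN/m, with unit conversion $1\ \text{Å}^2\,\text{mN/m} =
10^{-23}$ J (so a constant excess of $-1$ Å² over 0–25 mN/m gives
$-25 \times 10^{-23} \cdot N_A \approx -150.5$ J/mol — a closed-form
check frozen into the tests).  Two choices deserve comment:

* **The $0^+$ node.**  The integral formally starts at zero pressure, but
  measured isotherms begin above it.  The excess area is held constant
  below the lowest measured pressure: the 0-pressure node carries the
  excess evaluated at the lowest pressure common to all three curves.
  This is configurable (`extend_to_zero = FALSE` drops the node).
* **Excess, not total.**  No ideal-entropy term $RT\sum X_i \ln X_i$ is
  added.  With the excess convention, "ideal mixing" is exactly
  $\Delta G = 0$, which is the interpretation used throughout: the sign
  of $\Delta G_{exc}$ equals the sign of the trapezoid-weighted mean
  excess area (an invariant asserted in the tests).

The uncertainty propagates per-node excess-area variances (mixture and
pure-component contributions in quadrature) through the trapezoid
weights, treating nodes as independent.  Nodes sharing replicate curves
are in truth positively correlated, so this mildly understates the
variance; the package reports it as the conventional first-order band.

### Comparing isotherm groups

`compare_isotherm_groups()` summarises each replicate by the coefficients
of a polynomial regression of area on pressure and runs a one-way MANOVA
(Pillai trace, with its standard F approximation) on the coefficient
vectors.  The default is `degree = 1` — two coefficients, intercept and
slope — fitted over the 5–30 mN/m window, i.e. the liquid-expanded/
condensed region where isotherms are closest to linear.  Both the window
and the degree are exposed as parameters rather than fixed, because the
regression form behind a two-coefficient summary is a modelling choice,
not a derived quantity.  Under a shared-model null the coefficients are
Gaussian with equal covariance across groups, so the test is exact; the
acceptance suite verifies the empirical type-I error sits at the nominal
$\alpha = 0.05$ over 2,000 simulated null repetitions.

## Bilayer trajectory observables

The membrane normal is the laboratory $z$ axis throughout; frames must be
built or pre-aligned that way.  No instantaneous-normal or curvature
correction is applied — appropriate for flat, planar bilayer patches, not
for vesicles or strongly undulating membranes.

* **Centering and leaflets** (`center_and_assign_leaflets()`): the
  midplane is the mean $z$ of all molecules' anchor points (the
  C2/C21/C31 centre of geometry for phospholipids, the O3 hydroxyl for
  terpenoids); each molecule is labelled by the sign of its anchor $z$.
  A single-leaflet input is accepted with a warning so degenerate systems
  remain analysable.
* **Order parameters** (`scd_profile()`):
  $S_{CD} = \tfrac12\langle 3\cos^2\phi - 1\rangle$ per chain carbon,
  averaged over hydrogens, molecules and frames; range $[-0.5, 1]$.
  Carbonyl carbons carry no hydrogen and are skipped; sp² carbons
  contribute through their single vinyl hydrogen.  Signed values are
  reported with $|S_{CD}|$ alongside, since order-parameter figures are
  conventionally drawn as magnitudes.  The standard error comes from
  block averaging over 5 contiguous frame blocks (reduced when there are
  fewer frames) — the standard remedy for frame-to-frame correlation; 5
  blocks is a bias/variance compromise for the short synthetic
  trajectories used here.
* **Depth distributions** (`group_z_distribution()`): normalized
  histograms of group $z$ positions with 0.87 Å bins.  The double-bond
  position is the midpoint of the two sp² carbons — the natural single
  reference point for a bond.  Leaflet folding (binning $|z|$) is on by
  default: a symmetric bilayer carries the same information twice, and
  folding doubles the sample count per bin.  The overlap coefficient
  $\sum_b \min(d_1, d_2)\,w$ requires identical bin edges and is the
  standard bounded, symmetric measure of distribution overlap.
* **Tilt** (`tilt_distribution()`): the angle between the terpenoid's
  C24→O3 vector and $+z$, folded to $[0°, 90°]$ so the measure is
  agnostic to leaflet and to headgroup direction.
* **Area per lipid** (`voronoi_apl()`): per leaflet, a 2-D Voronoi
  tessellation (via `deldir`) of the anchor points, with the rectangular
  periodic boundary honoured by tiling the 8 neighbouring images and
  keeping the central-copy cells.  This is exact whenever every cell is
  smaller than the box — always true at realistic lipid densities — and
  the per-leaflet cell areas then sum to the box cross-section, an
  invariant asserted on every generated frame at $10^{-6}$ relative
  tolerance.  An independent pixel-counting oracle (nearest anchor under
  the torus metric at 0.1 Å resolution) bounds per-molecule deviations
  below 1 % in the acceptance suite.  Coincident anchors are a hard
  error naming the molecules involved.

## Cell-assay statistics

* **Growth rate**: phenol-red media report growth as an OD₅₆₂ decline
  while the pH indicator changes; the rate is the negative slope of an
  OLS line through the points with $0.40 \le \text{OD} \le 0.75$ (closed
  interval — boundary inclusion is a convention the package fixes and
  documents), with $R^2$ reported and at least 3 in-window points
  required.  On noiseless synthetic curves recovery is exact.  With
  noisy readings the *selection* of points by their noisy OD values
  induces a small truncation bias (of order a few percent of the rate at
  OD noise 0.02); the test suite measures and bounds it rather than
  pretending it away.
* **Lysed fraction**: $f = (F_x - F_0)/(F_{100} - F_0)$, normalizing each
  sample to its *own* 0 % and 100 % wash-buffer anchor wells (anchors are
  per-sample, not plate-global).  The estimate is affine-invariant in the
  fluorescence scale.  Values are reported unclamped with an explicit
  flag when outside $[0, 1]$ — clamping would hide instrument or
  normalization problems.  Raw signals are assumed blank-corrected
  upstream; no background model is applied.
* **Group comparison**: one-way ANOVA ("one-way" being the standard
  reading of the assay literature's phrasing) with Tukey HSD pairwise
  adjusted p-values.  Null calibration at $\alpha = 0.05$ is part of the
  acceptance suite.

## What the generators emulate — and what they do not

The synthetic-data layer exists so that every analysis operation can be
tested against closed-form ground truth.

* **Isotherms**: $A(\Pi) = A_{lim} + (A_0 - A_{lim})e^{-\Pi/\tau}$ —
  monotone, invertible, and spanning the realistic 30–90 Å² range.  Any
  monotone form would serve; this one was chosen for its two
  interpretable asymptotes.  Defaults (baseline 100 Å², limiting 55 Å²,
  decay 18 mN/m for the phospholipid; 48/36/25 for the more condensed
  terpenoid; replicate noise 0.8 Å²; 2:1 mixtures, i.e. $X_1 = 2/3$;
  injected excess $-4$ Å²) are typical of fluid PC monolayers and of the
  few-percent condensing effects the method must resolve.  Mixtures add
  a prescribed excess-area profile to ideal mixing, so the implied
  condensation and $\Delta G_{exc}$ are known exactly.
* **Bilayer frames**: stick-figure lipids — anchors plus chain carbons
  with explicit hydrogens — on a jittered lattice, two symmetric
  leaflets, midplane at $z = 0$.  C–H bonds are drawn from a two-point
  mixture on $\cos\phi$ (with probability $c$ along $\pm z$, otherwise
  in-plane at uniform azimuth), which gives $\langle\cos^2\phi\rangle =
  c$ *exactly* and hence an analytic $S_{CD} = (3c - 1)/2$ per carbon.
  Group depths (methyls M1–M4, double-bond midpoint) are Gaussian with
  prescribed mean and sd, mirrored across the midplane.  Default depths
  (12, 9.5, 7, 5 Å for M1–M4) stage the ring methyls through the upper
  acyl region; the Δ9-like build places the double bond at the M2 depth
  (9.5 Å) and the Δ11-like build between M3 and M4 (6 Å), reproducing
  the depth-relation logic the overlap analysis must detect.  These
  frames are **not** chemically valid conformers: no force field, no
  excluded volume, no bonded geometry beyond the C–H bond length, no
  lipid diffusion between frames.  Passing tests therefore demonstrate
  the correctness of the estimators, not the realism of any ensemble.
* **Assays**: linear OD declines and linearly ramped lysis plates with
  Gaussian noise and exact anchors.

Every generator is bit-reproducible under its integer seed (seeding is
scoped, so the caller's RNG stream is untouched), and the pipeline's
tables are byte-identical across reruns of the same configuration — a
property the acceptance suite asserts file by file.

## Problem sizes and runtime choices

Analyses in the tests and the acceptance script run on 50 lipids per
leaflet × 20–50 frames (order-parameter recovery uses 100 lipids × 50
frames; five $\cos^2$ targets spanning $[0,1]$), 3 isotherm replicates
per composition on a 0.5 mN/m grid, and 2,000 repetitions for the null
calibrations.  These sizes make every statistical check sharp (pooled
order-parameter standard errors ~0.002; binomial sd of a rejection rate
~0.005) while keeping a full run in tens of seconds on one core.
Scaling the bilayer up is a matter of `synthetic_bilayer_spec()`
arguments; the estimators are vectorised per frame.

## File formats

Isotherm, growth and lysis tables travel as plain CSV with fixed headers
(`pressure_mN_m,area_A2,replicate,composition,temperature_C`;
`sample,time_h,od562`; `sample,buffer_pct,fluorescence`).  Frames travel
as multi-model PDB (one `MODEL` per frame, written and read through
bio3d) with the atom-role map as a YAML topology keyed by residue name —
all plain text.  PDB coordinates carry three decimals, so a round trip is
exact to 0.001 Å; residue names are limited to three characters by the
fixed-column format.  Binary trajectory formats are out of scope.

## Known limitations

* The monolayer error model treats $A_0, A_1, A_2$ (and integration
  nodes) as independent; shared-replicate correlations are ignored.
* Leaflet assignment is by anchor sign at the first frame; lipid
  flip-flop between frames is not tracked (and cannot occur in the
  generator).
* The Voronoi construction assumes a rectangular box and cells smaller
  than the box; it will refuse coincident anchors rather than merge them.
* `group_z_distribution()` requires centered frames and errors otherwise;
  it does not re-wrap molecules split across the periodic $z$ boundary
  beyond what centering implies.
* The MANOVA comparison summarises isotherms by a low-degree polynomial;
  strongly curved isotherm windows need either a narrower window or a
  higher degree, both exposed as arguments.
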