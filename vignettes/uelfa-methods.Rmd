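---
title: "Methods: simulating and quantifying an ultrasound-enriched colorimetric LFA"
author: "uelfa developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying an ultrasound-enriched colorimetric LFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uelfa)
```

## Scope and model overview

`uelfa` models the analysis chain of a colloidal-gold lateral flow assay
(LFA) whose sample is pre-concentrated in an acoustofluidic cavity before it
reaches the strip: the physics of particle trapping in a standing ultrasound
wave, the colorimetric response of the test line to a protein biomarker
(tau, an Alzheimer's blood marker, is the motivating analyte), machine-read
quantification of strip photographs, and the statistical evaluation layer a
validation study needs. Because no raw strip data ship with the package,
every downstream stage is driven by a synthetic-data generator whose
statistical structure is stated explicitly below; the generator is
first-class, tested code, not a fixture.

## Acoustic enrichment

### Force model

A small spherical particle in a one-dimensional standing wave experiences
the time-averaged primary radiation force. With the cavity walls at pressure
antinodes (rigid reflectors, mode shape $p(x) \propto \cos kx$) we evaluate

$$F(x) = \frac{\pi P_a^2 V_p \beta_m}{2\lambda}\,
  \Phi(\beta,\rho)\,\sin(2 k x), \qquad
  \Phi = 1 + \frac{3(\rho_p-\rho_m)}{2\rho_p+\rho_m} - \frac{\beta_p}{\beta_m},$$

where $P_a$ is the pressure amplitude, $V_p$ the particle volume, $\lambda$
and $k$ wavelength and wavenumber, and $\rho$, $\beta$ densities and
compressibilities of particle (p) and medium (m). The textbook form of this
force is often written with a minus sign and a coordinate measured from the
nearest pressure node; substituting that node-referenced coordinate into our
wall-referenced frame yields the $+\sin(2kx)$ form above. The sign matters:
it makes pressure nodes the *stable* equilibria for $\Phi > 0$ (dense, rigid
particles such as gold in water, $\Phi \approx 2.39$), which is what drives
the observed centre-of-cavity aggregation. A resonant cavity of length
$L = m\lambda/2$ has exactly $m$ interior nodes; the fundamental has one, at
$L/2$. `pressure_nodes()` refuses non-resonant fields, where the mode
structure (and hence the node count) is undefined.

### Dynamics

The source experiments show aggregation but state no equation of motion, so
the simulator uses the standard low-Reynolds model: inertialess Stokes drag,
$x \leftarrow x + F(x)\,\Delta t / (6\pi\eta r)$, optionally with the
fluctuation-dissipation Brownian increment
$\sqrt{2 k_B T \Delta t/(6\pi\eta r)}\,\xi$, stepped by Euler-Maruyama. Two
numerical guards apply:

* **Step bound.** The maximal advective step $C|\Phi|\mu\,\Delta t$ must not
  exceed $\lambda/(2\pi)$. Below this bound the map contracts the distance
  to the nearest node monotonically (the Lyapunov property the tests
  assert); above it a particle could overshoot past an antinode into the
  wrong basin, so `simulate_migration()` raises an error instead of
  integrating garbage.
* **Convergence tolerance.** A particle counts as "arrived" within 1% of a
  wavelength of a stable node - dimensionless in the geometry and
  independent of any grid.

A single 40 nm nanoparticle's radiation force is orders of magnitude too
weak to traverse the cavity in tens of seconds; the experimental
aggregation is a collective effect (and acoustic streaming is out of
scope). The particle spec therefore exposes `effective_cluster_radius`, so
users simulate aggregate-scale migration explicitly; the examples use a
2 µm effective cluster. This is a documented limitation, not hidden
physics. The pressure amplitude in the physical device is unknown
(unmeasured, and the soft-walled cavity's acoustic boundary conditions are
uncharacterised), so $P_a$ is a free parameter; the 50 s experimental
aggregation time is deliberately *not* used as a quantitative target.

## Synthetic colorimetric data

### Dose-response

The test line's normalised colorimetric intensity follows a saturating
exponential

$$I(c) = s\,K\,(1 - e^{-c/K}),$$

with initial slope $s = 0.96041$ (the fitted calibration slope on the
0-0.4 ng/mL linear dynamic range) and saturation scale $K = 2$ ng/mL. The
reported facts constrain only linearity up to 0.4 ng/mL and distinct
signals up to 4 ng/mL; the exponential form is the simplest saturating
curve satisfying both, and $K = 2$ keeps the 1/2/4 ng/mL rungs apart. At
the defaults the curve deviates from the straight line $s\,c$ by at most
10% over the linear range.

### Noise model

Noise is injected in the **concentration domain**: each replicate at
nominal level $c$ receives $\varepsilon \sim N(\mu_b \mathbf{1}\{c=0\},
\sigma_b\,\iota(c))$ with the matrix-specific blank background
$\mu_b \pm \sigma_b$ equal to $0.0022 \pm 0.0021$ ng/mL in PBS and
$0.0025 \pm 0.0026$ ng/mL in serum. Because the assay's background is
*reported* in concentration units, this construction reproduces the printed
blank statistics exactly, which the blank + 3 SD detection limit then
inherits. Two deliberate choices:

* The signal is **not truncated at zero**. Optical background fluctuates
  below its mean as readily as above it; the dose-response is extended
  linearly below zero ($I = s\,c$ for $c<0$), keeping the inverse
  calibration well defined and the blank mean/SD unbiased. Truncation at
  zero would bias the blank mean by about +7% and the SD by about -12%,
  silently breaking the detection-limit arithmetic.
* $\iota(c)$ inflates the SD (default 1.25 in serum, 1 in PBS) only for
  non-blank levels below 0.04 ng/mL, emulating matrix interference that
  blurs the 0 vs 0.02 ng/mL boundary in serum without touching the blank
  statistics themselves.

### RGB mapping

Records carry *real-valued* RGB (a camera ROI mean over many pixels does
not quantise to integers): `rgb = channel_base - channel_gain * signal`
with base (235, 235, 235) and gains G = 120 > B = 72 > R = 32 per unit
intensity - a red gold-nanoparticle band absorbs green most strongly. The
gain magnitudes are free parameters (no numeric RGB values are published
for real strips); the 15:9:4 ratio was scaled so that the saturated
depletion $s\,K\,\mathrm{gain}_G = 230.5$ stays inside the 8-bit range for
the entire ladder - larger gains would push the generator's own
channel-underflow error on its default inputs, which is also why the
underflow check exists at all.

### Enrichment gain

Ultrasound pre-concentration multiplies the colorimetric signal by
`enrichment_gain` (default 10), capped so that no channel leaves
\[0, 255\] (the most-depleted channel floors at 0). In the linear regime a
10-fold signal gain equals a 10-fold concentration gain, so the noise-free
visual-detectability threshold moves exactly one decade down the ladder
(0.2 → 0.02 ng/mL); the threshold intensity 0.15 was fixed once, between
the noise-free intensities of the 0.1 and 0.2 ng/mL rungs. Above
≈0.21 ng/mL the cap engages and enriched strips saturate - enrichment is a
low-end sensitivity tool, and the full-ladder calibration datasets are
generated unenriched.

### What the generator does not emulate

Illumination gradients, perspective, camera radiometry, membrane texture,
inter-batch antibody variation, and hook effects. A green test therefore
establishes that the *analysis chain* is correct under the stated
statistical structure - not that a particular laboratory's strips meet the
printed performance.

## Image rendering and extraction

Rendered strips are h × w × 3 arrays (rows across the 4 mm width, columns
along flow) with the control band 7 mm downstream of the test band. Bands
have a flat core whose colour equals the record's RGB exactly, with
Gaussian shoulders (SD 0.15 mm); the flat core is the ground-truth ROI, so
`generate → render → extract` is an exact round trip at zero pixel noise -
a property the acceptance suite asserts.

Detection works on the green channel of the width-averaged longitudinal
profile: candidate bands are runs below `median(profile) - max(3*mad, 5)`.
The floor of 5 grey levels plays the role of a visual-detectability floor
and keeps Gaussian shoulders and faint noise out of the candidate set; it
means test bands below ≈0.05 ng/mL are reported `test_found = FALSE`
(their RGB is still extracted from the expected window upstream of the
control). The extraction ROI is a window centred on the detected band and
shrunk two pixels inside the nominal band half-width, so edge gradients
never bias the mean (an earlier run-based ROI eroded by one pixel was
measurably biased by shoulder pixels, ≈3 grey levels at 0.4 ng/mL).
Validity is defined solely by the control line: `qc_filter()` retains
exactly the records whose control band was found.

## Models

**KNN** (classifier): Euclidean distance in raw RGB space, majority vote
over the `k = 5` nearest neighbours (no neighbour count is published;
5 is odd and robust at ~15 replicates per class). Ties break by the
smaller summed distance of the tied classes, then by the nearest
neighbour's class, then by label order; equal distances at the k-th rank
resolve by training order. Every rule is deterministic, and the
implementation is tested against an independent brute-force oracle.

**GPR** (quantifier): RBF kernel
$k(u,v) = \sigma_f^2 \exp(-\|u-v\|^2/2\ell^2)$ plus noise $\sigma_n^2$ on
features standardised to zero mean/unit variance, targets on the raw ng/mL
scale centred at their mean (the prior mean, to which far-field
predictions revert). No kernel is published; the RBF + noise pair is the
standard default. Hyperparameters maximise the log marginal likelihood by
L-BFGS-B in log space from three starts (one data-scaled, the rest
seeded-random); a jitter of $10^{-10}$ keeps duplicate inputs
factorisable. The closed-form marginal likelihood is verified against a
dense linear-algebra oracle to $10^{-8}$.

**Cross-validation**: stratified 5-fold for classification (protects
3-per-class fold counts at 15 replicates), plain random for regression -
the source workflow states only "random division". Each sample is
predicted exactly once by a model that never saw it; metrics are computed
on the pooled out-of-fold predictions.

## Evaluation layer

* Overall accuracy is the confusion-matrix trace over the total; macro
  recall (mean per-class recall) is also reported because "average
  accuracy" is ambiguous between the two.
* $R^2$ for predicted-vs-true concentration is the squared Pearson
  correlation (the quantity called a correlation coefficient in assay
  reports); the *baseline* single-feature regressions report the
  coefficient of determination $1 - SS_{res}/SS_{tot}$. Both conventions
  are documented where they appear.
* Bland-Altman limits of agreement use the fixed multiplier 1.96;
  `fraction_within` counts boundary values as inside.
* The detection limit is the IUPAC blank + 3 SD rule applied to
  back-calculated blank concentrations: $0.0022 + 3 \times 0.0021 =
  0.0085$ ng/mL = 8.50 pg/mL in PBS, 10.30 pg/mL in serum.
* "Colorimetric intensity" for the linear calibration and the specificity
  t-test is normalised green-channel depletion
  $(\mathrm{base}_G - G)/\mathrm{gain}_G$, the channel a red band
  modulates most.
* The improvement of the ML models over the baselines is the relative
  gain $(R^2_{new} - R^2_{old})/R^2_{old} \times 100\%$ (the published
  improvement formula is unstated; this is the declared convention).
* The specificity comparison uses Welch's unequal-variance t-test - a
  conservative choice where only a generic two-tailed t-test is specified.
* The clinical call dichotomises predicted concentration at a user-supplied
  cut-off (boundary = positive). No default ships: the cut-off belongs to
  the clinical literature for the biomarker and population, and the
  pipeline raises an instructive error if it is requested but unset.

## Reproducibility

Every stochastic operation takes a `seed`; a fixed seed makes datasets,
splits, optimiser restarts, trajectories and the whole pipeline report
bit-reproducible. Internally a scoped RNG guard restores the caller's
random stream, so package calls never perturb user code.

## Worked example

```{r example, eval = FALSE}
data <- generate_dataset(seed = 1)                 # 9 levels x 15, PBS
knn <- cross_validate(data, "knn", k = 5, seed = 1)
gpr <- cross_validate(data, "gpr", seed = 1)
knn$metrics$overall_accuracy                       # 1.0
gpr$metrics$r_squared                              # > 0.99996
report <- run_pipeline(list(seed = 1))
report$calibration$lod_pg_ml                       # blank + 3 SD, pg/mL
```

## Known limitations

* Single-particle acoustics cannot reproduce collective 50 s aggregation;
  use `effective_cluster_radius` and treat timescales qualitatively.
* The enrichment cap makes enriched high-ladder strips degenerate by
  construction; classify enriched data only in the sub-LDR regime.
* Published serum-accuracy and baseline-improvement percentages depend on
  the study's unreleased raw data and are not desk-reproducible; the test
  suite substitutes property-based checks (oracle equivalence, round-trip
  exactness, parameter recovery) for them.
* Strip I/O is plain-text CSV; PNG reading would need an image package not
  assumed here.
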