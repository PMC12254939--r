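---
title: "Dynamic LED lighting analytics: models, parameters and design choices"
author: "cealux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic LED lighting analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cealux)
```

# Scope

`cealux` models the analytics around dynamic LED lighting in indoor
(vertical-farm) lettuce production: what a lighting regime delivers
photonically, what it costs on an hourly spot market, and how the plant's
photosynthetic apparatus, canopy phenotype and carbohydrate metabolism can
be quantified alongside.  Every instrument-facing stage has a seeded
synthetic generator with machine-readable ground truth, so the whole
pipeline is testable closed-loop without instrument data.

# Lighting regimes and the daily light integral

A regime is a piecewise-constant PPFD schedule over one 24-h cycle in
zeitgeber time (ZT, hours since lights-on), with explicit dark intervals
and a clock anchor for ZT 0.  Intervals are half-open, `[start, start +
duration)`.  The daily light integral is

$$\mathrm{DLI} = \sum_i \mathrm{PPFD}_i \, \Delta t_i \times 3600 \times
10^{-6} \quad [\mathrm{mol\,m^{-2}\,day^{-1}}],$$

and `cumulativeDLI()` is the same integral truncated at a ZT.  DLI is the
conserved quantity of the package's reference scenario sets: the four
small-scale regimes (18-h photoperiod from 06:00; a 155 µmol m⁻² s⁻¹
constant and three 275/95 µmol block permutations) share 10.044 mol m⁻²,
reported as 10.0 at three significant figures; the three larger-scale
regimes (from 11:00; a 196 µmol constant, a bipartite L6:D3:L12:D3
"Split-Night" at 196, and a five-level "Price-Based" profile) integrate to
12.7008 and 12.744 mol m⁻², both 12.7 at three significant figures.
Reported DLIs are therefore rounded to three significant figures; the
encodings themselves are exact and are *not* forced to agree beyond that
rounding.

Two operations matter for costing.  `scaleToDLI()` multiplies all
intensities by one scalar — the unique shape-preserving way to equalise
DLI across regimes (re-timing intervals would change the schedule being
compared).  `shiftStart()` moves the clock anchor cyclically and conserves
DLI exactly, because the ZT-relative pattern is untouched.

# Electricity-cost engine

The costing procedure mirrors spot-price-driven load shifting practice:

1. build the per-clock-hour mean price profile of a calendar year
   (`diurnalProfile()`; gap-free hourly coverage is enforced);
2. rank hours by mean price (`rankHours()`; ties to the earlier hour);
3. convert the regime's hourly PPFD into electrical energy
   (`hourlyEnergy()`);
4. cost the regime against the profile (`dailyCost()`,
   `sum_h energy_h \times price_h` joined on clock time);
5. compare against a baseline constant photoperiod
   (`savingsVsBaseline()`, `costReport()`).

**Hourly bins.** Intervals may have sub-hour resolution; costing
discretises to clock-hour bins by within-hour averaging.  For whole-hour
schedules (all built-ins) the binning is lossless, and under a linear
power model it is exact for any schedule because energy is linear in PPFD.

**Power model.** The default is linear with photon efficacy
2.5 µmol J⁻¹ — LED photon output is close to proportional to drive
current, and 2.5–3 µmol J⁻¹ is typical of current horticultural
luminaires.  Measured dimming curves that depart from proportionality are
supported as an interpolated table (`tablePowerModel()`); requests above
the table range are refused rather than extrapolated.  Because savings are
cost ratios, they are invariant to the efficacy value under the linear
model; the euro values are not.

**Anchoring.** Optimisation deliberately searches only the 24 cyclic
clock anchors of a fixed regime shape (`shiftScan()`,
`targetCheapHours()`): the engineering question is where to *position* a
horticulturally validated photoperiod, not how to redesign it.  A free
reallocation optimiser is out of scope.  In `costReport()`, regimes named
in `dynamic` are costed at their cheapest anchor while constant-photoperiod
scenarios (and always the baseline) keep their stated clocks — the
convention under which a dynamic schedule is a deliberate fit to the price
pattern, whereas the shifted constants are themselves fixed what-if
scenarios.  With the double-peaked price pattern below, this reproduces
the expected ordering: the price-tracking profile is cheapest, the
dynamic-intensity trio next, the bipartite split-night regime next, then
the shifted constants, then the baseline.

**Prices.** Negative spot prices are accepted and costed as printed (they
occur in day-ahead markets); timestamps are taken at face value in local
market time with no DST handling beyond what the input encodes (a
documented limitation); years are profiled independently.  Savings are
conventionally quoted to 0.1 %, euro costs to three decimals; the
functions return full precision and rounding is left to presentation.

# The synthetic price generator

`genPriceSeries()` emulates the recurring diurnal structure of a
day-ahead market: morning (08:00–11:00) and early-evening (17:00–20:00)
peaks at `base + amplitude`, a night trough (23:00–05:00) at
`base - amplitude`, i.i.d. Gaussian noise per hour, and a per-year scale
factor.  Defaults (base 0.08, amplitude 0.04, noise 0.02 €/kWh, year
scales 0.45/1/2.2/0.8 for 2020–2023) were chosen once as
Nord-Pool-realistic: a deep night trough of roughly half the daytime
level, and the large 2020→2022→2023 annual price swing.  The generator is
intentionally free of autocorrelation and weekend/season structure — the
costing contracts operate on annual hourly means, for which i.i.d. noise
suffices; conclusions about forecastability or day-to-day scheduling
cannot be drawn from it.

# Chlorophyll-fluorescence quenching analysis

Derived parameters are the field-standard ratios
$F_v/F_m = (F_m - F_o)/F_m$ and $\mathrm{NPQ} = (F_m - F_m')/F_m'$.

Two protocols are bundled.  The bench protocol has a 21.7-s initial dark
phase (saturating pulse at 5.06 s giving $F_m$), 70 s of actinic light at
155 µmol m⁻² s⁻¹ with pulses at 31.7/41.7/51.7/71.7/91.7 s (landmarks
L1–L4, Lss) and 100 s of dark relaxation with pulses at 121.7/181.7/191.7 s
(D1–D3); pulses are 800 ms at 1085 µmol m⁻² s⁻¹.  The whole-plant imaging
protocol has a 9-min high-light period at 800 µmol m⁻² s⁻¹, a 27-min dark
relaxation and a seven-step 3-min light ramp (100→1200 µmol m⁻² s⁻¹), with
800-ms pulses every 3 min.  *Partially relaxed NPQ* is NPQ at the pulse
nearest 9 min into the dark relaxation — on a 3-min pulse grid one pulse
falls there exactly; traces with no pulse within 90 s of the mark are
refused as protocol mismatches.  The ramp tail is landmarked (R1–R7) but
no derived summary uses it; it is exposed as a raw Fm′ series only.

Timing choices the instrument leaves unspecified, fixed here once: the
imaging protocol opens with a 6-min dark phase whose $F_m$ pulse fires at
180 s so that the 3-min grid hits the 9-min relaxation mark; $F_o$ is the
mean of the pre-pulse dark window (0–4.5 s bench, 0–150 s imaging) —
strictly before the first pulse, the standard choice when only the $F_m$
pulse is published.  Camera settings are metadata, not computation.

**Estimators.** $F_m'$ is the maximum of the trace within the 800-ms pulse
window — robust to sampling phase because the generator's pulses are
plateaus.  Under noise the window maximum carries an upward bias of about
$1.5\sigma$ (extreme value of ~8 samples), which propagates into NPQ with
leverage $F_m/F_m'^2$; a `median3` estimator (median of the top three
window samples) is available for noisier traces.  The recovery tolerances
asserted in the tests (Fv/Fm within 0.01, steady-state NPQ within 0.05,
partially relaxed NPQ within 0.02) hold at the generator's default noise,
sd 0.005 a.u. on an $F_m$ of 3 — the smoothness of per-plant ROI-mean
traces, which average thousands of pixels.  Single-pixel traces are far
noisier and would need the `median3` estimator and wider tolerances.

The trace generator uses single-pool NPQ kinetics —
$\dot N = k_\mathrm{ind}(N_\mathrm{ss} - N)$ in light,
$\dot N = -k_\mathrm{rel} N$ in dark, $F_m'(t) = F_m/(1+N(t))$ — with
defaults $k_\mathrm{ind} = 0.08\,\mathrm{s^{-1}}$ and a 5-min relaxation
half-time, typical of the energy-dependent quenching component.  Its
purpose is closed-loop recoverability; it does not model qE/qI
partitioning, photoinhibition or state transitions, so passing recovery
tests says nothing about those.

# RGB phenometrics

Segmentation defaults to an excess-green rule, $2G - R - B > \tau$ with
$\tau = 40$ on the 0–255 scale: vendor threshold sets are proprietary, and
excess green separates green canopies from achromatic or brown backgrounds
without per-channel tuning.  RGB and HSV box thresholds are available when
bounds are known.  Shape metrics are computed on the largest 8-connected
component.

* **Greenness** $(2\,\overline G - \overline R - \overline B)/(2\,\overline
  R + \overline G + \overline B)$ with channel means taken over the mask
  first, then the ratio — not a per-pixel index mean.  Closed forms: pure
  green → 2, any grey → 0.
* **Area** is pixel count × (mm/px)².
* **Expansion rate** is the averaged-log slope
  $(\overline{\ln A_2} - \overline{\ln A_1})/(t_2 - t_1)$ between two
  sampling days.
* **Roundness** is the isoperimetric ratio $4\pi A/P^2$, clamped to
  [0, 1].  $P$ is the oriented boundary-pixel contour length with diagonal
  steps weighted $\sqrt 2$; this estimator overestimates smooth perimeters
  by a few percent, so a rasterised disk scores ≈ 0.93–0.97 rather than
  exactly 1 — values are comparable within this implementation, not across
  software.
* **Compactness** is area over convex-hull area, with the hull taken over
  pixel *corners* so convex blobs score 1 up to rasterisation (a hull over
  pixel centres would undercount the hull by half a perimeter band).

The rosette generator draws a union of elliptical leaves whose target area
grows exponentially; each plant's leaf geometry is fixed across days, so
its expansion is exactly exponential and the emitted ground truth is the
actual rasterised pixel count.  It does not emulate leaf overlap changes,
specular highlights, shadows or soil texture — segmentation performance on
real tray images is not demonstrated by these tests.

# LC-MS feature-table preprocessing

Four feature-quality rules apply in a fixed order, and the filter report
telescopes (input = retained + removals per rule):

1. retention time within 0.4–4 min (inclusive bounds as printed);
2. maximum intensity over all samples ≥ 10 — read as "the feature must
   reach the floor somewhere"; requiring ≥ 10 in *every* sample would make
   the later presence rule vacuous;
3. RSD (sd/mean × 100) across pooled-QC injections strictly < 150 %,
   missing values treated as absent; a feature observed in fewer than two
   QCs has no defined repeatability and is removed;
4. presence (non-missing) in ≥ 2/3 of the samples of *at least one*
   biological class — a feature reliably present in any condition is kept;
   an all-classes mode is a switch for stricter designs.

For projection, QC samples are dropped, missing values are imputed per
feature with the mean of the lowest observed decile (the `ceiling(n/10)`
smallest values — idempotent, observed values never altered), intensities
are log-transformed and per-feature Z-scored (zero-variance features are
dropped with a warning), and samples are projected onto the top two
principal components with signs fixed by the largest-magnitude loading.
The feature-table generator is a null model by default — no class effect —
so the projection should show no class separation; the tests assert a mean
silhouette near zero, mirroring the situation where regime × timepoint
classes do not separate in PC1/PC2.

# Diel carbohydrates and cumulative DLI

The carbohydrate generator accumulates an excess over baseline in
proportion to cumulative DLI while lights are on and decays it
exponentially (default 0.15 h⁻¹) through dark hours, starting each day at
its 24-h periodic fixed point; replicates get lognormal scatter (default
CV 15 %, n = 3).  Accumulation coefficients (0.7 and 0.8 µmol g⁻¹ FW per
mol m⁻² for sucrose and starch) give diel amplitudes of a few to ~10
µmol g⁻¹ FW at DLI 10 mol m⁻², the magnitude seen in lettuce leaves.
`carbDliCorrelation()` correlates replicate-mean concentrations with
cumulative DLI over *photoperiod* timepoints; dark timepoints are excluded
by default because cumulative DLI is flat in darkness while sugars are
catabolised — including them can only dilute the association being
quantified.  A timepoint on the lights-off boundary (e.g. ZT 18 of an
18-h photoperiod) belongs to the photoperiod it terminates.  Equal-DLI
regimes converge at the end of the photoperiod by construction; with
replicate noise the convergence is within sampling error of the replicate
means.

# Numerical conventions and degenerate inputs

Interval coverage is validated to 1e-9 h; equal-DLI scaling is exact to
1e-9 relative; anchor ties resolve to the earliest clock hour; all-dark
regimes refuse scaling (division by zero) and flat traces yield Fv/Fm = 0
and NPQ ≡ 0; empty canopy masks make shape metrics `NA` in the tidy
per-plant path (`measureCanopy()`) and errors in the direct metric calls;
PCA refuses `k` above the data rank.  All generators scope their RNG, so
a generator call never perturbs the session stream, and equal seeds give
identical output.

# Problem sizes used by the test-suite

The suite runs entirely on generated data at desk scale, chosen to keep a
full run around half a minute while leaving comfortable statistical
margins: 200 seeded price profiles for the anchoring brute force, one
generated market year for the ordering check, 100 traces per quenching
protocol, rosette frames of 200 × 200 px with up to 10 plants, feature
tables of 40–200 features with 18 biological + 5 QC samples and 20 seeds
for the null-projection check.

# Known limitations

Euro-denominated cost *levels* depend on the luminaire's measured
consumption and the actual market series; with the bundled linear power
model and synthetic prices, only relative statements (savings, orderings,
anchors) are meaningful.  The cost engine ignores HVAC coupling, demand
charges and intraday re-trading.  The quenching generator's single pool
cannot represent slowly reversible quenching that a 27-min relaxation does
not clear.  Segmentation thresholds and shape metrics are
implementation-defined conventions, not reproductions of any vendor's
proprietary definitions.
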