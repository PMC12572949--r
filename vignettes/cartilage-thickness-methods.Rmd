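---
title: "Measuring femoral cartilage thickness from suprapatellar ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral cartilage thickness from suprapatellar ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartizone)
```

## The measurement

With the knee flexed, a transverse B-mode sweep over the suprapatellar
area shows the distal femoral cartilage as an anechoic band between the
bony cortex and the fat pad. After manual segmentation of that band, two
boundary polylines describe it: the cartilage--bone interface (the deep
boundary) and the synovial--cartilage boundary (the superficial one). A
single landmark — the centre of the intercondylar notch, marked manually
at the deepest point of the synovial boundary — anchors the regional
analysis.

`cartizone` implements the downstream computation:

1. **Partition.** The lateral--medial extent is split into three zones by
   two vertical cuts centred on the notch abscissa. By default the
   intercondylar zone spans 4.8 mm on either side of the notch
   (`convention = "absolute_mm"`); alternatively it is the middle 25% of
   the imaged cartilage width (`convention = "fraction_of_extent"`).
   Both conventions are in circulation for this protocol; on a typical
   38.4 mm field of view they coincide, which is why 4.8 mm is the
   default — it is the only unambiguous absolute figure. Zones are slabs
   in the image x-axis, not arc-length intervals along the bone, matching
   the "fraction of image width" formulation.
2. **Thickness.** Per zone, thickness is defined as cartilage
   cross-sectional area divided by the arc length of the cartilage--bone
   interface within the zone — a one-dimensional average of the local
   width that is robust to boundary wiggles. Area comes from the shoelace
   formula on the cartilage polygon clipped to the zone slab; the
   interface length is the clipped bone polyline's arc length. Clipping
   inserts vertices exactly at the cut abscissae, so zone areas sum to
   the total area and zone interface lengths to the total bone arc
   length; both identities are asserted on every call at `1e-9` relative
   tolerance.
3. **Averaging.** The protocol acquires three images per site; per-zone
   thickness is averaged arithmetically across images
   (`site_reading()`), and the per-image values are retained for
   reliability analysis.

The interface length is deliberately that of the bone-side polyline — not
the synovial side, nor a midline — because the metric is defined against
the cartilage--bone interface. For a curved interface this makes the
area/length ratio differ from the normal-offset thickness: on a circular
arc of radius $R$ with constant normal thickness $t$, the ratio is
$t\,(1 + t/2R)$ (about 7% above $t$ at $R = 20$ mm, $t = 3$ mm). The
phantom ground truth and the tests treat that as the defined quantity
rather than an error.

## Coordinates and mask handling

All geometry is in mm with the image y-axis pointing down; polylines run
lateral to medial along increasing x. Masks use the pixel-centre
convention (0-based pixel $i$ has centre $(i + 0.5)\,s$ at spacing $s$).
`boundaries_from_mask()` keeps the largest foreground component
(labelling and hole-filling via EBImage), then traces, per occupied
column, the outer edge of the deepest pixel as the bone vertex and the
outer edge of the shallowest as the synovial vertex. Tracing outer edges
rather than centres makes an axis-aligned solid band recover its exact
physical outline, and bounds the deviation from the true boundary by half
a pixel elsewhere; column-wise tracing is undefined where the boundary is
near-vertical (the extreme ends of a strongly curved band), which is why
recovery is validated over the central part of phantoms. The notch must
be supplied by the analyst; `suggest_notch()` proposes the deepest
central synovial point but is never used silently, and the snapping of a
supplied hint to the local deepest point can be disabled (`snap_mm = 0`).

## Phantoms: what the synthetic geometry covers

`make_phantom()` builds bands of known thickness over a flat or
circular-arc bone curve, with the synovial boundary offset along the
local normal. Ground truth per zone is computed by adaptive quadrature on
the *continuous* curves (area between the boundary functions over the
zone slab; closed-form arc lengths), so it is independent of the
discretised polylines handed to the measurement code. Offsets that would
self-intersect — thickness reaching the curvature radius on a concave
bone — are rejected with the violating x-range named.

The phantoms emulate geometry only: there is no speckle, attenuation,
probe physics or segmentation uncertainty. Passing the phantom suite
therefore validates the partition/area/length computation and the mask
tracer, not the human segmentation step or image quality effects in real
scans.

## Synthetic cohorts and the error model

`make_cohort()` draws reading $r$ of subject $i$ at site $s$ as
$y_{irs} = \mu_s + b_i + e_{ir}$ with
$b_i \sim N(0, \sigma_b^2)$ shared across sites and
$e_{ir} \sim N(0, \sigma_w^2)$. Homoscedastic Gaussian errors are the
assumption under which the two-way consistency ICC and SEM are defined,
which is why this (and not, say, a heavier-tailed or
proportional-error model) is the default. The planned single-reading
reliability is $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$.

Published reliability for this protocol reports SEM% of 1.3--2.3% but no
within-subject SD, so $\sigma_w$ is a free parameter calibrated as
SEM% $\times$ grand mean / 100 (e.g. 1.6% of 3.19 mm $\approx$ 0.05 mm).
Defaults $\sigma_b = 0.30$ mm and $\sigma_w = 0.05$ mm reproduce a
realistic site SD ($\approx 0.30$ mm, the magnitude seen in the
normative tables) and an ICC near 0.97, inside the published 0.91--0.99
band. Reliability-band simulations use cohorts of 232 subjects with
triplicate readings — the study size this generator emulates.

An `exact_moments` mode rescales each group's subject-level sample
affinely so its mean and SD equal the requested values exactly (readings
within a subject then coincide). This exists for one purpose: it makes
the raw-data engines reproduce summary-statistics results bit for bit,
turning engine equivalence into a deterministic oracle test.

## Reliability statistics

`two_way_anova()` decomposes the $n \times k$ readings matrix into
subject, reading and residual components. From it:

* **ICC(3,1)**, consistency form:
  $(\mathrm{BMS} - \mathrm{EMS}) / (\mathrm{BMS} + (k-1)\,\mathrm{EMS})$.
  The reading (trial) mean square is excluded from the denominator —
  systematic drift across the three acquisitions does not count against
  consistency. Confidence limits use the $F = \mathrm{BMS}/\mathrm{EMS}$
  pivot; a one-sided 95% lower bound is compared against the 0.70
  acceptability threshold.
* **SEM%** $= 100\sqrt{\mathrm{EMS}}/\bar{y}$, with the chi-square
  interval obtained from $\mathrm{SSE}/\sigma^2 \sim \chi^2_{(n-1)(k-1)}$;
  below 10% is flagged as minimal random error.
* **CV%** by the logarithmic method: the same decomposition on
  $\log y$ gives the within-subject log-variance $s^2$, mapped through
  $100\sqrt{e^{s^2} - 1}$ (the log-normal within-subject CV). Among the
  log-method variants in use this one reduces to $100\,s$ in the small-$s$
  limit; the first-order variant $100(e^{s} - 1)$ is available by flag
  since published descriptions rarely pin the formula down.

Degenerate inputs are handled by convention, not NaN: zero residual
variance yields ICC 1 with a degeneracy flag; subjects with incomplete
readings are dropped (complete-case) with a message, there being no
published missing-data rule to follow.

## Group comparisons: two engines

Every parametric comparison exists twice: a **summary engine** working
from per-group $(n, \bar{y}, s)$ alone — so published tables can be
re-analysed without subject-level data — and a **raw engine** on
observations. For one-way ANOVA, $\mathrm{SSB} = \sum n_i(\bar{y}_i -
\bar{y})^2$ and $\mathrm{SSW} = \sum (n_i - 1) s_i^2$; the raw engine is
an ordinary linear-model fit, and the two agree to floating precision on
exact-moments data. Post hoc pairwise tests use the Tukey--Kramer
studentized-range form with $\sqrt{\mathrm{MSW}(1/n_i + 1/n_j)/2}$
denominators, valid for unequal group sizes.

Routing mirrors common practice for this kind of normative study: a
Shapiro--Wilk gate sends two-group comparisons to the pooled t test
(Student, the historical software default consistent with the published
p values; Welch by flag) or to the Mann--Whitney U (exact enumeration
when both $n \le 10$ and untied, tie-corrected normal approximation
otherwise). A Brown--Forsythe gate (Levene on absolute deviations from
group *medians*; mean-centred by flag) sends multi-group comparisons to
ANOVA + Tukey or to Kruskal--Wallis with Dunn's rank comparisons under
Bonferroni correction over all pairs — "Bonferroni correction" alone
does not fix the pairwise statistic, and Dunn's z on tie-corrected mean
ranks is the standard companion. Categorical baselines use Fisher's
exact test, enumerated (Freeman--Halton) up to a table total of 300 and
seeded Monte-Carlo beyond.

One reported inconsistency is handled by computing both sides: for the
right-medial age comparison the homogeneity footnote prescribes
Kruskal--Wallis while an F statistic is also printed. The pipeline's
gate decides per dataset at $\alpha = 0.05$, and the summary engine
always reports the ANOVA F, so both numbers are available.

Reports print p to three decimals with a `<0.001` floor, two-tier
markers (`*` 0.05, `**` 0.001), and pair labels written larger mean
first ("4 > 2"), with same-winner pairs compressed to "4 > (1,2)".
Thickness is printed to three decimals (table precision); full precision
is kept internally.

## Problem sizes in the tests

The test suite fixes its seeds and uses sizes chosen to keep sampling
error well inside the asserted tolerances: moment recovery averages five
cohorts of 10,000 subjects (the sample SD of a single cohort fluctuates
by about 0.7%, 1 sigma, at that size); ICC calibration runs 500 cohorts
of 100 x 3; the reliability-band emulation 200 cohorts of 232 x 3 across
the SEM% 1.3--2.3 grid; ANOVA type-I calibration 2000 null cohorts at
group sizes 56/70/47/59. Phantom discretisations (up to 2000 boundary
points) put polyline error an order of magnitude below the asserted
bounds; the piecewise-profile oracle test samples the boundary on a grid
containing the profile kinks so the polyline represents the continuous
band exactly.

## Known limitations

* Zones are image-axis slabs; strongly oblique probe placement changes
  what "lateral/medial" means. No reorientation is attempted.
* The area/length thickness is convention-laden on curved interfaces
  (the $t(1 + t/2R)$ effect above); comparisons across probes or widths
  should use one partition convention throughout.
* The mask tracer assumes one cartilage band per column; it cannot
  represent folded or fragmented segmentations.
* The cohort generator is Gaussian and homoscedastic by design; it does
  not emulate skewed reading errors, rater drift within a session, or
  subject-by-site interactions beyond the shared random effect.
* Rank-based post hoc results (Dunn) and Tukey results are not
  interchangeable; the gate can route two very similar datasets down
  different branches near $p = 0.05$.

## A worked example

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(profile = 3, width = 38.4))
measure_zones(ph$segmentation)      # 3.000 mm in all three zones

sp <- cohort_spec(data.frame(site = "lateral", mean_mm = 3.19),
                  between_sd = 0.30, within_sd = 0.05,
                  n_per_group = 232, seed = 7)
icc_reliability(make_cohort(sp), site = "lateral")

rep <- build_report()               # bundled normative tables
rep$rollups$overall_mm
rep$age_male[, c("side", "site", "F", "sig_pairs")]
```
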