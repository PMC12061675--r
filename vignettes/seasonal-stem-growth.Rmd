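---
title: "Modelling seasonal stem growth with the Richards function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal stem growth with the Richards function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemseason)
library(dplyr)
```

## The model

Stem elongation of a perennial grass over one growth season follows a
sigmoid course: near-zero length at emergence, a roughly exponential
acceleration, an approximately linear ("logarithmic") phase, and a
plateau as growth ceases. `stemseason` models each plant-year with the
four-parameter Richards (generalized logistic) function

$$y(x) = a\,\bigl(1 + b\,e^{-cx}\bigr)^{-1/d},$$

where $x$ is the day of year (or accumulated degree days on the
thermal-time axis), $a$ is the asymptotic stem length (cm), $c$ a rate
parameter (per $x$-unit), $d$ a shape parameter controlling the
asymmetry of the sigmoid, and $b$ a scale parameter that positions the
curve along the season. With $d = 1$ the Richards curve is the ordinary
logistic.

Fitting one smooth curve per plant converts an irregular series of field
measurements into a function-valued trait, from which six growth
characteristics are extracted analytically:

* **MaxGR** — maximum growth rate, the first derivative at the
  inflection: $a c (1+d)^{-(d+1)/d}$;
* **DayMaxGR** — its timing, $\ln(b/d)/c$;
* **StartLogG**, **EndLogG** — start and end of the logarithmic phase,
  taken at the extrema of the second derivative. Substituting
  $u = b e^{-cx}$, the third derivative vanishes at the roots of
  $u^2 - d(d+3)u + d^2 = 0$; the larger root maps to the phase start,
  the smaller to its end;
* **Duration** — `EndLogG - StartLogG`;
* **AUC** — the integral of the fitted curve over a season window, a
  proxy for cumulative seasonal growth.

Because the two quadratic roots multiply to $d^2$, the phase boundaries
are exactly symmetric about DayMaxGR on the $x$ axis — a useful internal
consistency check, enforced in the test suite after first confirming the
closed forms against finite-difference extrema located numerically.
Day-at-height, the $x$ at which a plant reaches a reference height such
as 15 cm, is the closed-form inverse
$x = -\ln\!\bigl(((a/h)^d - 1)/b\bigr)/c$.

## Fitting

`fit_richards()` performs bounded nonlinear least squares with
Levenberg–Marquardt (`minpack.lm::nlsLM`) per plant-year. Richards fits
are sensitive to initialization, so the first start is data-driven:
$a_0 = 1.05\max(y)$, $d_0 = 1$, $c_0$ from a log-linearized logistic on
the interior observations, and $b_0$ from the intercept of that
regression. If the first attempt fails, or leaves more than 5% of the
series variance unexplained, up to 20 restarts jitter $(b, c, d)$
log-uniformly (a factor of 4 in either direction).

Two bound choices deserve comment:

* the lower bound on $a$ is $0.5\max(y)$, not $\max(y)$: once the
  plateau is sampled, the largest *observation* overshoots the true
  asymptote about half the time under measurement noise, so a bound at
  $\max(y)$ would exclude the true parameter and bias the asymptote —
  and with it Duration — upward;
* the upper bound on $b$ is $10^8$: a plant with its inflection late in
  the season at a brisk rate has $b = d\,e^{c\,\mathrm{DayMaxGR}}$ in
  the millions, so a tighter bound silently forbids realistic short-
  duration, late-season curves.

A plant-year enters downstream analyses only if the fit converged, used
at least 6 observations, and reached $r^2 \ge 0.8$ (all configurable);
exclusions are logged with machine-readable reasons. DayMaxGR is
reported to the nearest day on the day-of-year axis as a reporting
convention (`write_traits()`); analysis keeps full precision.

## Thermal time

Daily degree days above a 10 °C base are computed from daily maximum
and minimum air temperature, by either the simple average method
(`max(0, (tmax+tmin)/2 - 10)`, the default) or the single-sine
(Baskerville–Emin) method, which models the day as one sine cycle and
takes the area above the threshold analytically, crediting
above-threshold hours on days whose mean is below base. No upper
threshold is applied. Missing weather days are a hard error rather than
silently interpolated, and `reexpress_series()` converts measurement
days to accumulated degree days so curves can be fitted on the
thermal-time axis.

## Quantitative genetics

For a trial of clonally replicated genotypes in randomized complete
blocks, `estimate_variance_components()` fits the random-effects model
$y = \mu + \mathrm{genotype} + \mathrm{block} + \varepsilon$ by REML
(lme4), with components constrained non-negative. Broad-sense
heritability is

$$H^2 = \frac{V_g}{V_g + V_e},$$

the block component deliberately excluded from the denominator, and the
per-plant (not entry-mean) error variance used. On balanced data the
REML estimates coincide with the classical expected-mean-squares
decomposition whenever all components are interior, which the test
suite exploits as an independent oracle.

Trait correlations are Pearson product-moment coefficients on
pairwise-complete observations with two-sided $t$-distribution
p-values, reported raw (no multiplicity correction). Species are
compared with a type-III ANOVA (sum-to-zero contrasts), appropriate for
the unequal species group sizes, followed by Tukey–Kramer HSD pairwise
tests compacted into letter groups by the insert-and-absorb algorithm;
letter assignment order is by group size, then name. The analysis unit
throughout is the individual plant (one record per genotype × block):
with clonal replication this matches the row counts of a diversity
trial, at the cost of treating within-genotype replicates as
exchangeable.

## Seasonal analyses

Faster-growing plants tend to grow for shorter periods, which confounds
any direct correlation between growth timing and yield. The binned
analysis controls this by grouping plants with similar Duration —
bins aligned to multiples of the bin width from day 0 (width 3–10 d;
10 d default), discarding bins with fewer than 10 plants — and testing
the correlation between the start of the logarithmic phase and dry
weight (or MaxGR) *within* each bin at $\alpha = 0.05$. On synthetic
populations where rate depends only on duration, the within-bin
correlation with phase start is centred on zero, confirming the
confound is removed.

The extremes table asks which species are the most likely source of
extreme trait values, adjusting for unequal group sizes: the highest
and lowest 5% of the ranked population (tail size rounded half-up,
ties broken by stable rank order) are expressed as a percentage of each
species' own membership. Two composite traits probe the rate–duration
tradeoff: the MaxGR:Duration ratio and the sum of the two traits'
ascending ranks (average on ties), whose high tail captures plants that
are both fast and long-growing.

Early-growth timing (day, or degree days, at 15 cm stem height) is
regressed on collection-site coordinates: one simple regression per
predictor (latitude, longitude, altitude, altitude squared) plus an
optional two-term latitude + altitude² model whose p-value is the model
F-test. The most significant predictor is flagged; `"none"` if nothing
reaches $\alpha$.

## The synthetic trial generator

No field data ship with the package; instead `simulate_trial()` builds
a trial-shaped dataset with known ground truth so that every stage can
be tested end to end. Design choices:

* **Trait-targeted construction.** Field studies report derived traits,
  not curve parameters, so the generator samples *traits* and solves
  the Richards parameters to hit them exactly: the shape $d$ is drawn
  per genotype (log-normal around 1, sdlog 0.25), then
  $c = \ln(u_+/u_-)/\mathrm{Duration}$ from the quadratic roots,
  $a$ from the target MaxGR, and $b$ from the target DayMaxGR. Targets
  implying parameters outside the fitter's box are rejection-resampled
  (capped), so every true plant is recoverable in principle.
* **Calibration.** Species-group means and SDs of MaxGR, DayMaxGR and
  Duration follow the published means and SDs for a large *Miscanthus*
  diversity trial (seven species groups with weights proportional to
  their genotype counts); a single additive shift per trait aligns the
  mixture mean exactly to the all-plants calibration targets
  (2.1 cm/d, day 181.4, 74.2 d). MaxGR and Duration are drawn
  independently within species; the well-known negative rate–duration
  correlation emerges between species (fast species grow briefly), but
  the within-species component of that correlation is not emulated.
* **Variance split.** Genotype effects carry a fraction $H^2$ of each
  trait's variance (defaults 0.77 / 0.66 / 0.65 for MaxGR / DayMaxGR /
  Duration), block effects are small (5% of the trait SD), and the
  remainder is plant-level environment. Species differences add
  genetic variance on top of the configured within-species split, so
  population-level $H^2$ of a structured population exceeds the
  configured value — intended, since species differences are heritable.
* **Measurement model.** Lengths are the true curve plus i.i.d.
  Gaussian noise (SD 2 cm, a realistic precision for a tape
  measurement to the ligule), truncated at zero; fortnightly
  measurements from day 92 to 302 cover emergence through plateau. An
  optional positive bias emulates recording the tallest of three
  sampled stems (off by default).
* **Harvest.** Dry weight is proportional to true AUC with 10%
  multiplicative noise; moisture content is a bounded logistic function
  of standardized EndLogG minus standardized MaxGR (late-growing plants
  wetter, fast growers drier), and subsample wet/dry weights are
  back-computed so the harvest arithmetic round-trips exactly.
  Alternatively, a planted within-duration-bin correlation between dry
  weight and phase start (and zero outside a duration range) provides
  ground truth for the binned analysis.
* **Geography.** Collection-site latitude shifts growth timing within
  species (0.5 d per degree by default), leaving species means intact.

What passing the recovery tests does *not* show about real data: the
generator draws normal trait distributions, exchangeable residuals and
a single year; real trials have skewed traits, spatial field trends,
year effects, and fit failures from drought or damage that no r²
filter fully captures.

## Numerical notes and limitations

* The curve, its derivatives and the inverse are evaluated on the log
  scale (`log1p`) so early-season values with $b$ in the millions do
  not overflow.
* AUC uses adaptive quadrature (`stats::integrate`, tolerance 1e-10)
  over a configurable window, day 0–365 by default; the integration
  window is a choice, not a property of the data, and AUC magnitudes
  scale with it.
* Refitted Duration carries a small upward skew that grows with
  measurement noise (about +0.2 d per cm of noise SD at the default
  schedule): duration is a convex function of the weakly identified
  shape $d$, so noise in $\hat d$ inflates its mean. Noiseless round
  trips recover parameters to 1e-6 relative.
* The restart loop stops once the fit explains 95% of series variance,
  so pathological series get the full multi-start budget without
  slowing the typical case.
* `sim_config()` seeds every stochastic routine from one integer;
  `run_pipeline()` is byte-deterministic given inputs, settings and
  seed.

## Problem sizes used in the checks

The bundled checks run a full trial of 900 genotypes × 3 blocks
(2,700 curve fits), 20 replicates of the binned-correlation regime at
the same scale, 60 balanced heritability simulations of 200 genotypes
× 3 blocks, and parameter sweeps of 500 random curves — sizes chosen to
estimate each quantity's sampling error well below the tolerance it is
compared at.
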