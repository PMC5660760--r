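---
title: "Methods: uncertainty budgets for emission-tomography calibration factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty budgets for emission-tomography calibration factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calibudget)
```

## The measurement model

Calibration of a quantitative SPECT or PET system ties the reconstructed
count rate per volume to an absolute activity concentration. The
decay-corrected calibration factor is modelled as

$$
S_{rc} = \frac{R}{V\,C_a}\,
  \exp\!\Big(\frac{(T_0 - T_{cal})\ln 2}{T_{1/2}}\Big)\,
  \frac{\ln 2}{T_{1/2}}\,
  \Big(1 - e^{-T_{acq}\ln 2 / T_{1/2}}\Big)^{-1},
$$

with $R$ the summed VOI counts, $V$ the VOI volume, $C_a$ the activity
concentration (directly assayed or $A/V_{liq}$), $T_0$ the acquisition
start, $T_{cal}$ the activity reference time, $T_{1/2}$ the half-life and
$T_{acq}$ the acquisition duration. Counts and volume are inputs here: VOI
segmentation, reconstruction and their corrections (attenuation, scatter,
dead time, partial volume) are upstream of this model and enter only
through the uncertainties a user assigns to $R$ and $V$.

Grouping the inputs as $X_1 = R/(V C_a)$, $X_2 = T_0 - T_{cal}$,
$X_3 = \ln 2 / T_{1/2}$, $X_4 = T_{acq}$ makes the four groups independent
whenever the underlying inputs are, and two dimensionless parameters
summarize the decay geometry:

$$
\alpha = X_2 X_3, \qquad \beta = X_3 X_4 > 0 .
$$

$\alpha$ may take either sign — assaying the activity after the scan is as
valid as before, and the decay correction then divides rather than
multiplies. $\beta$ is the acquisition duration in units of the decay time;
clinically it is small (a 20 min acquisition of Lu-177 gives
$\beta \approx 1.4\times 10^{-3}$).

`derive_terms()` returns these six quantities; `calibration_factor()`
evaluates the model.

## Propagation: three budget flavours

For independent inputs, first-order variance propagation of
$\ln S_{rc}$ gives

$$
u_{rel}^2(S_{rc}) = u_{rel}^2(X_1) + \alpha^2 u_{rel}^2(X_2)
  + c_3^2\, u_{rel}^2(X_3) + c_4^2\, u_{rel}^2(X_4),
$$

where the dimensionless sensitivity coefficients follow from
differentiating the log of the factorized model with respect to the log of
each group:

$$
c_3 = (1+\alpha) - \frac{\beta e^{-\beta}}{1 - e^{-\beta}}, \qquad
c_4 = -\frac{\beta e^{-\beta}}{1 - e^{-\beta}} .
$$

We verify these closed forms against central finite differences of the log
model on 1000 random $(\alpha, \beta)$ points with
$\alpha \in [-3, 3]$ and $\beta \in [10^{-6}, 2]$ as part of the test
suite; the agreement criterion is $10^{-6}$ relative. This derivative check
is the authoritative statement of the coefficients — the algebra is easy
to mistranscribe, the derivative is not.

Three budget constructors expose this machinery:

* `combined_exact()` — the full coefficients, valid at any $\beta$.
* `combined_simplified()` — the $\beta \to 0$ limit: $c_3 \to \alpha$,
  $c_4 \to -1$. Since $\beta e^{-\beta}/(1-e^{-\beta})$ deviates from 1 by
  about $\beta/2$, the dropped factor reaches the half-percent level on the
  $X_4$ coefficient at $\beta = 0.1$; budgets built beyond that attach a
  regime warning (condition class `calibudget_regime_warning`). The paper
  trail for the threshold: no universal cut-off exists for
  "$\beta$ reasonably small", so we fixed the point where the coefficient
  error crosses 0.5% and documented it rather than guessing per call.
* `combined_practical()` — the clinic-facing closed formula: quadrature
  sum of $u_{rel}(R), u_{rel}(V), u_{rel}(A), u_{rel}(V_{liq})$, plus
  $((T_0-T_{cal})\ln 2/T_{1/2})^2\,[u_{rel}^2(T_0-T_{cal}) +
  u_{rel}^2(T_{1/2})]$, plus $u_{rel}^2(T_{acq})$. This is algebraically
  the simplified budget with the concentration term expanded, and the test
  suite asserts the identity to $10^{-12}$ on randomized scenarios.

Budgets store contributions in variance space (squared relative
fractions) and convert to percent only for display; summing squared terms
and square-rooting once avoids double rounding. $c_4$ is kept signed — the
calibration factor decreases when the acquisition lengthens — but only its
square enters the sum; displays show the magnitude.

### The clock-offset identity

The $X_2$ term has a structure worth singling out. Its contribution
$\alpha^2 u_{rel}^2(X_2)$ expands to

$$
\Big(\frac{(T_0-T_{cal})\ln 2}{T_{1/2}}\Big)^2
\Big(\frac{u(T_0-T_{cal})}{T_0-T_{cal}}\Big)^2
= \Big(\frac{u(T_0-T_{cal})\,\ln 2}{T_{1/2}}\Big)^2 :
$$

the absolute time difference cancels. What matters is how well the two
clocks agree and how fast the nuclide decays — not how long one waits
between assay and scan (the point estimate of $S_{rc}$ of course still
depends on the wait). `clock_offset_contribution()` implements the
right-hand side directly, and `component_uncertainties()` therefore
accepts the offset uncertainty in absolute form (`u_offset`), which is
both the natural clinical statement ("clocks synchronized to 1 min") and
the only well-defined form when $T_0 = T_{cal}$. A relative form
(`u_rel_offset`) is accepted too; a property test sweeps the time
difference over two decades at fixed clock uncertainty and checks the
contribution constant to $10^{-12}$.

Because the scenario only ever uses the difference $T_0 - T_{cal}$, the
`calibration_scenario()` constructor stores a single `time_offset`
quantity rather than two timestamps.

## Component sub-models

**Voxelization** (`voxelization_volume_uncertainty()`). Delineating a VOI
on a voxel grid leaves the boundary uncertain by about one voxel across,
so $u(r) = \ell/2$ for voxel side $\ell$. Any VOI with a meaningful mean
radius satisfies $V = C r^3$, so the shape constant cancels and
$u_{rel}(V) = 3 u_{rel}(r)$ exactly. A 150 mm sphere on a 3 mm grid gives
$u_{rel}(r) = 1\%$, $u_{rel}(V) = 3\%$ — volume uncertainty at this level
is rarely negligible.

**Half-life registry** (`nuclide_registry()`,
`load_nuclide_registry()`). Adopted half-lives with their standard
uncertainties for F-18, Tc-99m, I-131, Lu-177, Y-90 and Ra-223, stored in
concise parenthetic notation (`"6.0067(10) h"`) in a plain TSV that a site
can override. The relative uncertainty is always recomputed from the
parsed value and uncertainty rather than stored, because published
rounded columns are occasionally truncations; tests compare the recomputed
values to the printed ones within one unit of the last printed digit
rather than asserting a rounding rule. All registry half-lives are below
0.3% relative — half-life knowledge is essentially never the limiting
term.

**Parenthetic notation** (`parse_parenthetic()`,
`format_parenthetic()`). The parenthetic digits are the standard
uncertainty in units of the last displayed decimal place. Malformed
strings are a parse error, never a silent zero uncertainty; format/parse
round-trips exactly.

**Calibrator guidance** (`calibrator_guidance()`). Recommended expanded
uncertainties ($k = 2$) for activity assay by instrument class and
emission class: field instruments 5% (photons > 100 keV, medium/high-energy
beta) or 10% (photons < 100 keV, low-energy beta); secondary-standard and
reference calibrators 2% and 5% for the same splits.
`expanded_to_standard()` divides by the coverage factor on ingestion so
the budget always works in standard uncertainties.

**Weighing** (`weighing_defaults`). Named magnitudes, not a model:
analytic balances 0.001%, large-capacity balances 0.05% relative.

**Counts.** $u_{rel}(R)$ is a direct user input — typically a VOI
coefficient of variation. No noise model is implemented: the factors
behind image noise (reconstruction, counting statistics, physics
corrections) are scanner- and protocol-specific, and any packaged formula
would lend false authority.

**Concentration.** When the concentration is composed as $A/V_{liq}$, the
product/quotient propagation rule gives
$u_{rel}(C_a) = \sqrt{u_{rel}^2(A) + u_{rel}^2(V_{liq})}$. A scenario or
component set declaring both $C_a$ and the $(A, V_{liq})$ pair is rejected
outright rather than merged — the double-counting that would silently
follow is precisely the kind of error a budget tool must refuse.

## Monte-Carlo cross-check

`mc_propagate()` draws every input from an independent normal
distribution centred on its estimate with its standard uncertainty,
evaluates $S_{rc}$ per draw, and reports the empirical mean and relative
standard deviation. Normality is the minimal distributional commitment
consistent with quoting standard uncertainties only, and is recorded in
the result. Draws that land non-positive on a positive quantity are
rejected and counted; more than 1% rejection aborts the run, since
truncating would bias the comparison silently and a budget comparison at
such spreads is meaningless anyway. Relative uncertainties are capped at
20% for the same reason. The seed is a mandatory argument, the global RNG
state is saved and restored, and identical inputs give bit-identical
results.

The acceptance suite runs 20 randomized scenarios with component
uncertainties up to 5% at $10^5$ draws each and requires the MC relative
SD to match the exact budget within 2% relative — roughly three standard
errors of the SD estimator plus the first-order linearization error. At
these spreads the model is locally close to linear in its inputs, which is
why first-order propagation is adequate clinically.

What the MC check does *not* show: it validates the propagation arithmetic
under the stated assumptions (independence, normality, small spreads), not
the realism of those assumptions for a given clinic. Correlated inputs —
say, a VOI volume error that co-moves with the counts through partial
volume effects — are outside both the budgets and the check.

## Sweeps

`halflife_sweep()` maps the combined uncertainty against half-life for a
family of clock-offset uncertainties, with the other components fixed at a
packaged clinical baseline: counts 4%, volume 2%, activity 2%, half-life
0.05%, acquisition duration 0.1%. The zero-offset curve is the flat
quadrature baseline $\sqrt{16 + 4 + 4 + 0.0025 + 0.01}\% \approx 4.90\%$;
non-zero offsets add $(u_{off}\ln 2/T_{1/2})^2$, so every curve decreases
strictly in the half-life, curves are ordered by $u_{off}$, and all
converge to the baseline as $u_{off} \to 0$. The practical reading: the
larger the ratio of clock uncertainty to half-life, the worse the
calibration — a 24 h assay-to-scan clock error on Y-90 (64 h) alone
contributes 26% and dominates everything else.

Two deliberate choices here. First, the sweep leaves the absolute time
offset unspecified — the offset term never needs it, and fixing one would
only feed the half-life term's $\alpha^2$ weight, which at 0.05% input
uncertainty is invisible; the half-life and acquisition terms are instead
carried at unit weight, the conservative bound, so the baseline is exactly
the quadrature sum above. With `method = "exact"` the acquisition term
gets its $\beta$-dependent coefficient instead (default $T_{acq}$ 15 min),
which changes nothing at plotting resolution. Second, the sweep functions
return tables and `autoplot()` renders them separately; nothing in the
computational path touches a graphics device.

Default grids are 200 log-spaced half-lives over 0.5–12 h (short-lived
regime) or 24–300 h (long-lived regime, via the `t_half_h` argument).

`approximation_error_map()` quantifies the exact-vs-simplified
disagreement over an $(\alpha, \beta)$ grid. The error vanishes as
$\beta \to 0$ and grows along $\beta$ for moderate $\alpha$; at large
positive $\alpha$ the two curves cross and the absolute error dips through
zero, so monotonicity is asserted only where grid evaluation confirms it.

## Numerical choices

* **Canonical time unit.** All times are converted to seconds on
  ingestion. Published half-lives mix hours and days in one table;
  converting once at the boundary removes the classic silent h/d mix-up.
* **`expm1`.** $1 - e^{-\beta}$ is evaluated as `-expm1(-beta)` so that
  $\beta$ down to $10^{-8}$ and below keeps full relative precision; the
  test suite checks stability and the convergence of $S_{rc}$ to
  $X_1 e^{\alpha} / X_4$ at small $\beta$. $\beta = 0$ exactly (zero
  acquisition duration) is a domain error, not an infinity.
* **Finite-difference verification.** The derivative oracle uses a
  central difference with step $10^{-6}$ of the log model, itself
  evaluated with `expm1` to keep the oracle's roundoff at the $10^{-10}$
  level — the independence of the check lies in the differencing, not in
  re-deriving elementary functions badly.
* **Report precision.** JSON reports carry every numeric field at 17
  significant digits (the shortest decimal form that round-trips an IEEE
  double exactly) alongside a 2-significant-digit display column per the
  GUM reporting convention. `read_budget_report()` reconstructs the budget
  bit-exactly from the full-precision channel.
* **Validation errors vs I/O errors** are distinct condition classes
  (`calibudget_validation_error`, `calibudget_io_error`), which the CLI
  maps to distinct exit codes (2 and 4; other computation errors exit 3).

## Problem sizes in the shipped checks

The test suite uses 1000 random points for the derivative oracle, 200
random scenarios for the model-equivalence property, 100 for the
practical-equals-simplified identity, 20 scenarios × $10^5$ draws for the
Monte-Carlo comparison, and 200-point grids for the sweep properties. The
full suite runs in well under a minute on a single CPU.

## Limitations

* Independence of inputs is assumed throughout; no correlated propagation.
* Standard uncertainty only; no coverage intervals or effective degrees of
  freedom.
* First-order propagation: adequate for the ≤ 20% spreads the tool
  accepts, checked by Monte Carlo within that envelope, and unsuitable
  beyond it.
* No image I/O, segmentation or reconstruction modelling — counts and
  volumes arrive with their uncertainties already assessed.
* The registry ships six nuclides; anything else needs an override file or
  an explicit half-life.
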