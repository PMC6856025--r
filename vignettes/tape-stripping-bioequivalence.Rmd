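---
title: "Methods: dermatopharmacokinetic bioequivalence from stratum corneum sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dermatopharmacokinetic bioequivalence from stratum corneum sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpkbe)
```

## The measurement and its model

Tape-stripping samples the stratum corneum (SC) — the outermost skin layer
and the permeability barrier — by sequential adhesive strips after topical
application of a drug product. The two-time-point dermatopharmacokinetic
(DPK) protocol implemented here measures the areal drug amount in the SC
twice: `Q_up` at the end of an application ("uptake") period of `t_up`
hours (6 h by default), and `Q_cl` after a further clearance interval of
`delta_t` hours (17 h) during which the formulation has been removed and
drug drains into the viable tissue. Each product is applied to `nr`
replicate sites (duplicates by default) in each of `n` subjects, and a
reference product is typically applied twice so that the duplicated arm
acts as a positive control.

From the two amounts the package derives, per subject and product:

* the clearance flux into viable tissue,
  `J = (Q_up - Q_cl) / delta_t` (reported in ng cm^-2 h^-1; amounts are
  carried in ug/cm^2 and the factor 1000 is applied only at reporting);
* the first-order clearance rate constant,
  `k = -ln(Q_cl / Q_up) / delta_t` (h^-1).

Both can legitimately be negative when measurement variability makes
`Q_cl > Q_up`; negative values propagate unmodified into averages and
paired tests. The two metrics are linked by the exact identity
`J = Q_up [1 - exp(-k delta_t)] / delta_t`, which the test suite checks at
random inputs. Note that `k` is an instantaneous fractional rate: at
`k = 0.3` h^-1 the fraction leaving in one hour is `1 - exp(-0.3)`
(about 26%), not 30%; the package implements the exact exponential
reading throughout.

## Per-site processing

**Amount with LOQ handling.** A site's amount is
`Q = sum_g c_g V / A` over its tape groups, where `c_g` is the extract
concentration, `V` the extraction volume (3.6 mL) and `A` the sampled area
(5 cm^2). Groups below the assay limit of quantification (LOQ,
0.038 ug/mL by default) contribute zero — the conservative reading of the
substitution rule, which is documented only for the all-below case. A site
in which *every* group is below the LOQ receives half the areal LOQ,
`(LOQ V / A) / 2 = 0.0137` ug/cm^2 at the defaults, so that Q stays
log-transformable. A concentration exactly at the LOQ counts as
quantified. The first tape strips, conventionally extracted individually,
are ordinary groups of size one with no special weighting.

**Stopping rule.** Stripping of a site stops when the latest
transepidermal water loss (TEWL) reading reaches 60 g m^-2 h^-1, exceeds
6 times the pre-stripping baseline, or when 30 tapes have been removed.
The decision is order-independent; for reporting, the triggered criterion
is named in that fixed order (absolute limit, baseline multiple, tape
count).

**Mass and thickness.** SC mass per area converts to an apparent thickness
through the assumed SC density (1 g/cm^3): 1 mg/cm^2 corresponds to 10 um.

**Depth profiles.** Depth is expressed as the fraction of the *collected*
SC — the total SC thickness of a site is unknown — with segment widths
proportional to per-group SC mass and local concentrations equal to group
drug mass over removed SC volume.

## Bioequivalence assessment

Drug amounts in the SC are treated as log-normal. With per-subject
geometric means over replicate sites, `d_j = ln(test_j) - ln(ref_j)`:

* **ABE.** `GMR = exp(mean d)` with the 90% interval
  `exp(mean d ± t_{0.95, n-1} sd(d)/sqrt(n))`; the products pass when the
  interval lies within `[1/m, m]`. The margin `m` is a parameter with
  presets 1.25 (the accepted standard) and 1.33 (supported for
  sensitivity analyses only). On complete paired data the GMR estimate
  equals the ratio of product-level geometric means exactly (the pairing
  identity), which is how the worked examples reproduce published ratios
  from product-level means alone.
* **Reference variability.** `s_WR` is the closed-form replicate estimator
  `sqrt( sum_jk [ln Q_jk - ln Qbar_j]^2 / (n(nr-1)) )` (natural logs);
  a reference with `s_WR > 0.294` (strict inequality) is highly variable,
  which motivates scaling.
* **SABE.** The linearised scaled criterion is
  `eta = Delta^2 - s_WR^2 (ln m / 0.25)^2`. Its 95% upper confidence bound
  is assembled by Howe's approximation — the construction used for
  replicate-design and in-vitro permeation data — from a t-based 95% upper
  limit on `|Delta|` and a chi-square 95% lower limit on the
  within-subject variance (degrees of freedom `n(nr-1)`). The scaled
  assessment passes when `SCl_UB <= 0` *and* the point GMR lies in
  `[1/m, m]`.

Because no subject-level data are published for the motivating studies,
the SABE bound is validated by Monte-Carlo calibration rather than by
matching printed tables: at the scaled-criterion boundary
`|Delta| = s_WR ln(m)/0.25` the `SCl_UB <= 0` event occurs at close to its
nominal 5% rate (measured ~4.7% at n = 10, nr = 2 — Howe's bound is known
to be slightly conservative at small degrees of freedom). At that boundary
the GMR point constraint rejects almost surely (the boundary shift exceeds
`ln m` whenever `s_WR > 0.25`), so the calibration is a statement about
the bound alone; `power_scenario(criterion = "scaled_bound")` exposes
exactly that event. The TOST-style ABE size approaches 5% at its boundary
only where the interval can fit inside the limits at all, so the ABE
calibration runs at a small within-subject SD (0.15 with 12 subjects);
at high variability (sigma_WR = 0.6, n = 10) the boundary pass rate is
essentially zero by construction.

Subjects with missing cells are dropped listwise per comparison with a
warning. No outlier exclusion is performed, and no mixed-model variance
estimation: the replicate estimator above is the estimator.

## Power simulation

Trials are simulated from the log-scale variance-component model
`ln Q_{product,j,k} = mu + ln(GMR) 1[test] + S_j + eps_jk` with
`S_j ~ N(0, sigma_S^2)` shared by both products within a subject and
independent site noise `eps_jk ~ N(0, sigma_W^2)` (the test product's
within-subject SD defaults to the reference's). Because every statistic
used by either decider is a within-subject contrast or a within-subject
deviation, the subject effect cancels algebraically; the simulator
exploits this for speed without changing any distribution. Power is the
fraction of trials the chosen decider passes; curves carry binomial
Monte-Carlo standard errors, are deterministic given the master seed, and
use per-`n` derived seeds so grid points are reproducible independently.
The default 10,000 trials give a standard error under 0.5 percentage
points, sufficient for every property tested; production-scale runs
(e.g. 500,000 trials) are a parameter away.

Under these conditions (sigma_S = 0.4, sigma_WR = 0.6, GMR = 1,
m = 1.25) SABE reaches 80% power with roughly half the subjects ABE
needs, and moving from duplicate to triplicate sites reduces the required
subjects appreciably (17 to 12 on the default grid) — the size of that
replicate benefit depends strongly on the ratio of within- to
between-subject variability, so it is treated as a directional, not
numeric, property.

## The diffusion model and the C* chain

The SC is modelled as a homogeneous slab. During uptake the surface
concentration is constant (formulation present) and the inner face is a
perfect sink (viable tissue); during clearance the outer face carries zero
flux (formulation removed) and the sink remains. Time is scaled by the
diffusional lag time `t_lag = L^2/(6D)`. The relative membrane load
`u(tau) = Q/Q_ss` and the retained fraction
`W(tau_up, tau_cl) = Q(t_up + delta_t)/Q(t_up)` are eigenfunction series
(terms truncated at 1e-12 relative magnitude, capped at 10^4 terms; the
semi-infinite short-time law `(4/sqrt(pi)) sqrt(tau/6)` replaces the
series below `tau = 1e-4`). An independent finite-difference solver of the
same boundary-value problems (`fd_uptake_fraction()`,
`fd_clearance_fraction()`) agrees with the series to better than 0.5%
over `tau` in [0.01, 5] and exists precisely to keep that cross-check in
the test suite. These boundary conditions were selected over the
alternatives (sink at both faces, swapped faces, simplified initial
profiles) because only they reproduce the published worked example.

`fit_lag_time()` inverts `W = Q_cl/Q_up` for `t_lag` by bracketed
root-finding on [0.1, 1000] h (relative tolerance 1e-6), then
extrapolates: `F = 1/u(t_up/t_lag)`, `Q_ss = F Q_up`, and
`J_ss = Q_ss/(3 t_lag)` — the steady-state slab identity, which holds
exactly in every fit. A site where clearance did not reduce the amount
(`W >= 1`) returns a diagnostic no-fit result rather than an error. For
the published mean amounts (0.87 and 0.69 ug/cm^2) the fit gives
`t_lag = 18.5` h, `F = 1.91`, `J_ss = 29.9` ng cm^-2 h^-1; the published
values (18.9 h, 1.93, 29.6) correspond to the same model evaluated at the
unrounded amounts — the two-decimal rounding of the inputs spans
`W` from 0.783 to 0.803 and hence lag times from 17.7 to 19.2 h.

The C* concept converts a flux into a concentration at the site of action
(the basal epidermis for an antiviral such as acyclovir): `C* = J/P_D`,
with the clearance permeability `P_D = D_D/h_D`. The dermal diffusivity
`D_D` comes from either of two empirical molecular-weight correlations
(`log10 D = -4.15 - 0.655 log10 MW` or `-4.38 - 0.207 MW^(1/3)`, D in
cm^2/s); their arithmetic mean with a diffusion path of 100 um gives
`P_D = 0.78` cm/h, and a flux of 10.3 ng cm^-2 h^-1 maps to
`C* = 13` ng/mL. The molecular weight of acyclovir is taken as 225.2 Da.
A microperfusion (dOFM) measurement cross-checks the flux arithmetic:
perfusate flow times concentration over the probe's planar projection
(15 mm x 0.5 mm = 0.075 cm^2).

## The synthetic-study generator

The generator is first-class, tested code; it exists because no raw
subject-level data are publicly available for studies of this design. It
emulates:

* log-normal per-site amounts with subject (`sigma_S = 0.4`) and
  within-subject site (`sigma_W = 0.6`) variance components at the
  magnitudes of a real acyclovir study (reference uptake geometric mean
  0.65 ug/cm^2, highly variable reference);
* product effects as true GMRs (default: reference, positive control at
  GMR 1, test at GMR 0.6);
* clearance amounts derived from the diffusion model at a true lag time
  of 18.9 h (retained fraction ~0.80), so kinetic and diffusion stages
  have a recoverable ground truth; a pure log-normal clearance mode with a
  fixed retained fraction serves statistics-only tests;
* tape-level records: a Poisson tape count (capped at 30), per-tape SC
  masses declining geometrically with depth, leading tapes extracted
  individually and the rest grouped in twos to eights, the site's drug
  distributed over depth according to the series concentration profile at
  the sampling time, and extract concentrations that may fall below the
  LOQ for low-amount sites (the analysis side applies the censoring).

What the generator does *not* emulate — and what green tests therefore do
not demonstrate about real data: assay error beyond the log-normal site
noise, correlation between SC mass removed and drug recovered, incomplete
SC collection, product-by-subject interactions, or TEWL dynamics (tests
construct simple TEWL sequences directly). Parameter recovery on
synthetic data shows the estimators are consistent under the model's own
assumptions, nothing more.

## Numerical and design choices

* Canonical units: amounts ug/cm^2, SC mass mg, thickness um, time h,
  flux ng cm^-2 h^-1 (factor 1000 at the flux boundary only), diffusivity
  cm^2/s with an explicit 3600 conversion inside `permeability_p_d()`.
  These match how such results are conventionally tabulated and avoid
  silent rescaling.
* Product roles (reference/test/positive control) are analysis
  configuration, not data: the same product can be reference in one study
  and test in another, so codes are free strings.
* Problem sizes in the test suite: 20,000 trials for decider calibration
  (3-MC-SE band ±0.46 percentage points around 5%), 1,500–5,000 trials
  for directional power properties, 500 subjects for parameter recovery,
  200 seeded runs for the replicate-estimator sampling-law check; the full
  suite runs in well under a minute of simulation time.
* Residual-product weighing (applied-dose accounting) is metadata only; it
  enters no computation.
* `paired_difference_test()` flags the zero-variance degenerate path
  (identical differences) instead of dividing by zero, returning a point
  interval and a 0 (shift) or NA (identity) p-value.

## Known limitations

* The clearance rate constant is a fitted parameter of a single-exponential
  model whose full validation is open; the flux is model-independent and
  is the preferred comparison metric.
* The SABE bound's small-sample size is slightly conservative (~4.7% at
  10 subjects); this is a property of Howe's approximation, not of the
  implementation.
* The diffusion model assumes a homogeneous SC with a perfect inner sink;
  F and J_ss inherit those assumptions and the lag-time inversion is only
  as good as the two measured amounts.
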