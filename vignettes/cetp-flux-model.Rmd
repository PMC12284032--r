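---
title: "Modeling postprandial CETP-mediated triglyceride redistribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling postprandial CETP-mediated triglyceride redistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetpflux)
```

## The problem

After a fat-rich meal, plasma triglyceride (TG) rises transiently as
intestinally derived chylomicrons (CM, carrying one ApoB-48 each) and
hepatically derived VLDL (one ApoB-100 each) flood the circulation.
Cholesteryl ester transfer protein (CETP) continuously shuttles neutral
lipids among all lipoprotein particles: one TG or cholesteryl ester (CE) in
each direction per encounter, a diffusion-like equimolar heteroexchange. The
net effect is a TG stream from the TG-rich lipoproteins (TRL = CM +
VLDL + chylomicron remnants) into LDL and HDL, with CE flowing back.

`cetpflux` implements this pipeline end to end:

1. **Chylomicron quantification** from two-chamber ultracentrifugation
   (`cm_profile()`), recovering the CM-associated concentration of every
   measured component from inner/outer chamber measurements.
2. **Particle geometry** (`fraction_surface()`): particle counts, radii and
   total surface area per litre of plasma for each fraction.
3. **Flux modeling** (`instantaneous_tg_flux()`, `integrate_exchange()`):
   CETP-mediated TG net fluxes driven by the surfaces and the core
   composition gradient, calibrated against measured 1-hour TG
   redistribution (`calibrate_k()`).
4. **Cohort statistics** (`wilcoxon_signed_rank()`, `spearman_rho()`,
   `table1_analysis()`): paired fasting/postprandial changes and the ApoC3
   redistribution analysis.
5. **Synthetic data** (`generate_cohort()`): a ground-truth generator so
   every stage is testable without patient data.

## The spillover correction

During the two-chamber spin, all buoyant CMs float from the plasma-filled
outer chamber (volume $v_{out} = 2.6$ ml) into the saline-filled inner
chamber ($v_{in} = 0.9$ ml), dragging some plasma along. ApoA1 does not
travel with CMs, so the inner/outer ApoA1 ratio
$D = c_{in}(\mathrm{ApoA1}) / c_{out}(\mathrm{ApoA1})$ measures the plasma
spillover. For any component $X$ the CM-associated concentration on the
original plasma scale is

$$ g_{b,OC}(X) \;=\; F\,\big(c_{in}(X) - D\, c_{out}(X)\big),
   \qquad F = v_{in}/v_{out} = 0.9/2.6 . $$

This inversion is algebraically exact: for any noise-free forward
simulation (`simulate_airfuge()`), `cm_profile()` recovers the true CM
composition to floating-point precision, and it is unbiased under 2%
multiplicative measurement noise (both are acceptance tests).

Raw corrected values can dip below zero for components that are essentially
not CM-associated (noise on a near-zero difference). The default policy
clips them to zero and records the component in the `clipped` set; `keep`
and `error` policies are available. Spillover coefficients above 0.5 (or
above 1, which is physically impossible) trigger warnings.

## Particle geometry

Each fraction is treated as a monodisperse population of spheres.
ApoB-containing fractions carry exactly one ApoB per particle, so the molar
particle concentration is the ApoB mass over the isoform molar mass
(ApoB-48, 246 kDa, for CM; ApoB-100, 512.7 kDa, elsewhere). HDL particles
are counted via ApoA1 assuming 3 copies per particle (configurable; a
per-subfraction reference-diameter mode was considered and rejected as it
requires inputs the pipeline does not have).

The per-particle volume sums the molecular volumes of the lipid pools
(defaults: TG 1.61, CE 1.17, free cholesterol 0.64, phospholipid 1.26 nm³)
plus protein mass times a partial specific volume of 0.73 ml/g; the radius
and total surface follow from sphere geometry:

$$ V_p = \sum_X \frac{c_X}{N}\,v_X + \frac{m_{prot}}{N\,N_A}\,\bar v_{prot},
   \quad r = \Big(\tfrac{3V_p}{4\pi}\Big)^{1/3},
   \quad S = N\,N_A\,4\pi r^2 . $$

These constants are literature defaults exposed in the configuration; with
them, typical compositions give LDL radii near 9–10 nm and HDL radii near
4 nm. Free cholesterol is counted in the particle volume only (no explicit
core/shell partition), and the whole particle is one sphere with no
monolayer-thickness term — sufficient because the flux model consumes only
surface ratios. Missing ApoC/ApoE masses contribute zero protein volume
(silently; a per-call warning would flood cohort loops).

**Unit care.** With lipids in mmol/l and counts in nmol/l, molecules per
particle are $(c_X/N)\times 10^6$ — a factor that is easy to get wrong by
10³ and that moves all radii by a factor 10. The test suite freezes a
hand-computed example (N = 1 nmol/l, lipids 0.5/1.0/0.3/0.7 mmol/l →
$V_p = 3.049\times10^6$ nm³, r = 89.95 nm, S = 61.24 m²/l) against the
implementation.

## The flux model

The model uses only two parameters per fraction: the total surface $S_i$
and the core TG ratio $r_i = \mathrm{TG}_i/(\mathrm{TG}_i+\mathrm{CE}_i)$.
Encounters between fractions $i$ and $j$ occur at a rate proportional to
$S_i S_j / S_{tot}$; each encounter swaps one neutral lipid drawn from each
core (TG with probability $r$). The mean-field TG net flux into fraction
$i$ is

$$ J_i \;=\; k \sum_{j\neq i} \frac{S_i S_j}{S_{tot}}\,(r_j - r_i)
      \;=\; k\, S_i\,(\bar r_S - r_i),
   \qquad \bar r_S = \frac{\sum_j S_j r_j}{S_{tot}} , $$

in µmol/l per hour, with $k$ in (µmol/l/h) per (m²/l). This bilinear,
ratio-gradient kernel is the minimal form that is diffusion-like,
surface-driven, zero at equal ratios and exactly conservative
($\sum_i J_i = 0$ analytically); the per-fraction CE flux is its exact
negative (equimolar heteroexchange). The kernel sits behind a single
interface so alternatives can be swapped. An event-level stochastic shuttle
simulator (in the test suite, kept independent of the package code path)
confirms the mean-field expression to Monte-Carlo precision.

Five pools enter the discriminating configuration (CM, VLDL+CMR, IDL, LDL,
HDL) and four the nondiscriminating one (merged TRL, IDL, LDL, HDL).
LDL/HDL subfractions feed statistics only, and lipid-deficient serum is
excluded as a CETP pool.

### Calibration and time integration

The measured 1-h TG deltas (37 °C vs 4 °C incubation) are taken as the
CETP-mediated redistribution. With unit-rate fluxes $J^{(1)}$ over the
measured fractions, least squares through the origin gives
$k = \sum J^{(1)}_i \Delta_i / \sum (J^{(1)}_i)^2$, computed per subject
and state. When the model discriminates CM from VLDL+CMR but the
measurement covers only the merged TRL, the two unit fluxes are summed for
that residual. Optional zero-sum renormalization of the deltas is off by
default. A negative fitted $k$ (redistribution opposing the gradient)
warns.

The default mode is linear — instantaneous flux × 1 h — matching the
per-hour reporting of the method. An `ode` mode integrates
$\dot{\mathrm{TG}}_i = k S_i (\bar r_S - r_i(t))$ with
$\mathrm{CE}_i = T_i - \mathrm{TG}_i$ and surfaces held fixed
(composition drift over one hour is second-order for geometry), using
fixed-step classical RK4. A two-pool system has the closed form
$\mathrm{TG}_1(t) = \mathrm{TG}_1^{eq} + (\mathrm{TG}_1(0) -
\mathrm{TG}_1^{eq})\,e^{-\lambda t}$ with
$\lambda = k\,\frac{S_1 S_2}{S_{tot}}(1/T_1 + 1/T_2)$; the integrator
matches it to $10^{-6}$ at dt = $10^{-3}$ h (acceptance test). The system
relaxes to the common ratio $r = \sum \mathrm{TG} / \sum(\mathrm{TG} +
\mathrm{CE})$ (`equilibrium_ratio()`), the near-steady state seen in
hyperchylomicronemia, where predicted fluxes are near zero. Steps that
would drive a pool negative abort with a suggested smaller dt.

### Discriminating vs nondiscriminating configurations

Classical density-gradient ultracentrifugation yields one TRL fraction;
the Airfuge correction splits it into CM and VLDL+CMR.
`compare_model_configs()` runs both configurations under a shared
(default) or per-configuration rate constant and reports relative flux
differences for IDL, LDL and HDL.

Geometrically, treating two populations with different radii as one
monodisperse population overestimates the surface: with counts fixed, the
merged surface is $N \bar v^{2/3}$ against $\sum N_i v_i^{2/3}$, and
concavity of $v^{2/3}$ (power-mean inequality) makes the merged value
larger, with equality only at equal radii. Consequently the
nondiscriminating model slightly overestimates the net TG flux into LDL
and HDL (signed $J^{nondisc} \ge J^{disc}$ on every default postprandial
draw — the signed form is the robust one: on rare draws where HDL happens
to be a net TG donor the magnitude comparison inverts while the signed
one does not).

**A counting subtlety.** The inequality is a theorem only at *fixed
particle counts*. Counting the merged TRL ApoB mass entirely with the
ApoB-100 molar mass — as one must when no CM split exists — loses the
lighter ApoB-48 copies (factor 2.08) and can undercount by enough to
reverse the comparison. The nondiscriminating arm therefore uses a
count-preserving merge (`merged_trl_geometry()`: merged N = N(CM) +
N(VLDL+CMR), each with its own isoform) whenever the split is known; a
TRL measured without a split falls back to ApoB-100 counting.

## The synthetic generator

`generate_cohort()` draws fasting compositions from independent
log-normals around phenotype-specific medians and builds the postprandial
state by multiplicative shifts. The defaults are a *stated world*, chosen
once to satisfy the cohort-level ratios the method was characterized with,
and not revisited:

* normolipidemic fasting medians give CM TG ≈ 9.8% of TRL TG and ≈ 6% of
  total TG; CM ApoB 27.5 nmol/l ≈ 1.6% of total ApoB and ≈ 13% of TRL
  ApoB; total TG ≈ 1 mmol/l;
* postprandial CM multipliers PL ×4, FC ×7, TG ×8 (so CM TG reaches
  ≈ 31% of TRL TG); all VLDL+CMR components up (ApoB ×1.5, more than CM's
  ×1.3); all LDL components except TG down; HDL TG up, CE down; ApoC3
  moves from HDL to the TG-rich fractions;
* HTG subjects land slightly above 2 mmol/l total TG, hyperchylomicronemia
  (FCS) subjects above 35 mmol/l with CM-like VLDL+CMR composition; FCS
  subjects are fasting-only by default (no postprandial sampling in that
  group);
* the spillover coefficient is uniform on [0.05, 0.3] per subject; the
  exchange rate constant is uniform on [0.2, 0.35] (µmol/l/h)/(m²/l),
  centred on the value (≈ 0.27–0.30) that reproduces fasting fluxes of
  ≈ 22% of HDL TG and ≈ 11% of LDL TG per hour at the median subject;
* between-subject lognormal CVs are 0.25 (lipids) and 0.20
  (apolipoproteins); multiplier jitter has sdlog 0.05, the largest round
  value that keeps the stated postprandial directions — including all
  three non-TG LDL components jointly falling — in ≥ 95% of subjects;
  measurement and incubation noise are 2% multiplicative (mean-1
  lognormal);
* CM ApoB is left-censored at 18 nmol/l (reported at the limit; the
  ground truth keeps the uncensored value).

What the generator does **not** emulate: real between-fraction covariance
(components are independent log-normals; a shared lipemia factor is
available as an option for power studies), separation losses,
detection-limit behaviour of other assays, ultracentrifugation physics, or
clotting at extreme TG. A green test therefore establishes correctness of
the algorithms on data with the stated marginal structure, not calibration
to any particular laboratory.

Two printed cohort ratios are deliberately not matched: the measured CM
ApoB (27.5 nmol/l) together with the CM lipid levels implies fasting CM
radii near those of large VLDL, so the generated postprandial VLDL-to-CM
surface ratio is ≈ 4 rather than the reported ≈ 2.4, and the "40% more
likely to mediate a net flux" statement has no operational definition and
is not reproduced. The TG/ApoB share constraints were prioritised.

## Statistics

Paired changes use the exact Wilcoxon signed-rank test: zeros dropped
(classical convention), average ranks for ties, the full $2^n$ null
distribution via the shift algorithm for $n \le 25$ (doubled ranks keep
half-integer average ranks integral), and a tie-corrected,
continuity-corrected normal approximation above. The two-sided p value is
$\min(1,\, 2\min(P(W^+ \le w),\, P(W^+ \ge w)))$ — for 12 uniformly
positive differences, $p = 2/4096$. An independent enumeration oracle
checks every $n \le 10$ case in the test suite.

Spearman correlations are Pearson correlations of average ranks with exact
permutation p values below $n = 10$ and the t approximation otherwise.
The ApoC3 redistribution ratio is
$\Delta \mathrm{HDL}_{ApoC3} / (\mathrm{HDL}_{ApoC3} +
\mathrm{VLDL}_{ApoC3})$; the denominator state (fasting by default) and
whether "VLDL" includes CM (not, by default) are ambiguous in the source
description, so both are options and neither is claimed as the original
choice. `table1_analysis()` correlates the ratio against seven
delta-parameters, unadjusted for multiplicity by default (mirroring the
original reporting; Benjamini–Hochberg available), sorted by |rho|.
Summaries report quartiles throughout.

## Numerical and design notes

* **Exclusion rule.** Subjects whose total TG changes by < 20% between
  states are flagged with a warning, not dropped — downstream stages take
  explicit include lists.
* **Validation.** `validate_dataset()` reports (never throws): negative
  concentrations and TRL ≠ CM + VLDL+CMR are errors; FCS phenotype,
  single-state subjects, and LDL subfraction ApoB sums deviating > 10%
  from the parent (separation losses) are warnings.
* **Round-tripping.** The long CSV layout (one row per subject, state,
  fraction, component) round-trips numerically to 1e-9; units are
  normalized on read (mmol/l for lipids, g/l for apolipoproteins,
  cholesteryl ester derived as total minus free cholesterol when given
  that way).
* **Float dust.** `split_trl()` zeroes negative remainders below 1e-12 of
  the component scale silently (exact cancellations land there);
  larger negatives follow the clip/keep/error policy with a warning.
* **Determinism.** All randomness flows from a single integer seed;
  identical configuration + seed gives byte-identical CLI outputs.

## Limitations

The flux kernel is a reconstruction from stated properties, not the
original closed-source formula; absolute rate constants are therefore
meaningful only relative to this kernel's normalization. Surfaces are held
fixed during integration, lipolysis and particle interconversion (IDL→LDL
drift) are out of scope, and CE fluxes are reported only as the negative
of TG fluxes. The acceptance tier that would compare against the printed
cohort numbers requires the study's per-sample supplemental data, which is
not publicly deposited; the package's guarantees are the property-based
tier computed by `tests/testthat/test-acceptance.R`.
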