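---
title: "Bending rigidity of planar bilayers from voltage-dependent capacitance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bending rigidity of planar bilayers from voltage-dependent capacitance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrobend)
```

## The measurement and the model

A free-standing planar bilayer separates two aqueous chambers; its
hydrophobic acyl-chain core (relative permittivity $\varepsilon_r \approx
2.5$) behaves as a parallel-plate capacitor,
$$C = \frac{\varepsilon_0 \varepsilon_r A}{d},$$
so simultaneous capacitance and (imaged) area measurements determine the
hydrophobic thickness $d$.  An applied potential $\psi$ exerts a compressive
Maxwell stress on the film.  Two things happen at once:

1. the film **thins** (electrostriction), and
2. in oil-stabilised films the **area grows**, because lipid and solvent are
   recruited from the Plateau border annulus surrounding the bilayer.

Both raise the measured capacitance.  Treating the measured $C(\psi)$ as if
it reflected thinning alone therefore misattributes the area contribution
and biases the inferred stiffness low.  Unlike vesicles, these films can
change area by tens of percent, so the effect is not negligible.

### The constant-volume correction

Writing the membrane volume $V = A\,d$, the capacitance can be recast as
$C = \varepsilon_0\varepsilon_r V / d^2$.  From the zero-field state
($C_0$, $A_0$, hence $d_0$ and $V_0 = A_0 d_0$), each voltage step's
thickness $d_\psi$ is measured from its own $C$ and $A$, and the
**constant-volume capacitance**
$$C_\psi^{(V_0)} = \frac{\varepsilon_0\varepsilon_r V_0}{d_\psi^2}$$
is the capacitance the membrane would have shown had only its thickness
changed.  When the membrane actually conserves volume the correction is a
no-op ($C_\psi^{(V_0)} = C_\psi$ identically); the package's tests exercise
exactly this nullity.

### From capacitance to elastic moduli

The voltage-dependent capacitance follows the quadratic law
$C_\psi = C_0(1+\alpha\psi^2)$.  We fit $C_\psi^{(V_0)}$ against $\psi^2$ by
ordinary least squares with a free intercept, pooling positive and negative
polarities, and convert the slope $m$ via
$$\alpha = \frac{m}{3\,C_0}, \qquad
  E_\perp = \frac{C_m}{\alpha\, d_0}, \qquad C_m = C_0/A_0 .$$
Thin-plate linear elasticity (Poisson ratio $v$) then gives
$$K_A = \frac{E_\perp d}{1-v}, \qquad
  k_c = \frac{K_A d^2}{24(1+v)}
      = \frac{E_\perp d^3}{24(1-v)(1+v)},$$
which at the default $v = 1/2$ reduces to $k_c = E_\perp d^3/18$.  The
zero-field thickness $d_0$ is used throughout the elasticity conversion.

The classical estimator $E_\perp = C_m\psi^2/(2\Delta d)$, which assumes the
area is constant, is computed alongside (as a regression of $\Delta d$ on
$\psi^2$ for noise robustness, plus per-step values).  On a
volume-growing membrane the two estimators differ systematically: expanding
the thinning law to leading order shows their ratio approaches the slope
factor 3 as the maximum amplitude shrinks, and the test suite checks this
convergence against an independent series-expansion oracle.

### A note on the factor 3

The literal slope of $C_\psi = C_0(1+\alpha\psi^2)$ is $C_0\alpha$, which
would give $\alpha = m/C_0$.  The published convention for this analysis
divides by $3C_0$ instead, and the package follows it; `slope_factor` is a
named argument everywhere (fit, simulator, conversion) so the literal
convention (`slope_factor = 1`) can be used end to end.  Because the forward
simulator and the analysis share the factor, round-trip recovery is
convention-independent.

## The protocol and its segmentation

The standard schedule applies square pulses of 2 s on and 2 s off, starting
at ±1 mV and stepping by ±25 mV to ±200 mV, positive pulse before negative
at each magnitude.  Segmentation parameters (all configurable):

| parameter | default | meaning |
|---|---|---|
| `tolerance` | 2 mV | max sample-to-sample change within one level run |
| `level_floor` | 5 mV | minimum magnitude to count as a voltage step |
| `min_duration` | 0.5 s | shortest accepted step |
| `settle_fraction` | 0.5 | trailing fraction of each step averaged |
| `low_field_threshold` | 5 mV | baseline window for the zero-field state |

The ±1 mV reference level deliberately falls below `level_floor`: together
with all off-periods it feeds the zero-field baseline from which $C_0$ and
$A_0$ are averaged (an optional linear detrend of the baseline is available
but off by default, so baseline drift surfaces in diagnostics rather than
being silently removed).  How the original measurements were averaged within
each 2 s pulse is not standardised; averaging the trailing half is this
package's choice and discards any settling transient.

The fitted intercept is left free rather than pinned to $C_0$; the relative
deviation between the two (`intercept_rel_dev` in `glance()`) is reported as
a diagnostic, so a baseline error shows up instead of being absorbed.
Polarity branches are pooled in the headline fit — a symmetric membrane in a
symmetric bath gives overlapping branches — and the per-branch fit
difference is reported as `branch_asymmetry`, a diagnostic rather than a
gate.

## Uncertainty

Residual-resampling bootstrap of the $C_\psi^{(V_0)}$-vs-$\psi^2$
regression: leverage-adjusted, centred residuals
($r_i/\sqrt{1-h_i}$) are resampled onto the fitted line, the slope refitted
$B$ times (default 1000), and each replicate mapped through the full chain
to $\alpha$, $E_\perp$ and $k_c$; percentile intervals are reported.  A
fixed seed makes intervals reproducible; the default configuration seeds the
bootstrap so `run_analysis()` is deterministic end to end.  With 16 design
points the leverage adjustment matters: it restores the slight variance the
plain residuals lose to fitting, and the suite verifies ~95% empirical
coverage over 200 simulated replicates.

## The forward simulator

`simulate_trace()` is the exact inverse of the analysis chain: it chooses
$\alpha = C_m/(E_\perp d_0)$ and thins the membrane as
$$d_\psi = d_0\,(1 + 3\alpha\psi^2)^{-1/2},$$
so the constant-volume capacitance is exactly linear in $\psi^2$, while the
area grows independently as $A_\psi = A_0(1+\gamma\psi^2)$.  Design choices
where the measurement itself is silent:

* **Area-growth law.** Quadratic in $\psi$, mirroring the capacitance law;
  no functional form is established experimentally.  The default
  $\gamma = 2\alpha$ produces disproportionate area growth — membrane volume
  increasing with field — the regime the correction exists for.  The special
  value `"conserve_volume"` makes the area track thinning exactly
  ($A_\psi = A_0\sqrt{1+3\alpha\psi^2}$), because no quadratic $\gamma$
  conserves volume beyond leading order; this mode exercises the
  correction's nullity.
* **Step response.** Instantaneous by default; an optional first-order
  settling constant (`settle_tau`, a physical choice being ~50 ms) exercises
  the settle-window logic.
* **Noise.** Multiplicative Gaussian noise, independently per sample and per
  channel (capacitance, area), seeded and restoring the caller's RNG state.
  The potential channel is exact — the amplifier sets it, it is not
  measured.
* **Sampling.** 1 kHz by default (not critical; tests run at 50–200 Hz).

What the simulator does **not** emulate — and hence what passing round-trip
tests do not establish about real traces: capacitive charging transients in
the measured capacitance, slow baseline drift, electroporation at high
fields, solvent redistribution dynamics, or deviations from the quadratic
capacitance law.  On real data those appear as poor $r^2$, intercept
deviation or branch asymmetry in `glance()` rather than being corrected.

## Ionic asymmetry bookkeeping

Asymmetry experiments add 50 µL aliquots of 200 mM CaCl₂ stock to the top
chamber (starting from 2 mM symmetric); perfect-mixing dilution gives the
top concentration, and $x$ is the top/bottom ratio.  The chamber volume is a
required argument — it is an apparatus property with no defensible default —
and the fixtures use 1.0 mL, under which one aliquot gives 11.43 mM and
$x = 5.71$.  The 5-minute post-addition equilibration is metadata only; no
binding or transport kinetics are modelled.  `run_series()` tabulates
thickness and $k_c$ against $x$ with percent changes relative to the
symmetric ($x = 1$, else smallest-$x$) condition.

## Numerical choices and degenerate inputs

* SI units internally everywhere; mV/pF/nm/mm² appear only in plots and
  printed summaries.  $\varepsilon_0 = 8.8542\times10^{-12}$ F/m.
* A non-positive fitted slope yields $\alpha \le 0$: the moduli are reported
  as `NA` with a classed warning (not an error), so batch runs keep going
  and degenerate traces remain inspectable.
* Steps with no measurable compression ($\Delta d \le 0$) contribute `NA`
  per-step legacy moduli; the legacy regression requires a positive slope.
* Segmentation needs no protocol prior (an optional `protocol_hint` snaps
  levels); a trace without any step above `level_floor` is an error, as is a
  trace with no baseline samples.
* Problem sizes in the test suite: simulated traces at 50–200 Hz, bootstrap
  $B = 1000$, 200-replicate coverage and 500-replicate standard-error
  checks — sizes at which the Monte-Carlo error of those checks is well
  below the tolerances asserted.

## Known limitations

Residual oil in the film biases absolute thickness (and hence $k_c$) in a
lipid/solvent-dependent way; the method measures the film as formed.
Specific capacitance is assumed voltage-independent apart from geometry;
dielectric saturation is ignored.  The thin-plate conversion treats the
bilayer as a homogeneous elastic slab — monolayer coupling and tilt degrees
of freedom are outside its scope.  Area must be supplied as a measured
channel; extracting it from images is upstream of this package, as is
deriving capacitance from raw current transients.
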