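---
title: "Auto-tuning a quadrupole mass spectrometer with subpopulation-ranked differential evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-tuning a quadrupole mass spectrometer with subpopulation-ranked differential evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmstune)
```

## The tuning problem

A triple-quadrupole mass spectrometer delivers its specified sensitivity
only after its ion-source and ion-optics parameters are tuned: gas flows
(curtain gas CUR, nebulizer gas GS1) and lens voltages (de-clustering
potential DP, entrance potential EP) jointly determine the intensity of the
mass spectral peaks, while the mass-axis DAC count and the resolution
OFFSET voltage determine where a peak sits and how wide it is. Traditional
automatic tuning optimizes one parameter at a time over a small grid
(univariate search), which ignores interactions between parameters and
settles for whatever the one-dimensional sweeps happen to find. Because a
single spectrum costs seconds of instrument time and a full tuning session
must stay within a few hours, only on the order of 500–1000 measurements
are affordable — far too few for most global optimizers.

`qmstune` implements a differential evolution (DE) variant designed for
exactly this regime (small population, very few generations), together with
everything needed to exercise it without hardware: formula-defined
benchmark functions, a virtual instrument with a known ground-truth
optimum, the calibration loops, and the tuning pipeline with its
univariate-search baseline.

## The improved DE algorithm

Classic DE evolves a population of $N$ candidate vectors through mutation,
binomial crossover, boundary clipping and greedy one-to-one selection. The
variant implemented here keeps that loop but, before each generation's
mutation step, ranks the population by fitness and splits it into an elite
(ELS), a middle (MIS) and an inferior (INS) subpopulation whose size ratio
depends on the phase of the run:

| stage | condition | ELS : MIS : INS |
|---|---|---|
| early | $g \le G/3$ | 2 : 5 : 3 |
| middle | $G/3 < g \le 2G/3$ | 4 : 4 : 2 |
| late | $g > 2G/3$ | 6 : 3 : 1 |

Each subpopulation uses its own mutation rule:

* **ELS** searches near the incumbent best with a `best/1` step
  $v = x_{best} + F_1 (x_{r1} - x_{r2})$, where
  $F_1 = \alpha_1 u (1 - g/G)^2$ with $u \sim U[0,1]$ re-drawn for every
  mutant. The factor decays quadratically, shrinking the elite search
  radius as the run progresses.
* **MIS** moves toward the best while keeping a random component,
  $v = x_i + F_2 (x_{best} - x_i) + F_3 (x_{r1} - x_{r2})$ with constant
  $F_2$ and the deterministic schedule
  $F_3 = \alpha_2 + \alpha_3 (1 - \sqrt{g/G})$.
* **INS** is resampled uniformly inside the bounds — a restart mechanism
  that guards against premature convergence.

Defaults are $\alpha_1 = 1$, $F_2 = 0.4$, $\alpha_2 = \alpha_3 = 0.3$,
$CR = 0.75$. Selection is strict: a trial replaces its target only when
strictly better, so ties keep the incumbent.

Two implementation choices deserve a note. First, subpopulation membership
is assigned by fitness *rank* without physically reordering the
population: each individual keeps its index, and greedy selection is
per-individual, so this is mathematically equivalent to sorting first but
keeps the population order stable. That stability gives a sharp
correctness oracle: configuring the stage ratios to 0:10:0,
$\alpha_3 = 0$, $\alpha_2 = F$ and $F_2 = \lambda$ makes the improved DE
collapse, draw for draw, onto classic DE/rand-to-best/1/bin — the test
suite checks bit-equality of the two runs on a shared seed. Second, every
run draws all of its randomness from one seeded generator in a fixed
documented order (initialization; then per individual: donor indices, any
per-mutant factor, forced crossover index, crossover uniforms), which is
what makes that oracle, and exact reproducibility generally, possible.

The classic strategies (`de_rand_1`, `de_best_1`, `de_rand_to_best_1`) and
standard global-best PSO with inertia weight decreasing linearly from 0.9
to 0.4 ($c_1 = c_2 = 2$, velocity clamped to 20% of each coordinate range)
share the same configuration object and evaluation budget of $N(G+1)$
objective calls. Classic DE uses $F = 0.5$ and $\lambda = 0.5$ by default —
conventional mid-range values, since no canonical setting exists for this
problem class.

## Benchmark functions

Two multimodal functions from the CEC-2017 suite are formula-defined and
self-contained, and those are the two implemented: the shifted and rotated
Rastrigin function (F5, bias 500) and the shifted and rotated Lunacek
bi-Rastrigin function (F7, bias 700). Instances are *self-generated* from
a seed — shift drawn uniformly in the inner 80% of $[-100,100]^D$,
rotation Haar-distributed via QR of a Gaussian matrix — rather than loaded
from the suite's official data files. Published reference statistics were
obtained with the official instances, so repeated-trial means are
comparable only within trial-to-trial variability; the test suite treats
them as bands (mean ± reported std), not point targets.

F5 uses the plain shifted/rotated composition
$f(x) = 500 + \sum_i (z_i^2 - 10\cos 2\pi z_i + 10)$ with
$z = M (0.0512 (x - o))$. For F7 we implement the full standard Lunacek
bi-Rastrigin transformation — $y = 0.1(x-o)$, sign-doubling
$\hat x_i = 2\,\mathrm{sign}(o_i) y_i + \mu_0$, ill-conditioning diagonal
$\Lambda^{100}$ inside the cosine term, constants $\mu_0 = 2.5$, $d = 1$,
$s = 1 - 1/(2\sqrt{D+20} - 8.2)$, $\mu_1 = -\sqrt{(\mu_0^2 - d)/s}$ —
rather than a simplified re-scaling: the simplified form measurably
flattens the function (30-trial means drop by roughly 40 units at
$D = 10$) and no longer reflects the difficulty regime the reference
statistics describe. The depth constant $s$ is positive only for
$D \ge 2$, so F7 rejects $D = 1$. Both functions evaluate to exactly their
bias at the shift vector, which the suite fuzz-tests over 100 seeds.

Hybrid and composition functions (F16, F20, F26, F29) depend on internal
definitions that are not self-contained; they are rejected at the API
boundary by name rather than silently approximated.

## The virtual instrument

No physical model predicts peak intensity as a function of the tuning
parameters — on the real instrument that surface *is* the plant. The
simulator therefore defines an explicit synthetic stand-in with a known
optimum $p^*$: a Gaussian bump
$I(p) = I_{max} \exp(-\frac12 u^\top C^{-1} u)(1+\epsilon)$ over
normalized deviations $u_j = (p_j - p^*_j)/\sigma_j$. In the default
*interaction* mode, $C$ couples DP and EP with correlation 0.6 — the
simplest surface on which one-parameter-at-a-time search is provably
suboptimal while each single-parameter slice stays unimodal; a separable
mode ($C = I$) exists for oracle tests. Bounds (CUR, GS1 ∈ [5, 40],
DP ∈ [50, 200], EP ∈ [2, 15]) and the default optimum
(20, 16, 160, 11) sit in the neighbourhood of typical Q1-mode operating
points so that tuned outputs have realistic magnitudes; they are fixtures,
not claims about any particular instrument. Sensitivity widths default to
a quarter of each parameter range — wide enough that random starting
points still produce measurable signal, narrow enough that tuning matters.

Peak position and width follow the two linear factory relations a real
quadrupole exposes: measured centroid
$= (\mathrm{DAC} - b)/a$ for a mass–DAC line with slope $a = 32$ counts/u,
and FWHM $= c + 0.35 \cdot \mathrm{OFFSET}$ u. The three calibrant peaks
(m/z 172.88, 622.57, 922.36 — NaI/CsI cluster ions) start deliberately
mis-set: about 0.1 u of mass error and widths of 0.8–1.9 u, matching the
untuned state of a freshly assembled instrument. Intensity noise is
multiplicative Gaussian with CV 0.06 (mid-range of repeatability figures
reported for this instrument class); centroid and FWHM carry a small
measurement error of $0.15 \times$ CV u. With CV = 0 the whole plant is
deterministic. Measurements accumulate `mca = 5` scans, mirroring
multiple-channel acquisition.

What the simulator deliberately omits: ion-optics physics (Mathieu
stability), isotope patterns, detector saturation, drift over a tuning
session, and any nonlinearity in the DAC/OFFSET tables. Passing tests
therefore demonstrate that the *algorithmic* pipeline is correct and
beats its baseline on a plant with parameter interactions — not that any
particular intensity gain will materialize on hardware.

## Calibration loops

Mass axis and resolution are corrected by the same first-order update,
$\mathrm{setting}_m = \mathrm{setting}_{m-1} + k(\mathrm{target} -
\mathrm{measured}_{m-1})$, iterated until $|$error$| \le 0.1$ u (the
standard acceptance tolerance for both mass accuracy and a resolution
target of 0.7 u) or a 20-iteration budget runs out. On a noiseless linear
plant the error obeys $e_m = (1 - ks)e_{m-1}$, so a gain matching the
inverse plant slope converges in one step and any $|1 - ks| < 1$
converges geometrically — properties the tests check against the closed
form. Since no canonical gain values exist, the default estimates $k$ at
startup with a two-point probe (perturb, measure, fit, invert); a
fixed-coefficient mode supports the analytic tests. Non-convergence and
divergence (three consecutive error increases, the signature of a
sign-mismatched gain) are reported as status flags rather than thrown, so
the tuning loop can assign a failed candidate infinite fitness and move
on. Each iteration uses a single measurement by default — averaging costs
instrument time — with an `n_average` knob when noise demands it.

## The tuning pipeline

Candidates proposed by the optimizer are clipped to bounds *before* being
written to the instrument, applied, calibrated (mass axis then resolution,
per peak), measured, and scored with the weighted reciprocal-intensity
objective $f = \sum_k \lambda_k / \max(I_k, \varepsilon)$ with
$\lambda_k = 10^6$ — minimizing $f$ maximizes a weighted harmonic
combination of the peak intensities, and the floor $\varepsilon$ guards a
dead peak. By default calibration re-runs for every candidate (every
tuning parameter could plausibly shift a peak); a per-generation economy
mode exists because on plants like this one, where DAC and OFFSET are
independent of the gas/voltage parameters, recalibration after the first
candidate is a no-op. All instrument measurements are counted and
reported so the spectra budget of a run is auditable.

The univariate baseline scans 10 uniformly spaced levels per parameter
(endpoints included) in the order GS1, CUR, DP, EP, locking in each
parameter's best level before moving on — a single pass, as a commercial
auto-tune would do. Repeatability of repeated tuning runs is summarized
as the per-peak coefficient of variation of final intensities using the
sample standard deviation ($n-1$), the usual convention in analytical
chemistry reporting.

The optimizer side and the instrument side can also run as separate
processes exchanging plain `key=value` text files with a monotone
sequence number (`write_param_file()` / `read_intensity_file()` /
`wait_for_update()`), the integration route available when vendor
software permits scripted acquisition but not embedding.

## Problem sizes and test design

All comparative experiments use the operating point the time budget
dictates on hardware: $N = 20$, $G = 25$, i.e. 520 candidate evaluations.
Benchmark statistics use 30 trials at $D = 10$; the tuning comparison uses
20 paired seeds (same instrument noise stream for optimizer and baseline);
repeatability uses 10 runs at default noise; parameter recovery uses 20
noise-free runs. Stochastic assertions are property bounds (e.g. per-peak
CV ≤ 15%, win rate ≥ 90%) rather than point reproductions, because the
corresponding published figures are instrument-specific. Every stochastic
test fixes its seed, so failures are reproducible.

## Known limitations

* The improved DE's subpopulation ratios and factor schedules are fixed
  constants; no self-adaptation (JADE/SHADE-style archives or
  population-size reduction) is attempted.
* Only box constraints are supported; maximization requires negating the
  objective.
* Benchmark instances are self-generated, so exact reproduction of
  statistics computed with the official CEC-2017 instance files is out of
  reach by design.
* The virtual instrument's response surface is a labelled synthetic
  stand-in; conclusions about real hardware gains require hardware.
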