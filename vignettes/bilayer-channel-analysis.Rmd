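---
title: "Single-channel bilayer analysis: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel bilayer analysis: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bilayertools` analyses single-channel current recordings from planar lipid
bilayer experiments — the kind of data produced when proteoliposomes carrying
a reconstituted membrane protein (for example the chloroplast inner-envelope
translocon component Tic20) are fused into a bilayer and the current through
a single channel is recorded under voltage-step and voltage-ramp protocols.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

```{r setup}
library(bilayertools)
```

## Conventions

All quantities use one fixed unit system: current in pA, potential in mV,
conductance in pS, time in s, concentration in mM, temperature in K. The
command potential is that of the *cis* chamber (where the sample is added)
relative to *trans*, and positive current is cation flow cis→trans. Under
this convention a cation-selective channel with the concentrated salt on the
cis side reverses at a *positive* potential. Physical constants are pinned
to CODATA values (R = 8.314462618 J mol⁻¹ K⁻¹, F = 96485.33212 C mol⁻¹) so
results are bit-reproducible across platforms. The default temperature is
293.15 K (20 °C), a standard room-temperature assumption for bilayer rigs.

Traces travel through a plain tab-separated text format with a
`# key=value` metadata header (one trace per file); current is stored to 6
significant digits and voltage to 3, both far below recording noise, and
`read_trace(write_trace(x))` is the identity at that stored precision.

## The gating model and simulator

The simulator is a continuous-time Markov model: a set of conductance
levels (the first is the fully open state) and a matrix of transition rates
between them. `sample_state_path()` draws an exact (Gillespie) realisation —
dwells are exponential with the level's total exit rate, successors are
drawn proportionally to their rates — and `render_current()` turns a state
path into a sampled trace:

\[ I(t) = g_{\mathrm{level}(t)}(\mathrm{pol}) \cdot \frac{V(t) -
E_\mathrm{rev}}{1000} + \varepsilon_t, \qquad \varepsilon_t \sim
\mathcal N(0, \sigma^2) \]

Rectification is modelled as a *polarity-dependent slope conductance per
level* (two numbers, `g_neg`/`g_pos`, switched by the sign of
\(V - E_\mathrm{rev}\)), not as a continuous current-equation nonlinearity:
the experimental observable being emulated is a pair of polarity-specific
slope conductances, so two slopes are the faithful parameterisation. The
reversal potential comes from the GHK voltage equation (below) applied to
the model's permeability ratio, so simulated ramps reverse where the theory
says they should.

`tic20_channel_model()` packages the fixture used throughout the tests: a
fully open level of 1260/1010 pS (negative/positive polarity), two substates
reached by gating steps of 150 and 350 pS — one on each side of the
class boundaries — ≥ 90% open occupancy (open→substate 2 s⁻¹ each,
substate→open 40 s⁻¹, mean substate dwell 25 ms), 2 pA white Gaussian
noise. Dwell-time scales and event rates are *not* experimentally
constrained quantities here; they were chosen once so that a few hundred
gating events occur per 10 s trace, giving the recovery tests statistical
power. Only the conductances, the occupancy dominance of the open state,
the noise scale and the selectivity are meant to mirror the experimental
system.

What the generator deliberately does **not** emulate: baseline drift,
capacitive and leak currents, 50/60 Hz pickup, filter ringing,
multi-channel bilayers, and open-channel noise in excess of the baseline
noise. Passing the recovery tests therefore demonstrates correctness of the
analysis chain under idealised single-channel statistics, not robustness to
every artefact of real recordings.

## Idealization and event extraction

`estimate_noise_sd()` estimates σ as the median absolute deviation of the
first differences divided by \(\sqrt 2 \cdot 0.6745\); level steps touch a
vanishing fraction of the differences, so the estimate ignores gating where
a naive standard deviation inflates severely.

`idealize_trace()` uses a two-pass scheme. Pass one slides two adjacent
windows of width `min_dwell_s` (default 1 ms) across the trace and marks
candidate change points where the window-mean difference exceeds
`threshold_k`·σ (default `threshold_k = 4`); each contiguous candidate run
is refined to its sample of maximal difference. Pass two merges segments
shorter than the minimum dwell into the neighbour with the closer mean
(closest first, ties to the left) and then merges adjacent segments whose
means differ by less than the detection threshold, iterating to a fixed
point. The threshold is floored at the cumulative-sum round-off scale
(10⁻⁸ of the data range) so noiseless and reconstructed traces segment
exactly rather than flagging floating-point jitter; this also makes the
procedure idempotent on its own piecewise-constant reconstruction. With
2 pA noise and `threshold_k = 4` the smallest detectable step at ±100 mV is
about 8 pA ≈ 80 pS·mV⁻¹·100 mV, which places ~25 pS events at the detection
edge — the intended floor. Ramp traces are rejected: under a changing
driving force a conductance step has no single current amplitude.

`extract_gating_events()` converts each adjacent segment pair into an event
with signed amplitude ΔI and conductance \(|\Delta I| \cdot 1000 / |V -
E_\mathrm{rev,assumed}|\). Events within 10 mV of the assumed reversal are
dropped because the division is ill-conditioned there. For symmetric-buffer
recordings `e_rev_assumed_mV = 0`.

## Conductance classes, I-V fits, total conductance

`assign_classes()` splits events at polarity-specific thresholds (defaults
220 pS negative, 180 pS positive) with the deterministic boundary rule
*class II iff g ≥ threshold*. `fit_class_iv()` fits ordinary least squares
to polarity-signed amplitude versus voltage per (polarity, class); the
intercept is left free, since event amplitudes need not extrapolate through
the origin. `fully_open_conductance()` instead fits *through* the origin,
because the step recordings are made under a symmetric buffer where zero
current at zero drive is exact; it identifies the fully open level in each
idealized trace as the dwell-weighted pool of segments within one detection
threshold of the extreme mean current, and reports per-polarity slopes with
their standard errors from the fit covariance. Histograms use left-closed
right-open 25 pS bins by default, matching the smallest events of interest.

## Reversal potential and GHK selectivity

For a single binary salt (KCl) with permeability ratio
\(r = P_{K^+}/P_{Cl^-}\):

\[ E_\mathrm{rev} = \frac{RT}{F} \ln \frac{r\,C_\mathrm{cis} +
C_\mathrm{trans}}{r\,C_\mathrm{trans} + C_\mathrm{cis}} \qquad
\Longleftrightarrow \qquad r = \frac{\xi C_\mathrm{cis} -
C_\mathrm{trans}}{C_\mathrm{cis} - \xi C_\mathrm{trans}}, \quad \xi =
e^{E_\mathrm{rev} F / RT} \]

The two forms are exact inverses (property-tested to 10 significant
digits), \(E_\mathrm{rev}\) is strictly increasing in r and bounded by the
K⁺ Nernst potential, and the inversion raises a domain error when the
measured reversal lies outside the Nernst bounds, where no finite ratio
exists. At 250/20 mM and 293.15 K, r = 6.5 corresponds to +37.0 mV; this
pair is what the acceptance checks pin down.

`find_reversal_potential()` smooths each ramp's current with a centred
moving average spanning 5 mV of the ramp (the smoothing span is a free
choice; 5 mV suppresses noise without biasing a crossing that sits tens of
mV from the ramp edges), locates zero crossings by linear interpolation,
takes the median crossing per ramp if gating produces several, and pools
ramps by mean ± SEM. Ramps without a crossing are excluded with a warning.

## Hille pore-size estimate

`hille_pore_diameter()` treats the pore as an electrolyte-filled cylinder
of length l whose interior resistivity is the bulk value times a
crowding factor (default 5×). Two variants are first-class:

* `cylinder`: \(1/g = \rho_\mathrm{pore} l / (\pi r^2)\), inverted in
  closed form, \(d = 2\sqrt{g \rho_\mathrm{pore} l / \pi}\);
* `cylinder_plus_access`: adds the access resistance of the two mouths,
  \(1/g = \rho_\mathrm{pore} l / (\pi r^2) + \rho_\mathrm{bulk}/(2r)\),
  solved for r by bisection to 10⁻⁴ Å (cross-checked in the tests against
  the closed-form quadratic root).

Both variants are offered, and every report names the one used, because
published pore-size figures in this literature often cannot be reproduced
from their stated inputs: for g = 350 pS, l = 1–5 nm, ρ = 247.5 Ω cm and a
5× in-pore correction, the cylinder variant gives 23.5–52.5 Å and the
access variant 28.2–57.0 Å, whereas a figure of 7.8–14.1 Å has been quoted
for those same inputs. No combination of the stated parameters with either
formula (or with the correction factor applied to either resistivity term)
yields that range, so the package reports its own variant-labelled
estimates and deliberately does not tune parameters toward any published
number. The estimate is monotone increasing in both l and g
(\(d \propto \sqrt g\) exactly for the cylinder), so it is best read as an
order-of-magnitude bracket, not a measurement.

## Swelling assay

The osmotic swelling module addresses the complementary liposome assay:
salt addition shrinks vesicles (OD₅₀₀ drops), and ion influx through a
channel lets them re-swell (OD recovers). `simulate_swelling()` models an
instantaneous drop by `drop_fraction` at `salt_time_min` followed by
first-order recovery toward baseline (rate 0 = channel-free), plus Gaussian
noise; the default noise SD of 0.002 is 2% of the default 0.1 baseline,
inside the 1.5–3% replicate-variability band typical of the assay.
`summarize_swelling()` reduces a course to baseline, post-salt minimum and
the least-squares recovery slope from the minimum to the end, and calls
`channel_positive` when the slope exceeds 3 standard errors of itself — a
significance rule chosen because the experimental read-out is qualitative
and no published slope threshold exists. The summary is invariant to an
additive OD offset except for the level fields. The recovery rate of the
positive fixture (0.02 min⁻¹) was chosen once to give a clearly visible
recovery over an hour, and the classification check (≥ 95% correct calls
over 200 replicates) is run at exactly that setting.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes
simulate → idealize → classify → histogram → iv_fit → total_g → ramp →
ghk → pore (→ swell) with any subset of stages enabled, writes each stage's
table as TSV with a `# key=value` provenance header, logs every stage and
warning, and halts on a stage error naming the stage. Sub-stream seeds are
derived from the master seed with a Lehmer-style mix of (seed, stream
index), kept inside the 32-bit signed range, so adding traces never
perturbs earlier streams and identical (config, seed) give byte-identical
tables. There is no shell executable: the exported functions and
`run_pipeline()` are the interface, which suits an R analysis package.

Fixture problem sizes were set once, as a balance between statistical power
and a suite that runs in seconds: step traces of 10 s at 5 kHz per voltage
(15 voltages, −140…+140 mV in 20 mV steps; the experimental protocol holds
each voltage far longer, but recovery accuracy is already ≪ 1% at 10 s),
ramps of 20 s at 2 kHz (16 ramps, alternating direction), Gillespie
correctness paths of 2 × 10⁴ s, and 200 swelling replicates. At these sizes
the end-to-end recovery margins are comfortable: fully open conductance
within 0.1% of truth, substate slopes within ~2.5%, transition recovery
100% for ≥ 5σ events with dwells ≥ 5 ms.

## Known limitations

* The idealizer is a threshold detector, not a hidden-Markov smoother; it
  will miss sub-threshold events by construction and does not correct
  baseline drift.
* Conductance classes are fixed thresholds, not mixture fits; borderline
  events are assigned deterministically, and the class conductances are
  only as meaningful as the thresholds.
* The GHK treatment is single-salt and uses concentrations, not
  activities; with 250/20 mM KCl the activity-coefficient difference is a
  few percent and is ignored, as is any streaming-potential correction.
* The Hille estimate inherits every idealisation of the cylinder model;
  the factor-of-5 in-pore correction is itself a literature convention, not
  a measured quantity.
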