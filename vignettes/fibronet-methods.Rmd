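---
title: "Models and methods behind fibronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibronet simulates two-dimensional atrial tissue in which stochastic
spontaneous calcium release events (SCRE) interact with a patchy-fibrosis
substrate.  This vignette is the package's account of the models, the
tunable parameters, the numerical choices, and the limits of what the
simulations show.

## The minimal atrial cell model

Each lattice node carries a minimal action-potential model with eleven state
variables: membrane potential $V$; sodium-current gates $m, h, j$; L-type
calcium gates $d, f$; a lumped repolarising potassium activation gate $x$; a
two-variable calcium-induced-calcium-release (CICR) gate $a, r$; and the
cytosolic and sarcoplasmic-reticulum calcium concentrations
$[\mathrm{Ca}^{2+}]_i$ and $[\mathrm{Ca}^{2+}]_\mathrm{SR}$.  The membrane
currents (all per-capacitance, pA/pF) are

$$I_\mathrm{Na} = g_\mathrm{Na} m^3 h j (V - E_\mathrm{Na}), \quad
  I_\mathrm{CaL} = g_\mathrm{CaL} d f (V - E_\mathrm{CaL}), \quad
  I_K = g_K x (V - E_K),$$

an inward rectifier
$I_{K1} = g_{K1}(V - E_{K1}) / (1 + e^{0.05 (V + 80)})$, a standard
electrogenic sodium-calcium exchanger (NCX) with fixed sodium
concentrations, and (optionally) an ohmic fibroblast-coupling current
$I_\mathrm{fb} = g_\mathrm{fb} (V - E_\mathrm{fb})$.

The calcium subsystem is the part that carries the science: the SR release
flux is

$$J_\mathrm{rel} = g_\mathrm{rel}\, N_\mathrm{RyR}\,
  ([\mathrm{Ca}^{2+}]_\mathrm{SR} - [\mathrm{Ca}^{2+}]_i),$$

where the RyR open fraction $N_\mathrm{RyR}$ is the sum of the
voltage-triggered CICR gate (active during the action potential) and an
*externally imposed* spontaneous-release waveform (below), capped at 1.
SERCA uptake is a Hill function of cytosolic calcium and a linear leak
closes the loop.  A spontaneous release therefore produces a calcium
transient whose NCX current depolarises the membrane — a delayed
afterdepolarization (DAD) — and, if the sodium activation threshold is
reached, triggered activity (TA).  Because the release flux is proportional
to the SR-cytosol gradient, release magnitude grows with SR load for a
fixed waveform; this is why the protocols control the load explicitly.

### Calibration

The supplementary material that defines the original minimal model was not
available, so the model here is an own-design implementation calibrated to
the tissue-level contract that the study prints: planar-wave conduction
velocities of 1.27 mm/ms along and 0.4 mm/ms across the fibres at axial
coupling 1.28 nS/pF, 7:1 anisotropy, node spacing $\Delta x = 0.3125$ mm
and $\Delta t = 0.01$ ms; a resting potential near $-81$ mV; and an
atrial-like action potential (APD$_{90} \approx 100$ ms at a cycle length
of 1000 ms, with SR load increasing from 1.05 to 1.16 mM when pacing
accelerates from 1000 to 400 ms).

Two calibration facts shape the parameter set and are worth knowing:

* **The sodium activation midpoint sits at $-61$ mV** (slope 5 mV), lower
  than biophysically detailed models.  At a 0.3125 mm lattice spacing the
  transverse wavefront advances node-by-node in the discrete-propagation
  regime; reproducing both 1.27 and 0.4 mm/ms requires an excitable
  threshold this low.  The price is a sodium *window* near $-60$ to
  $-50$ mV: sustained depolarisations of more than a few millivolts are
  regenerative.
* **Fibroblast coupling therefore shifts the rest by $+2.7$ mV at the
  default $g_\mathrm{fb} = 0.02$ nS/pF** rather than the 5–10 mV a
  biophysically detailed myocyte could sustain: beyond roughly $+3$ mV the
  window current takes over and the rest jumps to a depolarised branch.
  The direction and monotonicity of the shift — the properties the science
  uses — hold throughout the stable range.

AF electrical remodelling is the documented overlay
$g_\mathrm{CaL} \times 0.6$, $g_{K1} \times 1.3$, $g_K \times 0.85$
(APD$_{90}$ ratio 0.69, SR load 0.59 vs 1.05 mM); sympathetic stimulation
(ISO) is $g_\mathrm{CaL} \times 1.4$, $g_\mathrm{up} \times 1.15$ (SR load
1.65 mM).  The mCRN variant is a reduced-fidelity overlay
($g_{K1} \times 1.6$, $g_K \times 1.2$) that gives the cell a larger
opposing current at rest, so that larger — and hence potentially
subthreshold-but-sodium-inactivating — release events are needed for TA;
it is not a reimplementation of the Courtemanche model.

Gates advance by the Rush–Larsen exponential update, voltage and
concentrations by forward Euler, all at $\Delta t = 0.01$ ms.
Voltage-dependent terms are evaluated through lookup tables on
$[-95, 65]$ mV at 0.05 mV resolution with linear interpolation, rebuilt per
run.  Halving $\Delta t$ moves activation times by well under 1 ms (this is
a test).

## The spontaneous release function (SRF)

A cellular SCRE is imposed as an analytic time course of the whole-cell RyR
open fraction.  Two free parameters define everything: the initiation time
$t_i$ and the duration $\lambda$.  For $\lambda \le 300$ ms the waveform is
a spike — a product of two sigmoids with midpoints halfway between $t_i$,
the peak time $t_p = t_i + \lambda/2$, and the end time $t_f$, and slopes
$k = 0.1689\,\Delta t_\mathrm{half} + 0.00255$.  For $\lambda > 300$ ms it
is a plateau at a lower level with a superimposed peak (fixed slope
5.946 ms, rise/fall centred 17.5 ms inside the interval, peak term offset
$-25/+17.5$ ms around $t_p$).  The two families are different analytic
forms: at the 300 ms morphology switch the pointwise difference can reach
about a third of the peak amplitude, which is documented here and asserted
as a bound in the tests rather than pretended away.

The amplitude map is the package's own choice (the original is
supplementary): $N^\mathrm{peak}(\lambda) = 0.02 + 0.55/(1 +
(\lambda/120)^{1.6})$, with $N^\mathrm{plateau} = 0.5\,N^\mathrm{peak}$.
It is monotone decreasing — short, synchronised release is strong; long,
desynchronised release is weak — and its scale was chosen once so that the
single cell crosses its TA threshold at $N^\mathrm{peak} \approx 0.15$ with
a 1.0 mM SR load, which places the tissue-level focal-excitation threshold
*inside* the $(\sigma_{ti}, \sigma_\lambda)$ control plane (see below).

$t_i$ and $\lambda$ are sampled by inverse transform through a skewed
two-branch sigmoidal CDF: separation point, cumulative frequency at
separation, and two independent branch slopes per parameter.  The inverse
is exact (round-trip identity to $10^{-10}$ is a test).  Two conveniences
follow the study design: sampled durations are clipped at a 10 ms floor,
and initiation times beyond the simulation end simply mean "no release this
trial".

The static control mapping interpolates every distribution parameter
linearly between documented endpoints: $\sigma = 0$ gives wide timing
distributions (hundreds of ms; $t_{i,\mathrm{sep}}$ 500 ms, slopes 120/200)
and long durations (median $\approx 500$ ms); $\sigma = 1$ gives tight
timing (tens of ms; 300 ms, slopes 10/15) and short durations (median
$\approx 54$ ms).  SCRE probability is 1 in this mode.  The dynamic mode
maps SR load to an SCRE probability sigmoid (0.5 at 0.9 mM, slope
0.025 mM) and drives the same interpolation with an effective sigma rising
linearly over 0.7–1.3 mM, so a fuller SR gives earlier, tighter, stronger
release — all monotone, all tested by seeded sampling.

## Tissue: orientation-weighted network coupling and patchy fibrosis

Nodes couple to up to eight neighbours along four undirected directions
(two axes, two diagonals).  For fibre angle $\theta$ and bond angle
$\phi_k$, the nodal weight is

$$w_k = \left[g_a \cos^2\delta + g_t \sin^2\delta\right]
        \cos^2(2\delta), \qquad \delta = \theta - \phi_k,$$

with diagonals additionally scaled by $1/\sqrt{2}$ for their longer
internodal distance, and the stored bond weight the mean of its two
endpoint evaluations (symmetry by construction).  The $\cos^2 2\delta$
selection factor reproduces the defining behaviour of the network model:
exactly two directions are non-zero when fibres align with an axis or
diagonal, all four otherwise.  Boundaries are no-flux.  The coupling
current $I_i = \sum_j w_{ij}(V_j - V_i)$ is accumulated pairwise, so
$\sum_i I_i = 0$ to machine precision.

Fibrosis maps are thresholded Gaussian random fields: white noise convolved
with an isotropic Gaussian kernel (FFT, circular), normalised, and cut at
the exact quantile so that the fibrotic node count is exactly
`round(fraction * n)`.  The "patch size seed" of the study conditions maps
to the GRF correlation length as `length_scale = patch_seed / 2.5` nodes —
chosen once so seed 10 gives many small patches and seed 50 a few large
ones at matched total area.  Patches are 4-connectivity components,
matching the axial bond directions.  Inside patches, bonds with at least
one fibrotic endpoint are classified longitudinal or transverse by whether
the fibre-bond alignment exceeds $1/\sqrt 2$, and an exact count
(`round(p * N)`, defaults 0.8 transverse / 0.2 longitudinal) is removed
uniformly without replacement.  Exact-count removal was preferred over
independent Bernoulli thinning because it makes the removed fractions
deterministic and testable while leaving expectations unchanged.

Orientation fields: `OY` is exactly $(0, 1)$ everywhere; `control` adds a
long-wavelength GRF perturbation (amplitude 0.55 rad, correlation length 25
nodes) so neighbouring nodes differ by at most a few degrees; `remodelled`
overwrites random rectangular blocks with angles near the x-axis, creating
abrupt discontinuities and a larger x-component representation.  These
fields are procedural stand-ins for fibre architecture, not validated
anatomy.

## Protocols

* **Pre-pacing.**  Single cells are paced to steady state (beat-to-beat
  change below 0.01 mV / $10^{-5}$ mM); tissues start from the broadcast
  single-cell state and are paced for 5 beats (the study default; the
  property tests use 2, which the periodicity test shows is already within
  1 ms of beat-to-beat steady state).
* **Focal trials.**  One stimulus; release disabled until the SR has
  refilled from the beat (detected as the post-repolarisation maximum of
  the mean SR load, monitored in 10 ms chunks, with a deadline 5 ms before
  the earliest sampled initiation time); SR load then set to exactly
  1.0 mM; release enabled; the model evolves for the trial window.
* **Focal detection.**  The study reports the classification but not the
  detector, so the detector is defined here: a focal excitation is at least
  10% of non-fibrotic nodes making their first $-20$ mV upstroke crossing
  inside some 200 ms interval beginning more than 50 ms after the last
  stimulus offset; the focus is the earliest node of that wave.  All
  thresholds are arguments.
* **P(TA).**  The fraction of `n` independently seeded trials (study
  default 30) with a focal excitation; per-trial seeds derive from a master
  seed.
* **Rapid pacing.**  Five edge-strip beats at 150–250 ms plus a follow-up
  window; outcomes classified from post-pacing activity duration (cutoffs
  200 ms / end-of-window) and late-window per-node cycle-length dispersion
  (stable below 10 ms SD).  The study lists the four classes without
  criteria; these are the package's documented ones.
* **Sinus interruption.**  Paced cycles at 1000 ms with a fresh per-node
  SRF assignment each cycle; global activations are upward crossings of the
  mean voltage above $-40$ mV, attributed to the stimulus when within 60 ms
  of one, otherwise focal.

## What the simulations show — and what they cannot

The synthetic substrates reproduce the *mechanistic ingredients* the study
isolates: anisotropic conduction at the printed velocities, patchy
connection loss that converts tissue into loosely coupled fibre strands,
stochastic cellular release with controllable timing and magnitude, and
the electrotonic source–sink competition between them.  At a near-threshold
release condition ($\sigma_{ti} = 0.25$, $\sigma_\lambda = 0.5$) control
tissue stays silent while 50%-fibrotic tissue produces focal excitations
localised to patches — the study's central trend, asserted statistically in
the acceptance tests (one-sided comparison on 10 seeds; binomial test of
locus enrichment).

They do not show: real atrial anatomy or LGE-MRI fibrosis distributions
(out of scope), validated fibre architecture, regional electrophysiological
heterogeneity, sino-atrial pacemaking, or the quantitative P(TA) surfaces
of the study (which are printed only as colour maps and therefore validated
here by shape and monotonicity, not by value).

Two trends deserve a caveat.  First, the directional asymmetry of
fibrotic slowing ("transverse markedly slowed, longitudinal largely
unchanged") reproduces only partially: transverse activation does slow
more than longitudinal on average, but uniform node-scale removal of 20%
of longitudinal bonds severs a fibre strand almost surely inside any patch
more than a couple of dozen nodes tall, and the lateral detours through
the sparse surviving transverse bonds slow longitudinal activation
measurably too (the acceptance test states the exact clause that fails and
the suite reports it as a failure by design).  Preserving strand
continuity would require spatially correlated removal, which the removal
rule as stated does not prescribe.

A further known limitation: rapid pacing of AF-remodelled fibrotic tissue
did not induce re-entry in this implementation on domains up to 200×200
(CL 120–150 ms, several substrates and seeds).  The CV-calibrated minimal
model has shallow action-potential-duration restitution, which
under-produces the rate-dependent unidirectional block that seeds
wavebreak; re-entry *outcome classification* is fully implemented and
tested on constructed activation records, but re-entry *induction* should
not be expected from the defaults.  Sinus-rhythm interruption by focal
beats, by contrast, reproduces readily (intervals of a few hundred ms
interposed between 1000 ms sinus beats on fibrotic substrates).

## Problem sizes and numerical choices

The full 300×300 activation-map computation runs in the acceptance checks;
the stochastic property checks run on 100×100 grids with 600 ms trials and
10 seeds per condition, and the reproducibility checks on 24×24 grids —
sizes chosen to exercise the full pipeline while keeping a complete test
run on a laptop-class single core comfortably under half an hour.  All
randomness flows through R's RNG (the C++ integrator is deterministic), so
every artifact is bitwise reproducible under a fixed seed; this too is a
test.  Degenerate inputs (zero-amplitude stimuli, zero release probability,
zero beats, empty regions) are contracts with their own tests rather than
undefined behaviour.
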