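---
title: "Simulating the chemical stage of water radiolysis with independent reaction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the chemical stage of water radiolysis with independent reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtrad)
```

## The problem

When ionizing radiation deposits energy in water, the first picosecond
produces a highly nonhomogeneous spatial distribution of radicals and
molecular products — the *track structure*. Sparsely ionizing radiation
(fast Compton electrons from ⁶⁰Co γ-rays, LET ≈ 0.3 eV nm⁻¹) leaves
isolated, roughly spherical clusters of reactive species ("spurs") spaced
hundreds of nanometres apart. The soft β-electrons of tritium
(effective initial energy ≈ 7.8 keV, mean LET ≈ 5.9 eV nm⁻¹) deposit the
same chemistry in densely overlapping events along a ~1.3 µm path — a
"short track". Because radical–radical combination competes with
out-diffusion, the local density of reactants controls the yields of
molecular products, and molecular hydrogen in particular.

`irtrad` simulates the *nonhomogeneous chemical stage* — 1 ps to 10 µs at
25 °C — of both geometries, with the azide anion N₃⁻ and dissolved O₂ as
scavengers, and reports radiation chemical yields
(G-values, molecules per 100 eV of absorbed energy):
time-dependent G(t) per species, the *escape yield* (the plateau of G(t)
once track expansion is complete), and the cumulative extent ΔG(t) of
every reaction channel.

Everything before 1 ps (ionization, dissociative electron attachment,
geminate recombination, electron thermalization and hydration) is **not**
simulated mechanistically; it enters only through configurable 1-ps
yields. In particular the sub-picosecond H₂ from dry/subexcitation
electron chemistry is carried as the fixed initialization
g(H₂) = 0.34 molecule/100 eV.

## The independent reaction times method

Instead of propagating trajectories, the IRT method samples, for every
reactive pair, the time at which that pair *would* react if it were alone,
from the diffusion-controlled first-passage law for an isolated pair
starting at separation $r$ with encounter radius $R$ and mutual diffusion
coefficient $D$:

$$ P(T \le t) = \frac{R}{r}\,
   \operatorname{erfc}\!\left[\frac{r-R}{\sqrt{4Dt}}\right]. $$

A uniform variate $u \ge R/r$ means the pair never reacts; otherwise
$t = (r-R)^2 / \{4D\,[\operatorname{erfc}^{-1}(u\,r/R)]^2\}$
(`sample_pair_time()`). Homogeneously distributed solutes (azide, O₂, the
solvent itself) compete through pseudo-first-order channels with
exponential times at rate $k[\mathrm{S}]$ — the *scavenging capacity* —
using time-independent (steady-state) rates, i.e. no transient
Smoluchowski term. The event loop executes the globally earliest pending
time, removes the reactants, cancels their other channels, creates the
products and gives them fresh channels against all survivors.

Encounter radii are obtained by inverting the Smoluchowski relation
$k_{\mathrm{obs}} = 4\pi N_A D R$ for each observed rate constant
(`encounter_radius()`). A radiation-boundary (Collins–Kimball) kernel
`sample_pair_time_partial()` is provided for rate constants below the
diffusion limit; the default engine uses effective fully-diffusion-
controlled radii throughout, the common IRT practice, which preserves the
long-time rate of every channel by construction.

### Approximations the engine makes

* **Independent pairs.** Pair reaction times ignore the positions of
  third parties. This is the defining IRT approximation; its error is
  bounded empirically by the Brownian-dynamics oracle (below), which on a
  6-particle two-channel cluster agrees with the engine within the Monte
  Carlo resolution of a few thousand replicates (≈1–2%).
* **Secondary products.** Products are placed at the diffusion-weighted
  point between their parents — the expected contact point sits closer to
  the slower parent, $p = p_a + (p_b-p_a)\,D_a/(D_a+D_b)$ — and their new
  channel distances are measured against the *birth* positions of the
  survivors, with the pair-law clock restarted at the event time. This is
  the standard IRT secondary-reaction treatment.
* **Contact rule.** Particles born closer than an encounter radius react
  immediately after the 1-ps snapshot (at $t_0 + 10^{-6}$ ps), so the
  snapshot yields themselves remain exactly the configured initial
  condition.
* **Interaction cutoff.** A pair is given a channel only if its
  react-by-10-µs probability exceeds $10^{-5}$; the resulting cutoff
  (≈1.3 µm for the fastest channel) makes distant spurs chemically
  independent, which is what the physics of low-LET tracks says anyway.
* **No interparticle forces.** Coulomb attraction/repulsion between track
  ions is not modelled explicitly; its mean effect is absorbed by the
  observed rate constants and by the spur-width calibration.

## The reaction network

The network (`default_network()`) contains the three H₂-forming
radical–radical combinations with their 25 °C rate constants,

| id | reaction | k (M⁻¹ s⁻¹) |
|----|-----------------------------------|---------|
| R1 | e⁻_aq + H• (+H₂O) → H₂ + OH⁻      | 2.5×10¹⁰ |
| R2 | e⁻_aq + e⁻_aq (+2H₂O) → H₂ + 2OH⁻ | 6.2×10⁹ |
| R3 | H• + H• → H₂                      | 4.6×10⁹ |

the azide chemistry — N₃⁻ reacts fast with H• (k₄ = 3.15×10⁹) and very
slowly with e⁻_aq (k₅ ≤ 1.5×10⁶, bound used as the default), hydrazoic
acid HN₃ does the reverse (k₇ = 1.2×10¹⁰ with e⁻_aq, k₈ = 6.3×10⁷ with
H•), •OH is converted to the azide radical N₃• (k₉ = 1.2×10¹⁰), and N₃•
reacts with e⁻_aq, H•, H₂O₂, itself, N₃⁻ and O₂•⁻ (R11–R16) — the
electron–water channel (k₁₇ = 19 M⁻¹ s⁻¹, folded into a pseudo-first-order
rate with [H₂O] = 55.34 M), and an 11-reaction pure-water background set
(W1–W11) with constants from the standard 25 °C compilations. Constants
printed in the literature only as bounds or ranges (k₅, k₁₀, k₁₃, the
forward proton transfer k₆) default to the bound / upper end and are
overridable (`k_overrides`). Every reaction with fully specified products
is element- and charge-balanced at construction time, with the solvent
bookkept through an `n_water` column; channels whose products the
literature leaves unspecified are flagged terminal sinks.

Total azide is split between N₃⁻ and HN₃ by the Henderson–Hasselbalch
equation with pKa = 4.7 (`hn3_fraction()`; ≈0.5% HN₃ at pH 7) as a static
partition — the explicit in-track proton-transfer channel R6 ships
disabled. Ionic strength (defaulting to the azide concentration, NaN₃
being a 1:1 salt) rescales every channel between two ions by the
Brønsted–Bjerrum factor
$\log_{10} f = 1.02\,z_A z_B \sqrt{I}/(1+\sqrt{I})$.

## The synthetic track generator

The physical/physicochemical transport codes that would normally provide
the 1-ps configuration are out of scope, so `generate_track()` builds
parametric stand-ins:

* **Spur content.** Species counts are Poisson with mean
  $g_s E/100$ per spur of energy $E$; every anion (e⁻_aq, OH⁻) is created
  together with an H₃O⁺ partner, so each spur is *exactly* charge neutral
  and g(H₃O⁺) = g(e⁻_aq) + g(OH⁻) by construction. Default 1-ps yields
  (molecules/100 eV): e⁻_aq 4.2, •OH 5.0, H• 0.6, H₂ 0.34, OH⁻ 0.5,
  H₂O₂ 0.2, H₃O⁺ 4.7 (derived).
* **Spur energies** follow an exponential truncated to [6.6, 100] eV with
  mean 40 eV — the conventional shape of spur energy spectra; the mean is
  exposed in `spur_params()`.
* **Geometry.** Positions are isotropic Gaussians: σ = 4.3 nm for the
  hydrated electron (thermalization spreads electrons much farther than
  the heavy radicals), σ = 1.0 nm for everything else. In gamma mode the
  spur centres sit on a line with exponential gaps of mean
  (spur energy)/LET, so the deposited energy per unit length averages to
  the LET (0.3 eV nm⁻¹ → mean spacing >100 nm: independent spurs). In
  tritium mode events are drawn until they sum to exactly 7.8 keV and
  placed with the same rule at 5.9 eV nm⁻¹, giving overlapping clusters
  along ≈1.3 µm — the short track. The path is straight: local density,
  which the LET fixes, is what drives the chemistry; track tortuosity is
  cosmetic at this level.

### Calibration of the spur widths

The spur widths are the only free geometric parameters. They were fixed
by a single documented calibration: with all other defaults held at the
values above, σ(e⁻_aq) was scanned over 3.5–5.0 nm and set to the value
for which the azide-free, air-saturated, low-LET escape yield of H₂
matches the accepted 0.45 molecule/100 eV (equivalently, a chemical-stage
gain of 0.11 over the 0.34 initialization). The confirmation run
(1000 histories of 15 µm segments) gave a plateau of 0.451 ± 0.003 at
σ(e⁻_aq) = 4.3 nm. The calibration was performed once and not revisited;
the acceptance suite re-derives both numbers from scratch.

### What the generator does and does not emulate

It reproduces the 1-ps yields, the charge structure, the spur energy
spectrum, and the density contrast between isolated spurs and short
tracks — the features that drive scavenger competition and
radical–radical kinetics. It does **not** transport electrons from cross
sections: there are no δ-rays, no energy-dependent thermalization
distances, no track-end effects, and no dose-rate (track overlap)
effects. Passing tests therefore validate the chemistry engine and the
geometry → yield coupling, not the microscopic faithfulness of any single
track image.

## The Brownian-dynamics oracle

`bd_pair_survival()` and `bd_cluster()` implement a step-by-step
random-flight simulator for ≤10 particles: Gaussian displacements of
variance $2D\,\Delta t$ per axis, all pairwise encounter tests per step,
exponential clocks for first-order channels. Two accuracy controls
matter:

* the enforced step rule $\sqrt{2D_{\max}\Delta t} < R_{\min}/5$, and
* the bridging probability
  $\exp[-(r_1-R)(r_2-R)/(D\,\Delta t)]$ of having crossed the encounter
  sphere *within* a step that starts and ends outside it.

The bridging term is essential, not optional: without it, end-of-step
detection under-reacts by several percent at any step size the R/5 rule
permits — the same order as the statistical resolution of the IRT↔BD
comparison the oracle exists to provide. With it, the oracle reproduces
the analytic pair law to better than 1% at ordinary steps.

For partially controlled channels the oracle uses the volume-reactivity
(Doi) rule — react with probability $1-e^{-q\Delta t}$ per step inside
$R$ — with $q$ tuned by `bd_tune_q()` through the closed form
$k = 4\pi N_A D R\,(1-\tanh x/x)$, $x = R\sqrt{q/D}$, so its long-time
rate and ultimate capture probability match the Collins–Kimball kernel
exactly.

The oracle never runs in production simulations; it validates the engine
on a fixed 6-particle fixture (`inst/extdata/cluster6.csv`) with two
competing channels, on isolated pairs, and on the homogeneous scavenging
limit.

## Analysis conventions

* **Plateau (escape yield):** mean of G(t) over the final decade,
  1–10 µs, with a batch-mean standard error. The *changeover time* — the
  earliest grid time after which G stays within 2% of the plateau — is
  reported as a diagnostic of the spur lifetime (≈0.2 µs in gamma mode);
  it is never asserted against. A drift flag is raised if G still moves
  by >2% of the plateau across the final decade.
* **Chemical-stage gain:** plateau minus G(1 ps); the identity
  G(1 ps) + gain = plateau holds exactly.
* **Time grid:** 120 log-spaced points over [1 ps, 10 µs]. An event at
  time $t$ contributes to the first grid point ≥ $t$.
* **Errors:** histories are split into 20 batches; species G(t), channel
  extents and plateaus carry batch-mean standard errors. All results are
  bit-for-bit reproducible from the master seed; scans derive one
  independent seed per (mode, concentration) label so results do not
  depend on evaluation order.
* **Bookkeeping closure:** for every species,
  $G(t) = G(1\,\mathrm{ps}) + \sum_{\mathrm{forming}} \Delta G -
  \sum_{\mathrm{consuming}} \Delta G$ exactly, which the tests assert.

## Problem sizes

Full-scale study conditions are 150 histories of 150 µm segments in gamma
mode and 6000 whole-track histories in tritium mode. The shipped tests
and the acceptance script run the same pipeline at desk scale — gamma
mode as 400–500 histories of 15 µm segments (≈45,000–56,000 independent
spurs, which at 0.3 eV nm⁻¹ is statistically equivalent to fewer, longer
segments because spurs are chemically independent) and 100 tritium
histories per concentration — sizes chosen so that the Monte Carlo
standard error of an escape yield is ≈0.004–0.010 molecule/100 eV.

## Known limitations

* No dry-electron (pre-hydration) scavenging: at azide concentrations
  above ~1 M the real system shows an extra suppression of H₂ for γ
  irradiation that this model deliberately does not contain.
* No direct radiation action on the solute (a few percent of the energy
  at molar azide concentrations).
* 25 °C only; rate constants, diffusion coefficients and pKa are fixed at
  their room-temperature values.
* The Brønsted–Bjerrum correction is applied at its extended
  Debye–Hückel form well beyond the ionic strengths where that form is
  quantitative (I ≈ 5 M); results at the highest concentration should be
  read accordingly.
* Survivor positions are frozen at birth for the purpose of assigning
  channels to later products (the standard IRT approximation); the BD
  comparison bounds the resulting error at the cluster scale.
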