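---
title: "clockwave: model, fitness function and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clockwave: model, fitness function and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockwave)
```

clockwave simulates the evolution of gene regulatory networks that segment
a growing one-dimensional body axis, and ships the automated analysis
pipeline (genome pruning, signed loop census, Fourier classification of
oscillators) needed to interpret what evolves. This vignette is the
package's own account of the model, the choices behind every tunable
number, and what the tests do and do not establish.

## The model

### Genome and network

An individual's genome is an ordered list of genes, each with an upstream
regulatory region carrying transcription-factor binding sites (TFBS). There
are 16 gene types (0–15). A TFBS names the protein type that binds it and
whether the interaction activates (+1) or represses (−1); the set of sites
upstream of a gene therefore defines the gene's incoming network edges,
and `build_network()` makes this explicit as a signed directed multigraph
over types. Two special types exist: type 0 encodes the morphogen, which
is never transcribed — the tissue clamps and decays it — so sites upstream
of type-0 genes are present in the genome but functionally inert; and
type 5 encodes the segmentation protein, whose final spatial pattern is
what selection acts on. Duplicate genes of one type feed a single protein
pool ("one node, several copies"), and since gene types never mutate,
duplication cannot be followed by sequence divergence.

### Expression dynamics

Each cell holds 16 protein concentrations $G_0..G_{15}$. Every
non-morphogen gene copy is transcribed at

$$R = \max_j\!\Big(\frac{A_j^n}{A_j^n+H^n}\Big)\;
      \prod_k\frac{H^n}{I_k^n+H^n}\; E,$$

an activating OR gate (the strongest activator wins) times a repressive
AND gate, and proteins decay at rate $\delta$:
$\mathrm{d}G_i/\mathrm{d}t = \sum_{\text{copies}} R - \delta G_i$.
There is no basal term, so a gene without activating sites is silent —
which is what keeps the morphogen-free head silent for ever. Defaults are
$E = 100$, $\delta = 0.3$, $H = 60$, integrated by forward Euler at
$\mathrm{d}t = 0.2$.

The Hill coefficient $n$ is not part of the published parameter set. We
default to $n = 2$, the smallest coefficient that keeps input integration
strongly nonlinear (a requirement of the model: bistability of the
segmentation switch needs a sigmoidal self-activation); it is exposed in
`kinetic_params()` and quantitative outcomes shift with it.

Expression noise, when enabled, perturbs each gene copy's rate at each
Euler step: $R_{\text{actual}} = \max(0, R + \varepsilon)$ with
$\varepsilon \sim \mathcal N(0, (lR)^2)$, so the coefficient of variation
is constant across expression levels. $l \in \{0.07, 0.14, 0.21\}$ are the
low/medium/high settings of the study design; $l = 0$ short-circuits the
noise path entirely (bitwise identical to the deterministic code, no RNG
draws). The sampling frequency (per copy per step) is the finest
granularity consistent with the model description; when $l > 0$ one
standard-normal draw is consumed even for rates of 0 so that the R
reference stepper (`step_cell()`) and the compiled integrator stay aligned
draw-for-draw — useful for equivalence testing.

### Development

Embryos start as 14 cells: a 9-cell head with no morphogen and a 5-cell
posterior growth zone where the morphogen is clamped at $M_{max} = 100$
(inferred from the half-maximal gradient value of 50). The posterior-most
cell divides every 5 integration steps for the first 600 steps (120
divisions, 134 cells); the four other zone cells never divide. A cell
pushed out of the zone keeps its concentrations, and its morphogen then
decays as $M \leftarrow M(1-d\,\mathrm{d}t)$ per step — the same Euler
scheme and time base as gene expression, so "a time step" means one thing
throughout. Decay rate $d = 0.2$ gives the steep gradient
($\lambda = \ln 2/d \approx 3.5$ time units), $d = 0.025$ the shallow one
($\lambda \approx 27.7$). After growth, dynamics continue for another 600
steps so the youngest cells also reach low morphogen and can settle.
Daughters inherit an exact copy of the mother's state; no division noise
is applied. Within a step the order is fixed for determinism: morphogen
clamp/decay, then expression, then (on division steps) division.

The deterministic path of the compiled integrator stores the tissue as one
array per protein type, so Hill terms and the gate reductions vectorise
across cells; the noisy path updates cell by cell in a fixed order to keep
the RNG stream well-defined.

## Fitness

At the end of development the segmentation-gene pattern is averaged over
the final 100 steps (`control period`), which denies credit to patterns
that still oscillate. Cells are labelled high/low/transition by two
thresholds; the published rule set specifies no numeric cut, so we use a
scale-aware hysteresis pair: $\theta_{hi} = 0.5\,E/\delta$ and
$\theta_{lo} = 0.25\,E/\delta$ (half and a quarter of the maximal steady
state $E/\delta \approx 333$). Two thresholds rather than one avoid
label chatter for cells near a single cut.

Segments are maximal plateaus: same-state plateau runs merge across
intervening transition cells (only plateau-level cells count toward the
width); a plateau is scored when each side is a tissue edge or a valid
boundary — a transition to the opposite state completed within 5 cells.
Scored plateaus at least 7 cells wide are well-formed, narrower ones are
penalised as narrow. The all-zero head is itself a low plateau: that is
why a uniformly expressing body already makes two segments (the primitive
"two-segment stage"), and why the 134-cell geometry (129 scored cells)
caps at $1 + \lfloor 120/7 \rfloor = 18$ well-formed segments —
`max_good_segments()` verifies this by run-length dynamic programming plus
a witness pattern evaluated through the actual segment caller. The
posterior 5 growth-zone cells are excluded from scoring, but the zone
boundary may terminate the last segment.

The score is
$F = n_{good} - n_{narrow} - G\,n_{genes} - T\,n_{TFBS} - U\,n_{unstable}$
with $G = 5\times10^{-4}$, $T = 5\times10^{-5}$, $U = 0.1$; cells whose
segmentation-gene variance over the control period exceeds 5.0 count as
unstable (population variance; the estimator is not specified upstream,
and over a 100-step window the distinction is negligible). All cells are
counted, growth zone included — persistent oscillators therefore carry a
small constant penalty, which is dwarfed by one segment. Realised fitness
is $e^{\max(0,F)}-1$, and individuals missing any of the 16 gene types
cannot reproduce at all. Gene/TFBS counts refer to the full genome;
pruning (below) is analysis-only.

## Evolution

Populations live on a toroidal 30×30 lattice (at most one individual per
site, hence at most 900). Each evolutionary step applies, in a fixed
order: death (probability 0.5 per individual), Margolus diffusion (two
half-steps, one per 2×2 block partition, each block rotating ±90° with
probability ½), then reproduction: every empty site, visited in random
order, draws a parent from the individuals of its 7×7 neighbourhood with
probability $f_i/\sum_j f_j$, the offspring genome is mutated, developed
and scored, and fills the site. Parents are taken from the
pre-reproduction snapshot, so a newborn cannot parent in the same step; a
neighbourhood with zero total fitness leaves the site empty. The order of
the three phases is our choice (the processes are listed upstream without
an order), as are the toroidal boundaries and sequential-random site
filling.

Two implementation notes. First, a full Margolus update conserves the
checkerboard parity of a lone walker's position (each rotation moves an
occupant to an adjacent cell, and an update is two rotations), so single
individuals observed at update boundaries mix uniformly over one colour
class — with many individuals this is immaterial, but tests of the mixing
behaviour must account for it. Second, on lattices smaller than the
competition window the wrapped neighbourhood is deduplicated: an
individual competes once however often the torus repeats.

Mutation applies, in fixed order, gene duplication (copy inserted adjacent
to the original, with its sites) at 0.006 and deletion at 0.009 per gene;
then per site: weight flip (0.001), type randomisation (0.001),
duplication (0.0015), deletion (0.004); finally de-novo innovation of one
random site per gene at 0.001. Innovation is interpreted per gene (the
source material only says new sites appear spontaneously); per-gene keeps
its rate on the same per-element scale as the other operators. A site hit
by duplication and deletion in the same event keeps one copy (the two are
independent per-element events).

Runs start from 50 copies of a random founder: one gene of each type in
random order with Poisson(2) random sites each. When noise is off,
development is deterministic, so `run_evolution()` memoizes scoring by
serialized genome and reuses a parent's fitness for offspring whose genome
came through reproduction unmutated; with noise on, every birth is a fresh
realization evaluated once, at birth, never again. Every statistic is
reproducible bit-for-bit from (configuration, seed).

## Analysis pipeline

### Pruning

`prune_genome()` reduces an evolved genome to its functional core:
tentatively remove each gene (then each site) in genome order, re-develop
with noise off, and keep the removal if the pattern is preserved; repeat
until a full pass removes nothing, which makes the result a fixed point of
the procedure. The preservation criterion is deliberately the stricter of
the two readings the source material allows: same number of well-formed
segments AND same boundary positions within ±1 cell
(`criterion = "pattern"`); `criterion = "count"` relaxes to the segment
count alone. Deterministic order makes cores reproducible; greedy
first-improvement means the core is one minimal-ish genome, not the
global minimum.

### Loop census

`enumerate_feedback_loops()` lists all simple directed cycles of the
type-level graph by ordered depth-first search (each cycle found once,
rooted at its smallest node), with the loop sign the product of edge signs.
Duplicate sites with identical source, sign and target collapse to one
edge; antagonistic parallel edges stay distinct, and every sign
combination along a node cycle counts as its own loop. Self-loops are
size-1 cycles. A configurable cap (default $10^5$) guards against the
combinatorial worst case; hitting it flags the result truncated.
`complexity_report()` adds gene/TFBS counts, the loop-size histogram and
feed-forward loops (ordered triples X→Y→Z with the X→Z shortcut, counted
once per triple regardless of signs). The census is validated in the test
suite against brute-force enumeration over vertex permutations on random
6-node signed graphs.

### Fourier classification

Cells leaving the growth zone undergo too few oscillations for a direct
spectral analysis, so `frequency_profile()` re-runs a genome as a single
cell at each of 50 fixed morphogen levels (a linear grid over
$[0, M_{max}]$) for 1800 steps, drops the first 300 steps as transient,
Fourier-transforms every gene's trajectory (`stats::fft`), and keeps the
spectra of the gene with the globally largest oscillation amplitude.
Frequencies are reported in cycles per integration step; the dominant
frequency is the highest-amplitude non-DC bin, which for these relaxation
oscillators is the fundamental, so harmonic eigenmodes stay visible in
the stored spectra without affecting peak extraction. A level counts as
oscillating when its dominant amplitude reaches the oscillation floor of
1.0 concentration units (≈0.3% of $E/\delta$); the floor, transient and
grid are configurable and recorded with outputs, since none is specified
upstream.

`window_profile()` repeats the analysis in sliding windows (length 256,
stride 128) of the growth-zone-level series — amplitude decay across
windows is the damping diagnostic, so no transient is discarded there.
`classify_oscillator()` then applies, in order: damped if the last
window's dominant amplitude falls below 10% of the maximum window
amplitude (a reproducible stand-in for the visual inspection used
upstream; as the fraction tends to 0 every nonzero tail counts as
persistent); otherwise persistent, and sloped versus constant by whether
the frequency difference between the highest and the lowest oscillating
morphogen level exceeds 0.02 cycles/step — the published cut, interpreted
on the model's native time base. Profiles with fewer than two oscillating
levels are unclassified. `freeze_point()` reports the highest grid level
such that it and everything below is non-oscillating: the morphogen
concentration at which dynamics commit to a stable state.

## Fixtures: what the built-in genomes emulate

`make_fixture_genome()` hand-builds the circuit motif that evolves in
these simulations — a delayed negative-feedback clock gated by the
morphogen, coupled to a bistable switch on the segmentation gene:

* `delay_oscillator`: a chain of `ring_size` genes closed into one
  negative loop, driven by the morphogen. Delay in this model can only
  come from chaining genes (decay rates don't evolve); `ring_size = 5`
  (default) oscillates robustly and persistently, while `ring_size = 3`
  relaxes to a fixed point — a structurally identical damped
  counter-example.
* `bistable_switch`: a self-activating segmentation gene; with $n = 2$
  the latch threshold sits near 11 concentration units and the high state
  near 322.
* `gated_clock_and_switch`: one clock gene activates the switch, the next
  clock gene (a quarter period later) represses it through a doubled
  site — one copy is too weak to push the switch back below threshold —
  and self-activation latches the phase at which morphogen decay freezes
  the clock. Under the steep gradient this patterns several segments.
* `decorated_core`: the same circuit plus provably inert decoration
  (an extra gene copy listening only to silent genes, and sites
  referencing silent genes, which can never win an OR gate or attenuate
  an AND gate) — the pruning test's known answer.

The fixtures exercise every analysis operation without running evolution.
What they do not emulate: evolved genomes are messier (redundant copies,
interlocking loops), real data-scale networks, and anything involving
cell–cell signalling, which is outside this model altogether. Passing
fixture tests therefore establishes the pipeline's correctness on known
circuits, not the biological realism of any particular evolved outcome.

## Problem sizes and numerical choices in the test suite

The test suite runs the full developmental scale everywhere (1200 steps,
134 cells): single developments are cheap. Stochastic checks use sizes
chosen to make their 3σ bands decisive: $2\times10^4$ mutated genomes for
the duplication rate, $10^5$ draws for the noise moments, 120 replicate
lattice steps for fitness-proportional parentage. The smoke evolutionary
check runs 10 seeds per gradient on a 10×10 lattice for up to 2000 steps,
stopping a run as soon as its best individual reaches two well-formed
segments (the waiting time being the measured quantity, later steps
cannot change it); the two gradients use disjoint seed sets because a
shared seed can follow the identical trajectory under both gradients
whenever the route to two segments happens to be gradient-independent,
tying the comparison by construction. Full-scale replication (60 runs of
10,000 steps per condition, 30×30 lattice) is what
`experiment_config(kind = "batch")` exists for; it is a batch-size
change, not new code.

The Euler scheme is validated against a 20× finer step on the oscillator
fixture (periods agree within 5%); concentrations are clamped at zero
after each update as a guard for user-supplied parameter combinations
(with the defaults the scheme cannot undershoot). Morphogen decay shares
the integrator, so its discrete half-life crosses $\ln 2/d$ within one
step.

## Known limitations

* One-dimensional tissues only; no cell death, rearrangement, motility or
  cell–cell signalling.
* Kinetic parameters ($E$, $\delta$, $H$) do not evolve, by design.
* The Hill coefficient is an assumption ($n = 2$), not a published value.
* Segment-calling thresholds are scale-aware defaults, not published
  values; results are reported with the thresholds that produced them.
* The pruning order is fixed and greedy; cores are reproducible minimal
  genomes, not provably minimum ones.
* Classification inherits the arbitrariness of its cut-offs (0.02
  cycles/step, 10% damping fraction, 1.0 oscillation floor); all are
  exposed as parameters and echoed in outputs.
```
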