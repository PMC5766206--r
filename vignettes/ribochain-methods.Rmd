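---
title: "Thermodynamic design of RNA hybridization networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic design of RNA hybridization networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribochain)
```

## The model

`ribochain` treats a set of interacting regulatory RNAs as a network whose
nodes are strands or complexes and whose edges are hybridization reactions.
Four assumptions underpin everything:

1. RNA–RNA interactions are nucleated by *toeholds* — single-stranded
   complementary regions; an interaction whose toeholds are sequestered in
   intramolecular structure is kinetically blocked.
2. The ribosome-binding site behaves like a toehold for the ribosome:
   occluding it in the 5′ UTR represses translation (OFF), exposing it
   activates translation (ON).
3. Secondary-structure (2D) free energies suffice to explain the
   energetics; tertiary structure and protein assistance are neglected.
4. Multi-strand assembly is hierarchical: once two strands have hybridized,
   their intermolecular helix persists through later assembly events.

Each ordered interaction $i \to j$ is characterized by two scalars:

* the **hybridization free energy**
  $\Delta G_{ij} = E(\text{cofold}) - E_i - E_j$, the thermodynamic driving
  force (negative = favorable, and the more negative the more irreversible);
* the **activation free energy** $\Delta G^{\#}_{ij} \ge 0$, the kinetic
  barrier to nucleation.

The activation energy is computed as the *toehold-opening sum*: the energy
needed to refold each partner with its declared toehold window forced
single-stranded, summed over the two partners. This realizes "degree of
toehold exposure" as an energy: it is zero exactly when some
minimum-free-energy structure already presents the toehold, grows
monotonically with occlusion, and is computable with any backend. (The
choice is recorded as `activation_model: toehold-opening-sum` in every run
manifest, since other operationalizations — e.g. including nucleation-length
terms — are conceivable.)

## Energy backends

The folding engine is a pluggable contract (fold, cofold, constrained fold)
with two implementations.

The **internal model** is a stacking-only nearest-neighbour model: every
stack of two adjacent Watson–Crick pairs contributes $-2$ kcal/mol (a stack
involving a G·U wobble contributes $-1$ when wobble pairs are enabled;
they are off by default), isolated pairs and loops are free, hairpin loops
need three unpaired nucleotides unless a strand nick lies inside, and
stacks are not credited across a nick. Structures are pseudoknot-free.
Minimization is exact dynamic programming (in C++), including hard
constraints (forced-unpaired positions and frozen pairs). Co-optimal
structures are resolved deterministically to the lexicographically smallest
dot-bracket string; because a subsegment's dot-bracket is a contiguous
substring, this tie-break composes over the dynamic-programming
decomposition and is therefore exact, not heuristic. The model is
deliberately crude — its virtue is that every minimum can be verified by
exhaustive enumeration (`enumerate_structures()`), which the test suite
does for hundreds of random short sequences, tie-breaks included.

The **ViennaRNA adapter** shells out to `RNAfold`/`RNAcofold` (full Turner
parameters, temperature configurable, constraints via `-C
--enforceConstraint`) for realistic design work. It supports at most two
strands per fold — three-strand states therefore require the internal
backend. The exact ViennaRNA version in use is embedded in the backend
identifier and written into every report, since published parameter sets
differ between releases.

Temperature defaults to 310.15 K (37 °C, the growth temperature of the
host); it only affects the external backend's energies and the
energy-to-Kd conversion.

## The design objective

Sequences are chosen by minimizing an empirical linear function:

* each **desired** interaction contributes
  $w_\mathrm{des}\,(\Delta G_{ij} + \alpha\,\Delta G^{\#}_{ij})$,
* each **undesired** interaction contributes the negated aggregate
  $-w_\mathrm{undes}\,(\Delta G_{ij} + \alpha\,\Delta G^{\#}_{ij})$,
* the **RBS term** is
  $-w_\mathrm{off}\,\mathrm{open}(\mathrm{RBS}\mid\mathrm{UTR}) +
  w_\mathrm{on}\,\mathrm{open}(\mathrm{RBS}\mid\mathrm{ON\ complex})$,
  rewarding occlusion in the lone UTR and exposure in the assembled
  complex,
* optional **structural sub-objectives** add the base-pair distance to a
  target structure (a bias, not a constraint).

All weights default to 1 and $\alpha = 1$, i.e. the plain sum
$\Delta G + \Delta G^{\#}$ with no term preferred. Maximizing the raw
aggregate of undesired pairs (rather than hinging it at zero) is the
default because it matches the "minimize desired / maximize undesired"
formulation directly; a hinge variant
(`objective_weights(undesired_hinge = TRUE)`) is available since an
off-target pair that is merely *unfavorable* arguably need not be driven
ever higher. Terms are reported raw, not normalized by toehold or sequence
length.

**Which pairs are implicitly undesired?** Every unordered pair of declared
nodes not related by a desired interaction. Taking *ordered* pairs
literally would score the reverse ordering of each desired interaction as
undesired with the identical energetics and cancel the desired term
exactly, leaving the designer with no signal, so reverse orderings are
excluded, as are complex/member pairs (a complex trivially "hybridizes"
with its own member). Homodimers are computed and reported separately by
`evaluate()` but kept out of the objective: whether self-pairing belongs to
the undesired set is genuinely ambiguous, and keeping it visible but
unpenalized lets the user decide.

## Simulated annealing

`design()` runs Metropolis Monte Carlo over the mutable positions:
single-nucleotide substitutions at a uniformly chosen mutable position
(fixed regions such as the RBS and start codon are never touched),
acceptance probability $\min(1, e^{-\Delta/T})$, geometric cooling
$T \leftarrow cT$. Defaults: $T_0 = 5$ objective units, $c = 0.9$, 100
steps per temperature, 40 temperatures (4000 proposals; a planted
three-species fixture run takes roughly 20 s on one CPU). Species whose
mutability mask is all-`FALSE` are frozen, which implements sequential
design (design the sRNAs first, then the UTR, or vice versa); provided
sequences are used as the start state, otherwise mutable positions are
initialized uniformly at random. A run is fully reproducible from its seed,
and the per-step trace (current, proposal, accepted, best-so-far) is
returned as a tibble.

Proposals are substitutions only — no insertions or deletions — because the
network's windows and fixed regions pin species lengths. The fold cache
memoises every (sequence, constraint) pair within a run, so proposals that
touch one species re-fold only the terms that involve it.

## The planted fixtures

`generate_chain()` emits a three-species chain with a *planted solution*:
sequences are filled into structural templates from two complementarity
classes (A/U and C/G), so that under the internal model, by construction:
every desired interaction has $\Delta G_{ij} < 0$ and
$\Delta G^{\#}_{ij} = 0$; every implicitly undesired pair has exactly
$\Delta G_{ij} = 0$ (off-target duplexes are always shorter than the
intramolecular stems that would have to open first — a pseudoknot-forbidden
crossing); and the RBS is occluded in the lone UTR but exposed in the fully
assembled complex. The geometry follows the chain-reaction logic: each
middle species hides the head of its downstream domain in a stem whose loop
is the upstream toehold, so upstream binding (which must cross the stem)
forces the stem open and activates the domain.

The template constraints are explicit: the first toehold must be longer
than the stem it opens; the downstream domain must be longer than the
RBS-occluding stem (so invasion wins); and the *exposed* part of a hidden
domain must stay more than two pairs short of that stem (the margin covers
the re-pairing bonus that freed stem arms can collect after invasion).
Recipes violating any of these are rejected as infeasible, as are chains of
more than three species: with only two complementarity classes, two middle
species of a longer chain can trade both of their domain pairings in a
"double invasion" whose gain exceeds the protecting stems, so exact
off-target zeros are not constructible — a four-letter-alphabet limitation,
not a parameter choice. Orthogonal fixture pairs assign the two networks'
platform-invading domains to the two different classes, which yields zero
cross-talk entries and strongly negative cognate entries.

What the fixtures do *not* emulate: realistic base composition (domains are
homopolymeric), loop penalties and dangles, wobble pairing, cellular
context (transcription, degradation, Hfq), and kinetics. Passing tests on
fixtures therefore demonstrates the correctness of the machinery — folding,
energetics, objective, annealing, reporting — not the in-vivo performance
of any particular sequence; realistic design runs should use the ViennaRNA
backend and experimental validation.

A note on design recovery: annealing on the planted chain routinely finds
objectives *below* the planted optimum (e.g. a longer SR:SRR duplex). In
about one seed in ten the improved optimum buys a slightly favorable
off-target contact with part of the gain, so the strict sign pattern
(every undesired term exactly zero) is recovered in roughly 9 of 10 seeded
runs rather than all of them — the trade-off is a property of the
equal-weight objective, not a search failure.

## Equilibrium and gel quantification

`kd_from_energy()` converts a hybridization energy to a dissociation
constant via $K_d = C^0 e^{\Delta G/RT}$ with $C^0 = 1$ M and
$R = 1.987\times10^{-3}$ kcal/(mol·K); $\log K_d$ is exactly linear in
$\Delta G$ with slope $1/RT$ — the mechanistic reason a correlation between
measured log-Kd and predicted energies is the model's natural validation
surface.

`solve_equilibrium()` solves mass action for hierarchically defined binary
binding reactions (a complex may bind a further strand, mirroring SRR*
binding SRRR as a single unit). Single-reaction systems use the closed-form
quadratic; general systems use a damped multiplicative fixed point on the
free concentrations (`free <- free * (total/(free + bound))^0.5`),
iterated until the worst relative conservation residual falls below
1e-12 — well inside the 1e-9 the reports guarantee. The iteration is
deterministic and monotone for binding systems; non-convergence raises a
solver error with diagnostics rather than returning a bad state.

Gel conversions assume band intensity proportional to mass. The complex
band's mass fraction is turned into molar concentrations with the strands'
molecular weights (computed from sequence when not supplied) and the
reaction volume; the apparent $K_d = [A][B]/[AB]$ follows. The forward map
(`predict_mass_fraction()`) is the exact inverse. Saturated (fraction 1)
and empty (fraction 0) bands return 0 and $\infty$ with a flag;
stoichiometrically impossible fractions are errors. The default
normalization is complex mass over *total* loaded mass; per-band fractions
of a full multi-species solve are available through `mass_fractions()`.

## Validation statistics

`correlation_test()` implements the two-tailed Student $t$ test of a
Pearson coefficient, $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of
freedom. `energy_activity_regression()` fits ordinary least squares of
log-measured quantity on predicted energy. Natural logarithms are used for
every "log scale" quantity — the base rescales the slope but leaves $r$,
$t$ and $p$ invariant, which are the reported statistics.

`induction_objective_energy()` scores an induced state of a chain network:
the hybridization plus activation energies between the active upstream node
(the assembled sRNA complex when both inducers are present, a single sRNA
otherwise) and the 5′ UTR, plus the energy still needed to de-repress the
RBS within the resulting complex — implemented, again, as the RBS-window
opening energy in that structural context. The uninduced state is the zero
reference. With a single-sRNA state the window used on the sRNA side is its
declared toehold window from the network specification.

## Numerical choices and limitations

* Energies are compared with a 1e-9 absolute snap-to-zero to keep derived
  quantities (opening energies, $\Delta G_{ij}$ of non-interacting pairs)
  exactly zero.
* Windows are 0-based half-open everywhere, including YAML serialization;
  dot-bracket strings mark nicks with `&`.
* Sequence length is capped at 400 nt by default: the engine is exact
  (cubic time and, for tie-breaking, string reconstruction over co-optimal
  sets), not heuristic, and is meant for riboregulator-scale molecules.
* The exhaustive-enumeration oracle refuses sequences beyond 16 nt.
* Test problem sizes: the oracle suite checks 200 random sequences of 6–14
  nt; the design-recovery suite runs ten seeded annealing runs of 4000
  proposals each; parameter recovery uses 100 replicates of 12 noisy
  points. These sizes keep the whole suite under a few minutes on one CPU
  while leaving the checks statistically meaningful.
* Kinetic (rate-based) strand displacement, co-transcriptional folding,
  pseudoknots, partition functions and base-pair probabilities are out of
  scope; the activation energy is an equilibrium proxy for a kinetic
  quantity.
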