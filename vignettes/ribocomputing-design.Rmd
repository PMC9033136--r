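---
title: "Designing and simulating toehold-switch logic circuits"
author: "ribologic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating toehold-switch logic circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribologic)
```

## The system being modeled

A toehold switch is a de-novo-designed riboregulator: a hairpin whose
stem sequesters the ribosome binding site (RBS) and start codon, so the
downstream reporter is translated only when a complementary *trigger*
RNA invades the single-stranded 5' toehold and opens the stem.  An
*antisense* RNA complementary to the trigger annihilates it — by direct
hybridization or by strand displacement of switch-bound trigger — and
thereby implements NOT logic.  From these three species the package
compiles a family of RNA-only gates:

* **NIMPLY** (A AND NOT B): one switch + trigger (input A) + antisense
  (input B).
* **OR**: two orthogonal switch sensors concatenated with a 9-nt linker
  ahead of one reporter; either trigger activates it.
* **XOR** = (A NIMPLY B) OR (B NIMPLY A): two NIMPLY gates on one
  concatenated switch, cross-wired so each inducer drives the trigger of
  one arm *and* the antisense of the other.
* **NAND**: the XOR netlist with both triggers made constitutive — it
  differs from XOR only in the no-input row.
* **Half adder** (XOR → SUM, AND → CARRY), **half subtractor** (XOR →
  DIFFERENCE, NIMPLY → BORROW) and the reversible **Feynman** gate
  (BUFFER → P, XOR → Q), each pairing two sub-gates on shared inducers
  and distinct reporter channels.

Triggers and antisenses carry *extended overhangs*: single-stranded
extensions that pair with each other but not with the switch, giving the
trigger–antisense duplex a lower free energy than the trigger–switch
duplex.  That energy difference is the design's driving force — at
equilibrium the antisense, expressed in excess, wins the competition for
the trigger.  Single-nucleotide *bulges* at the overhang–core junctions
interrupt long double-stranded RNA (a ribonuclease-III substrate); a
*full-match* (bulge-free) antisense binds more tightly still and gives
the strongest repression.  The default design preset therefore uses a
3'-only overhang on triggers, a 5'-only overhang on antisenses and
bulge-free antisenses; the earlier both-ends-with-bulges variant remains
available as `design_config(preset = "initial")`.

## The internal energy model

All screening runs on an internal, dependency-free engine rather than a
full thermodynamic package.  Energies are dimensionless **units**, not
kcal/mol: the model is a *rank-ordering* device, adequate for comparing
candidate designs and for a qualitative equilibrium model, and it is
deliberately simple enough to verify against exhaustive enumeration.

* Pair energies GC −3, AU −2, GU −1; a stacking bonus of −0.5 for each
  pair placed directly on another.
* `fold_mfe()` is a Nussinov-style dynamic program over nested
  structures (minimum hairpin loop 3 nt) with the stacking term.
  Traceback ties are broken toward the pair with the smallest 5' index,
  then the smallest partner index, so folds are deterministic.
* `duplex_energy()` finds the best antiparallel intermolecular pairing:
  duplex initiation +2, and each interruption charged +3 **per
  looped-out nucleotide** (a single-nucleotide bulge costs +3; larger
  internal loops cost proportionally more).  The per-nucleotide reading
  matters: a flat per-interruption charge would let the alignment chain
  arbitrarily many short complementary runs — random 60×80-nt pairs then
  score almost as low as a designed 30-bp duplex, and crosstalk
  screening would be meaningless.
* Scores derived from the engine: `defect_score()` (normalised base-pair
  distance between the predicted fold and a declared target — a cheap
  stand-in for ensemble defect), `accessibility()` (unpaired fraction of
  a region in the MFE), `crosstalk_matrix()` (all-against-all duplex
  energies with cognate pairs exempt) and `long_duplex_check()`
  (contiguous duplex runs above 20 bp; bulges break runs).

Because the model has no loop-entropy terms, its MFE is *dense*: almost
every base that can pair does.  Two consequences shaped the defaults.
First, overhang candidates are screened for accessibility on their own
fold plus pairwise crosstalk against an avoid-list, rather than on a
joint fold with the core (in a joint fold of random sequences ≥ 80%
accessibility is essentially unattainable).  `generate_overhang()` still
accepts an explicit flanking context for callers that want the joint
criterion.  Second, a toehold counts as single-stranded when its own
fold contains no *stacked helix*; isolated pairs are treated as
breathing (a literal zero-pair criterion passes ~0.2% of random
12-mers).

### Calibration of the screening thresholds

The crosstalk thresholds are properties of the energy model and were
fixed once from its measured landscape (random-sequence duplexes):
incidental complementarity scores around −15 for 15-nt candidates
against 80-nt species and around −25 to −35 for full-length species
pairs, while designed interactions score −80 and beyond.  Defaults:
candidate overhangs must stay above −25 against every avoid-list
species; a compiled netlist is flagged when any unintended full-species
pair drops below −45; fixture libraries require non-cognate
trigger-core-versus-switch energies above −30.  All are configurable.
One screen exemption is architectural: an antisense is
sequence-identical to its sensor's stem-bottom strand, so its naive
duplex energy against the stem-top is large — but the stem-top is
sequestered by the folded hairpin, so this pair is not treated as
crosstalk.

`compile_gate()` / `compile_circuit()` perform in-silico candidate
selection: a candidate netlist is designed, screened, and redrawn with
shifted overhang seeds (deterministically) until the screen is clean,
up to `max_design_attempts`.

## The equilibrium model

Circuit behaviour is predicted in three stages.

**Transcription.**  Each wired species is transcribed at
`copy_scale[plasmid] * (leak + (1 - leak) * theta)` with a Hill function
`theta = c^n / (K^n + c^n)` of its inducer; constitutive and unwired
species have `theta = 1`.  Defaults: copy scales 1:3:9 for
low:medium:high plasmids (switches low, triggers medium, antisenses
high, so the antisense is always in excess), leak 0.02, Hill `K = 10`,
`n = 2`, logical-1 concentration 100.  These are invented, documented
relative abundances — no claim of matching cellular copy numbers.  The
arabinose-driven T7 polymerase induction is modeled as a global master
switch (`t7_induced`), default on.

**Competitive hybridization.**  Every sensor of a concatenated switch is
a binding site whose total equals the switch abundance.  The model
solves the simultaneous mass-action equilibria S + T ⇌ S·T and
T + A ⇌ T·A with association constants
`K = exp((dG_ref − dG) / energy_scale)`, `dG_ref = −60`,
`energy_scale = 3` — calibrated once so a full cognate duplex (≈ −88
units) sits deep in the strong-binding regime (`K·total ≫ 1`) while
incidental complementarity (≈ −30) stays weak (`K·total ≪ 1`).  The
solver is a damped fixed-point iteration on the free concentrations
(geometric damping on the trigger pool, which is the species pulled in
both directions), iterated to a relative tolerance of 1e−12 and checked
against conservation; it reproduces the closed-form two-species solution
to ~1e−10.  Because binding is at equilibrium, antisense capture of free
trigger and strand displacement of switch-bound trigger reach the same
final state — the model deliberately does not distinguish the two
mechanisms, and contains no kinetics.

**Readout.**  A sensor's occupancy is its bound fraction; an OR-type
concatenated switch reports `1 − prod(1 − p)` (sensors are assumed
independent), the black-box AND sensor reports `prod(p)`, and reporter
level = `basal + gain * fraction` (defaults 1 and 100).  Boolean calls
use a threshold calibrated per netlist as the geometric mean of the ON
and OFF levels of a reference BUFFER gate (the netlist's first sensor
with its cognate trigger at full induction versus at leak), overridable
by an absolute `threshold`.  `dose_grid()` evaluates the model over an
inducer concentration grid; for XOR the surface is high on the
single-inducer edges and low at both the (0,0) and (max,max) corners,
and `xor_digitality()` summarises edge-to-corner contrast (the default
requirement is one order of magnitude; the model typically delivers
~100×).  One caveat: interior grid rows (with the row inducer near its
Hill midpoint) are *not* unimodal in the crossing inducer — the
cross-wired antisense creates a valley before the other arm recovers —
so only the boundary rows respond monotonically.

## The synthetic part generator

No real part collection ships with the package (the characterised
switch sequences live outside the printed text and are deliberately not
guessed).  `make_switch_library()` generates orthogonal stand-ins with
the template anatomy used throughout: 12-nt toehold, 18-bp stem, 11-nt
loop containing the RBS `AGGAGG` exactly once, 21-nt linker starting
with `AUG`.  Candidates are drawn at random, must pass
`validate_switch()`, and are accepted only if the cognate trigger core
of each switch hybridizes with every other switch (and vice versa) above
the orthogonality threshold; the default `disjoint-kmer` scheme
additionally forbids sharing any complementary 6-mer between sensing
domains, bounding Watson–Crick runs by construction
(`random-screened` relies on energy screening alone).  Loop and linker
padding is drawn from {A, C} so it cannot seed extra RBS motifs or
strong structure.  Everything is deterministic per seed.

What the fixtures do **not** emulate: real switches have
sequence-context effects on translation initiation, RNase-mediated
turnover, and folding kinetics during transcription.  Passing tests on
fixtures therefore demonstrate the *design and model machinery*, not
wet-lab performance; measured fold-changes of living cells are outside
the model's claims.

## Numerical and design choices

* Coordinates are 0-based half-open internally; all sequences are
  stored 5'→3' RNA, and DNA input (T) is transliterated on load.
* Bulge base identity: the alphabetically first base that cannot pair
  (Watson–Crick or GU) with the base it faces across the cognate
  duplex; at a junction with no facing base, "A".
* The antisense overhang is the reverse complement of the trigger's
  cognate overhang (proximal portion) when one exists — that is what
  creates the driving force; it is searched de novo only when the
  trigger has no overhang on that side.
* BORROW convention: the half subtractor computes A − B with
  BORROW = (NOT A) AND B, i.e. "B NIMPLY A"
  (`borrow_convention = "A_nimply_B"` flips it).
* The AND gate is a black-box two-trigger sensor: two library sensors
  on one transcript with product readout; its internal split-trigger
  sequence design is out of scope.
* The Feynman BUFFER arm defaults to the third library switch (the same
  parts as the half subtractor) with an overhang-free trigger; the
  assignment is exposed as `buffer_arm_switch`.
* Operators (lac/tet) gate transcription of the whole cassette; the
  operator sequence itself is given no post-transcriptional role and is
  assumed not to disturb the core signalling structure.
* Equilibrium solver: at most 50,000 damped iterations; convergence is
  declared at a relative step below 1e−12, and solutions are rejected if
  any conservation residual exceeds 1e−6 after exhausting iterations.

## Problem sizes used by the test-suite

The tests run the whole pipeline at desk scale: libraries of 2–4
switches, folding-engine oracle equivalence on ~520 random sequences of
length ≤ 12 (folding) and ≤ 6 + 6 (duplexes) against exhaustive
enumeration, a 100-point solver sweep against the closed form, 50
random binding systems for the monotonicity property, ten end-to-end
seeds for the generator, and 4×4 inducer grids for the dose surface.
These sizes were chosen so the full suite exercises every claim in
well under a minute of compute while the enumeration oracles remain
exact.

## Known limitations

* Energies are model units; no temperature dependence, no pseudoknots,
  no partition function or pair probabilities (the defect score is an
  MFE distance, not a true ensemble defect).
* The equilibrium model ignores antisense–switch and
  switch–switch binding entirely (only S·T and T·A complexes exist),
  and treats sensors of one transcript as independent sites.
* No kinetics: systems with large strand-displacement barriers could in
  reality be slower than the equilibrium picture suggests; the bulge's
  kinetic role appears here only through its equilibrium energy cost.
* Reporter readout is a linear map of occupancy; translation-level
  effects (RBS crowding by 5' overhangs, loop-size trade-offs) enter
  only through the structural screens, not the output model.
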