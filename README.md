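# ribologic

Design and simulation of RNA-only logic circuits built from toehold
switches, trigger RNAs and antisense RNAs.

A toehold switch is a hairpin riboregulator that hides the ribosome
binding site and start codon in its stem; a complementary trigger RNA
invades the 5′ toehold and opens the stem, switching translation on.  An
antisense RNA that titrates the trigger implements NOT logic, and the
two together give a NIMPLY gate (A ∧ ¬B).  Concatenating two orthogonal
switch sensors with a 9-nt linker gives an OR gate, and cross-wiring two
NIMPLY arms on one concatenated switch gives an RNA-only XOR:

    A XOR B = (A NIMPLY B) OR (B NIMPLY A)

with inducer A driving trigger 1 *and* antisense 2, and inducer B
driving trigger 2 *and* antisense 1.  From these pieces the package
compiles two-bit calculators — half adder (SUM = A⊕B, CARRY = A∧B),
half subtractor (DIFF = A⊕B, BORROW = ¬A∧B) and the reversible Feynman
gate (P = A, Q = A⊕B) — on dual reporter channels.

The package is aimed at people designing or teaching synthetic
riboregulator circuits who want the whole pipeline — part anatomy,
sequence design rules, in-silico screening and behaviour prediction —
in one reproducible, dependency-light toolbox.

## What it does

* **parts** — typed RNA parts (switch, trigger, antisense, concatenated
  multi-sensor switch, circuit netlist) with validation, FASTA I/O
  (`key=value` headers + optional YAML sidecar), netlist JSON and
  GenBank-style cassette export.
* **design** — derives triggers (reverse complement of toehold + stem
  bottom) and antisenses, applies the overhang/bulge design rules
  (15-nt extended overhangs, single-nucleotide junction bulges,
  full-match antisenses, loop expansion) and searches overhang
  sequences by seeded rejection sampling under accessibility and
  crosstalk screens.
* **fold** — an internal Nussinov-with-stacking folding and duplex
  engine (Rcpp) providing MFE structures, duplex energies, a
  structure-defect score, accessibility, crosstalk matrices and a
  long-duplex (RNase III) check.  Energies are model units for rank
  ordering, not kcal/mol.
* **compile** — compiles BUFFER/NOT/OR/AND/NIMPLY/XOR/NAND and the
  two-output calculators into netlists, wires inducers to operators
  (IPTG→lac, aTc→tet), assigns low/medium/high plasmid copy levels and
  screens every candidate design for crosstalk, redrawing overhangs
  until clean.
* **simulate** — Hill-gated transcription, a competitive hybridization
  equilibrium solver (mass-action S+T ⇌ S·T, T+A ⇌ T·A with
  conservation to 1e−9), reporter readout, truth tables with
  calibrated Boolean thresholds, and inducer dose-response surfaces.
* **fixtures** — deterministic generation of synthetic orthogonal
  switch libraries and decoy RNAs so everything is testable without any
  external part collection.

## Worked example

```r
library(ribologic)

lib <- make_switch_library(fixture_spec(n_switches = 3, seed = 11))
nl  <- compile_circuit(logic_spec("HALF_SUBTRACTOR"), lib,
                       design_config(rng_seed = 5))
nl  <- assign_plasmids(wire_inducers(nl, c(IPTG = "A", aTc = "B")))
nl
#> circuit netlist [HALF_SUBTRACTOR]: 2 switch(es), 3 trigger(s), 3 antisense(s), 6 edge(s)
#>   inducers: IPTG->lac, aTc->tet
#>   plasmids: sw1+sw2:low, sw3:low, T1:medium, T2:medium, T3:medium, A1:high, A2:high, A3:high

nl$triggers[["T1"]]
#> trigger 'T1': core 30 nt, 5'oh 0 nt, 3'oh 15 nt, 1 bulge(s), operator lac

truth_table(nl)
#> truth table (threshold 26.6):
#>  IPTG aTc level_green call_green margin_green level_red call_red margin_red
#>     0   0           1      FALSE      0.03762     1.000    FALSE    0.03761
#>     1   0         101       TRUE      3.79858     1.002    FALSE    0.03767
#>     0   1         101       TRUE      3.79867   100.994     TRUE    3.79867
#>     1   1           1      FALSE      0.03762     1.000    FALSE    0.03761
```

The green channel is the XOR (DIFFERENCE) output and the red channel
the NIMPLY (BORROW) output: levels are predicted reporter units
(basal 1, ON ≈ 101), calls compare each level with the calibrated
threshold (geometric mean of a reference BUFFER gate's ON and OFF
levels, here 26.6), and the margin is level/threshold.  The table shows
correct half-subtractor behaviour on every input row: DIFFERENCE fires
on exactly one inducer, BORROW only for aTc without IPTG (A−B with
borrow = ¬A∧B).

A dose-response surface over an inducer gradient shows the digital
response of the XOR arm — high along the single-inducer edges, low at
both the no-inducer and both-inducer corners:

```r
m <- dose_grid(nl, list(IPTG = c(0, 5, 20, 100), aTc = c(0, 5, 20, 100)),
               reporter = "green")
xor_digitality(m)   # edge / corner contrast
#> 101
```

A command-line interface wraps the same functions:

```sh
ribologic fixtures --n 4 --seed 7 -o fixtures.fasta
ribologic compile  --circuit half_adder --library fixtures.fasta -o netlist.json
ribologic screen   --netlist netlist.json -o screen_report.csv
ribologic simulate --netlist netlist.json --grid "IPTG=0,5,20,100;aTc=0,5,20,100" -o grid.csv
```

See `vignettes/ribocomputing-design.Rmd` for the model, its
assumptions, parameter calibration and limitations.

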