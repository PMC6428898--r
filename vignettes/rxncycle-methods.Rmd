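---
title: "Methods: from reaction-contingency knowledge bases to cell-cycle phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from reaction-contingency knowledge bases to cell-cycle phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxncycle)
```

## The knowledge-base layer

A reaction–contingency system describes a signalling network at the
resolution of empirical observables. *Elemental states* are site-specific:
a bond between two domain loci (`Cdc28_[cyclin]--Cln2_[cdc28]`), a covalent
modification at a residue (`Sic1_[t2]-P`), or their neutral complements
(`--0`, `-0`). All states at one locus are mutually exclusive *for a single
molecule*; the model, however, tracks whether each state is present
anywhere in the population, so exclusivity is deliberately not enforced at
runtime (see below). Components without declared loci — genes, mRNAs,
target-specific enzymatic activities, small molecules — carry a single
presence state named by the bare component name.

*Elemental reactions* are indivisible events fully determined by their type
and their two component specs. Skeleton state sets
(produced/consumed/synthesised/degraded) are generated from a data-driven
catalogue (`default_reaction_types()`): bond formation produces the bond
and consumes both unbound neutrals, phosphorylation produces `-P` and
consumes `-0`, transcription/translation synthesise the linked mRNA's or
protein's neutral states, degradation degrades every state of its target,
and the coarse-grained (macro) entry types consume/produce bracketed global
macro states. The catalogue is a table, not code: a model file can bind its
own type names (e.g. the fourteen types of a genome-scale curation) through
an SBtab `ReactionTypeList` sheet.

*Contingencies* constrain reactions: `!` (requirement), `x` (complete
block), `k+`/`k-` (quantitative, non-blocking influence), and AND/OR/NOT
membership rows that assemble Boolean gates for complex requirements.
`k+`/`k-` are parsed, stored, round-tripped and exported as graph edges but
compile to no executable constraint — in a Boolean regime a "decreases"
influence that does not block must not alter firing, and this distinction
is what separates `x` from `k-` in curated models.

Validation (`validate_system()`) implements the turnover conventions of
curated cell-cycle models as warnings, not hard errors: every covalent
modification should be removable (phosphatase) or cleared by degradation of
its carrier, and every synthesised component should be degradable; a
per-row `no_turnover` flag lifts the assumption case by case (stable
scaffolding proteins, degradation-cleared phosphorylations). Undefined
effectors are errors and abort compilation; never-produced effectors are
reported (neutral states are exempt because the default initial state makes
them present).

## Compilation into the bipartite Boolean model

`compile_network()` produces one node per elemental state, reaction,
Boolean gate and global, in a fixed canonical order, so identical systems
yield byte-identical serialisations (`network_json()` — uniqueness is
tested by hashing). The update rules are:

* **Reaction** `R`: `presence(A) ∧ presence(B) ∧ ⋀(! effectors) ∧
  ⋀(¬ x effectors)`, where `presence(C)` is an OR over all of C's state
  nodes, neutrals included. Source states are *not* part of the reaction
  rule; a reaction node reads as "catalytic opportunity".
* **State** `s`: `Production ∨ (s ∧ ¬Consumption)`. Each producing
  reaction contributes `R ∧ ⋀(sources of R)`; synthesis contributes the
  bare reaction node; each consuming reaction contributes `R ∧ ⋀(other
  sources of R)`; degradation reactions covering `s` contribute their bare
  node. Degradation of a bound component also re-produces the partner's
  unbound neutral — without this, binding partners would stay sequestered
  in degraded complexes and cyclic behaviour would be impossible.
  Production deliberately overrides consumption: a state being actively
  produced and consumed in the same step remains present at the population
  level. One consequence worth knowing: a component whose states are being
  re-produced every step (constitutive synthesis, or a producing partner
  that is itself resynthesised) cannot be cleared by degradation alone;
  model wiring has to shut the producers off first, exactly as in the
  fixture's CDK-inhibitor module.
* **Gate**: AND/OR/NOT over its children, materialised as its own node
  with one step of propagation latency — gates are first-class nodes of
  the regulatory graph, and inlining them would change the published
  node-accounting of compiled models.
* **Global**: macro states produced/consumed by macro reactions follow the
  state rule; outputs defined only by contingencies follow the reaction
  rule without presence factors; pure inputs hold their value and are
  driven by clamps.

**Timescale separation.** Boolean time makes short reaction chains faster
than long ones regardless of biology, so slow processes — transcription,
and the coarse-grained replication/growth progression steps flagged `slow`
in the model file — receive delay chains (`insert_delays()`, default
`k = 20`): `d1 = u`, `d(i+1) = d(i) ∧ u`, `reaction = d(k) ∧ u`, where `u`
is the undelayed rule. The reaction fires at step `t` iff `u` held at every
evaluation in `t-k … t` (k+1 consecutive steps), and the chain resets on
any lapse. The chain gates on the *full* rule (presence factors included),
not only on the contingency part; with constitutively present components
the two conventions coincide, and the full rule is the conservative choice
when presence itself fluctuates. Delay soundness is tested against an
explicit sliding-window oracle.

**Default initial state.** All components present in native form: neutral
states true, bonds/modifications false, reactions/gates/delays false,
globals false. The placeholder input `[Histones]` is set true by default
when it exists — it stands in for a resource requirement of replication
that the model does not regulate. Overrides of unknown nodes are errors.

## Simulation and attractors

Updating is synchronous and deterministic; clamps (inputs, mutants)
override rules at every step including step 0. `find_attractor()` hashes
every visited state with its first-seen time; the first recurrence gives
the transient and the attractor, whose period is minimal by construction
(all states between the two visits are distinct). Exhausting `max_steps`
returns an explicit `budget-exceeded` outcome rather than a truncated
attractor. On small networks the detector is verified against a deliberately
naive oracle that stores the whole trajectory and linearly scans for
repeats. Release-then-arrest protocols (nutrients at step 0, a drug later)
are expressed as clamp schedules (`simulate_schedule()`).

## Phenotype classification

The coarse-grained readout (`cgm_map()`) declares the macro states of the
three replication cycles in stage order, plus which states mark completed
replication, nuclear division and cytokinesis. Classification
(`classify_attractor()`):

* **Viable / full cycle** — a cyclic attractor in which every cycle's macro
  states all activate during one period and their *first* activations
  follow stage order up to cyclic rotation (the operational meaning of
  "ordered traversal"; rotation is anchored at the first stage because an
  attractor block has no distinguished origin).
* **Lethal / partial cycle (multinucleate)** — cyclic, replication and
  nuclear division complete but cytokinesis never occurs; DNA and nuclei
  counts are unbounded.
* **Lethal / point arrest** — the stage comes from a data-driven decision
  table (`inst/extdata/arrest_stages.yaml`, first match wins): replicating
  DNA is S, replicated is G2/M, segregated is M; post-division profiles
  split into G1 versus T on the nuclei count alone, because both have
  licensed-or-absent DNA and differ only in whether nuclear division
  completed without cytokinesis. Nuclei (and DNA) counts are bookkept as
  `1 + completed nuclear divisions − completed cell divisions` along the
  recorded trajectory; the package reports DNA count equal to the nuclei
  count, i.e. the number of separate DNA masses, which is the convention
  that distinguishes the post-division arrest groups. Profiles matching no
  rule get stage `NA` with a warning — the table is data and extensible.
* Residual small oscillations that traverse no cycle (possible when
  synthesis/degradation pairs flip states with period two) are classified
  like point arrests on their union profile.

Mutants (`apply_mutant()`): deletion clamps all states of the component and
of its declared gene/mRNA false; an alanine lock clamps `-P` false and `-0`
true (phosphomimetics the reverse); overexpression clamps the transcription
reaction true. Benchmarks start every mutant from the wild-type
nutrient-free arrest state with nutrients clamped on, record per-row errors
without aborting the run, and summarise correct calls by expected class
plus a census of distinct arrest profiles.

## The synthetic models

`generate_random_system()` emulates the *structure* of curated knowledge
bases so that parser, validator, compiler and simulator can be exercised on
arbitrarily many cases: a synthesis/degradation scaffold first (stable
components excepted), then modification and binding decoration, then
contingencies sampled only among producible states, so generated systems
always compile. With `turnover = TRUE` every modification is guaranteed
removable or degradable, mirroring the curation assumption. The defaults
(10 components, 20 % stable, 0.6 modification and 0.8 binding rates, one
regulatory contingency per reaction, 15 % gates) give densities in the
range of curated signalling networks — roughly one contingency per
reaction, as in the genome-scale cell-cycle curation. What the generator
does **not** emulate: meaningful feedback architecture, a coarse-grained
layer, or biologically sensible attractors — generated systems test
mechanics and invariants, not biology, and passing them says nothing about
any real network's behaviour.

The **miniCDC fixture** (`build_minicdc()`) is the biological test surface:
~15 molecular components in three regulatory modules (G1/S: nutrient →
Cln3 → SBF → Cln2/Clb5 with a Sic1 inhibitor cleared by Cln2-CDK; G2/M:
Clb2 expression gated on replicated DNA AND a large bud; M/G1: mitotic CDK
releases Cdc14 from Net1, and free Cdc14 with segregated DNA and separated
SPB drives reset and cytokinesis), coupled to an 11-state coarse-grained
layer. Its exact wiring is an implementation artefact; the behavioural
contract is what tests assert: quiescent arrest without nutrients, ordered
three-cycle progression with them, pheromone and replication-block arrests,
G1 arrest on deleting the G1 transcription driver, viability on deleting
the CDK inhibitor. Three wiring choices deserve explanation:

* Entry into the macro cycles from the all-false global vector is through
  "macro synthesis" reactions (licensing, satellite, unbudded) inhibited by
  the other states of their cycle — the quiescent profile must be reachable
  from the default vector, which starts all globals false.
* The commitment transitions out of G1 additionally require `[Nutrients]`.
  The default initial vector has *every* protein present, which produces a
  one-step spurious pulse of CDK–cyclin bonds during the settling
  transient; commitment requiring growth keeps that pulse from advancing
  the cycle in the nutrient-free condition (and is biologically the right
  dependency).
* Stable loci-bearing proteins (the CDK scaffold, SBF, Far1, the
  cytokinesis factor) have constitutive synthesis flagged `no_turnover`.
  This pins their neutral states present, which both reflects a constant
  pool and avoids artefactual period-two flip-flops between a neutral and
  its modified/bound form when producer and consumer fire simultaneously.

The fixture is frozen: `inst/extdata/minicdc.tsv` must equal
`write_model(build_minicdc()$system)` bit for bit, and the wild-type period
(60 steps) and quiescence transient (29 steps), computed once by
simulation, are regression values in the fixture metadata. The bundled
14-row mutant table (`minicdc_mutants.tsv`) is synthetic: its expected
phenotypes are the fixture's designed outcomes, so the benchmark machinery
is expected to score 14/14 on it; it is a correctness harness for the
pipeline, not a biological benchmark.

## Numerical and interface choices

* Tables are the native representation; the SBtab dialect is a
  multi-table TSV (one `!!SBtab` declaration per table, discovered by
  declaration line, never by sheet name), with `.xls`/`.xlsx` workbooks
  read through readxl when installed. Row order is preserved into
  canonical order; unknown columns round-trip untouched; writing is
  deterministic, so write→parse→write is byte-stable.
* In the contingency sheet, `!Contingency` carries the modifier symbol and
  `!Modifier` the effector, following the deposited-model convention.
* Evaluation compiles update trees once into a single R expression over
  the previous state vector; a few hundred nodes over a few hundred steps
  simulate in milliseconds, and a ~3 000-node genome-scale compilation
  stays well under a minute.
* Degenerate inputs: empty systems parse, write (headers only), compile
  (empty network, empty initial vector) and graph (empty GraphML);
  `k = 0` delays are the identity; an empty mutant spec is the wild type.
* Problem sizes in the test suite — 200 random networks of ≤ 14 nodes for
  the attractor oracle, 100 random systems for round-trip identity, 60 for
  density calibration, sliding-window checks over 60–80 steps — are chosen
  so the full suite completes in about a minute while each property still
  covers its input space many times over.

## Known limitations

* The Boolean, population-level semantics cannot express quantitative
  redundancy or partial penetrance; an inhibitor that "decreases" a rate
  (`k-`) has no executable effect at all.
* Synchronous update makes some timing artefacts (period-two flip-flops,
  gate latency) part of the model; the delay machinery mitigates but does
  not remove them.
* The DNA/nuclei bookkeeping counts completed macro events; it does not
  model ploidy beyond "unbounded" for repeated uncytokinetic cycles.
* Asynchronous or probabilistic updating, attractor-basin enumeration over
  all initial states, and export to rule-based or ODE formalisms are out
  of scope.
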