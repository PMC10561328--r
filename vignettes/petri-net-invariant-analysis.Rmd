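---
title: "Structural invariant analysis of biological Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural invariant analysis of biological Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrinet)
```

## The model

A place/transition Petri net is a bipartite structure `N = (S, T; F)`:
places `S` hold nonnegative integer token counts, transitions `T` are events,
and weighted directed arcs `F` connect the two node types. A *marking* `M`
assigns a token count to every place and is the system state. In qualitative
systems-biology models, places stand for molecular pools or physiological
states (a hormone, a symptom) and transitions for the events that move the
system between them; tokens are the conserved "resource" whose flow the model
tracks.

The token game is the operational semantics. Transition `t` is *enabled* at
`M` when `M(s) >= pre(t, s)` for every place `s`; firing it produces

    M'(s) = M(s) - pre(t, s) + post(t, s).

Places outside the pre- and post-set of `t` are untouched, and a place that
`t` both consumes from and produces to (a self-loop) is left balanced when
the weights agree. The classical formulation uses unweighted arcs; this
package generalizes to positive integer weights so the same machinery covers
stoichiometric networks. For weight-1 ("ordinary") nets — including the
built-in model — the two formulations coincide.

## Incidence matrices and the state equation

With transitions as rows and places as columns (the orientation used
throughout; the transpose also occurs in the literature), the input matrix
`A-` collects the consumption weights, the output matrix `A+` the production
weights, and the incidence matrix is `A = A+ - A-`: the net token change per
place when each transition fires once. For a firing-count vector `x` over
transitions the *state equation*

    M' = M + x' A

gives the marking after any executable sequence with those counts. `A`
cancels self-loops, which is why `A-` and `A+` are kept alongside it (and why
the text formats serialize the pair, never `A` alone); nets with overlapping
pre/post arcs get an explicit warning in the analysis report.

## S- and T-invariants

An *S-invariant* (P-invariant) is a semi-positive integer place-weight vector
`Y` with `A Y = 0`: the weighted token sum `Y' M` is invariant under every
firing, so the support of `Y` is a *conserved place set*. A *T-invariant* is
a semi-positive transition-count vector `X` with `A' X = 0`: a firing-count
vector that, if realizable, returns a marking to itself — cyclic behavior,
e.g. a metabolic steady state. Some texts write the definition as `Y > 0`;
since published solutions routinely contain zeros, the standard semi-positive
reading (`Y >= 0`, `Y != 0`) is used — the only one consistent with solutions
that exclude places from the support.

Two deliberate wording choices: the package reports S-invariant supports as
"conserved place sets", not "paths" — a conservation relation carries no
ordering or pathway semantics; and minimal invariants here are
*minimal-support* invariants normalized to gcd 1, the usual basis for
biological interpretation.

### Enumeration algorithm

`minimal_s_invariants()` / `minimal_t_invariants()` use Farkas-style
(Martinez–Silva) row elimination in exact integer arithmetic. The tableau
starts as `[C' | I]` (one row per variable: its equation values and a unit
vector). Each equation column is eliminated by keeping zero rows and adding
all positive/negative row combinations scaled to cancel; every generated row
is divided by its gcd to control growth. The identity part of the surviving
rows yields semi-positive solutions; a support-minimality filter (drop any
row whose support strictly contains another's) and deduplication leave
exactly the minimal gcd-normalized invariants. Output is sorted
lexicographically by vector so results are byte-reproducible across runs and
platforms. An intermediate-row cap (100,000) turns pathological blowup into
a classed size error instead of memory exhaustion.

The elimination is cross-checked by an independent oracle,
`brute_force_invariants()`, which exhaustively enumerates all vectors with
entries up to `max_entry` and applies the same minimality filter. A simple
product guard on `places * transitions` would reject the 8-place built-in
model that the oracle is expected to validate, so the guard is on the actual
enumeration size instead (`(max_entry + 1)^dim <= 2^20`; 3^8 = 6561 vectors
for the built-in model, trivially cheap). The oracle is
complete only for invariants with entries `<= max_entry`; on the small
random nets used in the property suite (at most 5 places and 5 transitions,
weight-1 arcs) minimal invariants never exceed entries of 3, so
`max_entry = 3` is exact there.

## Behavioral analysis

`reachability_graph()` explores the reachable markings breadth-first, firing
transitions in index order, so node and edge orderings are deterministic.
Duplicate markings are detected by exact vector equality. The exploration is
capped (`max_markings`, default 100,000) and truncation is *flagged*, not
raised: unbounded nets are legal inputs, and a partial graph is still
reportable. Bounds (`place_bounds()`) and the dead-marking set are only
meaningful on complete graphs; `place_bounds()` raises a completeness error
on truncated input, while `full_report()` marks the summary partial.
`check_conservation()` verifies `Y' M' = Y' M0` for every reachable marking —
the behavioral face of `A Y = 0` — and `has_cycle()` links the absence of
T-invariants to the absence of reproducible markings.

## The built-in DANA model

`build_dana()` returns the package's reference model of dopamine and
norepinephrine action in depression: 8 places (Weakened Energy, Cognitive
Decline, Bradykinesia, intellectual disability, Anhedonia, Blocking
Depression, Norepinephrine, Dopamine), 6 transitions (Low Norepinephrine
Levels, Decreased Willpower, Low Dopamine Levels, Psychomotor Block, Feeling
Down, Thinking Slow), 18 weight-1 arcs, and one initial token each on
Bradykinesia, Norepinephrine and Dopamine. The authoritative source of the
structure is the pair of printed 6x8 input/output matrices, decoded row-major
into a frozen arc list; the acceptance tests compare all 3 x 48 matrix
entries against the digit strings verbatim. One decoded arc is biologically
surprising — the low-norepinephrine event consumes a token from the
bradykinesia place — but it is unambiguous in the matrices and implemented
as printed. Label capitalization is preserved verbatim, including lowercase
"intellectual disability".

```{r dana}
dana <- build_dana()
minimal_s_invariants(dana$net)
shared_support(minimal_s_invariants(dana$net))
```

The model has exactly two minimal conserved place sets and no T-invariant;
both conserved sets contain Bradykinesia, Anhedonia, Blocking Depression and
Dopamine, which the report renders as the states common to all conserved
subsystems — the structural reading that both hormones funnel into the same
depressive end states. That sentence is *derived* from the labeled shared
support at report time, never hard-coded, so the identical pipeline applies
to any annotated net. Norepinephrine (P6) is covered by no S-invariant: its
token is consumed without compensation, so its weighted count cannot appear
in any conservation relation.

## Randomness and the synthetic-net generator

`random_run()` draws uniformly from the enabled set at each step. The source
material for this package specifies only "at random"; uniform choice is the
natural noninformative reading, and the seed is recorded in the returned
trace so every simulation is reproducible. Seeding is scoped: the caller's
RNG stream is saved and restored.

`random_ordinary_net()` generates the property-test harness: every potential
place-to-transition and transition-to-place arc is included independently
with probability `arc_prob`, weight 1. This emulates the structural variety
of small qualitative models — sources, sinks, self-loops, disconnected
elements all occur — but not the features of curated biological nets
(sparse, largely connected, weight diversity, hub places). A green
oracle-equivalence run therefore establishes correctness of the elimination
on arbitrary small ordinary structures, not performance or numerical
behavior on large stoichiometric models. Test parameters (seeds 1..200, up
to 5 places and 5 transitions, arc probabilities 0.2/0.4/0.6) were fixed
before any test was run.

## Numerical and design choices

* All arithmetic is exact integer arithmetic; no tolerances exist anywhere.
  Equality of markings, invariants and matrices is exact.
* Entry magnitudes stay far below R's exact-integer range for doubles
  (2^53) on any net the size guard admits.
* Canonical orderings everywhere: transition index order for enabling and
  BFS, lexicographic vector order for invariants, declaration order for
  places. Repeated runs produce byte-identical reports.
* Degenerate nets are legal: transitions with empty pre-sets are always
  enabled (sources); a net may lack places or transitions but not both.
  The fully empty net is rejected by the constructor, so "empty model"
  format round-trips are defined on single-node-type nets instead.
* `M0` always denotes the *initial* marking; successor markings are never
  renamed to it.
* PNML identifiers are sanitized to XML NCNames on write, with original
  labels preserved in `name/text`; ids that are already NCNames round-trip
  unchanged.

## Known limitations

Timed, colored, stochastic-rate, inhibitor-arc and continuous extensions are
out of scope, as are siphons/traps, coverability trees, liveness
classification and model checking. Invariant enumeration is worst-case
exponential (the minimal-invariant set itself can be exponential); the
intermediate cap makes this an explicit error rather than a hang. The
reachability explorer enumerates states explicitly and is intended for
desk-scale qualitative models, not for nets with astronomically large state
spaces.
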