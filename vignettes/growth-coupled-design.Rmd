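---
title: "Growth-coupled knockout design: model, objectives and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled knockout design: model, objectives and search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdesign)
```

## The modeling framework

`gcdesign` works on constraint-based metabolic models: a stoichiometric
matrix $S$ (metabolites $\times$ reactions), flux bounds
$lb \le v \le ub$ (mmol gDW$^{-1}$ h$^{-1}$; the biomass pseudo-reaction
in h$^{-1}$), a biomass objective column and a product exchange column.
All evaluations assume steady state ($Sv = 0$) and are linear programs.
The assumptions inherited from flux balance analysis apply: fluxes are
population averages at metabolic steady state, the cell maximizes
biomass yield, and kinetic or regulatory effects are invisible.

A reaction knockout is modeled as $lb_i = ub_i = 0$ — deletion semantics,
not down-regulation. Models may arrive as SBML Level 3 with the `fbc`
extension or as COBRA-community JSON; infinite or very large bounds are
capped at $\pm 1000$ so every LP is bounded. Growth-rate floors (used
for the guaranteed-synthesis objective) and envelope growth fixing are
implemented as bounds on the biomass column, so every LP the package
solves has the same shape; the backend is the simplex of
`pracma::linprog` called in standard form (variables shifted to
$x = v - lb \ge 0$, upper bounds as inequality rows).

## The three objectives

Each knockout design is scored by a triple, all maximized:

* **Growth** $\mu^*$: the FBA optimum under the knockout.
* **Guaranteed synthesis** $p_{guar}$: the *minimum* product flux
  compatible with growth at $\ge (1-\tau)\mu^*$. The minimum — not the
  maximum — is what growth coupling guarantees: it is the flux the cell
  cannot avoid secreting while growing optimally. An optimistic maximum
  would score designs that merely *permit* synthesis.
* **Coupling strength** $CS \in [-1, 1]$, a summary of the production
  envelope (per-growth-level min/max product flux, computed on an
  evenly spaced growth grid):
  * $CS = -1$ if no flux distribution can make product at all;
  * if synthesis is guaranteed at maximum growth (coupled),
    $CS = \frac{\int_0^{\mu^*} p_{lo}(\mu)\,d\mu}{\mu^* \, p_{max}}$
    (trapezoidal on the grid) — the fraction of the growth–synthesis
    bounding box that the guarantee fills. It approaches 1 when
    synthesis is forced in proportion to growth at *all* growth rates,
    and small positive values indicate coupling only near $\mu^*$;
  * otherwise (uncoupled), $CS = -(\mu^* - \mu_{apex})/\mu^*$, where
    $\mu_{apex}$ is the largest growth at which maximum synthesis is
    still reachable. Designs that could synthesize maximally at nearly
    optimal growth score close to 0; designs whose synthesis requires
    sacrificing all growth score toward $-1$.

  This functional was chosen because it is continuous across the
  coupled/uncoupled boundary, bounded, invariant to rescaling all
  fluxes, and it orders uncoupled designs by the growth cost of
  synthesis — which is what lets a genetic algorithm climb from
  uncoupled toward coupled designs instead of facing a flat landscape.
  Because it is an ordinary function of the envelope object, an
  alternative score can be substituted without touching the search.

The classification reported alongside is: *no-synthesis*, *uncoupled*
($p_{lo}(\mu^*) \approx 0$), *weak* (synthesis guaranteed only near
maximum growth), and *strong* (guaranteed at every tested growth above
$f_{min}\,\mu^*$). The sign of $CS$ agrees with the coupled/uncoupled
split by construction.

One subtlety: $p_{max}$ is computed by a growth-unconstrained LP rather
than as the grid maximum of the envelope's upper bound, which
systematically under-reads the apex when it falls between grid points
and would bias $CS$ upward for coupled designs.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `K_max` | 5 | knockouts | genome length; hard cap per design |
| `pop_size` | 200 | individuals | NSGA-II population (even, $\ge 4$) |
| `crossover_prob` | 0.8 | — | per-pair uniform crossover |
| `mutation_rate` | 1/`K_max` | — | per-slot reset mutation |
| `time_limit` | 3600 | s | wall-clock budget |
| `stall_generations`, `stall_tol` | 50, 1e-4 | — | stop when archive hypervolume stalls |
| `tau` | 1e-3 | — | relative growth tolerance in $p_{guar}$ |
| `eps_p` | 1e-4 | mmol/gDW/h | product-flux zero threshold |
| `f_min` | 0.1 | — | growth fraction defining *strong* |
| `n_env` | 10 | intervals | envelope grid resolution |
| `min_growth_frac` | 0.01 | — | viability cutoff vs. wild type |

$\tau$ exists because on large models the vertex LP at exactly $\mu^*$
can be numerically brittle; on the small fixture networks the exact
guarantee is well defined, so worked examples and the test suite
evaluate with $\tau = 0$, where the hand-derived values (e.g. a
guarantee of exactly 4 for the respiration knockout) are exact. The
envelope grid `n_env` trades LP count against $CS$ resolution: the
trapezoidal error scales with the square of the grid step around kinks
of $p_{lo}$, and tests that compare against closed-form integrals use
20–50 intervals.

## Pre-processing (search-space reduction)

Three screens run in the order dead → lump → essentials, chosen to
minimize LP count (dead removal shrinks the lumping problem; lumping
shrinks the number of essentiality LPs):

1. **Dead reactions**: flux variability confined to $[-10^{-6}, 10^{-6}]$
   under the configured medium. The test is medium-conditional on
   purpose — the search operates under one condition, and a reaction dead
   on glucose need not be dead elsewhere.
2. **Lumping**: a metabolite consumed and produced by exactly two
   internal reactions fixes their flux ratio at steady state, so the
   pair collapses into one composite column (iterated, so unbranched
   chains of any length become one target). Composites preserve every
   expressible design's objectives exactly — this is the testable
   contract — and knocking the composite means knocking all members.
   Exchange, biomass and target columns never participate.
3. **Essentiality**: each surviving candidate is knocked out alone and
   excluded if growth falls below `min_growth_frac` of wild type
   (growth-essential) or maximum product flux reaches zero
   (synthesis-essential). Environment exchanges, the biomass and target
   columns, reactions whose bounds exclude zero (maintenance
   constraints), optionally gene-less reactions, and a user-supplied
   exclusion list are filtered beforehand.

"Environment exchange" deserves a precise definition: a boundary
reaction (touching exactly one metabolite) *without* a gene
association. Boundary-ness alone is not enough — a cofactor-consuming
respiration step can be modeled as a single-metabolite sink yet is a
perfectly good enzymatic knockout target, whereas `EX_`-style medium
exchanges carry no gene and encode the assay, not genetics. The same
rule governs which boundary reactions a target metabolite may resolve
to. Demand reactions for exchange-less metabolites are only ever added
on explicit request (`--add-demand`), since silently appending one
changes the design space.

## The search

NSGA-II with a fixed-length integer genome (`K_max` slots, 0 = no
knockout; duplicates and zeros drop out on decoding). Binary tournament
on (front rank, crowding distance), uniform crossover, per-slot reset
mutation, elitist environmental selection over parents + children, and
an *unbounded* external archive of every non-dominated design evaluated
anywhere in the run — the front reported at the end is not limited to
the final population. The initial population always contains the empty
design, so the wild-type point anchors the front from generation 0.
Designs below the viability cutoff evaluate to the sentinel
$(0, 0, -1)$, which any viable design dominates; LP failures also map to
the sentinel (with a warning) so one pathological design cannot abort a
long run. Evaluations are memoized by canonical knockout set, which is
observationally transparent and makes repeat visits free.

Termination is whichever comes first: wall clock, generation cap, or
relative hypervolume stall (reference point $(0,0,-1)$) over
`stall_generations`. With a fixed seed the entire run — including the
archive and the CSV written at the end — is reproducible byte for byte.

Post-processing removes redundant knockouts: each archived design is
scanned in ascending target order, a knockout is dropped whenever the
re-evaluated triple is no worse in all three objectives (tolerance
$10^{-6}$, ties count as removable — "no loss in performance"), and the
scan restarts after each removal until a fixed point. Only single
deletions are attempted, not subsets: the goal is minimality of the
reported design, not a global minimal-cut-set computation. Distinct
designs with identical fitness are all reported — they are genuine
alternatives for the lab, and dominance is strict.

## Numerical choices

* LP tolerances: flux zero threshold $10^{-6}$; simplex iteration cap
  5000 (tiny for these problem sizes).
* Envelope growth fixing uses a two-sided band
  $\mu_i \pm 10^{-9}\mu^*$, and the top grid point is backed off to
  $\mu^*(1 - 10^{-9})$, so vertex LPs at the envelope's right edge stay
  feasible.
* Crowding-distance ties keep input order (stable sort); tournament
  ties prefer the first-drawn individual; redundancy removal scans in
  ascending index order — all so that a fixed seed fixes the run.
* Degenerate inputs: an infeasible knockout evaluates to growth 0 (not
  an error); an empty candidate set after screening is a configuration
  error; an empty archive writes a header-only CSV and no plot, each
  with a warning.

## What the synthetic generator does and does not emulate

`random_coupling_family()` generates seeded bundles of parallel growth
pathways sharing a substrate and a redox-like cofactor with a closable
sink — the minimal motif behind real growth coupling, at a size where
exhaustive enumeration of small knockout sets is feasible and every GA
result can be checked against ground truth. `cofactor_ratio = 0`
produces families where no knockout can couple (a negative control);
one cofactor-linked branch suffices for a coupled single knockout (a
positive control). Round-number capacities keep every optimum exact in
hand arithmetic.

What it deliberately does not emulate: genome-scale dimensionality
(thousands of reactions), highly reversible interior cycles
(thermodynamically infeasible loops — no loopless constraints are
imposed, a known caveat of plain FBA), compartments, gene–protein–
reaction logic beyond a per-reaction flag, and cofactor promiscuity.
Passing tests on these fixtures therefore demonstrates correctness of
the algorithms — LP evaluation, reduction equivalence, Pareto logic,
refinement, determinism — not performance claims on real genome-scale
models, which additionally stress LP solver speed and search-space
size. Test problem sizes: fixtures of 7–12 reactions, populations of
16–20 for up to 60 generations, envelope grids of 10–50 intervals;
the genome-scale benchmark path accepts an iML1515 SBML file if the
user supplies one, and is exercised at that scale only then.

## Known limitations

* Reaction-level knockouts only; gene-level deletion logic is reduced
  to a per-reaction association flag.
* Plain FBA/FVA — no loopless constraints, parsimonious FBA, or flux
  sampling; envelopes can include thermodynamically infeasible loops.
* The LP backend is a dense textbook simplex: ample for fixture-scale
  and medium models, slow for genome-scale matrices compared to
  GLPK/CPLEX-backed tools.
* The coupling-strength functional is this package's own definition
  with the properties stated above; other tools' coupling scores are
  not numerically comparable even when the ranking agrees.
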