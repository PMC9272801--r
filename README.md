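# gcdesign

Pareto-optimal growth-coupled knockout design for constraint-based
metabolic models.

## The problem

A standard route to a microbial cell factory is to delete reactions from
the host's metabolic network so that making the product becomes
*obligatory* whenever the cell grows: synthesis is then growth-coupled,
and adaptive laboratory evolution — selecting faster growers — automatically
selects better producers. Good designs must balance three competing
quantities, so the result is not one strain but a Pareto front of
alternatives.

For a genome-scale model with stoichiometric matrix *S*, flux vector *v*,
bounds *lb ≤ v ≤ ub*, biomass flux *μ* and product exchange flux *p*,
`gcdesign` searches over knockout sets *d* (each knockout forces
*v_i = 0*) and maximizes simultaneously:

1. **Growth**: `μ*(d) = max μ` subject to `S v = 0`, bounds, knockouts
   (flux balance analysis);
2. **Guaranteed synthesis**: `p_guar(d) = min p` subject to the same
   constraints and `μ ≥ (1 − τ) μ*(d)` — the product flux the design is
   *forced* to secrete at (near-)maximum growth;
3. **Coupling strength** `CS(d) ∈ [−1, 1]`, computed from the production
   envelope (the feasible region of (μ, p) pairs):
   * `CS = −1` when synthesis is impossible;
   * coupled designs (`p_guar > 0`):
     `CS = ∫₀^{μ*} p_lo(μ) dμ / (μ* · p_max)` — the normalized area under
     the envelope's guaranteed lower bound, approaching 1 when synthesis
     is forced in proportion to growth everywhere;
   * uncoupled designs: `CS = −(μ* − μ_apex)/μ*` — minus the relative
     growth sacrifice needed to reach maximum synthesis, so "cheap"
     synthesis scores near 0.

The search is an NSGA-II genetic algorithm (non-dominated sorting,
crowding distance, elitist selection) over a fixed-length knockout
genome, preceded by model reduction (dead-reaction removal, lumping of
unbranched pathways, screening of growth- and synthesis-essential single
knockouts) and followed by removal of redundant knockouts from every
archived design.

## Worked example

The built-in seven-reaction fixture couples synthesis through a redox
cofactor: substrate A fuels growth via `GRW` (producing cofactor N) or a
small bypass `ALT`; N is drained by respiration `RSP` or by product
synthesis `PRD`. Deleting `RSP` forces synthesis to re-oxidize N.

```sh
Rscript -e 'gcdesign::write_model(gcdesign::toy_redox_model(), "toy.json")'
Rscript inst/exec/gcdesign.R --model toy.json --target EXP \
    --max-kos 2 --pop 20 --max-gens 30 --seed 1 --tau 0 \
    --envelope-points 50 --out front.csv --plot front.png
```

writes `front.csv` (and prints the same table):

```
design_id,knockouts,n_kos,growth_rate,product_flux,coupling_strength,coupling_class
D001,,0,10,0,-0.5,uncoupled
D002,RSP,1,6,4,0.26672,weak
D003,ALT|RSP,2,5,5,0.5,strong
```

Reading the rows: the wild type grows at 10/h but guarantees no product
(uncoupled, CS −0.5 because reaching maximum synthesis costs half the
growth). Deleting respiration (`RSP`) caps growth at 6/h but guarantees
4 mmol/gDW/h of product at that optimum — weak coupling, since slow-growing
cells may still make nothing. Additionally deleting the bypass (`ALT`)
trades one more unit of growth for full proportional coupling
(p = μ, CS = 0.5, strong). No design can improve one objective without
losing another: this is the complete Pareto front, as exhaustive
enumeration confirms.

A `front_provenance.json` with the configuration, seed, reduction map and
search statistics is written next to the CSV.

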