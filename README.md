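# optorf

Growth-coupled strain design with integrated metabolic and transcriptional
regulatory networks, in R.

## The problem

Computational strain design asks which genetic modifications make a
microbe secrete a target chemical *as a side effect of growing*, so that
adaptive evolution toward faster growth also selects for production.  The
classical formulation (OptKnock-style) deletes **reactions** from a
flux-balance model.  Two things go wrong in practice:

1. **Genes are not reactions.**  Multi-subunit enzymes, multi-functional
   enzymes and isozymes make the gene-reaction map many-to-many: removing
   one reaction may require several gene deletions, and those deletions
   usually take out additional reactions — sometimes all the way to a
   lethal phenotype.  Reactions without any associated gene cannot be
   removed at all.
2. **Regulation vetoes designs.**  A deletion strategy may depend on an
   enzyme whose gene is simply not expressed under the production
   condition, because a transcription factor represses it.

This package implements the gene-level alternative: design directly over
**gene deletions, transcription-factor deletions and gene
overexpressions**, with Boolean gene-protein-reaction (GPR) associations
and a Boolean transcriptional regulatory network compiled into the
optimization itself (the OptORF approach).

## The optimization

The core is a bilevel program solved as a single MILP via strong duality:

```
maximize    c'v  -  α Σ z_g  -  β Σ w_g            (product, penalized interventions)
subject to  v  ∈  argmax { p'v : S v = 0,           (the cell maximizes growth)
                           v_j ≥ lb_j (j ∈ J_LB),
                           v_j = 0 when d_j = 0 }
            GPR logic:        d_j = OR_n AND_{g∈G(n)} ŷ_g
            regulation:       y_g = OR_m (activators on, repressors off),
                              flux indicators  x = [v ≥ ε] / [v ≤ -ε]
            interventions:    ŷ_g = y_g - z_g + w_g,  z_g ≤ y_g,  w_g ≤ 1 - y_g,
                              Σ z ≤ K1,  Σ w ≤ K2
```

The inner LP is replaced by primal feasibility, dual feasibility
(multipliers `u_i`, `λ_j ≥ 0`, `μ_j ≥ 0`, removal duals `h_j ∈ [-1, 1]`
active only for switched-off reactions) and the objective-equality row.
Alternative designs are enumerated with integer cuts requiring at least
`δ` intervention differences.  Every returned design carries its measured
primal-dual residual and can be re-verified by direct simulation.

All LPs/MILPs are solved with the open HiGHS solver through a bundled
`scipy` bridge (`python` with `scipy ≥ 1.9` must be on the PATH).

## A worked example

The bundled five-reaction network converts substrate S to biomass via two
routes; the better-yielding route is activated by a substrate-sensing TF
that also represses a subunit of the competing route, so by-product P1 is
not made when growth is maximized:

```r
library(optorf)
m   <- example_network()      # uptake capacity 10 mmol/gDW/hr
env <- orf_environment()

solve_regulated_fba(m, env)
#> Regulated FBA [optimal]  objective = 1.2  growth = 1.2

optorf(m, env, design_spec("EX_P1", k1 = 2, k2 = 0))
#> Strain design (gene-level, regulated)
#>   deletions:       G6, TF1
#>   overexpressions: (none)
#>   growth = 0.8 1/hr   product(EX_P1) = 10
#>   objective = 10   |primal - dual| = 0.00e+00
```

Deleting the TF de-represses the blocked subunit *and* silences the genes
it activates, so two deletions suffice; growth drops from 1.2 to 0.8/hr
but every growth-optimal flux state now secretes P1 at 10 mmol/gDW/hr
(100% of the theoretical maximum).  Enumeration surfaces the full strategy
families — the two TF-deletion doubles, then the three-intervention
alternatives that overexpress the repressed subunit instead:

```r
enumerate_optorf(m, env, design_spec("EX_P1", k1 = 2, k2 = 1), n = 6)
#> Design enumeration: 4 solution(s)
#>    1. ΔG6 ΔTF1          product = 10  growth = 0.8
#>    2. ΔG4 ΔTF1          product = 10  growth = 0.8
#>    3. ΔG3 ΔG4 +G1A      product = 10  growth = 0.8
#>    4. ΔG5 ΔG6 +G1A      product = 10  growth = 0.8
```

The reaction-level baseline shows why gene semantics matter.  Its best
single deletion (R5) needs both isozymes G5 and G6 knocked out, and that
strain is lethal once regulation is considered — while the gene-level
design stays viable and coupled:

```r
reevaluate_designs(m, env, list(list(reactions = "R5"), c("TF1", "G4")),
                   product = "EX_P1")
#>   id deletions overexpressions growth product yield_pct lethal
#> 1  1     G5;G6                  8e-05   1e-03     1e-02   TRUE
#> 2  2    TF1;G4                  8e-01   1e+01     1e+02  FALSE

min_overexpression_rescue(m, env, c("G5", "G6"), "EX_P1")$genes
#> [1] "G1A"
```

Other entry points: `optknock()` / `enumerate_optknock()` (reaction
deletions), `production_envelope()` (min/max product across growth
levels), `minimal_gene_cover()` (fewest gene deletions removing a reaction
set, with collateral damage), `yield_percent()`, `intervention_stats()`
(frequencies and co-occurrence correlations across design lists), and
`verify_design()` (re-simulation plus coupling robustness).  Models load
from SBML Level 3 (fbc), a JSON serialization, or a plain TSV dialect, with
regulatory rules as a two-column `target / rule` table
(`load_model()`); a command-line wrapper with `simulate`, `envelope`,
`optknock`, `optorf`, `cover`, `audit` and `stats` subcommands is in
`inst/cli/optorf-cli`.

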