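---
title: "Gene-level growth-coupled strain design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level growth-coupled strain design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind the package: what is being
optimized, which constraints encode the biology, which knobs matter and why
their defaults are what they are, and where the numerical edges lie.

## The integrated model

A model couples three layers:

* **Metabolism.** Metabolites $i$, reactions $j$ with stoichiometric matrix
  $S$, and steady-state mass balance $S v = 0$ over fluxes $v_j$
  (mmol/gDW/hr; the biomass reaction in 1/hr).  The environment sets
  exchange lower bounds: uptake is negative flux, so a maximum glucose
  uptake rate of 18.5 mmol/gDW/hr is the bound $v_{\mathrm{EX}} \ge -18.5$.
  Irreversible and exchange reactions carry finite lower bounds (the set
  $J_{LB}$); reversible fluxes are otherwise free.  Finite upper bounds are
  supported but the bundled generators do not use them: boundedness comes
  from stoichiometry plus uptake limits, mirroring common practice of
  avoiding large artificial box bounds.
* **GPR associations.** Each reaction with a known gene-protein-reaction
  rule is feasible ($d_j = 1$) iff at least one of its enzyme complexes is
  present ($b_n = 1$), and a complex is present iff all its subunit genes
  are expressed.  GPRs are AND/OR trees over genes (no negation); they are
  compiled to disjunctive normal form, complexes being the conjunctions.
  Reactions without a GPR are never constrained by gene states.
* **Transcriptional regulation.** Boolean rules give the condition under
  which each regulated gene is expressed or each transcription factor (TF)
  is active; targets without a rule are constitutive.  Rules are compiled
  to DNF: a target is on iff some condition holds, a condition holds iff
  all its activator effectors are active and all repressor effectors are
  inactive.  Effectors are TFs, environmental stimuli (absent unless the
  environment lists them), or flux indicators: a positive-flux effector is
  active iff $v_r \ge \varepsilon$ and a negative-flux effector iff
  $v_r \le -\varepsilon$, with $\varepsilon = 10^{-3}$ by default.  Flux
  indicators are what tie expression states to the metabolic state, e.g. a
  substrate-sensing TF that is active exactly when the substrate exchange
  carries uptake flux.

Regulated flux balance analysis (`solve_regulated_fba()`) maximizes an
objective over fluxes *and* Boolean variables jointly, demanding a
consistent fixed point of the whole system.  TF-over-TF rules may be
cyclic; the MILP accepts any consistent fixed point, and when several exist
the solver's choice is reported rather than hidden (`evaluate_state()`
enumerates fixed points at fixed fluxes and returns their count).  A
contradictory cycle (no fixed point) is an error naming the cycle.

## Interventions

Deletions $z_g$ and overexpressions $w_g$ act on expression through the
surrogate state $\hat y_g = y_g - z_g + w_g$ with $z_g \le y_g$ and
$w_g \le 1 - y_g$: only an expressed gene can be deleted and only a
repressed gene can be overexpressed; overexpression means forcing a
repressed gene on, never raising a flux bound.  TFs can be deleted but not
overexpressed (an indicator that would force an inactive TF active has no
mechanistic meaning in the Boolean model).  `apply_perturbations()` exposes
exactly this algebra and treats the forbidden combinations as errors.

When *auditing externally supplied designs* (`reevaluate_designs()`,
`min_overexpression_rescue()`, `verify_design()`), deletions instead force
genes off regardless of their regulated state.  This is deliberate:
reaction-derived gene sets legitimately contain genes that regulation
already switches off, and the audit's question is what the strain does,
not whether the intervention list is economical.

## The bilevel designer

The engineering question is bilevel: choose interventions maximizing
product secretion *at the growth optimum the perturbed cell itself would
reach*.  The inner problem — maximize biomass subject to mass balance,
bounds, and $v_j = 0$ for switched-off reactions — is an LP for fixed
binaries, so it is replaced by its optimality conditions: primal
feasibility, dual feasibility, and objective equality.  The dual carries a
free $u_i$ per metabolite, $\lambda_j \ge 0$ per finite lower bound,
$\mu_j \ge 0$ per finite upper bound, and a removal multiplier $h_j$ per
deletable reaction that is released only when the reaction is off
(enforced by $|h_j| \le h_{\max}(1 - d_j)$).  Objective equality reads
$p^\top v = \sum_j \mu_j ub_j - \sum_j \lambda_j lb_j$.

Two design surfaces share this block:

* `optorf()` — gene-level: binaries over gene/TF deletions and metabolic
  overexpressions, with the GPR and regulatory layers mapping them to
  reaction availability.  Outer objective
  $c^\top v - \alpha \sum z - \beta \sum w$.
* `optknock()` — reaction-level baseline: binaries directly on reactions,
  no GPRs, no regulation.  This is intentionally the semantics whose
  failure modes the gene-level designer avoids; `minimal_gene_cover()` and
  `reevaluate_designs()` quantify them (extra gene deletions, collateral
  reaction loss, regulated lethality).

Key parameters, defaults, and rationale:

| parameter | default | meaning |
|---|---|---|
| `k1`, `k2` | 2, 0 | caps on deletions / overexpressions |
| `alpha`, `beta` | $10^{-6}$ | per-intervention penalties; an intervention must buy at least this much product, which prunes gratuitous modifications without moving the optimum |
| `delta` | 1 | minimum intervention differences between enumerated designs (integer cuts on the $z, w$ vectors) |
| `min_growth` | 0.1 /hr | inner-LP lower bound on biomass; designs that cannot reach it are infeasible rather than returned |
| `epsilon` | $10^{-3}$ | flux-indicator threshold; configurable because toy-network fluxes may need rescaling |
| `big_M` | 1000 | linearization bound for flux gating and indicator constraints; far above any attainable flux at the bundled uptake rates |
| `h_bound` | 1 | removal-dual bound; a speed device, not a theorem |

The $h$ bound deserves its caveat: clamping dual variables can only
*exclude* candidate designs (weak duality still forces any accepted flux
vector to be inner-optimal), never admit a spurious one, but an
aggressive bound could hide the true optimum.  Every design object carries
its measured $|$primal $-$ dual$|$ residual, and `verify_design()`
re-solves the regulated FBA with interventions fixed, comparing growth and
product and reporting coupling robustness (the *minimum* product among
growth-optimal states — positive exactly when production is
growth-coupled).

### Enumeration and ties

`enumerate_optorf()` adds one integer cut per stored solution and solves
again; objectives are non-increasing.  Inside a cut-constrained subproblem
a redundant intervention can tie with a genuine alternative (e.g. after the
best double knockout is excluded, "that double plus a harmless
overexpression" ties with the real three-intervention alternative), so the
enumerator re-checks leave-one-out minimality of each candidate by direct
simulation and drops non-minimal ones while keeping their cuts.  The
reaction-level enumerator instead uses superset-excluding cuts (at least
one reaction of each stored set must stay) plus a deletion-minimizing
second stage against the attained product.

## The worked example and the generator

`example_network()` is the package's five-reaction pedagogical network: a
substrate converted to biomass via two routes, the better-yielding route
regulated by a substrate-sensing TF that also represses one subunit of the
alternative route's first enzyme.  Its whole design space is solvable by
hand, which makes it the anchor for the test-suite: wild-type growth
0.12 per unit uptake, by-product 1 uncoupled; a two-intervention strategy
with the TF deletion couples it, and three-intervention alternatives
overexpress the repressed subunit instead.  The default uptake of 10 puts
mutant growth (0.8/hr) safely above the 0.1/hr minimum-growth default.

`random_toy_model()` generates seeded test fixtures in the same idiom: a
substrate-to-biomass backbone (so growth is always attainable), two
terminal reactions secreting distinct by-products with different biomass
yields drawn from 0.05–0.3 (so coupling trades are possible), random
single-gene / two-subunit / isozyme-pair GPRs, a substrate-sensing first
TF, and random activator/repressor rules over one to three metabolic
genes.  All internal reactions are irreversible, which keeps the LPs
bounded without box constraints.  These networks emulate the *structure*
that makes gene-level design differ from reaction-level design —
isozymes, complexes, regulation — but not the scale, flux magnitudes,
cofactor stoichiometry or rule depth of a genome-scale reconstruction;
green tests certify the algorithms' correctness at toy scale (where
exhaustive enumeration is possible), not biological fidelity.

The brute-force oracles in the test-suite enumerate intervention subsets ×
flux-indicator assignments × Boolean fixed points and solve two plain LPs
per candidate (inner growth, then product at fixed optimal growth with the
indicator pattern imposed).  The acceptance checks compare designer
objectives against these oracles to $10^{-6}$ on 25 seeded networks of up
to 8 internal reactions, 5 genes and 2 TFs — sizes chosen so the
exhaustive oracle remains exact and the whole suite runs in minutes.

## Numerical choices and degenerate inputs

* LP/MILP feasibility tolerance $10^{-6}$, integrality $10^{-5}$ (solver
  defaults of HiGHS); binaries are read back with a 0.5 threshold.
* At a flux exactly equal to $\pm\varepsilon$ both indicator states are
  admissible (closed inequalities on both sides); this measure-zero
  degeneracy is inherent to threshold indicators and the fixed-point
  evaluator uses the closed convention $x = [v \ge \varepsilon]$.
* The indicator semantics admit a sub-threshold "leak": a flux in
  $(-\varepsilon, 0)$ counts as *no* uptake signal, so a
  regulation-starved strain can retain a vanishing growth rate of order
  $\varepsilon$ instead of exactly zero.  The solver layer flags growth
  $< 10^{-6}$ as zero-growth; the audit layer calls a strain lethal below
  `min_growth`, which is the scientifically meaningful threshold.
* Infeasible and unbounded LPs are reported as distinct statuses; an
  unbounded *product* objective is possible only through internal flux
  cycles, which the bundled generators exclude by construction.
* Ties between equally-valued designs are broken by the solver;
  enumeration is the supported way to surface alternatives.  Identical
  seeds and inputs give identical artifacts (HiGHS is deterministic
  single-threaded); where multiple regulatory fixed points exist the
  choice among them is solver-determined and exposed via the returned
  Boolean state.

## Solver backend

No LP/MILP solver is available as an R library in this package's target
environment, so all problems are assembled in R (sparse triplet form) and
solved by HiGHS through a small JSON bridge to `scipy.optimize.milp`
(`inst/python/milp.py`), batched so that oracle-style workloads of
thousands of tiny LPs pay one interpreter start per batch.  The bridge is
an implementation detail behind `solve_fba()` and friends; nothing in the
package's modeling logic lives in Python.

## Known limitations

* Boolean regulation only: no graded expression levels, no kinetics, and
  no iterated (time-stepped) regulatory dynamics — the constraints demand
  a simultaneous fixed point.
* Overexpression cannot exceed a reaction's capacity since it only flips
  expression states; flux modulation (partial up/down regulation) is out
  of scope.
* No parsimonious-FBA, loopless constraints, or MOMA-style objectives.
* Genome-scale design MILPs are expected to be slow with open solvers;
  `design_spec(time_limit = ...)` returns the incumbent with its
  optimality gap rather than blocking indefinitely.

```{r}
library(optorf)
m <- example_network()
env <- orf_environment()
enumerate_optorf(m, env, design_spec("EX_P1", k1 = 2, k2 = 1), n = 6)
```
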