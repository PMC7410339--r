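# cutsets

Minimal cut sets (MCS) for constraint-based metabolic models: computation of
intervention strategies — reaction and gene deletions combined with reaction
additions — that make *every* undesired steady-state flux distribution
infeasible while provably keeping desired behaviour (growth, stress
tolerance) possible. The package is aimed at people doing computational
strain design and metabolic network analysis: given a stoichiometric model,
one or more *target* flux regions to eliminate and *desired* regions to
protect, it enumerates all cost-minimal intervention sets up to a budget.

## The method

A metabolic network with stoichiometric matrix **N** constrains steady-state
fluxes by **N r = 0** and bounds *lb ≤ r ≤ ub*. A **target region** is a
polyhedron **T r ≤ t** of undesired flux states (for growth-coupled design,
typically all states with product yield below a threshold,
*r_P − Y·r_S ≤ 0*, plus a minimum uptake that excludes the zero flux
vector); a **desired region** **D r ≤ d** holds the states that must survive
(e.g. *r_BM ≥ 0.1*). A cut set must empty every target region and leave a
witness in every desired region.

Emptiness of a target region is certified by Farkas duality: the region is
infeasible exactly when multipliers *(u, v, w)* exist with

```
Nᵀ u + v + Tᵀ w = 0,    tᵀ w ≤ −c,    w ≥ 0     (c = 1)
```

where *v_i* must vanish for present reversible reactions, may only be
negative for present irreversible reactions, and is free exactly when
reaction *i* is removed. Binary indicators *z_i* (one per targetable unit)
gate the *v_i* through sign markers, every desired region enters as an
explicit primal flux block with knockout-gated bounds
(*lb(1−z) ≤ r ≤ ub(1−z)*; inverted, *z·lb ≤ r ≤ z·ub*, for addable
reactions), and the MILP minimizes the weighted intervention cost
**Σ p_i z_i**. Enumeration proceeds by re-solving under integer cuts
**Σ_{j∈C} z_j ≤ |C|−1**. Every reported solution is re-verified against a
plain LP oracle and reduced to minimal support.

Around this core the package implements the preprocessing that makes the
MILP tractable and gene-true:

* **GPR integration** — Boolean gene–protein–reaction rules become
  enzyme-pool pseudo-metabolites and pseudo-reactions, so gene knockouts are
  reaction knockouts; the encoding provably preserves all original flux
  ranges (no isoenzyme flux inflation).
* **GPR compression** — seven reduction rules (blocked-rule removal,
  protection of genes serving only essential reactions, rule dropping,
  protected-gene elimination, DNF minimization, lumping of equivalent genes
  and of rule-local disjunctions) shrink the number of binary variables; a
  lumped pseudo-gene carries the minimum deletion cost that falsifies its
  Boolean expression.
* **Network compression** — removal of blocked reactions and conservation
  relations, and exact-rational lumping of coupled reaction pairs, with an
  invertible record that re-attributes costs.
* **Decompression** — solutions found on the compressed model are expanded
  back to reaction and then gene level; the whole compress–solve–expand loop
  is lossless (tested against an exhaustive LP-probe oracle).

## Worked example

A nine-gene toy network converts substrate S into biomass and two products
through an intermediate; the goal is to abolish production of the unwanted
product D by gene knockouts while keeping growth feasible:

```r
library(cutsets)

b <- example_gene_mcs()          # model, target (d_ex >= 1), desired (bm_ex >= 1)
res <- compute_mcs(b$model, b$targets, b$desireds, max_cost = 3)
print(res)
#> # 4 minimal cut set(s) (2 at the compressed level)
#> # A tibble: 4 × 6
#>    rank  cost  size deletions additions level
#>   <int> <dbl> <int> <chr>     <chr>     <chr>
#> 1     1     1     1 g4        ""        gene
#> 2     2     1     1 g8        ""        gene
#> 3     3     2     2 g5,g7     ""        gene
#> 4     4     2     2 g7,g9     ""        gene
```

Four gene strategies knock out D production: deleting `g4` or `g8` removes a
required enzyme (cost 1 each), and the two pairs disable the isoenzyme
disjunction of the D-forming reaction (cost 2 each). The MILP itself only
had to consider two solutions — compression lumped the other alternatives
into pseudo-entities and decompression recovered them. `glance(res)` shows
the pipeline counts (9 genes → 4 after GPR compression; 17 reactions after
integration → 8 after network compression; 3 targetable units).

Intervention sets may mix deletions with additions. In the co-feeding
example a metabolite U is both a potential by-product and a potential
(addable, zero-cost) substrate, handled with two target regions
(`make_cofeeding_target_pair()`):

```r
bc <- example_cofeeding()
tidy(compute_mcs(bc$model, bc$targets, bc$desireds, max_cost = 4))
#> # A tibble: 2 × 6
#>    rank  cost  size deletions    additions level
#>   <int> <dbl> <int> <chr>        <chr>     <chr>
#> 1     1     1     2 r6           "u_up"    reaction
#> 2     2     4     4 r12,r3,r7,r9 ""        reaction
```

Either four knockouts couple growth to production on the single substrate,
or one knockout plus switching on U uptake splits metabolism into a
product-forming and a biomass-forming branch at cost 1.

Models load from the tabular dialect or SBML Level 3 + fbc
(`read_model()`), regions from YAML (`read_regions()`); a command-line
front end (`inst/cli/cutsets.R`) exposes `compute`, `verify`, `compress`
and `fixtures` subcommands. A documentation-grade region template for a
genome-scale 2,3-butanediol co-feeding design ships in
`inst/extdata/bdo_cofeeding_regions.yaml`.

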