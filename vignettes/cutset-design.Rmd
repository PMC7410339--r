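---
title: "Computing intervention strategies as minimal cut sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing intervention strategies as minimal cut sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the model behind the package, the choices made where
the design was genuinely open, and what the shipped tests do and do not show.

## Problem statement

A constraint-based metabolic model restricts steady-state flux vectors
$r \in \mathbb{R}^n$ by mass balance $N r = 0$, bounds $lb \le r \le ub$
(irreversibility means $lb_i \ge 0$) and optional extra linear constraints
$A r \le b$. A design task is posed as flux regions:

* **target regions** $T_j r \le t_j$ — undesired states, all of which must
  become infeasible after the interventions. A valid target region must
  exclude the zero flux vector, since no deletion can remove $r = 0$; the
  constructor rejects regions where $r = 0$ satisfies the region rows, the
  bounds and the extra constraints. Users typically exclude it with a
  minimum substrate-uptake row.
* **desired regions** $D_k r \le d_k$ — protected states, each of which must
  retain at least one feasible flux vector.

Multiple regions of either kind are supported because unions of polyhedra
are generally non-convex: "high biomass yield must remain possible *and*
anaerobic growth must remain possible" cannot be expressed as one region.
A *minimal cut set* is an intervention set — deletions of deletable units,
additions of addable units — that blocks every target, keeps every desired
region nonempty, and contains no redundant member.

## The duality formulation

For one target region, let $T$ collect the region rows, the global extra
constraints and the *finite* flux bounds rewritten as inequalities
($r_i \le ub_i$, $-r_i \le -lb_i$); pure irreversibility constraints
($lb_i = 0$) stay out. Infeasibility of
$\{N r = 0,\; r_i \ge 0\ (i \in \mathrm{Irrev}),\; T r \le t\}$
with additional pinning $r_i = 0$ for removed reactions is, by Farkas'
lemma, equivalent to the existence of $(u, v, w)$ with

$$N^\top u + v + T^\top w = 0,\qquad t^\top w \le -c,\qquad w \ge 0,$$

where $v_i$ aggregates the multipliers of the irreversibility and pinning
constraints: $v_i = 0$ for a present reversible reaction, $v_i \le 0$ for a
present irreversible one, and $v_i$ free exactly when reaction $i$ is
removed. The normalization constant is fixed to $c = 1$; any positive value
is equivalent by scaling.

Binary $z_i$ marks an intervention on targetable unit $i$. Sign markers
$z_{p,i}, z_{n,i}$ connect the certificate to the indicators through big-M
rows $v_i \le M z_{p,i}$ and, for reversible reactions only,
$-v_i \le M z_{n,i}$ (a negative $v_i$ on an irreversible reaction is an
ordinary irreversibility multiplier and must not count as a cut), with
$z_p + z_n \le z$ for deletable and $z_p + z_n \le 1 - z$ for addable units.
Each target region contributes its own $(u, v, w)$ block; all blocks share
the indicators. Each desired region contributes a primal block: an explicit
flux vector with $N r = 0$, its region rows, and indicator-gated bounds
($lb_i (1 - z_i) \le r_i \le ub_i (1 - z_i)$ for deletable units, the
inverted form $z_i\, lb_i \le r_i \le z_i\, ub_i$ for addable ones).
The objective minimizes $\sum_i p_i z_i$ with user-set nonnegative costs —
e.g. zero for removing oxygen supply or for a medium addition — and
enumeration adds an integer cut $\sum_{j \in C} z_j \le |C| - 1$ per found
solution $C$.

Three consequences of this construction are worth spelling out:

* **Feasible points are always sound.** Any feasible MILP point carries an
  explicit Farkas certificate per target and an explicit witness per desired
  region, independent of $M$. A too-small $M$ can therefore only *hide*
  solutions, never fabricate them. Solutions are nevertheless re-verified
  with plain LPs (always on), and the enumeration equality tests against the
  exhaustive oracle guard the completeness side at desk scale. The default
  $M = 1000$ comfortably covers the certificate magnitudes of the shipped
  networks.
* **Only $z$ needs branching.** For any relaxed point with integral $z$, the
  markers can be rounded feasibly ($z_p = \max(v,0)/M$ etc. shows the
  relaxed and the binary feasible sets project to the same $v$-intervals),
  so the branch-and-bound branches on $z$ alone.
* **Addable activation bounds must contain zero.** The target blocks absorb
  bound rows statically; for an absent addable reaction those rows must be
  satisfied by $r_i = 0$. Activation bounds excluding zero are rejected.
  Deletable reactions with infinite bounds are gated in desired blocks with
  a flux cap (`flux_M`, default 1000 mmol/gDW/h) — a conservative device
  that can only narrow desired witnesses, never widen targets.

When costs can be zero, a cost-minimal solution need not be
support-minimal; every incumbent is reduced by a greedy removal pass
(cheapest members first, LP-verified at each step) before being recorded,
and integer cuts are posted against the reduced support. In
`any_feasible` mode the first incumbent is accepted and reduced the same
way — a fast sampler whose results are valid cut sets but not in cost
order.

## Gene-level interventions

Gene rules (isoenzymes = OR, complexes = AND) are parsed to minimized DNF
and embedded structurally: each gene becomes an unbounded synthesis reaction
producing its gene-product species `E__<gene>`; each conjunction of a rule
becomes a pool reaction converting its member `E` species into the
reaction-specific pool `Q__<reaction>`; the reaction consumes one unit of
its own `Q`. Reversible GPR reactions split into two directions with mapped
bounds, each with its own pool fed from the same enzyme species. Because
every original reaction keeps a single flux variable and its original
bounds, the feasible projection onto original fluxes is exactly preserved —
the property the test suite checks as FVA equality — whereas encoding
isoenzymes by duplicating the reaction would double its effective capacity.

Before integration the ruleset is compressed. Essential reactions are found
by FVA on each desired region (an interval excluding zero means every
desired flux vector uses the reaction). Genes occurring only in essential
reactions' rules, or present in every conjunction of an essential reaction's
rule, are protected and eliminated; rules that protection makes
unfalsifiable are dropped; DNFs are minimized by absorption. Lumping then
replaces (a) groups of genes that co-occur in exactly the same conjunctions
ruleset-wide and share a status, and (b) rule-local disjunctions whose genes
appear nowhere else, by pseudo-genes. A pseudo-gene records its Boolean
expression over original genes and carries the minimum summed deletion cost
over the expression's minimal falsifying sets (its minimal hitting sets,
found exhaustively — lump expressions are small by construction, capped at
20 genes). Two ordering choices were open and are fixed as follows: the
co-occurrence pass runs once over original genes, then the rule-local pass
iterates to a fixed point; pseudo-genes never re-enter the co-occurrence
pass. This keeps a factored rule like `g4 and (lump)` as two entities rather
than collapsing everything reachable into one opaque pseudo-gene, and makes
compression idempotent. Deletion and addition candidates never share a
lump.

## Network compression

The integrated network is compressed losslessly: blocked reactions (FVA
range $\{0\}$ on the full network) are removed; linearly dependent
stoichiometry rows (conservation relations) are removed by exact rational
Gauss–Jordan elimination; and any metabolite with exactly one producer and
one consumer couples the pair into a lump whose scaling cancels the
metabolite. All compression arithmetic is exact rational (inputs
rationalized at absolute tolerance 1e-9), because row reduction and scaling
are brittle in floating point. Lump bounds are the intersection of member
bounds mapped through the scaling; lump cost is the minimum cost over
targetable members (deleting any member stops the coupled chain) and a lump
is non-targetable only if no member is targetable. Addable reactions are
excluded from lumping because absence/presence semantics do not commute with
coupling. GPR pseudo-reactions and metabolic reactions are lumped alike —
this is what shrinks the integrated network back down. Regions are rewritten
onto the compressed basis through the recorded column map, and solutions are
expanded back (each lumped deletion is replaced by each targetable member;
each lumped pseudo-gene by each minimal falsifying set), costs recomputed on
the union, over-budget expansions discarded, supersets filtered (a flag
retains them for users interested in equivalent variants).

Essentiality and blockedness are evaluated with addable reactions *active*
at their stated bounds: a reaction avoidable only via an addition is not
essential, and a reaction reachable only via an addition is not blocked.
Evaluating them on the wild type instead would silently remove
addition-based designs from the search space.

## Numerical layer

All LPs (feasibility probes, FVA, relaxations in the branch-and-bound) are
solved by a built-in dense two-phase simplex (C++): Dantzig pricing with
largest-pivot tie-breaking, an exact minimum-ratio test, and a switch to
Bland's rule after 200 stalled (degenerate) iterations, which guarantees
termination. Comparisons use an absolute tolerance of 1e-9; integrality of
indicators is accepted at 1e-6. The solver targets the desk-scale systems
this package produces (hundreds of variables); genome-scale enumeration
would require an industrial MILP code behind the same problem interface.

## What the random-network generator emulates

Property tests and the acceptance script draw random bundles: a linear
substrate-to-biomass backbone guaranteeing growth feasibility, random
conversions (25% reversible), by-product exports, an optional addable
uptake, sparse random one/two-gene rules on about half of the internal
reactions, a growth desired region, and one or two minimum-flux target
regions chosen among reactions that can carry flux in the wild type. Sizes
default to 5 metabolites, 8 internal reactions and 4 genes so that the
exhaustive LP-probe oracle — which tests every intervention subset up to the
cost bound using only rule evaluation and LP feasibility, with none of the
MILP/compression machinery — stays exact and fast; the shipped checks run
it on 100 seeded bundles up to cost 3, and compare all four
compression-flag combinations for identical results.

These networks are mass-balanced with unit stoichiometry and simple GPR
shapes. They exercise the algorithmic claims (duality soundness,
enumeration completeness, compression losslessness, cost re-attribution),
but they do not emulate genome-scale features: cofactor coupling density,
long GPR rules with hundreds of isoforms, thermodynamically motivated bound
patterns, or numerically awkward stoichiometries (fractional biomass
coefficients are supported but not stressed). Passing tests therefore
establish correctness of the machinery, not performance or numerical
robustness at genome scale.

## Degenerate inputs and edge behaviour

* A target region already infeasible in the wild type yields the empty cut
  set (cost 0) and enumeration stops.
* A model with no targetable unit returns an empty result (or the empty cut
  set if targets are already blocked); building the MILP directly on such a
  model is an error.
* A co-substrate whose uptake capacity is zero makes the co-feeding target
  pair degenerate and triggers a warning.
* Desired regions may be absent entirely (classical cut sets / synthetic
  lethals); then only the dual blocks remain.
* Equal-cost optima are returned in an order determined by the deterministic
  branch-and-bound; tests compare solution *sets*. Output tables sort by
  (cost, cardinality, members).

## Known limitations

* No thermodynamic, kinetic or regulatory constraints; regulatory
  interventions can be emulated by offering bound-modified reaction copies
  as addition candidates.
* The structural one-producer/one-consumer lumping criterion compresses less
  than full flux-coupling analysis would; this affects intermediate problem
  sizes, never the final solution set (enforced by the losslessness tests).
* Support minimization uses a greedy LP-verified removal pass; with strongly
  heterogeneous costs a confined MILP could in principle find a different
  same-cost support, but any returned set is verified sound and
  single-member-minimal.
* The built-in simplex is dense; models beyond a few hundred reactions after
  compression will be slow.
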