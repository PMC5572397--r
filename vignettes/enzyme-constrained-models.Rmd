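---
title: "Enzyme-constrained metabolic models with enzgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-constrained metabolic models with enzgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzgem)
```

## The model

Flux balance analysis treats metabolism as a linear program: a
stoichiometric matrix $S$ (metabolites $\times$ reactions), the
steady-state constraint $S v = 0$, flux bounds
$lb \le v \le ub$ (mmol/gDW/h), and a linear objective, usually growth.
Its classic weakness is that fluxes are limited only by exchange bounds:
nothing stops a solution from pushing arbitrarily much flux through a
pathway whose enzymes a real cell could never afford.

enzgem removes that freedom by making enzymes part of the stoichiometry.
Every catalyzed flux obeys the capacity law

$$ v_j \;\le\; k_{cat,ij}\,[E_i], $$

where $k_{cat,ij}$ is the turnover number (1/s, converted once to 1/h) of
enzyme $i$ on reaction $j$ and $[E_i]$ its abundance (mmol/gDW). This is
encoded structurally: the matrix gains one row per enzyme and one *usage*
column `draw_prot_<accession>` per enzyme. Each catalyzed column consumes
its enzyme row with coefficient $-s_i / (k_{cat,ij} \cdot 3600)$ ($s_i$ =
subunit stoichiometry), and the usage column produces one unit of it, so
the enzyme block of the matrix is kinetic coefficients on the left and an
identity on the right. Bounding a usage column bounds every flux the
enzyme carries.

Four structural formalisms make this exact for real gene-protein-reaction
rules:

* **Reversible reactions** are split into `<id>` and `<id>_REV` so each
  direction can carry its own kcat (queried with its own substrate side).
* **Isozymes** (OR in the gene rule) would otherwise let each alternative
  carry the full original bound; an *arm reaction* `arm_<id>` carries the
  original bounds from the substrates into a pseudo-metabolite
  `pmet_<id>`, which the per-isozyme copies `<id>No1..Nok` then convert to
  products.
* **Complexes** (AND in the rule) consume every subunit, each scaled by
  its stoichiometry in the complex, with one shared kcat per catalytic
  event.
* **Promiscuous enzymes** appear in several columns with possibly
  different kcats but a single usage column, so the reactions compete for
  one abundance.

Arbitrary rules are normalized to disjunctive normal form first; each
conjunct is one catalytic unit. Copies are ordered by sorted protein ids
for determinism, and duplicated units are removed. The expansion is
invertible: `strip_enzymes()` re-merges split halves and isozyme copies
and recovers the original stoichiometry exactly, which the test suite
checks to 1e-12.

## Turnover-number assignment

Turnover numbers come from a local kinetics table (EC number, substrate,
organism, kcat) standing in for a kinetics database export. Matching
relaxes in levels: exact EC + substrate + organism (level 0), then any
organism (1), then any substrate within the organism (2), then the EC
alone (3), then the EC with its last field wildcarded (4). The search
stops at the first level with hits and takes the **maximum** kcat there:
an optimistic bound that avoids over-constraining the model with slow
outliers. Ties break deterministically on (kcat desc, EC, substrate,
organism).

Two ordering decisions were genuinely open and are worth recording.
First, organism relaxation precedes substrate relaxation because the same
reaction measured in another organism is biologically closer than a
different chemistry in the same organism; the `relaxation` argument makes
the order configurable. Second, the backward direction of a reversible
reaction is queried with the product side as substrates; if only the
forward direction matches, its value is reused at level 3 rather than
leaving the backward direction uncapped — conservative, and recorded in
the provenance.

Pairs with no hit at any level are filled by a default policy (median of
the successful assignments, or a user constant) at provenance level -1.
`apply_manual_curation()` overrides individual (reaction, protein) pairs
with literature values at provenance -2; pathway-level curation before
quantitative use is expected practice, since database kcats are in-vitro
values spanning many orders of magnitude.

## Abundance constraints

Three regimes, matching data availability:

* **No proteomics** — a shared mass pool. A pool row `prot_pool` is added;
  each usage draws $MW_i$ g/mmol from it and the single pool source is
  bounded by $\sigma f P_{total}$ (g/gDW), i.e.
  $\sum_i MW_i e_i \le \sigma f P_{total}$. $P_{total}$ is total protein
  (default 0.448 g/gDW), $f$ the mass fraction of the proteome covered by
  the model's enzymes (default 0.4461, the proteome-wide estimate for the
  consensus yeast network), and $\sigma$ the average in-vivo saturation, a
  fitted scalar (default 0.44, the batch-growth fit; chemostat fits give
  0.46-0.51 depending on strain). Units are deliberately grams
  throughout the pool: MW in kDa equals g/mmol, so no per-enzyme unit
  conversions appear.
* **Full proteomics** — each measured usage is bounded by
  $e_i \le \mu_i + \sigma_i$, mean plus one sample standard deviation over
  the replicates in which the protein was detected (proteins seen in
  fewer than `min_replicates = 2` replicates are dropped). The one-SD
  flexibilization absorbs measurement variability without a tuning knob.
* **Hybrid** — measured enzymes get direct bounds; the unmeasured rest
  shares a pool of mass $f_{unmeasured} \cdot (P_{total} - m)$ where $m$
  is the matched mass $\sum MW_i \mu_i$. Whether the printed pool mass of
  such an integration includes $\sigma$ is ambiguous in the field's usage,
  so `proteomics_mass_report()` reports both the pre-saturation pool mass
  and the final $\sigma$-scaled bound.

`correct_complex_abundances()` handles unevenly quantified complexes
(some subunits detected at trace level): per-subunit relative abundances
$\mu_i / s_i$ are averaged and each measured subunit reset to
$s_i \times$ that average, SDs scaled by the same factor. Subunits with
$\mu_i = 0$ keep their SD, since no finite scale factor exists.

Biomass-composition rebalancing and polymerization-cost rescaling are
dataset-specific curation, not method; only the generic maintenance knobs
are automated (`apply_maintenance()`: growth-associated ATP rewritten in
the biomass reaction, non-growth maintenance as a lower bound; reference
aerobic yeast values GAM 31 mmol/gDW, NGAM 0.7 mmol/gDW/h, anaerobic
GAM 16).

## Simulation recipes

All multi-stage recipes are lexicographic LPs. Each stage fixes the
previous optimum inside a band of relative width 1e-6 (plus 1e-9
absolute) before optimizing the next quantity; exact equality is brittle
in floating point once stages chain. Residual fluxes of order 1e-6 times
the fixed value are therefore expected and the tests tolerate them.

* `fba()` — plain LP; infeasible/unbounded reported in the status, never
  thrown.
* `minimize_enzyme_usage()` — parsimonious refinement minimizing
  $\sum MW_i e_i$ at fixed fluxes. Mass weighting is the default (the
  alternative plain sum is one flag away): minimizing grams is what the
  pool constraint prices, and it is what makes the cheaper
  MW/kcat isozyme route win.
* `chemostat(D)` — fix growth to the dilution rate, minimize uptake, fix
  uptake, minimize enzyme mass.
* `batch()` — release the medium uptakes, maximize growth under the pool,
  then parsimoniously minimize uptake and enzyme mass. Refuses to run
  without an abundance constraint, because growth would be unbounded.
* `yield_envelope()` — sweep growth fractions 0..100% of the maximum at a
  capped substrate uptake, maximizing product then minimizing enzyme at
  each point. The uptake is enforced as an upper bound, not an equality:
  with strict fixing, low-growth points are infeasible on networks
  without an alternative carbon sink, since surplus substrate has
  nowhere to go. Yields are normalized by the cap (conservative for
  points that do not exhaust it).
* `knockout()` — usage bounds to zero; AND rules block the complex, OR
  rules are rescued by the sibling isozyme.
* `fva()` — per-reaction min/max at a fraction of the optimum. On
  expanded models the analysis reports **net** original-reaction fluxes
  (forward minus backward; arm reactions stand in for their isozyme
  copies), so original and expanded models are compared on the same
  reaction set; `compare_fva()` tabulates the per-reaction variability
  reduction.
* `flux_control_coefficients()` — scale one enzyme's kcats by
  $1+\delta$ (default $\delta$ = 1e-3; all reactions of a promiscuous
  enzyme together, since specific activity is one property of the
  protein), re-run the recipe, and report the relative response of the
  target flux. When the pool is the unique binding constraint the
  coefficients sum to 1 by LP homogeneity, which the tests verify.
* `fit_sigma()` — bisection on the saturation, converging when the
  observable is within 1e-4 (absolute) of the target. Growth under a
  binding pool is monotone — in fact linear — in $\sigma$, so the
  bisection is well-posed; targets at the $\sigma \to 0$ boundary are
  flagged rather than silently returned.

## The LP layer

No dedicated LP solver is assumed. The package carries a dense
bounded-variable two-phase primal simplex with Bland's rule
(anti-cycling), written for the small, highly degenerate LPs these
models produce: every right-hand side is zero and coefficients span from
$1/k_{cat,h}$ (~1e-5) to the default bound magnitude (1000 mmol/gDW/h).
Three numerical measures keep it stable: variables pinned by equal
bounds are substituted out before solving; infinite usage bounds are
tightened by one pass of implied-bound propagation through the balance
rows (a usage is implied by the capacity of the columns consuming its
enzyme row, or by the pool) and only capped at 1e6 when propagation
fails; and the remaining problem is equilibrated, scaling each variable
by its bound range and each row by its largest coefficient. Basis
systems are re-factorized every iteration — wasteful at scale,
unconditionally stable at these sizes. The solver is deterministic:
identical inputs give identical solutions, and degenerate alternative
optima (equal-cost isozymes) still have a unique objective value, which
is what the tests assert.

## What the fixtures do and do not show

`make_toy_gem()` packs every formalism into six reactions: a reversible
enzyme with direction-specific kcats, an isozyme pair with distinct
costs, a two-subunit complex with uneven stoichiometry, and a
promiscuous enzyme. Kcats are chosen so the 1/s to 1/h conversion gives
round coefficients (1/36000, 1/72000, 2/7200) that can be checked by
hand. One wrinkle is instructive: the promiscuous enzyme's two reactions
consume the same metabolite with the same EC number, so hierarchical
matching necessarily returns the same kcat for both — the slower second
kcat enters through the fixture's curation table, exactly as a real
pathway curation would.

`make_overflow_model()` is the minimal resource-allocation model of
overflow metabolism: an efficient but enzyme-expensive pathway (10 ATP
per substrate at 10 g·h/mmol) against an inefficient cheap one (2 ATP at
1 g·h/mmol) under a 10 g/gDW pool. Its optimum is a two-variable LP
solvable on paper: pure respiration up to uptake 1, a mixed vertex with
ATP $= (100-10U)/9 + 2(10U-10)/9$ for $1 < U < 10$, pure fermentation
capped at ATP 20 beyond. The byproduct appears exactly at the switch,
which is how the tests pin the threshold from both sides, and the test
suite re-derives every value by brute-force vertex enumeration rather
than trusting the solver.

What passing these tests does **not** show: the fixtures have a single
compartment (no transport classification pressure), metabolite-sized
networks (no degeneracy at scale), kcats chosen for roundness rather
than realism, and no measurement noise beyond the replicate SD entering
Eq-style bounds. Conclusions about genome-scale models — solver
performance, kcat coverage, the effect of matching-level dilution —
require the real model and database exports, which this package reads
but does not ship.

## Problem sizes and limitations

All shipped computations are deliberately small: the toy network (14
expanded reactions), the overflow model (8), 20-draw FVA-inclusion
sweeps, and bisection to 1e-4. The full test suite and the acceptance
script run in well under a minute on one core.

Known limitations: the dense simplex is for small and medium models, not
genome scale (a few thousand columns will work but not quickly);
SBML support covers the Level 3 + flux-bounds/objectives/gene-products
subset the tool itself writes, not arbitrary curation annotations; there
is no compartment-specific enzyme duplication and no splice-variant
handling; and kcat matching is exact-string on substrate names by
design — reproducibility over recall, with curation as the escape hatch.
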