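# enzgem

Enzyme-constrained genome-scale metabolic models in R.

Constraint-based models (FBA) bound fluxes only by exchange rates, so they
happily route arbitrary flux through pathways whose enzymes a cell could
never afford. `enzgem` rewrites a metabolic model so that every catalyzed
flux respects its kinetic capacity,

    v_j <= kcat_ij * [E_i]        (flux in mmol/gDW/h, abundance in mmol/gDW)

by adding one row per enzyme and one usage column per enzyme to the
stoichiometric matrix: catalyzed columns consume their enzyme rows with
coefficient `-s_i / (kcat_ij * 3600)` and the usage columns form an
identity block. Reversible reactions are split (direction-specific kcats),
isozymes get an arm reaction with a pseudo-metabolite, complexes consume
all subunits by their stoichiometry, and promiscuous enzymes share one
abundance across reactions.

Abundances come from three sources:

* a shared mass pool, `sum_i MW_i * e_i <= sigma * f * P_total` (g/gDW),
  when no proteomics is available;
* direct per-enzyme bounds `e_i <= mean_i + sd_i` from replicate absolute
  proteomics;
* a hybrid: measured enzymes bounded directly, the rest pooled with the
  remaining protein mass.

Turnover numbers are assigned from a local kinetics table by hierarchical
matching (EC + substrate + organism, relaxing stepwise to an EC wildcard,
maximum kcat at the first matching level), with manual curation overrides.
On top sit the field's standard analyses: FBA, parsimonious enzyme
minimization, chemostat and batch protocols, knockouts, yield envelopes,
flux variability analysis, flux control coefficients, and saturation
fitting. It is aimed at systems-biology users who want enzyme constraints
and proteomics integration for small and medium constraint-based models
without leaving R.

## Worked example

Build the bundled toy network (four metabolites; a reversible enzyme, an
isozyme pair, a complex, and a promiscuous enzyme), assign kcats, expand,
and simulate:

```r
library(enzgem)

toy <- make_toy_gem()
asg <- assign_kcats(toy$model, toy$enzymes, toy$kinetics, toy$organism)
asg <- apply_manual_curation(asg, toy$curation)
ec  <- expand_model(toy$model, toy$enzymes, asg)
ec
#> <ec_model> 10 metabolites, 14 reactions
#> objective: max GROWTH
#> enzymes: 5; pool: none

fba(ec)$objective          # usages unconstrained: uptake-limited growth
#> [1] 10

# bound one isozyme at 5e-5 mmol/gDW and block the other: the capacity law
# caps growth at kcat_h * e = 20/s * 3600 * 5e-5
ec2 <- set_bounds(ec, "draw_prot_P2A", ub = 5e-5)
ec2 <- set_bounds(ec2, "draw_prot_P2B", ub = 0)
fba(ec2)$objective
#> [1] 3.6
```

The overflow fixture shows the respiration-to-fermentation switch that a
shared enzyme pool produces: an efficient but enzyme-expensive pathway
loses to a cheap inefficient one once substrate is abundant.

```r
for (U in c(1, 2, 100)) {
  r <- fba(make_overflow_model(U = U))
  cat("U =", U, " ATP =", r$objective, " byproduct =", r$fluxes[["EX_B"]], "\n")
}
#> U = 1  ATP = 10  byproduct = 0
#> U = 2  ATP = 11.11111  byproduct = 1.111111
#> U = 100  ATP = 20  byproduct = 10
```

Proteomics integration and its mass bookkeeping:

```r
rep <- proteomics_mass_report(ptot = 0.448, matched_mass = 0.283,
                              f_unmeasured = 0.2154, sigma = 0.46)
rep$remaining_mass         # protein mass left for unmeasured enzymes
#> [1] 0.165
round(rep$pool_mass, 3)    # pool mass for the unmeasured enzymes
#> [1] 0.036
rep$matched_fraction_pct   # share of model enzyme mass measured directly
#> [1] 88.84257
```

A file-level pipeline is available as a thin CLI over the same functions:

```sh
Rscript inst/cli/enzgem.R toy --name TOY1 --out demo/
Rscript inst/cli/enzgem.R expand --model demo/toy1_model.xml \
    --enzymes demo/toy1_enzymes.tsv --kcats demo/toy1_kinetics.tsv \
    --curation demo/toy1_curation.tsv --out demo/ec.xml --report demo/stats.tsv
Rscript inst/cli/enzgem.R simulate --model demo/ec.xml --out demo/fluxes.tsv
```

See `vignettes/enzyme-constrained-models.Rmd` for the model, the matching
hierarchy, the numerical design of the LP layer, and the limits of what
the toy fixtures demonstrate.

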