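# Deterministic synthetic fixtures exercising every expansion formalism:
# TOY1 has a reversible enzyme with direction-specific kcats, an isozyme
# pair, a two-subunit complex with uneven stoichiometry, and a promiscuous
# enzyme; OVF1 is a two-pathway energy model whose pool constraint
# reproduces overflow metabolism with an analytically known switch point.

TOY_ORGANISM <- "Saccharomyces cerevisiae"

#' Toy genome-scale model TOY1
#'
#' Four metabolites A, B, C, D. Reactions: substrate exchange `EX_A`
#' (uptake bounded at 10 mmol/gDW/h); reversible `R1` A <-> B catalyzed by
#' P1 (40 kDa; kcat 10/s forward, 5/s backward, resolved via direction-
#' specific substrate records); `R2` B -> C with isozymes P2A (50 kDa,
#' 20/s) and P2B (60 kDa, 4/s); `R3` C -> D catalyzed by the complex CPX1 =
#' P3A x1 (30 kDa) + P3B x2 (20 kDa) at 2/s; `R4` B -> D by the promiscuous
#' P2A; `GROWTH` drains D and is the maximization objective. The kinetics
#' table carries every kcat at exact-match level; R4 shares P2A's EC and
#' substrate with R2, so its slower kcat (1/s) enters through the curation
#' table, exercising the manual-override path. Unconstrained maximal growth
#' is 10 (uptake-limited).
#'
#' @return list with `model` (a `metabolic_model`), `enzymes`, `kinetics`,
#'   `curation`, and `organism`.
#' @export
make_toy_gem <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"),
                     name = c("A", "B", "C", "D"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- make_reactions(
    ids = c("EX_A", "R1", "R2", "R3", "R4", "GROWTH"),
    names_ = c("A exchange", "A to B", "B to C", "C to D", "B to D",
               "growth"),
    lb = c(0, -1000, 0, 0, 0, 0),
    ub = c(10, 1000, 1000, 1000, 1000, 1000),
    gene_rule = c("", "GP1", "GP2A or GP2B", "GP3A and GP3B", "GP2A", ""),
    subsystem = "",
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1),
                  c(C = -1, D = 1), c(B = -1, D = 1), c(D = -1))
  )
  model <- metabolic_model(mets, rxns,
                           objective = list(reaction = "GROWTH",
                                            direction = "max"))
  enzymes <- enzyme_table(
    protein_id = c("P1", "P2A", "P2B", "P3A", "P3B"),
    gene = c("GP1", "GP2A", "GP2B", "GP3A", "GP3B"),
    mw_kda = c(40, 50, 60, 30, 20),
    ec_numbers = c("1.1.1.1", "1.2.1.1", "1.2.1.2", "3.1.1.1", "3.1.1.1"),
    complex_id = c(NA, NA, NA, "CPX1", "CPX1"),
    stoich = c(1, 1, 1, 1, 2)
  )
  kinetics <- data.frame(
    ec = c("1.1.1.1", "1.1.1.1", "1.2.1.1", "1.2.1.2", "3.1.1.1"),
    substrate = c("A", "B", "B", "B", "C"),
    organism = TOY_ORGANISM,
    kcat_per_s = c(10, 5, 20, 4, 2),
    stringsAsFactors = FALSE
  )
  curation <- data.frame(reaction_id = "R4", protein_id = "P2A",
                         kcat_per_s = 1, stringsAsFactors = FALSE)
  list(model = model, enzymes = enzymes, kinetics = kinetics,
       curation = curation, organism = TOY_ORGANISM)
}

#' Expanded enzyme-constrained TOY1
#'
#' Runs the full pipeline on [make_toy_gem()]: kcat assignment, manual
#' curation, and matrix expansion. The result has 14 reactions (9
#' metabolic/arm plus 5 enzyme usages) and 10 rows (4 metabolites, 1
#' pseudo-metabolite, 5 enzymes).
#'
#' @return An `ec_model`.
#' @export
make_toy_ec <- function() {
  toy <- make_toy_gem()
  asg <- assign_kcats(toy$model, toy$enzymes, toy$kinetics, toy$organism)
  asg <- apply_manual_curation(asg, toy$curation)
  expand_model(toy$model, toy$enzymes, asg)
}

#' Overflow-metabolism fixture OVF1
#'
#' A substrate S can be turned into ATP by respiration (RESP: S -> 10 ATP,
#' enzyme mass cost MW/kcat_h = 10 g h/mmol) or fermentation (FERM: S ->
#' 2 ATP + byproduct, cost 1 g h/mmol); growth drains ATP 1:1 and the
#' enzyme pool is bounded at `pool_size` g/gDW. With uptake bound U the
#' optimum is: pure respiration (ATP = 10 U) for U <= 1; a respiration/
#' fermentation mix with ATP = (100 - 10 U)/9 + 2 (10 U - 10)/9... i.e.
#' the vertex of `r + f = U`, `10 r + f = pool` for 1 < U < 10 (U = 2 gives
#' ATP = 100/9 and byproduct 10/9); and pure fermentation capped at ATP = 20
#' for U >= 10. The switch to byproduct secretion happens exactly at U = 1.
#'
#' @param U substrate uptake bound, mmol/gDW/h.
#' @param pool_size enzyme pool bound, g/gDW.
#' @return A pooled `ec_model`.
#' @export
make_overflow_model <- function(U = 10, pool_size = 10) {
  mets <- data.frame(id = c("S", "ATP", "Byp"),
                     name = c("S", "ATP", "Byp"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- make_reactions(
    ids = c("EX_S", "RESP", "FERM", "EX_B", "GROWTH"),
    names_ = c("substrate uptake", "respiration", "fermentation",
               "byproduct secretion", "growth"),
    lb = 0, ub = c(U, 1000, 1000, 1000, 1000),
    gene_rule = c("", "GR", "GF", "", ""),
    subsystem = "",
    stoich = list(c(S = 1), c(S = -1, ATP = 10),
                  c(S = -1, ATP = 2, Byp = 1), c(Byp = -1), c(ATP = -1))
  )
  model <- metabolic_model(mets, rxns,
                           objective = list(reaction = "GROWTH",
                                            direction = "max"))
  enzymes <- enzyme_table(
    protein_id = c("ER", "EF"), gene = c("GR", "GF"), mw_kda = c(36, 36),
    ec_numbers = c("7.1.1.1", "4.1.1.1")
  )
  kinetics <- data.frame(
    ec = c("7.1.1.1", "4.1.1.1"), substrate = "S", organism = TOY_ORGANISM,
    kcat_per_s = c(0.001, 0.01), stringsAsFactors = FALSE
  )
  asg <- assign_kcats(model, enzymes, kinetics, TOY_ORGANISM)
  ec <- expand_model(model, enzymes, asg)
  add_pool(ec, pool_config(ptot = pool_size, f = 1, sigma = 1))
}

#' Randomized-kcat null model
#'
#' Permutes the assigned turnover numbers across assignments with a seeded
#' generator, preserving their multiset. Used as a null to show that
#' predictions (e.g. the overflow switch point) depend on which enzyme
#' carries which kcat, not on the network alone.
#'
#' @param assignments a `kcat_assignments` table (>= 2 rows).
#' @param seed integer seed; identical seeds give identical permutations.
#' @return The permuted assignments.
#' @export
make_random_kcat_null <- function(assignments, seed) {
  if (nrow(assignments) < 2) {
    stop("need at least two assignments to permute", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  perm <- sample.int(nrow(assignments))
  assignments$kcat_per_s <- assignments$kcat_per_s[perm]
  assignments
}
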