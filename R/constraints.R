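# Abundance constraints: the shared enzyme-mass pool used when proteomics is
# absent, direct per-enzyme bounds when it is present, and the hybrid of the
# two. The pool is a mass balance in grams: each usage column draws MW_i
# g/mmol from a pool row whose source is bounded by sigma * f * P_total
# (g/gDW), i.e. sum_i MW_i * e_i <= sigma * f * P_total.

#' Enzyme pool configuration
#'
#' @param ptot total cellular protein content, g/gDW.
#' @param f dimensionless mass fraction of total protein covered by the
#'   model's enzymes (default 0.4461, the value estimated for the consensus
#'   yeast network from proteome-wide abundance data).
#' @param sigma dimensionless average in-vivo enzyme saturation in (0, 1]
#'   (default 0.44, the value fitted for batch growth on glucose minimal
#'   medium).
#' @return list of class `pool_config` with the derived bound
#'   `sigma * f * ptot` (g/gDW).
#' @export
pool_config <- function(ptot = 0.448, f = 0.4461, sigma = 0.44) {
  if (!(ptot > 0)) stop("ptot must be > 0", call. = FALSE)
  if (!(f > 0 && f <= 1)) stop("f must be in (0, 1]", call. = FALSE)
  if (!(sigma > 0 && sigma <= 1)) stop("sigma must be in (0, 1]",
                                       call. = FALSE)
  structure(list(ptot = ptot, f = f, sigma = sigma,
                 bound = sigma * f * ptot),
            class = "pool_config")
}

#' Add a shared enzyme-mass pool
#'
#' Introduces a pool pseudo-metabolite `prot_pool` with one source reaction
#' `prot_pool_exchange` bounded `[0, sigma * f * ptot]` g/gDW. Every in-scope
#' usage reaction additionally consumes `MW_i` g/mmol of pool per mmol of
#' enzyme drawn, and its direct upper bound is released to infinity, so total
#' enzyme mass rather than individual abundance becomes limiting.
#'
#' @param ec an `ec_model`.
#' @param cfg a [pool_config()].
#' @param scope protein ids to pool; `NULL` (default) pools every enzyme.
#' @return The pooled `ec_model`.
#' @export
add_pool <- function(ec, cfg = pool_config(), scope = NULL) {
  if (!inherits(ec, "ec_model")) stop("add_pool needs an ec_model",
                                      call. = FALSE)
  if (!is.null(ec$pool)) stop("model already has an enzyme pool",
                              call. = FALSE)
  enz_ids <- sub("^draw_prot_", "",
                 grep("^draw_prot_", ec$reactions$id, value = TRUE))
  if (is.null(scope)) scope <- enz_ids
  if (!length(scope)) {
    warning("empty pool scope; model returned unchanged", call. = FALSE)
    return(ec)
  }
  unknown <- setdiff(scope, enz_ids)
  if (length(unknown)) {
    stop("pool scope contains unknown enzyme(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ec$metabolites <- rbind(
    ec$metabolites,
    data.frame(id = "prot_pool", name = "enzyme mass pool",
               compartment = "enzyme", stringsAsFactors = FALSE))
  src <- make_reactions("prot_pool_exchange", "enzyme pool source",
                        lb = 0, ub = cfg$bound, gene_rule = "",
                        subsystem = "enzyme usage",
                        stoich = list(c(prot_pool = 1)))
  ec$reactions <- rbind(ec$reactions, src)
  ec$rxn_map <- rbind(ec$rxn_map,
                      new_map_row("prot_pool_exchange", "prot_pool_exchange",
                                  "prot_pool_exchange", "pool", 1L, 0,
                                  cfg$bound, ""))
  mw <- stats::setNames(ec$enzymes$mw_kda, ec$enzymes$protein_id)
  for (p in scope) {
    j <- rxn_index(ec, paste0("draw_prot_", p))
    st <- ec$reactions$stoich[[j]]
    st["prot_pool"] <- -mw[[p]]
    ec$reactions$stoich[[j]] <- st
    ec$reactions$ub[j] <- Inf
  }
  ec$pool <- c(unclass(cfg), list(scope = scope))
  validate_model(ec)
  ec
}

#' Rescale the pool saturation parameter
#'
#' @param ec a pooled `ec_model`.
#' @param sigma new average saturation in (0, 1].
#' @return The model with the pool bound recomputed as
#'   `sigma * f * ptot` (hybrid pools: `sigma * f * remaining mass`).
#' @export
set_pool_sigma <- function(ec, sigma) {
  if (is.null(ec$pool)) stop("model has no enzyme pool", call. = FALSE)
  if (!(sigma > 0 && sigma <= 1)) stop("sigma must be in (0, 1]",
                                       call. = FALSE)
  ec$pool$sigma <- sigma
  ec$pool$bound <- sigma * ec$pool$f * ec$pool$ptot
  set_bounds(ec, "prot_pool_exchange", ub = ec$pool$bound)
}

#' Bound enzyme usages by measured abundances
#'
#' Each measured enzyme's usage is bounded above by `mean + sd` of its
#' replicate abundances (mmol/gDW) - one standard deviation of flexibility
#' for measurement variability. Returns the matched enzyme mass
#' `sum MW_i * mean_i` (g/gDW) and the model enzymes left unmeasured.
#'
#' @param ec an `ec_model`.
#' @param prot a `proteomics_set`.
#' @return list with `model`, `matched_mass` (g/gDW), `matched` and
#'   `unmeasured` protein id vectors.
#' @export
set_proteomics_bounds <- function(ec, prot) {
  enz_ids <- sub("^draw_prot_", "",
                 grep("^draw_prot_", ec$reactions$id, value = TRUE))
  dat <- prot$data
  matched <- intersect(enz_ids, dat$protein_id)
  if (!length(matched)) {
    warning("no proteomics measurement matches a model enzyme", call. = FALSE)
  }
  mw <- stats::setNames(ec$enzymes$mw_kda, ec$enzymes$protein_id)
  matched_mass <- 0
  for (p in matched) {
    row <- dat[dat$protein_id == p, ]
    ec <- set_bounds(ec, paste0("draw_prot_", p), ub = row$mean + row$sd)
    matched_mass <- matched_mass + mw[[p]] * row$mean
  }
  list(model = ec, matched_mass = matched_mass, matched = matched,
       unmeasured = setdiff(enz_ids, matched))
}

#' Hybrid proteomics/pool constraints
#'
#' Measured enzymes are bounded by `mean + sd`; the unmeasured ones share a
#' pool whose mass is the total protein content minus the matched mass,
#' corrected by the mass fraction `f_unmeasured` of model enzymes among
#' unmatched proteins, and scaled by the saturation `sigma`.
#'
#' @param ec an `ec_model`.
#' @param prot a `proteomics_set` (its `ptot` is used unless `ptot` is given).
#' @param ptot total protein content, g/gDW.
#' @param f_unmeasured mass fraction for the unmeasured pool (the reference
#'   yeast integration used 0.2154).
#' @param sigma average saturation for the unmeasured pool.
#' @return The constrained `ec_model`, with attribute `mass_report` (see
#'   [proteomics_mass_report()]).
#' @export
hybrid_constraints <- function(ec, prot, ptot = prot$ptot,
                               f_unmeasured = 0.2154, sigma = 0.46) {
  res <- set_proteomics_bounds(ec, prot)
  if (res$matched_mass >= ptot) {
    stop("matched enzyme mass (", signif(res$matched_mass, 4),
         " g/gDW) is not below the total protein content (", ptot, ")",
         call. = FALSE)
  }
  out <- res$model
  if (length(res$unmeasured)) {
    out <- add_pool(out,
                    pool_config(ptot = ptot - res$matched_mass,
                                f = f_unmeasured, sigma = sigma),
                    scope = res$unmeasured)
  }
  attr(out, "mass_report") <- proteomics_mass_report(
    ptot, res$matched_mass, f_unmeasured, sigma)
  out
}

#' Mass bookkeeping of a proteomics integration
#'
#' The arithmetic of the measured/unmeasured split: remaining protein mass
#' `ptot - matched`, the pre-saturation pool mass `f_unmeasured * remaining`,
#' the final pool bound `sigma * f_unmeasured * remaining`, and the
#' percentage of the model's enzyme mass covered by direct measurements,
#' `matched / (matched + pool mass)`.
#'
#' @param ptot total protein content, g/gDW.
#' @param matched_mass directly measured enzyme mass, g/gDW.
#' @param f_unmeasured mass fraction for the unmeasured pool.
#' @param sigma average saturation applied to the pool bound.
#' @return list with `remaining_mass`, `pool_mass`, `pool_bound`,
#'   `matched_fraction_pct`.
#' @export
proteomics_mass_report <- function(ptot, matched_mass, f_unmeasured, sigma) {
  remaining <- ptot - matched_mass
  pool_mass <- f_unmeasured * remaining
  list(remaining_mass = remaining,
       pool_mass = pool_mass,
       pool_bound = sigma * pool_mass,
       matched_fraction_pct = 100 * matched_mass / (matched_mass + pool_mass))
}

#' Correct complex subunit abundances
#'
#' Multi-subunit complexes are sometimes quantified unevenly (some subunits
#' detected in very low amounts). For each flagged complex, the per-subunit
#' relative abundance `mean_i / stoich_i` is averaged over its measured
#' subunits, and every measured subunit's mean is reset to
#' `stoich_i * average`; the SD is scaled by the same factor.
#'
#' @param prot a `proteomics_set`.
#' @param enzymes an `enzyme_table` with complex membership.
#' @param complex_ids complexes to correct; `NULL` corrects every complex
#'   with more than one subunit.
#' @return The corrected `proteomics_set`.
#' @export
correct_complex_abundances <- function(prot, enzymes, complex_ids = NULL) {
  cids <- unique(enzymes$complex_id[!is.na(enzymes$complex_id)])
  if (!is.null(complex_ids)) cids <- intersect(cids, complex_ids)
  dat <- prot$data
  for (cid in cids) {
    members <- enzymes[!is.na(enzymes$complex_id) &
                         enzymes$complex_id == cid, , drop = FALSE]
    idx <- match(members$protein_id, dat$protein_id)
    measured <- !is.na(idx)
    if (!any(measured)) {
      warning("complex ", cid, " has no measured subunit; left untouched",
              call. = FALSE)
      next
    }
    mi <- idx[measured]
    rel <- dat$mean[mi] / members$stoich[measured]
    target <- members$stoich[measured] * mean(rel)
    factor <- ifelse(dat$mean[mi] > 0, target / dat$mean[mi], 1)
    dat$sd[mi] <- dat$sd[mi] * factor
    dat$mean[mi] <- target
  }
  prot$data <- dat
  prot
}

#' Set growth- and non-growth-associated maintenance
#'
#' Rewrites the ATP hydrolysis term (ATP + H2O -> ADP + Pi [+ H]) of the
#' biomass reaction to `gam` mmol ATP per gDW of biomass, and sets the lower
#' bound of the non-growth maintenance reaction to `ngam` mmol ATP/gDW/h.
#' Reference values for aerobic yeast: GAM 31, NGAM 0.7; anaerobic GAM 16.
#'
#' @param model a model with a biomass reaction containing an ATP term and a
#'   dedicated NGAM reaction.
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @param ngam non-growth-associated maintenance, mmol ATP/gDW/h.
#' @param biomass biomass reaction id (defaults to the objective reaction).
#' @param ngam_rxn NGAM reaction id.
#' @param species named list mapping the roles `atp`, `adp`, `pi`, `h2o`,
#'   `h` to metabolite ids; entries absent from the biomass reaction are
#'   skipped except `atp`, which must be present.
#' @return The modified model.
#' @export
apply_maintenance <- function(model, gam, ngam,
                              biomass = model$objective$reaction,
                              ngam_rxn = "NGAM",
                              species = list(atp = "atp", adp = "adp",
                                             pi = "pi", h2o = "h2o",
                                             h = "h")) {
  i <- rxn_index(model, biomass)
  st <- model$reactions$stoich[[i]]
  if (!species$atp %in% names(st) || st[[species$atp]] >= 0) {
    stop("biomass reaction ", biomass, " has no ATP hydrolysis term",
         call. = FALSE)
  }
  signs <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  for (role in names(signs)) {
    id <- species[[role]]
    if (!is.null(id) && id %in% names(st)) {
      st[[id]] <- signs[[role]] * gam
    }
  }
  model$reactions$stoich[[i]] <- st
  model <- set_bounds(model, ngam_rxn, lb = ngam)
  validate_model(model)
  model
}
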