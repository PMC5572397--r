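# Simulation recipes on (enzyme-constrained) models: FBA, parsimonious
# enzyme minimization, chemostat and batch protocols, knockouts, yield
# envelopes, FVA, flux control coefficients, and saturation fitting. The
# multi-stage recipes are lexicographic LPs: each stage fixes the previous
# optimum (with a 1e-6 relative slack band) before optimizing the next
# quantity.

#' Flux balance analysis
#'
#' @param model a `metabolic_model` or `ec_model`.
#' @param objective,direction optional override of the model objective (see
#'   [solve_lp()]).
#' @return A `sim_result`; infeasible or unbounded problems are reported in
#'   `status`, no exception is thrown.
#' @export
fba <- function(model, objective = NULL, direction = NULL) {
  lp <- solve_lp(model, objective, direction)
  sim_result(model, lp, "fba")
}

#' Minimize total enzyme usage at fixed fluxes
#'
#' Parsimonious refinement: fixes the given fluxes and minimizes the total
#' enzyme mass `sum MW_i * e_i` (or the plain usage sum when
#' `mass_weighted = FALSE`).
#'
#' @param ec an `ec_model`.
#' @param fixed named numeric vector of fluxes to fix (mmol/gDW/h).
#' @param mass_weighted weight usages by molecular weight (default TRUE).
#' @return A `sim_result`.
#' @export
minimize_enzyme_usage <- function(ec, fixed = NULL, mass_weighted = TRUE) {
  m <- ec
  for (id in names(fixed)) m <- fix_flux(m, id, fixed[[id]])
  lp <- solve_lp(m, enzyme_mass_objective(ec, mass_weighted), "min")
  sim_result(ec, lp,
             c(sprintf("fix %s=%g", names(fixed), fixed), "min enzyme mass"))
}

#' Chemostat simulation at a dilution rate
#'
#' Lexicographic protocol: fix the specific growth rate to the dilution rate
#' `D`, minimize the substrate uptake rate, fix the uptake at the optimum,
#' and minimize the enzyme mass.
#'
#' @param ec an `ec_model` (typically pooled or proteomics-bounded).
#' @param D dilution rate, 1/h.
#' @param substrate substrate exchange reaction id (positive flux = uptake).
#' @param growth growth reaction id (defaults to the model objective).
#' @param mass_weighted see [minimize_enzyme_usage()].
#' @return A `sim_result`; an unattainable `D` yields status `"infeasible"`.
#' @export
chemostat <- function(ec, D, substrate, growth = ec$objective$reaction,
                      mass_weighted = TRUE) {
  m <- fix_flux(ec, growth, D)
  lp1 <- solve_lp(m, stats::setNames(1, substrate), "min")
  if (lp1$status != "optimal") {
    return(sim_result(ec, lp1, sprintf("fix growth=%g (infeasible)", D)))
  }
  m <- fix_flux(m, substrate, lp1$value)
  lp2 <- solve_lp(m, enzyme_mass_objective(ec, mass_weighted), "min")
  sim_result(ec, lp2, c(sprintf("fix growth=%g", D),
                        sprintf("min uptake -> %g", lp1$value),
                        "min enzyme mass"))
}

#' Batch (substrate-excess) growth simulation
#'
#' Releases the uptake bounds of the medium components, maximizes growth
#' under the enzyme pool limit, then parsimoniously minimizes substrate
#' uptake and enzyme mass at the fixed optimum. Requires a pool (or
#' proteomics) constraint; without one growth is unbounded.
#'
#' @param ec a pooled `ec_model`.
#' @param medium named numeric vector: exchange reaction id -> uptake upper
#'   bound (mmol/gDW/h; use `Inf` for the excess carbon source; the field
#'   convention for amino acids or nucleotides in non-minimal media is a cap
#'   of 2 mmol/gDW/h).
#' @param substrate exchange id whose uptake is minimized at fixed growth
#'   (defaults to the first medium component).
#' @param growth growth reaction id.
#' @param mass_weighted see [minimize_enzyme_usage()].
#' @return A `sim_result`.
#' @export
batch <- function(ec, medium = NULL, substrate = NULL,
                  growth = ec$objective$reaction, mass_weighted = TRUE) {
  if (is.null(ec$pool) && !any(is.finite(ec$reactions$ub[
    grepl("^draw_prot_", ec$reactions$id)]))) {
    stop("growth is unbounded without an abundance constraint; ",
         "call add_pool() or set_proteomics_bounds() first", call. = FALSE)
  }
  m <- ec
  for (id in names(medium)) m <- set_bounds(m, id, ub = medium[[id]])
  lp1 <- solve_lp(m, stats::setNames(1, growth), "max")
  if (lp1$status != "optimal") return(sim_result(ec, lp1, "max growth"))
  m <- fix_flux(m, growth, lp1$value)
  prov <- sprintf("max growth -> %g", lp1$value)
  if (is.null(substrate) && length(medium)) substrate <- names(medium)[1]
  if (!is.null(substrate)) {
    lp2 <- solve_lp(m, stats::setNames(1, substrate), "min")
    m <- fix_flux(m, substrate, lp2$value)
    prov <- c(prov, sprintf("min uptake -> %g", lp2$value))
  }
  lp3 <- solve_lp(m, enzyme_mass_objective(ec, mass_weighted), "min")
  sim_result(ec, lp3, c(prov, "min enzyme mass"))
}

#' Block the usage of one or more enzymes
#'
#' Simulates a gene deletion by setting the usage bounds of the listed
#' proteins to zero; a complex is blocked by knocking out any subunit.
#'
#' @param ec an `ec_model`.
#' @param proteins protein ids to knock out.
#' @return The constrained `ec_model`.
#' @export
knockout <- function(ec, proteins) {
  draw_ids <- paste0("draw_prot_", proteins)
  unknown <- setdiff(draw_ids, ec$reactions$id)
  if (length(unknown)) {
    stop("unknown enzyme(s): ",
         paste(sub("^draw_prot_", "", unknown), collapse = ", "),
         call. = FALSE)
  }
  for (id in draw_ids) ec <- set_bounds(ec, id, lb = 0, ub = 0)
  ec
}

#' Production envelope in yield space
#'
#' Caps the substrate uptake at the given rate (an upper bound, so that
#' low-growth points without an alternative carbon sink stay feasible),
#' sweeps the growth rate from 0 to 100% of its maximum, and at each point
#' maximizes the product formation rate and then minimizes the enzyme
#' usage. Both axes are converted to g/g yields with the supplied molar
#' masses, normalized by the uptake cap.
#'
#' @param ec an `ec_model`.
#' @param product product exchange reaction id.
#' @param substrate substrate exchange reaction id.
#' @param n number of grid points (n = 2 gives the two corner points).
#' @param uptake substrate uptake cap (default: its current upper bound).
#' @param mw_product,mw_substrate,mw_biomass molar masses in g/mmol
#'   (biomass: g per unit of growth flux) for the g/g conversion.
#' @param growth growth reaction id.
#' @return data.frame with `fraction`, `growth`, `product_rate`,
#'   `biomass_yield`, `product_yield`.
#' @export
yield_envelope <- function(ec, product, substrate, n = 20, uptake = NULL,
                           mw_product = 1, mw_substrate = 1, mw_biomass = 1,
                           growth = ec$objective$reaction) {
  if (is.null(uptake)) {
    uptake <- ec$reactions$ub[rxn_index(ec, substrate)]
    if (!is.finite(uptake)) {
      stop("substrate uptake is unbounded; pass `uptake`", call. = FALSE)
    }
  }
  m0 <- set_bounds(ec, substrate, ub = uptake)
  top <- solve_lp(m0, stats::setNames(1, growth), "max")
  if (top$status != "optimal") {
    stop("no feasible growth at uptake ", uptake, call. = FALSE)
  }
  fracs <- seq(0, 1, length.out = n)
  out <- lapply(fracs, function(fr) {
    m <- fix_flux(m0, growth, fr * top$value)
    lp <- solve_lp(m, stats::setNames(1, product), "max")
    vp <- if (lp$status == "optimal" && lp$value > 1e-9) lp$value else 0
    if (vp > 0) {
      m <- fix_flux(m, product, vp)
      solve_lp(m, enzyme_mass_objective(ec), "min")  # parsimonious refinement
    }
    data.frame(fraction = fr, growth = fr * top$value, product_rate = vp,
               biomass_yield = fr * top$value * mw_biomass /
                 (uptake * mw_substrate),
               product_yield = vp * mw_product / (uptake * mw_substrate))
  })
  do.call(rbind, out)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux at a fixed fraction of the
#' objective optimum. On an expanded model the analysis reports net fluxes
#' of the original reactions (forward minus backward, isozyme copies summed
#' through their arm), so expanded and original models are comparable on the
#' same reaction set.
#'
#' @param model a `metabolic_model` or `ec_model`.
#' @param reactions reaction ids to analyze (default: all original ids).
#' @param fraction_of_optimum fraction in `[0, 1]` of the objective optimum
#'   to enforce (0 = analyze the whole feasible polytope).
#' @param fixed optional named numeric vector of fluxes to fix first.
#' @return data.frame with `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = NULL, fraction_of_optimum = 1,
                fixed = NULL) {
  m <- model
  for (id in names(fixed)) m <- fix_flux(m, id, fixed[[id]])
  if (fraction_of_optimum > 0 && !is.null(m$objective)) {
    opt <- solve_lp(m)
    if (opt$status != "optimal") {
      stop("model is ", opt$status, "; cannot anchor FVA at an optimum",
           call. = FALSE)
    }
    m <- fix_flux(m, m$objective$reaction, fraction_of_optimum * opt$value,
                  rel_slack = 0, abs_slack = 1e-9)
    if (fraction_of_optimum < 1) {
      m <- set_bounds(m, m$objective$reaction,
                      lb = fraction_of_optimum * opt$value - 1e-9,
                      ub = model$reactions$ub[rxn_index(model,
                                                        m$objective$reaction)])
    }
  }
  if (is.null(reactions)) {
    reactions <- if (!is.null(m$rxn_map)) {
      unique(m$rxn_map$orig_id[m$rxn_map$role %in%
                                 c("metabolic", "arm", "isozyme")])
    } else m$reactions$id
  }
  rows <- lapply(reactions, function(rid) {
    obj <- net_objective(m, rid)
    lo <- solve_lp(m, obj, "min")
    hi <- solve_lp(m, obj, "max")
    data.frame(reaction = rid, min = lo$value, max = hi$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare flux variability before and after enzyme constraints
#'
#' Runs [fva()] on the original and the expanded model over their shared
#' original reaction set and reports the per-reaction variability reduction
#' and the fraction of reactions whose range was reduced, unchanged, or
#' increased (increases beyond tolerance are numerical artifacts).
#'
#' @param original the pre-expansion `metabolic_model`.
#' @param ec the `ec_model`.
#' @param fraction_of_optimum,fixed passed to both [fva()] calls.
#' @param tol classification tolerance on the range difference.
#' @return data.frame per reaction with ranges and a `change` class;
#'   attribute `summary` holds the class fractions.
#' @export
compare_fva <- function(original, ec, fraction_of_optimum = 0, fixed = NULL,
                        tol = 1e-6) {
  f_orig <- fva(original, fraction_of_optimum = fraction_of_optimum,
                fixed = fixed)
  shared <- intersect(f_orig$reaction,
                      unique(ec$rxn_map$orig_id[ec$rxn_map$role %in%
                                                  c("metabolic", "arm",
                                                    "isozyme")]))
  f_ec <- fva(ec, reactions = shared,
              fraction_of_optimum = fraction_of_optimum, fixed = fixed)
  f_orig <- f_orig[match(shared, f_orig$reaction), ]
  out <- data.frame(reaction = shared,
                    min_original = f_orig$min, max_original = f_orig$max,
                    min_ec = f_ec$min, max_ec = f_ec$max,
                    stringsAsFactors = FALSE)
  out$range_original <- out$max_original - out$min_original
  out$range_ec <- out$max_ec - out$min_ec
  out$reduction <- out$range_original - out$range_ec
  out$change <- ifelse(out$reduction > tol, "reduced",
                       ifelse(out$reduction < -tol, "increased", "equal"))
  attr(out, "summary") <- prop.table(table(factor(
    out$change, levels = c("reduced", "equal", "increased"))))
  out
}

# Rescale the turnover numbers of one enzyme in every reaction it catalyzes,
# updating both the kcat table and the kinetic coefficients.
scale_enzyme_kcats <- function(ec, protein, factor) {
  rows <- which(ec$kcats$protein_id == protein)
  if (!length(rows)) stop("enzyme ", protein, " catalyzes nothing",
                          call. = FALSE)
  ec$kcats$kcat_per_s[rows] <- ec$kcats$kcat_per_s[rows] * factor
  ec$kcats$kcat_per_h[rows] <- ec$kcats$kcat_per_h[rows] * factor
  prot_row <- paste0("prot_", protein)
  for (i in rows) {
    j <- rxn_index(ec, ec$kcats$rxn_id[i])
    st <- ec$reactions$stoich[[j]]
    st[[prot_row]] <- -ec$kcats$subunit_stoich[i] / ec$kcats$kcat_per_h[i]
    ec$reactions$stoich[[j]] <- st
  }
  ec
}

#' Flux control coefficients over enzyme specific activities
#'
#' For each enzyme, all of its turnover numbers are scaled by `1 + delta`
#' (a promiscuous enzyme's specific activity is one property, so every
#' reaction it catalyzes is perturbed together), the recipe is re-run, and
#' the control coefficient is the relative response of the target flux:
#' `FCC_i = ((v' - v) / v) / delta`. When the enzyme pool is the unique
#' binding constraint the coefficients sum to ~1.
#'
#' @param ec an `ec_model`.
#' @param target target reaction id (must carry nonzero flux under the
#'   recipe).
#' @param delta relative kcat perturbation (default 1e-3).
#' @param recipe function mapping a model to a `sim_result`
#'   (default [fba()]).
#' @param threshold reporting threshold on `|FCC|`; the full table is always
#'   returned with a `reported` flag.
#' @return data.frame with `protein_id`, `fcc`, `reported`; attribute
#'   `delta`.
#' @export
flux_control_coefficients <- function(ec, target, delta = 1e-3,
                                      recipe = fba, threshold = 1e-6) {
  base <- recipe(ec)
  if (base$status != "optimal") {
    stop("base recipe is ", base$status, call. = FALSE)
  }
  v0 <- base$fluxes[[target]]
  if (!is.finite(v0) || abs(v0) < 1e-12) {
    stop("target reaction ", target, " carries no flux; pick a target with ",
         "nonzero optimal flux", call. = FALSE)
  }
  prots <- sort(unique(ec$kcats$protein_id))
  fcc <- vapply(prots, function(p) {
    pert <- recipe(scale_enzyme_kcats(ec, p, 1 + delta))
    if (pert$status != "optimal") return(NA_real_)
    ((pert$fluxes[[target]] - v0) / v0) / delta
  }, numeric(1))
  out <- data.frame(protein_id = prots, fcc = unname(fcc),
                    reported = abs(fcc) >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  out
}

#' Fit the average saturation to an observable
#'
#' Bisection on the pool saturation sigma: the pool bound scales as
#' `sigma * f * ptot`, and any observable that is monotone increasing in the
#' pool bound (growth under a binding pool is, and scales linearly with it)
#' can be matched to a target value.
#'
#' @param ec a pooled `ec_model`.
#' @param target target value of the observable.
#' @param recipe function mapping a model to the observable (default:
#'   maximal growth via [fba()]).
#' @param bracket search interval for sigma (default `(1e-6, 1]`).
#' @param tol absolute convergence tolerance on the observable
#'   (default 1e-4).
#' @param max_iter bisection iteration cap.
#' @return list with `sigma`, `value`, `converged`, and the bisection
#'   `trace`; errors when the target exceeds the value at sigma = 1.
#' @export
fit_sigma <- function(ec, target, recipe = function(m) fba(m)$objective,
                      bracket = c(1e-6, 1), tol = 1e-4, max_iter = 100) {
  if (is.null(ec$pool)) stop("fit_sigma needs a pooled model", call. = FALSE)
  g <- function(s) recipe(set_pool_sigma(ec, s))
  lo <- bracket[1]; hi <- bracket[2]
  v_hi <- g(hi)
  if (v_hi < target - tol) {
    stop("target ", target, " unreachable: maximum attainable at sigma=1 is ",
         signif(v_hi, 6), call. = FALSE)
  }
  v_lo <- g(lo)
  if (v_lo >= target - tol) {
    warning("target is at or below the sigma -> 0 boundary", call. = FALSE)
    return(list(sigma = lo, value = v_lo, converged = FALSE,
                trace = data.frame(iter = 0L, sigma = lo, value = v_lo)))
  }
  trace <- list()
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- g(mid)
    trace[[it]] <- data.frame(iter = it, sigma = mid, value = v)
    if (abs(v - target) <= tol) {
      return(list(sigma = mid, value = v, converged = TRUE,
                  trace = do.call(rbind, trace)))
    }
    if (v < target) lo <- mid else hi <- mid
  }
  list(sigma = (lo + hi) / 2, value = g((lo + hi) / 2), converged = FALSE,
       trace = do.call(rbind, trace))
}
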