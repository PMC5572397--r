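# The stoichiometric-matrix expansion: reversible splitting, isozyme arm
# reactions with pseudo-metabolites, enzyme rows with kinetic coefficients,
# and per-enzyme usage columns. The expanded matrix has four blocks: the
# original stoichiometry (upper left), zeros (upper right), -1/kcat entries
# (lower left), and the identity over enzyme usages (lower right).

is_enzyme_met <- function(ids) startsWith(ids, "prot_")
is_pmet <- function(ids) startsWith(ids, "pmet_")
ordinary_part <- function(st) st[!is_enzyme_met(names(st)) & !is_pmet(names(st))]

new_map_row <- function(rxn_id, orig_id, split_id, role, dir,
                        orig_lb, orig_ub, orig_rule) {
  data.frame(rxn_id = rxn_id, orig_id = orig_id, split_id = split_id,
             role = role, dir = dir, orig_lb = orig_lb, orig_ub = orig_ub,
             orig_rule = orig_rule, stringsAsFactors = FALSE)
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reaction with `lb < 0 < ub` becomes a forward copy `<id>` with
#' bounds `[0, ub]` and a backward copy `<id>_REV` with negated stoichiometry
#' and bounds `[0, -lb]`, so that each direction can later carry its own
#' enzyme coefficient. Pure-backward reactions (`ub <= 0 > lb`) are flipped
#' and renamed `<id>_REV`. Irreversible reactions are untouched. A reaction
#' map recording original ids, bounds, and gene rules is attached for later
#' reconstruction and net-flux reporting.
#'
#' @param model a `metabolic_model`.
#' @return The irreversible model with element `rxn_map`.
#' @export
split_reversible <- function(model) {
  rx <- model$reactions
  out <- list()
  maps <- list()
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, , drop = FALSE]
    st <- r$stoich[[1]]
    if (r$lb < 0 && r$ub > 0) {
      fwd <- r
      fwd$lb <- 0
      rev <- r
      rev$id <- paste0(r$id, "_REV")
      rev$name <- paste(r$name, "(reverse)")
      rev$lb <- 0
      rev$ub <- -r$lb
      rev$stoich <- list(-st)
      out <- c(out, list(fwd, rev))
      maps <- c(maps,
                list(new_map_row(fwd$id, r$id, fwd$id, "metabolic", 1L,
                                 r$lb, r$ub, r$gene_rule),
                     new_map_row(rev$id, r$id, rev$id, "metabolic", -1L,
                                 r$lb, r$ub, r$gene_rule)))
    } else if (r$ub <= 0 && r$lb < 0) {
      rev <- r
      rev$id <- paste0(r$id, "_REV")
      rev$name <- paste(r$name, "(reverse)")
      rev$lb <- -r$ub
      rev$ub <- -r$lb
      rev$stoich <- list(-st)
      out <- c(out, list(rev))
      maps <- c(maps, list(new_map_row(rev$id, r$id, rev$id, "metabolic", -1L,
                                       r$lb, r$ub, r$gene_rule)))
    } else {
      out <- c(out, list(r))
      maps <- c(maps, list(new_map_row(r$id, r$id, r$id, "metabolic", 1L,
                                       r$lb, r$ub, r$gene_rule)))
    }
  }
  model$reactions <- do.call(rbind, out)
  rownames(model$reactions) <- NULL
  model$rxn_map <- do.call(rbind, maps)
  validate_model(model)
  model
}

#' Introduce arm reactions for isozymes
#'
#' A reaction whose gene rule is an OR over k > 1 catalytic units (after
#' normalization to disjunctive normal form; duplicated units are removed)
#' is replaced by an arm reaction `arm_<id>` carrying the original bounds
#' from the substrates to a pseudo-metabolite `pmet_<id>`, plus k copies
#' `<id>No1..Nok` (ordered by sorted protein ids) from the pseudo-metabolite
#' to the products, each bounded `[0, ub]`. Single-unit and enzyme-free
#' reactions are untouched.
#'
#' @param model an irreversible model (run [split_reversible()] first).
#' @param enzymes an `enzyme_table` used to order copies by protein id.
#' @return The model with arm reactions and an updated reaction map.
#' @export
expand_isozymes <- function(model, enzymes) {
  if (any(model$reactions$lb < 0)) {
    stop("model must be in irreversible form; run split_reversible() first",
         call. = FALSE)
  }
  if (is.null(model$rxn_map)) {
    model$rxn_map <- new_map_row(model$reactions$id, model$reactions$id,
                                 model$reactions$id, "metabolic", 1L,
                                 model$reactions$lb, model$reactions$ub,
                                 model$reactions$gene_rule)
  }
  rx <- model$reactions
  out <- list()
  maps <- list()
  new_mets <- list()
  map_by_id <- model$rxn_map[match(rx$id, model$rxn_map$rxn_id), ]
  gene_key <- function(g) {
    p <- enzymes$protein_id[match(g, enzymes$gene)]
    ifelse(is.na(p), g, p)
  }
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, , drop = FALSE]
    m <- map_by_id[i, , drop = FALSE]
    rule <- r$gene_rule
    dnf <- if (is.na(rule) || !nzchar(rule)) list() else gene_rule_dnf(rule)
    if (length(dnf) <= 1) {
      out <- c(out, list(r))
      maps <- c(maps, list(m))
      next
    }
    keys <- vapply(dnf, function(u) paste(sort(gene_key(u)), collapse = "+"),
                   character(1))
    dnf <- dnf[order(keys)]
    st <- r$stoich[[1]]
    pmet <- paste0("pmet_", r$id)
    subs <- st[st < 0]
    prods <- st[st > 0]
    comp <- if (length(subs)) {
      model$metabolites$compartment[match(names(subs)[1],
                                          model$metabolites$id)]
    } else "c"
    new_mets[[length(new_mets) + 1L]] <- data.frame(
      id = pmet, name = pmet, compartment = comp, stringsAsFactors = FALSE)
    arm <- r
    arm$id <- paste0("arm_", r$id)
    arm$name <- paste("isozyme arm of", r$id)
    arm$gene_rule <- ""
    arm$stoich <- list(c(subs, stats::setNames(1, pmet)))
    out <- c(out, list(arm))
    maps <- c(maps, list(new_map_row(arm$id, m$orig_id, r$id, "arm", m$dir,
                                     m$orig_lb, m$orig_ub, m$orig_rule)))
    for (k in seq_along(dnf)) {
      cp <- r
      cp$id <- paste0(r$id, "No", k)
      cp$name <- paste0(r$name, " (isozyme ", k, ")")
      cp$lb <- 0
      cp$gene_rule <- paste(dnf[[k]], collapse = " and ")
      cp$stoich <- list(c(stats::setNames(-1, pmet), prods))
      out <- c(out, list(cp))
      maps <- c(maps, list(new_map_row(cp$id, m$orig_id, r$id, "isozyme",
                                       m$dir, m$orig_lb, m$orig_ub,
                                       m$orig_rule)))
    }
  }
  model$reactions <- do.call(rbind, out)
  rownames(model$reactions) <- NULL
  if (length(new_mets)) {
    model$metabolites <- rbind(model$metabolites, do.call(rbind, new_mets))
  }
  model$rxn_map <- do.call(rbind, maps)
  rownames(model$rxn_map) <- NULL
  validate_model(model)
  model
}

#' Attach enzyme rows and usage columns
#'
#' For every catalyzed reaction column j and catalyzing protein i, the
#' coefficient of row `prot_i` is set to `-s_i / (kcat_ij * 3600)`, where
#' `s_i` is the subunit stoichiometry within the complex and the factor 3600
#' converts kcat from 1/s to 1/h so that a flux in mmol/gDW/h draws enzyme in
#' mmol/gDW. One usage reaction `draw_prot_<accession>` per protein produces
#' its enzyme row, initially unbounded above; promiscuous proteins appear in
#' several columns and share the single usage.
#'
#' @param model output of [expand_isozymes()].
#' @param assignments a `kcat_assignments` table keyed by post-split
#'   reaction ids.
#' @param enzymes an `enzyme_table`.
#' @return An `ec_model`.
#' @export
attach_enzymes <- function(model, assignments, enzymes) {
  if (inherits(model, "ec_model")) {
    stop("model is already enzyme-constrained; expansion is not idempotent",
         call. = FALSE)
  }
  if (any(assignments$kcat_per_s <= 0, na.rm = TRUE)) {
    stop("all assigned kcat values must be positive", call. = FALSE)
  }
  map <- model$rxn_map
  kcat_rows <- list()
  unit_rows <- list()
  missing <- character(0)
  used_prot <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gene_rule[i]
    if (is.na(rule) || !nzchar(rule)) next
    id <- model$reactions$id[i]
    mrow <- map[map$rxn_id == id, , drop = FALSE]
    split_id <- if (nrow(mrow)) mrow$split_id[1] else id
    res <- resolve_units(rule, enzymes)
    if (length(res$units) > 1) {
      stop("reaction ", id, " still has ", length(res$units),
           " isozyme alternatives; run expand_isozymes() first",
           call. = FALSE)
    }
    if (!length(res$units)) next  # unresolved genes: reported as gaps upstream
    unit <- res$units[[1]]
    prot_set <- sort(unit$protein_id)
    hit <- which(assignments$rxn_id == split_id &
                   vapply(assignments$proteins, function(p)
                     identical(sort(p), prot_set), logical(1)))
    if (!length(hit)) {
      missing <- c(missing, paste0(split_id, "/", paste(prot_set,
                                                        collapse = "+")))
      next
    }
    kcat <- assignments$kcat_per_s[hit[1]]
    level <- assignments$level[hit[1]]
    st <- model$reactions$stoich[[i]]
    for (p in seq_len(nrow(unit))) {
      pid <- unit$protein_id[p]
      row_id <- paste0("prot_", pid)
      coef <- -unit$stoich[p] / (kcat * 3600)
      st[row_id] <- (if (row_id %in% names(st)) st[[row_id]] else 0) + coef
      kcat_rows[[length(kcat_rows) + 1L]] <- data.frame(
        rxn_id = id, protein_id = pid, kcat_per_s = kcat,
        kcat_per_h = kcat * 3600, level = level,
        subunit_stoich = unit$stoich[p], stringsAsFactors = FALSE)
      used_prot <- c(used_prot, pid)
    }
    unit_rows[[length(unit_rows) + 1L]] <- data.frame(
      rxn_id = id, unit_id = unit_label(unit), n_proteins = nrow(unit),
      stringsAsFactors = FALSE)
    model$reactions$stoich[[i]] <- st
  }
  if (length(missing)) {
    stop("missing kcat assignment for pair(s): ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  used_prot <- sort(unique(used_prot))
  if (length(used_prot)) {
    model$metabolites <- rbind(
      model$metabolites,
      data.frame(id = paste0("prot_", used_prot), name = used_prot,
                 compartment = "enzyme", stringsAsFactors = FALSE))
    draws <- make_reactions(
      ids = paste0("draw_prot_", used_prot),
      names_ = paste("usage of", used_prot),
      lb = 0, ub = Inf, gene_rule = "", subsystem = "enzyme usage",
      stoich = lapply(used_prot, function(p)
        stats::setNames(1, paste0("prot_", p))))
    model$reactions <- rbind(model$reactions, draws)
    model$rxn_map <- rbind(
      model$rxn_map,
      new_map_row(paste0("draw_prot_", used_prot),
                  paste0("draw_prot_", used_prot),
                  paste0("draw_prot_", used_prot),
                  "usage", 1L, 0, Inf, ""))
  }
  model$kcats <- if (length(kcat_rows)) do.call(rbind, kcat_rows) else
    data.frame(rxn_id = character(0), protein_id = character(0),
               kcat_per_s = numeric(0), kcat_per_h = numeric(0),
               level = integer(0), subunit_stoich = numeric(0))
  model$units <- if (length(unit_rows)) do.call(rbind, unit_rows) else
    data.frame(rxn_id = character(0), unit_id = character(0),
               n_proteins = integer(0))
  model$enzymes <- enzymes
  model$pool <- NULL
  class(model) <- c("ec_model", class(model))
  validate_model(model)
  model
}

#' Expand a metabolic model into an enzyme-constrained model
#'
#' Composition of [split_reversible()], [expand_isozymes()], and
#' [attach_enzymes()]. Re-expanding an already expanded model (or one whose
#' ids carry expansion markers) is rejected.
#'
#' @param model a `metabolic_model`.
#' @param enzymes an `enzyme_table`.
#' @param assignments a `kcat_assignments` table (see [assign_kcats()]).
#' @return An `ec_model`.
#' @export
expand_model <- function(model, enzymes, assignments) {
  if (inherits(model, "ec_model") ||
      any(grepl("^(arm_|draw_prot_)", model$reactions$id)) ||
      any(grepl("_REV$", model$reactions$id)) ||
      any(is_enzyme_met(model$metabolites$id)) ||
      any(is_pmet(model$metabolites$id))) {
    stop("model already carries expansion markers; refusing to expand twice",
         call. = FALSE)
  }
  model <- split_reversible(model)
  model <- expand_isozymes(model, enzymes)
  attach_enzymes(model, assignments, enzymes)
}

#' Validate the structural invariants of an enzyme-constrained model
#'
#' Checks that every usage column touches exactly its own enzyme row (plus
#' the pool row when pooled) and no ordinary metabolite, that every kinetic
#' coefficient equals `-subunit_stoich / kcat_h` to 1e-12, that every
#' pseudo-metabolite row is produced by exactly one arm reaction, and that
#' all bounds are non-negative (irreversible form).
#'
#' @param ec an `ec_model`.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_ec_model <- function(ec) {
  if (!inherits(ec, "ec_model")) stop("not an ec_model", call. = FALSE)
  validate_model(ec)
  if (any(ec$reactions$lb < 0)) {
    stop("ec_model must be irreversible (all lower bounds >= 0)",
         call. = FALSE)
  }
  mw <- stats::setNames(ec$enzymes$mw_kda, ec$enzymes$protein_id)
  map <- ec$rxn_map
  for (i in which(map$role == "usage")) {
    id <- map$rxn_id[i]
    st <- ec$reactions$stoich[[rxn_index(ec, id)]]
    pid <- sub("^draw_prot_", "", id)
    expected <- paste0("prot_", pid)
    extra <- setdiff(names(st), c(expected, "prot_pool"))
    if (length(extra) || !isTRUE(all.equal(unname(st[[expected]]), 1))) {
      stop("usage reaction ", id, " must produce exactly 1 ", expected,
           call. = FALSE)
    }
    if ("prot_pool" %in% names(st)) {
      if (abs(st[["prot_pool"]] + mw[[pid]]) > 1e-9) {
        stop("usage reaction ", id, " must draw MW g/mmol from the pool",
             call. = FALSE)
      }
    }
  }
  # kinetic coefficients
  for (i in seq_len(nrow(ec$kcats))) {
    k <- ec$kcats[i, ]
    st <- ec$reactions$stoich[[rxn_index(ec, k$rxn_id)]]
    coef <- st[[paste0("prot_", k$protein_id)]]
    want <- -k$subunit_stoich / k$kcat_per_h
    if (is.null(coef) || abs(coef - want) > 1e-12) {
      stop("reaction ", k$rxn_id, ": enzyme coefficient for ", k$protein_id,
           " is ", coef, ", expected ", want, call. = FALSE)
    }
  }
  # every enzyme row has exactly one usage column producing it
  prot_rows <- setdiff(grep("^prot_", ec$metabolites$id, value = TRUE),
                       "prot_pool")
  for (pr in prot_rows) {
    producers <- vapply(seq_len(nrow(ec$reactions)), function(j) {
      st <- ec$reactions$stoich[[j]]
      pr %in% names(st) && st[[pr]] > 0
    }, logical(1))
    if (sum(producers) != 1 ||
        ec$reactions$id[producers] != paste0("draw_", pr)) {
      stop("enzyme row ", pr, " must be produced by exactly its usage column",
           call. = FALSE)
    }
  }
  # pseudo-metabolite rows: one arm producer, >=1 isozyme consumer
  pmets <- grep("^pmet_", ec$metabolites$id, value = TRUE)
  for (pm in pmets) {
    prod_n <- cons_n <- 0L
    for (j in seq_len(nrow(ec$reactions))) {
      st <- ec$reactions$stoich[[j]]
      if (!pm %in% names(st)) next
      if (st[[pm]] > 0) prod_n <- prod_n + 1L else cons_n <- cons_n + 1L
    }
    if (prod_n != 1L || cons_n < 1L) {
      stop("pseudo-metabolite ", pm, " must have one arm producer and at ",
           "least one isozyme consumer", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Recover the original metabolic model from an expanded one
#'
#' Removes enzyme rows, pseudo-metabolites, usage and pool columns, re-merges
#' the `_REV` split halves and the isozyme copies, and restores the original
#' bounds and gene rules recorded in the reaction map.
#'
#' @param ec an `ec_model` (or a split/expanded model with a reaction map).
#' @return A `metabolic_model` with the pre-expansion stoichiometry.
#' @export
strip_enzymes <- function(ec) {
  map <- ec$rxn_map
  core <- map[map$role %in% c("metabolic", "arm", "isozyme"), , drop = FALSE]
  orig_ids <- unique(core$orig_id)
  rows <- list()
  for (oid in orig_ids) {
    sub <- core[core$orig_id == oid, , drop = FALSE]
    rebuild_dir <- function(d) {
      dsub <- sub[sub$dir == d, , drop = FALSE]
      if (!nrow(dsub)) return(NULL)
      if (any(dsub$role == "arm")) {
        arm_id <- dsub$rxn_id[dsub$role == "arm"][1]
        copy_id <- dsub$rxn_id[dsub$role == "isozyme"][1]
        st <- ec$reactions$stoich[[rxn_index(ec, arm_id)]]
        st2 <- ec$reactions$stoich[[rxn_index(ec, copy_id)]]
        tot <- ordinary_part(st)
        add <- ordinary_part(st2)
        for (m in names(add)) {
          tot[m] <- (if (m %in% names(tot)) tot[[m]] else 0) + add[[m]]
        }
        tot[tot != 0]
      } else {
        ordinary_part(ec$reactions$stoich[[rxn_index(ec, dsub$rxn_id[1])]])
      }
    }
    st <- rebuild_dir(1L)
    if (is.null(st)) st <- -rebuild_dir(-1L)
    rows[[length(rows) + 1L]] <- make_reactions(
      oid, oid, sub$orig_lb[1], sub$orig_ub[1], sub$orig_rule[1], "",
      list(st))
  }
  mets <- ec$metabolites
  keep <- !is_enzyme_met(mets$id) & !is_pmet(mets$id) & mets$id != "prot_pool"
  objective <- ec$objective
  metabolic_model(mets[keep, , drop = FALSE], do.call(rbind, rows), objective)
}

#' Classify reactions and metabolites of an enzyme-constrained model
#'
#' Produces the descriptor table of the expanded model: reaction classes
#' (enzyme-matched metabolic, unmatched metabolic, transport, exchange, arm,
#' usage), metabolite classes (original, enzymes, pseudo-metabolites), and
#' enzyme/reaction relationship counts (complexes, reactions with isozymes,
#' promiscuous enzymes). The classes partition the model, so class sums equal
#' the totals.
#'
#' @param ec an `ec_model`.
#' @return data.frame with columns `category`, `class`, `count`.
#' @export
classify_model <- function(ec) {
  map <- ec$rxn_map
  roles <- map$role[match(ec$reactions$id, map$rxn_id)]
  n_arm <- sum(roles == "arm")
  n_usage <- sum(roles == "usage")
  n_pool_src <- sum(roles == "pool")
  met_comp <- stats::setNames(ec$metabolites$compartment, ec$metabolites$id)
  met_name <- stats::setNames(ec$metabolites$name, ec$metabolites$id)
  n_exchange <- n_transport <- n_matched <- n_unmatched <- 0L
  for (i in which(roles %in% c("metabolic", "isozyme"))) {
    st <- ec$reactions$stoich[[i]]
    visible <- st[!is_enzyme_met(names(st))]  # pmets count for sidedness
    matched <- any(is_enzyme_met(names(st)) & names(st) != "prot_pool")
    if (all(visible >= 0) || all(visible <= 0)) {
      n_exchange <- n_exchange + 1L
    } else {
      nm_neg <- met_name[names(visible)[visible < 0]]
      nm_pos <- met_name[names(visible)[visible > 0]]
      cp_neg <- met_comp[names(visible)[visible < 0]]
      cp_pos <- met_comp[names(visible)[visible > 0]]
      shared <- intersect(nm_neg, nm_pos)
      is_transport <- any(vapply(shared, function(nm)
        !identical(sort(unique(cp_neg[nm_neg == nm])),
                   sort(unique(cp_pos[nm_pos == nm]))), logical(1)))
      if (is_transport) n_transport <- n_transport + 1L
      else if (matched) n_matched <- n_matched + 1L
      else n_unmatched <- n_unmatched + 1L
    }
  }
  n_exchange <- n_exchange + n_pool_src
  met_ids <- ec$metabolites$id
  n_enz <- sum(is_enzyme_met(met_ids) & met_ids != "prot_pool")
  n_pmet <- sum(is_pmet(met_ids))
  n_orig <- nrow(ec$metabolites) - n_enz - n_pmet -
    as.integer("prot_pool" %in% met_ids)
  complexes <- length(unique(ec$units$unit_id[ec$units$n_proteins > 1]))
  iso_rxns <- length(unique(map$orig_id[map$role == "arm"]))
  orig_of <- stats::setNames(map$orig_id, map$rxn_id)
  promiscuous <- sum(vapply(
    split(orig_of[ec$kcats$rxn_id], ec$kcats$protein_id),
    function(x) length(unique(x)) > 1, logical(1)))
  df <- data.frame(
    category = c(rep("reactions", 6), rep("metabolites", 3),
                 rep("relationships", 3)),
    class = c("enzyme_matched", "not_matched", "transport", "exchange",
              "arm", "usage", "original", "enzymes", "pseudo",
              "complexes", "isozyme_reactions", "promiscuous_enzymes"),
    count = c(n_matched, n_unmatched, n_transport, n_exchange, n_arm,
              n_usage, n_orig, n_enz, n_pmet, complexes, iso_rxns,
              promiscuous),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(df$count[df$category == "reactions"]) ==
              nrow(ec$reactions),
            sum(df$count[df$category == "metabolites"]) ==
              nrow(ec$metabolites) - as.integer("prot_pool" %in% met_ids))
  df
}

#' Sum a descriptor table into model totals
#'
#' @param descriptors data.frame with `category`, `class`, `count` (as
#'   returned by [classify_model()] or [ecyeast7_descriptors()]).
#' @return list with `reactions` and `metabolites` totals.
#' @export
summarize_descriptors <- function(descriptors) {
  list(
    reactions = sum(descriptors$count[descriptors$category == "reactions"]),
    metabolites = sum(descriptors$count[descriptors$category == "metabolites"])
  )
}

#' Published classification counts of the ecYeast7 model
#'
#' The reaction and metabolite class counts reported for ecYeast7, the
#' enzyme-constrained consensus yeast model, shipped as a reference table for
#' bookkeeping checks: reaction classes sum to 6,741 and metabolite classes
#' to 3,388.
#'
#' @return data.frame with columns `category`, `class`, `count`.
#' @export
ecyeast7_descriptors <- function() {
  path <- system.file("extdata", "ecyeast7_descriptors.tsv",
                      package = "enzgem", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
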