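# Turnover-number assignment by hierarchical matching against a local
# kinetics table. Matching relaxes in levels: exact (EC + substrate +
# organism), then any organism, then any substrate, then EC only, then an
# EC-number wildcard on the last field. At the first level with hits the
# MAXIMUM kcat is taken (the fastest reported enzyme), so the model is not
# over-constrained by slow outliers.

LEVEL_DEFAULT <- -1L  # filled by the default policy, no database hit
LEVEL_CURATED <- -2L  # manual override

norm_txt <- function(x) tolower(trimws(x))

ec_head <- function(ec) sub("\\.[^.]+$", "", ec)

#' Match a turnover number for one enzyme/reaction query
#'
#' Walks the relaxation hierarchy: level 0 requires EC, substrate, and
#' organism to match; level 1 drops the organism; level 2 drops the substrate
#' (keeps the organism); level 3 requires only the EC number; level 4
#' wildcards the last EC field. The search stops at the first level with at
#' least one hit and returns the maximum kcat at that level. Ties on kcat are
#' broken deterministically by (EC, substrate, organism) order.
#'
#' @param ec character vector of EC numbers of the enzyme (a complex queries
#'   the union of its subunits' EC numbers).
#' @param substrates character vector of substrate names on the consumed side
#'   of the queried direction; matching is case-insensitive after trimming.
#' @param organism organism name of the model.
#' @param table kinetics table (see [read_kinetics_table()]).
#' @param relaxation integer vector, the levels to try in order
#'   (default `0:4`).
#' @return `list(kcat_per_s, level, record)` or `NULL` when no level hits.
#' @export
match_kcat <- function(ec, substrates, organism, table, relaxation = 0:4) {
  if (!length(ec)) return(NULL)
  if (!nrow(table)) stop("kinetics table is empty", call. = FALSE)
  t_ec <- norm_txt(table$ec)
  t_sub <- norm_txt(table$substrate)
  t_org <- norm_txt(table$organism)
  q_ec <- norm_txt(ec)
  q_sub <- norm_txt(substrates)
  q_org <- norm_txt(organism)
  ec_hit <- t_ec %in% q_ec
  sub_hit <- t_sub %in% q_sub
  org_hit <- t_org == q_org
  wild_hit <- ec_head(t_ec) %in% unique(ec_head(q_ec))
  level_mask <- function(level) {
    switch(as.character(level),
           "0" = ec_hit & sub_hit & org_hit,
           "1" = ec_hit & sub_hit,
           "2" = ec_hit & org_hit,
           "3" = ec_hit,
           "4" = wild_hit,
           stop("unknown relaxation level: ", level, call. = FALSE))
  }
  for (lvl in relaxation) {
    idx <- which(level_mask(lvl))
    if (length(idx)) {
      ord <- order(-table$kcat_per_s[idx], t_ec[idx], t_sub[idx], t_org[idx])
      best <- idx[ord[1]]
      return(list(kcat_per_s = table$kcat_per_s[best], level = as.integer(lvl),
                  record = table[best, , drop = FALSE]))
    }
  }
  NULL
}

# Resolve the catalytic units (DNF conjuncts) of a gene rule against the
# enzyme table. Returns list(units = list of enzyme-table subsets,
# gaps = character vector of unmapped gene ids).
resolve_units <- function(rule, enzymes) {
  dnf <- gene_rule_dnf(rule)
  units <- list()
  gaps <- character(0)
  for (conj in dnf) {
    idx <- match(conj, enzymes$gene)
    if (anyNA(idx)) {
      gaps <- c(gaps, conj[is.na(idx)])
      next
    }
    units <- c(units, list(enzymes[idx, , drop = FALSE]))
  }
  list(units = units, gaps = unique(gaps))
}

unit_label <- function(unit) {
  cid <- unique(unit$complex_id[!is.na(unit$complex_id)])
  if (nrow(unit) > 1 && length(cid) == 1) cid
  else paste(sort(unit$protein_id), collapse = "+")
}

substrate_names <- function(model, stoich, side = c("consumed", "produced")) {
  side <- match.arg(side)
  ids <- names(stoich)[if (side == "consumed") stoich < 0 else stoich > 0]
  nm <- model$metabolites$name[match(ids, model$metabolites$id)]
  nm[is.na(nm) | !nzchar(nm)] <- ids[is.na(nm) | !nzchar(nm)]
  nm
}

#' Assign turnover numbers to every catalyzed reaction direction
#'
#' For every reaction with a gene rule, each direction that carries flux
#' (forward when `ub > 0`, backward when `lb < 0`) and each catalytic unit of
#' the rule (an isozyme or a complex) receives one kcat. Complexes are
#' queried once with the union of their subunits' EC numbers and the kcat is
#' shared by all subunits. The backward direction is queried with the product
#' side as substrates; if only the forward direction matches, its value is
#' reused at provenance level 3. Pairs with no database hit are filled by
#' `default_policy` with provenance level -1. Reaction ids in the output are
#' post-split ids: `<id>` for forward, `<id>_REV` for backward.
#'
#' @param model a `metabolic_model` (pre-expansion).
#' @param enzymes an `enzyme_table`.
#' @param table kinetics table.
#' @param organism organism name used for organism-level matching.
#' @param default_policy `"median"` (median kcat of all successful
#'   assignments) or `"constant"` (use `default_value`).
#' @param default_value kcat in 1/s used when `default_policy = "constant"`.
#' @param relaxation level order passed to [match_kcat()].
#' @return data.frame of class `kcat_assignments` with columns `rxn_id`,
#'   `unit_id`, `kcat_per_s`, `level`, list column `proteins`, and attribute
#'   `gaps` (reaction/gene pairs that could not be resolved).
#' @export
assign_kcats <- function(model, enzymes, table, organism,
                         default_policy = c("median", "constant"),
                         default_value = NULL, relaxation = 0:4) {
  default_policy <- match.arg(default_policy)
  rows <- list()
  gaps <- list()
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gene_rule[i]
    if (is.na(rule) || !nzchar(rule)) next
    id <- model$reactions$id[i]
    res <- resolve_units(rule, enzymes)
    for (g in res$gaps) {
      gaps[[length(gaps) + 1L]] <- data.frame(
        reaction_id = id, gene = g,
        reason = "gene absent from enzyme table", stringsAsFactors = FALSE)
    }
    if (!length(res$units)) next
    lb <- model$reactions$lb[i]
    ub <- model$reactions$ub[i]
    st <- model$reactions$stoich[[i]]
    dirs <- character(0)
    if (ub > 0) dirs <- c(dirs, "fwd")
    if (lb < 0) dirs <- c(dirs, "bwd")
    for (unit in res$units) {
      ecs <- unique(unlist(unit$ec_numbers))
      if (!length(ecs)) {
        gaps[[length(gaps) + 1L]] <- data.frame(
          reaction_id = id, gene = paste(unit$gene, collapse = "+"),
          reason = "no EC number for catalytic unit", stringsAsFactors = FALSE)
        next
      }
      fwd_hit <- NULL
      for (dir in dirs) {
        side <- if (dir == "fwd") "consumed" else "produced"
        hit <- match_kcat(ecs, substrate_names(model, st, side), organism,
                          table, relaxation)
        if (dir == "fwd") fwd_hit <- hit
        if (is.null(hit) && dir == "bwd" && !is.null(fwd_hit)) {
          hit <- list(kcat_per_s = fwd_hit$kcat_per_s, level = 3L,
                      record = fwd_hit$record)
        }
        rid <- if (dir == "fwd" && ub > 0) id else paste0(id, "_REV")
        rows[[length(rows) + 1L]] <- list(
          rxn_id = rid, unit_id = unit_label(unit),
          proteins = sort(unit$protein_id),
          kcat_per_s = if (is.null(hit)) NA_real_ else hit$kcat_per_s,
          level = if (is.null(hit)) LEVEL_DEFAULT else hit$level
        )
      }
    }
  }
  out <- data.frame(
    rxn_id = vapply(rows, `[[`, character(1), "rxn_id"),
    unit_id = vapply(rows, `[[`, character(1), "unit_id"),
    kcat_per_s = vapply(rows, `[[`, numeric(1), "kcat_per_s"),
    level = vapply(rows, `[[`, integer(1), "level"),
    stringsAsFactors = FALSE
  )
  out$proteins <- lapply(rows, `[[`, "proteins")
  if (anyNA(out$kcat_per_s)) {
    fill <- switch(default_policy,
      median = stats::median(out$kcat_per_s[!is.na(out$kcat_per_s)]),
      constant = default_value)
    if (is.null(fill) || !is.finite(fill)) {
      stop("cannot fill unmatched kcats: no successful assignments ",
           "(or default_value missing)", call. = FALSE)
    }
    out$kcat_per_s[is.na(out$kcat_per_s)] <- fill
  }
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(reaction_id = character(0), gene = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  class(out) <- c("kcat_assignments", "data.frame")
  out
}

#' Apply manual kcat curation overrides
#'
#' Replaces assigned turnover numbers with literature-curated values. Each
#' override is keyed by (reaction id, protein id) and replaces the kcat of
#' every assignment of that reaction whose catalytic unit contains the
#' protein; the provenance level is set to the curated marker (-2).
#'
#' @param assignments a `kcat_assignments` table.
#' @param overrides data.frame (or TSV path) with columns `reaction_id`,
#'   `protein_id`, `kcat_per_s`.
#' @return Updated assignments; overrides whose key matches nothing raise a
#'   warning, non-positive kcats an error.
#' @export
apply_manual_curation <- function(assignments, overrides) {
  if (is.character(overrides)) {
    overrides <- utils::read.delim(overrides, stringsAsFactors = FALSE)
  }
  for (col in c("reaction_id", "protein_id", "kcat_per_s")) {
    if (!col %in% names(overrides)) {
      stop("curation table needs column '", col, "'", call. = FALSE)
    }
  }
  if (any(overrides$kcat_per_s <= 0)) {
    stop("curated kcat values must be positive", call. = FALSE)
  }
  for (i in seq_len(nrow(overrides))) {
    hit <- assignments$rxn_id == overrides$reaction_id[i] &
      vapply(assignments$proteins, function(p)
        overrides$protein_id[i] %in% p, logical(1))
    if (!any(hit)) {
      warning("curation override for ", overrides$reaction_id[i], "/",
              overrides$protein_id[i], " matches no assignment; skipped",
              call. = FALSE)
      next
    }
    assignments$kcat_per_s[hit] <- overrides$kcat_per_s[i]
    assignments$level[hit] <- LEVEL_CURATED
  }
  assignments
}
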