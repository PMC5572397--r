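#' Construct a constraint-based metabolic model
#'
#' The container mirrors the standard constraint-based representation: a set of
#' metabolites (rows of the stoichiometric matrix), a set of bounded reactions
#' (columns), and a linear objective given by a single reaction and an
#' optimization direction. Units follow the field convention: fluxes in
#' mmol/gDW/h, default bound magnitude 1000 mmol/gDW/h.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `gene_rule`, `subsystem` and a list column `stoich` of named numeric
#'   vectors (metabolite id -> coefficient; negative = consumed).
#' @param objective list with elements `reaction` (a reaction id) and
#'   `direction` (`"max"` or `"min"`), or `NULL`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("id", "name", "compartment")) {
    if (!col %in% names(metabolites)) {
      stop("metabolites must have column '", col, "'", call. = FALSE)
    }
  }
  for (col in c("id", "name", "lb", "ub", "gene_rule", "subsystem", "stoich")) {
    if (!col %in% names(reactions)) {
      stop("reactions must have column '", col, "'", call. = FALSE)
    }
  }
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         objective = objective),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks id uniqueness, that every stoichiometry entry references a declared
#' metabolite, that `lb <= ub` everywhere, and that every gene rule parses as
#' a boolean AND/OR expression.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoich[[i]]
    if (length(st) && (is.null(names(st)) || any(!nzchar(names(st))))) {
      stop("reaction ", rxns$id[i], ": stoichiometry must be a named vector",
           call. = FALSE)
    }
    missing <- setdiff(names(st), mets$id)
    if (length(missing)) {
      stop("reaction ", rxns$id[i], " references undeclared metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (rxns$lb[i] > rxns$ub[i]) {
      stop("reaction ", rxns$id[i], ": lower bound exceeds upper bound",
           call. = FALSE)
    }
    rule <- rxns$gene_rule[i]
    if (!is.na(rule) && nzchar(rule)) {
      parse_gene_rule(rule)  # errors on unparseable rules
    }
  }
  if (!is.null(model$objective)) {
    if (!model$objective$reaction %in% rxns$id) {
      stop("objective reaction '", model$objective$reaction,
           "' is not in the model", call. = FALSE)
    }
    if (!model$objective$direction %in% c("max", "min")) {
      stop("objective direction must be 'max' or 'min'", call. = FALSE)
    }
  }
  invisible(model)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `metabolic_model` or `ec_model`.
#' @return Numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoich[[j]]
    if (length(st)) S[names(st), j] <- st
  }
  S
}

# Build a reaction table row-by-row from lists; internal convenience.
make_reactions <- function(ids, names_, lb, ub, gene_rule, subsystem, stoich) {
  df <- data.frame(id = ids, name = names_, lb = lb, ub = ub,
                   gene_rule = gene_rule, subsystem = subsystem,
                   stringsAsFactors = FALSE)
  df$stoich <- stoich
  df
}

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction id(s): ",
         paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Set flux bounds on a reaction
#'
#' @param model a model.
#' @param id reaction id.
#' @param lb,ub new bounds (mmol/gDW/h); `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

# Fix a flux to a value with a small relative slack band (pure equality is
# brittle in floating point once several stages are chained).
fix_flux <- function(model, id, value, rel_slack = 1e-6, abs_slack = 1e-9) {
  slack <- abs(value) * rel_slack + abs_slack
  set_bounds(model, id, lb = value - slack, ub = value + slack)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<%s> %d metabolites, %d reactions\n",
              class(x)[1], nrow(x$metabolites), nrow(x$reactions)))
  if (!is.null(x$objective)) {
    cat(sprintf("objective: %s %s\n", x$objective$direction,
                x$objective$reaction))
  }
  if (inherits(x, "ec_model")) {
    cat(sprintf("enzymes: %d; pool: %s\n",
                length(grep("^prot_", x$metabolites$id, value = TRUE)) -
                  as.integer("prot_pool" %in% x$metabolites$id),
                if (is.null(x$pool)) "none" else
                  sprintf("%.4g g/gDW", x$pool$bound)))
  }
  invisible(x)
}

#' Enzyme annotation table constructor
#'
#' One row per protein: UniProt-style accession, gene id, molecular weight in
#' kDa (numerically g/mmol), EC numbers, and optional complex membership with
#' subunit stoichiometry.
#'
#' @param protein_id,gene character vectors.
#' @param mw_kda positive numeric, molecular weight (kDa = g/mmol).
#' @param ec_numbers list of character vectors of dotted EC codes (the last
#'   field may be `-`), or a character vector of `;`-separated codes.
#' @param complex_id optional complex membership (NA = monomer).
#' @param stoich subunit stoichiometry within the complex (default 1).
#' @return data.frame of class `enzyme_table`.
#' @export
enzyme_table <- function(protein_id, gene, mw_kda, ec_numbers,
                         complex_id = NA_character_, stoich = 1) {
  if (is.character(ec_numbers)) {
    ec_numbers <- lapply(strsplit(ec_numbers, ";", fixed = TRUE),
                         function(x) trimws(x[nzchar(trimws(x))]))
  }
  n <- length(protein_id)
  df <- data.frame(protein_id = protein_id, gene = gene,
                   mw_kda = rep_len(mw_kda, n),
                   complex_id = rep_len(complex_id, n),
                   stoich = rep_len(stoich, n),
                   stringsAsFactors = FALSE)
  df$ec_numbers <- ec_numbers
  if (any(df$mw_kda <= 0)) {
    stop("molecular weight must be positive for all enzymes", call. = FALSE)
  }
  if (any(df$stoich <= 0)) {
    stop("subunit stoichiometry must be positive", call. = FALSE)
  }
  ok <- vapply(df$ec_numbers, function(e)
    all(grepl("^\\d+\\.\\d+\\.\\d+\\.(\\d+|-)$", e)), logical(1))
  if (!all(ok)) {
    stop("malformed EC number(s) for: ",
         paste(df$protein_id[!ok], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("enzyme_table", "data.frame")
  df
}

#' Proteomics replicate set
#'
#' Builds per-protein mean and standard deviation from replicate abundances,
#' dropping proteins detected in fewer than `min_replicates` replicates.
#' The sample (n-1) standard deviation is used; a single detected replicate
#' has SD 0.
#'
#' @param abundances numeric matrix or data.frame (proteins x replicates,
#'   rownames or a `protein_id` column give ids); NA = not detected. Units
#'   mmol/gDW.
#' @param total_protein total cellular protein content, g/gDW.
#' @param min_replicates minimum number of replicates a protein must be
#'   detected in to be retained (default 2).
#' @return Object of class `proteomics_set` with element `data`
#'   (protein_id, n_detected, mean, sd), `ptot`, `n_replicates`.
#' @export
proteomics_set <- function(abundances, total_protein, min_replicates = 2) {
  if (is.data.frame(abundances)) {
    if ("protein_id" %in% names(abundances)) {
      ids <- abundances$protein_id
      abundances <- as.matrix(abundances[setdiff(names(abundances),
                                                 "protein_id")])
      rownames(abundances) <- ids
    } else {
      abundances <- as.matrix(abundances)
    }
  }
  if (is.null(rownames(abundances))) {
    stop("abundance matrix must carry protein ids", call. = FALSE)
  }
  if (any(abundances < 0, na.rm = TRUE)) {
    stop("negative abundance found; abundances are mmol/gDW and must be >= 0",
         call. = FALSE)
  }
  if (total_protein <= 0) stop("total_protein must be > 0", call. = FALSE)
  n_det <- rowSums(!is.na(abundances))
  keep <- n_det >= min_replicates
  kept <- abundances[keep, , drop = FALSE]
  mu <- apply(kept, 1, mean, na.rm = TRUE)
  sdv <- apply(kept, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x)
  })
  structure(
    list(data = data.frame(protein_id = rownames(kept),
                           n_detected = n_det[keep],
                           mean = unname(mu), sd = unname(sdv),
                           stringsAsFactors = FALSE, row.names = NULL),
         ptot = total_protein,
         n_replicates = ncol(abundances),
         min_replicates = min_replicates),
    class = "proteomics_set"
  )
}
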