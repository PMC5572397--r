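# Readers and writers: repo tabular dialect (TSV), SBML Level 3 + FBC, and
# the enzyme / kinetics / proteomics tables.

DEFAULT_BOUND <- 1000

#' Read a metabolic model
#'
#' Dispatches on file extension: `.xml`/`.sbml` are parsed as SBML Level 3
#' with the FBC package (bounds, objective, gene products); anything else is
#' read as the tabular TSV dialect with columns `rxn_id`, `equation` (arrow
#' `-->` or `<=>`, blank side = exchange), and optional `name`, `lb`, `ub`,
#' `gene_rule`, `subsystem`, `objective`. Missing bounds default to
#' \eqn{[-1000, 1000]} mmol/gDW/h for reversible arrows and \eqn{[0, 1000]}
#' otherwise.
#'
#' @param path file path.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    read_model_sbml(path)
  } else {
    read_model_tabular(path)
  }
}

#' Write a metabolic model
#'
#' The inverse of [read_model()]: `.xml`/`.sbml` paths produce SBML Level 3 +
#' FBC, other paths the tabular dialect. Numeric output carries at least nine
#' significant digits so that a write/read round trip reproduces
#' stoichiometry and bounds to 1e-12.
#'
#' @param model a `metabolic_model` or `ec_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    write_model_sbml(model, path)
  } else {
    write_model_tabular(model, path)
  }
  invisible(path)
}

# ---- tabular dialect ------------------------------------------------------

parse_equation <- function(eq, rxn_id) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("-->", eq, fixed = TRUE)) "-->"
           else stop("reaction ", rxn_id, ": equation lacks an arrow (--> or <=>)",
                     call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (t in terms) {
      t <- trimws(t)
      if (!nzchar(t)) next
      parts <- strsplit(t, "\\s+")[[1]]
      if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) {
          stop("reaction ", rxn_id, ": bad term '", t, "'", call. = FALSE)
        }
        met <- parts[2]
      } else if (length(parts) == 1) {
        coef <- 1
        met <- parts[1]
      } else {
        stop("reaction ", rxn_id, ": bad term '", t, "'", call. = FALSE)
      }
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) + rhs[m]
  list(stoich = st[st != 0], reversible = arrow == "<=>")
}

read_model_tabular <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("rxn_id", "equation") %in% names(df))) {
    stop("tabular model needs columns rxn_id and equation", call. = FALSE)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  get <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  lb_raw <- num_or_na(get("lb", NA))
  ub_raw <- num_or_na(get("ub", NA))
  stoich <- vector("list", nrow(df))
  lb <- ub <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    pe <- parse_equation(df$equation[i], df$rxn_id[i])
    stoich[[i]] <- pe$stoich
    lb[i] <- if (is.na(lb_raw[i])) (if (pe$reversible) -DEFAULT_BOUND else 0) else lb_raw[i]
    ub[i] <- if (is.na(ub_raw[i])) DEFAULT_BOUND else ub_raw[i]
  }
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  if (is.null(met_ids)) met_ids <- character(0)
  comp <- sub("^.*\\[(.+)\\]$", "\\1", met_ids)
  comp[comp == met_ids] <- "c"
  met_name <- sub("\\[.+\\]$", "", met_ids)
  objective <- NULL
  if ("objective" %in% names(df)) {
    oi <- which(nzchar(trimws(df$objective)) & !is.na(df$objective))
    if (length(oi) > 1) stop("multiple objective rows in tabular model",
                             call. = FALSE)
    if (length(oi) == 1) {
      objective <- list(reaction = df$rxn_id[oi],
                        direction = tolower(trimws(df$objective[oi])))
    }
  }
  metabolic_model(
    metabolites = data.frame(id = met_ids, name = met_name,
                             compartment = comp, stringsAsFactors = FALSE),
    reactions = make_reactions(df$rxn_id, get("name", ""), lb, ub,
                               get("gene_rule", ""), get("subsystem", ""),
                               stoich),
    objective = objective
  )
}

format_num <- function(x) formatC(x, digits = 12, format = "g")

write_model_tabular <- function(model, path) {
  eqs <- vapply(seq_len(nrow(model$reactions)), function(i) {
    st <- model$reactions$stoich[[i]]
    side <- function(sel, sgn) {
      ms <- names(st)[sel]
      if (!length(ms)) return("")
      paste(vapply(ms, function(m) {
        c0 <- abs(st[[m]])
        if (c0 == 1) m else paste(format_num(c0), m)
      }, character(1)), collapse = " + ")
    }
    arrow <- if (model$reactions$lb[i] < 0) "<=>" else "-->"
    paste(side(st < 0), arrow, side(st > 0))
  }, character(1))
  obj <- rep("", nrow(model$reactions))
  if (!is.null(model$objective)) {
    obj[model$reactions$id == model$objective$reaction] <-
      model$objective$direction
  }
  out <- data.frame(rxn_id = model$reactions$id, name = model$reactions$name,
                    equation = eqs,
                    lb = format_num(model$reactions$lb),
                    ub = format_num(model$reactions$ub),
                    gene_rule = model$reactions$gene_rule,
                    subsystem = model$reactions$subsystem,
                    objective = obj, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- SBML Level 3 + FBC ---------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape_id <- function(x) {
  # SBML SIds cannot start with a digit and allow only [A-Za-z0-9_]
  gsub("[^A-Za-z0-9_]", "_", x)
}

rule_ast_to_fbc <- function(node, parent) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_escape_id(node)))
    return(invisible())
  }
  child <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
  for (a in node$args) rule_ast_to_fbc(a, child)
  invisible()
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")
  comps <- unique(model$metabolites$compartment)
  cl <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cid in comps) {
    xml2::xml_add_child(cl, "compartment", id = sbml_escape_id(cid),
                        constant = "true")
  }
  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(
      sl, "species",
      id = paste0("M_", sbml_escape_id(model$metabolites$id[i])),
      name = model$metabolites$name[i],
      compartment = sbml_escape_id(model$metabolites$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
  }
  # one shared parameter per distinct bound value
  bound_vals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bound_ids <- paste0("bnd_", seq_along(bound_vals))
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(bound_vals)) {
    xml2::xml_add_child(pl, "parameter", id = bound_ids[i],
                        value = format_num(bound_vals[i]),
                        constant = "true")
  }
  bid <- function(v) bound_ids[match(v, bound_vals)]
  genes <- sort(unique(unlist(lapply(model$reactions$gene_rule, function(r) {
    if (is.na(r) || !nzchar(r)) character(0)
    else unlist(gene_rule_dnf(r))
  }))))
  if (length(genes)) {
    gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_escape_id(g)),
                          "fbc:label" = g)
    }
  }
  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rx <- xml2::xml_add_child(
      rl, "reaction",
      id = paste0("R_", sbml_escape_id(model$reactions$id[i])),
      name = model$reactions$name[i],
      reversible = if (model$reactions$lb[i] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid(model$reactions$lb[i]),
      "fbc:upperFluxBound" = bid(model$reactions$ub[i])
    )
    st <- model$reactions$stoich[[i]]
    add_side <- function(tag, sel) {
      if (!any(sel)) return(invisible())
      side <- xml2::xml_add_child(rx, tag)
      for (m in names(st)[sel]) {
        xml2::xml_add_child(side, "speciesReference",
                            species = paste0("M_", sbml_escape_id(m)),
                            stoichiometry = format_num(abs(st[[m]])),
                            constant = "true")
      }
    }
    add_side("listOfReactants", st < 0)
    add_side("listOfProducts", st > 0)
    rule <- model$reactions$gene_rule[i]
    if (!is.na(rule) && nzchar(rule)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      rule_ast_to_fbc(parse_gene_rule(rule), gpa)
    }
  }
  if (!is.null(model$objective)) {
    ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    on <- xml2::xml_add_child(
      ol, "fbc:objective", "fbc:id" = "obj",
      "fbc:type" = if (model$objective$direction == "max") "maximize"
                   else "minimize"
    )
    fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(
      fl, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_escape_id(model$objective$reaction)),
      "fbc:coefficient" = "1"
    )
  }
  xml2::write_xml(doc, path)
}

strip_sid_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

local_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

fbc_to_rule <- function(node) {
  nm <- xml2::xml_name(node)  # name without prefix
  if (nm == "geneProductRef") {
    return(strip_sid_prefix(local_attr(node, "geneProduct"), "G_"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_rule, character(1))
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1) return(parts)  # geneProductAssociation wrapper
  stop("unsupported gene association element: ", nm, call. = FALSE)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  find_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  species <- find_all(doc, "species")
  if (!length(species)) stop("SBML file has no species elements", call. = FALSE)
  met_ids <- strip_sid_prefix(vapply(species, function(s)
    local_attr(s, "id"), character(1)), "M_")
  mets <- data.frame(
    id = met_ids,
    name = vapply(species, function(s) {
      n <- local_attr(s, "name"); if (is.na(n)) "" else n
    }, character(1)),
    compartment = vapply(species, function(s) {
      ci <- local_attr(s, "compartment"); if (is.na(ci)) "c" else ci
    }, character(1)),
    stringsAsFactors = FALSE
  )
  params <- find_all(doc, "parameter")
  pvals <- stats::setNames(
    vapply(params, function(p) as.numeric(local_attr(p, "value")), numeric(1)),
    vapply(params, function(p) local_attr(p, "id"), character(1))
  )
  rx_nodes <- find_all(doc, "reaction")
  n <- length(rx_nodes)
  ids <- names_ <- rules <- character(n)
  lb <- ub <- numeric(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    rx <- rx_nodes[[i]]
    ids[i] <- strip_sid_prefix(local_attr(rx, "id"), "R_")
    nm <- local_attr(rx, "name")
    names_[i] <- if (is.na(nm)) "" else nm
    reversible <- identical(local_attr(rx, "reversible"), "true")
    lb_ref <- local_attr(rx, "lowerFluxBound")
    ub_ref <- local_attr(rx, "upperFluxBound")
    lb[i] <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
             else if (reversible) -DEFAULT_BOUND else 0
    ub[i] <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
             else DEFAULT_BOUND
    st <- numeric(0)
    for (side in list(c("listOfReactants", -1), c("listOfProducts", +1))) {
      refs <- xml2::xml_find_all(
        rx, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                    side[1]))
      for (r in refs) {
        m <- strip_sid_prefix(local_attr(r, "species"), "M_")
        coef <- local_attr(r, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        st[m] <- (if (m %in% names(st)) st[m] else 0) + as.numeric(side[2]) * coef
      }
    }
    stoich[[i]] <- st[st != 0]
    gpa <- xml2::xml_find_first(
      rx, "./*[local-name()='geneProductAssociation']")
    rules[i] <- if (inherits(gpa, "xml_missing")) "" else fbc_to_rule(gpa)
  }
  objective <- NULL
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    on <- xml2::xml_find_first(doc, ".//*[local-name()='objective']")
    objective <- list(
      reaction = strip_sid_prefix(local_attr(fo, "reaction"), "R_"),
      direction = if (identical(local_attr(on, "type"), "minimize")) "min"
                  else "max"
    )
  }
  metabolic_model(metabolites = mets,
                  reactions = make_reactions(ids, names_, lb, ub, rules,
                                             "", stoich),
                  objective = objective)
}

# ---- annotation tables ----------------------------------------------------

#' Read an enzyme annotation table
#'
#' TSV with columns `protein_id`, `gene`, `mw_kDa`, `ec_numbers`
#' (`;`-separated), and optional `complex_id`, `stoichiometry` (default 1).
#'
#' @param path TSV path.
#' @return An `enzyme_table`.
#' @export
read_enzyme_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("protein_id", "gene", "mw_kda", "ec_numbers")) {
    if (!col %in% names(df)) {
      stop("enzyme table needs column '", col, "'", call. = FALSE)
    }
  }
  enzyme_table(
    protein_id = as.character(df$protein_id),
    gene = as.character(df$gene),
    mw_kda = as.numeric(df$mw_kda),
    ec_numbers = as.character(df$ec_numbers),
    complex_id = if ("complex_id" %in% names(df)) {
      x <- as.character(df$complex_id); x[!nzchar(x)] <- NA; x
    } else NA_character_,
    stoich = if ("stoichiometry" %in% names(df)) {
      s <- as.numeric(df$stoichiometry); s[is.na(s)] <- 1; s
    } else 1
  )
}

#' Read a local kinetics table
#'
#' TSV with columns `ec`, `substrate`, `organism`, `kcat_per_s`; a local
#' stand-in for a turnover-number database query.
#'
#' @param path TSV path.
#' @return data.frame of kinetic records; errors on non-positive kcat.
#' @export
read_kinetics_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("ec", "substrate", "organism", "kcat_per_s")) {
    if (!col %in% names(df)) {
      stop("kinetics table needs column '", col, "'", call. = FALSE)
    }
  }
  df$kcat_per_s <- as.numeric(df$kcat_per_s)
  if (any(!is.finite(df$kcat_per_s)) || any(df$kcat_per_s <= 0)) {
    stop("kcat_per_s must be finite and > 0 in all records", call. = FALSE)
  }
  df
}

#' Read absolute proteomics replicates
#'
#' TSV with columns `protein_id`, `rep1` .. `repK` in mmol/gDW; blank cells
#' mean "not detected". Proteins detected in fewer than `min_replicates`
#' replicates are dropped; mean and sample SD are computed over the detected
#' replicates.
#'
#' @param path TSV path.
#' @param total_protein total protein content, g/gDW.
#' @param min_replicates detection threshold (default 2).
#' @return A `proteomics_set`.
#' @export
read_proteomics <- function(path, total_protein, min_replicates = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- tolower(names(df)[1])
  if (names(df)[1] != "protein_id") {
    stop("proteomics table must start with a protein_id column", call. = FALSE)
  }
  reps <- as.matrix(df[, -1, drop = FALSE])
  mode(reps) <- "numeric"
  rownames(reps) <- df$protein_id
  proteomics_set(reps, total_protein = total_protein,
                 min_replicates = min_replicates)
}
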