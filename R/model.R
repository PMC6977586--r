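#' Construct a metabolite record
#'
#' A metabolite is a chemical entity shared across compartments. Cross
#' references are held in a named list keyed by namespace (`hmdb`, `pubchem`,
#' `metanetx`, `chebi`, `kegg`); duplicate identifiers within a namespace are
#' dropped.
#'
#' @param identifier Non-empty character scalar, unique within a model.
#' @param name Common name.
#' @param formula Chemical formula in Hill notation; may be `""`.
#' @param charge Integer formal charge.
#' @param references Named list of character vectors of external identifiers.
#' @return A `metnets_metabolite` list.
#' @export
metabolite <- function(identifier, name = identifier, formula = "",
                       charge = 0L, references = list()) {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            nzchar(identifier))
  structure(
    list(identifier = identifier, name = as.character(name),
         formula = as.character(formula), charge = as.integer(charge),
         references = normalize_references(references)),
    class = "metnets_metabolite")
}

normalize_references <- function(references) {
  if (length(references) == 0L) return(list())
  stopifnot(!is.null(names(references)), all(nzchar(names(references))))
  lapply(references, function(x) unique(as.character(x)))
}

#' Construct a reaction participant
#'
#' @param metabolite Metabolite identifier.
#' @param role `"reactant"` or `"product"`.
#' @param compartment Compartment identifier in which the participant occurs.
#' @param stoichiometry Positive number.
#' @return A one-row participant data frame.
#' @export
participant <- function(metabolite, role, compartment, stoichiometry = 1) {
  role <- match.arg(role, c("reactant", "product"))
  stopifnot(is.numeric(stoichiometry), stoichiometry > 0)
  data.frame(metabolite = as.character(metabolite), role = role,
             compartment = as.character(compartment),
             stoichiometry = as.numeric(stoichiometry),
             stringsAsFactors = FALSE)
}

#' Construct a reaction record
#'
#' @param identifier Unique reaction identifier.
#' @param participants Data frame with columns `metabolite`, `role`,
#'   `compartment`, `stoichiometry` (rbind of [participant()] rows); must
#'   contain at least one reactant and one product.
#' @param name Common name.
#' @param reversible Logical; reversible reactions link every participant in
#'   both directions when a network is built.
#' @param processes Character vector of process identifiers.
#' @param genes Character vector of gene references.
#' @param references Named list of namespace reference vectors.
#' @param behavior One of `"conversion"`, `"transport"`, `"both"`, `"unset"`;
#'   normally assigned by [classify_reaction_behavior()].
#' @return A `metnets_reaction` list.
#' @export
reaction <- function(identifier, participants, name = identifier,
                     reversible = FALSE, processes = character(),
                     genes = character(), references = list(),
                     behavior = "unset") {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            nzchar(identifier), is.data.frame(participants))
  required <- c("metabolite", "role", "compartment", "stoichiometry")
  stopifnot(all(required %in% names(participants)))
  if (!any(participants$role == "reactant") ||
      !any(participants$role == "product")) {
    stop("reaction '", identifier,
         "' needs at least one reactant and one product", call. = FALSE)
  }
  behavior <- match.arg(behavior, c("conversion", "transport", "both", "unset"))
  structure(
    list(identifier = identifier, name = as.character(name),
         reversible = isTRUE(reversible),
         participants = participants[, required],
         processes = unique(as.character(processes)),
         genes = unique(as.character(genes)),
         references = normalize_references(references),
         behavior = behavior),
    class = "metnets_reaction")
}

#' Construct a compartment or process record
#'
#' @param identifier Unique identifier within its kind.
#' @param name Common name.
#' @return A named list.
#' @export
compartment <- function(identifier, name = identifier) {
  stopifnot(nzchar(identifier))
  list(identifier = as.character(identifier), name = as.character(name))
}

#' @rdname compartment
#' @export
process <- function(identifier, name = identifier) {
  compartment(identifier, name)
}

#' Assemble a metabolic model
#'
#' The model is the curated substrate from which all network definitions are
#' derived: keyed collections of metabolites, reactions, compartments and
#' processes, with optional designation of the boundary and extracellular
#' compartments used when filtering simulation artifacts.
#'
#' @param metabolites List of [metabolite()] records.
#' @param reactions List of [reaction()] records.
#' @param compartments,processes Lists of [compartment()]/[process()] records.
#' @param boundary_compartment,extracellular_compartment Optional compartment
#'   identifiers.
#' @return A validated `metabolic_model`.
#' @export
metabolic_model <- function(metabolites = list(), reactions = list(),
                            compartments = list(), processes = list(),
                            boundary_compartment = NULL,
                            extracellular_compartment = NULL) {
  keyed <- function(x) stats::setNames(x, vapply(x, `[[`, "", "identifier"))
  model <- structure(
    list(metabolites = keyed(metabolites), reactions = keyed(reactions),
         compartments = keyed(compartments), processes = keyed(processes),
         boundary_compartment = boundary_compartment,
         extracellular_compartment = extracellular_compartment),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model integrity
#'
#' Checks identifier uniqueness and that every participant, process and
#' compartment referenced by a reaction resolves within the model.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; stops with a message listing offenders
#'   otherwise.
#' @export
validate_model <- function(model) {
  for (kind in c("metabolites", "reactions", "compartments", "processes")) {
    ids <- names(model[[kind]])
    if (anyDuplicated(ids)) {
      stop("duplicate ", kind, " identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
  }
  offenders <- character()
  for (rxn in model$reactions) {
    p <- rxn$participants
    bad_m <- setdiff(p$metabolite, names(model$metabolites))
    bad_c <- setdiff(p$compartment, names(model$compartments))
    if (length(bad_m)) {
      offenders <- c(offenders, paste0(rxn$identifier,
                                       ": unknown metabolite ", bad_m))
    }
    if (length(bad_c)) {
      offenders <- c(offenders, paste0(rxn$identifier,
                                       ": unknown compartment ", bad_c))
    }
    if (any(p$stoichiometry <= 0)) {
      offenders <- c(offenders, paste0(rxn$identifier,
                                       ": non-positive stoichiometry"))
    }
  }
  if (length(offenders)) {
    stop("dangling references in model:\n  ",
         paste(offenders, collapse = "\n  "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", length(x$compartments),
      "compartments,", length(x$processes), "processes\n")
  invisible(x)
}

# Aggregate (metabolite -> total stoichiometry) for one role, as a canonical
# named vector usable for multiset comparison.
role_multiset <- function(participants, role) {
  p <- participants[participants$role == role, , drop = FALSE]
  if (nrow(p) == 0L) return(stats::setNames(numeric(), character()))
  agg <- tapply(p$stoichiometry, p$metabolite, sum)
  agg[order(names(agg))]
}

#' Classify a reaction as conversion, transport, or both
#'
#' A reaction is a *transport* when some metabolite appears among its
#' reactants in one compartment and among its products in a different
#' compartment without net chemical change for that metabolite (identity
#' compared by consensus identifier). It is a *conversion* when the multiset
#' of reactant metabolite identities differs from the product multiset, and
#' *both* when both conditions hold. A degenerate reaction meeting neither
#' condition is reported as `"conversion"`.
#'
#' @param rxn A reaction record.
#' @param model The containing model (unused beyond validation; kept so
#'   classification can later consult model-level chemistry).
#' @return `"conversion"`, `"transport"`, or `"both"`.
#' @export
classify_reaction_behavior <- function(rxn, model = NULL) {
  p <- rxn$participants
  reactants <- role_multiset(p, "reactant")
  products <- role_multiset(p, "product")
  conversion <- !identical(reactants, products)
  transport <- FALSE
  shared <- intersect(names(reactants), names(products))
  for (m in shared) {
    rc <- unique(p$compartment[p$role == "reactant" & p$metabolite == m])
    pc <- unique(p$compartment[p$role == "product" & p$metabolite == m])
    if (length(setdiff(pc, rc)) > 0L || length(setdiff(rc, pc)) > 0L) {
      transport <- TRUE
      break
    }
  }
  if (transport && conversion) "both" else if (transport) "transport"
  else "conversion"
}

#' Classify every reaction in a model
#'
#' @param model A `metabolic_model`.
#' @return The model with each reaction's `behavior` field set.
#' @export
classify_model_behaviors <- function(model) {
  model$reactions <- lapply(model$reactions, function(rxn) {
    rxn$behavior <- classify_reaction_behavior(rxn, model)
    rxn
  })
  model
}

#' Filter settings for simulation-artifact removal
#'
#' @param boundary_compartment,extracellular_compartment Compartment
#'   identifiers; reactions with any participant in the boundary compartment
#'   are treated as boundary exchanges.
#' @param name_patterns Character vector of case-insensitive regular
#'   expressions matched against reaction identifiers and names; defaults
#'   target biomass accumulation and protein assembly/degradation reactions.
#' @return A `filter_config` list.
#' @export
filter_config <- function(boundary_compartment = NULL,
                          extracellular_compartment = NULL,
                          name_patterns = c("biomass",
                                            "protein (assembly|degradation)")) {
  structure(list(boundary_compartment = boundary_compartment,
                 extracellular_compartment = extracellular_compartment,
                 name_patterns = as.character(name_patterns)),
            class = "filter_config")
}

#' Remove reactions that only serve flux simulations
#'
#' Drops boundary-exchange reactions (any participant in the configured
#' boundary compartment) and reactions whose identifier or name matches a
#' configured pattern (biomass accumulation, protein turnover), then removes
#' metabolites that no longer participate in any reaction. The input model is
#' not modified. Idempotent.
#'
#' @param model A `metabolic_model`.
#' @param config A [filter_config()]; an empty configuration is a no-op.
#' @return The filtered model.
#' @export
filter_simulation_artifacts <- function(model, config = filter_config()) {
  drop <- vapply(model$reactions, function(rxn) {
    if (!is.null(config$boundary_compartment) &&
        config$boundary_compartment %in% rxn$participants$compartment) {
      return(TRUE)
    }
    if (length(config$name_patterns)) {
      target <- c(rxn$identifier, rxn$name)
      if (any(vapply(config$name_patterns, function(pat) {
        any(grepl(pat, target, ignore.case = TRUE))
      }, logical(1L)))) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1L))
  if (length(config$name_patterns) && length(model$reactions) &&
      !any(drop)) {
    warning("filter patterns matched no reaction", call. = FALSE)
  }
  model$reactions <- model$reactions[!drop]
  used <- unique(unlist(lapply(model$reactions,
                               function(r) r$participants$metabolite)))
  model$metabolites <- model$metabolites[names(model$metabolites) %in% used]
  model
}

#' Assign transport reactions to the processes they serve
#'
#' Transport reactions typically lack process annotation in source models. A
#' transport (or transport-and-conversion) reaction joins every process whose
#' member reactions span at least two compartments and which shares at least
#' one metabolite and one compartment with the transport reaction.
#'
#' @param model A model whose reaction behaviors have been classified (see
#'   [classify_model_behaviors()]).
#' @return The model with augmented process membership on transport reactions.
#' @export
assign_transport_processes <- function(model) {
  proc_members <- list()
  for (rxn in model$reactions) {
    for (pr in rxn$processes) {
      proc_members[[pr]] <- c(proc_members[[pr]], rxn$identifier)
    }
  }
  proc_info <- lapply(proc_members, function(rxn_ids) {
    parts <- do.call(rbind, lapply(model$reactions[rxn_ids],
                                   function(r) r$participants))
    list(compartments = unique(parts$compartment),
         metabolites = unique(parts$metabolite))
  })
  multi <- names(proc_info)[vapply(proc_info, function(i)
    length(i$compartments) >= 2L, logical(1L))]
  model$reactions <- lapply(model$reactions, function(rxn) {
    if (!rxn$behavior %in% c("transport", "both")) return(rxn)
    p <- rxn$participants
    join <- multi[vapply(multi, function(pr) {
      info <- proc_info[[pr]]
      length(intersect(info$metabolites, p$metabolite)) >= 1L &&
        length(intersect(info$compartments, p$compartment)) >= 1L
    }, logical(1L))]
    rxn$processes <- sort(unique(c(rxn$processes, join)))
    rxn
  })
  model
}

#' Summarize model curation coverage
#'
#' Reports entity counts and the reference coverage the curation pipeline
#' tracks: metabolites carrying an HMDB or PubChem reference and reactions
#' carrying a gene (or enzyme) reference, as percentages of the respective
#' totals to two decimal places.
#'
#' @param model A `metabolic_model`.
#' @return A `curation_summary` list with `counts` and `coverage`; an `empty`
#'   flag is set when the model has no entities of a class.
#' @export
summarize_curation <- function(model) {
  pct <- coverage_percent
  n_met <- length(model$metabolites)
  n_rxn <- length(model$reactions)
  met_cov <- sum(vapply(model$metabolites, function(m) {
    length(m$references$hmdb) > 0L || length(m$references$pubchem) > 0L
  }, logical(1L)))
  rxn_cov <- sum(vapply(model$reactions, function(r) {
    length(r$genes) > 0L || length(r$references$gene) > 0L ||
      length(r$references$enzyme) > 0L
  }, logical(1L)))
  structure(
    list(counts = c(metabolites = n_met, reactions = n_rxn,
                    compartments = length(model$compartments),
                    processes = length(model$processes)),
         coverage = data.frame(
           entity = c("metabolites", "reactions"),
           count = c(n_met, n_rxn),
           reference_class = c("hmdb_or_pubchem", "gene_or_enzyme"),
           covered = c(met_cov, rxn_cov),
           percent = c(pct(met_cov, n_met), pct(rxn_cov, n_rxn)),
           stringsAsFactors = FALSE),
         empty = n_met == 0L || n_rxn == 0L),
    class = "curation_summary")
}

#' Reference coverage percentage
#'
#' `100 * covered / total`, reported to two decimal places; 0 for an empty
#' collection. The rounding rule used throughout curation summaries.
#'
#' @param covered,total Non-negative counts.
#' @return Percentage in `[0, 100]`.
#' @export
coverage_percent <- function(covered, total) {
  if (total == 0L) 0 else round(100 * covered / total, 2L)
}

#' Write a curation summary as TSV
#'
#' Columns: `entity`, `count`, `reference_class`, `covered`, `percent`.
#'
#' @param summary A `curation_summary`.
#' @param path Output path.
#' @export
write_curation_summary <- function(summary, path) {
  utils::write.table(summary$coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
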