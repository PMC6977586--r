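# Native model serialization (documented JSON dialect) and an SBML L2V4
# subset importer. The native schema mirrors the in-memory model one-to-one:
# {
#   "format": "metnets-model", "version": 1,
#   "compartments": [{"identifier", "name"}], "processes": [...],
#   "metabolites": [{"identifier","name","formula","charge",
#                    "references": {"hmdb": [...], ...}}],
#   "reactions": [{"identifier","name","reversible",
#                  "participants": [{"metabolite","role","compartment",
#                                    "stoichiometry"}],
#                  "processes": [...], "genes": [...], "references": {...},
#                  "behavior"}],
#   "boundary_compartment": null, "extracellular_compartment": null
# }

#' Read a metabolic model from file
#'
#' @param path Path to a model file.
#' @param format `"native"` for the package's JSON dialect, `"sbml_subset"`
#'   for a strict subset of SBML Level 2 Version 4 (compartments, species,
#'   reactions, species-reference stoichiometry, reversibility; kinetic laws
#'   and non-identifier annotations are ignored with a message).
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("native", "sbml_subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(format,
         native = read_model_native(path),
         sbml_subset = read_model_sbml(path))
}

read_model_native <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "metnets-model")) {
    stop("file '", path, "' lacks the metnets-model format marker",
         call. = FALSE)
  }
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(m$identifier, name = m$name, formula = m$formula %||% "",
               charge = m$charge %||% 0L,
               references = lapply(m$references %||% list(),
                                   function(x) unlist(x, use.names = FALSE)))
  })
  rxns <- lapply(doc$reactions, function(r) {
    parts <- do.call(rbind, lapply(r$participants, function(p) {
      participant(p$metabolite, p$role, p$compartment, p$stoichiometry)
    }))
    reaction(r$identifier, parts, name = r$name,
             reversible = isTRUE(r$reversible),
             processes = unlist(r$processes, use.names = FALSE),
             genes = unlist(r$genes, use.names = FALSE),
             references = lapply(r$references %||% list(),
                                 function(x) unlist(x, use.names = FALSE)),
             behavior = r$behavior %||% "unset")
  })
  comps <- lapply(doc$compartments, function(x)
    compartment(x$identifier, x$name))
  procs <- lapply(doc$processes, function(x) process(x$identifier, x$name))
  metabolic_model(mets, rxns, comps, procs,
                  boundary_compartment = doc$boundary_compartment,
                  extracellular_compartment = doc$extracellular_compartment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to the native JSON format
#'
#' `read_model(write_model(model))` is the identity on the data model, and
#' re-serializing a freshly read model is byte-identical.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  ser_refs <- function(refs) {
    if (length(refs) == 0L) return(stats::setNames(list(), character()))
    lapply(refs, as.list)
  }
  doc <- list(
    format = "metnets-model", version = 1L,
    compartments = unname(lapply(model$compartments, function(x)
      list(identifier = x$identifier, name = x$name))),
    processes = unname(lapply(model$processes, function(x)
      list(identifier = x$identifier, name = x$name))),
    metabolites = unname(lapply(model$metabolites, function(m)
      list(identifier = m$identifier, name = m$name, formula = m$formula,
           charge = m$charge, references = ser_refs(m$references)))),
    reactions = unname(lapply(model$reactions, function(r)
      list(identifier = r$identifier, name = r$name,
           reversible = r$reversible,
           participants = unname(lapply(seq_len(nrow(r$participants)),
             function(i) {
               p <- r$participants[i, ]
               list(metabolite = p$metabolite, role = p$role,
                    compartment = p$compartment,
                    stoichiometry = p$stoichiometry)
             })),
           processes = as.list(r$processes), genes = as.list(r$genes),
           references = ser_refs(r$references), behavior = r$behavior))),
    boundary_compartment = model$boundary_compartment,
    extracellular_compartment = model$extracellular_compartment)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

sbml_ns <- c(sbml = "http://www.sbml.org/sbml/level2/version4")

sbml_find <- function(node, xpath) {
  hits <- xml2::xml_find_all(node, paste0("sbml:", xpath), ns = sbml_ns)
  if (length(hits) == 0L) hits <- xml2::xml_find_all(node, xpath)
  hits
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  model_node <- sbml_find(doc, "model")
  if (length(model_node) == 0L) {
    stop("SBML file '", path, "' has no <model> element", call. = FALSE)
  }
  model_node <- model_node[[1L]]
  ignored <- intersect(
    c("listOfUnitDefinitions", "listOfRules", "listOfEvents",
      "listOfInitialAssignments", "listOfConstraints"),
    xml2::xml_name(xml2::xml_children(model_node)))
  if (length(ignored)) {
    message("SBML import ignores: ", paste(ignored, collapse = ", "))
  }

  comp_nodes <- sbml_find(model_node, "listOfCompartments/sbml:compartment")
  if (length(comp_nodes) == 0L) {
    comp_nodes <- sbml_find(model_node, "listOfCompartments/compartment")
  }
  comps <- lapply(comp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    compartment(id, xml2::xml_attr(n, "name") %|NA|% id)
  })

  sp_nodes <- sbml_find(model_node, "listOfSpecies/sbml:species")
  if (length(sp_nodes) == 0L) {
    sp_nodes <- sbml_find(model_node, "listOfSpecies/species")
  }
  species_comp <- character()
  mets <- lapply(sp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    species_comp[[id]] <<- xml2::xml_attr(n, "compartment")
    metabolite(id, name = xml2::xml_attr(n, "name") %|NA|% id)
  })

  rxn_nodes <- sbml_find(model_node, "listOfReactions/sbml:reaction")
  if (length(rxn_nodes) == 0L) {
    rxn_nodes <- sbml_find(model_node, "listOfReactions/reaction")
  }
  refs_of <- function(rnode, list_name, role) {
    refs <- sbml_find(rnode, paste0(list_name, "/sbml:speciesReference"))
    if (length(refs) == 0L) {
      refs <- sbml_find(rnode, paste0(list_name, "/speciesReference"))
    }
    do.call(rbind, lapply(refs, function(sr) {
      sp <- xml2::xml_attr(sr, "species")
      st <- xml2::xml_attr(sr, "stoichiometry")
      st <- if (is.na(st)) 1 else as.numeric(st)
      cmp <- species_comp[[sp]]
      if (is.null(cmp) || is.na(cmp)) {
        stop("SBML reaction '", xml2::xml_attr(rnode, "id"),
             "' references unknown species '", sp, "'", call. = FALSE)
      }
      participant(sp, role, cmp, st)
    }))
  }
  rxns <- lapply(rxn_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    rev <- xml2::xml_attr(n, "reversible")
    rev <- if (is.na(rev)) TRUE else identical(rev, "true")  # L2 default
    parts <- rbind(refs_of(n, "listOfReactants", "reactant"),
                   refs_of(n, "listOfProducts", "product"))
    reaction(id, parts, name = xml2::xml_attr(n, "name") %|NA|% id,
             reversible = rev)
  })
  metabolic_model(mets, rxns, comps, list())
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
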