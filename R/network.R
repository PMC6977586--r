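#' Specification of a network definition
#'
#' Captures the three constraints under which a directional bipartite
#' metabolite-reaction network is defined from a model: compartmentalization,
#' filters by compartment and process, and exclusion of specific metabolites
#' (hub lists and/or a degree threshold).
#'
#' @param compartmentalize Logical. `TRUE` keeps one metabolite node per
#'   (metabolite, compartment) pair and retains transport reactions; `FALSE`
#'   consolidates compartmental instances to consensus nodes and excludes
#'   pure transport reactions.
#' @param compartment_filter Optional character vector of compartment
#'   identifiers; a reaction is kept only when every participant compartment
#'   is in the set.
#' @param process_filter Optional character vector of process identifiers; a
#'   reaction is kept when at least one of its processes is in the set.
#' @param excluded_metabolites Character vector of metabolite identifiers to
#'   exclude (typically category-1 hubs plus chosen category-2 hubs).
#' @param degree_threshold Optional integer >= 1; metabolite nodes whose
#'   total link count in the pre-exclusion network exceeds it are excluded.
#' @param keep_largest_component Logical; restrict the final network to its
#'   largest weakly connected component.
#' @param exclude_both_transport Logical; in non-compartmental networks also
#'   exclude reactions that both transport and convert (default keeps them).
#' @return A `network_spec`.
#' @export
network_spec <- function(compartmentalize = TRUE, compartment_filter = NULL,
                         process_filter = NULL,
                         excluded_metabolites = character(),
                         degree_threshold = NULL,
                         keep_largest_component = TRUE,
                         exclude_both_transport = FALSE) {
  if (!is.null(degree_threshold)) {
    stopifnot(is.numeric(degree_threshold), degree_threshold >= 1)
    degree_threshold <- as.integer(degree_threshold)
  }
  structure(list(compartmentalize = isTRUE(compartmentalize),
                 compartment_filter = compartment_filter,
                 process_filter = process_filter,
                 excluded_metabolites = as.character(excluded_metabolites),
                 degree_threshold = degree_threshold,
                 keep_largest_component = isTRUE(keep_largest_component),
                 exclude_both_transport = isTRUE(exclude_both_transport)),
            class = "network_spec")
}

new_network <- function(nodes, links, payload, spec,
                        annotations = NULL) {
  rownames(nodes) <- NULL
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links, payload = payload,
                 spec = spec, annotations = annotations),
            class = "metabolic_network")
}

empty_links <- function() {
  data.frame(from = character(), to = character(), role = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_m <- sum(x$nodes$type == "metabolite")
  n_r <- sum(x$nodes$type == "reaction")
  cat("metabolic_network:", n_m, "metabolite nodes,", n_r,
      "reaction nodes,", nrow(x$links), "links\n")
  invisible(x)
}

assert_bipartite <- function(network) {
  type <- stats::setNames(network$nodes$type, network$nodes$id)
  if (nrow(network$links)) {
    ok <- type[network$links$from] != type[network$links$to]
    if (any(is.na(ok)) || !all(ok)) {
      stop("internal error: network lost bipartiteness", call. = FALSE)
    }
  }
  invisible(network)
}

included_reactions <- function(model, spec) {
  keep <- vapply(model$reactions, function(rxn) {
    if (!is.null(spec$compartment_filter) &&
        !all(rxn$participants$compartment %in% spec$compartment_filter)) {
      return(FALSE)
    }
    if (!is.null(spec$process_filter) &&
        !any(rxn$processes %in% spec$process_filter)) {
      return(FALSE)
    }
    TRUE
  }, logical(1L))
  model$reactions[keep]
}

# Links for one reaction node given participant metabolite-node ids.
# Reversible reactions link every participant in both directions; duplicate
# links (same endpoints and direction) collapse to one.
reaction_links <- function(rxn_id, met_node, role, reversible) {
  from <- ifelse(role == "reactant", met_node, rxn_id)
  to <- ifelse(role == "reactant", rxn_id, met_node)
  tag <- ifelse(role == "reactant", "reactant", "product")
  links <- data.frame(from = from, to = to, role = tag,
                      stringsAsFactors = FALSE)
  if (reversible) {
    links <- rbind(links,
                   data.frame(from = ifelse(role == "reactant", rxn_id,
                                            met_node),
                              to = ifelse(role == "reactant", met_node,
                                          rxn_id),
                              role = ifelse(role == "reactant", "product",
                                            "reactant"),
                              stringsAsFactors = FALSE))
  }
  links[!duplicated(links[, c("from", "to")]), , drop = FALSE]
}

finish_build <- function(nodes, links, payload, spec) {
  if (nrow(nodes) == 0L) {
    stop("network definition excludes every reaction; ",
         "check compartment/process filters", call. = FALSE)
  }
  ord <- order(nodes$id)
  nodes <- nodes[ord, , drop = FALSE]
  links <- links[order(links$from, links$to), , drop = FALSE]
  net <- new_network(nodes, links, payload, spec)
  assert_bipartite(net)
  net
}

#' Build a compartmental bipartite network
#'
#' One metabolite node per (metabolite, compartment) pair occurring in an
#' included reaction, one node per included reaction, and directional links
#' reactant->reaction and reaction->product. Reversible reactions link every
#' participant in both directions. Transport reactions are retained.
#'
#' @param model A `metabolic_model`.
#' @param spec A [network_spec()] with `compartmentalize = TRUE`.
#' @return A `metabolic_network` (exclusions and component selection not yet
#'   applied; see [build_network()] for the full pipeline).
#' @export
build_compartmental <- function(model, spec = network_spec()) {
  stopifnot(spec$compartmentalize)
  rxns <- included_reactions(model, spec)
  nodes <- list()
  links <- list()
  payload <- list()
  for (rxn in rxns) {
    p <- rxn$participants
    met_node <- paste0(p$metabolite, "@", p$compartment)
    for (i in seq_along(met_node)) {
      id <- met_node[[i]]
      if (is.null(payload[[id]])) {
        payload[[id]] <- list(
          type = "metabolite",
          metabolite = model$metabolites[[p$metabolite[[i]]]],
          compartment = p$compartment[[i]],
          sources = id)
        nodes[[id]] <- data.frame(
          id = id, type = "metabolite",
          name = model$metabolites[[p$metabolite[[i]]]]$name,
          stringsAsFactors = FALSE)
      }
    }
    payload[[rxn$identifier]] <- list(type = "reaction", reaction = rxn,
                                      sources = rxn$identifier)
    nodes[[rxn$identifier]] <- data.frame(id = rxn$identifier,
                                          type = "reaction", name = rxn$name,
                                          stringsAsFactors = FALSE)
    links[[rxn$identifier]] <- reaction_links(rxn$identifier, met_node,
                                              p$role, rxn$reversible)
  }
  finish_build(do.call(rbind, unname(nodes)),
               if (length(links)) do.call(rbind, unname(links))
               else empty_links(),
               payload, spec)
}

# Canonical chemistry signature of a reaction with compartments dropped:
# sorted (metabolite, role, stoichiometry) triplets plus reversibility.
reaction_signature <- function(rxn) {
  p <- rxn$participants
  key <- paste(p$metabolite, p$role, format(p$stoichiometry), sep = "|")
  paste(c(sort(key), if (rxn$reversible) "rev" else "irr"), collapse = ";")
}

#' Build a non-compartmental bipartite network
#'
#' Metabolite nodes are compartment-free consensus entities. Pure transport
#' reactions are excluded (they are meaningless without compartments), and
#' chemically redundant reactions -- identical participant multisets after
#' dropping compartments and identical reversibility -- merge into one
#' consensus reaction node whose process, gene and reference annotations are
#' unions of the merged records.
#'
#' @param model A `metabolic_model` whose behaviors have been classified;
#'   unclassified reactions are classified on the fly.
#' @param spec A [network_spec()] with `compartmentalize = FALSE`.
#' @return A `metabolic_network`.
#' @export
build_noncompartmental <- function(model, spec = network_spec(
                                     compartmentalize = FALSE)) {
  stopifnot(!spec$compartmentalize)
  rxns <- included_reactions(model, spec)
  rxns <- Filter(function(rxn) {
    behavior <- if (rxn$behavior == "unset")
      classify_reaction_behavior(rxn, model) else rxn$behavior
    if (behavior == "transport") return(FALSE)
    if (behavior == "both" && spec$exclude_both_transport) return(FALSE)
    TRUE
  }, rxns)

  groups <- split(rxns, vapply(rxns, reaction_signature, ""))
  nodes <- list()
  links <- list()
  payload <- list()
  for (grp in groups) {
    ids <- sort(vapply(grp, `[[`, "", "identifier"))
    lead <- grp[[match(ids[[1L]], vapply(grp, `[[`, "", "identifier"))]]
    consensus <- lead
    consensus$processes <- sort(unique(unlist(lapply(grp, `[[`,
                                                     "processes"))))
    consensus$genes <- sort(unique(unlist(lapply(grp, `[[`, "genes"))))
    ref_ns <- unique(unlist(lapply(grp, function(r) names(r$references))))
    consensus$references <- stats::setNames(lapply(ref_ns, function(ns) {
      sort(unique(unlist(lapply(grp, function(r) r$references[[ns]]))))
    }), ref_ns)
    rid <- ids[[1L]]
    p <- consensus$participants
    # collapse compartmental duplicates of the same (metabolite, role)
    dedup <- !duplicated(p[, c("metabolite", "role")])
    met_ids <- p$metabolite[dedup]
    roles <- p$role[dedup]
    for (m in unique(met_ids)) {
      if (is.null(payload[[m]])) {
        payload[[m]] <- list(type = "metabolite",
                             metabolite = model$metabolites[[m]],
                             compartment = NA_character_,
                             sources = sort(unique(
                               paste0(m, "@",
                                      p$compartment[p$metabolite == m]))))
        nodes[[m]] <- data.frame(id = m, type = "metabolite",
                                 name = model$metabolites[[m]]$name,
                                 stringsAsFactors = FALSE)
      }
    }
    payload[[rid]] <- list(type = "reaction", reaction = consensus,
                           sources = ids)
    nodes[[rid]] <- data.frame(id = rid, type = "reaction",
                               name = consensus$name,
                               stringsAsFactors = FALSE)
    links[[rid]] <- reaction_links(rid, met_ids, roles,
                                   consensus$reversible)
  }
  finish_build(do.call(rbind, unname(nodes)),
               if (length(links)) do.call(rbind, unname(links))
               else empty_links(),
               payload, spec)
}

node_metabolite_id <- function(network, node_id) {
  pl <- network$payload[[node_id]]
  if (is.null(pl) || pl$type != "metabolite") return(NA_character_)
  pl$metabolite$identifier
}

node_degrees <- function(network) {
  tab <- table(c(network$links$from, network$links$to))
  deg <- stats::setNames(rep(0L, nrow(network$nodes)), network$nodes$id)
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Exclude metabolite nodes by list and by degree
#'
#' Removes metabolite nodes named in `spec$excluded_metabolites` (matched by
#' underlying metabolite identifier, so compartmental instances of an
#' excluded metabolite all go), then metabolite nodes whose total link count
#' -- measured in the network before any exclusion -- exceeds
#' `spec$degree_threshold`. Reaction nodes keep their full participant
#' payload; reaction nodes left without links are removed by the subsequent
#' component step.
#'
#' @param network A `metabolic_network`.
#' @param spec A [network_spec()]; defaults to the network's own spec.
#' @return The reduced network.
#' @export
apply_exclusions <- function(network, spec = network$spec) {
  met_nodes <- network$nodes$id[network$nodes$type == "metabolite"]
  met_of <- vapply(met_nodes, function(id) node_metabolite_id(network, id),
                   "")
  unknown <- setdiff(spec$excluded_metabolites, met_of)
  if (length(unknown)) {
    warning("excluded metabolites not in network: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop <- met_nodes[met_of %in% spec$excluded_metabolites]
  if (!is.null(spec$degree_threshold)) {
    deg <- node_degrees(network)[met_nodes]
    drop <- union(drop, met_nodes[deg > spec$degree_threshold])
  }
  if (length(drop) == 0L) return(network)
  keep <- !(network$nodes$id %in% drop)
  nodes <- network$nodes[keep, , drop = FALSE]
  links <- network$links[!(network$links$from %in% drop) &
                           !(network$links$to %in% drop), , drop = FALSE]
  net <- new_network(nodes, links, network$payload[nodes$id], spec,
                     network$annotations)
  assert_bipartite(net)
  net
}

#' Convert a metabolic network to an igraph graph
#'
#' Vertex attributes `name` (node identifier), `type`, `label`; edge
#' attribute `role`. Used internally by queries and metrics and exported for
#' interoperability.
#'
#' @param network A `metabolic_network`.
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(network) {
  vertices <- data.frame(name = network$nodes$id, type = network$nodes$type,
                         label = network$nodes$name,
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$links, directed = TRUE,
                                vertices = vertices)
}

subset_network <- function(network, node_ids, spec = network$spec,
                           provenance = NULL) {
  nodes <- network$nodes[network$nodes$id %in% node_ids, , drop = FALSE]
  links <- network$links[network$links$from %in% node_ids &
                           network$links$to %in% node_ids, , drop = FALSE]
  net <- new_network(nodes, links, network$payload[nodes$id], spec,
                     network$annotations)
  if (!is.null(provenance)) net$provenance <- provenance
  assert_bipartite(net)
  net
}

#' Restrict a network to its largest weakly connected component
#'
#' Ties between equally sized components are broken by the lexicographically
#' smallest member identifier. An empty network is returned unchanged.
#'
#' @param network A `metabolic_network`.
#' @return The induced subnetwork.
#' @export
largest_component <- function(network) {
  if (nrow(network$nodes) == 0L) return(network)
  g <- as_igraph(network)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  subset_network(network, keep)
}

#' Define a network from a model (full pipeline)
#'
#' Builds the compartmental or non-compartmental bipartite network, applies
#' metabolite exclusions, and (when requested by the spec) restricts to the
#' largest weakly connected component.
#'
#' @param model A `metabolic_model`.
#' @param spec A [network_spec()].
#' @return A `metabolic_network`.
#' @export
build_network <- function(model, spec = network_spec()) {
  net <- if (spec$compartmentalize) build_compartmental(model, spec)
  else build_noncompartmental(model, spec)
  net <- apply_exclusions(net, spec)
  if (spec$keep_largest_component) net <- largest_component(net)
  net
}

#' Breadth-first proximity query
#'
#' Returns the subnetwork induced on all nodes within `depth` links of the
#' focal node, traversing outgoing links, incoming links, or both.
#'
#' @param network A `metabolic_network`.
#' @param focus Node identifier.
#' @param depth Non-negative integer search radius (in links).
#' @param direction `"out"`, `"in"`, or `"both"`.
#' @return A subnetwork with a `provenance` description.
#' @export
query_proximity <- function(network, focus, depth,
                            direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  if (!focus %in% network$nodes$id) {
    stop("unknown focus node: ", focus, call. = FALSE)
  }
  stopifnot(depth >= 0)
  g <- as_igraph(network)
  mode <- switch(direction, both = "all", out = "out", `in` = "in")
  reach <- igraph::ego(g, order = depth, nodes = focus, mode = mode)[[1L]]
  subset_network(network, reach$name,
                 provenance = sprintf("proximity(%s, depth=%d, %s)", focus,
                                      as.integer(depth), direction))
}

#' Connection query between target nodes
#'
#' Returns the subnetwork induced on the union of all directed shortest
#' paths between every ordered pair of targets; pairs with no directed path
#' contribute nothing and are listed in the provenance.
#'
#' @param network A `metabolic_network`.
#' @param targets Character vector of >= 2 node identifiers.
#' @return A subnetwork with `provenance` noting unreachable pairs.
#' @export
query_connection <- function(network, targets) {
  targets <- unique(as.character(targets))
  if (length(targets) < 2L) {
    stop("query_connection needs at least two targets", call. = FALSE)
  }
  missing <- setdiff(targets, network$nodes$id)
  if (length(missing)) {
    stop("unknown targets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- as_igraph(network)
  keep <- character()
  unreachable <- character()
  for (s in targets) {
    for (t in setdiff(targets, s)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t, mode = "out"))
      if (length(paths$vpaths) == 0L) {
        unreachable <- c(unreachable, paste0(s, "->", t))
      } else {
        keep <- union(keep, unlist(lapply(paths$vpaths, function(v) v$name)))
      }
    }
  }
  keep <- union(keep, targets)
  prov <- sprintf("connection(%s)", paste(sort(targets), collapse = ","))
  if (length(unreachable)) {
    prov <- paste0(prov, "; unreachable: ",
                   paste(sort(unreachable), collapse = ", "))
  }
  subset_network(network, keep, provenance = prov)
}
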