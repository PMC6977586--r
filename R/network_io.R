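#' Export a network to file
#'
#' @param network A `metabolic_network`.
#' @param path Output path. For `cytoscape_tables` the path is a prefix:
#'   `<path>_nodes.tsv` and `<path>_edges.tsv` are written.
#' @param format `"graphml"` (round-trips partition tags and link roles via
#'   igraph), `"node_link_text"` (JSON node-link dialect), or
#'   `"cytoscape_tables"` (node and edge TSV ready for Cytoscape import).
#' @export
export_network <- function(network, path,
                           format = c("graphml", "node_link_text",
                                      "cytoscape_tables")) {
  format <- match.arg(format)
  switch(format,
         graphml = export_graphml(network, path),
         node_link_text = export_node_link(network, path),
         cytoscape_tables = export_cytoscape(network, path))
  invisible(path)
}

annotation_of <- function(network, id) {
  ann <- network$annotations
  if (is.null(ann)) return(c(log2fc = NA_real_, p_value = NA_real_))
  i <- match(id, ann$id)
  if (is.na(i)) return(c(log2fc = NA_real_, p_value = NA_real_))
  c(log2fc = ann$log2fc[[i]], p_value = ann$p_value[[i]])
}

export_graphml <- function(network, path) {
  g <- as_igraph(network)
  if (!is.null(network$annotations) && igraph::vcount(g) > 0L) {
    ann <- t(vapply(igraph::V(g)$name, function(id)
      annotation_of(network, id), c(log2fc = 0, p_value = 0)))
    igraph::V(g)$log2fc <- ann[, "log2fc"]
    igraph::V(g)$p_value <- ann[, "p_value"]
  }
  igraph::write_graph(g, path, format = "graphml")
}

#' Import a network written by [export_network()]
#'
#' Restores topology, partition tags and link roles (and, for
#' `node_link_text`, fold-change/p-value annotations). Model payloads are
#' not serialized: the imported object supports queries and metrics but not
#' payload-dependent operations.
#'
#' @param path Path produced by [export_network()].
#' @param format `"graphml"` or `"node_link_text"`.
#' @return A `metabolic_network`.
#' @export
import_network <- function(path, format = c("graphml", "node_link_text")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name, type = igraph::V(g)$type,
                        name = igraph::V(g)$label, stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    links <- data.frame(from = el[, 1L], to = el[, 2L],
                        role = igraph::E(g)$role, stringsAsFactors = FALSE)
    ann <- NULL
    if ("log2fc" %in% igraph::vertex_attr_names(g)) {
      keep <- !is.na(igraph::V(g)$log2fc)
      if (any(keep)) {
        ann <- data.frame(id = igraph::V(g)$name[keep],
                          log2fc = igraph::V(g)$log2fc[keep],
                          p_value = igraph::V(g)$p_value[keep],
                          stringsAsFactors = FALSE)
      }
    }
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    nodes <- do.call(rbind, lapply(doc$nodes, function(n)
      data.frame(id = n$id, type = n$type, name = n$name,
                 stringsAsFactors = FALSE)))
    links <- if (length(doc$links)) {
      do.call(rbind, lapply(doc$links, function(l)
        data.frame(from = l$source, to = l$target, role = l$role,
                   stringsAsFactors = FALSE)))
    } else empty_links()
    if (is.null(nodes)) {
      nodes <- data.frame(id = character(), type = character(),
                          name = character(), stringsAsFactors = FALSE)
    }
    ann <- NULL
    annotated <- Filter(function(n) !is.null(n$log2fc), doc$nodes)
    if (length(annotated)) {
      ann <- do.call(rbind, lapply(annotated, function(n)
        data.frame(id = n$id, log2fc = as.numeric(n$log2fc),
                   p_value = as.numeric(n$p_value),
                   stringsAsFactors = FALSE)))
    }
  }
  payload <- stats::setNames(lapply(seq_len(nrow(nodes)), function(i)
    list(type = nodes$type[[i]], sources = nodes$id[[i]])), nodes$id)
  net <- new_network(nodes, links, payload,
                     network_spec(keep_largest_component = FALSE),
                     annotations = ann)
  assert_bipartite(net)
  net
}

export_node_link <- function(network, path) {
  nodes <- lapply(seq_len(nrow(network$nodes)), function(i) {
    n <- as.list(network$nodes[i, ])
    ann <- annotation_of(network, n$id)
    if (!is.na(ann[["log2fc"]])) {
      n$log2fc <- ann[["log2fc"]]
      n$p_value <- ann[["p_value"]]
    }
    n
  })
  links <- lapply(seq_len(nrow(network$links)), function(i) {
    list(source = network$links$from[[i]], target = network$links$to[[i]],
         role = network$links$role[[i]])
  })
  json <- jsonlite::toJSON(list(directed = TRUE, nodes = nodes,
                                links = links),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
}

export_cytoscape <- function(network, path) {
  deg <- node_degrees(network)
  ann <- if (is.null(network$annotations)) {
    data.frame(id = character(), log2fc = numeric(), p_value = numeric())
  } else network$annotations
  nodes <- data.frame(identifier = network$nodes$id,
                      type = network$nodes$type,
                      name = network$nodes$name,
                      degree = as.integer(deg[network$nodes$id]),
                      stringsAsFactors = FALSE)
  nodes$log2fc <- ann$log2fc[match(nodes$identifier, ann$id)]
  nodes$p_value <- ann$p_value[match(nodes$identifier, ann$id)]
  if (!is.null(network$cluster_ids)) {
    nodes$cluster_id <- network$cluster_ids[match(nodes$identifier,
                                                  names(network$cluster_ids))]
  }
  edges <- data.frame(source = network$links$from,
                      target = network$links$to,
                      role = network$links$role, stringsAsFactors = FALSE)
  utils::write.table(nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
}
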