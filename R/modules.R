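# Detection of connected clusters of proximal measured metabolites enriched
# in small p-values. Per-metabolite p-values become standard normal
# quantiles z = qnorm(1 - p); a candidate subnetwork with k scored
# metabolites aggregates them as z_A = sum(z_i) / sqrt(k) (Stouffer form).
# Clusters are grown greedily from each scored metabolite, which replaces
# the simulated-annealing search of the classic active-modules method with
# a deterministic, desk-scale procedure.

#' Standard-normal quantile scores from p-values
#'
#' `z = qnorm(1 - p)`. `p = 1` maps to `-Inf` and is clamped to `floor`
#' (with attribute `clamped` listing the affected metabolites).
#'
#' @param comparisons Data frame with `metabolite` and `p_value` columns
#'   (rows with `NA` metabolite are dropped).
#' @param floor Lower clamp for z (default -10).
#' @return Named numeric vector metabolite -> z.
#' @export
node_z_scores <- function(comparisons, floor = -10) {
  comp <- comparisons[!is.na(comparisons$metabolite), , drop = FALSE]
  p <- comp$p_value
  if (any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  z <- stats::qnorm(1 - p)
  clamped <- comp$metabolite[z < floor]
  z[z < floor] <- floor
  structure(stats::setNames(z, comp$metabolite), clamped = clamped)
}

#' Aggregate score of a node set
#'
#' `z_A = sum(z_i) / sqrt(k)` over the `k` scored metabolites in the set;
#' unscored nodes (reactions, unmeasured metabolites) contribute nothing.
#'
#' @param nodes Character vector of node identifiers.
#' @param z_scores Named vector from [node_z_scores()].
#' @return The aggregate score.
#' @export
score_subnetwork <- function(nodes, z_scores) {
  z <- z_scores[intersect(nodes, names(z_scores))]
  if (length(z) == 0L) {
    stop("no scored metabolite among the nodes", call. = FALSE)
  }
  sum(z) / sqrt(length(z))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Greedy growth from one seed: repeatedly add the scored metabolite within
# `depth` undirected links of the current cluster that maximally increases
# z_A (together with one shortest connecting path of unscored nodes),
# stopping when no addition improves the score. Ties break by identifier.
grow_cluster <- function(g, seed_node, z_scores, depth) {
  members <- seed_node
  score <- score_subnetwork(members, z_scores)
  repeat {
    reach <- unique(unlist(lapply(
      igraph::ego(g, order = depth, nodes = members, mode = "all"),
      function(v) v$name)))
    candidates <- sort(setdiff(intersect(reach, names(z_scores)), members))
    if (length(candidates) == 0L) break
    gains <- vapply(candidates, function(cand) {
      score_subnetwork(c(members, cand), z_scores) - score
    }, numeric(1L))
    best <- candidates[order(-gains, candidates)][1L]
    if (gains[[best]] <= 1e-12) break
    path_opts <- igraph::all_shortest_paths(
      g, from = best, to = members, mode = "all")$vpaths
    lens <- vapply(path_opts, length, integer(1L))
    path_opts <- path_opts[lens == min(lens)]
    keys <- vapply(path_opts, function(v) paste(sort(v$name),
                                                collapse = "|"), "")
    connector <- path_opts[[order(keys)[1L]]]$name
    members <- union(members, c(best, connector))
    score <- score_subnetwork(members, z_scores)
  }
  list(members = sort(members), score = score)
}

#' Search for p-value-enriched clusters
#'
#' Grows one candidate cluster greedily from every scored metabolite node
#' (see source for the growth rule), ranks candidates by aggregate score,
#' and emits up to `n_modules` clusters per overlap threshold, suppressing
#' any candidate whose Jaccard node overlap with an already-emitted cluster
#' of the same threshold exceeds that threshold. Deterministic given the
#' network and scores; `seed` is recorded in provenance for pipeline
#' reproducibility bookkeeping.
#'
#' @param network An annotated `metabolic_network`.
#' @param z_scores Named vector from [node_z_scores()].
#' @param n_modules Maximum clusters per threshold (default 25).
#' @param depth Growth search radius in links (default 2).
#' @param overlap_thresholds Jaccard suppression thresholds (default
#'   `c(0.25, 0.50, 0.75)`).
#' @param seed Integer recorded in provenance.
#' @return List of `cluster_result` objects (fields `nodes`, `score`,
#'   `seed_node`, `overlap_threshold`, `depth`, `annotations`).
#' @export
search_modules <- function(network, z_scores, n_modules = 25L, depth = 2L,
                           overlap_thresholds = c(0.25, 0.50, 0.75),
                           seed = 1L) {
  scored <- intersect(names(z_scores), network$nodes$id)
  if (length(scored) == 0L) {
    message("no scored metabolite nodes; no clusters to search")
    return(list())
  }
  g <- as_igraph(network)
  candidates <- lapply(sort(scored), function(s)
    c(grow_cluster(g, s, z_scores, depth), list(seed_node = s)))
  ord <- order(-vapply(candidates, `[[`, 0, "score"),
               vapply(candidates, `[[`, "", "seed_node"))
  candidates <- candidates[ord]
  out <- list()
  for (thr in overlap_thresholds) {
    emitted <- list()
    for (cand in candidates) {
      if (length(emitted) >= n_modules) break
      overlaps <- vapply(emitted, function(e)
        jaccard(e$nodes, cand$members), numeric(1L))
      if (length(overlaps) && any(overlaps > thr)) next
      ann <- if (!is.null(network$annotations)) {
        network$annotations[network$annotations$id %in% cand$members, ,
                            drop = FALSE]
      } else NULL
      emitted[[length(emitted) + 1L]] <- structure(
        list(nodes = cand$members, score = cand$score,
             seed_node = cand$seed_node, overlap_threshold = thr,
             depth = as.integer(depth), seed = as.integer(seed),
             annotations = ann),
        class = "cluster_result")
    }
    out <- c(out, emitted)
  }
  out
}

cluster_reaction_nodes <- function(cluster, network) {
  intersect(cluster$nodes,
            network$nodes$id[network$nodes$type == "reaction"])
}

#' Filter clusters by the curation rules
#'
#' Keeps clusters with at most 3 reaction nodes, in which for every member
#' reaction the majority of its participant metabolites that are present in
#' the cluster have measurements, and which contain at least one metabolite
#' with positive and one with negative log2 fold change (both accumulation
#' and depletion among proximal metabolites). Idempotent; output is a
#' subset of the input.
#'
#' @param clusters List of `cluster_result` from [search_modules()].
#' @param network The annotated `metabolic_network` the clusters came from.
#' @param max_reactions Reaction-count cutoff (default 3).
#' @return Filtered list.
#' @export
filter_clusters <- function(clusters, network, max_reactions = 3L) {
  measured <- if (is.null(network$annotations)) character()
  else network$annotations$id
  Filter(function(cl) {
    rxns <- cluster_reaction_nodes(cl, network)
    if (length(rxns) > max_reactions) return(FALSE)
    for (r in rxns) {
      nbrs <- unique(c(network$links$from[network$links$to == r],
                       network$links$to[network$links$from == r]))
      in_cluster <- intersect(nbrs, cl$nodes)
      if (length(in_cluster) &&
          sum(in_cluster %in% measured) * 2L <= length(in_cluster)) {
        return(FALSE)
      }
    }
    if (is.null(cl$annotations) || nrow(cl$annotations) == 0L) return(FALSE)
    any(cl$annotations$log2fc > 0) && any(cl$annotations$log2fc < 0)
  }, clusters)
}

#' Export clusters as metabolite and reaction TSV tables
#'
#' Writes `<path>_metabolites.tsv` (cluster, identifier, name, log2fc,
#' p_value) and `<path>_reactions.tsv` (cluster, identifier, name, genes,
#' processes).
#'
#' @param clusters List of `cluster_result`.
#' @param network The parent `metabolic_network` (for names and payloads).
#' @param path Output path prefix.
#' @export
export_clusters <- function(clusters, network, path) {
  met_rows <- list()
  rxn_rows <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    for (id in cl$nodes) {
      node <- network$nodes[network$nodes$id == id, , drop = FALSE]
      if (nrow(node) == 0L) next
      if (node$type == "metabolite") {
        ann <- annotation_of(network, id)
        met_rows[[length(met_rows) + 1L]] <- data.frame(
          cluster = k, identifier = id, name = node$name,
          log2fc = ann[["log2fc"]], p_value = ann[["p_value"]],
          stringsAsFactors = FALSE)
      } else {
        rxn <- network$payload[[id]]$reaction
        rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
          cluster = k, identifier = id, name = node$name,
          genes = paste(rxn$genes %||% character(), collapse = ";"),
          processes = paste(rxn$processes %||% character(),
                            collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_met <- data.frame(cluster = integer(), identifier = character(),
                          name = character(), log2fc = numeric(),
                          p_value = numeric(), stringsAsFactors = FALSE)
  empty_rxn <- data.frame(cluster = integer(), identifier = character(),
                          name = character(), genes = character(),
                          processes = character(), stringsAsFactors = FALSE)
  utils::write.table(
    if (length(met_rows)) do.call(rbind, met_rows) else empty_met,
    paste0(path, "_metabolites.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  utils::write.table(
    if (length(rxn_rows)) do.call(rbind, rxn_rows) else empty_rxn,
    paste0(path, "_reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  invisible(path)
}
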