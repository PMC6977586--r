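# Single-mode metrics for directional bipartite metabolite-reaction
# networks. "Single-mode" means a metric is computed relative to one
# bipartite node set (metabolites or reactions) only; normalizations compare
# to the maximum possible for a directed bipartite network of the same
# dimensions ("comparison to maximum") or to the mean over random directed
# bipartite networks matched in part sizes and link count ("comparison to
# random").

mode_nodes <- function(network, mode) {
  mode <- match.arg(mode, c("metabolite", "reaction"))
  sort(network$nodes$id[network$nodes$type == mode])
}

opposite_mode <- function(mode) {
  if (mode == "metabolite") "reaction" else "metabolite"
}

#' Density of a directed bipartite network
#'
#' `size / (2 * n_metabolites * n_reactions)`: the realized fraction of the
#' maximum possible number of directed links between the two node sets.
#'
#' @param n_metabolites,n_reactions Part sizes (positive).
#' @param size Number of directed links.
#' @return Density in `[0, 1]`.
#' @export
bipartite_density <- function(n_metabolites, n_reactions, size) {
  if (n_metabolites <= 0 || n_reactions <= 0) {
    stop("density undefined for an empty bipartite part", call. = FALSE)
  }
  size / (2 * n_metabolites * n_reactions)
}

#' Single-mode degree centrality
#'
#' For a node in the chosen set, `(in-degree + out-degree)` normalized by the
#' maximum possible `2 * |opposite set|` (a bidirectional link to every
#' opposite node).
#'
#' @param network A `metabolic_network`.
#' @param mode `"metabolite"` or `"reaction"`.
#' @return Data frame `id`, `degree_centrality`.
#' @export
degree_centrality <- function(network, mode = "metabolite") {
  ids <- mode_nodes(network, mode)
  n_opp <- sum(network$nodes$type == opposite_mode(match.arg(
    mode, c("metabolite", "reaction"))))
  if (n_opp == 0L) stop("empty opposite node set", call. = FALSE)
  deg <- node_degrees(network)
  data.frame(id = ids, degree_centrality = as.numeric(deg[ids]) / (2 * n_opp),
             stringsAsFactors = FALSE)
}

# Borgatti-Everett normalizing denominator for bipartite betweenness. The
# maximum betweenness attainable by a node in a set of size n against an
# opposite set of size m, counted over unordered pairs, is
#   (1/2) * [ m^2 (s+1)^2 + m (s+1)(2t - s - 1) - t (2s - t + 3) ]
# with s = (n - 1) %/% m and t = (n - 1) %% m. Raw betweenness here counts
# ordered (source, target) pairs on the directed graph -- up to twice the
# unordered count -- so the denominator is doubled.
be_betweenness_max <- function(n_own, n_opp) {
  if (n_opp == 0L) return(NA_real_)
  s <- (n_own - 1) %/% n_opp
  t <- (n_own - 1) %% n_opp
  (n_opp^2 * (s + 1)^2 + n_opp * (s + 1) * (2 * t - s - 1) -
      t * (2 * s - t + 3))
}

#' Single-mode betweenness centrality
#'
#' Raw betweenness sums, over ordered source-target pairs, the fraction of
#' shortest directed paths passing through a node; values are normalized by
#' the bipartite maximum for the node's set (Borgatti-Everett denominator,
#' see source).
#'
#' @inheritParams degree_centrality
#' @return Data frame `id`, `betweenness_centrality`, `betweenness_raw`.
#' @export
betweenness_centrality <- function(network, mode = "metabolite") {
  mode <- match.arg(mode, c("metabolite", "reaction"))
  ids <- mode_nodes(network, mode)
  g <- as_igraph(network)
  raw <- igraph::betweenness(g, directed = TRUE)
  n_own <- length(ids)
  n_opp <- sum(network$nodes$type == opposite_mode(mode))
  denom <- be_betweenness_max(n_own, n_opp)
  norm <- if (is.na(denom) || denom == 0) rep(0, n_own)
  else as.numeric(raw[ids]) / denom
  data.frame(id = ids, betweenness_centrality = norm,
             betweenness_raw = as.numeric(raw[ids]),
             stringsAsFactors = FALSE)
}

#' Freeman-style centralization of a centrality distribution
#'
#' Sum of deficits from the observed maximum, normalized by `n - 1` (the
#' maximum attainable deficit sum when centralities are bounded by 1, reached
#' by the pattern one node at 1 and the rest at 0).
#'
#' @param centralities Numeric vector of normalized centralities in `[0, 1]`,
#'   length >= 2.
#' @return Centralization in `[0, 1]`.
#' @export
centralization <- function(centralities) {
  n <- length(centralities)
  if (n < 2L) stop("centralization needs >= 2 nodes", call. = FALSE)
  stopifnot(all(centralities >= 0), all(centralities <= 1 + 1e-12))
  sum(max(centralities) - centralities) / (n - 1)
}

undirected_adjacency <- function(network) {
  adj <- stats::setNames(vector("list", nrow(network$nodes)),
                         network$nodes$id)
  if (nrow(network$links)) {
    for (i in seq_len(nrow(network$links))) {
      a <- network$links$from[[i]]
      b <- network$links$to[[i]]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, unique)
}

#' Single-mode pairwise cluster coefficients
#'
#' For node `u`, the mean over its second-order neighbors `v` (same-set
#' nodes two links away in the undirected view) of the Jaccard overlap
#' `|N(u) n N(v)| / |N(u) u N(v)|` of first-order neighborhoods. Nodes
#' without second-order neighbors score 0.
#'
#' @inheritParams degree_centrality
#' @return Data frame `id`, `cluster_coefficient`.
#' @export
bipartite_clustering <- function(network, mode = "metabolite") {
  ids <- mode_nodes(network, mode)
  adj <- undirected_adjacency(network)
  coef <- vapply(ids, function(u) {
    nu <- adj[[u]]
    second <- setdiff(unique(unlist(adj[nu])), u)
    if (length(second) == 0L) return(0)
    mean(vapply(second, function(v) {
      nv <- adj[[v]]
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, numeric(1L)))
  }, numeric(1L))
  data.frame(id = ids, cluster_coefficient = as.numeric(coef),
             stringsAsFactors = FALSE)
}

#' Single-mode mean shortest path length
#'
#' Mean of directed shortest-path lengths, counted in links (so same-set
#' distances are even), over all ordered same-set pairs with a directed
#' path. The number of unreachable ordered pairs is attached as attribute
#' `unreachable_pairs`.
#'
#' @inheritParams degree_centrality
#' @return Positive number with attribute `unreachable_pairs`.
#' @export
mean_path_length <- function(network, mode = "metabolite") {
  ids <- mode_nodes(network, mode)
  if (length(ids) < 2L) stop("need >= 2 same-set nodes", call. = FALSE)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = ids, to = ids, mode = "out")
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  if (!any(finite)) {
    stop("no reachable same-set pair of nodes", call. = FALSE)
  }
  structure(mean(d[finite]), unreachable_pairs = sum(!finite))
}

#' Seeded random directed bipartite network
#'
#' Uniformly samples `size` distinct directed links between `n_metabolites`
#' generic metabolite nodes and `n_reactions` generic reaction nodes (both
#' directions allowed, maximum `2 * n_metabolites * n_reactions`).
#'
#' @param n_metabolites,n_reactions Part sizes.
#' @param size Number of links to draw.
#' @param seed Integer seed; same seed, same graph.
#' @return A `metabolic_network` without model payloads.
#' @export
random_bipartite <- function(n_metabolites, n_reactions, size, seed) {
  max_size <- 2 * n_metabolites * n_reactions
  if (size > max_size) {
    stop("requested size ", size, " exceeds bipartite maximum ", max_size,
         call. = FALSE)
  }
  mids <- sprintf("m%0*d", nchar(n_metabolites), seq_len(n_metabolites))
  rids <- sprintf("r%0*d", nchar(n_reactions), seq_len(n_reactions))
  # sample without replacement from the 2*n_m*n_r possible directed links:
  # index i encodes (metabolite, reaction, direction)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  idx <- sample.int(max_size, size)
  dir_out <- idx <= n_metabolites * n_reactions  # metabolite -> reaction
  base <- ifelse(dir_out, idx, idx - n_metabolites * n_reactions) - 1L
  m <- mids[base %% n_metabolites + 1L]
  r <- rids[base %/% n_metabolites + 1L]
  links <- data.frame(from = ifelse(dir_out, m, r),
                      to = ifelse(dir_out, r, m),
                      role = ifelse(dir_out, "reactant", "product"),
                      stringsAsFactors = FALSE)
  links <- links[order(links$from, links$to), , drop = FALSE]
  nodes <- data.frame(id = c(mids, rids),
                      type = rep(c("metabolite", "reaction"),
                                 c(n_metabolites, n_reactions)),
                      name = c(mids, rids), stringsAsFactors = FALSE)
  payload <- stats::setNames(lapply(seq_len(nrow(nodes)), function(i)
    list(type = nodes$type[[i]], sources = nodes$id[[i]])), nodes$id)
  net <- new_network(nodes, links, payload,
                     network_spec(keep_largest_component = FALSE))
  assert_bipartite(net)
  net
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Small-world sigma coefficient against a matched random ensemble
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` and `L` are the network's
#' single-mode mean cluster coefficient and mean path length and `C_rand`,
#' `L_rand` are their means over `replicates` random directed bipartite
#' networks matched in part sizes and link count. Values much greater than 1
#' indicate modularity combined with short paths.
#'
#' @inheritParams degree_centrality
#' @param replicates Ensemble size (default 10).
#' @param seed Integer seed for the ensemble.
#' @return Sigma, with attributes `C`, `L`, `C_rand`, `L_rand`.
#' @export
sigma_small_world <- function(network, mode = "metabolite",
                              replicates = 10L, seed) {
  n_m <- sum(network$nodes$type == "metabolite")
  n_r <- sum(network$nodes$type == "reaction")
  size <- nrow(network$links)
  C <- mean(bipartite_clustering(network, mode)$cluster_coefficient)
  L <- as.numeric(mean_path_length(network, mode))
  Cr <- numeric(replicates)
  Lr <- numeric(replicates)
  for (k in seq_len(replicates)) {
    rnet <- random_bipartite(n_m, n_r, size, seed = as.integer(seed) + k)
    Cr[[k]] <- mean(bipartite_clustering(rnet, mode)$cluster_coefficient)
    Lr[[k]] <- as.numeric(mean_path_length(rnet, mode))
  }
  C_rand <- mean(Cr)
  L_rand <- mean(Lr)
  if (C_rand == 0) {
    stop("degenerate ensemble: C_rand = 0; increase replicates or network ",
         "size", call. = FALSE)
  }
  structure((C / C_rand) / (L / L_rand),
            C = C, L = L, C_rand = C_rand, L_rand = L_rand)
}

#' Project the bipartite network onto one node set
#'
#' Directed unipartite projection: link `u -> w` whenever some reaction
#' (respectively metabolite, for reaction mode) receives a link from `u` and
#' sends a link to `w`, with `u != w` (self-links arising from reversible
#' reactions are dropped, matching standard bipartite projection behaviour).
#'
#' @inheritParams degree_centrality
#' @return Data frame of projected links `from`, `to`.
#' @export
project_unipartite <- function(network, mode = "metabolite") {
  ids <- mode_nodes(network, opposite_mode(match.arg(
    mode, c("metabolite", "reaction"))))
  links <- network$links
  out <- list()
  for (via in ids) {
    sources <- links$from[links$to == via]
    targets <- links$to[links$from == via]
    if (length(sources) && length(targets)) {
      grid <- expand.grid(from = sources, to = targets,
                          stringsAsFactors = FALSE)
      out[[via]] <- grid[grid$from != grid$to, , drop = FALSE]
    }
  }
  proj <- if (length(out)) do.call(rbind, unname(out))
  else data.frame(from = character(), to = character(),
                  stringsAsFactors = FALSE)
  proj <- proj[!duplicated(proj), , drop = FALSE]
  proj <- proj[order(proj$from, proj$to), , drop = FALSE]
  data.frame(from = proj$from, to = proj$to, stringsAsFactors = FALSE)
}

#' Degree assortativity of the unipartite projection
#'
#' Pearson correlation of degrees across the directed links of the
#' single-mode projection (out-degree of source against in-degree of
#' target). A projection whose degree sequence has zero variance has an
#' undefined correlation; 0 is returned with attribute `degenerate = TRUE`.
#'
#' @inheritParams degree_centrality
#' @return Number in `[-1, 1]` (attribute `degenerate` flags a constant
#'   degree sequence).
#' @export
assortativity <- function(network, mode = "metabolite") {
  proj <- project_unipartite(network, mode)
  if (nrow(proj) < 2L) {
    stop("projection has fewer than 2 links; assortativity undefined",
         call. = FALSE)
  }
  ids <- sort(unique(c(proj$from, proj$to)))
  g <- igraph::graph_from_data_frame(proj, directed = TRUE,
                                     vertices = data.frame(name = ids))
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = TRUE))
  if (is.na(r) || is.nan(r)) {
    structure(0, degenerate = TRUE)
  } else {
    structure(as.numeric(r), degenerate = FALSE)
  }
}

#' Rank metabolites by combined degree and betweenness influence
#'
#' Assigns descending ranks (1 = most central, average rank for ties) to
#' degree and betweenness centralities separately; the total rank is their
#' arithmetic mean. Output is sorted by ascending total rank, ties by
#' identifier.
#'
#' @param centralities Data frame with columns `id`, `degree_centrality`,
#'   `betweenness_centrality`.
#' @return Data frame `id`, `degree_rank`, `betweenness_rank`, `total_rank`.
#' @export
rank_metabolites <- function(centralities) {
  stopifnot(nrow(centralities) > 0L)
  dr <- rank(-centralities$degree_centrality, ties.method = "average")
  br <- rank(-centralities$betweenness_centrality, ties.method = "average")
  out <- data.frame(id = centralities$id, degree_rank = dr,
                    betweenness_rank = br, total_rank = (dr + br) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$total_rank, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the full single-mode metrics report
#'
#' One row of network-level metrics (orders, size, density, degree and
#' betweenness centralization, mean path length, mean cluster coefficient,
#' small-world sigma, assortativity) plus the per-node centrality table and
#' influence ranks, all relative to the chosen bipartite set.
#'
#' @inheritParams degree_centrality
#' @param replicates,seed Ensemble settings for [sigma_small_world()].
#' @return A `metrics_report` list; see [report_row()] for the tabular form.
#' @export
metrics_report <- function(network, mode = "metabolite", replicates = 10L,
                           seed = 1L) {
  mode <- match.arg(mode, c("metabolite", "reaction"))
  n_m <- sum(network$nodes$type == "metabolite")
  n_r <- sum(network$nodes$type == "reaction")
  size <- nrow(network$links)
  dc <- degree_centrality(network, mode)
  bc <- betweenness_centrality(network, mode)
  cc <- bipartite_clustering(network, mode)
  nodes <- merge(merge(dc, bc, by = "id"), cc, by = "id")
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  L <- mean_path_length(network, mode)
  sig <- sigma_small_world(network, mode, replicates = replicates,
                           seed = seed)
  structure(
    list(order_total = n_m + n_r, order_metabolites = n_m,
         order_reactions = n_r, size = size,
         density = bipartite_density(n_m, n_r, size),
         centralization_degree = centralization(dc$degree_centrality),
         centralization_betweenness =
           centralization(bc$betweenness_centrality),
         mean_path_length = as.numeric(L),
         unreachable_pairs = attr(L, "unreachable_pairs"),
         mean_cluster_coefficient = mean(cc$cluster_coefficient),
         sigma = as.numeric(sig),
         assortativity = as.numeric(assortativity(network, mode)),
         mode = mode, replicates = as.integer(replicates),
         seed = as.integer(seed),
         node_centralities = nodes,
         ranks = rank_metabolites(nodes)),
    class = "metrics_report")
}

#' Build a metrics report from already-known scalar values
#'
#' Useful for comparing a computed report against a published table row, or
#' two published rows against each other, with [compare_reports()].
#'
#' @param ... Named scalar metrics (any subset of the `metrics_report`
#'   scalar fields).
#' @param mode Bipartite reference set.
#' @return A `metrics_report` containing the supplied scalars.
#' @export
manual_report <- function(..., mode = "metabolite") {
  structure(c(list(...), list(mode = mode)), class = "metrics_report")
}

report_scalars <- c("order_total", "order_metabolites", "order_reactions",
                    "size", "density", "centralization_degree",
                    "centralization_betweenness", "mean_path_length",
                    "mean_cluster_coefficient", "sigma", "assortativity")

#' One-row tabular form of a metrics report
#'
#' @param report A `metrics_report`.
#' @return Single-row data frame with the scalar metrics in standard column
#'   order.
#' @export
report_row <- function(report) {
  present <- intersect(report_scalars, names(report))
  as.data.frame(report[present], stringsAsFactors = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report (mode:", x$mode, ")\n")
  print(report_row(x), row.names = FALSE)
  invisible(x)
}

#' Fold ratios between two metrics reports
#'
#' For every scalar metric present in both reports, the ratio of the larger
#' value to the smaller (3 significant figures) with a tag saying which
#' report is greater. A zero denominator flags the ratio as infinite.
#'
#' @param a,b `metrics_report` objects of the same mode.
#' @param label_a,label_b Names used in the `greater` column.
#' @return Data frame `metric`, `value_a`, `value_b`, `fold`, `greater`.
#' @export
compare_reports <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(identical(a$mode, b$mode))
  metrics <- intersect(intersect(report_scalars, names(a)), names(b))
  rows <- lapply(metrics, function(m) {
    va <- as.numeric(a[[m]])
    vb <- as.numeric(b[[m]])
    lo <- min(abs(va), abs(vb))
    hi <- max(abs(va), abs(vb))
    fold <- if (lo == hi) 1 else if (lo == 0) Inf else signif(hi / lo, 3L)
    greater <- if (abs(va) > abs(vb)) label_a
    else if (abs(vb) > abs(va)) label_b else "equal"
    data.frame(metric = m, value_a = va, value_b = vb, fold = fold,
               greater = greater, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a metrics report row as TSV
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report_row(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
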