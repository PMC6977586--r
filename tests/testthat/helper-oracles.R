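# Independent brute-force oracles for small fixtures (<= 20 nodes). These
# use only plain R on the network's link table -- no igraph -- so they stay
# independent of the implementation paths they check.

oracle_adjacency <- function(network, directed = TRUE) {
  ids <- network$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(network$links))) {
    a <- network$links$from[[i]]
    b <- network$links$to[[i]]
    adj[[a]] <- union(adj[[a]], b)
    if (!directed) adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

oracle_distances <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[[s]] <- 0
  queue <- s
  while (length(queue)) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (!is.finite(dist[[v]])) {
        dist[[v]] <- dist[[u]] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# All shortest directed paths s -> t by exhaustive expansion along
# distance-increasing links.
oracle_shortest_paths <- function(adj, radj, s, t) {
  dist <- oracle_distances(adj, s)
  rdist <- oracle_distances(radj, t)
  if (!is.finite(dist[[t]])) return(list())
  total <- dist[[t]]
  expand <- function(u) {
    if (u == t) return(list(u))
    out <- list()
    for (v in adj[[u]]) {
      if (dist[[v]] == dist[[u]] + 1 &&
          is.finite(rdist[[v]]) && dist[[v]] + rdist[[v]] == total) {
        for (p in expand(v)) out <- c(out, list(c(u, p)))
      }
    }
    out
  }
  expand(s)
}

oracle_reverse <- function(adj) {
  radj <- stats::setNames(vector("list", length(adj)), names(adj))
  for (u in names(adj)) {
    for (v in adj[[u]]) radj[[v]] <- union(radj[[v]], u)
  }
  radj
}

# Raw directed betweenness over ordered pairs by path enumeration.
oracle_betweenness <- function(network) {
  adj <- oracle_adjacency(network)
  radj <- oracle_reverse(adj)
  ids <- network$nodes$id
  bet <- stats::setNames(rep(0, length(ids)), ids)
  for (s in ids) {
    for (t in setdiff(ids, s)) {
      paths <- oracle_shortest_paths(adj, radj, s, t)
      if (length(paths) == 0L) next
      inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
      if (length(inner)) {
        counts <- table(inner)
        bet[names(counts)] <- bet[names(counts)] +
          as.numeric(counts) / length(paths)
      }
    }
  }
  bet
}

# Mean directed shortest-path length over reachable ordered same-set pairs.
oracle_mean_path <- function(network, mode = "metabolite") {
  ids <- sort(network$nodes$id[network$nodes$type == mode])
  adj <- oracle_adjacency(network)
  d <- c()
  unreachable <- 0L
  for (s in ids) {
    dist <- oracle_distances(adj, s)
    for (t in setdiff(ids, s)) {
      if (is.finite(dist[[t]])) d <- c(d, dist[[t]])
      else unreachable <- unreachable + 1L
    }
  }
  structure(if (length(d)) mean(d) else NA_real_,
            unreachable = unreachable)
}

# Pairwise Jaccard cluster coefficient from first principles: second-order
# neighbors found by checking undirected distance exactly 2.
oracle_clustering <- function(network, mode = "metabolite") {
  ids <- sort(network$nodes$id[network$nodes$type == mode])
  adj <- oracle_adjacency(network, directed = FALSE)
  vapply(stats::setNames(ids, ids), function(u) {
    dist <- oracle_distances(adj, u)
    second <- names(dist)[dist == 2]
    if (length(second) == 0L) return(0)
    mean(vapply(second, function(v) {
      nu <- adj[[u]]
      nv <- adj[[v]]
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, numeric(1L)))
  }, numeric(1L))
}

# Unipartite projection links by direct pairwise traversal of the link
# table: u -> w iff some opposite-set node receives a link from u and sends
# a link to w.
oracle_projection <- function(network, mode = "metabolite") {
  own <- network$nodes$id[network$nodes$type == mode]
  opp <- network$nodes$id[network$nodes$type != mode]
  links <- network$links
  out <- list()
  for (u in own) {
    for (w in setdiff(own, u)) {
      hit <- any(vapply(opp, function(r) {
        any(links$from == u & links$to == r) &&
          any(links$from == r & links$to == w)
      }, logical(1L)))
      if (hit) out[[length(out) + 1L]] <- data.frame(
        from = u, to = w, stringsAsFactors = FALSE)
    }
  }
  proj <- if (length(out)) do.call(rbind, out)
  else data.frame(from = character(), to = character(),
                  stringsAsFactors = FALSE)
  proj <- proj[order(proj$from, proj$to), , drop = FALSE]
  rownames(proj) <- NULL
  proj
}

# Extra small fixtures used across metric tests.
star_network <- function(n_reactions = 4L) {
  # one central metabolite consumed by every reaction, each reaction
  # producing its own terminal metabolite
  mets <- c(list(metabolite("HUB", references = list(pubchem = "1"))),
            lapply(seq_len(n_reactions), function(i)
              metabolite(paste0("X", i),
                         references = list(pubchem = as.character(i + 1)))))
  rxns <- lapply(seq_len(n_reactions), function(i)
    reaction(paste0("S", i),
             rbind(participant("HUB", "reactant", "c1"),
                   participant(paste0("X", i), "product", "c1"))))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  build_network(model, network_spec(keep_largest_component = FALSE))
}

chain_network <- function(n = 3L) {
  # linear pathway M1 -> R1 -> M2 -> R2 -> ... (a tree, no shared neighbors)
  mets <- lapply(seq_len(n + 1L), function(i)
    metabolite(paste0("M", i), references = list(pubchem = as.character(i))))
  rxns <- lapply(seq_len(n), function(i)
    reaction(paste0("R", i),
             rbind(participant(paste0("M", i), "reactant", "c1"),
                   participant(paste0("M", i + 1L), "product", "c1"))))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  build_network(model, network_spec(keep_largest_component = FALSE))
}

toy4_network <- function() {
  build_network(toy_model("toy4"), network_spec())
}
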