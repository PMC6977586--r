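test_that("bipartite density matches the directed-maximum formula", {
  expect_equal(signif(bipartite_density(1654, 2254, 13204), 4), 1.771e-3)
  expect_identical(bipartite_density(4, 4, 0), 0)
  expect_equal(bipartite_density(4, 4, 8), 0.25)
  expect_error(bipartite_density(0, 4, 0), "undefined")
})

test_that("degree centrality normalizes by twice the opposite set", {
  net <- toy4_network()
  dc <- degree_centrality(net)
  expect_equal(dc$degree_centrality, rep(0.25, 4))  # degree 2 / (2*4)
  # saturation: bidirectional links to every reaction give 1
  mets <- list(metabolite("HUB"), metabolite("Y"))
  rxns <- lapply(1:2, function(i)
    reaction(paste0("R", i), rbind(participant("HUB", "reactant", "c1"),
                                   participant("Y", "product", "c1")),
             reversible = TRUE))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  sat <- build_network(model, network_spec())
  expect_equal(
    degree_centrality(sat)$degree_centrality[
      degree_centrality(sat)$id == "HUB@c1"], 1)
})

test_that("betweenness matches the exhaustive path-enumeration oracle", {
  for (net in list(toy4_network(),
                   build_network(toy_model("toyhub"), network_spec()),
                   build_network(toy_model("toycomp"), network_spec()),
                   star_network(4L), chain_network(3L))) {
    got <- betweenness_centrality(net)
    oracle <- oracle_betweenness(net)
    expect_equal(got$betweenness_raw, unname(oracle[got$id]),
                 tolerance = 1e-12)
    rx <- betweenness_centrality(net, "reaction")
    expect_equal(rx$betweenness_raw, unname(oracle[rx$id]),
                 tolerance = 1e-12)
  }
  # star center is the most central metabolite
  star <- star_network(4L)
  bc <- betweenness_centrality(star)
  expect_identical(bc$id[which.max(bc$betweenness_centrality)], "HUB@c1")
  # 2-node network: all betweenness zero
  tiny <- chain_network(1L)
  expect_true(all(betweenness_centrality(tiny)$betweenness_raw == 0))
})

test_that("mean path length matches the oracle and counts links", {
  net <- toy4_network()
  expect_equal(as.numeric(mean_path_length(net)), 4)  # (2+4+6)/3
  for (cand in list(net, star_network(3L), chain_network(3L),
                    build_network(toy_model("toycomp"), network_spec()))) {
    got <- mean_path_length(cand)
    oracle <- oracle_mean_path(cand)
    expect_equal(as.numeric(got), as.numeric(oracle))
    expect_identical(attr(got, "unreachable_pairs"),
                     attr(oracle, "unreachable"))
  }
  # single reaction A -> B: one ordered pair at 2 links
  expect_equal(as.numeric(mean_path_length(chain_network(1L))), 2)
  # same-set distances in a bipartite graph are at least 2
  expect_gte(as.numeric(mean_path_length(net)), 2)
})

test_that("pairwise cluster coefficients match the oracle", {
  net <- toy4_network()
  cc <- bipartite_clustering(net)
  expect_equal(cc$cluster_coefficient, rep(1 / 3, 4))
  for (cand in list(net, star_network(4L), chain_network(3L),
                    build_network(toy_model("toyhub"), network_spec()))) {
    got <- bipartite_clustering(cand)
    oracle <- oracle_clustering(cand)
    expect_equal(got$cluster_coefficient, unname(oracle[got$id]))
  }
  # identical reaction neighborhoods give pairwise coefficient 1
  mets <- list(metabolite("A"), metabolite("B"))
  rxns <- lapply(c("R1", "R2"), function(id)
    reaction(id, rbind(participant("A", "reactant", "c1"),
                       participant("B", "product", "c1"))))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  twin <- build_network(model, network_spec())
  rc <- bipartite_clustering(twin, "reaction")
  expect_equal(rc$cluster_coefficient, c(1, 1))
  # chain end: one second-order neighbor sharing one of two reactions
  chain <- chain_network(3L)
  cl <- bipartite_clustering(chain)
  expect_equal(cl$cluster_coefficient[cl$id == "M1@c1"], 0.5)
  # no second-order neighbor at all scores 0 (the lone reaction)
  lone <- chain_network(1L)
  expect_equal(bipartite_clustering(lone, "reaction")$cluster_coefficient,
               0)
})

test_that("centralization is the normalized Freeman deficit sum", {
  expect_equal(centralization(c(0.3, 0.3, 0.3)), 0)
  expect_equal(centralization(c(1, 0, 0)), 1)
  expect_equal(centralization(c(0.5, 0.25, 0.25)), 0.25)
  expect_error(centralization(0.5), ">= 2")
})

test_that("random bipartite networks are seeded and exact in size", {
  a <- random_bipartite(6, 5, 20, seed = 42)
  b <- random_bipartite(6, 5, 20, seed = 42)
  expect_identical(a$links, b$links)
  expect_false(identical(a$links,
                         random_bipartite(6, 5, 20, seed = 43)$links))
  expect_identical(nrow(a$links), 20L)
  expect_false(any(duplicated(a$links[, c("from", "to")])))
  # complete graph at maximum size
  full <- random_bipartite(3, 2, 12, seed = 1)
  expect_identical(nrow(full$links), 12L)
  expect_error(random_bipartite(3, 2, 13, seed = 1), "maximum")
  # density is exact by construction
  expect_equal(bipartite_density(6, 5, nrow(a$links)), 20 / 60)
})

test_that("sigma is near 1 for a random network against its own ensemble", {
  net <- random_bipartite(30, 30, 240, seed = 7)
  sig <- sigma_small_world(net, replicates = 50L, seed = 100)
  expect_gt(as.numeric(sig), 0.75)
  expect_lt(as.numeric(sig), 1.33)
})

test_that("sigma regression on toy4 is stable under a fixed seed", {
  net <- toy4_network()
  s1 <- sigma_small_world(net, replicates = 10L, seed = 5)
  s2 <- sigma_small_world(net, replicates = 10L, seed = 5)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_gt(as.numeric(s1), 0)
})

test_that("unipartite projection matches the traversal oracle", {
  for (cand in list(toy4_network(), star_network(4L), chain_network(3L),
                    build_network(toy_model("toyhub"), network_spec()))) {
    got <- project_unipartite(cand)
    oracle <- oracle_projection(cand)
    expect_identical(got, oracle)
    got_r <- project_unipartite(cand, "reaction")
    expect_identical(got_r, oracle_projection(cand, "reaction"))
  }
})

test_that("assortativity handles degenerate and star projections", {
  # toy4 projects to a directed cycle: constant degrees, flagged 0
  r <- assortativity(toy4_network())
  expect_identical(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  # reversible star: projection is hub <-> leaves, the classic
  # disassortative pattern
  mets <- c(lapply(paste0("L", 1:4), metabolite), list(metabolite("HUB")))
  rxns <- lapply(1:4, function(i)
    reaction(paste0("S", i), rbind(participant("HUB", "reactant", "c1"),
                                   participant(paste0("L", i), "product",
                                               "c1")),
             reversible = TRUE))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  star <- build_network(model, network_spec())
  expect_lt(as.numeric(assortativity(star)), 0)
})

test_that("metabolite ranking averages ties and sorts by total", {
  tab <- data.frame(id = c("A", "B", "C"),
                    degree_centrality = c(5, 3, 1),
                    betweenness_centrality = c(0.5, 0.6, 0.1))
  rk <- rank_metabolites(tab)
  expect_identical(rk$id, c("A", "B", "C"))
  expect_equal(rk$total_rank, c(1.5, 1.5, 3))
  # single node: rank 1 everywhere
  one <- rank_metabolites(data.frame(id = "A", degree_centrality = 1,
                                     betweenness_centrality = 1))
  expect_equal(unlist(one[, -1]), c(degree_rank = 1, betweenness_rank = 1,
                                    total_rank = 1))
  # all equal: everyone gets the average rank; degree ranks sum to
  # n(n+1)/2 regardless of ties
  flat <- rank_metabolites(data.frame(id = letters[1:4],
                                      degree_centrality = rep(1, 4),
                                      betweenness_centrality = rep(1, 4)))
  expect_equal(unique(flat$total_rank), 2.5)
  expect_equal(sum(rk$degree_rank), 6)
  expect_equal(sum(flat$degree_rank), 10)
})

test_that("metrics report assembles all components deterministically", {
  net <- toy4_network()
  rep1 <- metrics_report(net, replicates = 5L, seed = 3)
  expect_identical(rep1$order_total, 8L)
  expect_identical(rep1$order_metabolites, 4L)
  expect_identical(rep1$size, 8L)
  expect_equal(rep1$density, 0.25)
  expect_equal(rep1$mean_path_length, 4)
  expect_equal(rep1$mean_cluster_coefficient, 1 / 3)
  rep2 <- metrics_report(net, replicates = 5L, seed = 3)
  expect_identical(report_row(rep1), report_row(rep2))
  row <- report_row(rep1)
  expect_identical(names(row)[1:5],
                   c("order_total", "order_metabolites", "order_reactions",
                     "size", "density"))
})

test_that("report comparison reproduces printed fold ratios", {
  a <- manual_report(density = 1.771e-3)
  b <- manual_report(density = 9.896e-4)
  cmp <- compare_reports(a, b)
  expect_equal(cmp$fold, 1.79)
  expect_identical(cmp$greater, "a")
  paths <- compare_reports(manual_report(mean_path_length = 1.457e1),
                           manual_report(mean_path_length = 4.743))
  expect_equal(paths$fold, 3.07)
  same <- compare_reports(manual_report(density = 0.5),
                          manual_report(density = 0.5))
  expect_equal(same$fold, 1)
  expect_identical(same$greater, "equal")
  zero <- compare_reports(manual_report(density = 0.5),
                          manual_report(density = 0))
  expect_identical(zero$fold, Inf)
})

test_that("removing the top-degree metabolite cannot grow the network", {
  net <- build_network(toy_model("toyhub"), network_spec())
  deg <- degree_centrality(net)
  top <- deg$id[which.max(deg$degree_centrality)]
  top_met <- sub("@.*$", "", top)
  smaller <- apply_exclusions(net,
                              network_spec(excluded_metabolites = top_met))
  expect_lt(nrow(smaller$links), nrow(net$links))
})
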