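test_that("compartmental build follows the link rules", {
  mets <- list(metabolite("A"), metabolite("B"), metabolite("X"))
  comps <- list(compartment("c1"), compartment("c2"))
  irr <- reaction("R_IRR", rbind(participant("A", "reactant", "c1"),
                                 participant("B", "product", "c1")))
  rev <- reaction("R_REV", rbind(participant("A", "reactant", "c1"),
                                 participant("B", "product", "c1")),
                  reversible = TRUE)
  tra <- reaction("T_X", rbind(participant("X", "reactant", "c1"),
                               participant("X", "product", "c2")))
  spec <- network_spec(keep_largest_component = FALSE)
  net_irr <- build_compartmental(
    metabolic_model(mets, list(irr), comps, list()), spec)
  expect_identical(nrow(net_irr$nodes), 3L)
  expect_identical(nrow(net_irr$links), 2L)
  net_rev <- build_compartmental(
    metabolic_model(mets, list(rev), comps, list()), spec)
  expect_identical(nrow(net_rev$nodes), 3L)
  expect_identical(nrow(net_rev$links), 4L)
  # transport keeps per-compartment metabolite instances
  net_tra <- build_compartmental(
    metabolic_model(mets, list(tra), comps, list()), spec)
  expect_setequal(net_tra$nodes$id, c("X@c1", "X@c2", "T_X"))
  expect_identical(nrow(net_tra$links), 2L)
})

test_that("reversible-link rule sets reaction degree", {
  model <- toy_model("toy4")
  model$reactions[["R1"]]$reversible <- TRUE
  net <- build_network(model, network_spec())
  deg <- table(c(net$links$from, net$links$to))
  expect_identical(as.integer(deg[["R1"]]), 4L)  # 2 x participants
  expect_identical(as.integer(deg[["R2"]]), 2L)
})

test_that("non-compartmental build consolidates and drops transports", {
  model <- toy_model("toycomp")
  spec <- network_spec(compartmentalize = FALSE)
  net <- build_noncompartmental(model, spec)
  expect_setequal(net$nodes$id[net$nodes$type == "metabolite"],
                  c("A", "B", "C", "D"))
  # consensus reactions merge the two compartmental instances
  expect_identical(sum(net$nodes$type == "reaction"), 4L)
  r1 <- net$payload[["R1_c1"]]
  expect_setequal(r1$sources, c("R1_c1", "R1_c2"))
  expect_setequal(r1$reaction$genes, c("gene_R1_c1", "gene_R1_c2"))
  # no transport survived
  expect_false(any(startsWith(net$nodes$id, "T_")))
  # single-compartment model: consolidation is topology-identity
  toy4 <- toy_model("toy4")
  nc <- build_noncompartmental(toy4, spec)
  cc <- build_compartmental(toy4, network_spec())
  expect_identical(nrow(nc$nodes), nrow(cc$nodes))
  expect_identical(nrow(nc$links), nrow(cc$links))
})

test_that("redundant reactions merge only with identical reversibility", {
  mets <- list(metabolite("A"), metabolite("B"))
  comps <- list(compartment("c1"), compartment("c2"))
  mk <- function(id, cmp, rev) {
    reaction(id, rbind(participant("A", "reactant", cmp),
                       participant("B", "product", cmp)),
             reversible = rev)
  }
  spec <- network_spec(compartmentalize = FALSE,
                       keep_largest_component = FALSE)
  merged <- build_noncompartmental(metabolic_model(
    mets, list(mk("Ra", "c1", TRUE), mk("Rb", "c2", TRUE)), comps,
    list()), spec)
  expect_identical(sum(merged$nodes$type == "reaction"), 1L)
  mixed <- build_noncompartmental(metabolic_model(
    mets, list(mk("Ra", "c1", TRUE), mk("Rb", "c2", FALSE)), comps,
    list()), spec)
  expect_identical(sum(mixed$nodes$type == "reaction"), 2L)
})

test_that("exclusions remove listed and high-degree metabolites", {
  hub_net <- build_network(toy_model("toyhub"),
                           network_spec(degree_threshold = 3L))
  toy4_net <- toy4_network()
  expect_identical(hub_net$nodes, toy4_net$nodes)
  expect_identical(hub_net$links, toy4_net$links)
  # identity when nothing is named
  plain <- build_compartmental(toy_model("toy4"), network_spec())
  expect_identical(apply_exclusions(plain, network_spec()), plain)
  # threshold 1 on toy4 removes every metabolite node (degree 2 each)
  bare <- apply_exclusions(plain, network_spec(degree_threshold = 1L))
  expect_identical(sum(bare$nodes$type == "metabolite"), 0L)
  expect_identical(nrow(bare$links), 0L)
  # size strictly decreases when a named node existed
  name_hit <- apply_exclusions(plain,
                               network_spec(excluded_metabolites = "A"))
  expect_lt(nrow(name_hit$links), nrow(plain$links))
  expect_warning(apply_exclusions(plain, network_spec(
    excluded_metabolites = "NOT_THERE")), "not in network")
})

test_that("largest component keeps the biggest weak component", {
  mets <- lapply(c("A", "B", "C", "D", "E"), metabolite)
  rxns <- list(
    reaction("R1", rbind(participant("A", "reactant", "c1"),
                         participant("B", "product", "c1"))),
    reaction("R2", rbind(participant("B", "reactant", "c1"),
                         participant("C", "product", "c1"))),
    reaction("R3", rbind(participant("D", "reactant", "c1"),
                         participant("E", "product", "c1"))))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  net <- build_compartmental(model,
                             network_spec(keep_largest_component = FALSE))
  big <- largest_component(net)
  expect_setequal(big$nodes$id, c("A@c1", "B@c1", "C@c1", "R1", "R2"))
  expect_identical(largest_component(big)$nodes, big$nodes)
})

test_that("compartmental vs non-compartmental order/size direction holds", {
  model <- toy_model("toycomp")
  comp <- build_network(model, network_spec())
  nonc <- build_network(model, network_spec(compartmentalize = FALSE))
  expect_lte(nrow(nonc$nodes), nrow(comp$nodes))
  expect_lte(nrow(nonc$links), nrow(comp$links))
})

test_that("proximity queries traverse the stated direction and depth", {
  net <- toy4_network()
  expect_identical(query_proximity(net, "A@c1", 0)$nodes$id, "A@c1")
  near <- query_proximity(net, "A@c1", 1, "both")
  expect_setequal(near$nodes$id, c("A@c1", "R1", "R4"))
  out1 <- query_proximity(net, "A@c1", 1, "out")
  expect_setequal(out1$nodes$id, c("A@c1", "R1"))
  # saturation at >= diameter recovers the whole component
  all_net <- query_proximity(net, "A@c1", 8, "both")
  expect_setequal(all_net$nodes$id, net$nodes$id)
  expect_error(query_proximity(net, "ZZZ", 1), "unknown focus")
})

test_that("connection queries unite pairwise shortest paths", {
  net <- toy4_network()
  both_ways <- query_connection(net, c("A@c1", "C@c1"))
  expect_setequal(both_ways$nodes$id, net$nodes$id)  # whole cycle
  # adjacent metabolite/reaction pair on a chain: just the connecting link
  chain <- chain_network(2L)
  adj <- query_connection(chain, c("M1@c1", "R1"))
  expect_setequal(adj$nodes$id, c("M1@c1", "R1"))
  expect_identical(nrow(adj$links), 1L)
  # supergraph of each pairwise query
  trio <- query_connection(net, c("A@c1", "B@c1", "C@c1"))
  pair <- query_connection(net, c("A@c1", "B@c1"))
  expect_true(all(pair$nodes$id %in% trio$nodes$id))
  expect_error(query_connection(net, "A@c1"), "at least two")
})

test_that("disconnected targets are reported, not dropped", {
  mets <- lapply(c("A", "B", "C", "D"), metabolite)
  rxns <- list(
    reaction("R1", rbind(participant("A", "reactant", "c1"),
                         participant("B", "product", "c1"))),
    reaction("R2", rbind(participant("C", "reactant", "c1"),
                         participant("D", "product", "c1"))))
  model <- metabolic_model(mets, rxns, list(compartment("c1")), list())
  net <- build_compartmental(model,
                             network_spec(keep_largest_component = FALSE))
  res <- query_connection(net, c("A@c1", "C@c1"))
  expect_setequal(res$nodes$id, c("A@c1", "C@c1"))
  expect_match(res$provenance, "unreachable")
})

test_that("every build preserves bipartiteness", {
  for (nm in c("toy4", "toyhub", "toycomp")) {
    for (compart in c(TRUE, FALSE)) {
      net <- build_network(toy_model(nm),
                           network_spec(compartmentalize = compart))
      type <- stats::setNames(net$nodes$type, net$nodes$id)
      expect_true(all(type[net$links$from] != type[net$links$to]))
    }
  }
})

test_that("network exports round-trip topology", {
  net <- toy4_network()
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_identical(back$nodes[order(back$nodes$id), ]$type,
                   net$nodes$type)
  expect_identical(back$links[order(back$links$from, back$links$to), ],
                   net$links)
  nl <- withr::local_tempfile(fileext = ".json")
  export_network(net, nl, "node_link_text")
  back2 <- import_network(nl, "node_link_text")
  expect_identical(back2$links, net$links)
  # cytoscape tables: toy4 has 8 node rows and 8 edge rows
  prefix <- withr::local_tempfile()
  export_network(net, prefix, "cytoscape_tables")
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"))
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_identical(nrow(nodes), 8L)
  expect_identical(nrow(edges), 8L)
})
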