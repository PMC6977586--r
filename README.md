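# metnets

Tools for studying metabolism as a **directional bipartite network** of
metabolite and reaction nodes, and for interpreting metabolomic
measurements in that context.

Genome-scale metabolic models are large and densely connected, which makes
them hard to use directly as context for metabolomic experiments. Two
modeling constraints dominate the structure of the resulting networks:

* **Compartmentalization** — whether each (metabolite, organelle) pair is a
  distinct node (with transport reactions between compartments), or
  chemically identical instances consolidate into consensus nodes and pure
  transport reactions drop out.
* **Hub exclusion** — whether prolifically connected "currency" metabolites
  (water, proton, coenzyme A, nucleoside phosphates, ...) keep their nodes,
  or are excluded by name lists and/or a degree threshold so that subtler
  pathway structure becomes visible.

`metnets` curates a model, builds networks under these constraints, and
quantifies their structure with single-mode bipartite metrics:

* density `d = |E| / (2·|M|·|R|)` for `|M|` metabolite and `|R|` reaction
  nodes and `|E|` directed links;
* normalized single-mode degree and betweenness centralities, and their
  Freeman-style centralizations `Σ(c_max − c_i) / (n − 1)`;
* mean directed shortest-path length `L` over same-set pairs (counted in
  links);
* pairwise-Jaccard cluster coefficients
  `c_u = mean_v |N(u)∩N(v)| / |N(u)∪N(v)|` over second-order neighbors `v`;
* the small-world coefficient `σ = (C/C_rand) / (L/L_rand)` against seeded
  random bipartite ensembles matched in part sizes and link count;
* degree assortativity `r` of the directed unipartite projection.

For metabolomic studies, the package normalizes analyte signals to each
sample's total, resolves redundant analytes by the index of dispersion,
computes log2 fold changes (case/control) with Student t-tests (paired or
independent), matches analytes to metabolites by PubChem references, and
searches the annotated network for connected clusters enriched in small
p-values, scored by the Stouffer aggregate `z_A = Σ z_i / √k` with
`z = Φ⁻¹(1 − p)`.

## Worked example

The bundled `toyhub` fixture is a four-metabolite cycle
(A→B→C→D→A) in which a fifth metabolite `H` is a by-product of all four
reactions — a miniature metabolite hub.

```r
library(metnets)
model    <- toy_model("toyhub")
with_hub <- build_network(model, network_spec())
no_hub   <- build_network(model, network_spec(degree_threshold = 3))

rep_hub <- metrics_report(with_hub, replicates = 10, seed = 1)
rep_no  <- metrics_report(no_hub,  replicates = 10, seed = 1)
compare_reports(rep_hub, rep_no, "with_hub", "no_hub")[, c("metric", "fold", "greater")]
```

```
                       metric fold  greater
1                 order_total 1.12 with_hub
2           order_metabolites 1.25 with_hub
3             order_reactions 1.00    equal
4                        size 1.50 with_hub
5                     density 1.20 with_hub
6       centralization_degree  Inf with_hub
7  centralization_betweenness  Inf with_hub
8            mean_path_length 1.14   no_hub
9    mean_cluster_coefficient 1.23 with_hub
10                      sigma 1.30 with_hub
11              assortativity 1.00    equal
```

Even on this toy, excluding the hub shrinks the network (1.50-fold fewer
links), removes all centralization (the remaining cycle is perfectly
regular, so the hub accounted for every deficit), and lengthens mean paths
— the qualitative signature hub exclusion has on real metabolic networks.
The per-node table and influence ranks (mean of degree and betweenness
ranks) are in `rep_no$node_centralities` and `rep_no$ranks`.

The full pipeline — curation, network definition, metrics, measurement
processing, integration, cluster search — runs from one YAML configuration
(template in `inst/extdata/default_config.yaml`):

```r
cfg <- default_config(output_dir = "out", seed = 1)
cfg$simulate$effects <- list(affected = list(A = 1.5, C = -1.5),
                             n_per_group = 10, paired = TRUE)
run_pipeline(cfg, c("simulate", "curate", "network", "metrics",
                    "measure", "integrate", "clusters"))
```

or from a shell via the thin wrapper `inst/scripts/metnet`. Reruns with
the same configuration and seed are byte-identical.

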