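---
title: "Defining and analyzing bipartite metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining and analyzing bipartite metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metnets)
```

# The representation

`metnets` represents metabolism as a **directional bipartite graph**: one
node set for metabolites (small molecules), one for reactions (chemical
events carrying gene and process annotation), and directed, unweighted
links reactant→reaction and reaction→product. Reversible reactions link
every participant in both directions. All links are unweighted: reaction
weights (mass conversion, flux) are condition-specific and hard to
measure, so keeping links weightless makes network definitions comparable.

Three constraints tune the definition; each is a field of
`network_spec()`:

1. **Compartmentalization** (`compartmentalize`). `TRUE` keeps one
   metabolite node per (metabolite, compartment) pair and retains
   transport reactions; `FALSE` consolidates compartmental instances into
   consensus nodes, merges chemically redundant reactions (identical
   participant multisets after dropping compartments *and* identical
   reversibility — a reversible and an irreversible version of the same
   chemistry stay distinct), and excludes pure transport reactions, which
   are meaningless without compartments. Reactions that both transport and
   convert are kept by default (`exclude_both_transport` drops them too).
2. **Filters** (`compartment_filter`, `process_filter`). A reaction passes
   a compartment filter only when *every* participant compartment is in
   the set (so a "mitochondrion" network stays inside the mitochondrion),
   and passes a process filter when *any* of its processes is in the set.
   The defaults apply no filter.
3. **Metabolite exclusion** (`excluded_metabolites`,
   `degree_threshold`). Named metabolites (hub lists) lose their nodes and
   links; then metabolite nodes whose total link count **in the
   pre-exclusion network** exceeds the degree threshold (default
   configuration: 50) are removed. Measuring degree before any exclusion
   makes list-based and degree-based exclusion commute. Reactions keep
   their full participant payload, so exclusion is a view decision, not a
   data loss. Whether reversible doubling counts toward the threshold is a
   genuine ambiguity; here it does (degree is the link count in the built
   network), and the threshold is configuration, not a constant.

After exclusion the network is restricted to its largest **weakly**
connected component (`keep_largest_component`, default on). Weak
connectivity is the deliberate choice: strong connectivity would discard
most of a directed metabolic graph, since many pathways are one-way.
Component ties break by the lexicographically smallest member identifier;
all orderings in the package are lexicographic so outputs are
deterministic.

# Model curation

Models arrive in the package's native JSON dialect (`read_model`,
`write_model`; write∘read is the identity and re-serialization is
byte-stable) or as a strict SBML Level 2 Version 4 subset (compartments,
species, reactions, stoichiometry, reversibility; anything else is ignored
with a notice). Curation steps:

* `classify_reaction_behavior()` labels each reaction *conversion*
  (reactant and product metabolite multisets differ), *transport* (some
  metabolite crosses compartments unchanged), or *both*. Identity is
  compared on consensus metabolite identifiers, not formulas, since
  consensus identifiers already encode chemistry.
* `filter_simulation_artifacts()` removes reactions that only serve flux
  simulation — boundary exchanges (any participant in the configured
  boundary compartment) and name-pattern matches (defaults: `biomass`,
  `protein (assembly|degradation)`). The patterns ship in the visible
  configuration template rather than being hard-coded truth, because
  real models vary in naming and record-level curation cannot be
  replicated generically. Orphaned metabolites are dropped afterwards;
  the operation is idempotent.
* `assign_transport_processes()` gives transport reactions membership in
  every process whose member reactions span ≥ 2 compartments and which
  shares ≥ 1 metabolite and ≥ 1 compartment with the transport reaction.
* `summarize_curation()` reports entity counts and reference coverage
  (metabolites with HMDB/PubChem, reactions with gene/enzyme references)
  to two decimals.

# Single-mode metrics

"Single-mode" means relative to one bipartite node set; reported values
default to metabolite mode. Conventions, each of which the test suite
checks against an independent brute-force oracle on ≤ 20-node fixtures:

* **Density** `size / (2·|M|·|R|)` — the directed bipartite maximum has a
  link in each direction for every (metabolite, reaction) pair.
* **Degree centrality** `(in + out) / (2·|opposite set|)`.
* **Betweenness centrality**: raw directed betweenness over ordered
  source–target pairs (fraction of shortest paths through the node),
  normalized by the Borgatti–Everett bipartite maximum for the node's
  set. That maximum is stated for unordered pairs, so the denominator is
  doubled for ordered-pair counting; the formula is documented in the
  source. Absolute normalized values are a convention — comparisons
  across networks, not the constants, carry the science.
* **Centralization** `Σ(c_max − c_i)/(n − 1)` on already-normalized
  centralities: 0 when all nodes are equal, 1 for the one-node-at-1
  pattern. The `n − 1` denominator is this package's convention,
  documented rather than inherited.
* **Cluster coefficient**: pairwise Jaccard overlap of undirected
  neighborhoods, averaged over each node's second-order (same-set)
  neighbors; nodes without second-order neighbors score 0.
* **Mean path length**: mean directed shortest-path length over all
  ordered same-set pairs with a path, counted in links (so same-set
  distances are even, ≥ 2). Unreachable pairs are excluded from the mean
  and their count reported alongside — averaging only over reachable
  pairs keeps the statistic defined on weakly connected directed graphs.
* **Small-world σ** `(C/C_rand)/(L/L_rand)`: the ensemble is
  `random_bipartite()` draws matched in **both** part sizes and link
  count (matching node counts alone would make `C_rand`/`L_rand`
  incomparable), 10 replicates by default, seed required. σ of a random
  network against its own ensemble concentrates near 1; modular networks
  with short paths score ≫ 1.
* **Assortativity**: the bipartite network is projected to a directed
  unipartite graph (`u → w` iff some reaction receives a link from `u`
  and sends one to `w`; self-links from reversible reactions are dropped,
  as in standard bipartite projection), then Pearson degree correlation
  over projected links. A constant degree sequence has no defined
  correlation; the package returns 0 with a `degenerate` flag instead of
  `NaN`.
* **Influence ranks**: descending ranks of degree and betweenness
  centrality (average rank for ties), combined as their mean.

# Measurement processing

Studies are analyte × sample tables with `case`/`control` groups and
optional pairing. The pipeline is: coverage filter (an analyte must be
measured in ≥ 50% of samples *in each group* — the threshold is
configurable since "adequate coverage" is a judgment), redundancy
resolution (among analytes mapping to one metabolite, keep the one with
the smallest control-group variance-to-mean ratio, sample variance with
denominator `n − 1`; a zero control mean flags dispersion infinite and
deprioritizes the analyte; ties break lexicographically), total-signal
normalization (each value divided by its sample's total over measured
analytes — idempotent and scale-invariant), then group comparison:

* paired: per-pair `log2(case/control)` on complete pairs, mean reported,
  two-sided one-sample t-test on the per-pair log ratios;
* independent: `log2(mean_case/mean_control)`, two-sided two-sample
  t-test on the normalized values, equal-variance by default (Welch by
  `var_equal = FALSE`).

Case is always the dividend. Missing values are excluded pairwise.
Analytes where a non-positive value would enter a logarithm are excluded
with a log entry. Raw p-values are reported without multiple-testing
correction, matching the exploratory role of the volcano plot;
`stats::p.adjust` composes trivially for users who want an FDR column.

Analytes match metabolites by intersecting normalized PubChem reference
sets (trim whitespace, strip `CID` prefixes and leading zeros). An
analyte matching several metabolites is reported as ambiguous and left
unassigned — expert critique of matches cannot be automated, so the
package surfaces the ambiguity instead of guessing.

# Cluster detection

Per-metabolite p-values become `z = Φ⁻¹(1 − p)` (floored at −10 so `p = 1`
stays finite); a candidate cluster with `k` scored metabolites scores
`z_A = Σ z_i / √k`. `search_modules()` grows one candidate from every
scored metabolite: repeatedly add the scored metabolite within the search
depth (default 2 links) whose addition maximally increases `z_A`,
together with one shortest connecting path (unscored connector reactions
never change `z_A`, so they ride along with the metabolite that needs
them), until no addition improves the score. This deterministic greedy
hill-climb is a deliberate replacement for the simulated-annealing search
of the classic active-modules method: reproducible, desk-scale, and
adequate for producing raw candidate clusters. Candidates are ranked by
`z_A` and emitted per overlap threshold (defaults 0.25/0.50/0.75, up to
25 clusters each), suppressing candidates whose Jaccard overlap with an
already-emitted cluster exceeds the threshold.

`filter_clusters()` applies the mechanical curation rules: ≤ 3 reaction
nodes, a measured majority among each reaction's in-cluster participant
metabolites, and both accumulation and depletion present. The manual
biological curation applied to final published clusters (excluding
unmeasured metabolites, adding relevant neighbors) is out of scope by
design; only the stated mechanical filters are automated. No Monte-Carlo
background calibration of `z_A` is applied by default — the top-cluster
score under a global null is positively biased by selection, and the test
suite checks the separation property (planted-signal scores exceed the
null distribution's 95th percentile) rather than an absolute scale.

# Synthetic data

`generate_toy_model()` builds linear or cyclic pathways, replicated
across compartments and joined by transport reactions, with optional hub
metabolites appended as extra products — the canonical motifs that the
network definitions react to. Named fixtures: `toy4` (4-metabolite
cycle), `toyhub` (`toy4` + hub of degree 4), `toycomp` (duplicated
pathway + transports). `generate_measurements()` draws lognormal signals,
`2^(baseline + effect + noise)`, with baseline mean 7 and SD 1 on the
log2 scale (raw signals around 2^7 spanning roughly an order of
magnitude, typical of relative-abundance metabolomics) and measurement
noise SD 0.25 — at 10 pairs this gives a dependent t-test power near 0.9
for a 2-fold effect, so recovery tests are informative without being
trivial. Paired studies share per-pair baselines.

What the generator does *not* emulate: heteroscedastic and
intensity-dependent noise, missingness that correlates with abundance,
batch effects, and correlated analytes. Passing tests therefore
demonstrate correctness of the computations and calibration under clean
lognormal conditions, not robustness to every artifact of real
spectrometry data.

Problem sizes used in the checked properties: type-I error is estimated
on 1,000 analytes at n = 10 per group; σ self-consistency on a
30 + 30-node random network against 50 ensemble replicates; planted-module
recovery on a 20-metabolite ring over 20 seeded replicates. These sizes
give stable statistics at interactive runtimes.

# Numerical and degenerate-input conventions

* All randomness is seeded; generators and the pipeline are pure
  functions of their configuration, and pipeline reruns are
  byte-identical.
* Duplicate links (same endpoints and direction, e.g. a metabolite
  appearing twice as reactant) collapse to one; stoichiometry stays in
  the reaction payload.
* A degenerate reaction that is neither transport nor conversion reports
  `conversion`.
* Both groups constant in a comparison: p = 1 if equal, else clamped to
  a tiny positive constant (1e-300) rather than 0 so downstream quantile
  scores stay defined.
* Empty networks export headers only; an empty network error from a
  filter configuration names the filters.

# Known limitations

* The SBML reader is a subset reader; models relying on `fbc` extensions,
  groups, or annotation-embedded identifiers need conversion to the
  native format first.
* Betweenness and centralization normalizations are documented
  conventions; absolute values are not comparable across tools that chose
  different denominators, fold comparisons are.
* The greedy module search can absorb high-scoring background nodes
  adjacent to a true cluster and, unlike annealing, cannot escape local
  optima; overlap suppression mitigates duplicated output but not local
  optimality.
* Analyte matching is only as good as the PubChem reference coverage on
  both sides.
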