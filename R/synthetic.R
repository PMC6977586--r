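# Synthetic model and measurement generators. Toy models emulate the
# canonical motifs of metabolic network definitions -- linear and cyclical
# pathways, compartmental duplication joined by transport, and prolific
# metabolite hubs -- so every pipeline stage is testable without external
# data. Measurement simulation draws lognormal abundances with
# multiplicative (2^effect) group differences, matching the pipeline's
# base-2 logarithmic analysis.

#' Specification for a toy metabolic model
#'
#' @param n_pathways Number of parallel pathways.
#' @param pathway_length Metabolites per pathway.
#' @param cyclic Logical; close each pathway into a cycle.
#' @param n_compartments Number of compartments; pathways are duplicated in
#'   each.
#' @param transport_pairs Number of leading pathway metabolites joined
#'   between compartments 1 and 2 by transport reactions (requires
#'   `n_compartments >= 2`).
#' @param hub_metabolites Named integer vector: hub identifier -> target
#'   degree (the hub is added as an extra product to that many reactions).
#' @param seed Integer seed (mandatory; generation is deterministic).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_pathways = 1L, pathway_length = 4L, cyclic = TRUE,
                     n_compartments = 1L, transport_pairs = 0L,
                     hub_metabolites = integer(), seed = 1L) {
  stopifnot(n_pathways >= 0, pathway_length >= 2, n_compartments >= 1,
            transport_pairs >= 0, !missing(seed) || TRUE)
  if (transport_pairs > 0 && n_compartments < 2L) {
    stop("transport pairs require >= 2 compartments", call. = FALSE)
  }
  structure(list(n_pathways = as.integer(n_pathways),
                 pathway_length = as.integer(pathway_length),
                 cyclic = isTRUE(cyclic),
                 n_compartments = as.integer(n_compartments),
                 transport_pairs = as.integer(transport_pairs),
                 hub_metabolites = hub_metabolites,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

# Synthetic PubChem references: metabolite index -> "9<index>" in a
# reserved-looking range so match_analytes can operate on toy data.
toy_pubchem <- function(index) as.character(90000L + index)

#' Generate a toy metabolic model
#'
#' Deterministic given the spec (including its seed). Metabolites are
#' labelled `M<p>_<i>` (pathway p, position i), reactions `R<p>_<i>`,
#' compartments `c1..cK`, and each pathway belongs to process `P<p>`.
#' Transport reactions `T_<metabolite>` move a metabolite unchanged from
#' compartment `c1` to `c2`. Hubs are appended as extra products of the
#' first reactions (in identifier order) until the requested degree is met.
#'
#' @param spec A [toy_spec()].
#' @return A validated `metabolic_model` with synthetic PubChem references.
#' @export
generate_toy_model <- function(spec = toy_spec()) {
  comps <- lapply(seq_len(spec$n_compartments), function(k)
    compartment(paste0("c", k), paste("compartment", k)))
  procs <- lapply(seq_len(spec$n_pathways), function(p)
    process(paste0("P", p), paste("pathway", p)))
  mets <- list()
  rxns <- list()
  idx <- 0L
  for (p in seq_len(spec$n_pathways)) {
    mids <- sprintf("M%d_%d", p, seq_len(spec$pathway_length))
    for (m in mids) {
      idx <- idx + 1L
      mets[[m]] <- metabolite(m, name = paste("metabolite", m),
                              references = list(pubchem = toy_pubchem(idx)))
    }
    n_rxn <- if (spec$cyclic) spec$pathway_length
    else spec$pathway_length - 1L
    for (k in seq_len(spec$n_compartments)) {
      cmp <- paste0("c", k)
      for (i in seq_len(n_rxn)) {
        j <- if (i == spec$pathway_length) 1L else i + 1L
        rid <- sprintf("R%d_%d%s", p, i,
                       if (spec$n_compartments > 1L) paste0("_", cmp)
                       else "")
        rxns[[rid]] <- reaction(
          rid, rbind(participant(mids[[i]], "reactant", cmp),
                     participant(mids[[j]], "product", cmp)),
          processes = paste0("P", p),
          genes = paste0("gene_", rid))
      }
    }
    if (spec$transport_pairs > 0L) {
      for (i in seq_len(min(spec$transport_pairs, spec$pathway_length))) {
        rid <- paste0("T_", mids[[i]])
        rxns[[rid]] <- reaction(
          rid, rbind(participant(mids[[i]], "reactant", "c1"),
                     participant(mids[[i]], "product", "c2")))
      }
    }
  }
  hubs <- spec$hub_metabolites
  for (h in names(hubs)) {
    idx <- idx + 1L
    mets[[h]] <- metabolite(h, name = paste("hub", h),
                            references = list(pubchem = toy_pubchem(idx)))
    target <- hubs[[h]]
    conv <- sort(names(rxns)[!startsWith(names(rxns), "T_")])
    if (target > length(conv)) {
      stop("infeasible hub degree ", target, " for ", h, ": only ",
           length(conv), " reactions available", call. = FALSE)
    }
    for (rid in conv[seq_len(target)]) {
      rxn <- rxns[[rid]]
      cmp <- rxn$participants$compartment[[1L]]
      rxn$participants <- rbind(rxn$participants,
                                participant(h, "product", cmp))
      rxns[[rid]] <- rxn
    }
  }
  model <- metabolic_model(unname(mets), unname(rxns), comps, procs)
  classify_model_behaviors(model)
}

#' Named toy fixtures
#'
#' * `toy4`: 4-metabolite irreversible cycle (A -> B -> C -> D -> A via
#'   R1..R4) in one compartment.
#' * `toyhub`: `toy4` plus metabolite `H` as an extra product of all four
#'   reactions (degree 4).
#' * `toycomp`: the `toy4` pathway duplicated in compartments `c1` and `c2`
#'   and joined by four transport reactions `T_A`..`T_D`.
#'
#' @param name One of `"toy4"`, `"toyhub"`, `"toycomp"`.
#' @return A `metabolic_model`.
#' @export
toy_model <- function(name = c("toy4", "toyhub", "toycomp")) {
  name <- match.arg(name)
  relabel <- c(M1_1 = "A", M1_2 = "B", M1_3 = "C", M1_4 = "D")
  base_spec <- switch(name,
    toy4 = toy_spec(),
    toyhub = toy_spec(hub_metabolites = c(H = 4L)),
    toycomp = toy_spec(n_compartments = 2L, transport_pairs = 4L))
  model <- generate_toy_model(base_spec)
  rename <- function(id) {
    for (old in names(relabel)) {
      id <- gsub(old, relabel[[old]], id, fixed = TRUE)
    }
    id <- gsub("R1_([0-9])", "R\\1", id)
    id
  }
  mets <- lapply(model$metabolites, function(m) {
    m$identifier <- rename(m$identifier)
    m$name <- rename(m$name)
    m
  })
  rxns <- lapply(model$reactions, function(r) {
    r$identifier <- rename(r$identifier)
    r$name <- rename(r$name)
    r$genes <- unname(vapply(r$genes, rename, ""))
    r$participants$metabolite <- unname(vapply(r$participants$metabolite,
                                               rename, ""))
    r
  })
  metabolic_model(unname(mets), unname(rxns), model$compartments,
                  model$processes)
}

#' Specification of simulated measurement effects
#'
#' @param affected Named numeric vector: metabolite identifier -> log2
#'   effect size applied to the case group.
#' @param n_per_group Samples per group (>= 2); for paired studies, the
#'   number of pairs.
#' @param paired Logical; paired samples share a per-pair baseline.
#' @param sigma Measurement noise SD on the log2 scale (default 0.25).
#' @param baseline_mu,baseline_sigma Lognormal baseline abundance
#'   parameters on the log2 scale (defaults 7 and 1: typical raw signals
#'   around 2^7 spanning roughly an order of magnitude).
#' @param seed Integer seed (mandatory).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(affected = numeric(), n_per_group = 10L,
                        paired = FALSE, sigma = 0.25, baseline_mu = 7,
                        baseline_sigma = 1, seed = 1L) {
  stopifnot(n_per_group >= 2, sigma > 0)
  structure(list(affected = affected, n_per_group = as.integer(n_per_group),
                 paired = isTRUE(paired), sigma = sigma,
                 baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Simulate a measurement study from a model
#'
#' One analyte per model metabolite, PubChem references copied from the
#' model so [match_analytes()] succeeds. Signals are lognormal:
#' `2^(baseline + noise)` for controls and `2^(baseline + effect + noise)`
#' for cases, where affected metabolites carry their configured log2
#' effect. Paired studies share the per-pair baseline between case and
#' control, emulating per-patient sampling. Deterministic given the spec.
#'
#' @param model A `metabolic_model`.
#' @param effects An [effect_spec()].
#' @return A `measurement_study`.
#' @export
generate_measurements <- function(model, effects = effect_spec()) {
  bad <- setdiff(names(effects$affected), names(model$metabolites))
  if (length(bad)) {
    stop("affected metabolites not in model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(effects$seed)
  n <- effects$n_per_group
  met_ids <- names(model$metabolites)
  n_a <- length(met_ids)
  case_ids <- sprintf("case_%02d", seq_len(n))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(n))
  samples <- data.frame(identifier = c(case_ids, ctrl_ids),
                        group = rep(c("case", "control"), each = n),
                        stringsAsFactors = FALSE)
  if (effects$paired) samples$pair <- rep(sprintf("p%02d", seq_len(n)), 2L)
  effect <- stats::setNames(rep(0, n_a), met_ids)
  effect[names(effects$affected)] <- effects$affected
  baseline_case <- matrix(stats::rnorm(n_a * n, effects$baseline_mu,
                                       effects$baseline_sigma),
                          nrow = n_a)
  baseline_ctrl <- if (effects$paired) baseline_case
  else matrix(stats::rnorm(n_a * n, effects$baseline_mu,
                           effects$baseline_sigma), nrow = n_a)
  noise_case <- matrix(stats::rnorm(n_a * n, 0, effects$sigma), nrow = n_a)
  noise_ctrl <- matrix(stats::rnorm(n_a * n, 0, effects$sigma), nrow = n_a)
  signals <- cbind(2^(baseline_case + effect + noise_case),
                   2^(baseline_ctrl + noise_ctrl))
  dimnames(signals) <- list(met_ids, c(case_ids, ctrl_ids))
  analytes <- data.frame(
    identifier = paste0("analyte_", met_ids),
    name = vapply(model$metabolites, `[[`, "", "name"),
    pubchem = vapply(model$metabolites, function(m)
      paste(m$references$pubchem, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(signals) <- analytes$identifier
  measurement_study(samples, analytes, signals, paired = effects$paired)
}
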