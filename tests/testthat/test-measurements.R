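make_study <- function(signals, paired = FALSE, pubchem = NULL) {
  n_a <- nrow(signals)
  n_s <- ncol(signals)
  samples <- data.frame(
    identifier = colnames(signals),
    group = rep(c("case", "control"), each = n_s / 2),
    stringsAsFactors = FALSE)
  if (paired) samples$pair <- rep(paste0("p", seq_len(n_s / 2)), 2)
  analytes <- data.frame(identifier = rownames(signals),
                         name = rownames(signals),
                         pubchem = pubchem %||%
                           as.character(seq_len(n_a)),
                         stringsAsFactors = FALSE)
  measurement_study(samples, analytes, signals, paired = paired)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("measurement TSV dialect round-trips including missing cells", {
  sig <- matrix(c(1, 2, NA, 4, 5, 6, 7, 8), nrow = 2, byrow = TRUE,
                dimnames = list(c("a1", "a2"),
                                c("s1", "s2", "s3", "s4")))
  study <- make_study(sig, paired = TRUE, pubchem = c("123;456", "789"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(study, path)
  back <- read_measurements(path)
  expect_identical(back$samples, study$samples)
  expect_identical(back$analytes$pubchem, study$analytes$pubchem)
  expect_equal(back$signals, study$signals)
  expect_true(back$paired)
  expect_true(is.na(back$signals["a1", "s3"]))
})

test_that("group labels and pairing are validated", {
  sig <- matrix(1:4, 2, 2,
                dimnames = list(c("a1", "a2"), c("s1", "s2")))
  samples <- data.frame(identifier = c("s1", "s2"),
                        group = c("case", "treated"))
  analytes <- data.frame(identifier = c("a1", "a2"), name = c("x", "y"),
                         pubchem = c("1", "2"))
  expect_error(measurement_study(samples, analytes, sig), "case")
  samples$group <- c("case", "control")
  expect_error(measurement_study(samples, analytes, sig, paired = TRUE),
               "pair")
})

test_that("coverage filter drops analytes thin in either group", {
  sig <- matrix(c(1, NA, NA, NA, NA, NA, NA, NA,
                  1, 2, 3, 4, NA, 5, 6, 7,
                  1, 2, 3, 4, 5, 6, 7, 8),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("sparse_case", "ok", "full"),
                                paste0("s", 1:8)))
  # columns 1:4 case, 5:8 control; "sparse_case" has 1/4 in case group,
  # and 0/4 in the control group
  study <- make_study(sig)
  kept <- suppressMessages(filter_coverage(study, 0.5))
  expect_setequal(kept$analytes$identifier, c("ok", "full"))
  # full matrix is untouched
  full <- make_study(sig[3, , drop = FALSE])
  expect_identical(suppressMessages(filter_coverage(full)), full)
  # 1 of 4 controls measured at threshold 0.5: dropped
  sig2 <- matrix(c(1, 2, 3, 4, NA, NA, NA, 5), nrow = 1,
                 dimnames = list("thin_ctrl", paste0("s", 1:8)))
  expect_identical(nrow(suppressMessages(
    filter_coverage(make_study(sig2), 0.5))$analytes), 0L)
})

test_that("redundancy resolves to the least-dispersed analyte", {
  # control values (2,2,2): dispersion 0; (1,3, plus filler): sample
  # variance 2 over mean 2 = 1
  sig <- matrix(c(9, 9, 9, 2, 2, 2,
                  9, 9, 9, 1, 3, 2),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("steady", "noisy"), paste0("s", 1:6)))
  study <- make_study(sig)
  expect_equal(dispersion_index(study, "steady"), 0)
  sig_n <- matrix(c(9, 9, 1, 3), nrow = 1,
                  dimnames = list("noisy", paste0("s", 1:4)))
  expect_equal(dispersion_index(make_study(sig_n), "noisy"), 1)
  key <- c(steady = "MET", noisy = "MET")
  out <- resolve_redundancy(study, key)
  expect_identical(out$analytes$identifier, "steady")
  # no redundancy: identity
  out2 <- resolve_redundancy(study, c(steady = "M1", noisy = "M2"))
  expect_identical(out2$analytes, study$analytes)
  # exact ties break lexicographically
  sig3 <- matrix(rep(c(5, 5, 5), 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("b_twin", "a_twin"), paste0("s", 1:6)))
  out3 <- resolve_redundancy(make_study(sig3), c(b_twin = "M", a_twin = "M"))
  expect_identical(out3$analytes$identifier, "a_twin")
})

test_that("total-signal normalization is idempotent and scale-invariant", {
  study <- make_study(matrix(c(2, 3, 5, 4, 6, 10, 1, 1, 1, 1, 1, 1),
                             nrow = 3,
                             dimnames = list(c("a", "b", "c"),
                                             paste0("s", 1:4))))
  norm <- normalize_total_signal(study)
  expect_equal(norm$signals[, "s1"], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(colSums(norm$signals), c(s1 = 1, s2 = 1, s3 = 1, s4 = 1))
  expect_equal(normalize_total_signal(norm)$signals, norm$signals)
  # scaling one sample changes nothing downstream
  scaled <- study
  scaled$signals[, "s1"] <- scaled$signals[, "s1"] * 1000
  expect_equal(normalize_total_signal(scaled)$signals, norm$signals)
  # missing values are excluded from totals
  miss <- study
  miss$signals["a", "s1"] <- NA
  expect_equal(normalize_total_signal(miss)$signals["b", "s1"], 3 / 8)
})

test_that("paired comparison reproduces hand-computed fold change and p", {
  sig <- matrix(c(4, 8, 2, 2), nrow = 1,
                dimnames = list("a1", c("s1", "s2", "s3", "s4")))
  study <- make_study(sig, paired = TRUE)  # pairs (4,2) and (8,2)
  comp <- compare_groups(study)
  expect_equal(comp$log2_fold_change, 1.5)  # mean of log2(2)=1, log2(4)=2
  expect_equal(comp$p_value, 2 * stats::pt(-3, df = 1), tolerance = 1e-12)
  expect_identical(comp$n_pairs, 2L)
})

test_that("unpaired comparison uses group means and the t-test", {
  sig <- matrix(c(8, 8, 8, 2, 2, 2), nrow = 1,
                dimnames = list("a1", paste0("s", 1:6)))
  comp <- compare_groups(make_study(sig))
  expect_equal(comp$log2_fold_change, 2)
  # identical groups: log2FC 0, p 1
  flat <- matrix(c(5, 6, 5, 6), nrow = 1,
                 dimnames = list("a1", paste0("s", 1:4)))
  comp2 <- compare_groups(make_study(flat))
  expect_equal(comp2$log2_fold_change, 0)
  expect_equal(comp2$p_value, 1)
  # agreement with stats::t.test directly
  set.seed(11)
  x <- matrix(rlnorm(12), nrow = 1, dimnames = list("a1", paste0("s", 1:12)))
  comp3 <- compare_groups(make_study(x))
  expect_equal(comp3$p_value,
               t.test(x[1, 1:6], x[1, 7:12], var.equal = TRUE)$p.value)
  welch <- compare_groups(make_study(x), var_equal = FALSE)
  expect_equal(welch$p_value, t.test(x[1, 1:6], x[1, 7:12])$p.value)
})

test_that("swapping group labels negates fold changes, keeps p-values", {
  set.seed(3)
  sig <- matrix(rlnorm(40, 2, 0.5), nrow = 5,
                dimnames = list(paste0("a", 1:5), paste0("s", 1:8)))
  study <- make_study(sig)
  swapped <- study
  swapped$samples$group <- rev(study$samples$group)
  a <- compare_groups(study)
  b <- compare_groups(swapped)
  expect_equal(a$log2_fold_change, -b$log2_fold_change)
  expect_equal(a$p_value, b$p_value)
})

test_that("type-I error under a seeded null simulation is nominal", {
  model <- generate_toy_model(toy_spec(n_pathways = 250L,
                                       pathway_length = 4L))
  study <- generate_measurements(model, effect_spec(n_per_group = 10L,
                                                    seed = 77L))
  study <- normalize_total_signal(study)
  comp <- compare_groups(study)
  expect_identical(nrow(comp), 1000L)
  frac <- mean(comp$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("analyte matching normalizes PubChem reference variants", {
  model <- toy_model("toy4")
  study <- generate_measurements(model, effect_spec(seed = 1L))
  key <- match_analytes(study, model)
  expect_identical(unname(key["analyte_A"]), "A")
  expect_length(key, 4L)
  # leading zeros, whitespace, CID prefix all normalize to equal
  study2 <- study
  study2$analytes$pubchem[[1]] <- " CID:090001 "
  key2 <- match_analytes(study2, model)
  expect_identical(unname(key2["analyte_A"]), "A")
  # disjoint references yield no match
  study3 <- study
  study3$analytes$pubchem[[1]] <- "55555"
  key3 <- match_analytes(study3, model)
  expect_false("analyte_A" %in% names(key3))
  expect_true("analyte_A" %in% attr(key3, "unmatched"))
  # ambiguous matches are reported, never silently assigned
  model2 <- model
  model2$metabolites[["B"]]$references$pubchem <- c("90002", "90001")
  expect_warning(match_analytes(study, model2), "ambiguous")
  key4 <- suppressWarnings(match_analytes(study, model2))
  expect_false("analyte_A" %in% names(key4))
  expect_identical(attr(key4, "ambiguous")$metabolite, c("A", "B"))
})

test_that("annotation attaches comparisons to network nodes", {
  model <- toy_model("toy4")
  net <- build_network(model, network_spec())
  comp <- data.frame(analyte = c("x", "y", "z"),
                     metabolite = c("A", "B", NA),
                     log2_fold_change = c(1, -1, 2),
                     p_value = c(0.01, 0.2, 0.5),
                     stringsAsFactors = FALSE)
  ann <- suppressMessages(annotate_network(net, comp))
  expect_identical(nrow(ann$annotations), 2L)
  expect_setequal(ann$annotations$id, c("A@c1", "B@c1"))
  # empty comparisons: no annotations
  none <- suppressMessages(annotate_network(net, comp[0, ]))
  expect_null(none$annotations)
  # unknown metabolite warns
  comp$metabolite[3] <- "GHOST"
  expect_warning(suppressMessages(annotate_network(net, comp)), "GHOST")
  # annotations survive a node-link export/import round-trip
  path <- withr::local_tempfile(fileext = ".json")
  export_network(ann, path, "node_link_text")
  back <- import_network(path, "node_link_text")
  expect_identical(back$annotations[order(back$annotations$id), ],
                   ann$annotations[order(ann$annotations$id), ])
})

test_that("volcano coordinates transform p-values", {
  comp <- data.frame(analyte = c("a", "b", "c"),
                     log2_fold_change = c(1, 0, -2),
                     p_value = c(0.05, 1, 0.001))
  v <- volcano_data(comp)
  expect_equal(v$neg_log10_p, c(-log10(0.05), 0, 3))
  expect_equal(v$neg_log10_p[1], 1.301, tolerance = 1e-3)
  expect_equal(v$log2_fold_change[2], 0)
})
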