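# Processing of metabolomic measurement tables: coverage filtering,
# redundancy resolution by index of dispersion, total-signal normalization,
# group comparison (log2 fold changes, Student t-tests), matching of
# analytes to model metabolites by PubChem references, and annotation of
# networks with the results.

#' Assemble a measurement study
#'
#' @param samples Data frame with columns `identifier`, `group` (exactly the
#'   labels `"case"` and `"control"`), and optionally `pair`.
#' @param analytes Data frame with columns `identifier`, `name`, `pubchem`
#'   (semicolon-separated reference string or list column).
#' @param signals Numeric matrix, analytes x samples (dimnames required);
#'   `NA` marks missing measurements; values must be non-negative.
#' @param paired Logical; if `TRUE`, every case sample must have exactly one
#'   control partner sharing its `pair` label.
#' @return A `measurement_study`.
#' @export
measurement_study <- function(samples, analytes, signals, paired = FALSE) {
  stopifnot(all(c("identifier", "group") %in% names(samples)),
            all(c("identifier", "name", "pubchem") %in% names(analytes)),
            is.matrix(signals))
  groups <- unique(samples$group)
  if (!setequal(groups, c("case", "control"))) {
    stop("sample groups must be exactly 'case' and 'control'; got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (paired) {
    if (is.null(samples$pair) || any(is.na(samples$pair))) {
      stop("paired study requires a complete 'pair' column", call. = FALSE)
    }
    tab <- table(samples$pair, samples$group)
    if (!all(tab == 1L)) {
      stop("paired study requires exactly one case and one control per pair",
           call. = FALSE)
    }
  }
  stopifnot(identical(rownames(signals), analytes$identifier),
            identical(colnames(signals), samples$identifier))
  if (any(signals < 0, na.rm = TRUE)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  if (!is.list(analytes$pubchem)) {
    analytes$pubchem <- strsplit(as.character(analytes$pubchem), ";",
                                 fixed = TRUE)
  }
  structure(list(samples = samples, analytes = analytes, signals = signals,
                 paired = isTRUE(paired)),
            class = "measurement_study")
}

#' @export
print.measurement_study <- function(x, ...) {
  cat("measurement_study:", nrow(x$analytes), "analytes,",
      nrow(x$samples), "samples",
      if (x$paired) "(paired)" else "(independent)", "\n")
  invisible(x)
}

#' Read a measurement study from the package's TSV dialect
#'
#' The table is rectangular with header
#' `row_type identifier name pubchem <sample ids...>`. One `group` row gives
#' the group label of each sample column, an optional `pair` row gives pair
#' labels, and each `analyte` row carries the analyte identifier, name,
#' semicolon-separated PubChem references, and per-sample signals (empty
#' cells are missing).
#'
#' @param path TSV path.
#' @return A `measurement_study`.
#' @export
read_measurements <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  meta_cols <- c("row_type", "identifier", "name", "pubchem")
  stopifnot(identical(names(raw)[1:4], meta_cols))
  sample_ids <- names(raw)[-(1:4)]
  group_row <- raw[raw$row_type == "group", -(1:4), drop = FALSE]
  if (nrow(group_row) != 1L) {
    stop("measurement file needs exactly one 'group' row", call. = FALSE)
  }
  pair_row <- raw[raw$row_type == "pair", -(1:4), drop = FALSE]
  paired <- nrow(pair_row) == 1L
  samples <- data.frame(identifier = sample_ids,
                        group = as.character(group_row[1L, ]),
                        stringsAsFactors = FALSE)
  if (paired) samples$pair <- as.character(pair_row[1L, ])
  arows <- raw[raw$row_type == "analyte", , drop = FALSE]
  analytes <- data.frame(identifier = arows$identifier, name = arows$name,
                         pubchem = arows$pubchem, stringsAsFactors = FALSE)
  signals <- as.matrix(arows[, -(1:4), drop = FALSE])
  signals <- apply(signals, 2L, function(x) {
    x[x == ""] <- NA
    as.numeric(x)
  })
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = nrow(arows))
  dimnames(signals) <- list(analytes$identifier, sample_ids)
  measurement_study(samples, analytes, signals, paired = paired)
}

#' Write a measurement study in the TSV dialect read by
#' [read_measurements()]
#'
#' @param study A `measurement_study`.
#' @param path Output path.
#' @export
write_measurements <- function(study, path) {
  n_s <- nrow(study$samples)
  header <- c("row_type", "identifier", "name", "pubchem",
              study$samples$identifier)
  rows <- list(c("group", "", "", "", study$samples$group))
  if (study$paired) {
    rows <- c(rows, list(c("pair", "", "", "", study$samples$pair)))
  }
  fmt_num <- function(x) ifelse(is.na(x), "",
                                formatC(x, digits = 15L, format = "g"))
  for (i in seq_len(nrow(study$analytes))) {
    rows <- c(rows, list(c(
      "analyte", study$analytes$identifier[[i]], study$analytes$name[[i]],
      paste(study$analytes$pubchem[[i]], collapse = ";"),
      fmt_num(study$signals[i, ]))))
  }
  tab <- do.call(rbind, c(list(header), rows))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

group_columns <- function(study, group) {
  study$samples$identifier[study$samples$group == group]
}

#' Drop analytes with inadequate measurement coverage
#'
#' An analyte is kept only when it is measured (non-missing) in at least
#' `min_fraction` of the samples of *each* group.
#'
#' @param study A `measurement_study`.
#' @param min_fraction Minimum per-group measured fraction (default 0.5).
#' @return The filtered study; dropped identifiers are reported via
#'   `message()`.
#' @export
filter_coverage <- function(study, min_fraction = 0.5) {
  keep <- vapply(seq_len(nrow(study$analytes)), function(i) {
    all(vapply(c("case", "control"), function(grp) {
      cols <- group_columns(study, grp)
      mean(!is.na(study$signals[i, cols])) >= min_fraction
    }, logical(1L)))
  }, logical(1L))
  dropped <- study$analytes$identifier[!keep]
  if (length(dropped)) {
    message("filter_coverage dropped: ", paste(dropped, collapse = ", "))
  }
  study$analytes <- study$analytes[keep, , drop = FALSE]
  study$signals <- study$signals[keep, , drop = FALSE]
  study
}

#' Index of dispersion of an analyte's control measurements
#'
#' Variance-to-mean ratio with the sample variance (denominator `n - 1`).
#' A zero control mean yields `Inf`, deprioritizing the analyte.
#'
#' @param study A `measurement_study`.
#' @param analyte Analyte identifier.
#' @return Non-negative number (possibly `Inf`).
#' @export
dispersion_index <- function(study, analyte) {
  x <- study$signals[analyte, group_columns(study, "control")]
  x <- x[!is.na(x)]
  m <- mean(x)
  if (length(x) < 2L || m == 0) return(Inf)
  stats::var(x) / m
}

#' Resolve redundant analytes mapping to one metabolite
#'
#' Among analytes mapped to the same metabolite, keeps the one with the
#' smallest control-group variance-to-mean ratio; ties break
#' lexicographically by analyte identifier. Unmapped analytes pass through.
#'
#' @param study A `measurement_study`.
#' @param chemistry_key Named character vector, analyte identifier ->
#'   metabolite identifier.
#' @return The reduced study.
#' @export
resolve_redundancy <- function(study, chemistry_key) {
  met <- chemistry_key[study$analytes$identifier]
  keep <- rep(TRUE, nrow(study$analytes))
  for (m in unique(met[!is.na(met)])) {
    members <- which(!is.na(met) & met == m)
    if (length(members) < 2L) next
    disp <- vapply(study$analytes$identifier[members], function(a)
      dispersion_index(study, a), numeric(1L))
    ord <- order(disp, study$analytes$identifier[members])
    keep[members[-ord[1L]]] <- FALSE
  }
  study$analytes <- study$analytes[keep, , drop = FALSE]
  study$signals <- study$signals[keep, , drop = FALSE]
  study
}

#' Normalize signals to each sample's total
#'
#' Divides every measurement by the total signal of its sample (sum over
#' measured analytes), controlling for sample loss and instrument
#' sensitivity. Idempotent up to the totals becoming 1.
#'
#' @param study A `measurement_study`.
#' @return The normalized study.
#' @export
normalize_total_signal <- function(study) {
  totals <- colSums(study$signals, na.rm = TRUE)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stop("zero total signal in sample(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  study$signals <- sweep(study$signals, 2L, totals, `/`)
  study
}

#' Compare analyte abundances between case and control groups
#'
#' For paired studies: the per-pair base-2 log ratio case/control is
#' computed for each complete pair, its mean reported as the log2 fold
#' change, and a two-sided one-sample t-test on the per-pair log ratios
#' gives the p-value (equivalent to the dependent-samples t-test). For
#' independent studies: the log2 ratio of group means, with a two-sided
#' two-sample t-test on the (normalized) values, equal-variance by default.
#' Case is always the dividend. Analytes where a non-positive value would
#' enter a logarithm are excluded with a message.
#'
#' @param study A normalized `measurement_study`.
#' @param var_equal Logical; `FALSE` uses the Welch test (independent
#'   studies only).
#' @return Data frame `analyte`, `metabolite` (NA until matched),
#'   `log2_fold_change`, `p_value`, `n_case`, `n_control`, `n_pairs`,
#'   `dispersion_control`.
#' @export
compare_groups <- function(study, var_equal = TRUE) {
  case_cols <- group_columns(study, "case")
  ctrl_cols <- group_columns(study, "control")
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(study$analytes))) {
    a <- study$analytes$identifier[[i]]
    if (study$paired) {
      pairs <- unique(study$samples$pair)
      ratios <- vapply(pairs, function(p) {
        pc <- study$samples$identifier[study$samples$pair == p &
                                         study$samples$group == "case"]
        pk <- study$samples$identifier[study$samples$pair == p &
                                         study$samples$group == "control"]
        x <- study$signals[a, pc]
        y <- study$signals[a, pk]
        if (is.na(x) || is.na(y)) return(NA_real_)
        if (x <= 0 || y <= 0) return(NaN)
        log2(x / y)
      }, numeric(1L))
      if (any(is.nan(ratios))) {
        skipped <- c(skipped, a)
        next
      }
      ratios <- ratios[!is.na(ratios)]
      if (length(ratios) < 2L) {
        skipped <- c(skipped, a)
        next
      }
      p <- if (stats::sd(ratios) == 0) {
        if (all(ratios == 0)) 1 else 1e-300
      } else {
        stats::t.test(ratios, mu = 0)$p.value
      }
      rows[[a]] <- data.frame(
        analyte = a, metabolite = NA_character_,
        log2_fold_change = mean(ratios), p_value = p,
        n_case = length(ratios), n_control = length(ratios),
        n_pairs = length(ratios),
        dispersion_control = dispersion_index(study, a),
        stringsAsFactors = FALSE)
    } else {
      x <- study$signals[a, case_cols]
      y <- study$signals[a, ctrl_cols]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) {
        skipped <- c(skipped, a)
        next
      }
      if (mean(x) <= 0 || mean(y) <= 0) {
        skipped <- c(skipped, a)
        next
      }
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # degenerate: both groups constant; t-statistic undefined
        if (mean(x) == mean(y)) 1 else 1e-300
      } else {
        stats::t.test(x, y, var.equal = var_equal)$p.value
      }
      rows[[a]] <- data.frame(
        analyte = a, metabolite = NA_character_,
        log2_fold_change = log2(mean(x) / mean(y)), p_value = p,
        n_case = length(x), n_control = length(y), n_pairs = NA_integer_,
        dispersion_control = dispersion_index(study, a),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    message("compare_groups excluded (non-positive or insufficient data): ",
            paste(skipped, collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, unname(rows))
  else data.frame(analyte = character(), metabolite = character(),
                  log2_fold_change = numeric(), p_value = numeric(),
                  n_case = integer(), n_control = integer(),
                  n_pairs = integer(), dispersion_control = numeric(),
                  stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

normalize_pubchem <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^(CID[:]?)", "", x, ignore.case = TRUE)
  x <- sub("^0+(?=.)", "", x, perl = TRUE)
  toupper(x[nzchar(x)])
}

#' Match analytes to model metabolites by PubChem references
#'
#' Two entities match when their normalized PubChem identifier sets
#' intersect (normalization trims whitespace, strips `CID` prefixes and
#' leading zeros, and upper-cases). Analytes matching more than one
#' metabolite are reported as ambiguous and left unmatched rather than
#' silently assigned.
#'
#' @param study A `measurement_study`.
#' @param model_or_network A `metabolic_model` or `metabolic_network`.
#' @return Named character vector analyte -> metabolite, with attributes
#'   `unmatched` (identifiers) and `ambiguous` (data frame of candidate
#'   matches).
#' @export
match_analytes <- function(study, model_or_network) {
  mets <- if (inherits(model_or_network, "metabolic_model")) {
    model_or_network$metabolites
  } else {
    pls <- Filter(function(p) p$type == "metabolite",
                  model_or_network$payload)
    lapply(pls, `[[`, "metabolite")
  }
  met_refs <- lapply(mets, function(m) normalize_pubchem(m$references$pubchem))
  met_ids <- vapply(mets, `[[`, "", "identifier")
  mapping <- character()
  unmatched <- character()
  ambiguous <- list()
  for (i in seq_len(nrow(study$analytes))) {
    a <- study$analytes$identifier[[i]]
    refs <- normalize_pubchem(study$analytes$pubchem[[i]])
    hits <- unique(met_ids[vapply(met_refs, function(r)
      length(intersect(r, refs)) > 0L, logical(1L))])
    if (length(hits) == 0L) {
      unmatched <- c(unmatched, a)
    } else if (length(hits) > 1L) {
      ambiguous[[a]] <- data.frame(analyte = a, metabolite = sort(hits),
                                   stringsAsFactors = FALSE)
    } else {
      mapping[[a]] <- hits
    }
  }
  if (length(ambiguous)) {
    warning("ambiguous analyte matches left unassigned: ",
            paste(names(ambiguous), collapse = ", "), call. = FALSE)
  }
  structure(mapping, unmatched = unmatched,
            ambiguous = if (length(ambiguous))
              do.call(rbind, unname(ambiguous))
            else data.frame(analyte = character(),
                            metabolite = character()))
}

#' Attach group-comparison results to network metabolite nodes
#'
#' Metabolite nodes whose underlying metabolite identifier appears in the
#' comparison table's `metabolite` column gain a (log2 fold change, p-value)
#' annotation, carried through exports.
#'
#' @param network A `metabolic_network`.
#' @param comparisons Output of [compare_groups()] with the `metabolite`
#'   column filled (see [match_analytes()]).
#' @return The annotated network.
#' @export
annotate_network <- function(network, comparisons) {
  comp <- comparisons[!is.na(comparisons$metabolite), , drop = FALSE]
  met_nodes <- network$nodes$id[network$nodes$type == "metabolite"]
  met_of <- vapply(met_nodes, function(id) node_metabolite_id(network, id),
                   "")
  rows <- list()
  absent <- character()
  for (i in seq_len(nrow(comp))) {
    hits <- met_nodes[met_of == comp$metabolite[[i]]]
    if (length(hits) == 0L) {
      absent <- c(absent, comp$metabolite[[i]])
      next
    }
    for (id in hits) {
      rows[[id]] <- data.frame(id = id,
                               log2fc = comp$log2_fold_change[[i]],
                               p_value = comp$p_value[[i]],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(absent)) {
    warning("comparisons reference metabolites absent from the network: ",
            paste(unique(absent), collapse = ", "), call. = FALSE)
  }
  network$annotations <- if (length(rows)) do.call(rbind, unname(rows))
  else NULL
  message("annotated ", length(rows), " metabolite nodes")
  network
}

#' Volcano plot coordinates
#'
#' @param comparisons Output of [compare_groups()].
#' @return Data frame `analyte`, `log2_fold_change`, `neg_log10_p`.
#' @export
volcano_data <- function(comparisons) {
  data.frame(analyte = comparisons$analyte,
             log2_fold_change = comparisons$log2_fold_change,
             neg_log10_p = -log10(comparisons$p_value),
             stringsAsFactors = FALSE)
}

#' Volcano plot of group comparisons
#'
#' Thin ggplot2 layer over [volcano_data()].
#'
#' @param comparisons Output of [compare_groups()].
#' @param p_cutoff Horizontal reference line (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(comparisons, p_cutoff = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_volcano requires ggplot2", call. = FALSE)
  }
  dat <- volcano_data(comparisons)
  ggplot2::ggplot(dat, ggplot2::aes(x = log2_fold_change,
                                    y = neg_log10_p)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p-value")
}

#' Write a comparison table as TSV
#'
#' Columns: `analyte`, `metabolite`, `log2fc`, `p_value`, `n`, `dispersion`.
#'
#' @param comparisons Output of [compare_groups()].
#' @param path Output path.
#' @export
write_comparisons <- function(comparisons, path) {
  n <- ifelse(is.na(comparisons$n_pairs),
              pmin(comparisons$n_case, comparisons$n_control),
              comparisons$n_pairs)
  out <- data.frame(analyte = comparisons$analyte,
                    metabolite = comparisons$metabolite,
                    log2fc = comparisons$log2_fold_change,
                    p_value = comparisons$p_value, n = n,
                    dispersion = comparisons$dispersion_control,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
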