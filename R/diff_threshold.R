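#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts a vector of p-values by the Benjamini-Hochberg false discovery
#' rate procedure: q for the i-th smallest p is
#' `min over j >= i of m * p_(j) / j`, capped at 1 and mapped back to input
#' order. Delegates to [stats::p.adjust()] after domain validation.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0L) return(numeric(0L))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group p-values by several classical tests
#'
#' Computes two-sided p-values comparing `x` against `y` for any subset of
#' Student's t-test (equal variance), Wilcoxon rank-sum, and one-way ANOVA.
#' For two groups the ANOVA p equals the equal-variance t-test p (F = t^2).
#'
#' The Wilcoxon p is exact when both groups have at most 25 observations and
#' there are no ties across the pooled sample; otherwise a tie-corrected
#' normal approximation with continuity correction is used (peptide ratios
#' can tie after rounding).
#'
#' Degenerate inputs: when both groups have zero variance, the t/ANOVA p is
#' 1 if the two constants coincide and 0 otherwise (the test statistic is
#' unbounded); a fully tied pooled sample yields a Wilcoxon p of 1.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param methods Character subset of
#'   `c("t_test", "wilcoxon_ranksum", "anova_oneway")`.
#' @return Named numeric vector of p-values, one per requested method.
#' @export
two_group_pvalues <- function(x, y,
                              methods = c("t_test", "wilcoxon_ranksum",
                                          "anova_oneway")) {
  methods <- match.arg(methods, several.ok = TRUE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  tp <- function() {
    if (degenerate) return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }
  out <- vapply(methods, function(m) {
    switch(m,
      t_test = tp(),
      anova_oneway = {
        if (degenerate) {
          if (mean(x) == mean(y)) 1 else 0
        } else {
          vals <- c(x, y)
          grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
          stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
        }
      },
      wilcoxon_ranksum = {
        exact <- length(x) <= 25L && length(y) <= 25L &&
          !anyDuplicated(c(x, y))
        p <- suppressWarnings(
          stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
        if (!is.finite(p)) 1 else p
      })
  }, numeric(1L))
  setNames(out, methods)
}

#' Apply the two-step qualification rule to summary q-values
#'
#' A protein qualifies when its control-channel peptide distributions are
#' comparable (`q_control > alpha_comparable`; q_control is the *lowest*
#' q over methods, the conservative direction for declaring comparability)
#' and its patient channel differs from both control channels
#' (`q_diff < alpha_diff`; q_diff is the *highest* q over methods and over
#' the patient-vs-control comparisons).
#'
#' @param q_control Numeric vector of control-vs-control q-values.
#' @param q_diff Numeric vector (same length) of patient-vs-control
#'   q-values, already reduced by max over comparisons.
#' @param alpha_comparable Comparability level (default 0.01).
#' @param alpha_diff Difference level (default 0.05).
#' @return Data frame with logical columns `passes_comparability`,
#'   `passes_difference`, `qualifies`.
#' @export
qualification_rule <- function(q_control, q_diff,
                               alpha_comparable = 0.01, alpha_diff = 0.05) {
  stopifnot(length(q_control) == length(q_diff))
  passes_comparability <- q_control > alpha_comparable
  passes_difference <- q_diff < alpha_diff
  data.frame(passes_comparability = passes_comparability,
             passes_difference = passes_difference,
             qualifies = passes_comparability & passes_difference)
}

#' Two-step peptide-distribution qualification of proteins
#'
#' For every protein with strictly more than `min_peptides` unique peptide
#' values, compares the per-channel peptide ratio distributions in two
#' steps: (i) the control channels against each other, to establish that
#' the two control labelings are comparable, and (ii) the non-reference
#' patient channel(s) against each control channel, to establish a
#' patient-control difference. Each requested test method is applied to each
#' comparison, p-values are Benjamini-Hochberg adjusted across proteins
#' within one (method, comparison) family, and the per-protein q-values are
#' reduced with `control_q_reduction` (default `min`) over the
#' comparability tests and `diff_q_reduction` (default `max`) over the
#' difference tests before applying [qualification_rule()].
#'
#' @param peptides A `peptide_quant` data frame (ratios-to-reference).
#' @param design A [channel_design()].
#' @param min_peptides Unique-peptide count filter; strictly greater-than
#'   (default 10, so a protein with exactly 10 peptides is excluded).
#' @param alpha_comparable,alpha_diff Qualification levels; see
#'   [qualification_rule()].
#' @param methods Test methods, see [two_group_pvalues()].
#' @param control_q_reduction,diff_q_reduction Reduction functions for the
#'   per-protein q-values of steps (i) and (ii).
#' @param rollup Protein rollup statistic used for the reported `cp_ratio`.
#' @return A data frame of class `qualification_result` with one row per
#'   tested protein: `accession`, `gene`, `n_unique_peptides`, `cp_ratio`,
#'   `q_control`, `q_diff`, `passes_comparability`, `passes_difference`,
#'   `qualifies`. The full per-(comparison, method) q-value array is kept
#'   in the `per_test_q` attribute.
#' @export
qualify_proteins <- function(peptides, design,
                             min_peptides = 10,
                             alpha_comparable = 0.01, alpha_diff = 0.05,
                             methods = c("t_test", "wilcoxon_ranksum",
                                         "anova_oneway"),
                             control_q_reduction = min,
                             diff_q_reduction = max,
                             rollup = c("median", "mean")) {
  stopifnot(inherits(design, "channel_design"))
  rollup <- match.arg(rollup)
  methods <- match.arg(methods, several.ok = TRUE)

  upep <- peptides[peptides$is_unique, , drop = FALSE]
  counts <- table(upep$accession)
  keep <- sort(names(counts)[counts > min_peptides])
  if (length(keep) == 0L) {
    stop("qualification error: no protein has more than ", min_peptides,
         " unique peptide values", call. = FALSE)
  }

  ctrl <- control_channels(design)
  pat <- patient_channels(design, include_reference = FALSE)
  if (length(pat) == 0L) {
    stop("design error: qualification needs a non-reference patient channel",
         call. = FALSE)
  }
  ctrl_pairs <- utils::combn(ctrl, 2L, simplify = FALSE)
  diff_pairs <- unlist(lapply(pat, function(p) {
    lapply(ctrl, function(cc) c(p, cc))
  }), recursive = FALSE)
  comparisons <- c(ctrl_pairs, diff_pairs)
  comp_type <- rep(c("control", "difference"),
                   c(length(ctrl_pairs), length(diff_pairs)))
  comp_names <- vapply(comparisons, paste, character(1L), collapse = "_vs_")

  by_acc <- split(upep, factor(upep$accession, levels = keep))

  # p[protein, comparison, method], then BH within each (comparison, method)
  p_arr <- array(NA_real_,
                 dim = c(length(keep), length(comparisons), length(methods)),
                 dimnames = list(keep, comp_names, methods))
  for (i in seq_along(keep)) {
    sub <- by_acc[[i]]
    for (j in seq_along(comparisons)) {
      a <- sub[[paste0("ch_", comparisons[[j]][1L])]]
      b <- sub[[paste0("ch_", comparisons[[j]][2L])]]
      p_arr[i, j, ] <- two_group_pvalues(a, b, methods = methods)
    }
  }
  q_arr <- p_arr
  for (j in seq_along(comparisons)) {
    for (m in seq_along(methods)) {
      q_arr[, j, m] <- bh_fdr(p_arr[, j, m])
    }
  }

  q_control <- apply(q_arr[, comp_type == "control", , drop = FALSE], 1L,
                     control_q_reduction)
  q_diff <- apply(q_arr[, comp_type == "difference", , drop = FALSE], 1L,
                  diff_q_reduction)
  flags <- qualification_rule(q_control, q_diff,
                              alpha_comparable = alpha_comparable,
                              alpha_diff = alpha_diff)

  prot <- aggregate_proteins(
    peptides[peptides$accession %in% keep, , drop = FALSE],
    design, method = rollup)
  prot <- prot[match(keep, prot$accession), , drop = FALSE]

  out <- data.frame(accession = keep,
                    gene = prot$gene,
                    n_unique_peptides = prot$n_unique_peptides,
                    cp_ratio = prot$cp_ratio,
                    q_control = unname(q_control),
                    q_diff = unname(q_diff),
                    stringsAsFactors = FALSE)
  out <- cbind(out, flags)
  rownames(out) <- NULL
  structure(out,
            per_test_q = q_arr,
            alpha_comparable = alpha_comparable,
            alpha_diff = alpha_diff,
            class = c("qualification_result", "data.frame"))
}

#' Derive the control/patient ratio threshold from the qualifying set
#'
#' The selection threshold is the arithmetic mean of the control/patient
#' value ratios of the qualifying proteins, carried unrounded internally.
#'
#' @param qualified Either a [qualify_proteins()] result (rows with
#'   `qualifies == TRUE` are used), or a data frame with `accession` and
#'   `cp_ratio` columns (all rows used), or a bare numeric vector of ratios.
#' @return An object of class `threshold_model`: list with `threshold`,
#'   `qualifying_accessions`, `n_qualifying`.
#' @export
derive_threshold <- function(qualified) {
  if (is.data.frame(qualified)) {
    if ("qualifies" %in% names(qualified)) {
      qualified <- qualified[qualified$qualifies, , drop = FALSE]
    }
    acc <- as.character(qualified$accession)
    ratios <- qualified$cp_ratio
  } else {
    ratios <- as.numeric(qualified)
    acc <- names(qualified)
    if (is.null(acc)) acc <- rep(NA_character_, length(ratios))
  }
  if (length(ratios) == 0L) {
    stop("threshold error: empty qualifying set", call. = FALSE)
  }
  structure(list(threshold = mean(ratios),
                 qualifying_accessions = acc,
                 n_qualifying = length(ratios)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("ratio threshold ", format(round(x$threshold, 3L), nsmall = 3L),
      " (mean over ", x$n_qualifying, " qualifying proteins)\n", sep = "")
  invisible(x)
}

#' Select candidate proteins above the derived threshold
#'
#' Returns the proteins whose control/patient value ratio strictly exceeds
#' the threshold, regardless of peptide count, sorted by decreasing ratio.
#' Each record carries a `twofold` flag: `TRUE` when any control channel's
#' protein-level ratio is at least 2 (an at-least-two-fold change relative
#' to the reference patient pool).
#'
#' @param proteins Data frame as returned by [aggregate_proteins()] (or a
#'   compatible table with `accession`, `gene`, `cp_ratio` and `ch_<tag>`
#'   columns for the control channels).
#' @param model A [derive_threshold()] result (or a single number).
#' @param design A [channel_design()].
#' @return Data frame of candidates with the input columns plus `twofold`,
#'   sorted by descending `cp_ratio`. May be empty.
#' @export
select_candidates <- function(proteins, model, design) {
  threshold <- if (inherits(model, "threshold_model")) model$threshold
               else as.numeric(model)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("selection threshold must be positive", call. = FALSE)
  }
  sel <- proteins[proteins$cp_ratio > threshold, , drop = FALSE]
  sel <- sel[order(-sel$cp_ratio, sel$accession), , drop = FALSE]
  ctrl_cols <- paste0("ch_", control_channels(design))
  missing_cols <- setdiff(ctrl_cols, names(sel))
  if (length(missing_cols)) {
    stop("protein table lacks control channel column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sel$twofold <- if (nrow(sel)) {
    apply(as.matrix(sel[ctrl_cols]), 1L, function(v) any(v >= 2.0))
  } else {
    logical(0L)
  }
  rownames(sel) <- NULL
  sel
}

#' Map candidates to reviewed SwissProt entries and deduplicate
#'
#' Replaces each candidate's source accession by its canonical reviewed
#' SwissProt accession and merges entries that share a canonical accession,
#' keeping the record with the maximum `cp_ratio` (ties broken by
#' lexicographic source accession). All contributing source accessions are
#' recorded. Accessions absent from the mapping are passed through with a
#' warning and flagged `mapped = FALSE`.
#'
#' @param candidates A [select_candidates()] result.
#' @param mapping Data frame with columns `accession` and `swissprot_id`
#'   (optionally `gene`, used to fill the merged record's gene symbol).
#' @return Data frame with one row per canonical entry: `swissprot_id`,
#'   `gene`, `cp_ratio`, `twofold`, `mapped`, `source_accessions`
#'   (semicolon-separated), sorted by descending `cp_ratio`.
#' @export
map_swissprot <- function(candidates, mapping) {
  if (!all(c("accession", "swissprot_id") %in% names(mapping))) {
    stop("mapping schema error: need columns accession, swissprot_id",
         call. = FALSE)
  }
  idx <- match(candidates$accession, mapping$accession)
  unmapped <- candidates$accession[is.na(idx)]
  if (length(unmapped)) {
    warning("no SwissProt mapping for: ",
            paste(unmapped, collapse = ", "),
            "; raw accession(s) passed through", call. = FALSE)
  }
  canonical <- ifelse(is.na(idx), candidates$accession,
                      as.character(mapping$swissprot_id[idx]))
  gene <- if ("gene" %in% names(mapping)) {
    ifelse(is.na(idx), candidates$gene, as.character(mapping$gene[idx]))
  } else {
    candidates$gene
  }
  tmp <- data.frame(swissprot_id = canonical, gene = gene,
                    accession = candidates$accession,
                    cp_ratio = candidates$cp_ratio,
                    twofold = candidates$twofold,
                    mapped = !is.na(idx),
                    stringsAsFactors = FALSE)
  rows <- lapply(split(tmp, tmp$swissprot_id), function(sub) {
    sub <- sub[order(-sub$cp_ratio, sub$accession), , drop = FALSE]
    data.frame(swissprot_id = sub$swissprot_id[1L],
               gene = sub$gene[1L],
               cp_ratio = sub$cp_ratio[1L],
               twofold = sub$twofold[1L],
               mapped = sub$mapped[1L],
               source_accessions = paste(sort(sub$accession),
                                         collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cp_ratio, out$swissprot_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
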