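#' Run the differential-expression stage end to end
#'
#' Qualification, threshold derivation and candidate selection in one call:
#' reads (or takes) a peptide table, runs [qualify_proteins()], derives the
#' ratio threshold from the qualifying set with [derive_threshold()], rolls
#' up *all* proteins regardless of peptide count, selects the candidates
#' with [select_candidates()] and, if a SwissProt mapping is supplied,
#' deduplicates them with [map_swissprot()]. When `out_dir` is given,
#' writes `qualification.tsv`, `candidates.tsv` (and `candidates_canonical
#' .tsv` when mapped) plus `threshold.txt`; stage counts and the threshold
#' are logged via [message()]. Reruns on identical inputs produce
#' byte-identical reports.
#'
#' @param peptides A `peptide_quant` data frame or a path passed to
#'   [read_peptide_table()].
#' @param design A [channel_design()].
#' @param out_dir Optional output directory (created if needed).
#' @param mapping Optional accession -> SwissProt mapping data frame; see
#'   [map_swissprot()].
#' @param ... Passed to [qualify_proteins()] (`min_peptides`, alphas,
#'   `methods`, `rollup`, ...).
#' @return Invisibly, a list with `qualification`, `model`
#'   (`threshold_model`), `proteins` (full rollup), `candidates`, and
#'   `canonical` (or `NULL`).
#' @export
run_diff <- function(peptides, design, out_dir = NULL, mapping = NULL,
                     ...) {
  if (is.character(peptides)) {
    peptides <- read_peptide_table(peptides, design)
  }
  qual <- qualify_proteins(peptides, design, ...)
  model <- derive_threshold(qual)
  dots <- list(...)
  rollup <- if (!is.null(dots$rollup)) dots$rollup else "median"
  proteins <- aggregate_proteins(peptides, design, method = rollup)
  candidates <- select_candidates(proteins, model, design)
  canonical <- if (!is.null(mapping)) {
    map_swissprot(candidates, mapping)
  }
  message("qualification: ", sum(qual$qualifies), " of ", nrow(qual),
          " tested proteins qualify; threshold ",
          format(round(model$threshold, 3L), nsmall = 3L))
  message("selection: ", nrow(candidates), " candidate(s) of ",
          nrow(proteins), " proteins",
          if (!is.null(canonical)) {
            paste0("; ", nrow(canonical), " canonical entr(ies), ",
                   sum(canonical$twofold), " two-fold")
          } else "")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report <- function(df, file) {
      df <- as.data.frame(df)
      num <- vapply(df, is.numeric, logical(1L))
      df[num] <- lapply(df[num], function(v) round(v, 6L))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_report(qual, "qualification.tsv")
    write_report(candidates, "candidates.tsv")
    if (!is.null(canonical)) {
      write_report(canonical, "candidates_canonical.tsv")
    }
    writeLines(format(model$threshold, digits = 15L),
               file.path(out_dir, "threshold.txt"))
  }
  invisible(list(qualification = qual, model = model, proteins = proteins,
                 candidates = candidates, canonical = canonical))
}

#' Run the topology stage around the selected candidates
#'
#' Loads the interactome and effector sets, computes each candidate's
#' direct interactors, motif assignments and the isolated-candidate list,
#' optionally attaches score tiers, and exports the radius-`radius`
#' subnetwork around the candidates as SIF (and GraphML).
#'
#' @param candidates Data frame with at least a `gene` column (typically
#'   the `canonical` or `candidates` element of [run_diff()]); `cp_ratio`
#'   and `twofold` travel into the export when present.
#' @param interactome Path to a SIF/TSV edge list, or an igraph object.
#' @param effectors Path to an effector-set file, or a named list.
#' @param scores Optional path to a `gene<TAB>score` table, or a data
#'   frame; tiers are added with [categorize_score()].
#' @param out_dir Optional output directory for `topology.tsv`,
#'   `subnetwork.sif`, `subnetwork.graphml`.
#' @param radius Hop radius of the exported subnetwork (default 1).
#' @return Invisibly, a list with `interactors` (named list), `isolated`,
#'   `motifs` (named list of data frames), `scores` (or `NULL`) and
#'   `table` (the per-candidate report).
#' @export
run_topology <- function(candidates, interactome, effectors,
                         scores = NULL, out_dir = NULL, radius = 1L) {
  if (is.null(candidates) || !"gene" %in% names(candidates)) {
    stop("dependency error: run_diff() candidates (with a gene column) ",
         "are required before the topology stage", call. = FALSE)
  }
  g <- if (is.character(interactome)) load_interactome(interactome)
       else interactome
  eff <- if (is.character(effectors)) read_effector_sets(effectors)
         else effectors
  genes <- unique(toupper(candidates$gene))
  inter <- suppressWarnings(direct_interactors(g, genes, eff))
  iso <- isolated_candidates(g, genes, eff)
  motifs <- setNames(lapply(genes, motif_assignment, effectors = eff,
                            g = g), genes)
  score_tab <- if (is.character(scores)) read_score_table(scores)
               else if (!is.null(scores)) {
                 data.frame(gene = toupper(scores$gene),
                            score = scores$score,
                            category = categorize_score(scores$score),
                            stringsAsFactors = FALSE)
               }
  tab <- data.frame(
    gene = genes,
    n_interactors = vapply(inter, length, integer(1L)),
    interactors = vapply(inter, paste, character(1L), collapse = ";"),
    isolated = genes %in% iso,
    motifs = vapply(motifs, function(m) {
      paste(m$motif, collapse = ";")
    }, character(1L)),
    stringsAsFactors = FALSE)
  if (!is.null(score_tab)) {
    idx <- match(genes, score_tab$gene)
    tab$score <- score_tab$score[idx]
    tab$category <- score_tab$category[idx]
  }
  message("topology: ", length(iso), " of ", length(genes),
          " candidates are isolated")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "topology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    attrs <- data.frame(gene = genes, candidate = TRUE,
                        stringsAsFactors = FALSE)
    for (col in c("cp_ratio", "twofold")) {
      if (col %in% names(candidates)) {
        attrs[[col]] <- candidates[[col]][match(genes,
                                                toupper(candidates$gene))]
      }
    }
    seeds <- intersect(genes, igraph::V(g)$name)
    if (length(seeds)) {
      export_subnetwork(g, seeds, radius,
                        sif_path = file.path(out_dir, "subnetwork.sif"),
                        graphml_path = file.path(out_dir,
                                                 "subnetwork.graphml"),
                        node_attrs = attrs)
    }
  }
  invisible(list(interactors = inter, isolated = iso, motifs = motifs,
                 scores = score_tab, table = tab))
}

#' Compose a plain-text summary of the pipeline stages
#'
#' Writes a Markdown summary of whichever stage results are supplied:
#' qualification count and threshold, candidate / canonical-entry /
#' two-fold counts, score-tier counts, the isolated-candidate list, blot
#' comparison p-values and the demographic block. Stages not supplied are
#' marked as not run. Rerunning on unchanged inputs reproduces the file
#' byte for byte.
#'
#' @param diff A [run_diff()] result, or `NULL`.
#' @param topology A [run_topology()] result, or `NULL`.
#' @param blot A [compare_blot_groups()] result, or `NULL`.
#' @param demographics A [cohort_demographics()] result, or `NULL`.
#' @param path Output file path; `NULL` returns the lines only.
#' @return Character vector of report lines, invisibly.
#' @export
run_report <- function(diff = NULL, topology = NULL, blot = NULL,
                       demographics = NULL, path = NULL) {
  if (is.null(diff) && is.null(topology) && is.null(blot) &&
      is.null(demographics)) {
    stop("dependency error: no stage results to report", call. = FALSE)
  }
  fmt <- function(x, d = 3L) format(round(x, d), nsmall = d)
  lines <- c("# Differential proteome analysis summary", "")
  if (!is.null(diff)) {
    lines <- c(lines, "## Differential expression",
      paste0("- proteins tested (peptide-count filter): ",
             nrow(diff$qualification)),
      paste0("- qualifying proteins: ", diff$model$n_qualifying),
      paste0("- control/patient ratio threshold: ",
             fmt(diff$model$threshold)),
      paste0("- candidates above threshold: ", nrow(diff$candidates)),
      if (!is.null(diff$canonical)) c(
        paste0("- unique reviewed entries: ", nrow(diff$canonical)),
        paste0("- entries with a two-fold control pool change: ",
               sum(diff$canonical$twofold))),
      "")
  } else {
    lines <- c(lines, "## Differential expression", "- not run", "")
  }
  if (!is.null(topology)) {
    lines <- c(lines, "## Topology")
    if (!is.null(topology$scores)) {
      tiers <- table(factor(topology$table$category,
                            levels = c("very_strong", "strong",
                                       "medium_strong", "weak")))
      lines <- c(lines,
        paste0("- score tiers: ",
               paste(names(tiers), as.integer(tiers), sep = "=",
                     collapse = ", ")))
    }
    lines <- c(lines,
      paste0("- isolated candidates (", length(topology$isolated), "): ",
             paste(topology$isolated, collapse = ", ")),
      "")
  } else {
    lines <- c(lines, "## Topology", "- not run", "")
  }
  if (!is.null(blot)) {
    lines <- c(lines, "## Blot validation",
      vapply(seq_len(nrow(blot)), function(i) {
        paste0("- ", blot$protein[i], ": p = ",
               format(signif(blot$p[i], 3L)),
               if (nzchar(blot$stars[i])) paste0(" ", blot$stars[i]) else "")
      }, character(1L)),
      "")
  } else {
    lines <- c(lines, "## Blot validation", "- not run", "")
  }
  if (!is.null(demographics)) {
    lines <- c(lines, "## Cohort demographics",
      paste0("- female share: patients ",
             fmt(demographics$sex$female_pct[["patient"]], 1L),
             "%, controls ",
             fmt(demographics$sex$female_pct[["control"]], 1L), "%"),
      paste0("- age (mean +/- SD): patients ",
             fmt(demographics$age$mean[["patient"]], 1L), " +/- ",
             fmt(demographics$age$sd[["patient"]], 1L),
             ", controls ",
             fmt(demographics$age$mean[["control"]], 1L), " +/- ",
             fmt(demographics$age$sd[["control"]], 1L)),
      "")
  } else {
    lines <- c(lines, "## Cohort demographics", "- not run", "")
  }
  lines <- unlist(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a YAML pipeline configuration
#'
#' Convenience reader for a flat YAML configuration with a `design` block
#' (`channels`, `groups`, `reference`), an optional `diff` block of
#' [qualify_proteins()] settings, and optional `topology` paths.
#'
#' @param path YAML file path.
#' @return List with a built `design` ([channel_design()]) plus the
#'   remaining blocks verbatim.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$design)) {
    cfg$design <- channel_design(channels = cfg$design$channels,
                                 groups = cfg$design$groups,
                                 reference = cfg$design$reference)
  }
  cfg
}
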