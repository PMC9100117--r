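#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "itraqdiff",
                      mustWork = FALSE)
  if (!nzchar(path)) {
    stop("unknown packaged file: ", file, call. = FALSE)
  }
  path
}

#' Load a packaged reference table
#'
#' The package ships, as plain TSV, the published summary tables of the
#' muscle case-control study it operationalizes: the two cohort tables
#' (8 patients, 8 controls), the 21-protein qualification table (printed
#' control/patient ratios and q-values), the 15-row candidate table
#' (printed channel values, ratios and reviewed SwissProt mapping), the
#' 14-row network-score/interactor table, and the motif -> effector-gene
#' sets. Loaders type and re-validate each table.
#'
#' @param name One of `"table1_cohort"`, `"table2_cohort"`,
#'   `"table3_qualification"`, `"table4_candidates"`,
#'   `"table5_scores_interactors"`, `"effector_sets"`.
#' @return A typed data frame, or for `"effector_sets"` a named list of
#'   gene-symbol vectors.
#' @examples
#' nrow(load_fixture("table3_qualification"))  # 21
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, c("table1_cohort", "table2_cohort",
                            "table3_qualification", "table4_candidates",
                            "table5_scores_interactors", "effector_sets"))
  path <- fixture_path(paste0(name, ".tsv"))
  if (name == "effector_sets") {
    return(read_effector_sets(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  switch(name,
    table1_cohort = ,
    table2_cohort = {
      stopifnot(all(c("id", "group", "age", "sex", "ck", "severity",
                      "muscle", "pygm_stain") %in% names(tab)))
      tab$age <- as.numeric(tab$age)
      if (any(tab$age <= 0)) stop("ages must be positive", call. = FALSE)
      if (!all(tab$sex %in% c("M", "F"))) {
        stop("sex must be M or F", call. = FALSE)
      }
      sev <- tab$severity[!is.na(tab$severity)]
      if (!all(sev %in% 0:3)) {
        stop("severity must be on the 0-3 scale", call. = FALSE)
      }
      if (!all(tab$pygm_stain %in% c("Absent", "Normal"))) {
        stop("pygm_stain must be Absent or Normal", call. = FALSE)
      }
      tab
    },
    table3_qualification = {
      stopifnot(all(c("uniprot_id", "protein", "gene", "cp_ratio",
                      "q_control", "q_diff_115v114", "q_diff_115v116")
                    %in% names(tab)))
      num <- c("cp_ratio", "q_control", "q_diff_115v114", "q_diff_115v116")
      for (col in num) tab[[col]] <- as.numeric(tab[[col]])
      if (any(tab$cp_ratio <= 0)) {
        stop("ratios must be positive", call. = FALSE)
      }
      qcols <- as.matrix(tab[c("q_control", "q_diff_115v114",
                               "q_diff_115v116")])
      if (any(qcols < 0 | qcols > 1)) {
        stop("q-values must lie in [0, 1]", call. = FALSE)
      }
      tab
    },
    table4_candidates = {
      stopifnot(all(c("uniprot_id", "ch_115", "ch_114", "ch_116",
                      "cp_ratio", "swissprot_id", "protein", "gene")
                    %in% names(tab)))
      num <- c("ch_115", "ch_114", "ch_116", "cp_ratio")
      for (col in num) tab[[col]] <- as.numeric(tab[[col]])
      if (any(as.matrix(tab[num]) <= 0)) {
        stop("channel values and ratios must be positive", call. = FALSE)
      }
      # the reference ratio is identically 1 by construction
      tab$ch_113 <- 1
      tab
    },
    table5_scores_interactors = {
      stopifnot(all(c("gene", "uniprot_id", "score", "category",
                      "effector_motifs", "interactors") %in% names(tab)))
      tab$score <- as.numeric(tab$score)
      if (any(tab$score < 0 | tab$score > 100)) {
        stop("scores must lie in [0, 100]", call. = FALSE)
      }
      split_field <- function(x) {
        lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
               function(v) trimws(v[nzchar(trimws(v))]))
      }
      tab$effector_motifs <- split_field(tab$effector_motifs)
      tab$interactors <- split_field(tab$interactors)
      tab
    })
}
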