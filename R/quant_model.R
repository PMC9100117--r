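#' Normalize raw reporter values to the reference channel
#'
#' Divides every channel value by the reference channel value, so the
#' reference ratio is exactly 1. Idempotent: already-normalized input is
#' returned unchanged. Scale-invariant: multiplying all raw values by a
#' common constant does not change the result.
#'
#' @param raw Named numeric vector of positive reporter values; names must
#'   cover the design's channels.
#' @param design A [channel_design()].
#' @return Named numeric vector of ratios-to-reference, in design channel
#'   order, with `out[reference] == 1`.
#' @examples
#' d <- channel_design()
#' normalize_to_reference(c("113" = 100, "114" = 200,
#'                          "115" = 100, "116" = 300), d)
#' @export
normalize_to_reference <- function(raw, design) {
  stopifnot(inherits(design, "channel_design"))
  if (!all(design$channels %in% names(raw))) {
    stop("`raw` must carry a value for every design channel", call. = FALSE)
  }
  raw <- raw[design$channels]
  ref <- raw[[design$reference]]
  if (!is.finite(ref) || ref <= 0) {
    stop("normalization error: reference channel value must be positive",
         call. = FALSE)
  }
  raw / ref
}

#' Read a peptide-level reporter quantification table
#'
#' Ingests the TSV/CSV export of a reporter-ion quantification pipeline:
#' one row per peptide with columns `accession`, `gene`, `peptide_id`,
#' `is_unique` and one `ch_<tag>` column per design channel (raw reporter
#' values or ratios; both are accepted because every row is re-normalized to
#' the reference channel). Rows with any missing or non-positive channel
#' value are dropped; the drop count is reported via [message()] and stored
#' in the `n_dropped` attribute.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param design A [channel_design()].
#' @param sep Field separator; `"auto"` (default) sniffs tab vs comma from
#'   the header line.
#' @return A data frame of class `peptide_quant` with character columns
#'   `accession`, `gene`, `peptide_id`, logical `is_unique`, and one numeric
#'   `ch_<tag>` column per channel (ratios-to-reference). Attributes:
#'   `design`, `n_dropped`.
#' @export
read_peptide_table <- function(path, design, sep = "auto") {
  stopifnot(inherits(design, "channel_design"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "auto")) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("accession", "gene", "peptide_id", "is_unique",
                channel_cols(design))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("peptide table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("peptide table is empty: ", path, call. = FALSE)
  }
  as_peptide_quant(tab, design)
}

# Validate, drop incomplete rows and normalize a raw peptide data frame.
# Shared by read_peptide_table() and the synthetic generator.
as_peptide_quant <- function(tab, design) {
  cc <- channel_cols(design)
  for (col in cc) tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab$is_unique <- as.logical(tab$is_unique)
  vals <- as.matrix(tab[cc])
  ok <- apply(vals, 1L, function(v) all(is.finite(v)) && all(v > 0))
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped,
            " peptide row(s) with missing or non-positive channel values")
  }
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no peptide rows left after dropping incomplete rows",
         call. = FALSE)
  }
  ref_col <- paste0("ch_", design$reference)
  scale <- tab[[ref_col]]
  for (col in cc) tab[[col]] <- tab[[col]] / scale
  rownames(tab) <- NULL
  structure(tab, design = design, n_dropped = n_dropped,
            class = c("peptide_quant", "data.frame"))
}

#' Control/patient value ratio of a protein
#'
#' The effect-size measure of the pipeline: the mean of the control channels'
#' protein-level ratios divided by the mean of the non-reference patient
#' channels' ratios. The reference channel (identically 1 after
#' normalization) is excluded from the patient mean so it does not dilute
#' the patient value.
#'
#' @param channel_value Named numeric vector of protein-level
#'   ratios-to-reference, names covering the design channels (or `ch_<tag>`
#'   column names).
#' @param design A [channel_design()].
#' @return A positive scalar.
#' @examples
#' d <- channel_design()
#' # reproduces ACTN3's printed ratio from its printed channel values
#' round(control_patient_ratio(
#'   c("113" = 1, "114" = 2.002, "115" = 0.933, "116" = 2.224), d), 3)
#' @export
control_patient_ratio <- function(channel_value, design) {
  stopifnot(inherits(design, "channel_design"))
  nm <- names(channel_value)
  if (all(channel_cols(design) %in% nm)) {
    channel_value <- setNames(as.numeric(channel_value[channel_cols(design)]),
                              design$channels)
  } else if (!all(design$channels %in% nm)) {
    stop("channel values must be named by channel tag", call. = FALSE)
  }
  ctrl <- control_channels(design)
  pat <- patient_channels(design, include_reference = FALSE)
  if (length(pat) == 0L) {
    stop("design error: no non-reference patient channel to form the ",
         "patient value", call. = FALSE)
  }
  mean(as.numeric(channel_value[ctrl])) / mean(as.numeric(channel_value[pat]))
}

#' Roll peptides up to a protein-level quantification
#'
#' Aggregates the per-peptide ratios-to-reference of one protein into one
#' protein-level ratio per channel (median by default, mean by
#' configuration), counts the unique peptides, and computes the
#' control/patient value ratio. Invariant to peptide row order.
#'
#' @param peptides A `peptide_quant` data frame (or compatible) restricted
#'   to one accession.
#' @param design A [channel_design()].
#' @param method Rollup statistic, `"median"` (default) or `"mean"`.
#' @param unique_only Use only peptides flagged unique (default `TRUE`).
#' @return An object of class `protein_quant`: a list with `accession`,
#'   `gene`, `n_unique_peptides`, `channel_value` (named numeric) and
#'   `cp_ratio`.
#' @export
aggregate_protein <- function(peptides, design,
                              method = c("median", "mean"),
                              unique_only = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(design, "channel_design"))
  acc <- unique(as.character(peptides$accession))
  if (length(acc) != 1L) {
    stop("aggregate_protein() expects peptides of a single accession",
         call. = FALSE)
  }
  n_unique <- sum(peptides$is_unique)
  if (unique_only) peptides <- peptides[peptides$is_unique, , drop = FALSE]
  if (nrow(peptides) == 0L) {
    stop("aggregation error: no usable peptides for accession ", acc,
         call. = FALSE)
  }
  fun <- if (method == "median") stats::median else mean
  cc <- channel_cols(design)
  channel_value <- setNames(vapply(cc, function(col) fun(peptides[[col]]),
                                   numeric(1L)), design$channels)
  structure(
    list(accession = acc,
         gene = as.character(peptides$gene[1L]),
         n_unique_peptides = n_unique,
         channel_value = channel_value,
         cp_ratio = control_patient_ratio(channel_value, design)),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(x$accession, " (", x$gene, "): ", x$n_unique_peptides,
      " unique peptides, control/patient ratio ",
      format(round(x$cp_ratio, 3L), nsmall = 3L), "\n", sep = "")
  invisible(x)
}

#' Roll up every protein of a peptide table
#'
#' @inheritParams aggregate_protein
#' @param peptides A `peptide_quant` data frame covering any number of
#'   accessions.
#' @return A data frame with one row per accession: `accession`, `gene`,
#'   `n_unique_peptides`, the `ch_<tag>` protein-level ratios and `cp_ratio`.
#'   Accessions whose unique-peptide set is empty are dropped with a
#'   message (they cannot be rolled up under `unique_only = TRUE`).
#' @export
aggregate_proteins <- function(peptides, design,
                               method = c("median", "mean"),
                               unique_only = TRUE) {
  method <- match.arg(method)
  pieces <- split(seq_len(nrow(peptides)), peptides$accession)
  rows <- lapply(names(pieces), function(acc) {
    sub <- peptides[pieces[[acc]], , drop = FALSE]
    if (unique_only && !any(sub$is_unique)) return(NULL)
    pq <- aggregate_protein(sub, design, method = method,
                            unique_only = unique_only)
    out <- data.frame(accession = pq$accession, gene = pq$gene,
                      n_unique_peptides = pq$n_unique_peptides,
                      stringsAsFactors = FALSE)
    for (ch in design$channels) {
      out[[paste0("ch_", ch)]] <- unname(pq$channel_value[[ch]])
    }
    out$cp_ratio <- pq$cp_ratio
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1L)))
  if (dropped > 0L) {
    message(dropped, " accession(s) without unique peptides were skipped")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}
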