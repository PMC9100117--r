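#' Configuration of the synthetic reporter-data generator
#'
#' Bundles and validates the parameters of [generate_dataset()], which
#' emulates the pooled parallel-double-labeling design: the same patient
#' pool split across two channels (one being the reference) and the same
#' control pool split across the other two, per-protein control/patient
#' fold changes planted on a fraction of proteins, per-peptide
#' multiplicative log-normal noise and per-channel bias.
#'
#' Defaults describe a realistic small discovery experiment: 200 proteins,
#' 20% differential with folds in the 1.4-4.5 range observed for candidate
#' proteins in muscle reporter data, shifted-Poisson peptide counts
#' (`1 + Poisson(14)`, so the >10-unique-peptide stratum used by the
#' qualification step is well populated), log-normal noise with sigma 0.2
#' on the natural-log scale (a typical reporter-ion coefficient of
#' variation), balanced channel biases, and 10% shared (non-unique)
#' peptides.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_differential Fraction carrying a planted fold change.
#' @param fold_range Length-2 numeric, lower bound > 1: planted
#'   control/patient folds are drawn uniformly from this range.
#' @param peptide_count_law List: either
#'   `list(kind = "poisson_shifted", lambda = ...)` (count = 1 + Poisson)
#'   or `list(kind = "negbin", r = ..., p = ...)` (count = 1 + NB).
#' @param noise_sigma SD (natural-log scale) of the per-peptide,
#'   per-channel multiplicative noise; `>= 0`.
#' @param channel_bias Named positive numeric, one entry per design
#'   channel; default all 1.
#' @param frac_nonunique Fraction of peptides flagged non-unique.
#' @param seed Integer seed; identical configurations produce
#'   byte-identical tables.
#' @param design A [channel_design()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200L,
                         frac_differential = 0.2,
                         fold_range = c(1.4, 4.5),
                         peptide_count_law = list(kind = "poisson_shifted",
                                                  lambda = 14),
                         noise_sigma = 0.2,
                         channel_bias = NULL,
                         frac_nonunique = 0.1,
                         seed = 1L,
                         design = channel_design()) {
  stopifnot(inherits(design, "channel_design"))
  if (n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (frac_differential < 0 || frac_differential > 1) {
    stop("frac_differential must lie in [0, 1]", call. = FALSE)
  }
  if (length(fold_range) != 2L || fold_range[1L] <= 1 ||
      fold_range[2L] < fold_range[1L]) {
    stop("fold_range must be increasing with lower bound > 1",
         call. = FALSE)
  }
  kind <- peptide_count_law$kind
  if (identical(kind, "poisson_shifted")) {
    if (is.null(peptide_count_law$lambda) || peptide_count_law$lambda <= 0) {
      stop("poisson_shifted law needs lambda > 0", call. = FALSE)
    }
  } else if (identical(kind, "negbin")) {
    if (is.null(peptide_count_law$r) || peptide_count_law$r <= 0 ||
        is.null(peptide_count_law$p) || peptide_count_law$p <= 0 ||
        peptide_count_law$p > 1) {
      stop("negbin law needs r > 0 and p in (0, 1]", call. = FALSE)
    }
  } else {
    stop("unknown peptide_count_law kind: ", kind, call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (is.null(channel_bias)) {
    channel_bias <- setNames(rep(1, length(design$channels)),
                             design$channels)
  }
  if (!all(design$channels %in% names(channel_bias)) ||
      any(channel_bias[design$channels] <= 0)) {
    stop("channel_bias needs a positive value per design channel",
         call. = FALSE)
  }
  if (frac_nonunique < 0 || frac_nonunique > 1) {
    stop("frac_nonunique must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         frac_differential = frac_differential,
         fold_range = as.numeric(fold_range),
         peptide_count_law = peptide_count_law,
         noise_sigma = noise_sigma,
         channel_bias = channel_bias[design$channels],
         frac_nonunique = frac_nonunique,
         seed = as.integer(seed),
         design = design),
    class = "synth_config")
}

draw_peptide_counts <- function(n, law) {
  if (identical(law$kind, "poisson_shifted")) {
    1L + stats::rpois(n, law$lambda)
  } else {
    1L + stats::rnbinom(n, size = law$r, prob = law$p)
  }
}

#' Generate a synthetic peptide table with known ground truth
#'
#' Simulates a pooled multiplexed reporter experiment: for each protein, a
#' Bernoulli draw decides whether a control/patient fold change (uniform in
#' `fold_range`) is planted; the latent level of a control channel is
#' `channel_bias * fold` and of a patient channel `channel_bias * 1` (both
#' patient channels share one latent level -- they carry the same pooled
#' sample under two labels). Each peptide observes every channel through
#' independent multiplicative log-normal noise, peptide counts follow the
#' configured law (minimum 1), a share of peptides is flagged non-unique,
#' and the table is normalized to the reference channel. Identical
#' configurations (including the seed) give byte-identical output.
#'
#' @param cfg A [synth_config()].
#' @return List with `peptides` (a `peptide_quant` data frame) and `truth`
#'   (data frame `accession`, `gene`, `is_differential`, `true_fold`,
#'   `n_peptides`; `true_fold` is 1 for non-differential proteins).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  design <- cfg$design
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    is_diff <- stats::runif(n) < cfg$frac_differential
    fold <- rep(1, n)
    fold[is_diff] <- stats::runif(sum(is_diff), cfg$fold_range[1L],
                                  cfg$fold_range[2L])
    npep <- draw_peptide_counts(n, cfg$peptide_count_law)
    acc <- sprintf("SYNP%04d", seq_len(n))
    bias <- cfg$channel_bias[design$channels]
    is_ctrl <- design$group_of[design$channels] == "control"
    ref_idx <- match(design$reference, design$channels)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- npep[i]
      latent <- unname(bias) * ifelse(is_ctrl, fold[i], 1)
      eps <- matrix(stats::rnorm(k * length(latent), 0, cfg$noise_sigma),
                    nrow = k)
      raw <- sweep(exp(eps), 2L, latent, `*`)
      ratio <- raw / raw[, ref_idx]
      uniq <- stats::runif(k) >= cfg$frac_nonunique
      row <- data.frame(accession = acc[i], gene = acc[i],
                        peptide_id = sprintf("%s_p%03d", acc[i],
                                             seq_len(k)),
                        is_unique = uniq, stringsAsFactors = FALSE)
      for (j in seq_along(design$channels)) {
        row[[paste0("ch_", design$channels[j])]] <- ratio[, j]
      }
      rows[[i]] <- row
    }
    peptides <- do.call(rbind, rows)
    rownames(peptides) <- NULL
    peptides <- structure(peptides, design = design, n_dropped = 0L,
                          class = c("peptide_quant", "data.frame"))
    truth <- data.frame(accession = acc, gene = acc,
                        is_differential = is_diff, true_fold = fold,
                        n_peptides = npep, stringsAsFactors = FALSE)
    list(peptides = peptides, truth = truth)
  })
}

#' Write a peptide table in the package's TSV dialect
#'
#' @param peptides A `peptide_quant` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(as.data.frame(peptides), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recovery metrics of a selection against the planted truth
#'
#' @param truth The `truth` table from [generate_dataset()].
#' @param selected Character vector of selected accessions (a subset of
#'   `truth$accession`).
#' @return List with `sensitivity` (TP / (TP + FN)), `specificity`
#'   (TN / (TN + FP)) and `fdp` (FP / max(1, selected)).
#' @export
recovery_metrics <- function(truth, selected) {
  selected <- unique(as.character(selected))
  unknown <- setdiff(selected, truth$accession)
  if (length(unknown)) {
    stop("selected accession(s) not in truth: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  pos <- truth$accession[truth$is_differential]
  neg <- truth$accession[!truth$is_differential]
  tp <- length(intersect(selected, pos))
  fp <- length(intersect(selected, neg))
  fn <- length(setdiff(pos, selected))
  tn <- length(setdiff(neg, selected))
  list(sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
       fdp = fp / max(1L, length(selected)))
}
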