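#' Normalize Western-blot band intensities to the loading control
#'
#' Per replicate, the normalized value is the target band intensity divided
#' by the loading-control band intensity of the same lane; per sample, the
#' replicate values are averaged (normalization before averaging -- the
#' order matters for ratios). Invariant to a common positive rescaling of
#' all intensities of one gel.
#'
#' @param blot Data frame with columns `sample_id`, `group`, `protein`,
#'   `replicate`, `target_intensity`, `loading_intensity` (all intensities
#'   positive, arbitrary densitometry units).
#' @return Data frame with one row per (sample, protein): `sample_id`,
#'   `group`, `protein`, `n_replicates`, `value`.
#' @export
normalize_blot <- function(blot) {
  required <- c("sample_id", "group", "protein", "replicate",
                "target_intensity", "loading_intensity")
  missing_cols <- setdiff(required, names(blot))
  if (length(missing_cols)) {
    stop("blot table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(blot$loading_intensity) | blot$loading_intensity <= 0
  if (any(bad)) {
    stop("normalization error: missing or non-positive loading band for ",
         "sample(s) ", paste(unique(blot$sample_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(blot$target_intensity) | blot$target_intensity <= 0)) {
    stop("target intensities must be positive", call. = FALSE)
  }
  key <- interaction(blot$sample_id, blot$protein, drop = TRUE)
  if (any(vapply(split(blot$replicate, key), anyDuplicated, integer(1L)) > 0L)) {
    stop("replicate indices must be unique per (sample, protein)",
         call. = FALSE)
  }
  blot$ratio <- blot$target_intensity / blot$loading_intensity
  agg <- stats::aggregate(ratio ~ sample_id + group + protein, data = blot,
                          FUN = mean)
  n <- stats::aggregate(ratio ~ sample_id + group + protein, data = blot,
                        FUN = length)
  out <- data.frame(sample_id = agg$sample_id, group = agg$group,
                    protein = agg$protein, n_replicates = n$ratio,
                    value = agg$ratio, stringsAsFactors = FALSE)
  out[order(out$protein, out$group, out$sample_id), , drop = FALSE]
}

#' Mann-Whitney U test for two small samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison. The p-value is
#' exact when the combined sample size is at most 20 and the pooled values
#' are tie-free; otherwise a tie-corrected normal approximation with
#' continuity correction is used. The reported `U` counts the pairs in
#' which a value of `a` exceeds a value of `b` (ties count one half), i.e.
#' the statistic of the first group.
#'
#' @param a,b Numeric vectors, each nonempty.
#' @return List with `U`, `p_two_sided`, `method_used` (`"exact"` or
#'   `"normal_approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied pooled sample
  list(U = unname(wt$statistic),
       p_two_sided = min(p, 1),
       method_used = if (exact) "exact" else "normal_approximation")
}

#' Group comparison of normalized blot values per protein
#'
#' Normalizes the blot table with [normalize_blot()], then compares the
#' patient and control per-sample values of each protein with
#' [mann_whitney_u()]. Star tiers follow the usual figure convention
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001); the significance flag
#' uses p <= 0.05. Proteins present in only one group are skipped with a
#' warning.
#'
#' @param blot Blot table; see [normalize_blot()].
#' @param tiers Decreasing significance thresholds for the stars.
#' @return Data frame per protein: `protein`, `n_patient`, `n_control`,
#'   `median_patient`, `median_control`, `U`, `p`, `stars`, `significant`,
#'   `method`.
#' @export
compare_blot_groups <- function(blot, tiers = c(0.05, 0.01, 0.001)) {
  tiers <- sort(as.numeric(tiers), decreasing = TRUE)
  norm <- normalize_blot(blot)
  rows <- lapply(split(norm, norm$protein), function(sub) {
    pat <- sub$value[sub$group == "patient"]
    ctl <- sub$value[sub$group == "control"]
    if (length(pat) == 0L || length(ctl) == 0L) {
      warning("protein ", sub$protein[1L],
              " present in only one group; skipped", call. = FALSE)
      return(NULL)
    }
    mw <- mann_whitney_u(pat, ctl)
    data.frame(protein = sub$protein[1L],
               n_patient = length(pat), n_control = length(ctl),
               median_patient = stats::median(pat),
               median_control = stats::median(ctl),
               U = mw$U, p = mw$p_two_sided,
               stars = strrep("*", sum(mw$p_two_sided < tiers)),
               significant = mw$p_two_sided <= 0.05,
               method = mw$method_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    stop("no protein has measurements in both groups", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Demographic comparability of the two cohorts
#'
#' Summarizes sex and age by group and tests their comparability: female
#' percentages with a Pearson chi-square on the 2x2 sex table (no
#' continuity correction), and age means with SDs plus a Mann-Whitney
#' comparison. The SD uses the population divisor n by default
#' (configurable to the sample divisor n - 1).
#'
#' @param cohort Data frame with columns `group` (`"patient"`/`"control"`),
#'   `sex` (`"M"`/`"F"`) and `age` (years).
#' @param sd_divisor `"population"` (default) or `"sample"`.
#' @return Nested list: `$sex` with `female_pct` (named by group),
#'   `statistic`, `p`; `$age` with `mean`, `sd` (named by group), `p`.
#' @export
cohort_demographics <- function(cohort, sd_divisor = c("population",
                                                       "sample")) {
  sd_divisor <- match.arg(sd_divisor)
  required <- c("group", "sex", "age")
  if (!all(required %in% names(cohort))) {
    stop("cohort table schema error: need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  groups <- c("patient", "control")
  if (!all(groups %in% cohort$group)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  by_group <- split(cohort, factor(cohort$group, levels = groups))

  female_pct <- vapply(by_group, function(sub) {
    100 * mean(sub$sex == "F")
  }, numeric(1L))
  sex_tab <- table(factor(cohort$group, levels = groups),
                   factor(cohort$sex, levels = c("F", "M")))
  chi <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))

  sd_fun <- if (sd_divisor == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd
  }
  age_mean <- vapply(by_group, function(sub) mean(sub$age), numeric(1L))
  age_sd <- vapply(by_group, function(sub) sd_fun(sub$age), numeric(1L))
  age_mw <- mann_whitney_u(by_group$patient$age, by_group$control$age)

  list(sex = list(female_pct = female_pct,
                  statistic = unname(chi$statistic),
                  p = chi$p.value),
       age = list(mean = age_mean, sd = age_sd,
                  p = age_mw$p_two_sided,
                  method = age_mw$method_used))
}
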