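test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.5, 0.5, 0.5)), rep(0.5, 3))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")

  # property sweep against the naive step-up oracle
  withr::with_seed(42, {
    for (i in 1:300) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  })
})

test_that("two-group p-values behave across methods and degenerate input", {
  # identical samples are not significant
  p <- two_group_pvalues(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(p["t_test"]), 1)
  # one-way ANOVA on two groups is the squared-t identity
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
      p <- two_group_pvalues(x, y, methods = c("t_test", "anova_oneway"))
      expect_lt(abs(p[["anova_oneway"]] - p[["t_test"]]), 1e-9)
    }
  })
  # exact rank-sum on 2 vs 2: most extreme split has p = 1/3
  p <- two_group_pvalues(c(1, 2), c(3, 4), methods = "wilcoxon_ranksum")
  expect_equal(unname(p), 1 / 3)
  # zero variance in both groups
  expect_equal(unname(two_group_pvalues(c(2, 2), c(2, 2))["t_test"]), 1)
  expect_equal(unname(two_group_pvalues(c(2, 2), c(3, 3))["anova_oneway"]),
               0)
  expect_equal(
    unname(two_group_pvalues(c(2, 2), c(2, 2))["wilcoxon_ranksum"]), 1)
  expect_error(two_group_pvalues(1, c(1, 2)), "at least 2")
})

test_that("two-step qualification separates planted from null proteins", {
  d <- test_design()
  withr::local_seed(11)
  sigma <- 0.1
  # planted: comparable controls, patient shifted by 3 sigma; 30 peptides
  planted <- peptide_block("DIFF1",
                           ch_114 = lognorm_ratios(30, 2, sigma),
                           ch_115 = lognorm_ratios(30, 2 * exp(-3 * sigma),
                                                   sigma),
                           ch_116 = lognorm_ratios(30, 2, sigma))
  # null: all channels at the same level
  null <- peptide_block("NULL1",
                        ch_114 = lognorm_ratios(30, 1, sigma),
                        ch_115 = lognorm_ratios(30, 1, sigma),
                        ch_116 = lognorm_ratios(30, 1, sigma))
  # exactly 10 peptides: excluded by the strict > 10 filter
  ten <- peptide_block("TEN1",
                       ch_114 = lognorm_ratios(10, 3, sigma),
                       ch_115 = lognorm_ratios(10, 1, sigma),
                       ch_116 = lognorm_ratios(10, 3, sigma))
  qual <- qualify_proteins(rbind(planted, null, ten), d)
  expect_setequal(qual$accession, c("DIFF1", "NULL1"))
  expect_true(qual$qualifies[qual$accession == "DIFF1"])
  expect_true(qual$passes_comparability[qual$accession == "DIFF1"])
  expect_false(qual$passes_difference[qual$accession == "NULL1"])
  expect_error(qualify_proteins(ten, d), "qualification error")
})

test_that("qualification q-values are invariant to protein input order", {
  d <- test_design()
  ds <- generate_dataset(synth_config(n_proteins = 20, seed = 5))
  q1 <- qualify_proteins(ds$peptides, d)
  withr::with_seed(1, {
    shuffled <- ds$peptides[sample(nrow(ds$peptides)), ]
  })
  q2 <- qualify_proteins(shuffled, d)
  q2 <- q2[match(q1$accession, q2$accession), ]
  expect_equal(q1$q_control, q2$q_control)
  expect_equal(q1$q_diff, q2$q_diff)
})

test_that("raising alphas moves the qualifying count monotonically", {
  d <- test_design()
  ds <- generate_dataset(synth_config(n_proteins = 40,
                                      frac_differential = 0.3,
                                      noise_sigma = 0.3, seed = 9))
  counts_comp <- vapply(c(0.001, 0.01, 0.1, 0.5), function(a) {
    sum(qualify_proteins(ds$peptides, d, alpha_comparable = a)$qualifies)
  }, numeric(1))
  # stricter comparability (higher alpha) can only shrink the set
  expect_true(all(diff(counts_comp) <= 0))
  counts_diff <- vapply(c(0.001, 0.01, 0.05, 0.5), function(a) {
    sum(qualify_proteins(ds$peptides, d, alpha_diff = a)$qualifies)
  }, numeric(1))
  expect_true(all(diff(counts_diff) >= 0))
})

test_that("difference-step pass rate on null data is bounded by its level", {
  d <- test_design()
  ds <- generate_dataset(synth_config(n_proteins = 200,
                                      frac_differential = 0,
                                      noise_sigma = 0.2, seed = 19))
  qual <- qualify_proteins(ds$peptides, d)
  n <- nrow(qual)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(mean(qual$passes_difference), 0.05 + 3 * se)
})

test_that("qualification rule applied to published q-values keeps all rows", {
  t3 <- load_fixture("table3_qualification")
  flags <- qualification_rule(t3$q_control,
                              pmax(t3$q_diff_115v114, t3$q_diff_115v116))
  expect_true(all(flags$qualifies))
  pygm <- t3$uniprot_id == "P11217"
  expect_equal(t3$q_control[pygm], 0.23)
  expect_equal(t3$q_diff_115v114[pygm], 5.99e-11)
})

test_that("threshold is the mean of the qualifying ratios", {
  expect_equal(derive_threshold(c(a = 1, b = 2, c = 3))$threshold, 2)
  single <- derive_threshold(c(x = 1.41))
  expect_equal(single$threshold, 1.41)
  expect_equal(single$n_qualifying, 1L)
  expect_error(derive_threshold(numeric(0)), "threshold error")
  t3 <- load_fixture("table3_qualification")
  m <- derive_threshold(setNames(t3$cp_ratio, t3$uniprot_id))
  expect_equal(round(m$threshold, 3), 1.676)
  expect_equal(m$n_qualifying, 21L)
})

test_that("candidate selection is strict, sorted, and flags two-fold pools", {
  d <- test_design()
  prot <- table4_as_proteins()
  model <- derive_threshold(load_fixture("table3_qualification")$cp_ratio)
  sel <- select_candidates(prot, model, d)
  expect_equal(nrow(sel), 15L)
  expect_true(all(diff(sel$cp_ratio) <= 0))
  # a protein sitting exactly on the threshold is excluded
  at <- data.frame(accession = "AT", gene = "AT", ch_113 = 1,
                   ch_114 = 1, ch_115 = 1, ch_116 = 1,
                   cp_ratio = model$threshold)
  expect_equal(nrow(select_candidates(rbind(prot, at), model, d)), 15L)
  # two-fold convention on the control channel values
  expect_true(sel$twofold[sel$accession == "Q08043"])
  expect_false(sel$twofold[sel$accession == "Q9NR12-6"])
})

test_that("SwissProt mapping deduplicates keeping the maximum ratio", {
  d <- test_design()
  model <- derive_threshold(load_fixture("table3_qualification")$cp_ratio)
  sel <- select_candidates(table4_as_proteins(), model, d)
  canon <- map_swissprot(sel, table4_mapping())
  expect_equal(nrow(canon), 14L)
  tnnt3 <- canon[canon$swissprot_id == "P45378", ]
  expect_equal(tnnt3$cp_ratio, 2.298)
  expect_equal(tnnt3$source_accessions, "C9JZN9;H9KVA2")
  expect_equal(sum(canon$twofold), 9L)
  # identity mapping leaves the set unchanged
  ident <- data.frame(accession = sel$accession,
                      swissprot_id = sel$accession)
  expect_equal(nrow(map_swissprot(sel, ident)), nrow(sel))
  # unmapped accessions pass through flagged
  expect_warning(out <- map_swissprot(sel, table4_mapping()[-1, ]),
                 "P11217")
  expect_false(out$mapped[out$swissprot_id == "P11217"])
})
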