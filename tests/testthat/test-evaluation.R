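test_that("Sn/Sp/MCC match the defining formulas", {
  m <- compute_metrics(TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(m, list(Sn = 1, Sp = 1, MCC = 1))

  # Worked case: numerator 71*92 - 29*8 = 6300 over sqrt(100*100*79*121).
  m2 <- compute_metrics(TP = 71, TN = 92, FP = 8, FN = 29)
  expect_equal(m2$Sn, 0.71)
  expect_equal(m2$Sp, 0.92)
  expect_equal(m2$MCC, 6300 / sqrt(100 * 100 * 79 * 121), tolerance = 1e-12)
  expect_equal(m2$MCC, 0.6444, tolerance = 1e-4)

  # Zero-denominator convention: no predicted positive -> MCC = 0.
  expect_equal(compute_metrics(TP = 0, TN = 10, FP = 0, FN = 10)$MCC, 0)

  expect_error(compute_metrics(TP = 0, TN = 5, FP = 5, FN = 0), "Sn")
  expect_error(compute_metrics(TP = 5, TN = 0, FP = 0, FN = 5), "Sp")
})

test_that("compute_metrics agrees with the direct-formula oracle on random tables", {
  set.seed(7)
  for (i in 1:300) {
    cts <- c(sample(1:500, 2), sample(0:500, 2))  # TP,TN >= 1 keeps margins
    m <- compute_metrics(TP = cts[1], TN = cts[2], FP = cts[3], FN = cts[4])
    o <- metrics_oracle(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$Sn, o$Sn, tolerance = 1e-12)
    expect_equal(m$Sp, o$Sp, tolerance = 1e-12)
    expect_equal(m$MCC, o$MCC, tolerance = 1e-12)
    expect_true(m$Sn >= 0 && m$Sn <= 1 && m$Sp >= 0 && m$Sp <= 1)
    expect_true(m$MCC >= -1 - 1e-12 && m$MCC <= 1 + 1e-12)
  }
})

test_that("protein-level splits partition proteins, never sites", {
  fx <- generate_fixture(small_config(seed = 12))
  sites <- extract_windows(fx$proteome, fx$positives, L = 21)

  sp <- protein_level_split(sites, fraction = 0.8, seed = 1)
  expect_length(intersect(unique(sp$train$protein_id),
                          unique(sp$test$protein_id)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(sites))

  # 10 proteins at 4/5 -> 8 train, 2 test.
  ten <- deacpred:::new_site_set(
    as.data.frame(sites)[match(unique(sites$protein_id)[1:10],
                               sites$protein_id), ], 21)
  sp10 <- protein_level_split(ten, fraction = 0.8, seed = 3)
  expect_equal(length(unique(sp10$train$protein_id)), 8)
  expect_equal(length(unique(sp10$test$protein_id)), 2)

  # Same seed, same split.
  spA <- protein_level_split(sites, seed = 42)
  spB <- protein_level_split(sites, seed = 42)
  expect_identical(as.data.frame(spA$train), as.data.frame(spB$train))

  one <- deacpred:::new_site_set(as.data.frame(sites)[
    sites$protein_id == sites$protein_id[1], ], 21)
  expect_error(protein_level_split(one), "at least 2")
})

test_that("proportion test reproduces the Yates-corrected chi-squared", {
  # Identical proportions: statistic clipped to 0, p = 1.
  t0 <- proportion_enrichment_test(10, 100, 10, 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # Hand-evaluated 2x2: (20,10;10,20) gives 5.4.
  t1 <- proportion_enrichment_test(20, 30, 10, 30)
  expect_equal(t1$statistic, 5.4, tolerance = 1e-12)
  expect_equal(t1$p_value,
               stats::pchisq(5.4, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(t1$p_value, 4), 0.0201)

  expect_error(proportion_enrichment_test(0, 10, 0, 10), "margin")
  expect_error(proportion_enrichment_test(5, 0, 1, 10), "positive")
  expect_error(proportion_enrichment_test(11, 10, 1, 10), "hits")
})

test_that("proportion test matches the textbook formula on random tables", {
  set.seed(11)
  for (i in 1:100) {
    tot <- sample(20:2000, 2)
    hits <- c(sample(1:(tot[1] - 1), 1), sample(1:(tot[2] - 1), 1))
    got <- proportion_enrichment_test(hits[1], tot[1], hits[2], tot[2])
    want <- yates_chi2_oracle(hits[1], tot[1] - hits[1],
                              hits[2], tot[2] - hits[2])
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  }
})

test_that("the harness evaluates held-out proteins over repeats", {
  fx <- generate_fixture(small_config(seed = 14))
  inp <- fixture_inputs(fx)

  # R = 1: a single repeat, SE reported as NA.
  r1 <- run_harness(inp$positives, inp$background, inp$annotations,
                    R = 1, seed = 2)
  expect_equal(nrow(r1$repeats), 1)
  expect_true(all(is.na(r1$se)))

  # R = 4 with all features on a planted fixture: metrics recorded per
  # repeat, SE = sd/sqrt(R).
  r4 <- run_harness(inp$positives, inp$background, inp$annotations,
                    R = 4, seed = 2)
  expect_equal(nrow(r4$repeats), 4)
  expect_equal(unname(r4$se[["MCC"]]),
               stats::sd(r4$repeats$MCC) / 2, tolerance = 1e-12)
  expect_true(all(r4$repeats$Sn >= 0 & r4$repeats$Sn <= 1))

  # Same master seed reproduces the repeats exactly.
  r4b <- run_harness(inp$positives, inp$background, inp$annotations,
                     R = 4, seed = 2)
  expect_identical(r4$repeats, r4b$repeats)

  expect_error(run_harness(inp$positives, inp$background, inp$annotations,
                           feature_groups = "nope", R = 1), "unknown")

  # Output files: one row per repeat plus a summary block.
  dir <- withr::local_tempdir()
  write_harness_result(r4, file.path(dir, "h.tsv"))
  expect_equal(nrow(utils::read.delim(file.path(dir, "h.tsv"))), 4)
  expect_true(file.exists(file.path(dir, "h.tsv.summary.tsv")))
})

test_that("feature selection on all positives leaks and inflates null performance", {
  # On a null fixture (labels independent of every feature), the honest
  # harness re-selects terms inside each training fold; selecting on all
  # positives lets test proteins' annotation profiles into the feature
  # space. With functional features only and the significance gate
  # relaxed, the leaky variant scores clearly higher - which is exactly
  # why per-fold re-selection is enforced by default.
  fx <- generate_fixture(null_config(synth_config(seed = 21)))
  inp <- fixture_inputs(fx)
  groups <- c("BP", "CC", "MF", "DOMAIN", "PPI")
  safe <- run_harness(inp$positives, inp$background, inp$annotations,
                      feature_groups = groups, R = 10, seed = 17,
                      alpha = 0.999, select_on = "train")
  leaky <- run_harness(inp$positives, inp$background, inp$annotations,
                       feature_groups = groups, R = 10, seed = 17,
                       alpha = 0.999, select_on = "all")
  expect_gt(leaky$mean[["MCC"]], safe$mean[["MCC"]])
})

test_that("predict_and_summarize reports proportions and their comparison", {
  fx <- generate_fixture(small_config(seed = 33))
  inp <- fixture_inputs(fx)
  ens <- train_ensemble(inp$positives, inp$background, inp$annotations,
                        K = 3, cutoff = 2, seed = 1)
  # Candidate set A: windows from substrate proteins (other lysines);
  # comparison set B: random background lysines.
  candA <- build_background(fx$proteome,
                            excluded_proteins = setdiff(
                              names(fx$proteome), fx$substrate_proteins),
                            L = 21)
  candB <- draw_negatives(inp$background, 200, seed = 9,
                          label = "unlabeled")
  s <- predict_and_summarize(ens, candA, inp$annotations, candB,
                             set_names = c("substrate_proteins", "random"))
  expect_equal(s$table$total, c(nrow(candA), 200))
  expect_match(s$table$percent, "^[0-9.]+%$")
  # Percent strings follow the half-up two-decimal rule.
  expect_equal(s$table$percent,
               format_proportion(s$table$predicted, s$table$total))
  if (is.null(s$note)) expect_true(s$p_value >= 0 && s$p_value <= 1)

  dir <- withr::local_tempdir()
  write_substrate_summary(s, file.path(dir, "s.tsv"))
  out <- utils::read.delim(file.path(dir, "s.tsv"))
  expect_equal(out$predicted, s$table$predicted)
})

test_that("proportion formatting rounds half-up to two decimals", {
  expect_equal(format_proportion(5412, 17572), "30.80%")
  expect_equal(format_proportion(3112, 19949), "15.60%")
  expect_equal(format_proportion(1, 800), "0.13%")    # 0.125 rounds up
  expect_equal(format_proportion(0, 10), "0.00%")
})
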