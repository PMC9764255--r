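test_that("presence filter applies both published criteria", {
  design <- toy_design()
  intens <- matrix(1000, 3, 12)
  msms <- matrix(2L, 3, 12)
  tcols <- which(design$group == "target")
  intens[1, tcols[2:3]] <- 0            # detected in only 1 of 3 targets
  msms[2, ] <- 0L; msms[2, tcols[1]] <- 1L  # 3/3 detected, total MS/MS 1
  tab <- quant_table(c("one_rep", "low_msms", "ok"), intens, msms,
                     list(), design)
  kept <- presence_filter(tab, filter_thresholds())
  expect_identical(kept$ids, "ok")
  expect_error(presence_filter(tab, filter_thresholds(min_target_replicates = 4L)),
               "exceeds")
})

test_that("compare_groups matches the classical pooled t-test", {
  design <- toy_design()
  tcols <- which(design$group == "target")
  ccols <- which(design$group == "ctrl_no_substrate")
  intens <- matrix(2^10, 2, 12)
  intens[1, tcols] <- 2^c(12, 12.1, 11.9)
  intens[1, ccols] <- 2^c(10, 10.1, 9.9)
  tab <- quant_table(c("up", "flat"), intens, matrix(5L, 2, 12),
                     list(), design)
  st <- compare_groups(tab, "ctrl_no_substrate")
  expect_equal(st$log2_ratio[1], 2)
  ref <- stats::t.test(c(12, 12.1, 11.9), c(10, 10.1, 9.9),
                       var.equal = TRUE)$p.value
  expect_equal(st$p_value[1], ref)
  expect_true(st$passed[1])
  # identical groups: ratio 0, degenerate p = 1, not passed
  expect_equal(st$log2_ratio[2], 0)
  expect_equal(st$p_value[2], 1)
  expect_false(st$passed[2])
})

test_that("Student p-values rank consistently with a permutation test", {
  # all 20 relabelings of 3 + 3 values; one-sided permutation p of the
  # mean difference should order proteins like the parametric p
  design <- toy_design()
  tcols <- which(design$group == "target")
  ccols <- which(design$group == "ctrl_no_substrate")
  set.seed(14)
  n <- 12L
  intens <- matrix(2^stats::rnorm(n * 12, 20, 1), n, 12)
  intens[1:4, tcols] <- intens[1:4, tcols] * 2^seq(2, 5)  # planted shifts
  tab <- quant_table(sprintf("P%02d", 1:n), intens, matrix(5L, n, 12),
                     list(), design)
  st <- compare_groups(tab, "ctrl_no_substrate")
  perm_p <- vapply(seq_len(n), function(i) {
    vals <- log2(c(intens[i, tcols], intens[i, ccols]))
    combs <- utils::combn(6L, 3L)
    obs <- mean(vals[1:3]) - mean(vals[4:6])
    stat <- apply(combs, 2L, function(ix) mean(vals[ix]) - mean(vals[-ix]))
    mean(stat >= obs)
  }, numeric(1))
  # strongly shifted proteins must rank top under both tests
  expect_setequal(order(st$p_value)[1:4], order(perm_p)[1:4])
  expect_true(all(perm_p[1:4] == min(perm_p)))
})

test_that("absent-in-control rule and unquantifiable sentinel", {
  design <- toy_design()
  tcols <- which(design$group == "target")
  ccols <- which(design$group == "ctrl_no_substrate")
  intens <- matrix(0, 2, 12)
  intens[1, tcols] <- 2^20          # 3/3 target, 0/3 control
  intens[2, tcols[1]] <- 2^20       # 1/3 target only: unquantifiable
  tab <- quant_table(c("exclusive", "thin"), intens, matrix(3L, 2, 12),
                     list(), design)
  st <- compare_groups(tab, "ctrl_no_substrate")
  expect_true(st$passed[1])
  expect_identical(st$log2_ratio[1], Inf)
  expect_true(is.na(st$p_value[1]))
  expect_false(st$passed[2])
  expect_true(is.na(st$p_value[2]))
})

test_that("imputation policy fills missing cells and keeps tests runnable", {
  tab <- random_quant_table(n = 60L, miss_rate = 0.35, seed = 19)
  thr <- filter_thresholds(missing_policy = "impute", impute_seed = 3L)
  st <- compare_groups(tab, "ctrl_wildtype", thr)
  # every protein with >=2 detected-or-imputed values per side is tested
  expect_true(all(!is.na(st$p_value)))
  # deterministic given the impute seed
  st2 <- compare_groups(tab, "ctrl_wildtype", thr)
  expect_equal(st$p_value, st2$p_value)
})

test_that("sequential filter composes stages and honors intersection", {
  p <- simulation_params(seed = 4L)
  sim <- simulate_experiment(generate_proteome(p), default_design(), p)
  thr <- filter_thresholds()
  report <- sequential_filter(sim$table, thr)
  present <- presence_filter(drop_flagged(sim$table), thr)
  single <- lapply(thr$control_order, function(ctrl) {
    st <- compare_groups(present, ctrl, thr)
    st$protein_id[st$passed]
  })
  expect_setequal(report$final_set, Reduce(intersect, single))
  expect_lte(length(report$final_set), report$n_after_presence)
  expect_lte(report$n_after_presence, report$n_input)
})

test_that("unattainably strict thresholds empty the final set", {
  tab <- random_quant_table(n = 20L, seed = 7)
  thr <- filter_thresholds(fold_change = 1e9)
  report <- suppressWarnings(sequential_filter(tab, thr))
  expect_length(report$final_set, 0L)
})

test_that("raising fold_change or lowering p_cutoff never grows the set", {
  p <- simulation_params(seed = 12L)
  sim <- simulate_experiment(generate_proteome(p), default_design(), p)
  base <- sequential_filter(sim$table, filter_thresholds())$final_set
  for (thr in list(filter_thresholds(fold_change = 4),
                   filter_thresholds(p_cutoff = 0.01),
                   filter_thresholds(fold_change = 8, p_cutoff = 0.001))) {
    strict <- suppressWarnings(sequential_filter(sim$table, thr))
    expect_true(all(strict$final_set %in% base))
  }
})

test_that("landmark_check arithmetic and conventions", {
  report <- list(final_set = c("A", "B", "C", "N1"))
  class(report) <- "FilterReport"
  lm <- landmark_check(report, positives = c("A", "B"),
                       negatives = c("N1", "N2", "N3", "N4"))
  expect_equal(lm$positives_retained, 1)
  expect_equal(lm$negatives_removed, 0.75)
  expect_identical(lm$negatives_leaked, "N1")
  # retained + leaked counts always sum to the set sizes
  set.seed(31)
  ids <- sprintf("X%02d", 1:20)
  report$final_set <- sample(ids, 8)
  neg <- sample(ids, 6)
  lm2 <- landmark_check(report, character(), neg)
  expect_equal(lm2$negatives_removed * 6 + length(lm2$negatives_leaked), 6)
  expect_equal(lm2$positives_retained, 1)  # empty set convention
})

test_that("replicate correlation: identity, hand-computed value, sentinel", {
  design <- toy_design()
  tab <- random_quant_table(n = 40L, miss_rate = 0, seed = 23)
  tab$intensities[, 2] <- tab$intensities[, 1]  # duplicated replicate
  r2 <- replicate_correlation(tab, "target")
  expect_equal(r2[1, 2], 1)
  expect_equal(diag(r2), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r2, t(r2))

  # 4-protein closed-form check against the Pearson formula
  x <- c(10, 11, 12, 14); y <- c(10.5, 10.9, 12.2, 13.6)
  intens <- matrix(0, 4, 12)
  intens[, 1] <- 2^x; intens[, 2] <- 2^y; intens[, 3] <- 2^x
  tab4 <- quant_table(paste0("Q", 1:4), intens, matrix(1L, 4, 12),
                      list(), design)
  r24 <- replicate_correlation(tab4, "target")
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r24[1, 2], (num / den)^2)

  # fewer than 3 co-detected proteins -> NA
  intens2 <- intens; intens2[3:4, 2] <- 0
  tab2 <- quant_table(paste0("Q", 1:4), intens2, matrix(1L, 4, 12),
                      list(), design)
  expect_true(is.na(replicate_correlation(tab2, "target")[1, 2]))
})
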