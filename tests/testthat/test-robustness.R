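test_that("robustness bins partition the line with the stated boundaries", {
  expect_equal(as.character(classify_robustness(0.80, 0.80)), "stable")
  expect_equal(as.character(classify_robustness(0.80, 0.84)), "increase")
  expect_equal(as.character(classify_robustness(0.80, 0.30)), "catastrophic")
  # boundary inclusivities: 0 and -5% are stable, exactly -50% is decrease
  expect_equal(as.character(classify_robustness(1, c(1, 0.95, 0.9499, 0.5, 0.4999))),
               c("stable", "stable", "decrease", "decrease", "catastrophic"))
  # every delta lands in exactly one bin
  deltas <- seq(-0.99, 0.5, by = 0.01)
  bins <- classify_robustness(rep(1, length(deltas)), 1 + deltas)
  expect_false(anyNA(bins))
  expect_error(classify_robustness(0, 0.5),
               class = "perturbr_undefined_baseline")
})

test_that("tabulation reproduces the published totals and percentages", {
  cells <- expand_counts(published_model_task_counts())
  tb <- tabulate_robustness(cells, group = NULL, digits = 2)
  tot <- tb[nrow(tb), ]
  expect_equal(as.integer(tot[robustness_levels()]), c(38L, 113L, 104L, 15L))
  expect_equal(tot$total, 270)
  pct <- attr(tb, "percent")
  expect_equal(unname(pct[c("increase", "stable", "catastrophic")]),
               c(14.07, 41.85, 5.56))
  # per-type table: published 5/35/28/4 with 48.6% stable at 1 decimal
  cells4 <- expand_counts(published_ptype_counts())
  tb4 <- tabulate_robustness(cells4, group = "ptype", digits = 1)
  tot4 <- tb4[nrow(tb4), ]
  expect_equal(as.integer(tot4[robustness_levels()]), c(5L, 35L, 28L, 4L))
  expect_equal(unname(attr(tb4, "percent")["stable"]), 48.6)
  # empty input gives an all-zero table
  empty <- tabulate_robustness(tibble::tibble(category = character()))
  expect_equal(as.integer(empty[1, robustness_levels()]), rep(0L, 4L))
})

test_that("pearson chi-squared matches its definition and the printed values", {
  cells <- expand_counts(published_model_task_counts())
  by_model <- tabulate_robustness(cells, group = "model")
  expect_equal(sort(as.integer(by_model$total[by_model$model != "Total"])),
               c(72L, 99L, 99L))
  t1 <- pearson_chi_squared(by_model)
  expect_equal(t1$df, 6L)
  expect_equal(round(t1$statistic, 2), 81.25)
  expect_lt(t1$p.value, 0.001)
  by_task <- tabulate_robustness(cells, group = "task")
  t2 <- pearson_chi_squared(by_task)
  expect_equal(round(t2$statistic, 2), 44.74)
  # agreement with the reference implementation, no continuity correction
  m <- perturbr:::as_robustness_matrix(by_model)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(t1$statistic, unname(ref$statistic))
  expect_equal(t1$p.value, unname(ref$p.value))
  # permutation invariance
  mp <- m[c(2, 3, 1), c(3, 1, 4, 2)]
  expect_equal(pearson_chi_squared(mp)$statistic, t1$statistic)
  # identical row distributions carry no association
  flat <- rbind(a = c(10, 20, 5, 5), b = c(20, 40, 10, 10))
  expect_equal(pearson_chi_squared(flat)$statistic, 0)
  # zero margins are dropped with a warning
  withzero <- rbind(a = c(5, 6, 1, 0), b = c(7, 2, 3, 0), c = c(0, 0, 0, 0))
  expect_warning(t3 <- pearson_chi_squared(withzero), "zero")
  expect_equal(t3$df, 2L)
})

test_that("friedman statistic matches oracles, closed forms, and invariances", {
  # no effect: identical treatments in every block
  expect_equal(friedman_test(matrix(rep(1:4, 3), 4, 3))$statistic, 0)
  # perfectly consistent ranking with k = 3 gives statistic 2n
  for (n in c(4L, 10L, 25L)) {
    m <- outer(rep(0, n), c(1, 2, 3), "+")
    expect_equal(friedman_test(m)$statistic, 2 * n)
    expect_equal(friedman_test(m)$df, 2L)
  }
  # exhaustive small-matrix agreement with the reference implementation,
  # including tied data
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(sample(1:4, 12L, replace = TRUE), 4L, 3L)
    got <- friedman_test(m)$statistic
    want <- unname(stats::friedman.test(m)$statistic)
    if (is.nan(want)) want <- 0  # reference yields NaN on fully tied input
    expect_equal(got, want)
    # and with an independently coded rank-sum formula
    r <- t(apply(m, 1, rank))
    rj <- colSums(r)
    denom <- sum(r^2) - 4 * 3 * 16 / 4
    want2 <- if (denom <= 0) 0 else 2 * sum((rj - 4 * 2)^2) / denom
    expect_equal(got, want2)
  }
  # invariance under monotone within-block transforms
  set.seed(12)
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(friedman_test(exp(m))$statistic, friedman_test(m)$statistic)
  expect_equal(friedman_test(m * 100 + 7)$statistic,
               friedman_test(m)$statistic)
})

test_that("conover post hoc matches the textbook formula and bonferroni rules", {
  # identical treatments: t = 0, corrected p = 1
  mc <- matrix(rep(1:5, 3), 5, 3)
  ph <- conover_posthoc(mc)
  expect_equal(ph$statistic, rep(0, 3))
  expect_equal(ph$p.value, rep(1, 3))
  # toy 5x3 matrix against an independently coded evaluation
  set.seed(13)
  m <- matrix(rnorm(15, 5), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  ph2 <- conover_posthoc(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  n <- 5; k <- 3
  a1 <- sum(r^2); b1 <- sum(rj^2) / n
  dfree <- (n - 1) * (k - 1)
  se <- sqrt(2 * n * (a1 - b1) / dfree)
  for (row in seq_len(nrow(ph2))) {
    i <- match(ph2$group1[row], colnames(m))
    j <- match(ph2$group2[row], colnames(m))
    t_want <- abs(rj[i] - rj[j]) / se
    expect_equal(ph2$statistic[row], unname(t_want))
    p_want <- min(1, 2 * pt(t_want, dfree, lower.tail = FALSE) * 3)
    expect_equal(ph2$p.value[row], unname(p_want))
    expect_equal(ph2$effect_size[row],
                 unname(abs(t_want) / sqrt(t_want^2 + dfree)))
    # corrected p never below the uncorrected p
    expect_gte(ph2$p.value[row],
               2 * pt(abs(ph2$statistic[row]), dfree, lower.tail = FALSE) - 1e-12)
  }
  # fewer than 3 treatments: skipped with a notice
  expect_message(out <- conover_posthoc(m[, 1:2]), "skipped")
  expect_null(out)
})

test_that("repeated-measures anova matches aov and the paired-t equivalence", {
  # zero between-treatment variance
  m0 <- matrix(rep(c(2, 5, 3, 4), 3), 4, 3)
  expect_equal(repeated_measures_anova(m0)$statistic, 0)
  # toy 3x3 against the explicit sums-of-squares partition
  m <- matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9), 3, 3)
  got <- repeated_measures_anova(m)
  grand <- mean(m)
  sst <- 3 * sum((colMeans(m) - grand)^2)
  sss <- 3 * sum((rowMeans(m) - grand)^2)
  sse <- sum((m - grand)^2) - sst - sss
  expect_equal(got$statistic, (sst / 2) / (sse / 4))
  # two treatments: F equals the squared paired t statistic
  set.seed(14)
  m2 <- matrix(rnorm(20, 5), 10, 2)
  expect_equal(repeated_measures_anova(m2)$statistic,
               unname(t.test(m2[, 1], m2[, 2], paired = TRUE)$statistic^2))
  # agreement with the reference within-subjects fit
  set.seed(15)
  m3 <- matrix(rnorm(18, 3), 6, 3)
  d <- data.frame(y = as.vector(m3), subj = factor(rep(1:6, 3)),
                  tr = factor(rep(1:3, each = 6)))
  sm <- summary(stats::aov(y ~ tr + Error(subj / tr), data = d))
  expect_equal(repeated_measures_anova(m3)$statistic,
               sm[["Error: subj:tr"]][[1]]["tr", "F value"])
  # missing cells are an error, not imputed
  m3[2, 3] <- NA
  expect_error(repeated_measures_anova(m3), class = "perturbr_bad_table")
})

test_that("medical perturbation profile buckets ratios and recovers ordering", {
  expect_warning(
    prof0 <- medical_perturbation_profile(tibble::tibble(
      n_perturbed = c(4L, 0L), n_perturbed_medical = c(1L, 0L),
      level = 0.1, score = c(0.5, 0.9))),
    "no perturbed tokens")
  expect_equal(nrow(prof0), 1L)
  # ratio arithmetic: 1 of 4 perturbed tokens medical -> 0.25 (first bucket
  # covers (0.2, 0.3])
  expect_equal(as.numeric(prof0$ratio_mid), 0.25)
  # programmed monotone degradation is recovered in bucket medians
  set.seed(16)
  ratios <- rep(c(0.05, 0.35, 0.65, 0.95), each = 50L)
  ex <- tibble::tibble(
    n_perturbed = 20L,
    n_perturbed_medical = as.integer(round(20 * ratios)),
    level = 0.1,
    score = 1 - 0.5 * ratios + rnorm(200, 0, 0.01))
  prof <- medical_perturbation_profile(ex)
  ord <- order(prof$ratio_mid)
  expect_true(all(diff(prof$median_score[ord]) < 0))
  # all perturbed tokens medical -> ratio 1 lands in the top bucket
  top <- medical_perturbation_profile(tibble::tibble(
    n_perturbed = 3L, n_perturbed_medical = 3L, level = 0.3, score = 0.4))
  expect_equal(as.numeric(top$ratio_mid), 0.95)
})
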