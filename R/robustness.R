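#' Four-bin robustness classification
#'
#' The relative change of a metric under perturbation,
#' `delta = (perturbed - original) / original`, is binned into:
#'
#' * `increase`: `delta > 0`
#' * `stable`: `-0.05 <= delta <= 0` (drop of less than 5%)
#' * `decrease`: `-0.50 <= delta < -0.05` (drop of more than 5% but at most 50%)
#' * `catastrophic`: `delta < -0.50` (performance falls below half the
#'   original)
#'
#' Boundary values are assigned to the milder bin so the four bins partition
#' the real line. A zero baseline has no defined relative change and is
#' rejected.
#'
#' @param original_value Baseline metric value(s), strictly positive.
#' @param perturbed_value Perturbed metric value(s).
#' @return A factor with levels increase/stable/decrease/catastrophic.
#' @examples
#' classify_robustness(0.80, c(0.84, 0.80, 0.60, 0.30))
#' @export
classify_robustness <- function(original_value, perturbed_value) {
  stopifnot(length(original_value) == length(perturbed_value) ||
              length(original_value) == 1L)
  if (any(original_value <= 0)) {
    abort("Baseline metric value must be > 0 (undefined relative change).",
          class = "perturbr_undefined_baseline")
  }
  delta <- (perturbed_value - original_value) / original_value
  # boundary comparisons tolerate floating-point representation error so a
  # drop of exactly 5% (or 50%) lands in its stated bin
  eps <- 1e-9
  cat <- dplyr::case_when(
    delta > 0 ~ "increase",
    delta >= -0.05 - eps ~ "stable",
    delta >= -0.50 - eps ~ "decrease",
    TRUE ~ "catastrophic")
  factor(cat, levels = robustness_levels())
}

#' @rdname classify_robustness
#' @export
robustness_levels <- function() {
  c("increase", "stable", "decrease", "catastrophic")
}

#' Tabulate robustness categories into a contingency table
#'
#' Counts categories per grouping factor (model, task, perturbation type, or
#' any combination; `NULL` gives the totals only) and appends a `Total` row
#' with percentages rounded half-up to `digits` decimals.
#'
#' @param data Tibble with a `category` column (factor or character) plus any
#'   grouping columns.
#' @param group Character vector of grouping column names, or `NULL`.
#' @param digits Decimals for the total-row percentages (2 in the per-model
#'   tables, 1 in the per-type table).
#' @return A `robustness_table`: a wide tibble with one row per group plus a
#'   `Total` row, count columns per category, `total`, and total-row
#'   percentages in attribute `"percent"`.
#' @export
tabulate_robustness <- function(data, group = NULL, digits = 2) {
  data <- tibble::as_tibble(data)
  stopifnot("category" %in% names(data))
  lv <- robustness_levels()
  data$category <- factor(as.character(data$category), levels = lv)
  if (is.null(group)) {
    data$.group <- "all"
    group <- ".group"
  }
  counts <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(group)), .data$category,
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  counts$total <- as.integer(rowSums(counts[lv]))
  tot <- colSums(counts[c(lv, "total")])
  pct <- round_half_up(100 * tot[lv] / tot[["total"]] * 10^digits) / 10^digits
  total_row <- tibble::as_tibble(as.list(tot))
  total_row[[group[[1]]]] <- "Total"
  out <- dplyr::bind_rows(counts, total_row)
  if (".group" %in% names(out)) out$.group <- NULL
  structure(out, percent = pct, class = c("robustness_table", class(out)))
}

# Extract the count matrix (group rows x 4 category columns) from a
# robustness_table, matrix, or plain data frame.
as_robustness_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- tibble::as_tibble(x)
  lv <- intersect(robustness_levels(), names(x))
  stopifnot(length(lv) >= 2L)
  rows <- !apply(x[lv], 1L, function(r) any(is.na(r)))
  label_col <- setdiff(names(x), c(lv, "total"))
  lab <- if (length(label_col)) as.character(x[[label_col[[1]]]]) else
    as.character(seq_len(nrow(x)))
  keep <- rows & lab != "Total"
  m <- as.matrix(x[keep, lv])
  rownames(m) <- lab[keep]
  m
}

.new_test <- function(method, statistic, df, p.value, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p.value = unname(p.value), ...),
            class = "perturbr_test")
}

#' @export
print.perturbr_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(x$df, collapse = ", "),
              x$p.value))
  invisible(x)
}

#' Pearson chi-squared test of independence on a robustness table
#'
#' Computes `sum((O - E)^2 / E)` against the margins-derived expected counts,
#' without continuity correction; degrees of freedom `(rows-1) * (cols-1)`.
#' All-zero rows or columns are dropped with a warning before testing.
#'
#' @param table A `robustness_table`, count matrix, or wide count data frame.
#' @return A `perturbr_test` with `statistic`, `df`, `p.value`, and the
#'   observed and expected matrices.
#' @export
pearson_chi_squared <- function(table) {
  m <- as_robustness_matrix(table)
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warn("Dropping all-zero row(s)/column(s) before the chi-squared test.")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("Chi-squared test needs at least a 2x2 table.",
          class = "perturbr_bad_table")
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  .new_test("Pearson chi-squared test of independence",
            stat, df, pchisq(stat, df, lower.tail = FALSE),
            observed = m, expected = e)
}

# Within-block mid-ranks of a blocks x treatments matrix.
.block_ranks <- function(m) {
  t(apply(m, 1L, rank))
}

#' Friedman rank test over related treatments
#'
#' Nonparametric test for differences among `k` treatments measured on the
#' same `n` blocks. Values are ranked within blocks with mid-ranks for ties;
#' the tie-corrected statistic
#' `(k - 1) * sum((R_j - n(k+1)/2)^2) / (sum(r^2) - n k (k+1)^2 / 4)`
#' is referred to a chi-squared distribution with `k - 1` degrees of freedom.
#' A matrix that is constant within every block has no rank information and
#' yields statistic 0.
#'
#' @param m Numeric matrix, blocks in rows, treatments in columns.
#' @return A `perturbr_test` with the rank sums in `rank_sums`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort("Friedman test needs at least 2 blocks and 2 treatments.",
          class = "perturbr_bad_table")
  }
  if (anyNA(m)) abort("Friedman test needs complete blocks.",
                      class = "perturbr_bad_table")
  r <- .block_ranks(m)
  rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  stat <- if (denom <= 0) 0 else
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / denom
  .new_test("Friedman rank test", stat, k - 1L,
            pchisq(stat, k - 1L, lower.tail = FALSE),
            rank_sums = setNames(rj, colnames(m)), n_blocks = n)
}

#' Conover post hoc comparisons after a Friedman test
#'
#' Pairwise rank-sum comparisons between treatments following a significant
#' Friedman test: `t = |R_i - R_j| / sqrt(2 n (A1 - B1) / ((n-1)(k-1)))`
#' where `A1` is the sum of squared within-block ranks and `B1 = sum(R_j^2)/n`,
#' referred to a t distribution with `(n-1)(k-1)` degrees of freedom.
#' P-values are Bonferroni-corrected (multiplied by the number of pairs,
#' capped at 1). The effect size `r = |t| / sqrt(t^2 + df)` is the standard
#' r-from-t convention for ranked tests. With identical treatments the
#' denominator vanishes and all comparisons report `t = 0`, `p = 1`.
#'
#' @param m Numeric matrix, blocks in rows, treatments in columns (at least
#'   3 treatments; with fewer, the post hoc is skipped with a message).
#' @param correction Only `"bonferroni"` is implemented.
#' @return A tibble `group1`, `group2`, `statistic`, `df`, `p.value`,
#'   `effect_size`, or `NULL` (invisibly, with a message) for k < 3.
#' @export
conover_posthoc <- function(m, correction = "bonferroni") {
  stopifnot(identical(correction, "bonferroni"))
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 3L) {
    message("Fewer than 3 treatments: post hoc comparisons skipped.")
    return(invisible(NULL))
  }
  if (anyNA(m)) abort("Conover post hoc needs complete blocks.",
                      class = "perturbr_bad_table")
  r <- .block_ranks(m)
  rj <- colSums(r)
  a1 <- sum(r^2)
  b1 <- sum(rj^2) / n
  df <- (n - 1L) * (k - 1L)
  denom <- sqrt(2 * n * (a1 - b1) / df)
  labs <- colnames(m) %||% paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    tval <- if (denom == 0) 0 else abs(rj[i] - rj[j]) / denom
    pval <- if (denom == 0) 1 else
      min(1, 2 * pt(abs(tval), df, lower.tail = FALSE) * n_pairs)
    tibble::tibble(group1 = labs[i], group2 = labs[j],
                   statistic = unname(tval), df = df, p.value = pval,
                   effect_size = unname(abs(tval) / sqrt(tval^2 + df)))
  })
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects F test over complete blocks using the standard
#' sums-of-squares partition (treatment, subject, error):
#' `F = (SS_treat / (k-1)) / (SS_err / ((n-1)(k-1)))`. With two treatments
#' the statistic equals the squared paired t statistic. Missing cells are an
#' error — no imputation is performed.
#'
#' @param m Numeric matrix, subjects (blocks) in rows, treatments in columns.
#' @return A `perturbr_test`; `df` is `c(k - 1, (n-1)(k-1))`.
#' @export
repeated_measures_anova <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort("Repeated-measures ANOVA needs at least 2 subjects and 2 treatments.",
          class = "perturbr_bad_table")
  }
  if (anyNA(m)) {
    abort("Repeated-measures ANOVA requires complete blocks (no missing cells).",
          class = "perturbr_bad_table")
  }
  grand <- mean(m)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_err <- ss_err / df2
  f <- if (ms_err <= 0) {
    if (ss_treat <= 1e-12) 0 else Inf
  } else {
    (ss_treat / df1) / ms_err
  }
  .new_test("One-way repeated-measures ANOVA", f, c(df1, df2),
            if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE),
            ss = c(treatment = ss_treat, subject = ss_subj, error = ss_err))
}

#' Medical-term perturbation profile
#'
#' For each perturbed example, the medical-term ratio is the fraction of
#' perturbed tokens that are medical terms. Examples are bucketed by that
#' ratio (default: ten equal-width buckets on \[0, 1\]) and the median score
#' is reported per bucket and perturbation level. Examples with no perturbed
#' tokens are excluded with a warning.
#'
#' @param examples Tibble with columns `n_perturbed`, `n_perturbed_medical`,
#'   `level`, and `score`.
#' @param n_buckets Number of equal-width ratio buckets.
#' @return A tibble `level`, `bucket` (ordered factor), `ratio_mid`,
#'   `median_score`, `n`.
#' @export
medical_perturbation_profile <- function(examples, n_buckets = 10L) {
  examples <- tibble::as_tibble(examples)
  need <- c("n_perturbed", "n_perturbed_medical", "level", "score")
  stopifnot(all(need %in% names(examples)))
  none <- examples$n_perturbed == 0L
  if (any(none)) {
    warn(sprintf("Excluding %d example(s) with no perturbed tokens.",
                 sum(none)))
    examples <- examples[!none, ]
  }
  breaks <- seq(0, 1, length.out = n_buckets + 1L)
  examples |>
    dplyr::mutate(
      ratio = .data$n_perturbed_medical / .data$n_perturbed,
      bucket = cut(.data$ratio, breaks = breaks, include.lowest = TRUE,
                   ordered_result = TRUE)) |>
    dplyr::group_by(.data$level, .data$bucket) |>
    dplyr::summarise(
      ratio_mid = (breaks[as.integer(.data$bucket[[1]])] +
                     breaks[as.integer(.data$bucket[[1]]) + 1L]) / 2,
      median_score = median(.data$score), n = dplyr::n(), .groups = "drop")
}
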