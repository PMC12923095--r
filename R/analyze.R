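#' Attach robustness bins to a long results table
#'
#' Joins each perturbed cell `(task, model, ptype, level, metric)` to its
#' unperturbed baseline `(task, model, metric, ptype = "original")` and
#' classifies the relative change into the four robustness bins.
#'
#' @param results Long results tibble: `task`, `model`, `ptype`, `level`,
#'   `metric`, `value`, including `ptype == "original"` baseline rows.
#' @param metrics `"all"` to bin every metric cell (the 270-cell view), or
#'   `"primary"` to keep one analysis metric per task (accuracy for
#'   classification, ROUGE for question answering — the 72-cell view).
#' @return The perturbed rows with added columns `original`, `delta`,
#'   `category`.
#' @export
robustness_bins <- function(results, metrics = c("all", "primary")) {
  metrics <- match.arg(metrics)
  results <- tibble::as_tibble(results)
  need <- c("task", "model", "ptype", "level", "metric", "value")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort(paste0("Results table missing column(s): ",
                 paste(miss, collapse = ", ")), class = "perturbr_bad_results")
  }
  if (metrics == "primary") {
    results <- results |>
      dplyr::filter((.data$task == "qa" & .data$metric == "rouge") |
                      (.data$task != "qa" & .data$metric == "accuracy"))
  }
  base <- results |>
    dplyr::filter(.data$ptype == "original") |>
    dplyr::select("task", "model", "metric", original = "value")
  pert <- results |> dplyr::filter(.data$ptype != "original")
  if (nrow(base) == 0L || nrow(pert) == 0L) {
    abort("Results must contain both original and perturbed rows.",
          class = "perturbr_bad_results")
  }
  pert |>
    dplyr::inner_join(base, by = c("task", "model", "metric")) |>
    dplyr::mutate(delta = (.data$value - .data$original) / .data$original,
                  category = classify_robustness(.data$original, .data$value))
}

#' Friedman test along one experimental dimension
#'
#' Pivots the long results table into a blocks-by-treatments matrix for the
#' chosen dimension and runs [friedman_test()] plus [conover_posthoc()].
#' Treatments are the dimension's levels; blocks are every complete
#' combination of the remaining identifiers (incomplete blocks — e.g. a model
#' that never ran a task — are dropped).
#'
#' @param results Long results tibble (perturbed rows; original rows are
#'   ignored except for `dimension = "level"` where only perturbed levels
#'   form treatments).
#' @param dimension One of `"ptype"`, `"level"`, `"model"`, `"task"`.
#' @return A list with elements `friedman` (a `perturbr_test`), `posthoc`
#'   (tibble), and `matrix` (the blocks-by-treatments matrix used).
#' @export
friedman_by_dimension <- function(results,
                                  dimension = c("ptype", "level", "model", "task")) {
  dimension <- match.arg(dimension)
  results <- tibble::as_tibble(results) |>
    dplyr::filter(.data$ptype != "original")
  if (dimension == "task") {
    # metric sets differ across tasks; compare on each task's analysis metric
    results <- results |>
      dplyr::filter((.data$task == "qa" & .data$metric == "rouge") |
                      (.data$task != "qa" & .data$metric == "accuracy"))
  }
  # levels are matched by position (low/medium/high), not by numeric value:
  # the grids differ across perturbation types
  results <- results |>
    dplyr::group_by(.data$ptype) |>
    dplyr::mutate(level_name = c("low", "medium", "high",
                                 "l4", "l5")[dplyr::dense_rank(.data$level)]) |>
    dplyr::ungroup()
  dim_col <- if (dimension == "level") "level_name" else dimension
  ids <- setdiff(c("task", "model", "ptype", "level_name", "metric"), dim_col)
  # after restricting to one analysis metric per task, `metric` is implied by
  # `task` and must not split blocks across tasks
  if (dimension == "task") ids <- setdiff(ids, "metric")
  wide <- results |>
    dplyr::select(dplyr::all_of(c(ids, dim_col, "value"))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(dim_col),
                       values_from = "value") |>
    dplyr::filter(dplyr::if_all(dplyr::everything(), ~ !is.na(.x)))
  m <- as.matrix(wide[setdiff(names(wide), ids)])
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort(sprintf("Not enough complete blocks for dimension '%s'.", dimension),
          class = "perturbr_bad_results")
  }
  list(friedman = friedman_test(m),
       posthoc = conover_posthoc(m),
       matrix = m)
}

#' Run the full robustness-analysis chain on a results table
#'
#' Produces the study's analysis bundle: the four-bin classification of every
#' metric cell; contingency tables by model and by task (with Pearson
#' chi-squared tests); the per-perturbation-type table on the primary-metric
#' cells; Friedman tests with Conover-Bonferroni post hoc comparisons along
#' each dimension; one-way repeated-measures ANOVA along each dimension; and
#' the headline proportions (share of cells stable or improved, share
#' catastrophic).
#'
#' @param results Long results tibble (see [robustness_bins()]).
#' @param dimensions Dimensions for the rank tests and ANOVA.
#' @return An `analysis_bundle` list: `bins`, `table_by_model`,
#'   `table_by_task`, `table_by_ptype`, `chisq_by_model`, `chisq_by_task`,
#'   `friedman` (named list per dimension), `anova` (named list),
#'   `proportions`.
#' @export
analyze_results <- function(results,
                            dimensions = c("ptype", "level", "model", "task")) {
  bins <- robustness_bins(results, metrics = "all")
  bins_primary <- robustness_bins(results, metrics = "primary")
  tb_model <- tabulate_robustness(bins, group = "model", digits = 2)
  tb_task <- tabulate_robustness(bins, group = "task", digits = 2)
  tb_ptype <- tabulate_robustness(bins_primary, group = "ptype", digits = 1)
  fried <- list(); rma <- list()
  for (d in dimensions) {
    fd <- tryCatch(friedman_by_dimension(results, d), error = function(e) NULL)
    fried[[d]] <- fd
    rma[[d]] <- if (!is.null(fd)) repeated_measures_anova(fd$matrix) else NULL
  }
  n_cells <- nrow(bins)
  counts <- table(bins$category)
  structure(list(
    bins = bins,
    table_by_model = tb_model, table_by_task = tb_task,
    table_by_ptype = tb_ptype,
    chisq_by_model = pearson_chi_squared(tb_model),
    chisq_by_task = pearson_chi_squared(tb_task),
    friedman = fried, anova = rma,
    proportions = tibble::tibble(
      category = names(counts), n = as.integer(counts),
      percent = round_half_up(10000 * as.integer(counts) / n_cells) / 100),
    n_cells = n_cells
  ), class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("<analysis_bundle> %d metric cells\n", x$n_cells))
  print(x$proportions)
  cat("\nChi-squared (by model): ")
  print(x$chisq_by_model)
  cat("Chi-squared (by task): ")
  print(x$chisq_by_task)
  invisible(x)
}

#' @rdname tidy_perturbr
#' @export
tidy.perturbr_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = paste(x$df, collapse = ","), p.value = x$p.value)
}

#' Broom-style tidiers for perturbr test objects
#'
#' `tidy()` returns the statistic, degrees of freedom and p-value as a
#' one-row tibble; `glance()` is an alias for test objects.
#'
#' @param x A `perturbr_test` object.
#' @param ... Unused.
#' @name tidy_perturbr
#' @export
glance.perturbr_test <- function(x, ...) tidy.perturbr_test(x)
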