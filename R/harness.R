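#' Evaluate one (task, perturbation type, level) condition
#'
#' Builds a self-contained prompt per item, calls the adapter once per item
#' (session isolation), parses/scores the responses, and aggregates one
#' metric row per metric. Per-item adapter errors are recorded and the item
#' excluded from `n_items`; the condition itself fails only when every item
#' fails. Raw responses are kept in the `"responses"` attribute for audit.
#'
#' @param items Corpus variant rows, homogeneous in `task`, `ptype`, `level`.
#' @param adapter An adapter function `(prompt, item) -> response`.
#' @param template A [prompt_template()] for the items' task.
#' @param model Model name recorded in the results.
#' @param label_set Label set for classification tasks (defaults to the gold
#'   labels present).
#' @param bertscore_fn Optional embedding scorer for QA.
#' @return A tibble `task`, `model`, `ptype`, `level`, `metric`, `value`,
#'   `n_items` (the per-condition result cells).
#' @export
run_condition <- function(items, adapter, template, model = "mock",
                          label_set = NULL, bertscore_fn = NULL) {
  items <- tibble::as_tibble(items)
  stopifnot(nrow(items) > 0L)
  for (col in c("task", "ptype")) {
    if (length(unique(items[[col]])) != 1L) {
      abort(sprintf("Condition slice must be homogeneous in `%s`.", col))
    }
  }
  if (length(unique(items$level[!is.na(items$level)])) > 1L) {
    abort("Condition slice must be homogeneous in `level`.")
  }
  task <- items$task[[1]]
  responses <- character(nrow(items))
  errors <- rep(NA_character_, nrow(items))
  for (i in seq_len(nrow(items))) {
    item <- items[i, ]
    resp <- tryCatch(adapter(build_prompt(template, item), item),
                     error = function(e) e)
    if (inherits(resp, "error")) {
      errors[i] <- conditionMessage(resp)
      responses[i] <- NA_character_
    } else {
      responses[i] <- resp
    }
  }
  ok <- is.na(errors)
  if (!any(ok)) {
    abort(sprintf("All %d items failed in condition %s/%s.",
                  nrow(items), task, items$ptype[[1]]),
          class = "perturbr_adapter_error")
  }
  if (task == "qa") {
    per_item <- purrr::map2_dfr(responses[ok], items$gold[ok],
                                score_qa, bertscore_fn = bertscore_fn)
    agg <- per_item |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  } else {
    label_set <- label_set %||% sort(unique(items$gold))
    preds <- vapply(responses[ok], parse_classification_response, "",
                    label_set = label_set, USE.NAMES = FALSE)
    agg <- score_classification(preds, items$gold[ok], label_set)
  }
  out <- tibble::tibble(
    task = task, model = model, ptype = items$ptype[[1]],
    level = items$level[[1]], metric = agg$metric, value = agg$value,
    n_items = sum(ok))
  attr(out, "responses") <- tibble::tibble(
    record_id = items$record_id, response = responses, error = errors)
  out
}

#' Evaluate a corpus across all its conditions
#'
#' Splits the corpus by (task, ptype, level), runs [run_condition()] on each
#' slice, and binds the per-condition metric rows — the long results table
#' the robustness analysis consumes. When `out_csv` is given, completed
#' conditions already present in the file are skipped and new rows appended,
#' so an interrupted evaluation can resume without duplicating work.
#'
#' @param corpus Corpus tibble from [build_perturbed_corpus()].
#' @param adapter Adapter function.
#' @param model Model name recorded in the results.
#' @param templates Named list of [prompt_template()] per task present.
#' @param label_sets Optional named list of label sets per task.
#' @param out_csv Optional path for incremental CSV output.
#' @param bertscore_fn Optional embedding scorer for QA.
#' @return The results tibble (all conditions, including any previously
#'   completed ones read back from `out_csv`).
#' @export
run_evaluation <- function(corpus, adapter, model, templates,
                           label_sets = NULL, out_csv = NULL,
                           bertscore_fn = NULL) {
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- readr::read_csv(out_csv, show_col_types = FALSE, progress = FALSE)
  }
  keys <- corpus |>
    dplyr::distinct(.data$task, .data$ptype, .data$level)
  res <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    if (!is.null(done) &&
        nrow(dplyr::semi_join(done, dplyr::mutate(k, model = model),
                              by = c("task", "ptype", "level", "model"))) > 0L) {
      next
    }
    slice <- corpus |>
      dplyr::filter(.data$task == k$task, .data$ptype == k$ptype,
                    (is.na(k$level) & is.na(.data$level)) |
                      (!is.na(k$level) & !is.na(.data$level) &
                         .data$level == k$level))
    one <- run_condition(slice, adapter, templates[[k$task]], model = model,
                         label_set = label_sets[[k$task]],
                         bertscore_fn = bertscore_fn)
    res[[length(res) + 1L]] <- one
    if (!is.null(out_csv)) {
      readr::write_csv(one, out_csv, append = file.exists(out_csv))
    }
  }
  dplyr::bind_rows(c(list(done), res))
}
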