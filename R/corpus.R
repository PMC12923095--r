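#' The study perturbation grid
#'
#' Three levels per perturbation type: typographical 10/30/50%, homophone
#' 10/20/30% (fewer words have sound-alikes, so lower fractions are
#' realistic), redaction 10/30/50%. Levels are labelled low/medium/high in
#' grid order.
#'
#' @return A tibble with columns `ptype`, `level`, `level_name`.
#' @export
perturbation_grid <- function() {
  tibble::tibble(
    ptype = rep(c("typographical", "homophone", "redaction"), each = 3L),
    level = c(0.10, 0.30, 0.50, 0.10, 0.20, 0.30, 0.10, 0.30, 0.50),
    level_name = rep(c("low", "medium", "high"), times = 3L)
  )
}

.validate_grid <- function(grid) {
  stopifnot(all(c("ptype", "level") %in% names(grid)))
  for (pt in unique(grid$ptype)) {
    lv <- grid$level[grid$ptype == pt]
    if (any(diff(lv) <= 0)) abort("Grid levels must be strictly increasing.")
  }
  grid
}

#' Validate a task-record table
#'
#' Task records are tibbles with columns `id`, `task`
#' (`"sentiment_binary"`, `"condition_ternary"`, or `"qa"`), `text`, and
#' `gold`; QA records additionally carry non-empty `note_id`, `note`,
#' `question` (the perturbed field) and `answer`.
#'
#' @param records A data frame of task records.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_task_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("id", "task", "text", "gold")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("Task records missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad_task <- setdiff(unique(records$task),
                      c("sentiment_binary", "condition_ternary", "qa"))
  if (length(bad_task)) {
    abort(paste0("Unknown task kind(s): ", paste(bad_task, collapse = ", ")))
  }
  if (anyDuplicated(records$id)) abort("Record ids must be unique.")
  qa <- records[records$task == "qa", , drop = FALSE]
  if (nrow(qa) > 0L) {
    for (col in c("note_id", "note", "question", "answer")) {
      if (!col %in% names(records) || any(!nzchar(trimws(qa[[col]])))) {
        abort(sprintf("QA records need a non-empty `%s` column.", col))
      }
    }
  }
  records
}

#' Build the perturbed corpus across the full grid
#'
#' For every record, attempts every (type, level) cell of the grid. A record
#' is retained only if *all* cells are feasible (the retention rule); retained
#' records contribute one original variant plus one variant per grid cell.
#' For QA records the question is the perturbed field. Dropped records are
#' reported, with the failing cells, in the `"dropped"` attribute, and a run
#' manifest (grid, seed, provider version, counts) in `"manifest"`.
#'
#' @param records Task records (see [validate_task_records()]).
#' @param grid Perturbation grid tibble; defaults to [perturbation_grid()].
#' @param seed Global integer seed; per-(record, cell) seeds are derived from
#'   it so results are independent of processing order.
#' @param provider,lexicon,tagger Passed to [perturb_example()].
#' @param letter_fraction_range Typo intensity range.
#' @return A tibble of variants: `record_id`, `task`, `ptype` (`"original"`
#'   included), `level` (`NA` for originals), `text`, `gold`, QA columns when
#'   present, `n_words`, `n_perturbed`, `n_perturbed_medical`, and an `edits`
#'   list-column.
#' @export
build_perturbed_corpus <- function(records, grid = perturbation_grid(),
                                   seed = 1L,
                                   provider = homophone_provider_dictionary(),
                                   lexicon = default_medical_lexicon(),
                                   tagger = rule_pos_tagger,
                                   letter_fraction_range = c(0.20, 0.50)) {
  records <- validate_task_records(records)
  grid <- .validate_grid(grid)
  is_qa <- records$task == "qa"
  out <- vector("list", nrow(records))
  dropped <- list()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    target_text <- if (is_qa[r]) rec$question else rec$text
    variants <- vector("list", nrow(grid))
    failed <- character(0)
    for (g in seq_len(nrow(grid))) {
      sp <- perturbation_spec(
        ptype = grid$ptype[g], level = grid$level[g],
        letter_fraction_range = letter_fraction_range,
        seed = derive_seed(seed, paste(rec$id, grid$ptype[g], grid$level[g]))
      )
      px <- tryCatch(
        perturb_example(target_text, sp, provider = provider,
                        lexicon = lexicon, tagger = tagger),
        perturbr_infeasible = function(e) e
      )
      if (inherits(px, "condition")) {
        failed <- c(failed, sprintf("%s:%g", grid$ptype[g], grid$level[g]))
      } else {
        variants[[g]] <- px
      }
    }
    if (length(failed) > 0L) {
      dropped[[length(dropped) + 1L]] <-
        tibble::tibble(record_id = rec$id,
                       reason = paste(failed, collapse = ";"))
      next
    }
    n_words <- sum(variants[[1]]$annotations$is_word)
    rows <- purrr::map2(variants, seq_len(nrow(grid)), function(px, g) {
      med <- sum(px$annotations$is_medical[px$edits$token_index])
      v <- rec
      v$text <- if (is_qa[r]) rec$text else px$perturbed
      if (is_qa[r]) v$question <- px$perturbed
      dplyr::mutate(v, ptype = grid$ptype[g], level = grid$level[g],
                    n_words = n_words, n_perturbed = px$target_count,
                    n_perturbed_medical = med, edits = list(px$edits))
    })
    orig <- dplyr::mutate(rec, ptype = "original", level = NA_real_,
                          n_words = n_words, n_perturbed = 0L,
                          n_perturbed_medical = 0L,
                          edits = list(tibble::tibble(
                            token_index = integer(), operation = character(),
                            before = character(), after = character())))
    out[[r]] <- dplyr::bind_rows(c(list(orig), rows))
  }
  corpus <- dplyr::bind_rows(out)
  if (nrow(corpus) > 0L) {
    corpus <- dplyr::rename(corpus, record_id = "id")
  }
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(record_id = character(), reason = character())
  attr(corpus, "dropped") <- dropped
  attr(corpus, "manifest") <- list(
    seed = seed,
    grid = as.data.frame(grid),
    provider_version = attr(provider, "version") %||% "none",
    letter_fraction_range = letter_fraction_range,
    n_input_records = nrow(records),
    n_retained_records = nrow(records) - nrow(dropped),
    n_dropped_records = nrow(dropped),
    drop_reasons = as.data.frame(dropped)
  )
  corpus
}

#' Keep one question per medical note
#'
#' Source QA corpora can attach several questions to one note; exactly one is
#' kept per note, chosen deterministically as the lowest record id.
#'
#' @param records QA task records with a `note_id` column.
#' @return The surviving records, one per distinct note.
#' @export
select_one_question_per_note <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot("note_id" %in% names(records))
  records |>
    dplyr::group_by(.data$note_id) |>
    dplyr::slice_min(order_by = .data$id, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Assign prompt-tuning / test / validation splits
#'
#' Carves out the prompt-tuning fraction first (default 20%), then draws
#' `n_test` random records (default 1000) from the remainder; everything left
#' is validation. QA records are split over unique medical notes so no note
#' appears in two splits.
#'
#' @param records Task records.
#' @param n_test Test-set size.
#' @param fraction_prompt_tuning Prompt-tuning fraction of the whole set.
#' @param seed Integer seed.
#' @return A tibble `id`, `split` with
#'   `split` in `prompt_tuning`/`test`/`validation`.
#' @export
assign_splits <- function(records, n_test = 1000L,
                          fraction_prompt_tuning = 0.20, seed = 1L) {
  records <- validate_task_records(records)
  qa <- all(records$task == "qa") && "note_id" %in% names(records)
  units <- if (qa) unique(records$note_id) else records$id
  n <- length(units)
  n_pt <- as.integer(round_half_up(fraction_prompt_tuning * n))
  if (n_pt >= n) {
    abort("Insufficient records for the prompt-tuning carve-out.",
          class = "perturbr_split_error")
  }
  if (n_test >= n - n_pt) {
    abort(sprintf(
      "Insufficient records for the test carve-out: need %d, have %d after prompt tuning.",
      n_test, n - n_pt), class = "perturbr_split_error")
  }
  assign <- with_seed_(derive_seed(seed, "splits"), {
    pt <- sample(units, n_pt)
    rest <- setdiff(units, pt)
    te <- sample(rest, n_test)
    tibble::tibble(
      unit = units,
      split = dplyr::case_when(units %in% pt ~ "prompt_tuning",
                               units %in% te ~ "test",
                               TRUE ~ "validation"))
  })
  if (qa) {
    dplyr::left_join(tibble::tibble(id = records$id, unit = records$note_id),
                     assign, by = "unit")[, c("id", "split")]
  } else {
    dplyr::rename(assign, id = "unit")
  }
}

#' Read and write perturbation corpora as JSONL
#'
#' One JSON object per variant, carrying the record id, task, perturbation
#' type (or `"original"`), level, text, gold, QA fields when present, the
#' perturbation bookkeeping counts, and the per-token edit records. The
#' manifest travels as a sidecar `<path>.manifest.json`.
#'
#' @param corpus A corpus tibble from [build_perturbed_corpus()].
#' @param path Output path for `write_corpus_jsonl()`; input path for
#'   `read_corpus_jsonl()`.
#' @param manifest Write the manifest sidecar (default TRUE).
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path, manifest = TRUE) {
  rows <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    row <- as.list(corpus[i, setdiff(names(corpus), "edits")])
    row$edits <- corpus$edits[[i]]
    jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA)
  })
  writeLines(rows, path, useBytes = TRUE)
  mf <- attr(corpus, "manifest")
  if (manifest && !is.null(mf)) {
    jsonlite::write_json(mf, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    ed <- x$edits
    x$edits <- NULL
    x <- purrr::map(x, function(v) if (is.null(v)) NA else v)
    out <- tibble::as_tibble(x)
    out$edits <- list(if (is.data.frame(ed)) tibble::as_tibble(ed) else
      tibble::tibble(token_index = integer(), operation = character(),
                     before = character(), after = character()))
    out
  })
  dplyr::bind_rows(rows)
}

#' Read task records from CSV or JSONL
#'
#' Classification CSVs need columns `id`, `text`, `label` (mapped to `gold`)
#' and a `task` column or the `task` argument. QA corpora are JSONL with
#' fields `note_id`, `note`, `question`, `answer`.
#'
#' @param path Input file (`.csv` or `.jsonl`).
#' @param task Task kind used when the file does not carry one.
#' @return A validated task-record tibble.
#' @export
read_task_records <- function(path, task = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if ("label" %in% names(df) && !"gold" %in% names(df)) {
      df <- dplyr::rename(df, gold = "label")
    }
  } else {
    df <- dplyr::bind_rows(purrr::map(
      readr::read_lines(path, progress = FALSE),
      function(l) tibble::as_tibble(jsonlite::fromJSON(l))))
    if (all(c("note_id", "question", "answer") %in% names(df))) {
      if (!"gold" %in% names(df)) df$gold <- df$answer
      if (!"text" %in% names(df)) df$text <- df$note
      if (!"task" %in% names(df)) df$task <- "qa"
      if (!"id" %in% names(df)) df$id <- paste0(df$note_id, "_q")
    }
  }
  if (!is.null(task) && !"task" %in% names(df)) df$task <- task
  df$id <- as.character(df$id)
  df$gold <- as.character(df$gold)
  validate_task_records(df)
}
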