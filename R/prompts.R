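.default_roles <- c(
  sentiment_binary = "You are an assistant that classifies the sentiment of health-related sentences.",
  condition_ternary = "You are a medical assistant that classifies medical abstracts by disease condition.",
  qa = "You are a medical assistant that answers questions about medical notes."
)

.default_instructions <- c(
  sentiment_binary = "Classify the input sentence into exactly one of the listed labels.",
  condition_ternary = "Classify the medical abstract into exactly one of the listed condition labels.",
  qa = "Answer the question about the medical note."
)

#' Build a few-shot prompt template
#'
#' A template bundles the role statement, exactly `k` worked examples
#' (shots), task instructions, the session-isolation instruction (each item
#' is judged in its own session, ignoring any earlier conversation), and the
#' justification request. QA templates additionally carry the grounding
#' instruction to answer based only on the medical note provided.
#'
#' @param task Task kind.
#' @param shots Tibble of worked examples with columns `input` and `gold`
#'   (from [select_shots()]).
#' @param k Required number of shots (default 5).
#' @param role,instructions Override the per-task defaults.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(task = c("sentiment_binary", "condition_ternary", "qa"),
                            shots, k = 5L, role = NULL, instructions = NULL) {
  task <- match.arg(task)
  shots <- tibble::as_tibble(shots)
  if (k < 1L) abort("`k` must be at least 1.", class = "perturbr_bad_prompt")
  if (nrow(shots) != k || !all(c("input", "gold") %in% names(shots))) {
    abort(sprintf("`shots` must have exactly %d rows with columns input, gold.", k),
          class = "perturbr_bad_prompt")
  }
  structure(
    list(task = task, shots = shots, k = as.integer(k),
         role = role %||% unname(.default_roles[task]),
         instructions = instructions %||% unname(.default_instructions[task]),
         isolation_instruction = paste(
           "Treat this request as a completely new, independent session;",
           "ignore any previous prompts, notes, or answers."),
         justification_instruction = paste(
           "Provide a short justification for your answer; if no",
           "justification can be given, say so."),
         qa_grounding_instruction = if (task == "qa")
           "Provide an answer based only on the medical note provided." else NULL),
    class = "prompt_template"
  )
}

#' Select few-shot examples from the prompt-tuning split
#'
#' Seeded sample of `k` records. For classification tasks the shots are
#' label-balanced as evenly as `k` allows (e.g. a 3/2 split of 5 shots over
#' two labels), with the labels receiving the extra shot chosen at random.
#'
#' @param records Task records from the prompt-tuning split.
#' @param k Number of shots.
#' @param seed Integer seed.
#' @return A tibble with columns `input` and `gold`.
#' @export
select_shots <- function(records, k = 5L, seed = 1L) {
  records <- validate_task_records(records)
  if (k < 1L) abort("`k` must be at least 1.", class = "perturbr_bad_prompt")
  if (nrow(records) < k) {
    abort(sprintf("Need at least %d records to draw shots, have %d.",
                  k, nrow(records)), class = "perturbr_bad_prompt")
  }
  task <- records$task[[1]]
  inputs <- if (task == "qa") {
    paste0("Medical note: ", records$note, "\nQuestion: ", records$question)
  } else {
    records$text
  }
  pool <- tibble::tibble(input = inputs, gold = records$gold)
  if (task == "qa") {
    return(with_seed_(derive_seed(seed, "shots"),
                      pool[sample.int(nrow(pool), k), ]))
  }
  labels <- sort(unique(pool$gold))
  if (any(table(pool$gold) < 1L) || length(labels) < 1L) {
    abort("Each label needs at least one record.", class = "perturbr_bad_prompt")
  }
  with_seed_(derive_seed(seed, "shots"), {
    base <- k %/% length(labels)
    extra <- k %% length(labels)
    quota <- setNames(rep(base, length(labels)), labels)
    if (extra > 0L) {
      bump <- sample(labels, extra)
      quota[bump] <- quota[bump] + 1L
    }
    if (any(quota > table(factor(pool$gold, levels = labels)))) {
      abort("Not enough records per label for balanced shots.",
            class = "perturbr_bad_prompt")
    }
    picked <- purrr::map(labels, function(lb) {
      idx <- which(pool$gold == lb)
      pool[idx[sample.int(length(idx), quota[[lb]])], ]
    })
    out <- dplyr::bind_rows(picked)
    out[sample.int(nrow(out)), ]
  })
}

#' Render the full prompt for one item
#'
#' Concatenates the role statement, the `k` worked examples, the task
#' instructions, the item input, the isolation instruction and the
#' justification request (plus the QA grounding instruction).
#'
#' @param template A [prompt_template()].
#' @param item One corpus variant row (tibble row or list) with `task` and
#'   `text` (QA items use `note` and `question`).
#' @return The prompt string.
#' @export
build_prompt <- function(template, item) {
  stopifnot(inherits(template, "prompt_template"))
  if (!identical(template$task, item$task)) {
    abort(sprintf("Template task %s does not match item task %s.",
                  template$task, item$task), class = "perturbr_bad_prompt")
  }
  shot_block <- paste0("Example ", seq_len(template$k), ":\nInput: ",
                       template$shots$input, "\nAnswer: ",
                       template$shots$gold, collapse = "\n\n")
  input <- if (template$task == "qa") {
    paste0("Medical note: ", item$note, "\nQuestion: ", item$question)
  } else {
    item$text
  }
  paste(c(template$role, "", shot_block, "", template$instructions,
          template$qa_grounding_instruction,
          paste0("Input: ", input),
          template$isolation_instruction,
          template$justification_instruction),
        collapse = "\n")
}
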