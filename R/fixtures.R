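# Synthetic fixture corpora with planted, perturbation-sensitive label
# signal. Sentences are assembled from slot pools whose words have a known
# coarse part of speech and known homophone availability in the bundled
# dictionary, so every record supports the full perturbation grid by
# construction and no record is lost to the retention rule.

.fx_pools <- list(
  body = c("heel", "muscle", "vein", "knee", "waist"),
  time = c("night", "week"),
  act  = c("rest", "board", "role"),
  drug = c("metformin", "insulin", "voxelotor"),
  name = c("rivera", "chen", "osei", "novak", "amari")
)

.fx_signals <- list(
  sentiment_binary = list(
    positive = c("calm", "strong", "steady", "happy"),
    negative = c("tense", "weary", "sad", "poor")),
  condition_ternary = list(
    cardiovascular = c("cardiac", "coronary"),
    digestive = c("gastric", "digestive"),
    neurological = c("neural", "cranial"))
)

#' Keyword-to-label map planted in the fixture corpora
#'
#' Feed this to [adapter_keyword()] to build the keyword mock classifier that
#' reads the planted signal: it is perfect on unperturbed fixture text and
#' degrades predictably when the signal word is corrupted or redacted.
#'
#' @param task `"sentiment_binary"` or `"condition_ternary"`.
#' @return Named character vector keyword -> label.
#' @export
fixture_keyword_map <- function(task = c("sentiment_binary", "condition_ternary")) {
  task <- match.arg(task)
  sig <- .fx_signals[[task]]
  setNames(rep(names(sig), lengths(sig)), unlist(sig))
}

#' Generate a synthetic classification corpus
#'
#' Ten-word sentences of the form "the patient felt SIGNAL BODY pain during
#' TIME ACT care": 8 valid (content) words, at least 4 of which have
#' homophones in the bundled dictionary, so every grid cell (including 50%
#' typo/redaction and 30% homophone) is feasible for every record. The
#' `SIGNAL` slot carries the label: a label-specific keyword with probability
#' `signal_strength`, otherwise the neutral word "mild". Labels alternate
#' round-robin so shots can always be balanced.
#'
#' @param n_records Number of records.
#' @param task `"sentiment_binary"` or `"condition_ternary"`.
#' @param signal_strength Probability in \[0, 1\] that the signal keyword is
#'   present (default 1).
#' @param seed Integer seed.
#' @return A task-record tibble (`id`, `task`, `text`, `gold`).
#' @export
generate_classification_corpus <- function(n_records = 100L,
                                           task = c("sentiment_binary",
                                                    "condition_ternary"),
                                           signal_strength = 1,
                                           seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_records >= 1L, signal_strength >= 0, signal_strength <= 1)
  sig <- .fx_signals[[task]]
  labels <- names(sig)
  with_seed_(derive_seed(seed, paste0("cls:", task)), {
    gold <- labels[((seq_len(n_records) - 1L) %% length(labels)) + 1L]
    kw <- vapply(gold, function(g) sample(sig[[g]], 1L), "", USE.NAMES = FALSE)
    kw[runif(n_records) > signal_strength] <- "mild"
    tibble::tibble(
      id = sprintf("%s%05d", substr(task, 1, 3), seq_len(n_records)),
      task = task,
      text = paste("the patient felt", kw,
                   sample(.fx_pools$body, n_records, replace = TRUE),
                   "pain during",
                   sample(.fx_pools$time, n_records, replace = TRUE),
                   sample(.fx_pools$act, n_records, replace = TRUE),
                   "care"),
      gold = gold)
  })
}

#' Generate a synthetic question-answering corpus
#'
#' Each record is a three-sentence medical note with slot-filled facts, one
#' question per note by construction, and a reference answer that is exactly
#' the note sentence stating the queried fact — so the extractive mock
#' answerer ([adapter_extractive_qa()]) scores ROUGE-L 1.0 on unperturbed
#' questions and degrades once the question's anchor words are corrupted or
#' redacted. Questions are ten words with 7 valid words, 3 of them
#' homophone-capable, so the full grid is feasible for every record.
#'
#' @param n_notes Number of notes (= records).
#' @param seed Integer seed.
#' @return A QA task-record tibble (`id`, `task`, `text`, `gold`, `note_id`,
#'   `note`, `question`, `answer`).
#' @export
generate_qa_corpus <- function(n_notes = 50L, seed = 1L) {
  stopifnot(n_notes >= 1L)
  with_seed_(derive_seed(seed, "qa"), {
    body <- sample(.fx_pools$body, n_notes, replace = TRUE)
    time <- sample(.fx_pools$time, n_notes, replace = TRUE)
    drug <- sample(.fx_pools$drug, n_notes, replace = TRUE)
    name <- sample(.fx_pools$name, n_notes, replace = TRUE)
    answer <- paste("the doctor prescribed", drug, "therapy for the pain")
    note <- paste0("patient ", name, " reported ", body, " pain during ",
                   time, " shifts. ", answer, ". recovery of the ", body,
                   " region required steady rest.")
    tibble::tibble(
      id = sprintf("qarec%05d", seq_len(n_notes)),
      task = "qa",
      text = note,
      gold = answer,
      note_id = sprintf("note%05d", seq_len(n_notes)),
      note = note,
      question = paste("what healing therapy was prescribed for the sore",
                       body, "pain"),
      answer = answer)
  })
}

#' Generate a synthetic per-condition results table
#'
#' Emulates the shape of the study's full results grid: 8 task-model
#' combinations (sentiment and medical-abstract classification for three
#' models; question answering for two), each evaluated on 9 perturbation
#' conditions plus the original, with 4 classification metrics or 3 QA
#' metrics — 270 perturbed metric cells. Perturbed values are
#' `original * (1 + effect_ptype + effect_level + effect_model + effect_task
#' + noise)` with Gaussian noise of standard deviation `sigma`, clamped to
#' (0, 1]. With all effects zero the treatments are exchangeable within every
#' block, so rank tests on the table are calibrated under the null.
#'
#' @param seed Integer seed.
#' @param effects List with optional named numeric vectors `ptype` (names
#'   typographical/homophone/redaction), `level` (low/medium/high), `model`
#'   (GPT/BlueBERT/Llama), `task` (sentiment_binary/condition_ternary/qa);
#'   missing entries are zero.
#' @param sigma Noise standard deviation (relative scale).
#' @param base Center of the baseline metric values.
#' @return A long results tibble `task`, `model`, `ptype`, `level`, `metric`,
#'   `value`, `n_items`, including `ptype = "original"` rows.
#' @export
generate_result_table <- function(seed = 1L, effects = list(), sigma = 0.05,
                                  base = 0.8) {
  grid <- perturbation_grid()
  combos <- dplyr::bind_rows(
    tidyr::expand_grid(task = c("sentiment_binary", "condition_ternary"),
                       model = c("GPT", "BlueBERT", "Llama"),
                       metric = c("accuracy", "precision", "recall", "f1")),
    tidyr::expand_grid(task = "qa", model = c("GPT", "Llama"),
                       metric = c("bleu", "rouge", "bertscore")))
  eff <- function(dim, key) {
    v <- effects[[dim]]
    if (is.null(v)) return(0)
    out <- unname(v[key])
    if (is.na(out)) 0 else out
  }
  with_seed_(derive_seed(seed, "results"), {
    combos$original <- pmin(1, pmax(0.05, base + runif(nrow(combos), -0.05, 0.05)))
    pert <- tidyr::expand_grid(combos, grid)
    shift <- vapply(seq_len(nrow(pert)), function(i) {
      eff("ptype", pert$ptype[i]) + eff("level", pert$level_name[i]) +
        eff("model", pert$model[i]) + eff("task", pert$task[i])
    }, numeric(1))
    pert$value <- pmin(1, pmax(0.001,
      pert$original * (1 + shift + stats::rnorm(nrow(pert), 0, sigma))))
    orig <- combos |>
      dplyr::mutate(ptype = "original", level = NA_real_,
                    value = .data$original)
    dplyr::bind_rows(orig, pert) |>
      dplyr::transmute(.data$task, .data$model, .data$ptype, .data$level,
                       .data$metric, .data$value, n_items = 500L)
  })
}
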