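#' Extract the predicted label from a free-text model response
#'
#' Responses carry justifications, so the label is located rather than
#' matched exactly: the first label (case-insensitive, word-boundary match)
#' appearing anywhere in the response wins. Unparseable responses return
#' `NA` and are scored as incorrect downstream.
#'
#' @param response Model response string.
#' @param label_set Non-empty character vector of legal labels.
#' @return The matched label, or `NA_character_`.
#' @examples
#' parse_classification_response("Classification: 2 - because ...",
#'                               c("0", "1", "2"))
#' @export
parse_classification_response <- function(response, label_set) {
  stopifnot(length(label_set) >= 1L)
  if (is.na(response) || !nzchar(response)) return(NA_character_)
  pos <- vapply(label_set, function(lb) {
    m <- regexpr(paste0("\\b", .rx_escape(lb), "\\b"), response,
                 ignore.case = TRUE, perl = TRUE)
    as.integer(m[1])
  }, integer(1))
  pos[pos < 0L] <- NA_integer_
  if (all(is.na(pos))) return(NA_character_)
  label_set[[which.min(pos)]]
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Classification metrics: accuracy and macro precision/recall/F1
#'
#' Accuracy is the exact-match fraction. Precision, recall and F1 are
#' computed per label and macro-averaged over the full label set, treating
#' the binary and ternary tasks symmetrically; a label with no predicted
#' items takes precision 0, and F1 is 0 when precision + recall is 0.
#' `NA` predictions (unparseable responses) count as incorrect for accuracy
#' and as missed items (false negatives) of their gold label.
#'
#' @param predictions Character vector of predicted labels (`NA` allowed).
#' @param golds Character vector of gold labels, same length.
#' @param label_set Full label set of the task.
#' @return A tibble `metric`, `value` with rows accuracy, precision, recall,
#'   f1; the per-label breakdown is in attribute `"by_class"`.
#' @export
score_classification <- function(predictions, golds,
                                 label_set = sort(unique(golds))) {
  if (length(golds) == 0L) {
    abort("Empty input.", class = "perturbr_bad_metric_input")
  }
  stopifnot(length(predictions) == length(golds))
  acc <- mean(!is.na(predictions) & predictions == golds)
  by_class <- purrr::map_dfr(label_set, function(lb) {
    tp <- sum(!is.na(predictions) & predictions == lb & golds == lb)
    fp <- sum(!is.na(predictions) & predictions == lb & golds != lb)
    fn <- sum(golds == lb) - tp
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble::tibble(label = lb, precision = p, recall = r, f1 = f)
  })
  out <- tibble::tibble(
    metric = c("accuracy", "precision", "recall", "f1"),
    value = c(acc, mean(by_class$precision), mean(by_class$recall),
              mean(by_class$f1)))
  attr(out, "by_class") <- by_class
  out
}

.qa_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

.lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L F-measure between a candidate and a reference answer
#'
#' Longest-common-subsequence overlap on lowercased alphanumeric tokens:
#' precision = LCS / candidate length, recall = LCS / reference length,
#' F = harmonic mean. An empty candidate scores 0.
#'
#' @param candidate Candidate answer string.
#' @param reference Non-empty reference answer string.
#' @return ROUGE-L F score in \[0, 1\].
#' @export
rouge_l <- function(candidate, reference) {
  ref <- .qa_tokens(reference)
  if (length(ref) == 0L) {
    abort("Reference must be non-empty.", class = "perturbr_bad_metric_input")
  }
  cand <- .qa_tokens(candidate %na% "")
  if (length(cand) == 0L) return(0)
  l <- .lcs_length(cand, ref)
  p <- l / length(cand); r <- l / length(ref)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Sentence BLEU with add-one smoothing
#'
#' Modified n-gram precision up to order `max_n` (capped at the candidate
#' length) with a brevity penalty. Orders with zero matches are smoothed by
#' adding one to numerator and denominator — short clinical answers otherwise
#' collapse to zero whenever one order is unmatched. An exact match scores 1.
#'
#' @param candidate Candidate answer string.
#' @param reference Non-empty reference answer string.
#' @param max_n Maximum n-gram order (default 4).
#' @return BLEU score in \[0, 1\].
#' @export
bleu_score <- function(candidate, reference, max_n = 4L) {
  ref <- .qa_tokens(reference)
  if (length(ref) == 0L) {
    abort("Reference must be non-empty.", class = "perturbr_bad_metric_input")
  }
  cand <- .qa_tokens(candidate %na% "")
  if (length(cand) == 0L) return(0)
  max_n <- min(max_n, length(cand))
  ngrams <- function(x, n) {
    if (length(x) < n) return(character(0))
    vapply(seq_len(length(x) - n + 1L),
           function(i) paste(x[i:(i + n - 1L)], collapse = " "), "")
  }
  logp <- vapply(seq_len(max_n), function(n) {
    cg <- ngrams(cand, n); rg <- ngrams(ref, n)
    ct <- table(cg); rt <- table(rg)
    m <- sum(pmin(ct, rt[names(ct)] %na0% 0))
    tot <- length(cg)
    if (m == 0L) log((m + 1) / (tot + 1)) else log(m / tot)
  }, numeric(1))
  bp <- if (length(cand) >= length(ref)) 1 else
    exp(1 - length(ref) / length(cand))
  bp * exp(mean(logp))
}

`%na0%` <- function(x, y) { x[is.na(x)] <- y; x }

#' Score one question-answer pair
#'
#' BLEU and ROUGE-L are always reported; a BERTScore-style embedding score is
#' included only when a scorer function `(candidate, reference) -> value` is
#' injected, keeping the core free of any neural-model dependency. The study
#' analysis metric is ROUGE-L.
#'
#' @param candidate Candidate answer.
#' @param reference Non-empty reference answer.
#' @param bertscore_fn Optional embedding scorer function.
#' @return A tibble `metric`, `value`.
#' @export
score_qa <- function(candidate, reference, bertscore_fn = NULL) {
  out <- tibble::tibble(
    metric = c("bleu", "rouge"),
    value = c(bleu_score(candidate, reference), rouge_l(candidate, reference)))
  if (!is.null(bertscore_fn)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "bertscore", value = bertscore_fn(candidate, reference)))
  }
  out
}
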