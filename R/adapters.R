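#' Model adapters
#'
#' An adapter is a function `(prompt, item) -> response string` called once
#' per evaluation item with a fully self-contained prompt — no conversational
#' state is carried between calls. Built-in mock adapters let the whole
#' pipeline run without any hosted model:
#'
#' * `adapter_oracle()` echoes the gold answer — the best-possible model.
#' * `adapter_adversarial()` never produces a parseable/overlapping answer.
#' * `adapter_keyword(keyword_map, fallback)` classifies by scanning the item
#'   text for planted keywords (the fixture corpora carry such signal).
#' * `adapter_extractive_qa()` answers a question by returning the note
#'   sentence containing the question's medical keyword, or a refusal when
#'   the (possibly perturbed) question no longer names one.
#' * `adapter_noisy(...)` a noisy channel over the oracle with a programmed
#'   relative performance change per perturbation condition (see below).
#' * `adapter_http(...)` a generic chat-completion client for hosted models.
#'
#' @name adapters
NULL

#' @rdname adapters
#' @export
adapter_oracle <- function() {
  function(prompt, item) paste0(item$gold, " - answer taken verbatim.")
}

#' @rdname adapters
#' @export
adapter_adversarial <- function() {
  function(prompt, item) "qqxyzzq"
}

#' @rdname adapters
#' @param keyword_map Named character vector mapping keyword -> label.
#' @param fallback Label returned when no keyword is present.
#' @export
adapter_keyword <- function(keyword_map, fallback) {
  function(prompt, item) {
    text <- if (identical(item$task, "qa")) item$question else item$text
    low <- tolower(text)
    for (kw in names(keyword_map)) {
      if (grepl(paste0("\\b", kw, "\\b"), low)) {
        return(paste0(keyword_map[[kw]],
                      " - the text mentions '", kw, "'."))
      }
    }
    paste0(fallback, " - no signal keyword found.")
  }
}

#' @rdname adapters
#' @param refusal Response used when the question names no known entity.
#' @export
adapter_extractive_qa <- function(refusal = "the note does not say") {
  function(prompt, item) {
    sentences <- strsplit(item$note, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    qtok <- setdiff(.qa_tokens(item$question),
                    c("the", "a", "an", "was", "what", "for", "of", "in",
                      "to", "and"))
    # return the note sentence sharing the most content tokens with the
    # (possibly perturbed) question; refuse below two shared tokens
    n_anchor <- vapply(sentences, function(s) {
      length(intersect(qtok, .qa_tokens(s)))
    }, integer(1), USE.NAMES = FALSE)
    if (max(n_anchor) < 2L) return(refusal)
    sub("[.!?]$", "", sentences[[which.max(n_anchor)]])
  }
}

#' @rdname adapters
#'
#' @details
#' `adapter_noisy()` models a channel whose correctness is paired across
#' conditions: each item is assigned a latent baseline correctness draw
#' (probability `base_accuracy`), reused for every condition. Under a
#' condition with programmed relative change `d < 0`, items correct at
#' baseline stay correct with probability `1 + d`; under `d > 0`, items
#' wrong at baseline flip to correct with probability
#' `d * base_accuracy / (1 - base_accuracy)`. The expected accuracy of the
#' condition is therefore exactly `base_accuracy * (1 + d)`, and the measured
#' relative change concentrates on `d` as the number of items grows.
#'
#' @param degradation Named numeric vector of relative performance changes,
#'   keyed `"<ptype>:<level>"` (e.g. `"redaction:0.5"`), with `"original"`
#'   implicitly 0.
#' @param base_accuracy Baseline probability of a correct answer.
#' @param seed Integer seed; correctness draws are keyed by (seed, record id)
#'   so they do not depend on evaluation order.
#' @param wrong_pool Labels/answers to emit when incorrect (a label distinct
#'   from the gold is chosen).
#' @export
adapter_noisy <- function(degradation, base_accuracy = 0.8, seed = 1L,
                          wrong_pool = NULL) {
  stopifnot(is.numeric(degradation), !is.null(names(degradation)))
  function(prompt, item) {
    key <- if (identical(item$ptype, "original") || is.null(item$ptype)) {
      "original"
    } else {
      paste0(item$ptype, ":", format(item$level, trim = TRUE))
    }
    d <- if (key == "original") 0 else degradation[[key]] %na% 0
    u <- with_seed_(derive_seed(seed, paste0("base:", item$record_id)),
                    runif(1))
    base_ok <- u < base_accuracy
    ok <- if (d >= 0) {
      flip_p <- if (base_accuracy >= 1) 0 else
        min(1, d * base_accuracy / (1 - base_accuracy))
      base_ok || with_seed_(
        derive_seed(seed, paste0("flip:", item$record_id, ":", key)),
        runif(1)) < flip_p
    } else {
      base_ok && with_seed_(
        derive_seed(seed, paste0("keep:", item$record_id, ":", key)),
        runif(1)) < (1 + d)
    }
    if (ok) return(paste0(item$gold, " - confident."))
    if (!is.null(wrong_pool)) {
      w <- setdiff(wrong_pool, item$gold)
      return(paste0(w[[1L + (nchar(item$record_id) %% length(w))]],
                    " - uncertain."))
    }
    "qqxyzzq"
  }
}

#' @rdname adapters
#' @param endpoint Chat-completion URL.
#' @param model Model name sent in the request body.
#' @param api_key_env Name of the environment variable holding the API key
#'   (credentials are never stored in configs or manifests).
#' @param temperature Sampling temperature.
#' @export
adapter_http <- function(endpoint, model, api_key_env = "PERTURBR_API_KEY",
                         temperature = 0) {
  function(prompt, item) {
    key <- Sys.getenv(api_key_env, unset = "")
    if (!nzchar(key)) {
      abort(sprintf("API key environment variable %s is not set.", api_key_env),
            class = "perturbr_adapter_error")
    }
    body <- jsonlite::toJSON(list(
      model = model, temperature = temperature,
      messages = list(list(role = "user", content = prompt))),
      auto_unbox = TRUE)
    tmp <- tempfile(fileext = ".json"); on.exit(unlink(tmp))
    writeLines(body, tmp, useBytes = TRUE)
    res <- suppressWarnings(system2(
      "curl", c("-sS", "-X", "POST", shQuote(endpoint),
                "-H", shQuote("Content-Type: application/json"),
                "-H", shQuote(paste0("Authorization: Bearer ", key)),
                "--data-binary", paste0("@", tmp)),
      stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0L) {
      abort(paste("HTTP adapter call failed:", paste(res, collapse = " ")),
            class = "perturbr_adapter_error")
    }
    parsed <- jsonlite::fromJSON(paste(res, collapse = "\n"),
                                 simplifyVector = FALSE)
    parsed$choices[[1]]$message$content %||%
      abort("HTTP adapter: no message content in response.",
            class = "perturbr_adapter_error")
  }
}

#' Look up a built-in adapter by name
#'
#' @param name One of `"oracle"`, `"adversarial"`, `"keyword"`,
#'   `"extractive_qa"`, `"noisy"`, `"http"`.
#' @param settings List of arguments for the adapter factory.
#' @return An adapter function.
#' @export
get_adapter <- function(name, settings = list()) {
  factory <- switch(name,
    oracle = adapter_oracle, adversarial = adapter_adversarial,
    keyword = adapter_keyword, extractive_qa = adapter_extractive_qa,
    noisy = adapter_noisy, http = adapter_http,
    abort(sprintf("Unknown adapter '%s'.", name),
          class = "perturbr_adapter_error"))
  do.call(factory, settings)
}
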