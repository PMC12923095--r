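#' Homophone providers
#'
#' A homophone provider is any function taking a single word and returning an
#' ordered character vector of sound-alike candidates (possibly empty), plus a
#' `"version"` attribute on the function identifying the dictionary it
#' answers from. Two implementations ship with the package:
#'
#' * `homophone_provider_dictionary()` reads a two-column TSV (word, then a
#'   pipe-separated candidate list) bundled under `extdata/homophones.tsv`, or
#'   any file with the same layout. Lookups are deterministic and offline.
#' * `homophone_provider_datamuse()` queries a sounds-like HTTP endpoint
#'   (the Datamuse `rel_hom` relation by default). It needs network access and
#'   signals an explicit error on lookup failure rather than silently
#'   returning no candidates.
#'
#' @param path Path to a homophone TSV; defaults to the bundled dictionary.
#' @return A provider function `word -> character vector of homophones`.
#' @examples
#' prov <- homophone_provider_dictionary()
#' prov("did")
#' prov("voxelotor")
#' @export
homophone_provider_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "homophones.tsv",
                        package = "perturbr", mustWork = TRUE)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed homophone dictionary line: %s",
                  lines[which(bad)[1]]))
  }
  dict <- setNames(
    lapply(parts, function(p) strsplit(p[[2]], "|", fixed = TRUE)[[1]]),
    vapply(parts, `[[`, "", 1L)
  )
  f <- function(word) {
    stopifnot(is.character(word), length(word) == 1L)
    dict[[tolower(word)]] %||% character(0)
  }
  attr(f, "version") <- paste0("dictionary:", basename(path), ":",
                               length(dict), "w")
  f
}

#' @rdname homophone_provider_dictionary
#' @param endpoint Base URL of the sounds-like service.
#' @param max_results Maximum number of candidates requested per word.
#' @export
homophone_provider_datamuse <- function(endpoint = "https://api.datamuse.com/words",
                                        max_results = 10L) {
  f <- function(word) {
    stopifnot(is.character(word), length(word) == 1L)
    u <- paste0(endpoint, "?rel_hom=", utils::URLencode(tolower(word)),
                "&max=", max_results)
    res <- tryCatch(jsonlite::fromJSON(u), error = function(e) {
      abort(sprintf("Homophone lookup for %s failed: %s",
                    word, conditionMessage(e)),
            class = "perturbr_provider_error")
    })
    if (length(res) == 0L || is.null(res$word)) character(0) else res$word
  }
  attr(f, "version") <- paste0("datamuse:", endpoint)
  f
}

#' Replace a word by its first spelled-differently homophone
#'
#' Asks the provider for sound-alike candidates and returns the first one
#' whose spelling differs (case-insensitively) from the input. Leading-case of
#' the input is preserved on the replacement. Returns `NA` when the provider
#' has no usable candidate; callers re-select a different valid word or mark
#' the perturbation budget infeasible.
#'
#' @param word A single word.
#' @param provider A homophone provider function; defaults to the bundled
#'   dictionary.
#' @return The replacement word, or `NA_character_` when none exists.
#' @examples
#' apply_homophone("did")  # "deed"
#' apply_homophone("in")   # "inn"
#' @export
apply_homophone <- function(word, provider = homophone_provider_dictionary()) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word))
  cands <- provider(word)
  cands <- cands[tolower(cands) != tolower(word)]
  if (length(cands) == 0L) return(NA_character_)
  out <- cands[[1]]
  # preserve leading capitalisation ("Did" -> "Deed")
  if (grepl("^[[:upper:]]", word)) {
    out <- paste0(toupper(substr(out, 1, 1)), substr(out, 2, nchar(out)))
  }
  out
}
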