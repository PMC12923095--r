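#' Bundled resources: medical lexicon and homophone dictionary paths
#'
#' @return `default_medical_lexicon()` returns a character vector of lowercase
#'   medical terms read from the lexicon file shipped with the package.
#' @param path Path to a newline-delimited lowercase term file.
#' @export
read_medical_lexicon <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(tolower(x))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_medical_lexicon
#' @export
default_medical_lexicon <- function() {
  read_medical_lexicon(system.file("extdata", "medical_lexicon.txt",
                                   package = "perturbr", mustWork = TRUE))
}

# Closed-class function words: never eligible for perturbation.
.fn_words <- list(
  determiner  = c("the", "a", "an", "this", "that", "these", "those", "each",
                  "every", "either", "neither", "some", "any", "all", "both"),
  pronoun     = c("i", "you", "he", "she", "it", "we", "they", "me", "him",
                  "her", "us", "them", "his", "their", "my", "your", "its",
                  "our", "mine", "yours", "theirs", "himself", "herself",
                  "itself", "themselves", "who", "whom", "whose", "what",
                  "which", "when", "where", "why", "how"),
  preposition = c("in", "on", "at", "of", "to", "for", "with", "from", "by",
                  "about", "into", "onto", "over", "under", "between",
                  "during", "without", "within", "through", "after", "before",
                  "above", "below", "against", "among", "upon", "per"),
  conjunction = c("and", "or", "but", "nor", "so", "yet", "because",
                  "although", "while", "if", "than", "as", "since", "unless",
                  "whereas"),
  particle    = c("not", "no", "nor", "off", "out", "up", "down")
)

.adj_list <- c("good", "bad", "severe", "mild", "chronic", "acute", "red",
               "sore", "weak", "high", "low", "happy", "sad", "great", "poor",
               "overall", "steady", "calm", "tense", "weary", "strong",
               "pale", "hoarse", "plain", "whole", "main", "new", "old",
               "left", "right", "daily", "stable")
.adv_list <- c("very", "quite", "often", "never", "always", "soon", "again",
               "here", "there", "now", "then", "also", "too", "well")
.verb_list <- c("be", "is", "are", "was", "were", "been", "being", "am",
                "do", "did", "does", "done", "have", "has", "had", "felt",
                "feel", "affect", "gave", "give", "given", "took", "take",
                "taken", "went", "go", "gone", "made", "make", "said", "say",
                "saw", "see", "seen", "knew", "know", "known", "get", "got",
                "can", "could", "will", "would", "may", "might", "shall",
                "should", "must", "wrest", "heal")

#' Deterministic rule-based coarse part-of-speech tagger
#'
#' A small closed-class lexicon plus suffix heuristics mapping each word to a
#' coarse category: `"adjective"`, `"adverb"`, `"verb"`, `"noun"`,
#' `"determiner"`, `"pronoun"`, `"preposition"`, `"conjunction"`,
#' `"particle"`, or `"number"`. Unknown words default to `"noun"`, the safe
#' choice for content words in clinical text. The tagger is deterministic and
#' dependency-free; any function with the same signature (character vector in,
#' category vector out) can be injected wherever a tagger is accepted.
#'
#' @param words Character vector of word tokens.
#' @return Character vector of coarse part-of-speech categories.
#' @export
rule_pos_tagger <- function(words) {
  w <- tolower(words)
  # strip possessive clitics before lookup
  w <- sub("('s|’s)$", "", w)
  out <- rep(NA_character_, length(w))
  for (cls in names(.fn_words)) {
    out[is.na(out) & w %in% .fn_words[[cls]]] <- cls
  }
  out[is.na(out) & grepl("^[0-9]+([.,][0-9]+)?$", w)] <- "number"
  out[is.na(out) & w %in% .verb_list] <- "verb"
  out[is.na(out) & w %in% .adv_list] <- "adverb"
  out[is.na(out) & w %in% .adj_list] <- "adjective"
  out[is.na(out) & grepl("ly$", w) & nchar(w) > 3] <- "adverb"
  out[is.na(out) &
        grepl("(ful|ous|ive|able|ible|ish|less|ic|al)$", w) &
        nchar(w) > 4] <- "adjective"
  out[is.na(out) & grepl("(ing|ed|ize|ise|ate)$", w) & nchar(w) > 4] <- "verb"
  out[is.na(out)] <- "noun"
  out
}

#' Part-of-speech categories eligible for perturbation
#'
#' Only adjectives, adverbs, verbs and nouns are "valid words": the content
#' words whose corruption plausibly changes meaning. Function words are left
#' untouched by every perturbation operator.
#'
#' @export
valid_pos_default <- function() c("adjective", "adverb", "verb", "noun")

#' Tokenize text and annotate each token
#'
#' Splits `text` on whitespace, separates leading/trailing punctuation into
#' their own tokens (word-internal apostrophes and hyphens stay inside the
#' word), records 0-based half-open character spans, tags word tokens with a
#' coarse part of speech, and flags tokens that are perturbation-eligible
#' (`is_valid`) or members of the medical lexicon (`is_medical`).
#'
#' @param text A non-empty character scalar.
#' @param lexicon Character vector of lowercase medical terms. The lowercased
#'   token, its possessive-stripped form, and a naive depluralized form are
#'   looked up.
#' @param tagger A function mapping a character vector of words to coarse
#'   part-of-speech categories; defaults to [rule_pos_tagger()].
#' @param valid_pos Character vector of categories counted as valid words.
#' @return A tibble with one row per token: `token`, `start`, `end`,
#'   `is_word`, `pos`, `is_valid`, `is_medical`.
#' @examples
#' annotate_tokens("How did voxelotor affect the patient",
#'                 lexicon = "voxelotor")
#' @export
annotate_tokens <- function(text, lexicon = character(),
                            tagger = rule_pos_tagger,
                            valid_pos = valid_pos_default()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    abort("`text` must be a non-empty, non-whitespace character scalar.",
          class = "perturbr_degenerate_input")
  }
  stopifnot(length(valid_pos) >= 1L)
  runs <- gregexpr("\\S+", text)[[1]]
  starts <- as.integer(runs) - 1L          # to 0-based
  lens <- attr(runs, "match.length")
  tok <- character(0); tstart <- integer(0); tend <- integer(0)
  word_re <- "[[:alnum:]]([[:alnum:]'’-]*[[:alnum:]])?"
  for (i in seq_along(starts)) {
    run <- substr(text, starts[i] + 1L, starts[i] + lens[i])
    m <- regexpr(word_re, run, perl = TRUE)
    if (m[1] == -1L) {                      # pure punctuation run
      tok <- c(tok, run)
      tstart <- c(tstart, starts[i]); tend <- c(tend, starts[i] + lens[i])
      next
    }
    ws <- as.integer(m) - 1L; wl <- attr(m, "match.length")
    if (ws > 0L) {
      tok <- c(tok, substr(run, 1L, ws))
      tstart <- c(tstart, starts[i]); tend <- c(tend, starts[i] + ws)
    }
    tok <- c(tok, substr(run, ws + 1L, ws + wl))
    tstart <- c(tstart, starts[i] + ws); tend <- c(tend, starts[i] + ws + wl)
    if (ws + wl < lens[i]) {
      tok <- c(tok, substr(run, ws + wl + 1L, lens[i]))
      tstart <- c(tstart, starts[i] + ws + wl)
      tend <- c(tend, starts[i] + lens[i])
    }
  }
  is_word <- grepl("[[:alnum:]]", tok)
  pos <- rep("punct", length(tok))
  if (any(is_word)) pos[is_word] <- tagger(tok[is_word])
  lex <- tolower(lexicon)
  low <- tolower(tok)
  base <- sub("('s|’s)$", "", low)
  sing <- sub("s$", "", base)
  is_medical <- is_word & (low %in% lex | base %in% lex | sing %in% lex)
  tibble::tibble(
    token = tok, start = tstart, end = tend,
    is_word = is_word, pos = pos,
    is_valid = is_word & pos %in% valid_pos,
    is_medical = is_medical
  )
}
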