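#' Construct and validate a perturbation specification
#'
#' A perturbation spec fixes everything one perturbation run needs: the
#' perturbation type, the level (the fraction of all words to perturb — the
#' 10/20/30/50% grids), the within-word typo intensity range, the RNG seed,
#' and the part-of-speech categories counted as valid words.
#'
#' @param ptype One of `"typographical"`, `"homophone"`, `"redaction"`.
#' @param level Fraction of total words to perturb, in (0, 1].
#' @param letter_fraction_range Ordered pair of fractions in \[0, 1\]: the
#'   fraction of letters inside a chosen word that a typo touches (a value is
#'   drawn uniformly from this range per word). Default 0.20–0.50.
#' @param seed Integer RNG seed.
#' @param valid_pos Non-empty set of part-of-speech categories eligible for
#'   perturbation.
#' @return A `perturbation_spec` object (a validated list).
#' @export
perturbation_spec <- function(ptype = c("typographical", "homophone", "redaction"),
                              level,
                              letter_fraction_range = c(0.20, 0.50),
                              seed = 1L,
                              valid_pos = valid_pos_default()) {
  ptype <- match.arg(ptype)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level > 1) {
    abort("`level` must be a single fraction in (0, 1].",
          class = "perturbr_bad_spec")
  }
  r <- letter_fraction_range
  if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) ||
      any(r < 0) || any(r > 1) || r[1] > r[2]) {
    abort("`letter_fraction_range` must be an ordered pair within [0, 1].",
          class = "perturbr_bad_spec")
  }
  if (length(valid_pos) == 0L) {
    abort("`valid_pos` must be non-empty.", class = "perturbr_bad_spec")
  }
  structure(
    list(ptype = ptype, level = as.numeric(level),
         letter_fraction_range = as.numeric(r), seed = as.integer(seed),
         valid_pos = as.character(valid_pos)),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> %s @ %.0f%% (letters %.0f-%.0f%%, seed %d)\n",
              x$ptype, 100 * x$level, 100 * x$letter_fraction_range[1],
              100 * x$letter_fraction_range[2], x$seed))
  invisible(x)
}

#' Number of words to perturb at a level
#'
#' The perturbation budget is a fraction of *all* words in the text, but only
#' valid words may be touched: `round(level * n_total_words)` (half-up, floor
#' of 1). In a 10-word sentence with 5 valid words, a 10% level perturbs 1
#' valid word — effectively 20% of the valid words. When the budget exceeds
#' the number of valid words the perturbation is infeasible and
#' `NA_integer_` is returned; the corpus retention rule drops such records.
#'
#' @param n_total_words Total number of word tokens.
#' @param n_valid_words Number of valid (eligible) word tokens.
#' @param level Fraction in (0, 1].
#' @return Integer target count, or `NA_integer_` when infeasible.
#' @examples
#' compute_target_count(10, 5, 0.10)  # 1
#' compute_target_count(10, 2, 0.50)  # NA: 5 > 2
#' @export
compute_target_count <- function(n_total_words, n_valid_words, level) {
  stopifnot(is.numeric(n_total_words), is.numeric(n_valid_words),
            n_valid_words <= n_total_words)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level <= 0) {
    abort("`level` must be > 0.", class = "perturbr_bad_spec")
  }
  target <- max(1L, as.integer(round_half_up(level * n_total_words)))
  if (target > n_valid_words) return(NA_integer_)
  target
}

#' Select which valid words to perturb
#'
#' Uniform, seeded sample without replacement among the valid-token rows of an
#' annotation table. Identical seeds give identical selections.
#'
#' @param annotations Tibble from [annotate_tokens()].
#' @param target_count Number of tokens to select.
#' @param seed Integer seed.
#' @return Integer vector of row indices into `annotations`, in draw order.
#' @export
select_words <- function(annotations, target_count, seed = 1L) {
  valid_idx <- which(annotations$is_valid)
  if (target_count > length(valid_idx)) {
    abort(sprintf("Budget infeasible: need %d words but only %d are valid.",
                  target_count, length(valid_idx)),
          class = "perturbr_infeasible")
  }
  with_seed_(seed, valid_idx[sample.int(length(valid_idx), target_count)])
}

.typo_ops <- c("insert", "delete", "substitute", "transpose")

#' Apply a typographical corruption to one word
#'
#' One operator (insertion, deletion, substitution, or adjacent transposition)
#' is drawn uniformly; the number of letter positions it touches is
#' `round(u * nchar(word))` with `u` uniform on `letter_fraction_range`,
#' never fewer than 1. The result always differs from the input: deletions
#' keep at least one letter, substitutions avoid the original letter,
#' transpositions fall back to substitution when no adjacent pair differs,
#' and single-letter words receive exactly one insertion or substitution.
#' Untouched letters keep their casing.
#'
#' @param word A word of length >= 1.
#' @param letter_fraction_range Ordered pair in \[0, 1\].
#' @param seed Integer seed.
#' @return The corrupted word, with the operator used in attribute
#'   `"operation"` (`"typo_insert"`, `"typo_delete"`, `"typo_substitute"`, or
#'   `"typo_transpose"`).
#' @examples
#' apply_typo("discharge", seed = 3)
#' @export
apply_typo <- function(word, letter_fraction_range = c(0.20, 0.50), seed = 1L) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) >= 1L)
  n <- nchar(word)
  with_seed_(seed, {
    op <- sample(.typo_ops, 1L)
    if (n == 1L && op %in% c("delete", "transpose")) {
      op <- sample(c("insert", "substitute"), 1L)
    }
    u <- runif(1, letter_fraction_range[1], letter_fraction_range[2])
    n_edit <- max(1L, as.integer(round_half_up(u * n)))
    chars <- strsplit(word, "", fixed = TRUE)[[1]]
    out <- switch(op,
      insert = {
        for (k in seq_len(n_edit)) {
          gap <- sample.int(length(chars) + 1L, 1L) - 1L
          chars <- append(chars, sample(letters, 1L), after = gap)
        }
        chars
      },
      delete = {
        n_del <- min(n_edit, n - 1L)
        chars[-sample.int(n, n_del)]
      },
      substitute = {
        pos <- sample.int(n, min(n_edit, n))
        for (p in pos) chars[p] <- sample(setdiff(letters, tolower(chars[p])), 1L)
        chars
      },
      transpose = {
        cand <- which(chars[-n] != chars[-1])
        if (length(cand) == 0L) {
          op <- "substitute"
          p <- sample.int(n, 1L)
          chars[p] <- sample(setdiff(letters, tolower(chars[p])), 1L)
          chars
        } else {
          pos <- sort(sample(cand, min(n_edit, length(cand))))
          for (p in pos) chars[c(p, p + 1L)] <- chars[c(p + 1L, p)]
          if (paste(chars, collapse = "") == word) {
            # overlapping swaps cancelled out; force a visible change
            op <- "substitute"
            p <- sample.int(n, 1L)
            chars[p] <- sample(setdiff(letters, tolower(chars[p])), 1L)
          }
          chars
        }
      }
    )
    structure(paste(out, collapse = ""), operation = paste0("typo_", op))
  })
}

#' Redact selected word tokens from a text
#'
#' Removes the word tokens at `indices`, collapses the whitespace left behind
#' to single spaces, and keeps punctuation that did not belong to a removed
#' token (a space stranded before sentence punctuation is also absorbed).
#'
#' @param text Source text.
#' @param annotations Tibble from [annotate_tokens()] for `text`.
#' @param indices Integer row indices of tokens to remove.
#' @return The redacted text.
#' @export
apply_redaction <- function(text, annotations, indices) {
  if (length(indices) == 0L) return(text)
  stopifnot(all(indices >= 1L), all(indices <= nrow(annotations)))
  keep <- rep(TRUE, nchar(text))
  for (i in indices) {
    span <- (annotations$start[i] + 1L):annotations$end[i]
    keep[span] <- FALSE
  }
  out <- paste(strsplit(text, "", fixed = TRUE)[[1]][keep], collapse = "")
  out <- gsub("[[:space:]]+", " ", out)
  out <- gsub(" +([.,;:!?])", "\\1", out)
  trimws(out)
}

# Rebuild the perturbed text from (original text, annotations, edits).
# Substitution-style edits are applied right-to-left over the recorded spans;
# redactions go through apply_redaction(). Used both to *produce* the
# perturbed text and, in tests, to replay recorded edits byte-for-byte.
replay_edits <- function(text, annotations, edits) {
  if (nrow(edits) == 0L) return(text)
  red <- edits$token_index[edits$operation == "redact"]
  sub <- edits[edits$operation != "redact", , drop = FALSE]
  out <- text
  if (nrow(sub) > 0L) {
    ord <- order(annotations$start[sub$token_index], decreasing = TRUE)
    for (j in ord) {
      i <- sub$token_index[j]
      s <- annotations$start[i]; e <- annotations$end[i]
      out <- paste0(substr(out, 1L, s), sub$after[j],
                    substr(out, e + 1L, nchar(out)))
    }
  }
  if (length(red) > 0L) out <- apply_redaction(out, annotations, red)
  out
}

#' Perturb one text under a perturbation spec
#'
#' Composes the engine: annotate tokens, size the budget, select valid words
#' under the spec's seed, and apply the spec's operator family. For homophone
#' perturbations, selected words with no sound-alike candidate are replaced by
#' other unused valid words (seeded draw order); only when the budget still
#' cannot be met is the example infeasible. Budget infeasibility is signalled
#' as a condition of class `"perturbr_infeasible"`, which the corpus
#' retention rule consumes.
#'
#' @param text Input text.
#' @param spec A [perturbation_spec()].
#' @param provider Homophone provider (used for `ptype = "homophone"`).
#' @param lexicon Medical lexicon (character vector of lowercase terms).
#' @param tagger Part-of-speech tagger function.
#' @return A `perturbed_example` object: a list with `original`, `perturbed`,
#'   `spec`, `edits` (tibble: `token_index`, `operation`, `before`, `after`),
#'   `target_count`, and the token `annotations`.
#' @export
perturb_example <- function(text, spec,
                            provider = homophone_provider_dictionary(),
                            lexicon = default_medical_lexicon(),
                            tagger = rule_pos_tagger) {
  stopifnot(inherits(spec, "perturbation_spec"))
  ann <- annotate_tokens(text, lexicon = lexicon, tagger = tagger,
                         valid_pos = spec$valid_pos)
  n_total <- sum(ann$is_word)
  n_valid <- sum(ann$is_valid)
  target <- compute_target_count(n_total, n_valid, spec$level)
  if (is.na(target)) {
    abort(sprintf(
      "Budget infeasible: level %.0f%% of %d words needs %d valid words, have %d.",
      100 * spec$level, n_total,
      max(1L, as.integer(round_half_up(spec$level * n_total))), n_valid),
      class = "perturbr_infeasible")
  }

  if (spec$ptype == "homophone") {
    # walk a seeded permutation of valid tokens; skip words with no homophone
    valid_idx <- which(ann$is_valid)
    ordered <- with_seed_(spec$seed,
                          valid_idx[sample.int(length(valid_idx))])
    sel <- integer(0); repl <- character(0)
    for (i in ordered) {
      if (length(sel) == target) break
      h <- apply_homophone(ann$token[i], provider)
      if (!is.na(h)) { sel <- c(sel, i); repl <- c(repl, h) }
    }
    if (length(sel) < target) {
      abort(sprintf(
        "Budget infeasible: %d homophone swaps needed, only %d valid words have homophones.",
        target, length(sel)),
        class = "perturbr_infeasible")
    }
    edits <- tibble::tibble(token_index = sel, operation = "homophone_swap",
                            before = ann$token[sel], after = repl)
  } else {
    sel <- select_words(ann, target, seed = spec$seed)
    if (spec$ptype == "typographical") {
      out <- character(length(sel)); ops <- character(length(sel))
      for (j in seq_along(sel)) {
        res <- apply_typo(ann$token[sel[j]], spec$letter_fraction_range,
                          seed = derive_seed(spec$seed, paste0("w", sel[j])))
        out[j] <- res; ops[j] <- attr(res, "operation")
      }
      edits <- tibble::tibble(token_index = sel, operation = ops,
                              before = ann$token[sel], after = out)
    } else {
      edits <- tibble::tibble(token_index = sel, operation = "redact",
                              before = ann$token[sel], after = "")
    }
  }
  structure(
    list(original = text,
         perturbed = replay_edits(text, ann, edits),
         spec = spec, edits = edits, target_count = target,
         annotations = ann),
    class = "perturbed_example"
  )
}

#' @export
print.perturbed_example <- function(x, ...) {
  cat(sprintf("<perturbed_example> %s @ %.0f%% (%d edit%s)\n",
              x$spec$ptype, 100 * x$spec$level, nrow(x$edits),
              if (nrow(x$edits) == 1L) "" else "s"))
  cat("original :", x$original, "\n")
  cat("perturbed:", x$perturbed, "\n")
  invisible(x)
}
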