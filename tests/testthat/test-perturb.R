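test_that("target count is a half-up word budget floored at one", {
  # a 10-word sentence with 5 valid words at 10% perturbs exactly 1 word
  expect_identical(compute_target_count(10, 5, 0.10), 1L)
  expect_identical(compute_target_count(10, 10, 1.0), 10L)
  # budget beyond the valid words is the infeasibility signal
  expect_identical(compute_target_count(10, 2, 0.50), NA_integer_)
  expect_identical(compute_target_count(10, 10, 0.25), 3L)  # half-up at 2.5
  expect_identical(compute_target_count(3, 3, 0.10), 1L)    # floor at 1
  expect_error(compute_target_count(10, 5, 0), class = "perturbr_bad_spec")
  expect_error(compute_target_count(10, 5, -0.1), class = "perturbr_bad_spec")
})

test_that("spec validation rejects out-of-range levels and empty POS sets", {
  expect_error(perturbation_spec("redaction", 0), class = "perturbr_bad_spec")
  expect_error(perturbation_spec("redaction", 1.2), class = "perturbr_bad_spec")
  expect_error(perturbation_spec("homophone", 0.2, valid_pos = character()),
               class = "perturbr_bad_spec")
  expect_error(perturbation_spec("homophone", 0.2,
                                 letter_fraction_range = c(0.5, 0.2)),
               class = "perturbr_bad_spec")
})

test_that("word selection is uniform, seeded, and exhaustive at full budget", {
  ann <- annotate_tokens("alpha beta gamma delta the epsilon")
  expect_equal(sum(ann$is_valid), 5L)
  # full budget selects every valid token regardless of seed
  for (s in c(1L, 99L)) {
    expect_setequal(select_words(ann, 5L, seed = s), which(ann$is_valid))
  }
  expect_identical(select_words(ann, 3L, seed = 7L),
                   select_words(ann, 3L, seed = 7L))
  expect_error(select_words(ann, 6L, seed = 1L),
               class = "perturbr_infeasible")
  # frequency of single draws from 4 valid tokens is binomially uniform
  ann4 <- annotate_tokens("alpha beta gamma delta")
  draws <- vapply(seq_len(10000L),
                  function(s) select_words(ann4, 1L, seed = s), integer(1))
  freq <- table(factor(draws, levels = 1:4))
  # 3 sigma band around n * p for Binomial(10000, 1/4)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(freq - 2500) < 3 * sigma))
})

test_that("typo operator always changes the word and respects its budget", {
  for (w in c("a", "aa", "ab", "discharge", "Voxelotor")) {
    changed <- vapply(1:1000, function(s) as.vector(apply_typo(w, seed = s)) != w,
                      logical(1))
    expect_true(all(changed))
  }
  # published exemplar outcomes are reachable operator outputs
  r1 <- apply_typo("affect", c(0.2, 0.5), seed = 114)
  expect_equal(as.vector(r1), "affec")
  expect_equal(attr(r1, "operation"), "typo_delete")
  r2 <- apply_typo("discharge", c(0.10, 0.12), seed = 4)
  expect_equal(as.vector(r2), "dicsharge")
  expect_equal(attr(r2, "operation"), "typo_transpose")
  # every outcome is labelled with one of the four operators
  ops <- unique(vapply(1:200, function(s)
    attr(apply_typo("discharge", seed = s), "operation"), ""))
  expect_setequal(ops, c("typo_insert", "typo_delete", "typo_substitute",
                         "typo_transpose"))
  # deletion never consumes the whole word
  for (s in 1:200) {
    r <- apply_typo("ab", c(0.9, 1.0), seed = s)
    expect_gte(nchar(r), 1L)
  }
  # untouched letters keep their case: substitutions insert lowercase only,
  # so an all-caps word keeps >= (n - budget) uppercase letters
  for (s in 1:50) {
    r <- apply_typo("ABCDEFGH", c(0.2, 0.3), seed = s)
    expect_gte(sum(strsplit(unclass(r), "")[[1]] %in% LETTERS), 5L)
  }
})

test_that("homophone swap returns the first spelled-differently candidate", {
  expect_equal(apply_homophone("did"), "deed")
  expect_equal(apply_homophone("in"), "inn")
  expect_equal(apply_homophone("Did"), "Deed")  # case carried over
  expect_identical(apply_homophone("voxelotor"), NA_character_)
  # candidate equal in spelling is skipped in favour of the next one
  prov <- function(word) c("did", "deed")
  expect_equal(apply_homophone("did", prov), "deed")
  # provider failure propagates, never silently skipped
  failing <- function(word) rlang::abort("lookup unreachable",
                                         class = "perturbr_provider_error")
  expect_error(apply_homophone("did", failing),
               class = "perturbr_provider_error")
})

test_that("redaction removes words, collapses whitespace, keeps punctuation", {
  ann <- annotate_tokens(table1_sentence, lexicon = default_medical_lexicon())
  idx <- which(ann$token %in% c("icterus", "life"))
  expect_equal(apply_redaction(table1_sentence, ann, idx), table1_redacted)
  expect_equal(apply_redaction(table1_sentence, ann, integer(0)),
               table1_sentence)
  ann3 <- annotate_tokens("a b c")
  expect_equal(apply_redaction("a b c", ann3, 1:3), "")
})

test_that("perturb_example composes the engine under its invariants", {
  lex <- default_medical_lexicon()
  sent <- "the patient felt happy muscle pain during night rest care"
  for (ptype in c("typographical", "homophone", "redaction")) {
    sp <- perturbation_spec(ptype, 0.30, seed = 5L)
    px <- perturb_example(sent, sp, lexicon = lex)
    # budget exactness
    expect_equal(nrow(px$edits), px$target_count)
    expect_equal(px$target_count, compute_target_count(
      sum(px$annotations$is_word), sum(px$annotations$is_valid), 0.30))
    # eligibility: only valid tokens are ever edited
    expect_true(all(px$annotations$is_valid[px$edits$token_index]))
    # determinism
    px2 <- perturb_example(sent, sp, lexicon = lex)
    expect_identical(px$perturbed, px2$perturbed)
    expect_identical(px$edits, px2$edits)
    # replaying recorded edits reproduces the perturbed text byte-for-byte
    expect_identical(
      perturbr:::replay_edits(px$original, px$annotations, px$edits),
      px$perturbed)
  }
  # redaction monotonicity: word count drops by exactly the budget
  spr <- perturbation_spec("redaction", 0.30, seed = 2L)
  pxr <- perturb_example(sent, spr, lexicon = lex)
  n_before <- sum(annotate_tokens(sent)$is_word)
  n_after <- sum(annotate_tokens(pxr$perturbed)$is_word)
  expect_equal(n_after, n_before - pxr$target_count)
  # typo locality: unedited tokens unchanged as a multiset
  spt <- perturbation_spec("typographical", 0.30, seed = 3L)
  pxt <- perturb_example(sent, spt, lexicon = lex)
  before <- pxt$annotations$token[-pxt$edits$token_index]
  after_ann <- annotate_tokens(pxt$perturbed)
  expect_true(all(before %in% after_ann$token))
  # homophone property: every after-string is listed under the before-string
  prov <- homophone_provider_dictionary()
  sph <- perturbation_spec("homophone", 0.30, seed = 4L)
  pxh <- perturb_example(sent, sph, lexicon = lex)
  for (j in seq_len(nrow(pxh$edits))) {
    expect_true(tolower(pxh$edits$after[j]) %in%
                  prov(tolower(pxh$edits$before[j])))
  }
})

test_that("published homophone row is reproduced when prepositions are eligible", {
  # the worked example swaps "did" and "in"; admitting prepositions makes
  # exactly those two the only homophone-capable words, so any seed hits them
  sp <- perturbation_spec("homophone", 2 / 18, seed = 1L,
                          valid_pos = c(valid_pos_default(), "preposition"))
  px <- perturb_example(table1_sentence, sp)
  expect_identical(px$perturbed, table1_homophone)
  expect_equal(px$target_count, 2L)
})

test_that("infeasible budgets raise the dedicated condition", {
  # 4 words, 1 valid: 50% redaction needs 2
  one_valid <- function(words) c("noun", rep("determiner", length(words) - 1L))
  sp <- perturbation_spec("redaction", 0.50, seed = 1L)
  expect_error(perturb_example("pain the the the", sp, tagger = one_valid),
               class = "perturbr_infeasible")
  # homophone budget unreachable even after reselection
  sph <- perturbation_spec("homophone", 0.50, seed = 1L)
  expect_error(
    perturb_example("voxelotor icterus mucosa lesion", sph),
    class = "perturbr_infeasible")
})
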