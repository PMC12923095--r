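test_that("the grid holds three strictly increasing levels per type", {
  grid <- perturbation_grid()
  expect_equal(nrow(grid), 9L)
  expect_equal(grid$level[grid$ptype == "typographical"], c(0.10, 0.30, 0.50))
  expect_equal(grid$level[grid$ptype == "homophone"], c(0.10, 0.20, 0.30))
  expect_equal(grid$level[grid$ptype == "redaction"], c(0.10, 0.30, 0.50))
})

test_that("retention keeps a record only when all nine cells are feasible", {
  # a 4-word sentence with 1 valid word fails 50% redaction (needs 2)
  recs <- dplyr::bind_rows(
    tibble::tibble(id = "ok1", task = "sentiment_binary",
                   text = "the patient felt happy muscle pain during night rest care",
                   gold = "positive"),
    tibble::tibble(id = "bad1", task = "sentiment_binary",
                   text = "pain the the the", gold = "negative"))
  corpus <- build_perturbed_corpus(recs, seed = 1L)
  expect_setequal(unique(corpus$record_id), "ok1")
  # a surviving record has exactly 10 variants: 1 original + 3 types x 3 levels
  expect_equal(nrow(corpus), 10L)
  expect_equal(sum(corpus$ptype == "original"), 1L)
  dropped <- attr(corpus, "dropped")
  expect_equal(dropped$record_id, "bad1")
  expect_match(dropped$reason, "redaction:0.5")
  # manifest records the run conditions
  mf <- attr(corpus, "manifest")
  expect_equal(mf$n_retained_records, 1L)
  expect_equal(mf$n_dropped_records, 1L)
  expect_match(mf$provider_version, "dictionary")
})

test_that("retention soundness holds on replay of every emitted variant", {
  recs <- generate_classification_corpus(12L, "condition_ternary", seed = 8L)
  corpus <- build_perturbed_corpus(recs, seed = 8L)
  expect_equal(nrow(attr(corpus, "dropped")), 0L)
  pert <- dplyr::filter(corpus, ptype != "original")
  expect_equal(nrow(pert), 12L * 9L)
  # every perturbed variant edited exactly its budget
  expect_true(all(pert$n_perturbed ==
                    pmax(1, floor(pert$level * pert$n_words + 0.5))))
})

test_that("corpus rebuild under the same seed is byte-identical", {
  recs <- generate_classification_corpus(6L, "sentiment_binary", seed = 21L)
  c1 <- build_perturbed_corpus(recs, seed = 5L)
  c2 <- build_perturbed_corpus(recs, seed = 5L)
  expect_identical(c1$text, c2$text)
  c3 <- build_perturbed_corpus(recs, seed = 6L)
  expect_false(identical(c1$text, c3$text))
})

test_that("splits carve prompt-tuning then test then validation", {
  recs <- generate_classification_corpus(5000L, "condition_ternary", seed = 1L)
  sp <- assign_splits(recs, n_test = 1000L, fraction_prompt_tuning = 0.20,
                      seed = 1L)
  expect_equal(unname(table(sp$split)["prompt_tuning"]), 1000L,
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$split)["test"]), 1000L, ignore_attr = TRUE)
  expect_equal(unname(table(sp$split)["validation"]), 3000L,
               ignore_attr = TRUE)
  # partition: every record in exactly one split
  expect_setequal(sp$id, recs$id)
  expect_false(anyDuplicated(sp$id) > 0L)
  # infeasible carve-outs fail loudly, naming the carve-out
  expect_error(assign_splits(recs, n_test = nrow(recs), seed = 1L),
               class = "perturbr_split_error")
  expect_error(assign_splits(recs, n_test = 10L, fraction_prompt_tuning = 1,
                             seed = 1L),
               class = "perturbr_split_error")
})

test_that("qa splits keep all questions of a note together", {
  qa <- generate_qa_corpus(40L, seed = 2L)
  # simulate a source corpus with multiple questions per note
  multi <- dplyr::bind_rows(
    qa,
    dplyr::mutate(qa[1:10, ], id = paste0(id, "b"),
                  question = paste(question, "again")))
  one <- select_one_question_per_note(multi)
  expect_equal(nrow(one), 40L)  # one survivor per distinct note
  expect_equal(dplyr::n_distinct(one$note_id), 40L)
  # deterministic: the lowest record id survives
  expect_true(all(sort(one$id[order(one$note_id)]) == sort(qa$id)))
  sp <- assign_splits(one, n_test = 10L, fraction_prompt_tuning = 0.25,
                      seed = 3L)
  joined <- dplyr::left_join(one, sp, by = "id")
  leak <- joined |>
    dplyr::distinct(note_id, split) |>
    dplyr::count(note_id) |>
    dplyr::filter(n > 1L)
  expect_equal(nrow(leak), 0L)
})

test_that("jsonl round trip preserves the corpus and its edit records", {
  recs <- generate_classification_corpus(4L, "sentiment_binary", seed = 13L)
  corpus <- build_perturbed_corpus(recs, seed = 13L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- read_corpus_jsonl(path)
  expect_equal(nrow(back), nrow(corpus))
  expect_equal(back$text, corpus$text)
  expect_equal(back$record_id, corpus$record_id)
  i <- which(back$ptype == "typographical" & back$level == 0.3)[1]
  expect_equal(back$edits[[i]], corpus$edits[[i]])
})

test_that("task records are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = c("a", "b"),
                                  text = c("mild pain", "severe pain"),
                                  label = c("positive", "negative")), path)
  recs <- read_task_records(path, task = "sentiment_binary")
  expect_equal(recs$gold, c("positive", "negative"))
  expect_error(validate_task_records(tibble::tibble(id = "a", text = "x")))
  expect_error(validate_task_records(
    tibble::tibble(id = "a", task = "bad_kind", text = "x", gold = "y")))
  qa_bad <- tibble::tibble(id = "q1", task = "qa", text = "n", gold = "a",
                           note_id = "n1", note = "n", question = " ",
                           answer = "a")
  expect_error(validate_task_records(qa_bad), "question")
})
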