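# Shared fixtures: the published worked-example sentence and the published
# robustness-count tables used as inputs to the analysis chain.

table1_sentence <- paste0(
  "How did voxelotor affect the patient’s scleral icterus and overall ",
  "quality of life in the given discharge summary?")

table1_redacted <- paste0(
  "How did voxelotor affect the patient’s scleral and overall quality ",
  "of in the given discharge summary?")

table1_homophone <- paste0(
  "How deed voxelotor affect the patient’s scleral icterus and overall ",
  "quality of life inn the given discharge summary?")

# Published per-(task, model) robustness counts
# (increase / stable / decrease / catastrophic).
published_model_task_counts <- function() {
  tibble::tribble(
    ~task,               ~model,     ~increase, ~stable, ~decrease, ~catastrophic,
    "sentiment_binary",  "GPT",       6L,  2L, 19L, 9L,
    "sentiment_binary",  "BlueBERT",  0L, 16L, 20L, 0L,
    "sentiment_binary",  "Llama",     0L, 19L, 14L, 3L,
    "condition_ternary", "GPT",      13L, 15L,  5L, 3L,
    "condition_ternary", "BlueBERT",  0L, 28L,  8L, 0L,
    "condition_ternary", "Llama",     0L, 15L, 21L, 0L,
    "qa",                "GPT",      15L,  1L, 11L, 0L,
    "qa",                "Llama",     4L, 17L,  6L, 0L
  )
}

# Published per-perturbation-type robustness counts.
published_ptype_counts <- function() {
  tibble::tribble(
    ~ptype,          ~increase, ~stable, ~decrease, ~catastrophic,
    "typographical", 4L, 11L,  9L, 0L,
    "homophone",     1L, 16L,  7L, 0L,
    "redaction",     0L,  8L, 12L, 4L
  )
}

# Expand a wide count table into one row per cell (the `category` long form
# consumed by tabulate_robustness()).
expand_counts <- function(wide) {
  lv <- robustness_levels()
  keys <- setdiff(names(wide), lv)
  purrr::pmap_dfr(wide, function(...) {
    row <- list(...)
    purrr::map_dfr(lv, function(cat) {
      n <- row[[cat]]
      if (n == 0L) return(NULL)
      out <- tibble::as_tibble(row[keys])
      out[rep(1L, n), ] |> dplyr::mutate(category = cat)
    })
  })
}

# Independent longest-common-subsequence oracle: naive memoized recursion,
# structurally unlike the iterative rolling-array used by the package.
lcs_bruteforce <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a[i] == b[j]) rec(i - 1L, j - 1L) + 1L
           else max(rec(i - 1L, j), rec(i, j - 1L))
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

qa_tokens_oracle <- function(x) {
  t <- strsplit(tolower(x), "[^[:alnum:]]+")[[1]]
  t[nzchar(t)]
}
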