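---
title: "Calibrated text perturbation and robustness analysis with perturbr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated text perturbation and robustness analysis with perturbr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbr)
library(dplyr)
```

## The problem

Text models deployed in health settings receive imperfect input: patients
type under stress or illness, speech-to-text introduces sound-alike words,
and people redact information for privacy. perturbr makes that imperfection
reproducible. It injects three families of human-like noise — typographical
errors, homophone substitutions, and redactions — into health-related text at
calibrated levels, evaluates any text model on original versus perturbed
inputs through a pluggable adapter, and runs the downstream robustness
statistics on the resulting performance grid.

## The perturbation model

### Word budget

A perturbation level is a fraction of *all* words in a text, but only
**valid words** — adjectives, adverbs, verbs, and nouns — may be touched.
The budget is

$$t = \max\{1,\ \mathrm{round}(\ell \cdot n_{\mathrm{words}})\}$$

with half-up rounding. In a 10-word sentence with 5 valid words, a 10% level
perturbs 1 valid word — effectively 20% of the valid words. When the budget
exceeds the number of valid words, the perturbation is *infeasible*; the
corpus builder's retention rule drops any record that cannot support every
cell of the grid, so the released corpus is complete by construction.

The grid pairs each type with three levels, labelled low/medium/high:
typographical 10/30/50%, homophone 10/20/30% (fewer words have
sound-alikes, so lower fractions are the realistic range), redaction
10/30/50%.

```{r}
perturbation_grid()
```

### Operators

* **Typographical**: one of insertion, deletion, substitution, or adjacent
  transposition, drawn uniformly per word. The number of letter positions
  touched is `round(u * nchar(word))` with `u` uniform on
  `letter_fraction_range` (default 0.20–0.50), never fewer than one. The
  output always differs from the input: deletions keep at least one letter,
  substitutions avoid the original letter, transpositions fall back to a
  substitution when no adjacent pair differs, and single-letter words get
  exactly one insertion or substitution.
* **Homophone**: the first provider candidate whose spelling differs
  replaces the word. Two providers share one contract (`word -> ordered
  candidates` plus a version attribute): a bundled, versioned TSV dictionary
  (offline, used by all tests) and a sounds-like HTTP lookup. A selected
  word without a homophone is *reselected* — another unused valid word takes
  its place — and only when the budget still cannot be met is the example
  infeasible.
* **Redaction**: the selected words are removed; whitespace collapses to
  single spaces and punctuation that did not belong to a removed token is
  preserved.

Every accepted example records its edits (token index, operator, before,
after), and replaying the edits against the original reproduces the
perturbed text byte-for-byte — the property the corpus tests re-check.

### Tokenization and tagging

Tokens are whitespace runs with leading/trailing punctuation split off
(word-internal apostrophes and hyphens stay put), carrying 0-based half-open
character spans. Parts of speech come from an injected tagger; the bundled
`rule_pos_tagger()` is a deterministic closed-class lexicon plus suffix
heuristics, defaulting unknown words to noun. That is deliberately simple:
it removes tagger nondeterminism from tests, and any external tagger with
the same signature can be swapped in for real corpora. Medical terms are
flagged against a newline-delimited lowercase lexicon (a small default
ships with the package).

### Reproducibility

One RNG stream is derived per (record, type, level) from the global seed via
a string hash (`derive_seed()`), so corpus-level results are independent of
processing order and a rerun under the same seed is byte-identical.

## Evaluation harness

Prompts follow a fixed few-shot structure: role statement, exactly *k* = 5
worked examples, task instructions, the item input, an isolation instruction
(each item is judged in its own session), and a justification request; QA
prompts add the instruction to answer only from the provided note. Shots are
drawn from the prompt-tuning split, label-balanced as evenly as *k* allows.
Splits carve the prompt-tuning fraction (default 20%) first, then a random
test set (default 1000), leaving validation; QA corpora are split over
unique notes, with one question kept per note (lowest record id), so no note
leaks across splits.

Adapters are plain functions `(prompt, item) -> response`, one call per
item. Classification responses are parsed by first word-boundary label
match (unparseable responses score as wrong); accuracy plus macro-averaged
precision/recall/F1 treat the binary and ternary tasks symmetrically. QA
answers are scored with ROUGE-L (the analysis metric) and BLEU with add-one
smoothing on zero-match orders — short clinical answers otherwise collapse
to zero. A BERTScore-style scorer can be injected as a function; the core
has no neural-model dependency.

The built-in mock adapters make the whole pipeline testable offline: an
oracle, an adversary, a keyword classifier that reads the fixtures' planted
signal, an extractive QA answerer, and a noisy channel (below).

## Robustness statistics

Each perturbed cell is compared to its own unperturbed baseline through the
relative change $\Delta = (v_{\mathrm{pert}} - v_{\mathrm{orig}}) /
v_{\mathrm{orig}}$ and binned:

| bin | rule |
|---|---|
| increase | $\Delta > 0$ |
| stable | $-0.05 \le \Delta \le 0$ |
| decrease | $-0.50 \le \Delta < -0.05$ |
| catastrophic | $\Delta < -0.50$ |

The verbal definitions of the bins leave the boundary points open; here the
boundaries are assigned to the milder bin so the four bins partition the
line, and the comparisons carry a 1e-9 tolerance so a drop of exactly 5%
(or 50%) lands in its stated bin despite floating-point representation.
A zero baseline has no defined relative change and is rejected.

Binned cells feed contingency tables (with half-up percentage rounding at
the table's printed precision) and a Pearson chi-squared test of
independence — $\sum (O-E)^2/E$, no continuity correction, all-zero margins
dropped with a warning. Differences along each experimental dimension
(perturbation type, level, model, task) are tested with the tie-corrected
Friedman statistic

$$Q = \frac{(k-1)\sum_j \left(R_j - \tfrac{n(k+1)}{2}\right)^2}
           {\sum_{ij} r_{ij}^2 - \tfrac{nk(k+1)^2}{4}}$$

followed, when $k \ge 3$, by Conover's pairwise comparisons
$t = |R_i - R_j| / \sqrt{2n(A_1 - B_1)/((n-1)(k-1))}$ with Bonferroni
correction, and by a one-way repeated-measures ANOVA on the same
blocks-by-treatments matrix. The effect size reported for the ranked pairs
is $r = |t|/\sqrt{t^2 + \mathrm{df}}$, a standard r-from-t convention (the
convention behind the original analysis is not stated, so these values are
descriptive, not reproductions). Blocks match levels by *position*
(low/medium/high) across types, because the numeric grids differ between
types. The level dimension compares the three perturbed levels.

For the medical-term question, each example's ratio of perturbed medical
tokens to perturbed tokens is bucketed into ten equal-width bins on [0, 1]
and the median score per bucket and level is reported
(`medical_perturbation_profile()`), with `plot_medical_profile()` as the
companion figure.

## Synthetic fixtures and what they do (not) show

The fixture generators exist so that every stage has known ground truth
without any third-party download:

* Classification sentences are ten words with eight valid words, at least
  four of them homophone-capable in the bundled dictionary, so the full grid
  is feasible for every record and the retention rule drops nothing. One
  slot carries the label signal (a keyword the mock classifier reads);
  corrupting or redacting it degrades the mock predictably.
* QA notes are three slot-filled sentences; the reference answer *is* the
  fact sentence, so the extractive mock scores ROUGE-L 1.0 on clean
  questions and falls once the question's anchor words are perturbed.
* `generate_result_table()` emulates the full results grid — 8 task-model
  combinations, 9 conditions plus baseline, 4 classification or 3 QA
  metrics, 270 perturbed cells — with programmed per-dimension effects and
  Gaussian noise. With all effects zero, treatments are exchangeable within
  blocks, which is what the null-calibration check exploits.

The noisy-channel mock is *paired*: each item has a latent baseline
correctness draw reused across conditions, and a programmed relative change
$d$ modifies that same set (keep probability $1+d$ for $d<0$; flip
probability $d\,p/(1-p)$ for $d>0$). The measured relative change then
concentrates on $d$ fast enough that regimes of +2%, −3%, −20% and −70%
are recovered as increase/stable/decrease/catastrophic bins in well over
95% of runs at 500 items per condition.

Fixtures are structural stand-ins, not clinical language: they use a small
closed vocabulary, a rule tagger, and planted signal. Passing tests show the
*machinery* is correct — budgets exact, edits replayable, metrics equal to
their brute-force oracles, tests calibrated — not that any particular hosted
model is robust. Real-model conclusions require running the harness with an
HTTP adapter on real corpora.

## Problem sizes and numerical choices

The shipped checks use sizes chosen to make the statistical properties
sharp while keeping a desktop run comfortable: 1,000 fixture sentences
(9,000 perturbations) for budget exactness, 100 seeded runs at 500 items
per condition for bin recovery, and 1,000 synthetic grids for the Friedman
null calibration (nominal 5% rejection, accepted band 3–7%). Half-up
rounding is used wherever a published table prints rounded values; rank ties
take mid-ranks; a constant-within-blocks matrix yields a Friedman statistic
of 0 and Conover comparisons of $t=0,\ p=1$ rather than 0/0.

## Known limitations

* The rule tagger is coarse; real corpora deserve an injected tagger, and
  valid-word decisions change with it.
* The bundled homophone dictionary is small and sounds-like rather than
  strictly phonetic (it includes published near-homophone exemplars such as
  "did"/"deed"); the HTTP provider needs network access.
* The engine perturbs the question field of QA records, not the note.
* BLEU here is a single-reference sentence score with a fixed smoothing
  choice; cross-toolkit BLEU comparisons are not meaningful at that
  granularity.
* The repeated-measures ANOVA is one-way per dimension; no factorial
  decomposition is attempted.
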