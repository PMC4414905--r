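---
title: "Mining hospital service quality signals from online health communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hospital service quality signals from online health communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parents and caregivers discuss pediatric hospitals at length in online
community forums: which clinic to choose, how long the wait was, whether a
doctor was kind or a prescription worked. These messages carry qualitative
judgments that surveys capture only slowly and expensively, but they are
noisy — hospital names appear as acronyms, abbreviations and misspellings,
spacing and casing are erratic, and a single short message can swing from
praise to complaint between sentences.

`hospmine` implements a lexicon-driven pipeline that turns such a corpus
(threads → messages → sentences, with region and posting-date metadata) into
structured signals:

1. **Preprocessing** — HTML stripping, text normalization (casefolding,
   whitespace collapse) with an offset map back to the raw text, sentence
   splitting and tokenization.
2. **Hospital name extraction** — dictionary-based recognition with a
   stepwise normalization of noisy surface forms to canonical hospitals.
3. **Message filtering** — only messages with a clear, unambiguous hospital
   mention are analyzed further.
4. **Quality factor detection** — keyword-lexicon matching of six service
   quality factors (*service*, *professionalism*, *process*, *environment*,
   *impression*, *popularity*), each with subcategory codes f1–f29
   (functional) or e1–e10 (emotional).
5. **Recommendation classification** — lexicon-based sentence polarity and
   mood-flow analysis yield a four-class message label (positive, neutral,
   bilateral, negative) and a binary reduction.
6. **Evaluation and analytics** — precision/recall/F1 against gold labels per
   region with macro averages, factor share distributions by region and
   time, within-factor item shares, and term–hospital co-occurrence in
   negatively opinionated threads.

A seeded synthetic corpus generator produces gold-labeled corpora with the
same statistical structure, so every stage is testable end to end without
any external data.

## Text normalization and matching

All dictionary matching operates on normalized text: lowercase, with every
whitespace run collapsed to a single space, applied identically when
lexicons are loaded and when messages are scanned. This neutralizes the
casing and spacing noise that dominates community text. `normalize_text()`
additionally returns an offset map so any span found in normalized text can
be projected back onto the raw message. Morphological analysis is
deliberately out of scope: the normalizer is a pluggable seam, and the
substring-at-token-boundary matching strategy below does not depend on any
particular language's morphology.

Sentences are delimited by `.`, `!`, `?` or a newline, with the punctuation
kept attached to the preceding sentence and no abbreviation handling —
community messages are short and fragmentary, and a heavier segmenter would
add failure modes without changing the sentence-presence statistics the
classifier consumes. Tokens are maximal runs of Unicode letters and digits,
with 0-based half-open offsets throughout.

## Hospital name normalization

Each hospital lexicon entry carries a canonical name, a region, and a set of
aliases (acronyms, abbreviations, known misspellings). A candidate span —
a token n-gram of the normalized message, up to 5 tokens — is resolved by a
stepwise procedure:

1. exact equality with a canonical name;
2. exact equality with any listed alias;
3. fuzzy matching: the minimal Levenshtein distance to any alias, accepted
   only if `distance <= max(1, floor(0.25 * nchar(alias)))`.

The relative threshold (default `max_rel_distance = 0.25`, configurable)
scales the tolerated corruption with alias length while always allowing one
edit. Fuzzy ties are broken by smallest distance, then a preference for
hospitals in the message's own region, then longest alias, then smallest
canonical id; a fuzzy tie between distinct hospitals that survives the
region preference marks the span *ambiguous*, and ambiguous messages are
dropped by the filtering stage rather than guessed at. Ambiguity defined as
a minimal-distance tie is this package's operationalization; it is the
weakest assumption that makes "ambiguous" decidable from the lexicon alone.

Overlapping candidate matches are resolved best-quality-first: smallest edit
distance, then longest span, then leftmost. Quality precedes length because
a generous relative threshold lets an n-gram one filler word wider than a
verbatim long alias slip under the fuzzy bound; distance-first guarantees a
verbatim mention keeps exactly its own span. Among equal-quality overlaps
(the common case for keyword lexicons) longest-match-first applies, so
"waiting time" beats "waiting".

## Factor detection and counting

Factor keywords and their equivalents (high-frequency alternative surface
forms that resolve to the same entry) are matched exactly, at token
boundaries, per sentence, longest-first and non-overlapping. There is no
stemming and no compound-noun decomposition — the keyword-list mechanism is
the method, and its known blind spots (compounds, homonyms) are the reason
detection is evaluated against gold labels rather than assumed correct.
Counts partition exactly by any requested grouping (region, year, month,
factor, subcategory, hospital): the sum over groups always equals the number
of mentions.

A message "contains quality factors" iff it has at least one factor mention;
that operationalizes the corpus statistic reported by `corpus_stats()`
alongside thread counts and messages-per-thread ratios, whose `Average` row
is the macro mean of per-region ratios (each region weighted equally).

## Recommendation classification

Sentence polarity is the sign of (positive cue count − negative cue count);
a cue within `negation_window` tokens (default 2) after a negation marker
flips sign; ties give 0 — a neutral sentence — which is symmetric and avoids
positive bias. The *mood flow* of a message is its ordered sequence of
sentence polarities. The default presence rule assigns:

- **positive** — some sentence is +1 and none is −1;
- **negative** — some sentence is −1 and none is +1;
- **bilateral** — both polarities occur (a within-message polarity
  transition);
- **neutral** — no polarized sentence.

An alternative `"last"` mode (last polarized sentence wins) is exposed
behind configuration for corpora where the closing sentence carries the
verdict; it never produces bilateral labels. The binary reduction maps
bilateral to negative — when praise and complaint coexist, treating the
message as a recommendation is the costlier mistake — and excludes neutral
messages.

Factor mentions inherit polarity sentence-first with message fallback: a
mention in a polarized sentence takes that sentence's polarity, and a
mention in an unpolarized sentence takes the message label. This keeps
instance polarities consistent with the mood flow at the finest granularity
available.

## Evaluation

Hospital-name extraction is scored on `(message, canonical hospital)` pairs,
factor detection on `(message, factor)` pairs, and recommendation
classification on binary labels per message — message-level keys are the
weakest assumption about annotation granularity. Reports carry one row per
region plus a macro-average row (the arithmetic mean of per-region values;
the package always reports the computed mean, never a separately stated
aggregate). Recommendation reports precision only. Percentages are kept
unrounded internally; presentation rounding is round-half-up via
`round_half_up()`, and `F1 = 2PR/(P+R)` with `F1 = 0` when `P + R = 0`.

## Analytics

`factor_distribution()` computes per-group factor shares that sum to 100%
within every group; by default the denominator is the classified
(non-neutral) instances, with `include_neutral = TRUE` as the explicit
alternative, and `polarity = "negative"` restricts to negatively polarized
instances (the yearly negative-attitude trend when grouped by year). Both
denominator modes are provided because either convention is defensible;
making the switch explicit keeps any figure reproducible from its caption.
`item_share()` drills into one factor's keywords or subcategories.
`cooccurrence()` calls a thread *negatively opinionated* iff at least one
member message is binary-negative and none is binary-positive — a
deliberately conservative roll-up, stated in the output metadata along with
the denominator. `recommendation_share()` is the share of positive instances
among all classified instances.

## The synthetic generator

`generator_config()` defaults encode the corpus shape the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `regions` | six cities | Seoul, Daegu, Busan, Daejeon, Incheon, Gwangju |
| `messages_per_thread_mean` | 5.59 | thread sizes are 1 + Poisson(4.59) |
| `factor_probs` | 0.0334 each | ⇒ ≈18.45% of messages carry ≥1 factor keyword |
| `polarity_mix` | .36/.56/.03/.05 | positive/neutral/bilateral/negative; negative incl. bilateral ≈ 8% |
| `hospital_mention_prob` | 0.9 | messages mentioning a hospital |
| `typo_rate`, `max_typo_ops` | 0.10, 1 | a realistic mild misspelling rate for planted aliases |
| `date_range` | 2007-04 – 2013-05 | thread months drawn uniformly |

Messages are assembled from lowercase token slots (filler vocabulary, an
optional alias possibly corrupted by bounded random edits, planted factor
keywords, sentiment cues consistent with the drawn four-class label), so raw
text equals its normalized form and every planted span is known exactly.
The generator emulates the *structural and statistical* properties the
pipeline consumes — mention noise, factor planting rates, polarity mixtures,
region/month metadata — and none of the linguistic ones: no morphology, no
compound nouns, no sarcasm, no topic coherence. Tests passing on synthetic
corpora therefore certify the pipeline mechanics (matching, thresholds,
inheritance, aggregation arithmetic), not performance on real Korean forum
text, which is exactly why the evaluation harness takes external gold files.

The shipped lexicons under `inst/extdata` are small synthetic stand-ins
(tens of keywords per factor), designed together with the generator
vocabulary to be collision-free — no filler n-gram falls within the fuzzy
threshold of any alias, and with at most one typo edit a corrupted alias is
always strictly closer to its own entry than to any other. Under those
conditions extraction and detection are provably perfect on noise-free
corpora, a closure property the test suite asserts at about 2,000 messages.

## Numerical and design choices

- Offsets are 0-based half-open everywhere; spans refer to normalized text
  with projection to raw text available.
- One seeded RNG per generator run (`withr::with_seed`); no global state.
  Re-running any stage with the same inputs is bit-identical.
- Sentence-level ties (equal cue counts) are neutral by construction.
- Thread titles are not scanned by default; `include_titles = TRUE`
  concatenates each title ahead of its thread's first message, as the choice
  is not derivable from the data model.
- Degenerate inputs are values, not errors: empty corpora produce all-zero
  manifests, empty messages are dropped by filtering (never by I/O), and a
  candidate with no match is a no-match value.
- Test and acceptance problem sizes (≈2,000 messages for the closure
  property, ≈5,000 for mixture recovery, 1,500 threads for co-occurrence
  recovery) were chosen as the smallest corpora at which 3-standard-error
  bands around the planted parameters are a few percentage points wide.

## Limitations

- Keyword matching cannot see compounds, homonyms or spelling variants
  absent from the lexicon; real-corpus recall depends entirely on lexicon
  coverage.
- The sentiment model is cue counting with a short negation window; no
  intensity, sarcasm or machine-learned generalization.
- Coreference ("that hospital") and context-based disambiguation beyond the
  region-preference tie rule are out of scope.
- The fuzzy threshold trades recall against false merges between similarly
  named hospitals; 0.25 is a reasonable default for multi-word names but
  short acronym aliases should be curated with care.
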