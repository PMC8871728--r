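---
title: "Dictionary-based sentiment analysis of comment streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based sentiment analysis of comment streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentidict)
```

sentidict analyses public opinion in social-media comment streams on
public-health topics (its motivating use case is Chinese-microblog
discussion of an intimate-partner-violence event) with a *dictionary*
method: no statistical classifier is trained, and every score is an exact,
auditable function of the comment's tokens and a sentiment lexicon. This
vignette describes the model, the parameters that matter, the synthetic
corpus generator the tests rest on, and the design decisions taken where
the method family leaves choices open.

## The sentiment lexicon

A lexicon maps each surface form to exactly one of four roles:

* **polarity** words carry the base weight $B_{v_i}$, conventionally $+1$
  (praise) or $-1$ (criticism);
* **negation** (privative) words carry $C_{v_i} = -1$ and flip the next
  sentiment word;
* **degree adverbs** carry an intensity weight $A_{v_i}$ fixed by one of
  six levels — extremely/most (2), super (1.5), very (1.25), relatively
  (1.2), slightly (0.8), under (0.5) — and scale the next sentiment word;
* **emoji** glosses (the bracketed platform names of emoticons, e.g.
  `[smile]`) behave as polarity words with $B = \pm 1$.

These weights are structural constants of the method, enforced at load
time by `validate_lexicon()`: a file claiming a "very"-level adverb with
weight 2 is rejected, not repaired. Polarity weights outside $\pm 1$ are
admitted by default so graded user lexicons load; `strict = TRUE` enforces
the $\pm 1$ convention.

Composite lexicons are assembled from fragments (a general dictionary, a
user-defined domain dictionary, automatically expanded entries) with
`merge_lexicons()`. The method family does not define what happens when a
word occurs in two fragments under different roles, so the package fixes
an explicit, logged rule: role precedence **negation > degree adverb >
emoji > polarity**, then last-fragment-wins within a role. Negation first
is the conservative choice — mistaking a negator for a polarity word
corrupts both the word's own score and its neighbour's, whereas the
reverse error costs only one term. Every resolved conflict is returned in
the `conflicts` attribute so a user can audit the merge.

## Scoring

Scoring is a single left-to-right scan per sentence (`score_sentence()`,
batched by `score_comments()`). Degree adverbs and negators accumulate as
*pending modifiers*; the next token whose word has role polarity or emoji
consumes them:

$$E_i = \Big(\prod A\Big) \times \Big(\prod C\Big) \times B_{v_i},
\qquad E_{s_i} = \sum_i E_i, \qquad E = \sum_i E_{s_i}.$$

A comment is labelled positive when $E > 0$, negative when $E < 0$, and
neutral at $E = 0$.

Three points in this scheme are genuine design decisions:

* **The privative-word rule.** Read literally, the base algorithm scores a
  negation word *itself* ($E_i = C_{v_i} \times B_{v_i}$), but a negator
  has no base weight of its own, and under the literal reading the $-1$
  weight could never flip a polarity word — the stated purpose of the
  negation dictionary. The package therefore scores a sentiment word
  *preceded by* a privative word as $C \times B$, the only reading under
  which both printed cases ($A \times B$ and $C \times B$) come out
  exactly, and the standard convention in the dictionary-method
  literature. Both readings are documented here; the adopted one is what
  the test suite pins down.
* **Joint modifiers.** The two cases are stated separately and the
  combined case (adverb *and* negator before one word) is never defined.
  sentidict composes multiplicatively, $A \times C \times B$, which agrees
  with each printed case alone and makes double negation restore sign
  exactly ($(-1)(-1) = 1$). The composition sits behind
  `scoring_config()` should a different rule ever be needed.
* **Modifier scope.** Modifiers attach to the *next* sentiment word,
  looking back no further than the previous sentiment word, never across
  a sentence boundary, and each modifier is consumed by exactly one word.
  Tokens without any lexicon role do not interrupt the scope. A
  fixed-window alternative (`modifier_scope = "fixed_window"`) restricts
  collection to the $k$ tokens immediately before the sentiment word. A
  dangling modifier with no following sentiment word contributes nothing.

Numerically, sums of products of the weights $\{\pm 1, 2, 1.5, 1.25, 1.2,
0.8, 0.5\}$ can carry binary floating-point error (1.2 and 0.8 are not
exact in binary), so the neutral band is configurable with default
`neutral_tolerance = 1e-9` — far above accumulated rounding error at
comment length, far below the smallest nonzero exact score. The scorer's
correctness is pinned by an independently coded brute-force scorer (a
backward-scanning implementation kept in the test helpers) that must agree
*exactly*, mismatch count zero, on ten thousand random sentences.

## Automated lexicon induction

**Co-occurrence and PMI.** `build_cooccurrence()` counts, per word and
unordered word pair, the number of *units* containing them. The default
unit is the document, i.e. one comment: microblog comments are short, so
document-level co-occurrence is the natural granularity; a sliding window
of $k$ tokens is available for long texts. Pointwise mutual information is

$$\mathrm{PMI}(w_1, w_2) = \log_2
\frac{P(w_1 \wedge w_2)}{P(w_1)\,P(w_2)},$$

with probabilities counts over units. With additive smoothing
$\varepsilon$ (default 1, add-one on the pair count, with the matching
mass $\varepsilon/n$ added to the independence product) unseen pairs stay
finite; $\varepsilon = 0$ reproduces the bare formula exactly and treats a
zero pair count as an error, which is the mode the closed-form tests use.

**SO-PMI.** The semantic orientation of a candidate word is the summed
PMI with a positive seed vocabulary minus the summed PMI with a negative
seed vocabulary; its sign assigns polarity ($> 0$ positive, $< 0$
negative, $= 0$ neutral). As printed in its source, the negative-seed sum
is indexed with a membership typo ("$\notin$"); the package implements
membership ($\in$), which is what the accompanying definition of the seed
vocabularies supports. Because exact zero is measure-zero under smoothing,
"neutral" is a band of half-width `tol = 1e-12`. Neutral candidates are
excluded from the expanded lexicon; the rest enter with weight $\pm 1$
and provenance `sopmi_expanded`. Seed words absent from the corpus
contribute zero and are reported. SO-PMI is antisymmetric under a seed-set
swap by construction, and the tests require that swap to flip every
non-neutral label exactly.

**TextRank.** Seed-emotion-word *candidates* are nominated by ranking the
word co-occurrence graph (an edge joins words appearing within
`window_size` tokens of each other) with the damped iteration

$$WS(v) = (1 - d) + d \sum_{u \in \mathrm{adj}(v)} \frac{WS(u)}{\deg(u)},$$

run to sup-norm convergence. Defaults are the standard values of this
algorithm family — window 5, damping $d = 0.85$, tolerance $10^{-6}$, cap
200 iterations — none of which the method's source specifies. The fixed
point is verified in tests against a direct linear solve of
$(I - dAD^{-1})\,ws = (1-d)\mathbf{1}$ to $10^{-8}$. The ranked list is a
*template for manual polarity labelling*: turning candidates into seeds is
a human judgment and deliberately not automated.

**TF-IDF adverb nomination.** Candidate degree adverbs are ranked by the
classical $\mathrm{tf}(w) \cdot \ln(N/\mathrm{df}(w))$ (total corpus
frequency times log inverse document frequency; the variant is isolated
in one function for substitution). How the candidate pool is restricted to
adverbs is corpus- and language-specific, so it is exposed as a predicate
or word list (`candidates =`), and terms already in the degree-adverb
dictionary are removed afterwards (`exclude =`). Level assignment of the
retained adverbs is again manual by design: the six-level weights encode
human intensity judgments.

## Preprocessing

Cleaning removes invalid records (empty text, missing timestamp, texts
matching configurable irrelevance patterns, by default URL-only comments),
collapses duplicates, and sorts chronologically. "Duplicate" is read
conservatively as *same user, same whitespace-normalised text*; a global
text-identity mode is available (`dedupe_key = "text"`) since the stricter
reading cannot be recovered from the looser one. Every removal is counted
in a `CleaningReport`; nothing is dropped silently, and
`n_output = n_input - n_duplicates - n_invalid` always holds.

Emoji arrive as bracket-marked glosses; glosses known to the emoji lexicon
are kept as atomic tokens, unknown ones (emoticons without a clear
emotional tendency) are deleted. Tokenization is dictionary-first: any
dictionary word occurring in the text is emitted as one token, and
out-of-dictionary spans fall to a pluggable segmenter whose built-in
default is deterministic greedy longest match, character-by-character
otherwise. A statistical CJK segmenter can be plugged in behind the same
contract; the built-in default exists so that every test is reproducible
without a language model. Stop-word removal exempts emoji glosses and any
protected surface — the pipeline protects all lexicon words, because
public stop lists routinely contain negators and would silently disable
negation scoring.

## Opinion aggregation

**Stages.** An event timeline is split into contiguous stages. The
faithful mode takes explicit breakpoint dates (the analyst's "important
time nodes"); each breakpoint ends a stage, and three stages are labelled
outbreak / fluctuation / recession. Because eyeballed boundaries are not
reproducible, an explicit heuristic is also provided (`auto = TRUE`):
outbreak ends at the last day with volume at least 50% of the peak;
recession begins at the first day of the terminal run of days at or below
10% of the peak. The two thresholds are package choices, stated here so
they can be criticised; the manual mode remains the default.

**Summaries.** Per stage: counts and proportions of the three labels, the
extreme values of $E$, the positive mass $\sum_{E>0} E$ and the negative
mass $\sum_{E<0} |E|$ (their comparison shows which pole dominates), and
the daily volume series. Rather than describing where the distribution
"concentrates", the summary reports exact extremes and masses — a
deliberate sharpening of a vaguer prose convention. Geographic aggregation
maps free-text region strings through a province-to-macro-region table
(the four economic macro-regions of mainland China are bundled as
`china_region_map()`), with unknown or empty strings in an explicit
`unspecified` bucket, and reports shares over two denominators — all
users, and region-known domestic users — because both are conventional
and they answer different questions.

**Kendall's W.** Expert-panel agreement uses the coefficient of
concordance with mid-rank ties and the tie correction
$W = 12S / (m^2(n^3-n) - m\sum_j T_j)$, the standard form for Likert-type
ratings, with the $\chi^2 = m(n-1)W$ approximation on $n-1$ degrees of
freedom and the usual Delphi consensus rule ($W > 0.6$ and $p < 0.05$)
as a reported flag. The implementation is cross-checked in the tests
against an independent community-ecology implementation
(`vegan::kendall.global`) on tied data.

## The synthetic generator

The raw corpus this pipeline family is applied to (crawled microblog
comments) is not redistributable, so the package carries a first-class
generator (`synthetic_spec()`, `make_lexicon()`, `generate_comments()`)
whose output has *known ground truth*. Its defaults emulate the shape of
a real multi-week event stream:

* a 37-day range with an outbreak-shaped daily volume curve peaking on
  day 2 (peak 400 comments, exponential decay 0.18/day, floor 3);
* three mixture periods: a negative-dominated outbreak (days 1–2;
  negative/neutral/positive = 0.485/0.172/0.343), a mildly positive
  fluctuation period (days 3–21; 0.35/0.20/0.45), and an even recession
  (a third each);
* a region distribution of roughly 73% domestic (split eastern 55.5%,
  western 23.3%, central 15.4%, northeast 5.9% of domestic), 6.8%
  overseas, 20.6% unspecified, realised as concrete province strings;
* 5% planted duplicates and 3% invalid records.

The outbreak mixture and the regional split are taken from published
descriptive statistics of such an event; the fluctuation and recession
mixtures are qualitative descriptions ("positive ascendant", "relatively
even") made concrete once, here, and not tuned thereafter.

Each non-neutral comment plants $k \ge 2$ sentiment units of its label's
sign — the *strong-signal regime*, in which the scorer must reproduce
planted labels with 100% agreement, and does. A planted negation is always
paired with a polarity flip of its head word, so the planted value $E$
remains exact ground truth rather than an approximation; degree adverbs
multiply the planted contribution by their level weight. Surfaces are
collision-free ASCII pseudo-words: the generator tests the *pipeline*, not
Chinese morphology (CJK dictionary segmentation is exercised separately by
fixture strings). What the generator deliberately does **not** emulate:
Zipfian token frequencies, discourse structure, sarcasm, code-switching,
or real emoji usage. Passing tests therefore demonstrate correctness of
the mechanics on well-posed input, not field accuracy of the dictionary
method on real language — the known limitation of all dictionary scorers.

Everything is drawn through a seed-restoring RNG wrapper: a fixed spec
yields byte-identical corpora, and generation does not disturb the
caller's RNG state.

## Problem sizes and runtime choices

The test suite pins the scorer to its oracle on 10,000 random sentences,
checks sign antisymmetry on 1,000 comments, recovers planted stage
mixtures at 5,000 comments per stage (±0.02, the ~3-sigma binomial band)
and region shares at n = 10,000 (±0.015), SO-PMI sign recovery on a
500-document contrast corpus (contrast 0.6 vs 0.1, ≥90% required),
Kendall's W bounds on 1,000 random matrices, and byte-identical pipeline
reruns. These sizes keep every statistical tolerance comfortably above
sampling noise while the whole suite runs in a few minutes on one CPU.

## Known limitations

* Dictionary scoring has no notion of sarcasm, irony, or context beyond
  the modifier scope; intensity calibration is fixed by the six levels.
* The built-in greedy segmenter is a deterministic fallback, not a
  competitive CJK segmenter.
* The chi-square approximation for Kendall's W is asymptotic; for very
  small panels an exact permutation test would be preferable.
* Stage boundaries found by the auto heuristic depend on its two
  thresholds; for published analyses, explicit breakpoints chosen from
  event knowledge remain the recommended mode.
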