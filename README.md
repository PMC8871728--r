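# sentidict

Dictionary-based sentiment analysis for social-media comment streams on
public-health topics — the kind of corpus produced when a
violence-against-women event breaks on a microblog platform and tens of
thousands of comments accumulate over a few weeks. sentidict is aimed at
infodemiology and computational-social-science researchers who need
sentiment scores that are *auditable*: every comment's score is an exact
function of its tokens and a declared lexicon, with no trained model in
the loop.

The package covers the full pipeline:

* **Lexicon construction** — composite sentiment lexicons built from
  fragments: polarity words (weight *B* = ±1), negation words (*C* = −1),
  degree adverbs on six fixed levels
  (*A* ∈ {2, 1.5, 1.25, 1.2, 0.8, 0.5}), and emoji glosses; plus automated
  expansion via TF-IDF adverb nomination, TextRank seed-keyword
  extraction, and SO-PMI polarity classification.
* **Scoring** — each sentiment word receives
  `Ei = (Π A) × (Π C) × B` from the degree adverbs and negators in its
  modifier scope; sentence values are `Esi = Σ Ei`, the comment total is
  `E = Σ Esi`, and the sign of `E` labels the comment positive, neutral,
  or negative.
* **Opinion aggregation** — outbreak / fluctuation / recession stage
  segmentation of the timeline, per-stage emotion statistics and keyword
  rankings, macro-region geographic aggregation, and Kendall's
  coefficient of concordance *W* (with tie correction and the
  `W > 0.6, p < 0.05` consensus rule) for expert-panel robustness checks.
* **Synthetic data** — a fully parameterised comment-stream generator
  with planted labels, planted sentiment values, planted duplicate and
  invalid records, and a planted region distribution, so the whole
  pipeline is testable without any platform crawl.

Lexicon induction uses pointwise mutual information over document-level
co-occurrence,

```
PMI(w1, w2) = log2( P(w1 & w2) / (P(w1) P(w2)) )
SO-PMI(w)   = Σ_{p ∈ positive seeds} PMI(w, p) − Σ_{q ∈ negative seeds} PMI(w, q)
```

with the sign of SO-PMI assigning polarity, and TextRank's damped
iteration `WS(v) = (1 − d) + d Σ_{u∈adj(v)} WS(u)/deg(u)` ranking
seed-word candidates on the word co-occurrence graph.

## Worked example

Generate a synthetic five-week event stream (outbreak-shaped volume,
planted per-period emotion mixtures), clean it, score it, and aggregate:

```r
library(sentidict)

spec <- synthetic_spec(seed = 2024)
lex  <- make_lexicon(spec)
gen  <- generate_comments(spec, lex)

cleaned <- clean_comments(gen$comments)
attr(cleaned, "report")
#> # A tibble: 1 × 7
#>   n_input n_duplicates_removed n_invalid_removed n_output n_empty_text ...
#> 1    2712                  129                74     2509           49
```

The report is exhaustive: 2712 records in, 129 duplicates and 74 invalid
records removed (exactly the counts the generator planted), 2509 kept.
Tokenize and score:

```r
cleaned$text <- normalize_emojis(cleaned$text, lex$lexicon)
tokens <- tokenize_comments(cleaned, gen$user_dict)
scored <- score_comments(tokens, lex$lexicon, comments = cleaned)
head(scored, 3)
#> # A tibble: 3 × 6
#>   id      time                region         E label    n_sentences
#> 1 c000063 2019-11-25 00:37:05 "Shanghai"   0   neutral            1
#> 2 c000140 2019-11-25 00:42:26 ""           2.8 positive           1
#> 3 c000070 2019-11-25 01:00:37 "Tianjin"   -2   negative           3
```

`E` is the comment's total sentiment value (e.g. 2.8 = a degree adverb
times a positive word plus more positive material); its sign gives the
label. Segment the timeline at the analyst's breakpoints and summarise:

```r
plan   <- segment_stages(daily_volume(scored),
                         breakpoints = spec$start_date + c(1, 20))
stage_summary(scored, plan)
#>   label       n_comments prop_negative prop_neutral prop_positive min_E max_E
#> 1 outbreak           527         0.472        0.194         0.334 -6.5    6
#> 2 fluctuation       1908         0.356        0.196         0.448 -6.75   6.7
#> 3 recession           74         0.365        0.365         0.270 -5.7    6.7
```

The recovered outbreak mixture (47/19/33) sits within binomial noise of
the planted one (48.5/17.2/34.3). Regional aggregation reports shares over
all users and over region-known domestic users:

```r
region_aggregate(cleaned, gen$region_map)
#>   region          n share_all share_domestic
#> 1 eastern      1002    0.399          0.543
#> 2 western       437    0.174          0.237
#> 3 central       295    0.118          0.160
#> 4 northeast     110    0.0438         0.0597
#> 5 unspecified   506    0.202         NA
#> 6 overseas      159    0.0634        NA
```

Expert-panel concordance:

```r
kendalls_w(generate_ratings(5, 15, 0.9, seed = 11))
#> Kendall's coefficient of concordance
#>   W = 0.9909 (m = 5 raters, n = 15 items)
#>   chi-squared = 69.3648, df = 14, p = 2.515e-09
#>   consensus (W > 0.60 and p < 0.05): yes
```

`autoplot()` methods exist for stage and region summaries, plus
`plot_daily_volume()` and `plot_sentiment_distribution()`; `tidy()` and
`glance()` methods cover the Kendall's W object.

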