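# run code under a fixed RNG seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# pronounceable, collision-free ASCII pseudo-words
make_pseudo_words <- function(n, n_syllables = 3, taken = character()) {
  if (n == 0) return(character())
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
                  "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    words <- vapply(seq_len(need * 2), function(i) {
      paste0(paste0(sample(consonants, n_syllables, replace = TRUE),
                    sample(vowels, n_syllables, replace = TRUE)),
             collapse = "")
    }, character(1))
    words <- setdiff(unique(words), c(taken, out))
    out <- c(out, utils::head(words, need))
  }
  out
}

# default planted mixtures: a negative-dominated outbreak (days 1-2), a
# mildly positive fluctuation period (through day 21) and an even
# recession, truncated to short streams
default_mixtures <- function(n_days) {
  cuts <- unique(pmin(c(2L, 21L, as.integer(n_days)), as.integer(n_days)))
  mixes <- list(c(0.343, 0.172, 0.485), c(0.45, 0.20, 0.35),
                c(1 / 3, 1 / 3, 1 / 3))[seq_along(cuts)]
  tibble::tibble(
    from_day = c(1L, utils::head(cuts, -1) + 1L),
    to_day = cuts,
    pi_pos = purrr::map_dbl(mixes, 1),
    pi_neu = purrr::map_dbl(mixes, 2),
    pi_neg = purrr::map_dbl(mixes, 3)
  )
}

#' Parameterise a synthetic comment stream
#'
#' Bundles every knob of the synthetic generator: corpus shape (an
#' outbreak-shaped daily volume curve over `n_days`), the planted
#' positive/neutral/negative mixture per period, vocabulary sizes per
#' lexicon role, token composition of a comment, modifier insertion rates,
#' duplicate/invalid record rates, and the categorical region and gender
#' distributions (with an "unspecified" region mass). The defaults emulate
#' a multi-week microblog comment stream around a violence-against-women
#' event: a sharp two-day outbreak peak followed by exponential decay, a
#' negative-dominated outbreak mixture, a mildly positive fluctuation
#' period and an even recession period, and a region distribution with
#' roughly 73% domestic, 7% overseas and 21% unspecified users.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param start_date First day of the stream.
#' @param n_days Number of days.
#' @param volume Daily volume curve: `list(type = "unimodal_outbreak",
#'   peak_day, peak_volume, decay_rate)` or `list(type = "constant", v)`.
#' @param mixtures Tibble with columns `from_day`, `to_day`, `pi_pos`,
#'   `pi_neu`, `pi_neg` (each row a period; rows must tile `1..n_days` and
#'   each mixture must sum to 1).
#' @param vocab Named list of vocabulary sizes: `n_pos`, `n_neg`,
#'   `n_adverbs_per_level`, `n_negation`, `n_emoji`, `n_distractor`.
#' @param n_sentiment_units Range (min, max) of sentiment units planted in
#'   a non-neutral comment; the default minimum of 2 is the strong-signal
#'   regime in which the scorer must reproduce planted labels exactly.
#' @param n_distractors Range (min, max) of neutral filler tokens.
#' @param p_adverb,p_negation Per-unit probabilities of inserting a degree
#'   adverb / a negator. A negation insertion is always paired with a
#'   polarity flip of its head word, so the planted sign is preserved and
#'   the stored planted value stays exact ground truth.
#' @param p_emoji Probability of appending a sign-aligned emoji gloss.
#' @param p_unknown_emoji Probability of appending an unknown emoji code
#'   (deleted by [normalize_emojis()]).
#' @param p_sentence_break Probability of a sentence delimiter between
#'   adjacent items.
#' @param duplicate_rate,invalid_rate Fractions of duplicated (same user,
#'   same text) and invalid (empty-text or URL-only) records planted.
#' @param region_probs Named probabilities over region buckets.
#' @param gender_probs Named probabilities over `female`/`male`/`unknown`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    seed = 1L,
    start_date = as.Date("2019-11-25"),
    n_days = 37L,
    volume = list(type = "unimodal_outbreak", peak_day = 2L,
                  peak_volume = 400L, decay_rate = 0.18),
    mixtures = default_mixtures(n_days),
    vocab = list(n_pos = 40L, n_neg = 40L, n_adverbs_per_level = 4L,
                 n_negation = 8L, n_emoji = 12L, n_distractor = 150L),
    n_sentiment_units = c(2L, 4L),
    n_distractors = c(4L, 12L),
    p_adverb = 0.4,
    p_negation = 0.3,
    p_emoji = 0.15,
    p_unknown_emoji = 0.05,
    p_sentence_break = 0.2,
    duplicate_rate = 0.05,
    invalid_rate = 0.03,
    region_probs = c(eastern = 0.4027, central = 0.1117, western = 0.1690,
                     northeast = 0.0428, overseas = 0.0678,
                     unspecified = 0.2060),
    gender_probs = c(female = 0.55, male = 0.40, unknown = 0.05)) {
  spec <- list(
    seed = as.integer(seed), start_date = as.Date(start_date),
    n_days = as.integer(n_days), volume = volume, mixtures = mixtures,
    vocab = vocab, n_sentiment_units = n_sentiment_units,
    n_distractors = n_distractors, p_adverb = p_adverb,
    p_negation = p_negation, p_emoji = p_emoji,
    p_unknown_emoji = p_unknown_emoji,
    p_sentence_break = p_sentence_break,
    duplicate_rate = duplicate_rate, invalid_rate = invalid_rate,
    region_probs = region_probs / sum(region_probs),
    gender_probs = gender_probs / sum(gender_probs)
  )
  rates <- c(p_adverb, p_negation, p_emoji, p_unknown_emoji,
             p_sentence_break, duplicate_rate, invalid_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            all(abs(rowSums(mixtures[, c("pi_pos", "pi_neu", "pi_neg")]) - 1) < 1e-9),
            mixtures$from_day[1] == 1L,
            all(mixtures$to_day >= mixtures$from_day),
            utils::tail(mixtures$to_day, 1) == spec$n_days)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic sentiment lexicon
#'
#' Collision-free ASCII pseudo-words for every lexicon role: positive and
#' negative polarity words at +1/-1, degree adverbs spread over the six
#' levels with the fixed level weights, negators at -1, emoji glosses at
#' +1/-1 (half each), plus a distractor vocabulary with no lexicon role.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `lexicon` (a validated `sentilex` tibble), `words` (a
#'   list of surface vectors by role: `positive`, `negative`, `adverbs`
#'   (tibble word/level/weight), `negation`, `emoji` (tibble word/weight),
#'   `distractor`).
#' @export
make_lexicon <- function(spec) {
  v <- spec$vocab
  local_seed(spec$seed, {
    n_adv <- v$n_adverbs_per_level * length(degree_levels)
    n_all <- v$n_pos + v$n_neg + n_adv + v$n_negation + v$n_emoji +
      v$n_distractor
    words <- make_pseudo_words(n_all)
    take <- function(n) {
      out <- utils::head(words, n)
      words <<- utils::tail(words, length(words) - n)
      out
    }
    positive <- take(v$n_pos)
    negative <- take(v$n_neg)
    adverbs <- tibble::tibble(
      word = take(n_adv),
      level = rep(names(degree_levels), each = v$n_adverbs_per_level),
      weight = rep(unname(degree_levels), each = v$n_adverbs_per_level)
    )
    negation <- take(v$n_negation)
    emoji <- tibble::tibble(
      word = take(v$n_emoji),
      weight = rep_len(c(1, -1), v$n_emoji)
    )
    distractor <- take(v$n_distractor)

    lex <- dplyr::bind_rows(
      tibble::tibble(word = positive, role = "polarity",
                     level = NA_character_, weight = 1,
                     provenance = "base"),
      tibble::tibble(word = negative, role = "polarity",
                     level = NA_character_, weight = -1,
                     provenance = "base"),
      tibble::tibble(word = adverbs$word, role = "degree_adverb",
                     level = adverbs$level, weight = adverbs$weight,
                     provenance = "base"),
      tibble::tibble(word = negation, role = "negation",
                     level = NA_character_, weight = -1,
                     provenance = "base"),
      tibble::tibble(word = emoji$word, role = "emoji",
                     level = NA_character_, weight = emoji$weight,
                     provenance = "emoji")
    )
    list(
      lexicon = validate_lexicon(lex),
      words = list(positive = positive, negative = negative,
                   adverbs = adverbs, negation = negation, emoji = emoji,
                   distractor = distractor)
    )
  })
}

#' Province-to-macro-region map of mainland China
#'
#' The bundled division of provinces into the four economic macro-regions
#' (eastern, central, western, northeast), plus an `Overseas` row. Used by
#' the synthetic generator and available as a default for
#' [region_aggregate()].
#'
#' @return Tibble `province`, `region`.
#' @export
china_region_map <- function() {
  read_region_map(system.file("extdata", "region_map_china.tsv",
                              package = "sentidict", mustWork = TRUE))
}

daily_volumes <- function(spec) {
  vol <- spec$volume
  days <- seq_len(spec$n_days)
  if (vol$type == "constant") {
    rep(as.integer(vol$v), spec$n_days)
  } else {
    rise <- 1.0   # sharp onset: volume doubles into the peak day by e-fold
    n <- ifelse(
      days <= vol$peak_day,
      vol$peak_volume * exp(-rise * (vol$peak_day - days)),
      vol$peak_volume * exp(-vol$decay_rate * (days - vol$peak_day))
    )
    pmax(3L, as.integer(round(n)))
  }
}

compose_comment <- function(label, lex_words, spec) {
  units <- character(0)
  planted_e <- 0
  if (label != "neutral") {
    sign <- if (label == "positive") 1 else -1
    k <- sample(spec$n_sentiment_units[1]:spec$n_sentiment_units[2], 1)
    for (u in seq_len(k)) {
      negated <- stats::runif(1) < spec$p_negation
      word_sign <- if (negated) -sign else sign
      word <- if (word_sign > 0) {
        sample(lex_words$positive, 1)
      } else {
        sample(lex_words$negative, 1)
      }
      toks <- word
      contrib <- sign  # C x B always recovers the planted sign
      if (negated) toks <- c(sample(lex_words$negation, 1), toks)
      if (stats::runif(1) < spec$p_adverb) {
        adv <- lex_words$adverbs[sample(nrow(lex_words$adverbs), 1), ]
        toks <- c(adv$word, toks)
        contrib <- contrib * adv$weight
      }
      units <- c(units, paste(toks, collapse = " "))
      planted_e <- planted_e + contrib
    }
    if (stats::runif(1) < spec$p_emoji) {
      em <- lex_words$emoji[lex_words$emoji$weight == sign, , drop = FALSE]
      if (nrow(em) > 0) {
        units <- c(units, paste0("[", em$word[sample(nrow(em), 1)], "]"))
        planted_e <- planted_e + sign
      }
    }
  }
  n_dist <- sample(spec$n_distractors[1]:spec$n_distractors[2], 1)
  items <- c(units, sample(lex_words$distractor, n_dist, replace = TRUE))
  if (stats::runif(1) < spec$p_unknown_emoji) {
    items <- c(items, paste0("[x", paste(sample(letters, 4, replace = TRUE),
                                         collapse = ""), "]"))
  }
  items <- sample(items)
  breaks <- stats::runif(length(items)) < spec$p_sentence_break
  breaks[length(items)] <- FALSE
  text <- paste(ifelse(breaks, paste(items, "."), items), collapse = " ")
  list(text = text, planted_E = planted_e)
}

#' Generate a synthetic comment stream with planted ground truth
#'
#' Draws a daily volume from the spec's curve, plants each comment's label
#' from its period's mixture, and composes its text from the synthetic
#' lexicon: `k >= 2` sentiment units of the planted sign (each optionally
#' intensified by a degree adverb and/or negated — with the head word
#' flipped so the net sign is preserved), an optional sign-aligned emoji
#' gloss, neutral distractor tokens and occasional sentence breaks.
#' Duplicate records (same user, same text, slightly later timestamp) and
#' invalid records (empty or URL-only text) are injected at the configured
#' rates. The ground-truth table records, per record, the planted label,
#' the planted sentiment value E implied by the scoring rules, the true
#' region bucket and the duplicate/invalid flags.
#'
#' @param spec A [synthetic_spec()].
#' @param lex A [make_lexicon()] result (built from the same spec if
#'   omitted).
#' @return A list: `comments` (tibble in the on-disk comment schema),
#'   `truth` (tibble `id`, `date`, `label`, `planted_E`, `region_bucket`,
#'   `duplicate`, `invalid`), `user_dict` (every surface the tokenizer must
#'   keep atomic), `region_map` (the bundled province map).
#' @export
generate_comments <- function(spec, lex = make_lexicon(spec)) {
  w <- lex$words
  if (any(spec$mixtures$pi_pos > 0) && length(w$positive) == 0) {
    stop("infeasible spec: positive labels planted but no positive words",
         call. = FALSE)
  }
  if (any(spec$mixtures$pi_neg > 0) && length(w$negative) == 0) {
    stop("infeasible spec: negative labels planted but no negative words",
         call. = FALSE)
  }
  region_map <- china_region_map()
  local_seed(spec$seed + 1L, {
    vols <- daily_volumes(spec)
    day <- rep(seq_len(spec$n_days), vols)
    n <- length(day)
    mix_row <- purrr::map_int(day, function(d) {
      which(spec$mixtures$from_day <= d & spec$mixtures$to_day >= d)[1]
    })
    label <- vapply(mix_row, function(r) {
      sample(c("positive", "neutral", "negative"), 1,
             prob = unlist(spec$mixtures[r, c("pi_pos", "pi_neu", "pi_neg")]))
    }, character(1))

    date <- spec$start_date + (day - 1L)
    secs <- floor(stats::runif(n, 0, 86340))
    time <- as.POSIXct(paste(date), tz = "Asia/Shanghai") + secs

    bucket <- sample(names(spec$region_probs), n, replace = TRUE,
                     prob = spec$region_probs)
    province <- vapply(bucket, function(b) {
      if (b == "unspecified") return("")
      if (b == "overseas") return("Overseas")
      sample(region_map$province[region_map$region == b], 1)
    }, character(1))
    gender <- sample(names(spec$gender_probs), n, replace = TRUE,
                     prob = spec$gender_probs)

    invalid <- stats::runif(n) < spec$invalid_rate
    composed <- purrr::map(seq_len(n), function(i) {
      if (invalid[i]) {
        if (stats::runif(1) < 0.5) {
          list(text = "", planted_E = NA_real_)
        } else {
          list(text = paste0("http://spam.example/",
                             paste(sample(letters, 6, TRUE), collapse = "")),
               planted_E = NA_real_)
        }
      } else {
        compose_comment(label[i], w, spec)
      }
    })

    base <- tibble::tibble(
      id = sprintf("c%06d", seq_len(n)),
      time = time,
      user = sprintf("u%06d", seq_len(n)),
      region = province,
      gender = gender,
      text = purrr::map_chr(composed, "text")
    )
    truth <- tibble::tibble(
      id = base$id, date = date, label = label,
      planted_E = purrr::map_dbl(composed, "planted_E"),
      region_bucket = bucket, duplicate = FALSE, invalid = invalid
    )
    truth$label[invalid] <- NA_character_

    n_dup <- floor(spec$duplicate_rate * n)
    if (n_dup > 0) {
      victims <- sample(which(!invalid), min(n_dup, sum(!invalid)))
      day_end <- as.POSIXct(paste(date[victims]), tz = "Asia/Shanghai") + 86399
      dup <- base[victims, ]
      dup$id <- sprintf("d%06d", seq_along(victims))
      dup$time <- pmin(dup$time + 60, day_end)
      dup_truth <- truth[victims, ]
      dup_truth$id <- dup$id
      dup_truth$duplicate <- TRUE
      base <- dplyr::bind_rows(base, dup)
      truth <- dplyr::bind_rows(truth, dup_truth)
    }
    ord <- sample(nrow(base))
    list(
      comments = base[ord, ],
      truth = truth[ord, ],
      user_dict = c(w$positive, w$negative, w$adverbs$word, w$negation,
                    w$distractor),
      region_map = region_map
    )
  })
}

#' Generate a planted-contrast corpus for SO-PMI testing
#'
#' Builds token documents in which positive-class candidate words co-occur
#' with positive seeds at a high rate and with negative seeds at a low
#' rate, and symmetrically for negative-class candidates, so the sign each
#' candidate should receive from SO-PMI is known by construction.
#'
#' @param n_docs Number of documents.
#' @param n_seeds Length-2 integer vector: positive and negative seed
#'   counts.
#' @param n_candidates Length-2 integer vector: positive- and
#'   negative-class candidate counts.
#' @param contrast Length-2 numeric `(p_aligned, p_opposed)`: per-document
#'   inclusion probability of a seed aligned / opposed to the document
#'   candidate's class.
#' @param seed RNG seed.
#' @return A list: `docs` (list of token vectors), `seeds`
#'   (`list(positive, negative)`), `truth` (tibble `word`, `class`).
#' @export
generate_seed_corpus <- function(n_docs = 500L, n_seeds = c(5L, 5L),
                                 n_candidates = c(20L, 20L),
                                 contrast = c(0.6, 0.1), seed = 1L) {
  stopifnot(all(contrast >= 0 & contrast <= 1))
  local_seed(seed, {
    words <- make_pseudo_words(sum(n_seeds) + sum(n_candidates) + 20)
    pos_seeds <- words[seq_len(n_seeds[1])]
    neg_seeds <- words[n_seeds[1] + seq_len(n_seeds[2])]
    pos_cand <- words[sum(n_seeds) + seq_len(n_candidates[1])]
    neg_cand <- words[sum(n_seeds) + n_candidates[1] + seq_len(n_candidates[2])]
    filler <- utils::tail(words, 20)
    cands <- c(pos_cand, neg_cand)
    classes <- rep(c("positive", "negative"), n_candidates)
    docs <- purrr::map(seq_len(n_docs), function(d) {
      i <- ((d - 1L) %% length(cands)) + 1L
      aligned <- if (classes[i] == "positive") pos_seeds else neg_seeds
      opposed <- if (classes[i] == "positive") neg_seeds else pos_seeds
      c(cands[i],
        aligned[stats::runif(length(aligned)) < contrast[1]],
        opposed[stats::runif(length(opposed)) < contrast[2]],
        sample(filler, 2))
    })
    list(docs = docs,
         seeds = list(positive = pos_seeds, negative = neg_seeds),
         truth = tibble::tibble(word = cands, class = classes))
  })
}

#' Generate a rating matrix with controllable rater agreement
#'
#' Each rater's scores are `a * (1..n) + (1 - a) * (a random permutation)`:
#' agreement `a = 1` gives identical rankings (W = 1), `a = 0` gives
#' independent permutations (W near 0 for large n).
#'
#' @param m Number of raters.
#' @param n Number of items.
#' @param agreement Agreement level in `[0, 1]`.
#' @param seed RNG seed.
#' @return An `m x n` numeric matrix.
#' @export
generate_ratings <- function(m, n, agreement, seed = 1L) {
  stopifnot(agreement >= 0, agreement <= 1)
  local_seed(seed, {
    t(vapply(seq_len(m), function(r) {
      agreement * seq_len(n) + (1 - agreement) * sample(n)
    }, numeric(n)))
  })
}
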