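sentence_delims <- c("。", "！", "？", "!", "?", ".", ";",
                     "；", "\n")

#' Scoring configuration
#'
#' @param modifier_scope `"since_last_sentiment_word"` (default: a degree
#'   adverb or negator modifies the next sentiment word in the sentence,
#'   looking back no further than the previous sentiment word) or
#'   `"fixed_window"` (modifiers only within the `window` tokens
#'   immediately preceding the sentiment word).
#' @param window Window size when `modifier_scope = "fixed_window"`.
#' @param neutral_tolerance Non-negative; a total value with
#'   `|E| <= neutral_tolerance` is classified neutral. The default 1e-9
#'   absorbs float error in sums of products of the dictionary weights.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(modifier_scope = c("since_last_sentiment_word",
                                              "fixed_window"),
                           window = 3L, neutral_tolerance = 1e-9) {
  modifier_scope <- match.arg(modifier_scope)
  stopifnot(neutral_tolerance >= 0, window >= 1)
  structure(list(modifier_scope = modifier_scope, window = as.integer(window),
                 neutral_tolerance = neutral_tolerance),
            class = "scoring_config")
}

#' Split a token sequence into sentences
#'
#' Splits at sentence-final punctuation tokens (Chinese and ASCII
#' full stops, exclamation and question marks, semicolons, line breaks);
#' delimiter tokens are excluded from the sublists and no empty sentence is
#' produced. A sequence with no delimiter is a single sentence.
#'
#' @param surfaces Character vector of token surfaces.
#' @return Integer vector, same length: 1-based sentence index per token,
#'   `NA` for delimiter tokens.
#' @export
split_sentences <- function(surfaces) {
  if (length(surfaces) == 0) return(integer(0))
  is_delim <- surfaces %in% sentence_delims
  sent <- cumsum(c(TRUE, is_delim[-length(is_delim)]))
  sent[is_delim] <- NA_integer_
  # renumber so that sentence ids are consecutive over non-empty sentences
  ids <- sent[!is.na(sent)]
  if (length(ids) == 0) return(sent)
  sent[!is.na(sent)] <- match(ids, sort(unique(ids)))
  sent
}

# score one sentence: left-to-right scan; degree adverbs and negators
# accumulate as pending modifiers and are consumed by the next polarity or
# emoji token; Ei = prod(A) * prod(C) * B
score_sentence_tokens <- function(surfaces, positions, role, weight, config) {
  pending_pos <- integer(0)    # token index of each pending modifier
  pending_a <- double(0)       # degree weight contribution (A or 1)
  pending_c <- double(0)       # negation weight contribution (C or 1)
  hit_i <- integer(0)
  hit_a <- double(0)
  hit_c <- double(0)
  r <- unname(role[surfaces])
  w <- unname(weight[surfaces])
  for (i in seq_along(surfaces)) {
    ri <- r[i]
    if (is.na(ri)) next
    if (ri == "degree_adverb") {
      pending_pos <- c(pending_pos, i)
      pending_a <- c(pending_a, w[i])
      pending_c <- c(pending_c, 1)
    } else if (ri == "negation") {
      pending_pos <- c(pending_pos, i)
      pending_a <- c(pending_a, 1)
      pending_c <- c(pending_c, w[i])
    } else { # polarity or emoji: a sentiment word consumes its modifiers
      in_scope <- if (config$modifier_scope == "fixed_window") {
        pending_pos >= i - config$window
      } else {
        rep(TRUE, length(pending_pos))
      }
      hit_i <- c(hit_i, i)
      hit_a <- c(hit_a, prod(pending_a[in_scope]))
      hit_c <- c(hit_c, prod(pending_c[in_scope]))
      pending_pos <- integer(0)
      pending_a <- double(0)
      pending_c <- double(0)
    }
  }
  tibble::tibble(
    position = positions[hit_i], word = surfaces[hit_i],
    degree_weight = hit_a, negation_weight = hit_c,
    base_weight = w[hit_i], score = hit_a * hit_c * w[hit_i]
  )
}

#' Score one sentence of tokens
#'
#' Computes the per-word sentiment values Ei and their sum Esi for a single
#' sentence. Scanning left to right, each token whose surface has role
#' `polarity` or `emoji` in the lexicon receives
#' `Ei = (prod of pending degree weights A) x (prod of pending negation
#' weights C) x (base weight B)`; the pending modifiers are those degree
#' adverbs and negators seen since the previous sentiment word (or sentence
#' start), and they are consumed — each modifier applies to at most one
#' sentiment word. Tokens with no lexicon role contribute nothing and do
#' not interrupt modifier scope. A negator with no following sentiment word
#' contributes nothing.
#'
#' @param surfaces Character vector: the sentence's token surfaces.
#' @param lexicon A merged lexicon tibble.
#' @param config A [scoring_config()].
#' @return A list with `Esi` (the sentence value, 0 for a sentence without
#'   lexicon words) and `word_scores` (a tibble with one row per scored
#'   word: `position`, `word`, `degree_weight`, `negation_weight`,
#'   `base_weight`, `score`).
#' @examples
#' lex <- lexicon(c("good", "not", "very"),
#'                role = c("polarity", "negation", "degree_adverb"),
#'                weight = c(1, -1, NA), level = c(NA, NA, "very"))
#' score_sentence(c("not", "good"), lex)$Esi        # -1
#' score_sentence(c("very", "good"), lex)$Esi       # 1.25
#' @export
score_sentence <- function(surfaces, lexicon, config = scoring_config()) {
  lut <- lexicon_lookup(lexicon)
  ws <- score_sentence_tokens(surfaces, seq_along(surfaces) - 1L,
                              lut$role, lut$weight, config)
  list(Esi = if (nrow(ws)) sum(ws$score) else 0, word_scores = ws)
}

score_one_comment <- function(surfaces, positions, lut, config) {
  sent <- split_sentences(surfaces)
  keep <- !is.na(sent)
  surfaces <- surfaces[keep]
  positions <- positions[keep]
  sent <- sent[keep]
  if (length(surfaces) == 0) {
    return(list(E = 0, sentence_scores = double(0),
                word_scores = tibble::tibble()))
  }
  word_scores <- list()
  esi <- double(0)
  for (s in unique(sent)) {
    idx <- which(sent == s)
    ws <- score_sentence_tokens(surfaces[idx], positions[idx],
                                lut$role, lut$weight, config)
    esi <- c(esi, if (nrow(ws)) sum(ws$score) else 0)
    if (nrow(ws)) {
      ws$sentence <- s
      word_scores[[length(word_scores) + 1L]] <- ws
    }
  }
  list(E = sum(esi), sentence_scores = esi,
       word_scores = dplyr::bind_rows(word_scores))
}

# single pass over one comment's annotated tokens: role code rc
# (0 none, 1 degree adverb, 2 negation, 3 sentiment), weight wv, delimiter
# flag; returns c(E, n_sentences)
score_fast <- function(rc, wv, delim, config) {
  windowed <- config$modifier_scope == "fixed_window"
  e <- 0
  n_sent <- 0L
  in_sent <- FALSE
  pa <- double(0)   # pending degree weights
  pc <- double(0)   # pending negation weights
  pp <- integer(0)  # pending modifier token indices (fixed-window scope)
  for (i in seq_along(rc)) {
    if (delim[i]) {
      in_sent <- FALSE
      pa <- double(0); pc <- double(0); pp <- integer(0)
      next
    }
    if (!in_sent) {
      n_sent <- n_sent + 1L
      in_sent <- TRUE
    }
    if (rc[i] == 1L) {
      pa <- c(pa, wv[i]); pc <- c(pc, 1); pp <- c(pp, i)
    } else if (rc[i] == 2L) {
      pa <- c(pa, 1); pc <- c(pc, wv[i]); pp <- c(pp, i)
    } else if (rc[i] == 3L) {
      if (windowed) {
        keep <- pp >= i - config$window
        e <- e + prod(pa[keep]) * prod(pc[keep]) * wv[i]
      } else {
        e <- e + prod(pa) * prod(pc) * wv[i]
      }
      pa <- double(0); pc <- double(0); pp <- integer(0)
    }
  }
  c(e, n_sent)
}

label_from_value <- function(E, tol) {
  dplyr::case_when(E > tol ~ "positive", E < -tol ~ "negative",
                   .default = "neutral")
}

#' Score a corpus of tokenized comments
#'
#' Order-preserving batch scorer. For every comment the sentence values are
#' `Esi = sum of word values Ei` and the comment total is `E = sum of Esi`;
#' the sign of E classifies the comment: positive if `E > 0`, negative if
#' `E < 0`, neutral at 0 (within the configured tolerance). A comment with
#' no lexicon word scores 0 and is neutral.
#'
#' @param tokens Token tibble (`id`, `position`, `surface`, `kind`) from
#'   [tokenize_comments()] (after stop-word removal).
#' @param lexicon Merged sentiment lexicon.
#' @param config A [scoring_config()].
#' @param comments Optional comment tibble; when given, `time` and `region`
#'   are carried onto the result and comments without any token are scored
#'   0/neutral rather than omitted.
#' @param audit If `TRUE`, attach a per-word audit table (attribute
#'   `word_scores`): comment id, sentence, token position, matched word,
#'   applied degree product A, negation product C, base weight B and Ei.
#' @return A tibble with one row per comment: `id`, (`time`, `region` when
#'   available), `E`, `label`, `n_sentences`.
#' @export
score_comments <- function(tokens, lexicon, config = scoring_config(),
                           comments = NULL, audit = FALSE) {
  lut <- lexicon_lookup(lexicon)
  ids <- if (!is.null(comments)) comments$id else unique(tokens$id)
  if (audit) {
    tok_split <- split(tokens[, c("position", "surface")],
                       factor(tokens$id, levels = ids))
    res <- purrr::map(ids, function(cid) {
      tk <- tok_split[[cid]]
      if (is.null(tk) || nrow(tk) == 0) {
        return(list(E = 0, sentence_scores = double(0),
                    word_scores = tibble::tibble()))
      }
      score_one_comment(tk$surface, tk$position, lut, config)
    })
    E <- purrr::map_dbl(res, "E")
    n_sent <- purrr::map_int(res, ~ length(.x$sentence_scores))
  } else {
    # fast path: annotate every token once, then one tight pass per comment
    role <- unname(lut$role[tokens$surface])
    rc <- dplyr::case_match(role, "degree_adverb" ~ 1L, "negation" ~ 2L,
                            "polarity" ~ 3L, "emoji" ~ 3L, .default = 0L)
    wv <- unname(lut$weight[tokens$surface])
    delim <- tokens$surface %in% sentence_delims
    grp <- split(seq_len(nrow(tokens)), factor(tokens$id, levels = ids))
    scores <- purrr::map(ids, function(cid) {
      score_fast(rc[grp[[cid]]], wv[grp[[cid]]], delim[grp[[cid]]], config)
    })
    E <- purrr::map_dbl(scores, 1)
    n_sent <- purrr::map_int(scores, ~ as.integer(.x[2]))
  }
  out <- tibble::tibble(id = ids, E = E, n_sentences = n_sent)
  out$label <- label_from_value(out$E, config$neutral_tolerance)
  if (!is.null(comments)) {
    out <- dplyr::left_join(
      out, comments[, intersect(c("id", "time", "region"), names(comments))],
      by = "id"
    )
    out <- out[, c("id", intersect(c("time", "region"), names(out)),
                   "E", "label", "n_sentences")]
  } else {
    out <- out[, c("id", "E", "label", "n_sentences")]
  }
  if (audit) {
    attr(out, "sentence_scores") <- purrr::map(res, "sentence_scores")
    aud <- purrr::map2(res, ids, function(r, cid) {
      if (nrow(r$word_scores) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(id = cid), r$word_scores)
    })
    attr(out, "word_scores") <- dplyr::bind_rows(purrr::compact(aud))
  }
  attr(out, "config") <- config
  out
}
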