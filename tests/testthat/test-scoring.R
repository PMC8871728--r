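test_that("sentence splitting partitions non-delimiter tokens in order", {
  expect_equal(split_sentences(c("a", "。", "b")), c(1L, NA, 2L))
  expect_equal(split_sentences(character()), integer())
  expect_equal(split_sentences(c("a", "b")), c(1L, 1L))
  # leading/trailing/double delimiters never create empty sentences
  expect_equal(split_sentences(c(".", "a", "!", "!", "b", ".")),
               c(NA, 1L, NA, NA, 2L, NA))

  set.seed(4)
  for (i in 1:20) {
    toks <- sample(c(letters[1:5], ".", "!"), 30, replace = TRUE)
    sent <- split_sentences(toks)
    kept <- toks[!is.na(sent)]
    expect_equal(kept, toks[!toks %in% c(".", "!")])
    ids <- sent[!is.na(sent)]
    expect_equal(sort(unique(ids)), seq_len(max(ids)))  # consecutive ids
    expect_false(is.unsorted(ids))
  }
})

test_that("degree adverbs scale and negators flip the following sentiment word", {
  lex <- toy_lexicon()
  # one unmodified positive word
  expect_equal(score_sentence("pos1", lex)$Esi, 1)
  # every level weight, against B = +1 and B = -1
  for (lv in names(degree_levels)) {
    a <- degree_levels[[lv]]
    expect_equal(score_sentence(c(paste0("adv_", lv), "pos1"), lex)$Esi, a * 1)
    expect_equal(score_sentence(c(paste0("adv_", lv), "neg1"), lex)$Esi, a * -1)
  }
  # negation: C x B
  expect_equal(score_sentence(c("not1", "pos1"), lex)$Esi, -1)
  expect_equal(score_sentence(c("not1", "neg1"), lex)$Esi, 1)
  # combined: A x C x B
  expect_equal(score_sentence(c("adv_super", "not1", "pos1"), lex)$Esi,
               1.5 * -1 * 1)
  # double negation restores the sign
  expect_equal(score_sentence(c("not1", "not2", "pos1"), lex)$Esi, 1)
})

test_that("modifiers are consumed by the nearest following sentiment word", {
  lex <- toy_lexicon()
  res <- score_sentence(c("adv_extremely_most", "pos1", "pos2"), lex)
  expect_equal(res$word_scores$score, c(2, 1))  # second word unmodified
  # a trailing negator with no head contributes nothing
  expect_equal(score_sentence(c("pos1", "not1"), lex)$Esi, 1)
  # no-role fillers do not interrupt modifier scope
  expect_equal(score_sentence(c("not1", "filler1", "pos1"), lex)$Esi, -1)
  # a sentence break clears pending modifiers
  toks <- as_token_tbl(list(c("not1", ".", "pos1")))
  expect_equal(score_comments(toks, lex)$E, 1)
})

test_that("fixed-window scope only collects modifiers within the window", {
  lex <- toy_lexicon()
  cfg <- scoring_config(modifier_scope = "fixed_window", window = 1)
  expect_equal(score_sentence(c("not1", "filler1", "pos1"), lex, cfg)$Esi, 1)
  expect_equal(score_sentence(c("not1", "pos1"), lex, cfg)$Esi, -1)
})

test_that("comment totals decompose exactly into word scores and classify by sign", {
  lex <- toy_lexicon()
  toks <- as_token_tbl(list(
    c("adv_extremely_most", "pos1", ".", "neg1", "neg2"),  # +2 then -2
    c("filler1", "filler2"),
    c("pos1", "pos2", "。", "neg1")
  ))
  scored <- score_comments(toks, lex, audit = TRUE)
  expect_equal(scored$E, c(0, 0, 1))
  expect_equal(scored$label, c("neutral", "neutral", "positive"))
  expect_equal(scored$n_sentences, c(2L, 1L, 2L))
  aud <- attr(scored, "word_scores")
  # conservation: E equals the sum of word-level scores per comment
  sums <- tapply(aud$score, aud$id, sum)
  expect_equal(as.numeric(sums[scored$id[c(1, 3)]]), scored$E[c(1, 3)])
  expect_equal(aud$score,
               aud$degree_weight * aud$negation_weight * aud$base_weight)
})

test_that("batch scoring is an order-preserving map", {
  lex <- toy_lexicon()
  sent <- random_sentences(30, seed = 100)
  toks <- as_token_tbl(sent)
  batch <- score_comments(toks, lex)
  expect_equal(batch$id, as.character(seq_along(sent)))
  # singleton batch equals the batch row
  one <- score_comments(toks[toks$id == "7", ], lex)
  expect_equal(one$E, batch$E[batch$id == "7"])
  # permuting input comments permutes output identically
  perm <- sample(length(sent))
  toks_p <- as_token_tbl(sent[perm], ids = as.character(perm))
  batch_p <- score_comments(toks_p, lex)
  expect_equal(batch_p$E, batch$E[match(batch_p$id, batch$id)])
  # empty batch
  expect_equal(nrow(score_comments(toks[0, ], lex)), 0)
})

test_that("scorer agrees exactly with the brute-force oracle on random sentences", {
  lex <- toy_lexicon()
  sent <- random_sentences(1500, seed = 202)
  toks <- as_token_tbl(sent)
  got <- score_comments(toks, lex)
  want <- vapply(sent, oracle_score, numeric(1), lex = lex)
  expect_identical(sum(abs(got$E - want) > 0), 0L)

  cfg <- scoring_config(modifier_scope = "fixed_window", window = 2)
  got_w <- score_comments(toks, lex, cfg)
  want_w <- vapply(sent, oracle_score, numeric(1), lex = lex,
                   scope = "fixed_window", window = 2)
  expect_identical(sum(abs(got_w$E - want_w) > 0), 0L)
})

test_that("negating every polarity and emoji weight negates E and swaps labels", {
  lex <- toy_lexicon()
  flipped <- lex
  pol <- flipped$role %in% c("polarity", "emoji")
  flipped$weight[pol] <- -flipped$weight[pol]
  sent <- random_sentences(300, seed = 77)
  toks <- as_token_tbl(sent)
  a <- score_comments(toks, lex)
  b <- score_comments(toks, flipped)
  expect_equal(b$E, -a$E)
  swap <- c(positive = "negative", neutral = "neutral", negative = "positive")
  expect_equal(b$label, unname(swap[a$label]))
})

test_that("appending an unmodified positive word raises E by exactly its weight", {
  lex <- toy_lexicon()
  sent <- random_sentences(50, seed = 8)
  base <- score_comments(as_token_tbl(sent), lex)
  # append after a sentence break so no dangling modifier can attach to it
  extended <- score_comments(as_token_tbl(lapply(sent, c, ".", "pos1")), lex)
  expect_equal(extended$E, base$E + 1)
})
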