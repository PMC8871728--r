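test_that("co-occurrence counts match brute-force nested-loop counting", {
  docs <- list(c("w1", "w2", "x"), c("w1", "w2"), c("w3"), c("w1"))
  m <- build_cooccurrence(docs)
  expect_equal(pmi(m, "w1", "w2", smoothing = 0),
               log2((2 / 4) / ((3 / 4) * (2 / 4))))
  expect_equal(unname(m$doc_freq[c("w1", "w2", "w3")]), c(3, 2, 1))

  set.seed(15)
  rdocs <- lapply(1:50, function(i) {
    sample(paste0("t", 1:12), sample(2:6, 1), replace = TRUE)
  })
  m <- build_cooccurrence(rdocs)
  for (pair in list(c("t1", "t2"), c("t3", "t7"), c("t5", "t5"),
                    c("t2", "t11"))) {
    i <- match(pair[1], m$vocab)
    j <- match(pair[2], m$vocab)
    expect_equal(as.numeric(m$pair[i, j]),
                 oracle_pair_count(rdocs, pair[1], pair[2]))
  }
  # invariant: pair count never exceeds either marginal
  pw <- as.matrix(m$pair)
  expect_true(all(pw <= pmin(outer(m$doc_freq, rep(1, length(m$vocab))),
                             outer(rep(1, length(m$vocab)), m$doc_freq))))
  expect_true(all(m$doc_freq <= m$n_units))
  expect_error(build_cooccurrence(list()), "empty corpus")
})

test_that("sliding-window model counts windows, not documents", {
  m <- build_cooccurrence(list(c("a", "b", "c", "d")), window = "sliding",
                          k = 2)
  expect_equal(m$n_units, 3)  # windows ab, bc, cd
  expect_equal(pair_counts <- as.numeric(m$pair[match("a", m$vocab),
                                                match("b", m$vocab)]), 1)
  expect_equal(as.numeric(m$pair[match("a", m$vocab), match("c", m$vocab)]), 0)
})

test_that("PMI closed forms: half-overlap gives 1 bit, independence gives 0", {
  # both words in half the units, always together
  m <- build_cooccurrence(list(c("a", "b"), c("a", "b"), "x", "y"))
  expect_equal(pmi(m, "a", "b", smoothing = 0), 1, tolerance = 1e-12)
  # constructed independence: P12 = P1 * P2
  m2 <- build_cooccurrence(list(c("a", "b"), c("a"), c("b"), c("x")))
  expect_equal(pmi(m2, "a", "b", smoothing = 0), 0, tolerance = 1e-12)

  expect_error(pmi(m, "a", "nope"), "not seen")
  expect_error(pmi(m, "a", "x", smoothing = 0), "zero co-occurrence")
})

test_that("PMI with no smoothing reproduces the bare formula on random corpora", {
  set.seed(31)
  docs <- lapply(1:60, function(i) {
    sample(paste0("v", 1:8), sample(3:6, 1))
  })
  m <- build_cooccurrence(docs)
  vocab <- m$vocab
  for (i in 1:15) {
    pair <- sample(vocab, 2)
    if (oracle_pair_count(docs, pair[1], pair[2]) == 0) next
    expect_equal(pmi(m, pair[1], pair[2], smoothing = 0),
                 oracle_pmi(docs, pair[1], pair[2]))
  }
})

test_that("SO-PMI is antisymmetric under seed swap and zero under symmetry", {
  gen <- generate_seed_corpus(n_docs = 200, seed = 9)
  m <- build_cooccurrence(gen$docs)
  word <- gen$truth$word[1]
  v <- so_pmi(m, word, gen$seeds)
  swapped <- list(positive = gen$seeds$negative,
                  negative = gen$seeds$positive)
  expect_equal(so_pmi(m, word, swapped), -v)

  # identical co-occurrence with all seeds cancels exactly
  docs <- list(c("w", "p1", "n1"), c("w", "p1", "n1"), c("p1", "n1"), "z")
  ms <- build_cooccurrence(docs)
  expect_equal(so_pmi(ms, "w", list(positive = "p1", negative = "n1")), 0)

  expect_error(so_pmi(m, word, list(positive = "a", negative = "a")),
               "disjoint")
  expect_warning(
    so_pmi(m, word, list(positive = c(gen$seeds$positive, "zzz_unseen"),
                         negative = gen$seeds$negative)),
    "unseen"
  )
})

test_that("SO-PMI values match the brute-force pairwise summation on a planted corpus", {
  gen <- generate_seed_corpus(n_docs = 300, contrast = c(0.6, 0.1), seed = 13)
  m <- build_cooccurrence(gen$docs)
  for (word in gen$truth$word[c(1, 10, 25, 40)]) {
    expect_equal(so_pmi(m, word, gen$seeds, smoothing = 1),
                 oracle_so_pmi(gen$docs, word, gen$seeds, smoothing = 1))
  }
})

test_that("SO-PMI classification recovers planted polarity and flips under seed swap", {
  gen <- generate_seed_corpus(n_docs = 500, contrast = c(0.6, 0.1), seed = 2)
  m <- build_cooccurrence(gen$docs)
  cls <- classify_by_sopmi(gen$truth$word, m, gen$seeds)
  acc <- mean(cls$polarity == gen$truth$class)
  expect_gte(acc, 0.9)

  swapped <- classify_by_sopmi(gen$truth$word, m,
                               list(positive = gen$seeds$negative,
                                    negative = gen$seeds$positive))
  nonneutral <- cls$polarity != "neutral"
  flip <- c(positive = "negative", negative = "positive")
  expect_equal(swapped$polarity[nonneutral],
               unname(flip[cls$polarity[nonneutral]]))
  expect_equal(swapped$polarity[!nonneutral], cls$polarity[!nonneutral])

  frag <- sopmi_lexicon(cls)
  expect_true(all(frag$weight %in% c(1, -1)))
  expect_true(all(frag$provenance == "sopmi_expanded"))
  expect_false(any(cls$word[cls$polarity == "neutral"] %in% frag$word))
})

test_that("TF-IDF scores equal tf * log(N/df) and rank deterministically", {
  docs <- list(c("a", "a", "b"), c("a", "c"), c("c", "b", "b"))
  r <- tfidf_rank(docs)
  # 'a' occurs in 2 of 3 docs, total frequency 3
  expect_equal(r$score[r$word == "a"], 3 * log(3 / 2))
  # a term in every document has IDF 0 and ranks last
  docs2 <- list(c("x", "u1"), c("x", "u2"), c("x", "u3"))
  r2 <- tfidf_rank(docs2)
  expect_equal(r2$score[r2$word == "x"], 0)
  expect_equal(r2$word[nrow(r2)], "x")
  # single-doc corpus, one term
  expect_equal(tfidf_rank(list("only"))$rank, 1)

  set.seed(41)
  rdocs <- lapply(1:30, function(i) sample(paste0("k", 1:10),
                                           sample(2:5, 1), replace = TRUE))
  got <- tfidf_rank(rdocs)
  for (i in seq_len(nrow(got))) {
    w <- got$word[i]
    tf <- sum(unlist(rdocs) == w)
    df <- sum(vapply(rdocs, function(d) w %in% d, logical(1)))
    expect_equal(got$score[i], tf * log(30 / df))
  }
  # candidate filter and dictionary dedupe
  filt <- tfidf_rank(rdocs, candidates = c("k1", "k2", "k3"), exclude = "k2")
  expect_setequal(filt$word, c("k1", "k3"))
  # ranks are a permutation consistent with non-increasing score
  expect_true(all(diff(got$score) <= 1e-12))
  expect_equal(got$rank, seq_len(nrow(got)))
})

test_that("TextRank matches an independent fixed-point solve and honours symmetry", {
  # two words always adjacent: identical scores
  tr <- textrank_keywords(list(c("a", "b"), c("a", "b")))
  expect_equal(tr$score[1], tr$score[2])
  # one-word corpus: that word ranks first
  expect_equal(textrank_keywords(list("solo"))$word, "solo")

  set.seed(23)
  for (rep in 1:3) {
    docs <- lapply(1:6, function(i) sample(paste0("n", 1:10), 8, replace = TRUE))
    got <- textrank_keywords(docs, window_size = 3, tol = 1e-12,
                             max_iter = 10000)
    adj <- oracle_word_graph(docs, window_size = 3)
    want <- oracle_textrank(adj)
    expect_lt(max(abs(got$score[match(rownames(adj), got$word)] - want)), 1e-8)
  }
})

test_that("TextRank is invariant to document and token-container order", {
  set.seed(5)
  docs <- lapply(1:5, function(i) sample(paste0("m", 1:8), 6, replace = TRUE))
  a <- textrank_keywords(docs)
  b <- textrank_keywords(rev(docs))
  expect_equal(a, b)
  expect_warning(textrank_keywords(docs, max_iter = 2), "did not converge")
})
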