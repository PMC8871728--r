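test_that("lexicon construction fills and enforces degree-level weights", {
  lex <- lexicon(paste0("a", 1:6), role = "degree_adverb",
                 level = names(degree_levels))
  expect_equal(lex$weight, c(2, 1.5, 1.25, 1.2, 0.8, 0.5))
  expect_error(
    lexicon("w", role = "degree_adverb", level = "very", weight = 2),
    "does not match its level"
  )
  expect_error(lexicon("w", role = "negation", weight = 1), "must be -1")
  expect_error(lexicon(c("w", "w"), weight = 1), "duplicate")
  expect_error(lexicon("w", role = "polarity", weight = 0.4, strict = TRUE),
               "strict")
  # non-strict mode admits graded polarity weights
  expect_silent(lexicon("w", role = "polarity", weight = 0.4))
})

test_that("lexicon TSV round-trips and is validated at load time", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\trole\tlevel\tweight",
               "# a comment line",
               "不\tnegation\t\t-1",
               "good\tpolarity\t\t1"), tmp)
  lex <- read_lexicon(tmp)
  expect_equal(lex$weight[lex$word == "不"], -1)
  expect_equal(lex$role[lex$word == "不"], "negation")

  # one adverb per level round-trips with the six fixed weights
  six <- lexicon(paste0("adv", 1:6), role = "degree_adverb",
                 level = names(degree_levels))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(six, out)
  back <- read_lexicon(out)
  expect_equal(back$weight, c(2, 1.5, 1.25, 1.2, 0.8, 0.5))
  expect_equal(back[, c("word", "role", "level", "weight")],
               six[, c("word", "role", "level", "weight")],
               ignore_attr = TRUE)

  # a corrupted degree weight is rejected with the row named
  writeLines(c("word\trole\tlevel\tweight",
               "advx\tdegree_adverb\tvery\t2"), tmp)
  expect_error(read_lexicon(tmp), "advx")

  # duplicates within one file are rejected
  writeLines(c("word\trole\tlevel\tweight",
               "good\tpolarity\t\t1",
               "good\tpolarity\t\t-1"), tmp)
  expect_error(read_lexicon(tmp), "duplicate")
})

test_that("an empty lexicon file yields an empty fragment", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("word\trole\tlevel\tweight", tmp)
  expect_equal(nrow(read_lexicon(tmp)), 0)
})

test_that("merge precedence: negation > degree_adverb > emoji > polarity; later fragment wins within role", {
  base <- lexicon(c("w", "x"), role = "polarity", weight = c(1, 1),
                  provenance = "base")
  sopmi <- lexicon("w", role = "polarity", weight = -1,
                   provenance = "sopmi_expanded")
  merged <- merge_lexicons(base, sopmi)
  expect_equal(merged$weight[merged$word == "w"], -1)
  expect_gt(nrow(attr(merged, "conflicts")), 0)

  neg <- lexicon("w", role = "negation", weight = -1)
  merged2 <- merge_lexicons(neg, base, sopmi)  # negation wins despite order
  expect_equal(merged2$role[merged2$word == "w"], "negation")

  # disjoint fragments merge to their union
  a <- lexicon("a", weight = 1)
  b <- lexicon("b", weight = -1)
  u <- merge_lexicons(a, b)
  expect_setequal(u$word, c("a", "b"))
  expect_equal(nrow(attr(u, "conflicts")), 0)
})

test_that("merge equals brute-force word-by-word precedence on random fragments", {
  set.seed(11)
  words <- paste0("w", 1:30)
  for (rep in 1:5) {
    frags <- lapply(1:3, function(i) {
      n <- sample(5:15, 1)
      picked <- sample(words, n)
      role <- sample(c("polarity", "negation", "degree_adverb", "emoji"),
                     n, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
      lexicon(picked, role = role,
              weight = ifelse(role == "negation", -1,
                              ifelse(role == "degree_adverb", NA,
                                     sample(c(1, -1), n, replace = TRUE))),
              level = ifelse(role == "degree_adverb",
                             sample(names(degree_levels), n, replace = TRUE),
                             NA))
    })
    got <- merge_lexicons(frags)
    want <- oracle_merge(frags)
    expect_equal(
      as.data.frame(got[order(got$word), c("word", "role", "weight")]),
      as.data.frame(want[order(want$word), c("word", "role", "weight")]),
      ignore_attr = TRUE
    )
  }
})

test_that("merged lookup is independent of fragment-internal row order", {
  frag1 <- lexicon(c("a", "b", "c"), role = c("polarity", "negation", "emoji"),
                   weight = c(1, -1, -1))
  frag1_shuffled <- validate_lexicon(frag1[c(3, 1, 2), ])
  frag2 <- lexicon("a", weight = -1)
  m1 <- merge_lexicons(frag1, frag2)
  m2 <- merge_lexicons(frag1_shuffled, frag2)
  expect_equal(as.data.frame(m1), as.data.frame(m2), ignore_attr = TRUE)
})
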