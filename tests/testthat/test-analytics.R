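test_that("explicit breakpoints reproduce the three canonical stage windows", {
  days <- seq(as.Date("2019-11-25"), as.Date("2019-12-31"), by = "day")
  vol <- tibble::tibble(date = days, n = 10L)
  plan <- segment_stages(vol, breakpoints = as.Date(c("2019-11-26",
                                                      "2019-12-15")))
  expect_equal(plan$label, c("outbreak", "fluctuation", "recession"))
  expect_equal(plan$start, as.Date(c("2019-11-25", "2019-11-27",
                                     "2019-12-16")))
  expect_equal(plan$end, as.Date(c("2019-11-26", "2019-12-15",
                                   "2019-12-31")))
  # contiguity and coverage
  expect_equal(plan$start[-1], plan$end[-3] + 1)

  single <- segment_stages(vol)
  expect_equal(nrow(single), 1)
  expect_equal(single$label, "stage-1")
  expect_equal(c(single$start, single$end), range(days))

  expect_error(segment_stages(vol, breakpoints = as.Date("2020-05-01")),
               "inside the corpus date range")
  expect_error(segment_stages(vol, breakpoints = as.Date("2019-11-26"),
                              auto = TRUE), "not both")
})

test_that("auto segmentation recovers boundaries computed by direct scan", {
  start <- as.Date("2021-03-01")
  n_days <- 30
  peak_day <- 4
  n <- round(500 * exp(-0.35 * abs(seq_len(n_days) - peak_day)))
  vol <- tibble::tibble(date = start + seq_len(n_days) - 1, n = as.integer(n))
  plan <- segment_stages(vol, auto = TRUE)
  # direct scan on the curve
  peak <- max(n)
  o_end <- max(which(n >= 0.5 * peak))
  low <- n <= 0.1 * peak
  r_start <- min(which(rev(cumprod(rev(low))) == 1))
  expect_equal(plan$label, c("outbreak", "fluctuation", "recession"))
  expect_equal(plan$end[1], vol$date[o_end])
  expect_equal(plan$start[3], vol$date[r_start])
})

test_that("stage summaries report counts, proportions, extremes and polarity masses", {
  t0 <- as.POSIXct("2020-01-01 10:00:00", tz = "Asia/Shanghai")
  scored <- tibble::tibble(
    id = paste0("c", 1:6),
    time = t0 + c(0, 3600, 86400 * 2, 86400 * 2 + 60, 86400 * 3, 86400 * 3 + 1),
    E = c(2, 1.5, -3, 2, 0, -1),
    label = c("positive", "positive", "negative", "positive", "neutral",
              "negative")
  )
  vol <- daily_volume(scored)
  plan <- segment_stages(vol, breakpoints = as.Date(c("2020-01-01",
                                                      "2020-01-02")))
  s <- stage_summary(scored, plan)
  expect_equal(s$n_comments, c(2L, 0L, 4L))
  expect_equal(s$prop_positive[1], 1)
  expect_true(is.na(s$prop_positive[2]))  # empty stage sentinel
  expect_true(is.na(s$min_E[2]))
  expect_equal(s$min_E[3], -3)
  expect_equal(s$max_E[3], 2)
  expect_equal(s$sum_positive_E[3], 2)
  expect_equal(s$sum_negative_E_abs[3], 4)
  # counts partition the corpus and proportions sum to one
  expect_equal(sum(s$n_comments), nrow(scored))
  props <- rowSums(s[s$n_comments > 0,
                     c("prop_negative", "prop_neutral", "prop_positive")])
  expect_equal(unname(props), rep(1, 2), tolerance = 1e-9)

  # input order invariance
  s2 <- stage_summary(scored[sample(6), ], plan)
  expect_equal(as.data.frame(s2), as.data.frame(s), ignore_attr = TRUE)

  out_of_range <- scored
  out_of_range$time[1] <- t0 - 86400 * 30
  expect_error(stage_summary(out_of_range, plan), "c1")
})

test_that("per-stage keyword ranking counts tokens with lexicographic ties", {
  comments <- make_comment_tbl(id = c("x", "y"), text = c("", ""))
  tokens <- as_token_tbl(list(c("a", "a", "b"), c("c", "b", "b")),
                         ids = c("x", "y"))
  vol <- daily_volume(comments)
  plan <- segment_stages(vol)
  kw <- keyword_frequency_by_stage(tokens, comments, plan, top_k = 2)
  expect_equal(kw$word, c("b", "a"))
  expect_equal(kw$n, c(3L, 2L))

  set.seed(6)
  toks <- lapply(1:20, function(i) sample(letters[1:6], 10, replace = TRUE))
  comments2 <- make_comment_tbl(id = as.character(1:20),
                                text = rep("", 20))
  kw2 <- keyword_frequency_by_stage(as_token_tbl(toks), comments2,
                                    segment_stages(daily_volume(comments2)),
                                    top_k = 100)
  counts <- table(unlist(toks))
  expect_equal(stats::setNames(kw2$n, kw2$word)[names(counts)],
               stats::setNames(as.integer(counts), names(counts)))
})

test_that("region aggregation computes both share denominators", {
  map <- china_region_map()
  comments <- make_comment_tbl(
    id = as.character(1:8),
    text = "t",
    region = c("Beijing", "Beijing", "Sichuan", "Henan", "Liaoning",
               "Overseas", "", "NotAPlace")
  )
  r <- region_aggregate(comments, map)
  expect_equal(sum(r$n), 8)
  expect_equal(r$n[r$region == "eastern"], 2L)
  expect_equal(r$n[r$region == "unspecified"], 2L)  # empty + unknown
  expect_equal(sum(r$share_all), 1)
  expect_equal(sum(r$share_domestic, na.rm = TRUE), 1)
  expect_equal(r$share_domestic[r$region == "eastern"], 2 / 5)
  expect_true(is.na(r$share_domestic[r$region == "overseas"]))

  one <- region_aggregate(make_comment_tbl("a", "t", region = "Beijing"), map)
  expect_equal(one$share_domestic[one$region == "eastern"], 1)
})

test_that("Kendall's W closed forms and bounds hold", {
  # identical rankings: W = 1 exactly
  r <- matrix(rep(1:5, 4), nrow = 4, byrow = TRUE)
  w <- kendalls_w(r)
  expect_equal(w$W, 1)
  expect_true(w$consensus)

  # two reversed raters on 3 items: rank sums equal, W = 0
  w0 <- kendalls_w(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(w0$W, 0)
  expect_false(w0$consensus)

  set.seed(12)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    n <- sample(3:8, 1)
    x <- matrix(stats::runif(m * n), m, n)
    wr <- kendalls_w(x)$W
    expect_gte(wr, 0)
    expect_lte(wr, 1)
  }
  expect_error(kendalls_w(matrix(1, 3, 4)), "undefined W")
  expect_error(kendalls_w(matrix(1:3, 1, 3)), "at least 2")
})

test_that("Kendall's W is invariant to item relabeling and monotone transforms", {
  set.seed(3)
  x <- matrix(stats::runif(20), 4, 5)
  w <- kendalls_w(x)$W
  perm <- sample(5)
  expect_equal(kendalls_w(x[, perm])$W, w)
  y <- x
  y[2, ] <- exp(3 * y[2, ]) + 1  # strictly monotone transform of one rater
  expect_equal(kendalls_w(y)$W, w)
})

test_that("Kendall's W agrees with an independent implementation under ties", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (i in 1:5) {
    x <- matrix(sample(1:4, 24, replace = TRUE), 4, 6)  # Likert-style ties
    if (any(apply(x, 1, function(r) length(unique(r))) == 1)) next
    ours <- kendalls_w(x)$W
    ref <- vegan::kendall.global(t(x))$Concordance_analysis["W", 1]
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
  td <- tidy(kendalls_w(x))
  expect_equal(names(td), c("statistic", "chi_squared", "df", "p.value",
                            "consensus"))
  gl <- glance(kendalls_w(x))
  expect_equal(gl$n_raters, 4)
})
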