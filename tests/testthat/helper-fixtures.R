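# small hand-built lexicon used across scoring tests: two polarity words
# per sign, one adverb per level, two negators, one emoji per sign
toy_lexicon <- function() {
  lexicon(
    word = c("pos1", "pos2", "neg1", "neg2",
             paste0("adv_", names(sentidict::degree_levels)),
             "not1", "not2", "em_pos", "em_neg"),
    role = c(rep("polarity", 4), rep("degree_adverb", 6),
             rep("negation", 2), rep("emoji", 2)),
    weight = c(1, 1, -1, -1, rep(NA, 6), -1, -1, 1, -1),
    level = c(rep(NA, 4), names(sentidict::degree_levels), rep(NA, 4))
  )
}

# random token sequences over the toy lexicon plus no-role fillers and
# sentence delimiters; used for oracle-equivalence and property tests
random_sentences <- function(n, seed, min_len = 3, max_len = 50,
                             p_delim = 0.08) {
  lex <- toy_lexicon()
  pool <- c(lex$word, paste0("filler", 1:20))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    toks <- sample(pool, len, replace = TRUE)
    delim <- runif(len) < p_delim
    toks[delim] <- sample(c(".", "!", "?", "。"), sum(delim), replace = TRUE)
    toks
  })
}

# token tibble for a list of token vectors
as_token_tbl <- function(token_list, ids = as.character(seq_along(token_list))) {
  dplyr::bind_rows(lapply(seq_along(token_list), function(i) {
    toks <- token_list[[i]]
    tibble::tibble(id = ids[i], position = seq_along(toks) - 1L,
                   surface = toks,
                   kind = ifelse(startsWith(toks, "em_"), "emoji_gloss", "word"))
  }))
}

# write a small synthetic working set (comments, lexicon, stopwords,
# config) into dir and return the config path plus the generating objects
write_pipeline_fixture <- function(dir, seed = 17, n_days = 6, v = 60) {
  spec <- synthetic_spec(seed = seed, n_days = n_days,
                         volume = list(type = "constant", v = v))
  lex <- make_lexicon(spec)
  gen <- generate_comments(spec, lex)
  write_comments(gen$comments, file.path(dir, "comments.csv"))
  write_lexicon(lex$lexicon, file.path(dir, "lexicon.tsv"))
  writeLines(gen$user_dict, file.path(dir, "user_dict.txt"))
  writeLines(c(lex$words$distractor[1:5], "filler_stop"),
             file.path(dir, "stopwords.txt"))
  bp <- format(spec$start_date + c(1, 3))
  yaml::write_yaml(list(
    comments = "comments.csv",
    lexicons = list("lexicon.tsv"),
    user_dict = "user_dict.txt",
    stopwords = "stopwords.txt",
    out_dir = "out",
    breakpoints = bp,
    top_k_keywords = 10,
    seed = seed
  ), file.path(dir, "config.yaml"))
  list(config = file.path(dir, "config.yaml"), spec = spec, gen = gen,
       lex = lex)
}

make_comment_tbl <- function(id, text, time = NULL, user = NULL,
                             region = "", gender = "unknown") {
  n <- length(id)
  tibble::tibble(
    id = id,
    time = if (is.null(time)) {
      as.POSIXct("2019-11-25 12:00:00", tz = "Asia/Shanghai") + seq_len(n)
    } else {
      time
    },
    user = if (is.null(user)) paste0("u", seq_len(n)) else user,
    region = rep_len(region, n), gender = rep_len(gender, n), text = text
  )
}
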