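# Independent brute-force implementations used as oracles. These are kept
# deliberately naive and structurally different from the package code:
# the scorer looks BACKWARD from each sentiment word, the co-occurrence
# counter is a nested loop, TextRank is a direct linear solve.

oracle_delims <- c("。", "！", "？", "!", "?", ".", ";",
                   "；", "\n")

# split token vector into sentences (list of index vectors)
oracle_sentences <- function(surfaces) {
  idx <- seq_along(surfaces)
  is_d <- surfaces %in% oracle_delims
  out <- list()
  cur <- integer(0)
  for (i in idx) {
    if (is_d[i]) {
      if (length(cur)) out[[length(out) + 1]] <- cur
      cur <- integer(0)
    } else {
      cur <- c(cur, i)
    }
  }
  if (length(cur)) out[[length(out) + 1]] <- cur
  out
}

# brute-force comment score: for each sentiment token, scan backward to
# the previous sentiment token (within the sentence) and collect modifiers
oracle_score <- function(surfaces, lex,
                         scope = c("since_last_sentiment_word", "fixed_window"),
                         window = 3) {
  scope <- match.arg(scope)
  role <- lex$role[match(surfaces, lex$word)]
  weight <- lex$weight[match(surfaces, lex$word)]
  total <- 0
  for (sent in oracle_sentences(surfaces)) {
    r <- role[sent]
    w <- weight[sent]
    sent_idx <- which(!is.na(r) & r %in% c("polarity", "emoji"))
    for (k in seq_along(sent_idx)) {
      i <- sent_idx[k]
      lo <- if (k == 1) 1 else sent_idx[k - 1] + 1
      mods <- seq(lo, i)[-length(seq(lo, i))]
      if (scope == "fixed_window") mods <- mods[mods >= i - window]
      a <- w[mods][!is.na(r[mods]) & r[mods] == "degree_adverb"]
      cc <- w[mods][!is.na(r[mods]) & r[mods] == "negation"]
      # canonical grouping (prod A) x (prod C) x B, so equality is exact
      total <- total + prod(a) * prod(cc) * w[i]
    }
  }
  total
}

# nested-loop document co-occurrence counts
oracle_pair_count <- function(docs, w1, w2) {
  n <- 0
  for (d in docs) {
    if (w1 %in% d && w2 %in% d) n <- n + 1
  }
  n
}

oracle_doc_freq <- function(docs, w) {
  sum(vapply(docs, function(d) w %in% d, logical(1)))
}

# bare PMI from raw counts (no smoothing)
oracle_pmi <- function(docs, w1, w2) {
  n <- length(docs)
  log2((oracle_pair_count(docs, w1, w2) / n) /
         ((oracle_doc_freq(docs, w1) / n) * (oracle_doc_freq(docs, w2) / n)))
}

oracle_so_pmi <- function(docs, word, seeds, smoothing = 1) {
  n <- length(docs)
  one <- function(s) {
    p12 <- (oracle_pair_count(docs, word, s) + smoothing) / n
    p1p2 <- (oracle_doc_freq(docs, word) / n) * (oracle_doc_freq(docs, s) / n)
    log2(p12 / (p1p2 + smoothing / n))
  }
  sum(vapply(seeds$positive, one, numeric(1))) -
    sum(vapply(seeds$negative, one, numeric(1)))
}

# TextRank fixed point by direct linear solve of
# (I - d * A %*% diag(1/deg)) ws = (1 - d) 1  on the dense adjacency
oracle_textrank <- function(adj, damping = 0.85) {
  nv <- nrow(adj)
  deg <- rowSums(adj)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  m <- diag(nv) - damping * adj %*% diag(inv)
  as.numeric(solve(m, rep(1 - damping, nv)))
}

# dense adjacency of the word graph the package builds, computed naively
oracle_word_graph <- function(token_docs, window_size) {
  vocab <- sort(unique(unlist(token_docs)))
  adj <- matrix(0, length(vocab), length(vocab),
                dimnames = list(vocab, vocab))
  for (toks in token_docs) {
    n <- length(toks)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):min(n, i + window_size - 1)) {
        if (toks[i] != toks[j]) {
          adj[toks[i], toks[j]] <- 1
          adj[toks[j], toks[i]] <- 1
        }
      }
    }
  }
  adj
}

# word-by-word reapplication of the lexicon merge precedence rules
oracle_merge <- function(frags) {
  prec <- c(negation = 1, degree_adverb = 2, emoji = 3, polarity = 4)
  all <- dplyr::bind_rows(lapply(seq_along(frags), function(i) {
    f <- tibble::as_tibble(frags[[i]])
    f$frag <- i
    f
  }))
  rows <- lapply(sort(unique(all$word)), function(w) {
    sub <- all[all$word == w, ]
    sub <- sub[prec[sub$role] == min(prec[sub$role]), ]
    sub[which.max(sub$frag), ]
  })
  out <- dplyr::bind_rows(rows)
  out$frag <- NULL
  out
}
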