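#' Build a word co-occurrence model from tokenized documents
#'
#' Counts, for every word and unordered word pair, the number of counting
#' units in which they occur. With the default `window = "document"` each
#' document (one comment) is a unit — the natural granularity for short
#' microblog comments; with `window = "sliding"` each window of `k`
#' consecutive tokens is a unit, for longer texts. Probabilities for PMI
#' are counts divided by the number of units.
#'
#' @param token_docs List of character vectors, one per document.
#' @param window `"document"` or `"sliding"`.
#' @param k Sliding-window width (tokens), used when `window = "sliding"`.
#' @return An object of class `cooccurrence_model`: number of units,
#'   per-word unit frequencies and a sparse pair-count matrix.
#' @export
build_cooccurrence <- function(token_docs, window = c("document", "sliding"),
                               k = 5L) {
  window <- match.arg(window)
  token_docs <- purrr::map(token_docs, as.character)
  if (length(token_docs) == 0 || all(purrr::map_int(token_docs, length) == 0)) {
    stop("empty corpus: co-occurrence model needs at least one non-empty document",
         call. = FALSE)
  }
  units <- if (window == "document") {
    token_docs
  } else {
    purrr::flatten(purrr::map(token_docs, function(toks) {
      n <- length(toks)
      if (n == 0) return(list())
      if (n <= k) return(list(toks))
      purrr::map(seq_len(n - k + 1L), ~ toks[.x:(.x + k - 1L)])
    }))
  }
  units <- purrr::map(units, unique)
  units <- units[purrr::map_int(units, length) > 0]
  vocab <- sort(unique(unlist(units)))
  n_units <- length(units)
  lens <- purrr::map_int(units, length)
  # binary unit-by-word incidence; crossprod gives all pair unit-counts at once
  x <- Matrix::sparseMatrix(
    i = rep(seq_len(n_units), lens),
    j = match(unlist(units), vocab),
    x = 1,
    dims = c(n_units, length(vocab))
  )
  pair <- Matrix::crossprod(x)
  structure(list(
    n_units = n_units,
    vocab = vocab,
    doc_freq = stats::setNames(Matrix::diag(pair), vocab),
    pair = pair,
    window = window,
    k = if (window == "sliding") as.integer(k) else NA_integer_
  ), class = "cooccurrence_model")
}

#' @method print cooccurrence_model
#' @export
print.cooccurrence_model <- function(x, ...) {
  cat(sprintf("<co-occurrence model: %d %s units, %d words>\n",
              x$n_units,
              if (x$window == "document") "document" else
                sprintf("sliding(%d)", x$k),
              length(x$vocab)))
  invisible(x)
}

pair_count <- function(model, w1, w2) {
  i <- match(w1, model$vocab)
  j <- match(w2, model$vocab)
  as.numeric(model$pair[i, j])
}

#' Pointwise mutual information of a word pair
#'
#' `PMI(w1, w2) = log2( P(w1 & w2) / (P(w1) P(w2)) )`, where P(w1 & w2) is
#' the probability of the two words appearing in the same counting unit
#' and P(w) the probability of a word appearing at all. Positive PMI means
#' the words co-occur more often than independence predicts. Additive
#' smoothing adds `smoothing` pseudo-occurrences to the pair count (and the
#' same mass, `smoothing / n_units`, to the independence product) so that
#' unseen pairs stay finite; `smoothing = 0` reproduces the bare formula
#' and raises an error on a zero co-occurrence count.
#'
#' @param model A [build_cooccurrence()] model.
#' @param w1,w2 Words; both must occur in the corpus.
#' @param smoothing Additive pseudo-count on the pair count (default 1).
#' @return The PMI value in bits.
#' @examples
#' m <- build_cooccurrence(list(c("a", "b"), c("a", "b"), c("c"), c("d")))
#' pmi(m, "a", "b", smoothing = 0)  # both in half the units, always together: 1 bit
#' @export
pmi <- function(model, w1, w2, smoothing = 1) {
  for (w in c(w1, w2)) {
    if (!w %in% model$vocab) {
      stop("word not seen in corpus: ", w, call. = FALSE)
    }
  }
  n <- model$n_units
  n12 <- pair_count(model, w1, w2)
  if (smoothing == 0 && n12 == 0) {
    stop(sprintf("zero co-occurrence for (%s, %s) with no smoothing", w1, w2),
         call. = FALSE)
  }
  p12 <- (n12 + smoothing) / n
  p1 <- model$doc_freq[[w1]] / n
  p2 <- model$doc_freq[[w2]] / n
  log2(p12 / (p1 * p2 + smoothing / n))
}

#' Semantic orientation by SO-PMI
#'
#' `SO-PMI(word) = sum over positive seeds of PMI(word, seed) - sum over
#' negative seeds of PMI(word, seed)`: a word that co-occurs more with the
#' praise vocabulary than with the derogatory vocabulary gets a positive
#' orientation. Seed words never seen in the corpus contribute 0 and are
#' reported via a warning.
#'
#' @param model A [build_cooccurrence()] model.
#' @param word Target word (must occur in the corpus).
#' @param seeds A list with character elements `positive` and `negative`,
#'   both non-empty and disjoint.
#' @param smoothing Additive pair-count smoothing applied pairwise.
#' @return The SO-PMI value.
#' @export
so_pmi <- function(model, word, seeds, smoothing = 1) {
  stopifnot(is.list(seeds), length(seeds$positive) > 0, length(seeds$negative) > 0)
  if (length(intersect(seeds$positive, seeds$negative)) > 0) {
    stop("seed sets must be disjoint", call. = FALSE)
  }
  unseen <- setdiff(c(seeds$positive, seeds$negative), model$vocab)
  if (length(unseen) > 0) {
    warning("seed word(s) unseen in corpus contribute 0: ",
            paste(unseen, collapse = ", "), call. = FALSE)
  }
  pos <- intersect(seeds$positive, model$vocab)
  neg <- intersect(seeds$negative, model$vocab)
  s_pos <- sum(purrr::map_dbl(pos, ~ pmi(model, word, .x, smoothing)))
  s_neg <- sum(purrr::map_dbl(neg, ~ pmi(model, word, .x, smoothing)))
  s_pos - s_neg
}

#' Classify candidate words by the sign of SO-PMI
#'
#' A candidate is positive iff its SO-PMI is above the neutral tolerance,
#' negative iff below its negative, neutral otherwise. Neutral words are
#' excluded when the result is turned into a lexicon fragment; positive
#' and negative words enter the expanded lexicon with weight +1 / -1.
#'
#' @param candidates Character vector of candidate words (seen in corpus).
#' @param model A [build_cooccurrence()] model.
#' @param seeds Seed sets as in [so_pmi()].
#' @param smoothing Additive pair-count smoothing.
#' @param tol Neutral tolerance on SO-PMI; exact zero is measure-zero
#'   under smoothing, so a tiny band (default 1e-12) stands in for it.
#' @return Tibble with columns `word`, `so_pmi`, `polarity`
#'   (positive/neutral/negative).
#' @seealso [sopmi_lexicon()] to convert the result into a lexicon fragment.
#' @export
classify_by_sopmi <- function(candidates, model, seeds, smoothing = 1,
                              tol = 1e-12) {
  values <- purrr::map_dbl(candidates, ~ so_pmi(model, .x, seeds, smoothing))
  tibble::tibble(
    word = candidates,
    so_pmi = values,
    polarity = dplyr::case_when(values > tol ~ "positive",
                                values < -tol ~ "negative",
                                .default = "neutral")
  )
}

#' Turn an SO-PMI classification into a polarity lexicon fragment
#'
#' @param classified Tibble from [classify_by_sopmi()].
#' @return A `sentilex` fragment: non-neutral words with weight +1/-1 and
#'   provenance `"sopmi_expanded"`.
#' @export
sopmi_lexicon <- function(classified) {
  kept <- classified[classified$polarity != "neutral", ]
  lexicon(kept$word, role = "polarity",
          weight = ifelse(kept$polarity == "positive", 1, -1),
          provenance = "sopmi_expanded")
}

#' Rank terms by TF-IDF
#'
#' `score(w) = tf(w) * log(n_docs / df(w))` with tf the total corpus
#' frequency and df the number of documents containing the word — the
#' classical form. Used to nominate candidate degree adverbs: rank the
#' corpus, keep the top `top_k` among the candidate set, then drop terms
#' already present in the degree-adverb dictionary (`exclude`); what
#' remains is a template for manual level assignment (no automatic level
#' guessing).
#'
#' @param token_docs List of character vectors, one per document.
#' @param candidates Optional character vector or predicate function
#'   restricting which terms compete (e.g. an adverb candidate list).
#' @param top_k Number of terms returned (default 100).
#' @param exclude Terms removed from the ranking after scoring (already in
#'   the dictionary).
#' @return Tibble `word`, `tf`, `df`, `score`, `rank` (1-based, ties
#'   broken lexicographically), at most `top_k` rows.
#' @export
tfidf_rank <- function(token_docs, candidates = NULL, top_k = 100,
                       exclude = character()) {
  token_docs <- purrr::map(token_docs, as.character)
  if (length(token_docs) == 0 || all(purrr::map_int(token_docs, length) == 0)) {
    stop("empty corpus: TF-IDF needs at least one non-empty document",
         call. = FALSE)
  }
  n_docs <- length(token_docs)
  tf_tab <- table(unlist(token_docs))
  df_tab <- table(unlist(purrr::map(token_docs, unique)))
  out <- tibble::tibble(
    word = names(tf_tab),
    tf = as.numeric(tf_tab),
    df = as.numeric(df_tab[names(tf_tab)])
  )
  if (!is.null(candidates)) {
    keep <- if (is.function(candidates)) {
      purrr::map_lgl(out$word, candidates)
    } else {
      out$word %in% candidates
    }
    out <- out[keep, ]
  }
  out <- out[!out$word %in% exclude, ]
  out$score <- out$tf * log(n_docs / out$df)
  out <- out[order(-out$score, out$word), ]
  out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  out
}

#' Extract keywords with TextRank
#'
#' Builds an undirected word co-occurrence graph (an edge joins two words
#' that appear within `window_size` tokens of each other in some document)
#' and ranks words by the damped iterative score
#' `WS(v) = (1 - d) + d * sum over neighbours u of WS(u) / deg(u)`,
#' iterated until the largest score change is below `tol`. Words that
#' follow many different words sit on many edges and rank high; the top
#' terms are the seed-emotion-word candidates handed to manual polarity
#' labelling.
#'
#' @param token_docs List of character vectors, one per document.
#' @param window_size Co-occurrence window in tokens (>= 2, default 5).
#' @param damping Damping factor d (default 0.85).
#' @param tol Convergence threshold on the sup-norm of the score change.
#' @param max_iter Iteration cap; non-convergence yields a warning and the
#'   last iterate.
#' @param top_k Optional cap on the number of returned terms.
#' @return Tibble `word`, `score`, `rank` (ties lexicographic); empty when
#'   the corpus has no co-occurrence at all.
#' @export
textrank_keywords <- function(token_docs, window_size = 5L, damping = 0.85,
                              tol = 1e-6, max_iter = 200L, top_k = NULL) {
  stopifnot(window_size >= 2)
  token_docs <- purrr::map(token_docs, as.character)
  vocab <- sort(unique(unlist(token_docs)))
  nv <- length(vocab)
  if (nv == 0) {
    return(tibble::tibble(word = character(), score = double(),
                          rank = integer()))
  }
  # adjacency: accumulate edges from all in-window pairs across documents
  ii <- integer(0); jj <- integer(0)
  for (toks in token_docs) {
    n <- length(toks)
    if (n < 2) next
    idx <- match(toks, vocab)
    for (off in 1:(min(window_size, n) - 1L)) {
      a <- idx[seq_len(n - off)]
      b <- idx[seq_len(n - off) + off]
      keep <- a != b
      ii <- c(ii, a[keep]); jj <- c(jj, b[keep])
    }
  }
  adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(nv, nv), use.last.ij = TRUE)
  adj@x[] <- 1  # unweighted: edge present or not
  deg <- Matrix::rowSums(adj)
  ws <- rep(1, nv)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ws_new <- (1 - damping) + damping * as.numeric(adj %*% (ws * inv_deg))
    if (max(abs(ws_new - ws)) < tol) {
      ws <- ws_new
      converged <- TRUE
      break
    }
    ws <- ws_new
  }
  if (!converged) {
    warning("TextRank did not converge within ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  out <- tibble::tibble(word = vocab, score = ws)
  out <- out[order(-out$score, out$word), ]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  out
}
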