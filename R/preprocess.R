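#' Clean a comment stream
#'
#' Removes invalid records (empty text, missing timestamp, and texts
#' matching configurable irrelevance patterns such as URL-only comments or
#' ad keywords), collapses duplicates to their first occurrence, and sorts
#' the survivors chronologically (ties broken by id). Nothing is removed
#' silently: every removal is counted in the attached cleaning report.
#'
#' @param comments A comment tibble.
#' @param dedupe_key `"user_text"` (default: same user posting the same
#'   whitespace-normalised text) or `"text"` (global text deduplication).
#' @param invalid_patterns Named character vector of regular expressions; a
#'   comment whose text matches any of them is removed as irrelevant. The
#'   default flags URL-only comments.
#' @return The cleaned comment tibble, sorted by `(time, id)`, with
#'   attribute `report`: a one-row tibble with `n_input`,
#'   `n_duplicates_removed`, `n_invalid_removed`, `n_output` and per-rule
#'   counts (`n_empty_text`, `n_missing_time`, `n_pattern`). Always
#'   `n_output = n_input - n_duplicates_removed - n_invalid_removed`.
#' @examples
#' x <- tibble::tibble(
#'   id = c("a", "b", "c"), time = as.POSIXct("2020-01-01") + 1:3,
#'   user = c("u1", "u1", "u2"), region = "", gender = "unknown",
#'   text = c("same thing", "same  thing", "")
#' )
#' cleaned <- clean_comments(x)
#' attr(cleaned, "report")
#' @export
clean_comments <- function(comments,
                           dedupe_key = c("user_text", "text"),
                           invalid_patterns = c(
                             url_only = "^\\s*(https?://\\S+)(\\s+https?://\\S+)*\\s*$"
                           )) {
  dedupe_key <- match.arg(dedupe_key)
  n_input <- nrow(comments)

  empty_text <- is.na(comments$text) | !nzchar(trimws(comments$text))
  missing_time <- is.na(comments$time)
  pattern <- rep(FALSE, n_input)
  for (p in invalid_patterns) {
    pattern <- pattern | (!empty_text & stringr::str_detect(comments$text, p))
  }
  invalid <- empty_text | missing_time | pattern

  kept <- comments[!invalid, ]
  norm_text <- stringr::str_squish(kept$text)
  key <- if (dedupe_key == "user_text") paste(kept$user, norm_text, sep = "\r") else norm_text
  # first occurrence in time order, so the retained copy is the earliest post
  ord <- order(kept$time, kept$id)
  kept <- kept[ord, ]
  key <- key[ord]
  dup <- duplicated(key)
  out <- kept[!dup, ]

  report <- tibble::tibble(
    n_input = n_input,
    n_duplicates_removed = sum(dup),
    n_invalid_removed = sum(invalid),
    n_output = nrow(out),
    n_empty_text = sum(empty_text),
    n_missing_time = sum(missing_time & !empty_text),
    n_pattern = sum(pattern & !empty_text & !missing_time)
  )
  attr(out, "report") <- report
  out
}

#' Normalise platform emoji in comment text
#'
#' Platform emoji arrive as bracket-marked glosses such as `[smile]`. Each
#' gloss known to the emoji lexicon is kept as a single bracket-marked
#' token that survives tokenization atomically; brackets whose gloss the
#' lexicon does not know (emoji with no clear emotional tendency) are
#' deleted.
#'
#' @param text Character vector of raw comment texts.
#' @param emoji_glosses Character vector of known emoji glosses (the `word`
#'   column of emoji-role lexicon entries), or a lexicon tibble from which
#'   they are taken.
#' @return Character vector of normalised texts (whitespace squished).
#' @export
normalize_emojis <- function(text, emoji_glosses) {
  if (is.data.frame(emoji_glosses)) {
    emoji_glosses <- emoji_glosses$word[emoji_glosses$role == "emoji"]
  }
  out <- stringr::str_replace_all(text, "\\[([^\\[\\]]*)\\]", function(m) {
    gloss <- substr(m, 2, nchar(m) - 1)
    if (gloss %in% emoji_glosses) paste0(" ", m, " ") else " "
  })
  stringr::str_squish(out)
}

# greedy longest-prefix segmentation of one unspaced span against a
# dictionary; out-of-dictionary characters become single-character tokens
segment_greedy <- function(span, dict_words, max_len) {
  if (!nzchar(span)) return(character())
  chars <- strsplit(span, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- 1L
    upper <- min(max_len, n - i + 1L)
    if (upper >= 2L) {
      for (len in upper:2L) {
        cand <- paste(chars[i:(i + len - 1L)], collapse = "")
        if (cand %in% dict_words) {
          matched <- len
          break
        }
      }
    }
    out <- c(out, paste(chars[i:(i + matched - 1L)], collapse = ""))
    i <- i + matched
  }
  out
}

tokenize_one <- function(text, dict_words, max_len, segmenter = NULL) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(position = integer(), surface = character(),
                          kind = character()))
  }
  # peel off bracket-marked emoji glosses first: they are atomic tokens
  pieces <- stringr::str_split(text, "(?=\\[)|(?<=\\])")[[1]]
  surfaces <- character(0)
  kinds <- character(0)
  for (piece in pieces) {
    if (!nzchar(piece)) next
    if (stringr::str_detect(piece, "^\\[[^\\[\\]]+\\]$")) {
      surfaces <- c(surfaces, substr(piece, 2, nchar(piece) - 1))
      kinds <- c(kinds, "emoji_gloss")
      next
    }
    for (span in stringr::str_split_1(stringr::str_squish(piece), " ")) {
      if (!nzchar(span)) next
      toks <- if (span %in% dict_words) {
        span
      } else if (!is.null(segmenter)) {
        segmenter(span)
      } else {
        segment_greedy(span, dict_words, max_len)
      }
      surfaces <- c(surfaces, toks)
      kinds <- c(kinds, rep("word", length(toks)))
    }
  }
  tibble::tibble(position = seq_along(surfaces), surface = surfaces, kind = kinds)
}

#' Tokenize comment texts against a user dictionary
#'
#' Dictionary-aware segmentation: any multi-character word of the combined
#' user dictionary occurring in the text is emitted as a single, atomic
#' token, and bracket-marked emoji glosses become single tokens of kind
#' `emoji_gloss`. Spans not covered by the dictionary fall back to the
#' pluggable segmenter; the deterministic built-in default is greedy
#' longest match against the dictionary, character by character otherwise.
#' Whitespace always separates tokens.
#'
#' @param comments A comment tibble (columns `id`, `text`), or a character
#'   vector of texts (then ids `1..n` are assigned).
#' @param dict_words Character vector: the combined user dictionary
#'   (lexicon surfaces plus event/official/user-defined vocabulary).
#' @param segmenter Optional function `character(1) -> character()` used
#'   for out-of-dictionary spans instead of the built-in greedy matcher.
#' @return A token tibble with columns `id`, `position` (0-based),
#'   `surface`, `kind` (`"word"` or `"emoji_gloss"`).
#' @examples
#' tokenize_comments("abcc", dict_words = c("ab", "abc", "c"))
#' @export
tokenize_comments <- function(comments, dict_words, segmenter = NULL) {
  if (is.character(comments)) {
    comments <- tibble::tibble(id = as.character(seq_along(comments)),
                               text = comments)
  }
  dict_words <- unique(dict_words[nzchar(dict_words)])
  max_len <- if (length(dict_words)) max(nchar(dict_words)) else 1L
  empty <- tibble::tibble(id = character(), position = integer(),
                          surface = character(), kind = character())
  if (nrow(comments) == 0) return(empty)
  toks <- purrr::map(comments$text, tokenize_one,
                     dict_words = dict_words, max_len = max_len,
                     segmenter = segmenter)
  n_tok <- purrr::map_int(toks, nrow)
  out <- dplyr::bind_rows(toks)
  if (nrow(out) == 0) return(empty)
  out$id <- rep(comments$id, n_tok)
  out$position <- out$position - 1L
  out[, c("id", "position", "surface", "kind")]
}

#' Read a stop-word list
#'
#' UTF-8 text, one surface form per line; blank lines ignored.
#'
#' @param path Path to the list.
#' @return Character vector of stop words.
#' @export
read_stopwords <- function(path) {
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  unique(words[nzchar(words)])
}

#' Remove stop words from a token table
#'
#' Order-preserving filter. Emoji-gloss tokens are exempt (they carry
#' sentiment weight and must reach the scorer), as are any explicitly
#' protected surfaces — the pipeline protects all lexicon words so that
#' stop lists containing negators cannot disturb scoring.
#'
#' @param tokens A token tibble from [tokenize_comments()].
#' @param stopwords Character vector of stop surfaces.
#' @param protect Character vector of surfaces never removed.
#' @return The filtered token tibble (original `position` values kept).
#' @export
remove_stopwords <- function(tokens, stopwords, protect = character()) {
  drop <- tokens$surface %in% stopwords &
    tokens$kind != "emoji_gloss" &
    !tokens$surface %in% protect
  tokens[!drop, ]
}
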