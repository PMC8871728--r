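#' Degree-adverb levels and their fixed weights
#'
#' The six intensity levels used for degree adverbs, from strongest to
#' weakest, with their multiplicative weights: extremely_most (2), super
#' (1.5), very (1.25), relatively (1.2), slightly (0.8), under (0.5).
#' A degree adverb scales the polarity weight of the sentiment word it
#' modifies by its level weight.
#'
#' @format A named numeric vector; names are level identifiers.
#' @export
degree_levels <- c(
  extremely_most = 2,
  super          = 1.5,
  very           = 1.25,
  relatively     = 1.2,
  slightly       = 0.8,
  under          = 0.5
)

lexicon_roles <- c("polarity", "negation", "degree_adverb", "emoji")

# merge precedence: lower rank wins when a surface occurs under two roles
role_rank <- c(negation = 1L, degree_adverb = 2L, emoji = 3L, polarity = 4L)

#' Construct a sentiment-lexicon tibble
#'
#' A sentiment lexicon is a tibble with one row per entry and columns
#' `word`, `role` (one of `"polarity"`, `"negation"`, `"degree_adverb"`,
#' `"emoji"`), `level` (a degree level for degree adverbs, otherwise `NA`),
#' `weight` and `provenance`. It is the single source of word semantics for
#' scoring: polarity and emoji entries carry the base weight B (by
#' convention +1/-1), negation entries carry the flip weight C = -1, and
#' degree-adverb entries carry the intensity weight A fixed by their level.
#'
#' @param word Character vector of surface forms.
#' @param role Character vector (recycled) of entry roles.
#' @param weight Numeric vector of weights. For degree adverbs the weight
#'   may be omitted (`NA`) and is then filled from [degree_levels].
#' @param level Degree level, required iff `role == "degree_adverb"`.
#' @param provenance Free-text origin tag (`"base"`, `"user_defined"`,
#'   `"tfidf_adverb"`, `"sopmi_expanded"`, `"emoji"`, ...).
#' @param strict If `TRUE`, polarity/emoji weights are restricted to +1/-1;
#'   by default any real weight is admitted so graded user lexicons load.
#' @return A validated lexicon tibble of class `sentilex`.
#' @examples
#' lexicon(c("good", "bad", "not", "very"),
#'         role = c("polarity", "polarity", "negation", "degree_adverb"),
#'         weight = c(1, -1, -1, NA),
#'         level = c(NA, NA, NA, "very"))
#' @export
lexicon <- function(word, role = "polarity", weight = NULL, level = NA_character_,
                    provenance = "user_defined", strict = FALSE) {
  n <- length(word)
  entries <- tibble::tibble(
    word = as.character(word),
    role = rep_len(as.character(role), n),
    level = rep_len(as.character(level), n),
    weight = if (is.null(weight)) NA_real_ else rep_len(as.numeric(weight), n),
    provenance = rep_len(as.character(provenance), n)
  )
  fill <- entries$role == "degree_adverb" & is.na(entries$weight) &
    entries$level %in% names(degree_levels)
  entries$weight[fill] <- degree_levels[entries$level[fill]]
  validate_lexicon(entries, strict = strict)
}

#' Validate sentiment-lexicon entries
#'
#' Enforces the structural invariants of a lexicon: known roles; negation
#' weight exactly -1; degree-adverb entries carrying a recognised level with
#' the weight fixed for that level; levels absent outside degree adverbs;
#' no duplicated word within the table. With `strict = TRUE`, polarity and
#' emoji weights must be exactly +1 or -1.
#'
#' @param entries A data frame with columns `word`, `role`, `level`,
#'   `weight` (and optionally `provenance`).
#' @inheritParams lexicon
#' @return The entries as a `sentilex` tibble, invisibly checked.
#' @export
validate_lexicon <- function(entries, strict = FALSE) {
  entries <- tibble::as_tibble(entries)
  required <- c("word", "role", "weight")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop("lexicon is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"level" %in% names(entries)) entries$level <- NA_character_
  if (!"provenance" %in% names(entries)) entries$provenance <- "user_defined"
  entries$level[!is.na(entries$level) & entries$level == ""] <- NA_character_

  bad_row <- function(idx, why) {
    stop(sprintf("invalid lexicon entr%s (%s): row %s [word: %s]",
                 if (length(idx) > 1) "ies" else "y", why,
                 paste(idx, collapse = ", "),
                 paste(entries$word[idx], collapse = ", ")),
         call. = FALSE)
  }

  i <- which(is.na(entries$word) | entries$word == "")
  if (length(i)) bad_row(i, "empty word")
  i <- which(!entries$role %in% lexicon_roles)
  if (length(i)) bad_row(i, "unknown role")
  i <- which(entries$role == "negation" &
               (is.na(entries$weight) | entries$weight != -1))
  if (length(i)) bad_row(i, "negation weight must be -1")
  is_deg <- entries$role == "degree_adverb"
  i <- which(is_deg & !entries$level %in% names(degree_levels))
  if (length(i)) bad_row(i, "degree adverb without a recognised level")
  i <- which(is_deg & entries$level %in% names(degree_levels) &
               (is.na(entries$weight) |
                  entries$weight != degree_levels[entries$level]))
  if (length(i)) bad_row(i, "degree-adverb weight does not match its level")
  i <- which(!is_deg & !is.na(entries$level))
  if (length(i)) bad_row(i, "level present outside degree_adverb role")
  i <- which(entries$role %in% c("polarity", "emoji") & is.na(entries$weight))
  if (length(i)) bad_row(i, "missing polarity weight")
  if (strict) {
    i <- which(entries$role %in% c("polarity", "emoji") &
                 !entries$weight %in% c(1, -1))
    if (length(i)) bad_row(i, "strict mode requires polarity/emoji weight +1 or -1")
  }
  dup <- entries$word[duplicated(entries$word)]
  if (length(dup)) {
    stop("duplicate word(s) within one lexicon fragment: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  class(entries) <- c("sentilex", class(tibble::tibble()))
  entries
}

#' Read a lexicon fragment from a TSV file
#'
#' The on-disk dialect is UTF-8 tab-separated text with a header line and
#' columns `word`, `role`, `level`, `weight`; `#`-prefixed lines and blank
#' lines are ignored. Entries are validated at load time, so a file whose
#' degree-adverb weight disagrees with its level, or that repeats a word,
#' is rejected with an error naming the offending row.
#'
#' @param path Path to the TSV file.
#' @param role_default Role to assign to rows with an empty `role` field.
#' @param provenance Provenance tag recorded on all loaded entries.
#' @inheritParams lexicon
#' @return A `sentilex` tibble.
#' @export
read_lexicon <- function(path, role_default = NULL, provenance = "base",
                         strict = FALSE) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path, comment = "#", na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      word = readr::col_character(), role = readr::col_character(),
      level = readr::col_character(), weight = readr::col_double()
    )
  )
  if (nrow(raw) == 0) {
    return(validate_lexicon(tibble::tibble(
      word = character(), role = character(), level = character(),
      weight = double(), provenance = character()
    ), strict = strict))
  }
  if (!is.null(role_default)) raw$role[is.na(raw$role)] <- role_default
  raw$provenance <- provenance
  validate_lexicon(raw, strict = strict)
}

#' Write a lexicon to the TSV dialect read by [read_lexicon()]
#'
#' @param lex A lexicon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  out <- tibble::as_tibble(lex)[, c("word", "role", "level", "weight")]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Merge lexicon fragments into one lexicon
#'
#' Combines fragments (in the given order) into a single lexicon in which
#' each word carries exactly one role. Conflicts are resolved by role
#' precedence negation > degree_adverb > emoji > polarity — a word that is
#' both a negator somewhere and a polarity word elsewhere scores as a
#' negator, which prevents scope errors — and, within equal role, by
#' last-fragment-wins override. All resolved conflicts are returned in the
#' `conflicts` attribute so the merge can be audited.
#'
#' @param ... Lexicon fragments (tibbles), earliest first, or a single list
#'   of fragments.
#' @return A `sentilex` tibble with attribute `conflicts`: a tibble of
#'   words that occurred in more than one fragment, with the kept and
#'   dropped roles/weights.
#' @export
merge_lexicons <- function(...) {
  frags <- list(...)
  if (length(frags) == 1 && is.list(frags[[1]]) && !is.data.frame(frags[[1]])) {
    frags <- frags[[1]]
  }
  frags <- purrr::map(frags, validate_lexicon)
  all <- dplyr::bind_rows(frags, .id = ".fragment")
  if (nrow(all) == 0) {
    out <- validate_lexicon(all[, c("word", "role", "level", "weight", "provenance")])
    attr(out, "conflicts") <- all[0, ]
    return(out)
  }
  all$.fragment <- as.integer(all$.fragment)
  all$.rank <- role_rank[all$role]
  all$.row <- seq_len(nrow(all))

  kept <- all |>
    dplyr::group_by(.data$word) |>
    dplyr::arrange(.data$.rank, dplyr::desc(.data$.fragment), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  conflicts <- all |>
    dplyr::filter(!.data$.row %in% kept$.row) |>
    dplyr::left_join(
      kept |> dplyr::select("word", kept_role = "role", kept_weight = "weight"),
      by = "word"
    ) |>
    dplyr::select("word", dropped_role = "role", dropped_weight = "weight",
                  fragment = ".fragment", "kept_role", "kept_weight")

  out <- kept |>
    dplyr::select("word", "role", "level", "weight", "provenance") |>
    dplyr::arrange(.data$word)
  out <- validate_lexicon(out)
  attr(out, "conflicts") <- conflicts
  out
}

# fast lookup structure used by the scorer: named vectors over the merged lexicon
lexicon_lookup <- function(lex) {
  list(
    role = stats::setNames(lex$role, lex$word),
    weight = stats::setNames(lex$weight, lex$word)
  )
}

#' @method print sentilex
#' @export
print.sentilex <- function(x, ...) {
  counts <- table(factor(x$role, levels = lexicon_roles))
  cat(sprintf(
    "<sentiment lexicon: %d entries (%d polarity, %d negation, %d degree adverb, %d emoji)>\n",
    nrow(x), counts[["polarity"]], counts[["negation"]],
    counts[["degree_adverb"]], counts[["emoji"]]
  ))
  NextMethod()
}
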