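comment_fields <- c("id", "time", "user", "region", "gender", "text")
genders <- c("female", "male", "unknown")
region_buckets <- c("eastern", "central", "western", "northeast",
                    "overseas", "unspecified")

empty_comments <- function() {
  tibble::tibble(
    id = character(), time = as.POSIXct(character(), tz = "UTC"),
    user = character(), region = character(), gender = character(),
    text = character()
  )
}

comment_problem <- function(line, field, message) {
  tibble::tibble(line = as.integer(line), field = field, message = message)
}

# validate a raw record tibble; returns list(comments, problems)
validate_comment_records <- function(raw, lines, tz) {
  problems <- comment_problem(integer(), character(), character())
  keep <- rep(TRUE, nrow(raw))

  if (!"gender" %in% names(raw)) raw$gender <- NA_character_
  if (!"region" %in% names(raw)) raw$region <- NA_character_
  raw$region[is.na(raw$region)] <- ""
  raw$gender[is.na(raw$gender) | !raw$gender %in% genders] <- "unknown"

  bad <- is.na(raw$id) | raw$id == ""
  if (any(bad)) {
    problems <- dplyr::bind_rows(problems,
      comment_problem(lines[bad], "id", "missing id"))
    keep <- keep & !bad
  }
  time <- as.POSIXct(raw$time, tz = tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%d"),
                     optional = TRUE)
  bad <- keep & is.na(time)
  if (any(bad)) {
    problems <- dplyr::bind_rows(problems,
      comment_problem(lines[bad], "time", "unparseable timestamp"))
    keep <- keep & !bad
  }
  bad <- keep & is.na(raw$text)
  if (any(bad)) {
    problems <- dplyr::bind_rows(problems,
      comment_problem(lines[bad], "text", "missing text field"))
    keep <- keep & !bad
  }
  dup <- keep & duplicated(raw$id)
  if (any(dup)) {
    problems <- dplyr::bind_rows(problems,
      comment_problem(lines[dup], "id", "duplicate comment id"))
    keep <- keep & !dup
  }

  comments <- tibble::tibble(
    id = raw$id, time = time, user = as.character(raw$user),
    region = raw$region, gender = raw$gender, text = raw$text
  )[keep, ]
  list(comments = comments, problems = problems)
}

#' Read a comment stream from CSV or JSON-lines
#'
#' Comment records carry the fields `id`, `time` (ISO-8601), `user`,
#' `region` (free-text province/area, may be empty), optional `gender`
#' (`female`/`male`/`unknown`) and `text`. Malformed records — an
#' unparseable timestamp, a missing text field, a duplicated id — are never
#' silently dropped: they are excluded from the result and reported, with
#' their line numbers, in the `problems` attribute.
#'
#' @param path Path to the file.
#' @param format `"csv"` (RFC-4180 quoting, header row) or `"jsonl"` (one
#'   JSON object per line).
#' @param tz Timezone in which naive timestamps are interpreted
#'   (the platform's convention; defaults to `"Asia/Shanghai"`).
#' @return A tibble of comments with attribute `problems`, a tibble with
#'   columns `line`, `field`, `message` (empty when all records parsed).
#' @export
read_comments <- function(path, format = c("csv", "jsonl"),
                          tz = "Asia/Shanghai") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("comment file not found: ", path, call. = FALSE)

  if (format == "csv") {
    # empty string is a value (empty text is a cleaning concern, not a parse
    # failure); only a truly absent field is a record-level problem
    raw <- readr::read_csv(
      path, show_col_types = FALSE, progress = FALSE, na = character(),
      col_types = readr::cols(.default = readr::col_character())
    )
    missing <- setdiff(c("id", "time", "user", "text"), names(raw))
    if (length(missing) > 0) {
      stop("comment CSV is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  } else {
    txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
    nonblank <- which(nzchar(trimws(txt)))
    recs <- purrr::map(nonblank, function(i) {
      rec <- tryCatch(jsonlite::fromJSON(txt[i]), error = function(e) NULL)
      if (is.null(rec)) return(NULL)
      tibble::tibble(
        id = as.character(rec$id %||% NA), time = as.character(rec$time %||% NA),
        user = as.character(rec$user %||% NA),
        region = as.character(rec$region %||% ""),
        gender = as.character(rec$gender %||% "unknown"),
        text = if (is.null(rec$text)) NA_character_ else as.character(rec$text)
      )
    })
    bad_json <- nonblank[purrr::map_lgl(recs, is.null)]
    raw <- dplyr::bind_rows(recs)
    lines <- nonblank[!nonblank %in% bad_json]
    if (nrow(raw) == 0) {
      out <- empty_comments()
      attr(out, "problems") <- comment_problem(bad_json, "record",
                                               rep("invalid JSON", length(bad_json)))
      return(out)
    }
    res <- validate_comment_records(raw, lines, tz)
    res$problems <- dplyr::bind_rows(
      comment_problem(bad_json, "record", rep("invalid JSON", length(bad_json))),
      res$problems
    )
    out <- res$comments
    attr(out, "problems") <- res$problems
    return(out)
  }

  res <- validate_comment_records(raw, lines, tz)
  out <- res$comments
  attr(out, "problems") <- res$problems
  out
}

#' Write a comment stream as CSV
#'
#' Writes the dialect read back by [read_comments()]; writing then reading
#' is the identity on all record fields.
#'
#' @param comments A comment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comments <- function(comments, path) {
  out <- comments
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out[, comment_fields], path, progress = FALSE)
  invisible(path)
}

#' Write scored comments as CSV
#'
#' One row per comment with its id, timestamp, region, total sentiment
#' value E and sign label; an empty input produces a header-only file.
#'
#' @param scored A scored-comment tibble (from [score_comments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  cols <- intersect(c("id", "time", "region", "E", "label"), names(scored))
  out <- scored[, cols]
  if ("time" %in% cols) out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read scored comments written by [write_scored()]
#'
#' @param path Path to the CSV file.
#' @param tz Timezone for the timestamps.
#' @return A tibble with columns `id`, `time`, `region`, `E`, `label`.
#' @export
read_scored <- function(path, tz = "Asia/Shanghai") {
  out <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      id = readr::col_character(), time = readr::col_character(),
      region = readr::col_character(), E = readr::col_double(),
      label = readr::col_character()
    )
  )
  out$time <- as.POSIXct(out$time, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  out$region[is.na(out$region)] <- ""
  out
}

#' Read a province-to-macro-region map
#'
#' TSV with header columns `province` and `region`; region values must be
#' one of eastern, central, western, northeast, overseas, unspecified.
#' The mapping is made total at use time: region strings absent from the
#' map (including the empty string) fall back to `"unspecified"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `province` and `region`.
#' @export
read_region_map <- function(path) {
  map <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("province", "region") %in% names(map))) {
    stop("region map needs columns 'province' and 'region'", call. = FALSE)
  }
  bad <- !map$region %in% region_buckets
  if (any(bad)) {
    stop("unknown region bucket(s): ",
         paste(unique(map$region[bad]), collapse = ", "), call. = FALSE)
  }
  dup <- map$province[duplicated(map$province)]
  if (length(dup)) {
    stop("duplicate province(s) in region map: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  map
}

#' Map free-text region strings to macro-region buckets
#'
#' @param region Character vector of region strings as found on comments.
#' @param region_map Tibble from [read_region_map()].
#' @return Character vector of buckets; unknown or empty strings map to
#'   `"unspecified"`.
#' @export
map_region <- function(region, region_map) {
  lut <- stats::setNames(region_map$region, region_map$province)
  out <- unname(lut[region])
  out[is.na(out)] <- "unspecified"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
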