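#' Daily comment volume
#'
#' @param comments A comment (or scored-comment) tibble with a `time`
#'   column.
#' @return Tibble `date`, `n`, one row per calendar day present (days with
#'   no comments between the extremes are filled with 0).
#' @export
daily_volume <- function(comments) {
  date <- as.Date(comments$time, tz = attr(comments$time, "tzone") %||% "UTC")
  counts <- table(date)
  days <- seq(min(date), max(date), by = "day")
  tibble::tibble(
    date = days,
    n = as.integer(ifelse(is.na(counts[as.character(days)]), 0,
                          counts[as.character(days)]))
  )
}

#' Segment a comment timeline into opinion stages
#'
#' Splits the corpus date range into contiguous stages. With explicit
#' `breakpoints` (the faithful mode: important time nodes chosen by the
#' analyst), each breakpoint date ends a stage; three stages are labelled
#' outbreak / fluctuation / recession, any other number stage-1..T. With
#' `auto = TRUE` a reproducible heuristic is applied to the daily volume
#' curve: the outbreak stage ends at the last day whose volume is at least
#' 50% of the peak, and the recession stage begins at the first day of the
#' terminal run of days at or below 10% of the peak; the fluctuation stage
#' lies between.
#'
#' @param volume Tibble `date`, `n` from [daily_volume()].
#' @param breakpoints Optional strictly increasing `Date` vector inside the
#'   corpus range; each one is the last day of a stage.
#' @param auto Use the volume heuristic instead of breakpoints.
#' @return A `stage_plan` tibble: `stage`, `label`, `start`, `end` —
#'   contiguous, non-overlapping, covering the corpus date range.
#' @export
segment_stages <- function(volume, breakpoints = NULL, auto = FALSE) {
  stopifnot(nrow(volume) > 0)
  if (!is.null(breakpoints) && auto) {
    stop("give either explicit breakpoints or auto = TRUE, not both",
         call. = FALSE)
  }
  range_start <- min(volume$date)
  range_end <- max(volume$date)

  if (auto) {
    peak <- max(volume$n)
    o_end <- max(volume$date[volume$n >= 0.5 * peak])
    low <- volume$n <= 0.1 * peak
    # terminal run of low-volume days
    run <- rev(cumprod(rev(low))) == 1
    r_start <- if (any(run)) min(volume$date[run]) else NA
    breakpoints <- o_end
    if (!is.na(r_start) && r_start > o_end + 1) {
      breakpoints <- c(o_end, r_start - 1)
    }
    breakpoints <- breakpoints[breakpoints < range_end]
  }
  breakpoints <- as.Date(breakpoints)
  if (length(breakpoints) > 0) {
    if (any(breakpoints < range_start | breakpoints >= range_end)) {
      stop("breakpoints must fall inside the corpus date range ",
           range_start, "..", range_end, call. = FALSE)
    }
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      stop("breakpoints must be strictly increasing", call. = FALSE)
    }
  }
  starts <- c(range_start, breakpoints + 1)
  ends <- c(breakpoints, range_end)
  t_stages <- length(starts)
  labels <- if (t_stages == 3) {
    c("outbreak", "fluctuation", "recession")
  } else {
    paste0("stage-", seq_len(t_stages))
  }
  out <- tibble::tibble(stage = seq_len(t_stages), label = labels,
                        start = starts, end = ends)
  class(out) <- c("stage_plan", class(tibble::tibble()))
  out
}

stage_of <- function(date, plan) {
  idx <- rep(NA_integer_, length(date))
  for (s in seq_len(nrow(plan))) {
    idx[date >= plan$start[s] & date <= plan$end[s]] <- plan$stage[s]
  }
  idx
}

#' Per-stage emotion statistics
#'
#' For each stage of the plan: comment count, counts and proportions of
#' negative/neutral/positive labels, the extreme sentiment values, the sum
#' of positive values and the absolute sum of negative values (their
#' comparison shows which pole dominates the stage). An empty stage
#' reports `n = 0` with `NA` proportions and extremes.
#'
#' @param scored Scored-comment tibble (needs `id`, `time`, `E`, `label`).
#' @param plan A [segment_stages()] plan covering every comment date.
#' @return A `stage_summary` tibble, one row per stage, with the daily
#'   volume series attached as attribute `daily_volume` (with stage ids).
#' @export
stage_summary <- function(scored, plan) {
  date <- as.Date(scored$time, tz = attr(scored$time, "tzone") %||% "UTC")
  idx <- stage_of(date, plan)
  if (anyNA(idx)) {
    stop("comment(s) outside the stage plan range: ",
         paste(utils::head(scored$id[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  }
  per_stage <- purrr::map(seq_len(nrow(plan)), function(s) {
    e <- scored$E[idx == s]
    lab <- scored$label[idx == s]
    n <- length(e)
    tibble::tibble(
      stage = plan$stage[s], label = plan$label[s],
      start = plan$start[s], end = plan$end[s],
      n_comments = n,
      n_negative = sum(lab == "negative"),
      n_neutral = sum(lab == "neutral"),
      n_positive = sum(lab == "positive"),
      prop_negative = if (n > 0) sum(lab == "negative") / n else NA_real_,
      prop_neutral = if (n > 0) sum(lab == "neutral") / n else NA_real_,
      prop_positive = if (n > 0) sum(lab == "positive") / n else NA_real_,
      min_E = if (n > 0) min(e) else NA_real_,
      max_E = if (n > 0) max(e) else NA_real_,
      sum_positive_E = sum(e[e > 0]),
      sum_negative_E_abs = sum(abs(e[e < 0]))
    )
  })
  out <- dplyr::bind_rows(per_stage)
  vol <- daily_volume(scored)
  vol$stage <- stage_of(vol$date, plan)
  attr(out, "daily_volume") <- vol
  class(out) <- c("stage_summary", class(tibble::tibble()))
  out
}

#' Per-stage keyword frequency ranking
#'
#' Counts token frequencies within each stage and returns the `top_k`
#' tokens per stage, ranked by count with lexicographic tie-break — the
#' ranked-list content behind per-stage subject-word clouds.
#'
#' @param tokens Token tibble (after stop-word removal).
#' @param comments Comment tibble supplying `id` -> `time`.
#' @param plan A [segment_stages()] plan.
#' @param top_k Terms kept per stage (default 20).
#' @return Tibble `stage`, `label`, `word`, `n`, `rank`.
#' @export
keyword_frequency_by_stage <- function(tokens, comments, plan, top_k = 20) {
  date <- as.Date(comments$time, tz = attr(comments$time, "tzone") %||% "UTC")
  idx <- stage_of(date, plan)
  tok_stage <- idx[match(tokens$id, comments$id)]
  purrr::map_dfr(seq_len(nrow(plan)), function(s) {
    surf <- tokens$surface[!is.na(tok_stage) & tok_stage == s]
    if (length(surf) == 0) {
      return(tibble::tibble(stage = integer(), label = character(),
                            word = character(), n = integer(),
                            rank = integer()))
    }
    counts <- table(surf)
    out <- tibble::tibble(
      stage = plan$stage[s], label = plan$label[s],
      word = names(counts), n = as.integer(counts)
    )
    out <- out[order(-out$n, out$word), ]
    out <- utils::head(out, top_k)
    out$rank <- seq_len(nrow(out))
    out
  })
}

#' Aggregate comments over macro-regions
#'
#' Maps each comment's free-text region string through the region map
#' (exact match, anything else to `unspecified`) and reports counts and two
#' share vectors: over all users, and over region-known domestic users
#' (the four economic macro-regions only) — the two denominators used when
#' reporting where an event's audience sits.
#'
#' @param comments Comment tibble with a `region` column.
#' @param region_map Tibble from [read_region_map()].
#' @return A `region_summary` tibble `region`, `n`, `share_all`,
#'   `share_domestic` (NA outside the four domestic regions), ordered by
#'   descending share within domestic regions first.
#' @export
region_aggregate <- function(comments, region_map) {
  bucket <- map_region(comments$region, region_map)
  counts <- table(factor(bucket, levels = region_buckets))
  out <- tibble::tibble(
    region = region_buckets,
    n = as.integer(counts)
  )
  domestic <- c("eastern", "central", "western", "northeast")
  n_total <- sum(out$n)
  n_domestic <- sum(out$n[out$region %in% domestic])
  out$share_all <- if (n_total > 0) out$n / n_total else NA_real_
  out$share_domestic <- ifelse(
    out$region %in% domestic,
    if (n_domestic > 0) out$n / n_domestic else NA_real_,
    NA_real_
  )
  # presentation order: domestic regions by descending share, then the rest
  out$.dom <- out$region %in% domestic
  out <- out[order(-out$.dom, -out$n), ]
  out$.dom <- NULL
  class(out) <- c("region_summary", class(tibble::tibble()))
  out
}
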