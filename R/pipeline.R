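#' Pipeline configuration
#'
#' Collects every input path and parameter of an end-to-end run. Paths are
#' checked at validation time; all randomness (only the optional lexicon
#' induction samples anything) flows from `seed`, so a fixed config plus
#' seed reruns byte-identically.
#'
#' @param comments Path to the comment file.
#' @param lexicons Character vector of lexicon TSV paths, merged in order
#'   (later fragments override earlier ones within equal role).
#' @param out_dir Output directory (created if absent).
#' @param format Comment file format, `"csv"` or `"jsonl"`.
#' @param stopwords Optional path to a stop-word list.
#' @param user_dict Optional path to extra user-dictionary surfaces (one
#'   per line) kept atomic by the tokenizer.
#' @param region_map Optional path to a province-region TSV; defaults to
#'   the bundled China macro-region map.
#' @param seeds Optional path to a seed-set TSV (`word`, `polarity`) for
#'   SO-PMI lexicon induction.
#' @param induce_lexicon If `TRUE` (and `seeds` given), expand the lexicon
#'   by SO-PMI before scoring; default `FALSE` — the usual run loads a
#'   prebuilt dictionary.
#' @param min_candidate_df Minimum document frequency for a word to become
#'   an SO-PMI candidate during induction.
#' @param smoothing Additive pair-count smoothing for induction PMI.
#' @param breakpoints Optional vector of stage-ending dates
#'   (`"YYYY-MM-DD"`); mutually exclusive with `auto_stages`.
#' @param auto_stages Use the volume heuristic of [segment_stages()].
#' @param top_k_keywords Keywords reported per stage.
#' @param dedupe_key,invalid_patterns Passed to [clean_comments()].
#' @param scoring A [scoring_config()].
#' @param tz Timezone for timestamps and day bucketing.
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(comments, lexicons, out_dir,
                            format = c("csv", "jsonl"),
                            stopwords = NULL, user_dict = NULL,
                            region_map = NULL, seeds = NULL,
                            induce_lexicon = FALSE, min_candidate_df = 5L,
                            smoothing = 1,
                            breakpoints = NULL, auto_stages = FALSE,
                            top_k_keywords = 20L,
                            dedupe_key = "user_text",
                            invalid_patterns = c(
                              url_only = "^\\s*(https?://\\S+)(\\s+https?://\\S+)*\\s*$"
                            ),
                            scoring = scoring_config(),
                            tz = "Asia/Shanghai", seed = 1L) {
  format <- match.arg(format)
  cfg <- list(
    comments = comments, lexicons = lexicons, out_dir = out_dir,
    format = format, stopwords = stopwords, user_dict = user_dict,
    region_map = region_map, seeds = seeds,
    induce_lexicon = isTRUE(induce_lexicon),
    min_candidate_df = as.integer(min_candidate_df), smoothing = smoothing,
    breakpoints = if (!is.null(breakpoints)) as.Date(breakpoints),
    auto_stages = isTRUE(auto_stages),
    top_k_keywords = as.integer(top_k_keywords),
    dedupe_key = dedupe_key, invalid_patterns = invalid_patterns,
    scoring = scoring, tz = tz, seed = as.integer(seed)
  )
  for (p in c(cfg$comments, cfg$lexicons, cfg$stopwords, cfg$user_dict,
              cfg$region_map, cfg$seeds)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  if (!is.null(cfg$breakpoints) && cfg$auto_stages) {
    stop("breakpoints and auto_stages are mutually exclusive", call. = FALSE)
  }
  if (cfg$induce_lexicon && is.null(cfg$seeds)) {
    stop("lexicon induction needs a seed-set file", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the arguments of [pipeline_config()] (nested
#' `scoring:` keys become the [scoring_config()]); relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x) {
      if (file.exists(x)) x else file.path(base, x)
    }, character(1), USE.NAMES = FALSE)
  }
  for (key in c("comments", "lexicons", "stopwords", "user_dict",
                "region_map", "seeds")) {
    raw[[key]] <- resolve(raw[[key]])
  }
  if (!is.null(raw$out_dir) && !grepl("^/", raw$out_dir)) {
    raw$out_dir <- file.path(base, raw$out_dir)
  }
  if (!is.null(raw$scoring)) raw$scoring <- do.call(scoring_config, raw$scoring)
  if (!is.null(raw$invalid_patterns)) {
    raw$invalid_patterns <- unlist(raw$invalid_patterns)
  }
  do.call(pipeline_config, raw)
}

read_seed_sets <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("word", "polarity") %in% names(tab)))
  list(positive = tab$word[tab$polarity == "positive"],
       negative = tab$word[tab$polarity == "negative"])
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full sentiment-analysis pipeline
#'
#' Executes clean -> normalise emoji -> tokenize -> stop-word filter ->
#' (optional SO-PMI lexicon induction) -> merge -> score -> stage
#' segmentation -> per-stage and regional summaries, and writes every
#' result plus a run manifest into the output directory. The manifest
#' records the configuration, the package version, the seed, per-stage
#' record counts and an MD5 content hash of every output file; rerunning
#' the same config and seed is byte-identical on all outputs.
#'
#' @param config A [pipeline_config()] or a path to a YAML config.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`scored`,
#'   `stage_summary`, `region_summary`, `keywords`, `cleaning_report`,
#'   `lexicon`, `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[sentidict] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("reading comments from %s", config$comments)
  comments <- read_comments(config$comments, config$format, tz = config$tz)
  problems <- attr(comments, "problems")
  if (nrow(problems) > 0) {
    say("%d malformed record(s) reported (see cleaning report)", nrow(problems))
  }

  fragments <- purrr::imap(config$lexicons, function(p, i) {
    read_lexicon(p, provenance = paste0("file:", basename(p)))
  })
  lex <- merge_lexicons(fragments)
  say("lexicon: %d entries after merge (%d conflicts resolved)",
      nrow(lex), nrow(attr(lex, "conflicts")))

  cleaned <- clean_comments(comments, dedupe_key = config$dedupe_key,
                            invalid_patterns = config$invalid_patterns)
  report <- attr(cleaned, "report")
  say("cleaning: %d -> %d (%d duplicates, %d invalid)",
      report$n_input, report$n_output, report$n_duplicates_removed,
      report$n_invalid_removed)

  cleaned$text <- normalize_emojis(cleaned$text, lex)
  user_dict <- lex$word[lex$role != "emoji"]
  if (!is.null(config$user_dict)) {
    user_dict <- union(user_dict, read_stopwords(config$user_dict))
  }
  tokens <- tokenize_comments(cleaned, user_dict)
  say("tokenized %d comments into %d tokens", nrow(cleaned), nrow(tokens))
  if (!is.null(config$stopwords)) {
    tokens <- remove_stopwords(tokens, read_stopwords(config$stopwords),
                               protect = lex$word)
  }

  if (config$induce_lexicon) {
    seeds <- read_seed_sets(config$seeds)
    docs <- split(tokens$surface, factor(tokens$id, levels = cleaned$id))
    model <- build_cooccurrence(docs)
    known <- c(lex$word, seeds$positive, seeds$negative)
    cand <- setdiff(names(model$doc_freq)[
      model$doc_freq >= config$min_candidate_df], known)
    if (length(cand) > 0) {
      set.seed(config$seed)
      classified <- classify_by_sopmi(cand, model, seeds,
                                      smoothing = config$smoothing)
      expanded <- sopmi_lexicon(classified)
      say("SO-PMI induction: %d candidates, %d entered the lexicon",
          length(cand), nrow(expanded))
      if (nrow(expanded) > 0) lex <- merge_lexicons(list(lex, expanded))
    }
  }

  scored <- score_comments(tokens, lex, config$scoring, comments = cleaned)
  say("scored %d comments (%d positive / %d neutral / %d negative)",
      nrow(scored), sum(scored$label == "positive"),
      sum(scored$label == "neutral"), sum(scored$label == "negative"))

  if (nrow(scored) > 0) {
    vol <- daily_volume(scored)
    plan <- segment_stages(vol, breakpoints = config$breakpoints,
                           auto = config$auto_stages)
    stages <- stage_summary(scored, plan)
    keywords <- keyword_frequency_by_stage(tokens, cleaned, plan,
                                           top_k = config$top_k_keywords)
  } else {
    vol <- tibble::tibble(date = as.Date(character()), n = integer())
    plan <- NULL
    stages <- tibble::tibble(stage = integer(), label = character(),
                             n_comments = integer())
    keywords <- tibble::tibble(stage = integer(), label = character(),
                               word = character(), n = integer(),
                               rank = integer())
  }
  region_map <- if (!is.null(config$region_map)) {
    read_region_map(config$region_map)
  } else {
    china_region_map()
  }
  regions <- region_aggregate(cleaned, region_map)

  # ---- write outputs ----
  out <- function(f) file.path(config$out_dir, f)
  write_scored(scored, out("scored.csv"))
  write_lexicon(lex, out("lexicon_merged.tsv"))
  write_report_json(c(as.list(report), list(
    n_malformed_records = nrow(problems))), out("cleaning_report.json"))
  write_report_json(
    purrr::map(purrr::transpose(as.list(tibble::as_tibble(stages))),
               function(row) {
                 row$start <- as.character(row$start)
                 row$end <- as.character(row$end)
                 row
               }),
    out("stage_summary.json"))
  write_report_json(purrr::transpose(as.list(tibble::as_tibble(regions))),
                    out("region_summary.json"))
  for (s in unique(keywords$stage)) {
    readr::write_tsv(keywords[keywords$stage == s, ],
                     out(sprintf("keywords_stage-%d.tsv", s)))
  }
  vol_out <- vol
  vol_out$date <- as.character(vol_out$date)
  readr::write_tsv(vol_out, out("daily_volume.tsv"))

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "sentidict",
    version = as.character(utils::packageVersion("sentidict")),
    seed = config$seed,
    config = config_fingerprint(config),
    n_input = report$n_input,
    n_scored = nrow(scored),
    stage_counts = stats::setNames(as.list(stages$n_comments), stages$label),
    outputs = purrr::map(files, function(f) {
      list(file = f, md5 = unname(tools::md5sum(out(f))))
    })
  )
  write_report_json(manifest, out("manifest.json"))
  say("wrote %d output files to %s", length(files) + 1, config$out_dir)

  invisible(list(
    scored = scored, stage_plan = plan, stage_summary = stages,
    region_summary = regions, keywords = keywords,
    cleaning_report = report, lexicon = lex, manifest = manifest,
    out_dir = config$out_dir
  ))
}

# canonical, path-independent fingerprint of the configuration
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$scoring <- unclass(cfg$scoring)
  for (key in c("comments", "lexicons", "stopwords", "user_dict",
                "region_map", "seeds", "out_dir")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- basename(cfg[[key]])
  }
  if (!is.null(cfg$breakpoints)) cfg$breakpoints <- as.character(cfg$breakpoints)
  cfg
}
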