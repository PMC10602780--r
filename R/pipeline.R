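#' @title End-to-end analysis pipeline
#'
#' @description
#' `run_pipeline()` chains parsing, information-structure metrics, pause
#' analysis, retracing mining and prominence acoustics into a report
#' bundle of TSV tables, a machine-readable JSON summary, and a log of
#' every parameter used. Stages whose inputs are absent (e.g. audio) are
#' skipped and logged; identical configurations yield identical bundles.
#'
#' @name pipeline
NULL

default_config <- function() {
  list(transcript = NULL, groups = NULL, wav = NULL, alignment = NULL,
       spans = NULL, out_dir = "prosopath_out",
       params = list(min_dur_ms = 150, rel_db = 25, hop_ms = 10,
                     ref_hz = 1, cutoff = "auto", mlu_policy = "semantic",
                     floor_hz = 50, ceil_hz = 300),
       seed = 1L)
}

#' Run the full analysis pipeline
#'
#' @param config a list, or a path to a YAML file, with elements
#'   `transcript` (path or character lines), `groups` (named vector or
#'   path to a two-column TSV `code group`), optional `wav`,
#'   `alignment`, `spans` (prominence span TSV with header), `out_dir`,
#'   `params` (overrides of `min_dur_ms`, `rel_db`, `hop_ms`, `ref_hz`,
#'   `cutoff`, `mlu_policy`, `floor_hz`, `ceil_hz`) and `seed`.
#' @param quiet suppress console logging.
#' @return invisibly, a list with every computed table plus the paths of
#'   the written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(config$params))
    cfg$params <- utils::modifyList(default_config()$params, config$params)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  log("parameters: %s",
      paste(names(cfg$params), unlist(cfg$params), sep = "=",
            collapse = " "))
  groups <- cfg$groups
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gdf <- utils::read.table(groups, header = FALSE,
                             col.names = c("code", "group"),
                             stringsAsFactors = FALSE)
    groups <- stats::setNames(gdf$group, gdf$code)
  }
  if (is.null(cfg$transcript))
    stop_prosopath("config lacks a transcript", "prosopath_config_error")
  is_path <- length(cfg$transcript) == 1L && file.exists(cfg$transcript)
  tr <- parse_transcript(cfg$transcript, groups = groups,
                         is_file = is_path)
  lint <- lint_transcript(if (is_path)
    readLines(cfg$transcript, warn = FALSE) else cfg$transcript)
  out <- list(transcript = tr, lint = lint)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    df2 <- df
    for (cl in names(df2)) if (is.list(df2[[cl]])) df2[[cl]] <- NULL
    utils::write.table(df2, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[name] <<- p
    log("wrote %s", p)
    df
  }
  # text-only stages
  out$ts_classes <- emit(ts_class_table(tr), "ts_classes")
  out$unit_presence <- emit(unit_presence_table(tr), "unit_presence")
  out$mlu <- emit(mlu(tr, policy = cfg$params$mlu_policy), "mlu")
  out$retracing_rates <- emit(episode_rates_by_ts_type(tr),
                              "retracing_rates")
  out$retracing_positions <- emit(position_distribution(tr),
                                  "retracing_positions")
  spk <- tracked_speakers(tr)
  out$retracted_tokens <- emit(data.frame(
    speaker = spk,
    pct = vapply(spk, function(s)
      round_half_up(retracted_token_rate(tr, s), 2), numeric(1))),
    "retracted_tokens")
  # audio stages
  if (!is.null(cfg$wav) && !is.null(cfg$alignment)) {
    audio <- if (inherits(cfg$wav, "audio_signal")) cfg$wav
             else read_wav(cfg$wav)
    align <- if (inherits(cfg$alignment, "alignment_tier")) cfg$alignment
             else read_alignment(cfg$alignment)
    tr_al <- attach_alignment(tr, align)
    sil <- detect_silences(audio, min_dur_ms = cfg$params$min_dur_ms,
                           threshold_db = cfg$params$rel_db,
                           hop_ms = cfg$params$hop_ms)
    out$silences <- emit(classify_pause_position(sil, tr_al), "silences")
    pp <- lapply(spk, function(s)
      pause_profile(tr_al, audio = NULL, speaker = s, silences = sil))
    names(pp) <- spk
    out$pause_profiles <- pp
    for (s in spk) emit(pp[[s]], paste0("pauses_", s))
  } else {
    log("audio or alignment missing: pause stage skipped")
  }
  if (!is.null(cfg$wav) && !is.null(cfg$spans)) {
    audio <- if (inherits(cfg$wav, "audio_signal")) cfg$wav
             else read_wav(cfg$wav)
    spans <- if (is.data.frame(cfg$spans)) cfg$spans
             else utils::read.table(cfg$spans, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    prof <- prominence_profiles(audio, spans,
                                ref_hz = cfg$params$ref_hz,
                                cutoff_policy = cfg$params$cutoff,
                                floor_hz = cfg$params$floor_hz,
                                ceil_hz = cfg$params$ceil_hz)
    out$prominence <- emit(prof, "prominence")
    gmap <- tr$speakers
    out$prominence_summary <- emit(group_summary(prof, gmap),
                                   "prominence_summary")
  } else {
    log("audio or span table missing: prominence stage skipped")
  }
  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(
    list(params = cfg$params,
         n_ts = sum(out$ts_classes$n_ts[out$ts_classes$speaker != "ALL"]),
         tables = as.list(paths)),
    summary_path, auto_unbox = TRUE, pretty = TRUE)
  paths["summary"] <- summary_path
  log_path <- file.path(cfg$out_dir, "run.log")
  writeLines(log_lines, log_path)
  paths["log"] <- log_path
  out$paths <- paths
  invisible(out)
}
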