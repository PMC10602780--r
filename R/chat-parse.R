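#' @title CHAT-LABLITA transcript parsing
#'
#' @description
#' The transcript format follows the CHAT-LABLITA conventions used for
#' L-AcT annotated spoken corpora: one `*SPK:`-prefixed line per
#' terminated sequence (TS), `//` marking the terminal prosodic boundary,
#' `/` non-terminal boundaries, `^TAG^` information-unit labels suffixed
#' to the boundary they close (COM, COB, TOP, APC, or any other label),
#' `*` opening a retracted span and `[/]` closing it, and a leading `&`
#' marking a word fragment. Header lines starting with `@` are kept as
#' metadata; `@group: CODE GROUP` lines assign speakers to the
#' patient / control / interviewer groups.
#'
#' @name chat_corpus
NULL

new_token_df <- function(surface = character(), is_retracted = logical(),
                         is_fragment = logical(), retr_group = integer()) {
  data.frame(surface = surface, is_retracted = is_retracted,
             is_fragment = is_fragment, retr_group = retr_group,
             stringsAsFactors = FALSE)
}

new_unit <- function(tokens, tag = NA_character_, tag_explicit = FALSE,
                     trailing_boundary = "non_terminal",
                     scansion_breaks = integer(), time_span = NULL) {
  list(tag = tag, tag_explicit = tag_explicit, tokens = tokens,
       trailing_boundary = trailing_boundary,
       scansion_breaks = scansion_breaks, time_span = time_span)
}

unit_scansion_prefixes <- function(unit) length(unit$scansion_breaks)

new_ts <- function(units, speaker, time_span = NULL) {
  list(speaker = speaker, units = units, time_span = time_span)
}

new_turn <- function(speaker, sequences, time_span = NULL) {
  list(speaker = speaker, sequences = sequences, time_span = time_span)
}

#' Construct a transcript object
#' @param turns list of turns.
#' @param speakers named character vector mapping speaker code to group
#'   (`"patient"`, `"control"`, `"interviewer"`, or other).
#' @param metadata free-form list.
#' @return an object of class `transcript`.
#' @keywords internal
new_transcript <- function(turns, speakers, metadata = list()) {
  structure(list(turns = turns, speakers = speakers, metadata = metadata),
            class = "transcript")
}

boundary_re <- "^(//|/)(\\^([^^]+)\\^)?$"

# tokenize one utterance body into chunks; each chunk is
# list(tokens = token df, boundary = "terminal"/"non_terminal",
#      tag = chr or NA)
parse_line_chunks <- function(body, line_no, issues) {
  raw <- strsplit(trimws(body), "[ \t]+")[[1]]
  raw <- raw[nzchar(raw)]
  chunks <- list()
  cur <- new_token_df()
  in_retr <- FALSE
  group_id <- 0L
  for (w in raw) {
    if (identical(w, "[/]")) {
      if (!in_retr)
        issues$err(line_no, "retracing marker [/] without opening *")
      in_retr <- FALSE
      next
    }
    m <- regmatches(w, regexec(boundary_re, w))[[1]]
    if (length(m) > 0) {
      if (in_retr) {
        issues$err(line_no,
                   "unmatched * without [/] before a prosodic boundary")
        in_retr <- FALSE  # recover in lint mode
      }
      tag <- if (nzchar(m[4] %||% "")) m[4] else NA_character_
      if (nrow(cur) == 0L) {
        if (!is.na(tag))
          issues$err(line_no, sprintf("tag ^%s^ with no preceding text", tag))
        # stray empty chunk (e.g. doubled boundary): recoverable, dropped
        issues$warn(line_no, "empty prosodic chunk dropped")
        next
      }
      chunks[[length(chunks) + 1L]] <- list(
        tokens = cur,
        boundary = if (identical(m[2], "//")) "terminal" else "non_terminal",
        tag = tag)
      cur <- new_token_df()
      next
    }
    starts_retr <- startsWith(w, "*")
    if (starts_retr) {
      if (in_retr)
        issues$err(line_no, "nested * inside an open retracing span")
      in_retr <- TRUE
      group_id <- group_id + 1L
      w <- substring(w, 2L)
    }
    if (!nzchar(w)) {
      issues$err(line_no, "bare * with no token")
      next
    }
    cur <- rbind(cur, new_token_df(
      surface = w,
      is_retracted = in_retr,
      is_fragment = startsWith(w, "&"),
      retr_group = if (in_retr) group_id else NA_integer_))
  }
  if (in_retr)
    issues$err(line_no, "unmatched * without [/] at end of line")
  if (nrow(cur) > 0L) {
    issues$warn(line_no,
                "missing terminal boundary; line treated as one TS")
    chunks[[length(chunks) + 1L]] <-
      list(tokens = cur, boundary = "terminal", tag = NA_character_)
  } else if (length(chunks) > 0L &&
             chunks[[length(chunks)]]$boundary != "terminal") {
    issues$warn(line_no,
                "missing terminal boundary; line treated as one TS")
    chunks[[length(chunks)]]$boundary <- "terminal"
  }
  chunks
}

# assemble chunks of one TS into information units:
# untagged chunks attach FORWARD to the next explicitly tagged unit
# (scansion); if the TS carries no explicit COM/COB, the unit with the
# terminal boundary is inferred to be the COM.
assemble_units <- function(chunks) {
  tagged_at <- which(!vapply(chunks, function(c) is.na(c$tag), logical(1)))
  units <- list()
  pending <- list()  # untagged chunks waiting to merge forward
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    if (is.na(ch$tag) && any(tagged_at > i)) {
      pending[[length(pending) + 1L]] <- ch
      next
    }
    toks <- ch$tokens
    breaks <- integer()
    if (length(pending) > 0L) {
      all_toks <- new_token_df()
      for (p in pending) {
        all_toks <- rbind(all_toks, p$tokens)
        breaks <- c(breaks, nrow(all_toks))
      }
      toks <- rbind(all_toks, toks)
      pending <- list()
    }
    # retracing groups are numbered per line while scanning; renumber
    # densely within the unit so identity is stable under serialization
    g <- toks$retr_group
    if (any(!is.na(g)))
      toks$retr_group <- match(g, unique(g[!is.na(g)]))
    units[[length(units) + 1L]] <- new_unit(
      tokens = toks, tag = ch$tag, tag_explicit = !is.na(ch$tag),
      trailing_boundary = ch$boundary, scansion_breaks = breaks)
  }
  has_illoc <- any(vapply(units, function(u)
    !is.na(u$tag) && u$tag %in% c("COM", "COB"), logical(1)))
  if (!has_illoc && length(units) > 0L) {
    last <- length(units)
    if (is.na(units[[last]]$tag)) {
      units[[last]]$tag <- "COM"
      units[[last]]$tag_explicit <- FALSE
    }
  }
  units
}

make_issue_collector <- function(strict = TRUE) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$add <- function(line, severity, message) {
    env$rows[[length(env$rows) + 1L]] <-
      data.frame(line = line, severity = severity, message = message,
                 stringsAsFactors = FALSE)
  }
  env$err <- function(line, message) {
    env$add(line, "error", message)
    if (strict)
      stop_prosopath(sprintf("line %d: %s", line, message),
                     "prosopath_annotation_error")
  }
  env$warn <- function(line, message) {
    env$add(line, "warning", message)
  }
  env$table <- function() {
    if (length(env$rows) == 0L)
      data.frame(line = integer(), severity = character(),
                 message = character(), stringsAsFactors = FALSE)
    else do.call(rbind, env$rows)
  }
  env
}

parse_transcript_impl <- function(text, groups, strict) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  issues <- make_issue_collector(strict)
  metadata <- list()
  speakers <- character()
  utt <- list()  # list of (speaker, chunks-per-TS)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "%")) next  # dependent tiers ignored
    if (startsWith(line, "@")) {
      m <- regmatches(line,
        regexec("^@group:\\s*(\\S+)\\s+(\\S+)\\s*$", line,
                ignore.case = TRUE))[[1]]
      if (length(m) > 0) {
        speakers[m[2]] <- tolower(m[3])
      } else {
        metadata[[length(metadata) + 1L]] <- line
      }
      next
    }
    m <- regmatches(line, regexec("^\\*([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      issues$err(i, "utterance line lacks a *SPK: speaker prefix")
      next
    }
    spk <- trimws(m[2])
    chunks <- parse_line_chunks(m[3], i, issues)
    # split at terminal boundaries: one TS per terminated group of chunks
    if (length(chunks) == 0L) next
    term <- vapply(chunks, function(c) c$boundary == "terminal", logical(1))
    ts_end <- which(term)
    start <- 1L
    for (e in ts_end) {
      units <- assemble_units(chunks[start:e])
      if (length(units) > 0L)
        utt[[length(utt) + 1L]] <- list(speaker = spk, units = units)
      start <- e + 1L
    }
  }
  # merge consecutive same-speaker TS lines into turns
  turns <- list()
  for (u in utt) {
    n <- length(turns)
    if (n > 0L && turns[[n]]$speaker == u$speaker) {
      turns[[n]]$sequences[[length(turns[[n]]$sequences) + 1L]] <-
        new_ts(u$units, u$speaker)
    } else {
      turns[[n + 1L]] <- new_turn(u$speaker, list(new_ts(u$units, u$speaker)))
    }
  }
  if (!is.null(groups)) speakers[names(groups)] <- unname(groups)
  seen <- unique(vapply(turns, function(tu) tu$speaker, character(1)))
  missing <- setdiff(seen, names(speakers))
  if (length(missing) > 0L)
    speakers[missing] <- "unknown"
  list(transcript = new_transcript(turns, speakers, metadata),
       issues = issues$table())
}

#' Parse a CHAT-LABLITA transcript
#'
#' Builds the Transcript -> Turn -> Terminated sequence -> Information
#' unit -> Token hierarchy. Consecutive lines by the same speaker merge
#' into one turn. Untagged `/`-delimited chunks (scansion) attach forward
#' to the next explicitly tagged unit; when a TS carries no explicit
#' COM/COB tag, the unit closed by the terminal boundary is inferred to
#' be the Comment (an utterance must carry an illocution).
#'
#' @param text a character vector of lines, or a single string with
#'   embedded newlines, or a file path (when `is_file = TRUE`).
#' @param groups optional named character vector mapping speaker codes to
#'   groups (`patient`, `control`, `interviewer`); overrides any
#'   `@group:` header lines.
#' @param is_file read `text` as a file path.
#' @return an object of class `transcript`.
#' @seealso [serialize_transcript()], [lint_transcript()]
#' @export
parse_transcript <- function(text, groups = NULL, is_file = FALSE) {
  if (is_file) text <- readLines(text, encoding = "UTF-8", warn = FALSE)
  res <- withCallingHandlers(
    parse_transcript_impl(text, groups, strict = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  warn <- res$issues[res$issues$severity == "warning", , drop = FALSE]
  for (k in seq_len(nrow(warn)))
    warning(sprintf("line %d: %s", warn$line[k], warn$message[k]),
            call. = FALSE)
  res$transcript
}

#' Validate a CHAT-LABLITA transcript without stopping
#'
#' Collects all annotation problems (unmatched retracing markers, tags
#' without text, missing terminal boundaries, malformed lines) into a
#' report instead of signalling on the first error.
#'
#' @inheritParams parse_transcript
#' @return data.frame with columns `line`, `severity`, `message`.
#' @export
lint_transcript <- function(text, is_file = FALSE) {
  if (is_file) text <- readLines(text, encoding = "UTF-8", warn = FALSE)
  parse_transcript_impl(text, NULL, strict = FALSE)$issues
}

#' @export
print.transcript <- function(x, ...) {
  n_ts <- sum(vapply(x$turns, function(tu) length(tu$sequences), integer(1)))
  cat(sprintf("<transcript> %d turns, %d terminated sequences, %d speakers\n",
              length(x$turns), n_ts, length(x$speakers)))
  grp <- table(unname(x$speakers))
  cat("  speakers:",
      paste(sprintf("%s (%s)", names(x$speakers), unname(x$speakers)),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- iteration helpers used across metric modules ----

#' Flatten a transcript into its terminated sequences
#' @param t a `transcript`.
#' @param speakers optional character vector of speaker codes to keep;
#'   default keeps every speaker whose group is not `"interviewer"`.
#' @return list of terminated sequences (each carries its `speaker`).
#' @export
transcript_ts <- function(t, speakers = NULL) {
  if (is.null(speakers)) speakers <- tracked_speakers(t)
  out <- list()
  for (tu in t$turns) {
    if (!(tu$speaker %in% speakers)) next
    out <- c(out, tu$sequences)
  }
  out
}

#' Speakers tracked for per-speaker metrics
#'
#' Every speaker whose group is not `"interviewer"`: interviewer turns are
#' parsed but excluded from all per-speaker metrics.
#'
#' @param t a `transcript`.
#' @return character vector of speaker codes.
#' @export
tracked_speakers <- function(t) {
  names(t$speakers)[t$speakers != "interviewer"]
}

# combined token data.frame of a TS (unit column added)
ts_tokens <- function(ts) {
  dfs <- lapply(seq_along(ts$units), function(i) {
    tk <- ts$units[[i]]$tokens
    if (nrow(tk) > 0L) tk$unit <- i
    tk
  })
  do.call(rbind, dfs[vapply(dfs, nrow, integer(1)) > 0])
}
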