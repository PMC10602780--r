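#' @title Silent pause detection and positional typology
#'
#' @description
#' Silences are found with a Praat-style sounding/silent criterion: frame
#' RMS intensity in dB, frames more than `threshold_db` below the file
#' maximum are silent, adjacent silent frames merge, and intervals
#' shorter than `min_dur_ms` (default 150 ms, about the duration of a
#' stop-consonant closure) are dropped. Each remaining silence is binned
#' by duration and classified by its position relative to the aligned
#' annotation: `T` at turn-taking (before a tracked speaker's turn), `UT`
#' between two utterances of the same turn, `IU` between two information
#' units of the same utterance, or `excluded`.
#'
#' @name pauses
NULL

pause_bins <- c("b150_250", "b251_500", "b501_1000", "b1001_plus")

#' Detect silent intervals in audio
#'
#' @param audio an `audio_signal`.
#' @param min_dur_ms minimum silence duration kept, in ms.
#' @param threshold_db silence threshold relative to the file's maximum
#'   frame intensity, in dB.
#' @param frame_ms analysis frame length in ms.
#' @param hop_ms hop between frames in ms; edge accuracy is about one
#'   hop.
#' @return data.frame of class `silences` with columns `start_s`,
#'   `end_s`, `duration_ms` (integer ms, floored).
#' @export
detect_silences <- function(audio, min_dur_ms = 150, threshold_db = 25,
                            frame_ms = 25, hop_ms = 10) {
  if (length(audio$samples) < 2L)
    stop_prosopath("audio too short for silence detection",
                   "prosopath_audio_error")
  fr <- frame_rms(audio, frame_ms, hop_ms)
  db <- 20 * log10(pmax(fr$rms, .Machine$double.xmin))
  max_db <- max(db)
  dur <- audio_duration(audio)
  if (max_db <= 20 * log10(.Machine$double.xmin) + 1) {
    # digital silence throughout
    out <- data.frame(start_s = 0, end_s = dur,
                      duration_ms = floor(dur * 1000))
    class(out) <- c("silences", "data.frame")
    return(out)
  }
  silent <- db < max_db - threshold_db
  r <- rle(silent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  frame_s <- frame_ms / 1000
  rows <- lapply(keep, function(k) {
    s <- fr$time[starts[k]]
    e <- fr$time[ends[k]] + frame_s
    # a silent run touching the file end extends to the true end
    if (ends[k] == length(silent)) e <- dur
    data.frame(start_s = s, end_s = e)
  })
  out <- if (length(rows) == 0L)
    data.frame(start_s = numeric(), end_s = numeric())
  else do.call(rbind, rows)
  out$duration_ms <- floor((out$end_s - out$start_s) * 1000 + 1e-9)
  out <- out[out$duration_ms >= min_dur_ms, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("silences", "data.frame")
  out
}

#' Assign a silence duration to its bin
#'
#' The four duration classes on integer milliseconds:
#' 150-250, 251-500, 501-1000, and over 1000 ms.
#'
#' @param duration_ms numeric vector of durations in ms (all >= 150).
#' @return character vector of bin labels.
#' @export
bin_duration <- function(duration_ms) {
  d <- floor(duration_ms)
  if (any(d < 150))
    stop_prosopath("silence shorter than the 150 ms minimum",
                   "prosopath_pause_error")
  cut_idx <- findInterval(d, c(150, 251, 501, 1001))
  pause_bins[cut_idx]
}

# Enumerate annotated gaps (the pause opportunities) of an aligned
# transcript. Returns data.frame(position, start_s, end_s, speaker) with
# one row per opportunity:
#   T  - gap before a tracked speaker's turn following a different
#        speaker's turn (only pauses *before* the turn count: they index
#        the speaker's reaction time);
#   UT - gap between consecutive TS spans of one turn;
#   IU - gap between consecutive unit spans of one TS.
pause_opportunities <- function(t) {
  tracked <- tracked_speakers(t)
  rows <- list()
  add <- function(position, start_s, end_s, speaker) {
    rows[[length(rows) + 1L]] <<-
      data.frame(position = position, start_s = start_s, end_s = end_s,
                 speaker = speaker, stringsAsFactors = FALSE)
  }
  turns <- t$turns
  for (i in seq_along(turns)) {
    tu <- turns[[i]]
    if (is.null(tu$time_span))
      stop_prosopath("transcript has no attached time spans",
                     "prosopath_alignment_error")
    if (i > 1L && turns[[i - 1L]]$speaker != tu$speaker &&
        tu$speaker %in% tracked)
      add("T", turns[[i - 1L]]$time_span[2], tu$time_span[1], tu$speaker)
    seqs <- tu$sequences
    for (j in seq_along(seqs)) {
      if (j > 1L)
        add("UT", seqs[[j - 1L]]$time_span[2], seqs[[j]]$time_span[1],
            tu$speaker)
      units <- seqs[[j]]$units
      for (u in seq_along(units)) {
        if (u > 1L)
          add("IU", units[[u - 1L]]$time_span[2], units[[u]]$time_span[1],
              tu$speaker)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(position = character(), start_s = numeric(),
                      end_s = numeric(), speaker = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify a silent interval by position
#'
#' A silence is assigned by its midpoint to the annotated gap it falls
#' into: `T` when the gap separates two turns by different speakers and
#' the following turn belongs to a tracked (non-interviewer) speaker,
#' `UT` between two terminated sequences of one turn, `IU` between two
#' information units of one utterance, `excluded` otherwise (inside a
#' unit, before an interviewer's turn, or outside the annotation).
#'
#' @param silences a `silences` data.frame (or any data.frame with
#'   `start_s`/`end_s`).
#' @param t a `transcript` with attached time spans (see
#'   [attach_alignment()]).
#' @return the input with a `position` column added.
#' @export
classify_pause_position <- function(silences, t) {
  opp <- pause_opportunities(t)
  mid <- (silences$start_s + silences$end_s) / 2
  pos <- rep("excluded", length(mid))
  for (i in seq_along(mid)) {
    hit <- which(opp$start_s - 1e-9 <= mid[i] & mid[i] <= opp$end_s + 1e-9)
    if (length(hit) > 0L) pos[i] <- opp$position[hit[1]]
  }
  silences$position <- pos
  silences
}

#' Pause profile of one speaker
#'
#' For each position (`T`, `UT`, `IU`) the annotated gaps of the aligned
#' transcript are the opportunities; each opportunity either contains a
#' detected silence (binned by its duration; if several silences fall in
#' one gap the longest is taken) or counts as "no pause". Percentages are
#' over opportunities.
#'
#' @param t a `transcript` with attached time spans.
#' @param audio an `audio_signal`, or `NULL` when `silences` is given.
#' @param speaker speaker code.
#' @param silences optional precomputed (possibly hand-edited)
#'   `silences` table overriding detection on `audio`.
#' @param ... passed to [detect_silences()].
#' @return data.frame of class `pause_profile` with one row per position
#'   and columns `position`, `n_opportunities`, `n_no_pause`, one count
#'   and one percentage column per duration bin, and `pct_no_pause`.
#' @export
pause_profile <- function(t, audio = NULL, speaker, silences = NULL, ...) {
  if (is.null(silences)) {
    if (is.null(audio))
      stop_prosopath("either audio or a silences table is required",
                     "prosopath_pause_error")
    silences <- detect_silences(audio, ...)
  }
  opp <- pause_opportunities(t)
  opp <- opp[opp$speaker == speaker, , drop = FALSE]
  mid <- (silences$start_s + silences$end_s) / 2
  rows <- list()
  for (pos in c("T", "UT", "IU")) {
    g <- opp[opp$position == pos, , drop = FALSE]
    if (nrow(g) == 0L) next
    bins <- stats::setNames(integer(length(pause_bins)), pause_bins)
    no_pause <- 0L
    for (i in seq_len(nrow(g))) {
      inside <- which(g$start_s[i] - 1e-9 <= mid & mid <= g$end_s[i] + 1e-9)
      if (length(inside) == 0L) {
        no_pause <- no_pause + 1L
      } else {
        d <- max(silences$duration_ms[inside])
        b <- bin_duration(d)
        bins[b] <- bins[b] + 1L
      }
    }
    row <- data.frame(position = pos, n_opportunities = nrow(g),
                      n_no_pause = no_pause)
    for (b in pause_bins) row[[paste0("n_", b)]] <- bins[[b]]
    row$pct_no_pause <- round_half_up(100 * no_pause / nrow(g), 1)
    for (b in pause_bins)
      row[[paste0("pct_", b)]] <-
        round_half_up(100 * bins[[b]] / nrow(g), 1)
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) == 0L) {
    data.frame(position = character(), n_opportunities = integer(),
               n_no_pause = integer())
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pause_profile", "data.frame")
  attr(out, "speaker") <- speaker
  out
}
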