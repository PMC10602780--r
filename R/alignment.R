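#' @title Time alignment of transcripts to audio
#'
#' @description
#' Alignment files are plain TSV with columns
#' `tier<TAB>start_s<TAB>end_s<TAB>label`. Three structural tiers align
#' the annotation hierarchy to the signal: `turn`, `ts` (terminated
#' sequences) and `iu` (information units), with intervals listed in
#' document order. Extra tiers (e.g. `prominence`, `syllable`) are
#' preserved. A converter to and from Praat TextGrid interval tiers is
#' provided.
#'
#' @name alignment
NULL

tier_aliases <- c(turns = "turn", turn = "turn",
                  terminated_sequences = "ts", ts = "ts", TS = "ts",
                  information_units = "iu", iu = "iu", IU = "iu")

normalize_tier <- function(x) {
  ifelse(x %in% names(tier_aliases), tier_aliases[x], x)
}

#' Construct an alignment-tier object
#' @param intervals data.frame with columns `tier`, `start_s`, `end_s`,
#'   `label`.
#' @return an object of class `alignment_tier`.
#' @export
alignment_tier <- function(intervals) {
  stopifnot(all(c("tier", "start_s", "end_s", "label") %in% names(intervals)))
  intervals$tier <- unname(normalize_tier(as.character(intervals$tier)))
  intervals <- intervals[order(match(intervals$tier, unique(intervals$tier)),
                               intervals$start_s), , drop = FALSE]
  rownames(intervals) <- NULL
  obj <- structure(list(intervals = intervals), class = "alignment_tier")
  validate_alignment(obj)
  obj
}

tier_intervals <- function(a, tier) {
  a$intervals[a$intervals$tier == tier, , drop = FALSE]
}

validate_alignment <- function(a) {
  iv <- a$intervals
  if (any(iv$end_s <= iv$start_s))
    stop_prosopath("alignment interval with end <= start",
                   "prosopath_alignment_error")
  for (tr in unique(iv$tier)) {
    x <- iv[iv$tier == tr, , drop = FALSE]
    x <- x[order(x$start_s), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start_s[-1] < x$end_s[-nrow(x)] - 1e-9))
      stop_prosopath(sprintf("overlapping intervals within tier '%s'", tr),
                     "prosopath_alignment_error")
  }
  nested_in <- function(inner, outer) {
    # every inner interval must lie within a single outer interval
    for (i in seq_len(nrow(inner))) {
      ok <- any(outer$start_s <= inner$start_s[i] + 1e-9 &
                outer$end_s >= inner$end_s[i] - 1e-9)
      if (!ok) return(i)
    }
    0L
  }
  ts <- tier_intervals(a, "ts"); tu <- tier_intervals(a, "turn")
  iu <- tier_intervals(a, "iu")
  if (nrow(ts) > 0L && nrow(tu) > 0L) {
    bad <- nested_in(ts, tu)
    if (bad > 0L)
      stop_prosopath(sprintf("TS interval %d crosses a turn boundary", bad),
                     "prosopath_alignment_error")
  }
  if (nrow(iu) > 0L && nrow(ts) > 0L) {
    bad <- nested_in(iu, ts)
    if (bad > 0L)
      stop_prosopath(sprintf("unit interval %d crosses a TS boundary", bad),
                     "prosopath_alignment_error")
  }
  invisible(a)
}

#' @export
print.alignment_tier <- function(x, ...) {
  tb <- table(x$intervals$tier)
  cat("<alignment_tier>",
      paste(sprintf("%s: %d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an alignment TSV file
#'
#' @param path path to a TSV file with columns
#'   `tier  start_s  end_s  label` (no header).
#' @return an `alignment_tier`.
#' @export
read_alignment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tier", "start_s", "end_s", "label"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"),
                          quote = "", comment.char = "",
                          encoding = "UTF-8")
  alignment_tier(df)
}

#' Write an alignment TSV file
#' @param a an `alignment_tier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  utils::write.table(a$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach time spans from an alignment to a transcript
#'
#' Interval counts per structural tier must equal the transcript's counts
#' of turns, terminated sequences and information units, in document
#' order; the spans are copied onto the corresponding objects.
#'
#' @param t a `transcript`.
#' @param a an `alignment_tier`.
#' @return the `transcript` with `time_span` fields populated.
#' @export
attach_alignment <- function(t, a) {
  tu_iv <- tier_intervals(a, "turn")
  ts_iv <- tier_intervals(a, "ts")
  iu_iv <- tier_intervals(a, "iu")
  n_turn <- length(t$turns)
  n_ts <- sum(vapply(t$turns, function(x) length(x$sequences), integer(1)))
  n_iu <- 0L
  for (tu in t$turns) for (ts in tu$sequences)
    n_iu <- n_iu + length(ts$units)
  if (nrow(tu_iv) != n_turn)
    stop_prosopath(sprintf(
      "turn tier: %d intervals for %d turns", nrow(tu_iv), n_turn),
      "prosopath_alignment_error")
  if (nrow(ts_iv) != n_ts)
    stop_prosopath(sprintf(
      "ts tier: %d intervals for %d terminated sequences",
      nrow(ts_iv), n_ts), "prosopath_alignment_error")
  if (nrow(iu_iv) != n_iu)
    stop_prosopath(sprintf(
      "iu tier: %d intervals for %d information units", nrow(iu_iv), n_iu),
      "prosopath_alignment_error")
  k_ts <- 0L; k_iu <- 0L
  for (i in seq_along(t$turns)) {
    t$turns[[i]]$time_span <- c(tu_iv$start_s[i], tu_iv$end_s[i])
    for (j in seq_along(t$turns[[i]]$sequences)) {
      k_ts <- k_ts + 1L
      t$turns[[i]]$sequences[[j]]$time_span <-
        c(ts_iv$start_s[k_ts], ts_iv$end_s[k_ts])
      for (u in seq_along(t$turns[[i]]$sequences[[j]]$units)) {
        k_iu <- k_iu + 1L
        t$turns[[i]]$sequences[[j]]$units[[u]]$time_span <-
          c(iu_iv$start_s[k_iu], iu_iv$end_s[k_iu])
      }
    }
  }
  t
}

#' Write an alignment as a Praat TextGrid
#'
#' Emits a full-format `ooTextFile` TextGrid with one interval tier per
#' alignment tier. Gaps between annotated intervals become empty-label
#' intervals so each tier tiles the file duration, as Praat requires.
#'
#' @param a an `alignment_tier`.
#' @param path output path.
#' @param xmax total duration; default the largest interval end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(a, path, xmax = NULL) {
  iv <- a$intervals
  if (is.null(xmax)) xmax <- max(iv$end_s)
  tiers <- unique(iv$tier)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0", sprintf("xmax = %.10g", xmax),
           "tiers? <exists>", sprintf("size = %d", length(tiers)),
           "item []:")
  for (k in seq_along(tiers)) {
    x <- iv[iv$tier == tiers[k], , drop = FALSE]
    x <- x[order(x$start_s), , drop = FALSE]
    # tile with empty intervals
    full <- data.frame(start_s = numeric(), end_s = numeric(),
                       label = character())
    cur <- 0
    for (i in seq_len(nrow(x))) {
      if (x$start_s[i] > cur + 1e-9)
        full <- rbind(full, data.frame(start_s = cur, end_s = x$start_s[i],
                                       label = ""))
      full <- rbind(full, x[i, c("start_s", "end_s", "label")])
      cur <- x$end_s[i]
    }
    if (cur < xmax - 1e-9)
      full <- rbind(full, data.frame(start_s = cur, end_s = xmax,
                                     label = ""))
    out <- c(out,
             sprintf("    item [%d]:", k),
             '        class = "IntervalTier"',
             sprintf('        name = "%s"', tiers[k]),
             "        xmin = 0",
             sprintf("        xmax = %.10g", xmax),
             sprintf("        intervals: size = %d", nrow(full)))
    for (i in seq_len(nrow(full))) {
      out <- c(out,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %.10g", full$start_s[i]),
               sprintf("            xmax = %.10g", full$end_s[i]),
               sprintf('            text = "%s"', full$label[i]))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read interval tiers from a Praat TextGrid
#'
#' Minimal reader for full-format TextGrids: empty-label intervals are
#' dropped, everything else becomes an alignment row.
#'
#' @param path path to a TextGrid file.
#' @return an `alignment_tier`.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  tier <- NA_character_
  xmin <- NA_real_; xmax <- NA_real_
  for (line in lines) {
    s <- trimws(line)
    m <- regmatches(s, regexec('^name\\s*=\\s*"(.*)"$', s))[[1]]
    if (length(m) > 0) { tier <- m[2]; next }
    m <- regmatches(s, regexec("^xmin\\s*=\\s*([0-9.eE+-]+)$", s))[[1]]
    if (length(m) > 0) { xmin <- as.numeric(m[2]); next }
    m <- regmatches(s, regexec("^xmax\\s*=\\s*([0-9.eE+-]+)$", s))[[1]]
    if (length(m) > 0) { xmax <- as.numeric(m[2]); next }
    m <- regmatches(s, regexec('^text\\s*=\\s*"(.*)"$', s))[[1]]
    if (length(m) > 0 && !is.na(tier)) {
      if (nzchar(m[2]))
        rows[[length(rows) + 1L]] <-
          data.frame(tier = tier, start_s = xmin, end_s = xmax,
                     label = m[2], stringsAsFactors = FALSE)
      next
    }
  }
  if (length(rows) == 0L)
    stop_prosopath("no labeled intervals found in TextGrid",
                   "prosopath_alignment_error")
  alignment_tier(do.call(rbind, rows))
}
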