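#' @title Information structure metrics
#'
#' @description
#' In L-AcT a terminated sequence (TS) realizes either an utterance or a
#' stanza. A simple utterance is one information unit, necessarily a
#' Comment (COM); a complex utterance has several units, one of which is
#' the COM; a stanza chains weak-illocution Bound Comments (COB).
#' These functions classify TSs, tabulate the class proportions and the
#' presence of Topic (TOP) and Appendix (APC) units, and compute the mean
#' length of utterance (MLU) in words per TS.
#'
#' @name info_structure
NULL

#' Classify a terminated sequence
#'
#' Stanza if the TS contains at least one COB unit (stanza takes
#' precedence when TOP/APC are also present); otherwise simple if it is a
#' single tagged unit (scansion chunks absorbed into that unit do not
#' count); otherwise complex.
#'
#' @param ts a terminated sequence as produced by [parse_transcript()].
#' @return one of `"simple"`, `"complex"`, `"stanza"`.
#' @export
classify_ts <- function(ts) {
  tags <- vapply(ts$units, function(u) u$tag %||% NA_character_,
                 character(1))
  if (!any(tags %in% c("COM", "COB"), na.rm = TRUE))
    stop_prosopath("terminated sequence with neither COM nor COB",
                   "prosopath_annotation_error")
  if (any(tags == "COB", na.rm = TRUE)) return("stanza")
  if (length(ts$units) == 1L) "simple" else "complex"
}

per_speaker_ts <- function(t, speakers) {
  if (is.null(speakers)) speakers <- tracked_speakers(t)
  all_ts <- transcript_ts(t, speakers)
  if (length(all_ts) == 0L)
    stop_prosopath("no terminated sequences for the selected speakers",
                   "prosopath_selection_error")
  split(all_ts, vapply(all_ts, function(x) x$speaker, character(1)))
}

#' Tabulate terminated-sequence classes per speaker
#'
#' One row per selected speaker plus a pooled row (`ALL`) whose
#' percentages are recomputed from the summed counts. Percentages are
#' rounded half-up to one decimal, the convention of the printed report
#' tables.
#'
#' @param t a `transcript`.
#' @param speakers speaker codes to include; default all non-interviewer
#'   speakers.
#' @return data.frame with columns `speaker`, `n_ts`, `n_simple`,
#'   `n_complex`, `n_stanza`, `pct_simple`, `pct_complex`, `pct_stanza`.
#' @export
ts_class_table <- function(t, speakers = NULL) {
  by_spk <- per_speaker_ts(t, speakers)
  rows <- lapply(names(by_spk), function(spk) {
    cls <- vapply(by_spk[[spk]], classify_ts, character(1))
    data.frame(speaker = spk, n_ts = length(cls),
               n_simple = sum(cls == "simple"),
               n_complex = sum(cls == "complex"),
               n_stanza = sum(cls == "stanza"))
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(speaker = "ALL", n_ts = sum(out$n_ts),
                       n_simple = sum(out$n_simple),
                       n_complex = sum(out$n_complex),
                       n_stanza = sum(out$n_stanza))
  out <- rbind(out, pooled)
  for (cl in c("simple", "complex", "stanza"))
    out[[paste0("pct_", cl)]] <-
      round_half_up(100 * out[[paste0("n_", cl)]] / out$n_ts, 1)
  out
}

#' Tabulate Topic and Appendix presence per speaker
#'
#' A TS counts once toward the TOP column if it contains at least one TOP
#' unit (presence, not multiplicity), likewise for APC.
#'
#' @inheritParams ts_class_table
#' @return data.frame with columns `speaker`, `n_ts`, `n_with_top`,
#'   `n_with_apc`, `pct_top`, `pct_apc`.
#' @export
unit_presence_table <- function(t, speakers = NULL) {
  by_spk <- per_speaker_ts(t, speakers)
  has_tag <- function(ts, tag)
    any(vapply(ts$units, function(u) identical(u$tag, tag), logical(1)))
  rows <- lapply(names(by_spk), function(spk) {
    tss <- by_spk[[spk]]
    data.frame(speaker = spk, n_ts = length(tss),
               n_with_top = sum(vapply(tss, has_tag, logical(1), "TOP")),
               n_with_apc = sum(vapply(tss, has_tag, logical(1), "APC")))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(speaker = "ALL", n_ts = sum(out$n_ts),
                               n_with_top = sum(out$n_with_top),
                               n_with_apc = sum(out$n_with_apc)))
  out$pct_top <- round_half_up(100 * out$n_with_top / out$n_ts, 1)
  out$pct_apc <- round_half_up(100 * out$n_with_apc / out$n_ts, 1)
  out
}

#' Words of a terminated sequence under a counting policy
#'
#' `"semantic"` (default) counts tokens that contribute to the semantic
#' content: retracted tokens and word fragments are excluded, fillers and
#' interjections are kept. `"non_retracted"` excludes retracted tokens
#' only; `"all"` counts every token.
#'
#' @param ts a terminated sequence.
#' @param policy word-count policy.
#' @return integer word count.
#' @export
ts_word_count <- function(ts, policy = c("semantic", "non_retracted",
                                         "all")) {
  policy <- match.arg(policy)
  tk <- ts_tokens(ts)
  keep <- switch(policy,
                 semantic = !tk$is_retracted & !tk$is_fragment,
                 non_retracted = !tk$is_retracted,
                 all = rep(TRUE, nrow(tk)))
  sum(keep)
}

#' Mean length of utterance per speaker
#'
#' MLU = words per terminated sequence, averaged over a speaker's TSs;
#' it measures the amount of semantic content packed into each utterance.
#'
#' @inheritParams ts_class_table
#' @param policy word-count policy, see [ts_word_count()].
#' @return data.frame with columns `speaker`, `n_ts`, `n_words`, `mlu`,
#'   plus a list-column `per_ts_lengths`.
#' @export
mlu <- function(t, speakers = NULL, policy = "semantic") {
  by_spk <- per_speaker_ts(t, speakers)
  rows <- lapply(names(by_spk), function(spk) {
    lens <- vapply(by_spk[[spk]], ts_word_count, integer(1), policy = policy)
    df <- data.frame(speaker = spk, n_ts = length(lens),
                     n_words = sum(lens), mlu = sum(lens) / length(lens))
    df$per_ts_lengths <- list(lens)
    df
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test on two or more groups
#'
#' Thin wrapper around [stats::kruskal.test()] (mid-ranks, tie-corrected
#' H, chi-square reference with k-1 df), with the degenerate all-equal
#' case mapped to H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with elements `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L)
    stop_prosopath("need at least 3 observations in total",
                   "prosopath_stats_error")
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Realize a summary count table as a minimal transcript
#'
#' Builds a transcript whose per-speaker terminated-sequence counts,
#' class composition and Topic/Appendix presence equal a given summary
#' table, so that published corpus summaries can be re-analyzed with the
#' same machinery as raw transcripts. Topic and Appendix units are laid
#' onto the non-simple TSs (their natural hosts); placeholder words are
#' used throughout.
#'
#' @param counts data.frame with columns `speaker`, `n_simple`,
#'   `n_complex`, `n_stanza`, and optionally `n_with_top`, `n_with_apc`.
#' @param group group assigned to every speaker (default `"patient"`).
#' @return a `transcript`.
#' @export
counts_to_transcript <- function(counts, group = "patient") {
  lines <- character()
  for (i in seq_len(nrow(counts))) {
    spk <- counts$speaker[i]
    n_top <- if ("n_with_top" %in% names(counts)) counts$n_with_top[i] else 0L
    n_apc <- if ("n_with_apc" %in% names(counts)) counts$n_with_apc[i] else 0L
    n_host <- counts$n_complex[i] + counts$n_stanza[i]
    if (n_top > n_host || n_apc > n_host)
      stop_prosopath(
        "more TOP/APC terminated sequences than non-simple hosts",
        "prosopath_fixture_error")
    host <- 0L
    mk <- function(cls) {
      host <<- host + if (cls != "simple") 1L else 0L
      top <- cls != "simple" && host <= n_top
      apc <- cls != "simple" && host <= n_apc
      core <- switch(cls,
                     simple = "toto //^COM^",
                     complex = if (apc) "lena /^PAR^ toto /^COM^ fine //^APC^"
                               else "lena /^PAR^ toto //^COM^",
                     stanza = if (apc) "lena /^COB^ toto /^COB^ fine //^APC^"
                              else "lena /^COB^ toto //^COB^")
      paste0("*", spk, ":\t", if (top) "mira /^TOP^ " else "", core)
    }
    cls_seq <- c(rep("complex", counts$n_complex[i]),
                 rep("stanza", counts$n_stanza[i]),
                 rep("simple", counts$n_simple[i]))
    lines <- c(lines, vapply(cls_seq, mk, character(1)))
  }
  groups <- stats::setNames(rep(group, nrow(counts)), counts$speaker)
  parse_transcript(lines, groups = groups)
}
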