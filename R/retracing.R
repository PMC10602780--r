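#' @title Retracing (repair) mining
#'
#' @description
#' Retracing is the disfluent restart marked `* ... [/]` in CHAT-LABLITA:
#' the speaker abandons material and starts again. Each marked group is
#' one episode; adjacent episodes with no intervening non-retracted token
#' form a chain (a succession of restarts on the same material).
#' Episodes are classified by position in the terminated sequence
#' (start of TS, start of a non-first information unit, or inside the
#' ongoing unit) and by kind: total repetition (the repair repeats the
#' retracted tokens exactly), partial repetition (shared material, e.g. a
#' fragment completed by the repair), or modification.
#'
#' @name retracing
NULL

strip_fragment <- function(x) sub("^&", "", x)

classify_kind <- function(retr_tokens, repair_tokens) {
  n <- length(retr_tokens)
  if (length(repair_tokens) == 0L) return("modification")
  m <- min(n, length(repair_tokens))
  a <- retr_tokens[seq_len(m)]
  b <- repair_tokens[seq_len(m)]
  if (m == n && all(a == b)) return("repetition_total")
  sa <- strip_fragment(a); sb <- strip_fragment(b)
  partial <- any(mapply(function(x, y) nzchar(x) && startsWith(y, x),
                        sa, sb))
  if (partial) "repetition_partial" else "modification"
}

#' Find retracing episodes and chains in a terminated sequence
#'
#' @param ts a terminated sequence.
#' @param ts_ref identifier recorded in the output (default 1).
#' @return data.frame of class `retracing_episodes`: one row per episode
#'   with columns `ts_ref`, `unit_ref`, `start_token`, `n_retracted_tokens`,
#'   `position` (`start_of_ts` / `start_of_iu_inside_ts` / `inside_ts`),
#'   `kind`, `chain_id` (NA for single episodes) and `is_single`.
#' @export
find_episodes <- function(ts, ts_ref = 1L) {
  rows <- list()
  for (ui in seq_along(ts$units)) {
    tk <- ts$units[[ui]]$tokens
    if (nrow(tk) == 0L || !any(tk$is_retracted)) next
    groups <- unique(tk$retr_group[!is.na(tk$retr_group)])
    for (g in groups) {
      idx <- which(tk$retr_group %in% g)
      first <- min(idx); last <- max(idx)
      # repair = the next non-retracted tokens after the group (skipping
      # any following retracted groups of the same chain)
      rest <- tk[-seq_len(last), , drop = FALSE]
      repair <- rest$surface[!rest$is_retracted]
      if (length(repair) == 0L && ui < length(ts$units)) {
        nxt <- ts$units[[ui + 1L]]$tokens
        repair <- nxt$surface[!nxt$is_retracted]
      }
      position <-
        if (ui == 1L && first == 1L) "start_of_ts"
        else if (ui > 1L && first == 1L) "start_of_iu_inside_ts"
        else "inside_ts"
      rows[[length(rows) + 1L]] <- data.frame(
        ts_ref = ts_ref, unit_ref = ui, start_token = first,
        n_retracted_tokens = length(idx), position = position,
        kind = classify_kind(tk$surface[idx],
                             repair[seq_len(min(length(idx),
                                                length(repair)))]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(ts_ref = integer(), unit_ref = integer(),
               start_token = integer(), n_retracted_tokens = integer(),
               position = character(), kind = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  # chains: adjacent episodes in one unit with no non-retracted token
  # between the end of one group and the start of the next
  out$chain_id <- rep(NA_integer_, nrow(out))
  chain_counter <- 0L
  if (nrow(out) > 1L) {
    for (i in 2:nrow(out)) {
      if (out$unit_ref[i] != out$unit_ref[i - 1L]) next
      tk <- ts$units[[out$unit_ref[i]]]$tokens
      prev_end <- out$start_token[i - 1L] +
        out$n_retracted_tokens[i - 1L] - 1L
      between <- seq_len(nrow(tk)) > prev_end &
        seq_len(nrow(tk)) < out$start_token[i]
      if (any(between & !tk$is_retracted)) next
      if (is.na(out$chain_id[i - 1L])) {
        chain_counter <- chain_counter + 1L
        out$chain_id[i - 1L] <- chain_counter
      }
      out$chain_id[i] <- out$chain_id[i - 1L]
    }
  }
  # a chain is one restart event: its members inherit the position of
  # the first episode (later members only start mid-unit because the
  # chain's own retracted tokens precede them)
  for (cid in unique(out$chain_id[!is.na(out$chain_id)])) {
    m <- which(out$chain_id == cid)
    out$position[m] <- out$position[m[1]]
  }
  out$is_single <- is.na(out$chain_id)
  class(out) <- c("retracing_episodes", "data.frame")
  out
}

# all episodes of the selected speakers, with TS class attached
transcript_episodes <- function(t, speakers = NULL) {
  tss <- transcript_ts(t, speakers)
  eps <- lapply(seq_along(tss), function(i) {
    e <- find_episodes(tss[[i]], ts_ref = i)
    if (nrow(e) > 0L) {
      e$speaker <- tss[[i]]$speaker
      e$ts_class <- classify_ts(tss[[i]])
      # chain ids are unique within one TS; disambiguate across TSs
      e$chain_id <- ifelse(is.na(e$chain_id),
                           NA_character_,
                           paste0(i, "_", e$chain_id))
    }
    e
  })
  eps <- eps[vapply(eps, nrow, integer(1)) > 0]
  if (length(eps) == 0L)
    return(data.frame(ts_ref = integer(), unit_ref = integer(),
                      start_token = integer(),
                      n_retracted_tokens = integer(),
                      position = character(), kind = character(),
                      chain_id = integer(), is_single = logical(),
                      speaker = character(), ts_class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, eps)
}

#' Percentage of retracted tokens
#'
#' 100 x retracted tokens / total tokens for one speaker (fragments count
#' as tokens on both sides).
#'
#' @param t a `transcript`.
#' @param speaker speaker code.
#' @return percentage (numeric scalar).
#' @export
retracted_token_rate <- function(t, speaker) {
  tss <- transcript_ts(t, speaker)
  tot <- 0L; retr <- 0L
  for (ts in tss) {
    tk <- ts_tokens(ts)
    tot <- tot + nrow(tk)
    retr <- retr + sum(tk$is_retracted)
  }
  if (tot == 0L)
    stop_prosopath("speaker has no tokens", "prosopath_selection_error")
  100 * retr / tot
}

#' Single-episode and chain rates by terminated-sequence type
#'
#' The rate divides the number of single episodes (respectively chains)
#' occurring in TSs of a type by the number of information units of that
#' type containing no retracing at all ("not retracted units"). A chain
#' counts once, not once per member episode. `all` pools the types.
#'
#' @param t a `transcript`.
#' @param speakers speaker codes; default all non-interviewer speakers.
#' @return data.frame of class `retracing_rates` with columns `ts_type`,
#'   `n_single`, `n_chains`, `n_clean_units`, `single_rate`, `chain_rate`
#'   (percent; `NA` where the denominator is zero).
#' @export
episode_rates_by_ts_type <- function(t, speakers = NULL) {
  tss <- transcript_ts(t, speakers)
  eps <- transcript_episodes(t, speakers)
  types <- c("all", "simple", "complex", "stanza")
  clean_units <- stats::setNames(integer(4), types)
  for (i in seq_along(tss)) {
    cls <- classify_ts(tss[[i]])
    tse <- eps[eps$ts_ref == i, , drop = FALSE]
    for (ui in seq_along(tss[[i]]$units)) {
      clean <- !(ui %in% tse$unit_ref)
      if (clean) {
        clean_units[["all"]] <- clean_units[["all"]] + 1L
        clean_units[[cls]] <- clean_units[[cls]] + 1L
      }
    }
  }
  rows <- lapply(types, function(ty) {
    e <- if (ty == "all") eps else eps[eps$ts_class == ty, , drop = FALSE]
    n_single <- sum(e$is_single)
    n_chains <- length(unique(e$chain_id[!is.na(e$chain_id)]))
    den <- clean_units[[ty]]
    data.frame(ts_type = ty, n_single = n_single, n_chains = n_chains,
               n_clean_units = den,
               single_rate = if (den > 0) 100 * n_single / den else NA_real_,
               chain_rate = if (den > 0) 100 * n_chains / den else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("retracing_rates", "data.frame")
  out
}

#' Positional distribution of retracing events
#'
#' Percentages of retracing events at start of TS, start of a non-first
#' information unit, and inside an ongoing unit. A chain counts once, at
#' its first episode's position.
#'
#' @inheritParams episode_rates_by_ts_type
#' @return data.frame with columns `position`, `n_events`, `pct`
#'   (empty when there are no events).
#' @export
position_distribution <- function(t, speakers = NULL) {
  eps <- transcript_episodes(t, speakers)
  positions <- c("start_of_ts", "start_of_iu_inside_ts", "inside_ts")
  if (nrow(eps) == 0L)
    return(data.frame(position = character(), n_events = integer(),
                      pct = numeric()))
  events <- eps[eps$is_single, , drop = FALSE]
  for (cid in unique(eps$chain_id[!is.na(eps$chain_id)])) {
    ch <- eps[!is.na(eps$chain_id) & eps$chain_id == cid, , drop = FALSE]
    events <- rbind(events, ch[1L, , drop = FALSE])
  }
  n <- vapply(positions, function(p) sum(events$position == p), integer(1))
  data.frame(position = positions, n_events = unname(n),
             pct = unname(round_half_up(100 * n / sum(n), 1)))
}
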