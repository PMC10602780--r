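#' @title Synthetic corpus generation
#'
#' @description
#' Seeded generators for interview-style corpora with full ground truth:
#' CHAT-LABLITA transcripts whose terminated-sequence classes, unit tags,
#' word counts and retracing events follow prescribed probabilities, and
#' audio rendered as concatenated harmonic complexes with prescribed f0
#' contours, spectral slopes, amplitude modulation and silent gaps. Every
#' pipeline stage can thus be validated against known truth without any
#' corpus download.
#'
#' @name synth
NULL

synth_lexicon <- c("mano", "pira", "dolo", "sera", "tavo", "lino",
                   "caru", "mela", "pane", "vita", "rosa", "fiume",
                   "campo", "luce", "verde", "notte", "strada", "lumo",
                   "salto", "perla", "fondo", "ramo", "corte", "brivo")

#' Specification of a synthetic interview corpus
#'
#' The parameters are the generative ground truth: terminated-sequence
#' class probabilities, Topic/Appendix probabilities per non-simple TS,
#' mean words per TS, retracing episode/chain rates and position
#' weights, per-position pause probabilities with duration-bin weights,
#' and the acoustic rendering parameters (base f0, nucleus excursion in
#' semitones, spectral slope, amplitude modulation).
#'
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @param n_turns total number of turns (interviewer and main speaker
#'   alternate, interviewer first).
#' @param speakers named character vector code -> group.
#' @param main_speaker,interviewer speaker codes.
#' @param mean_ts_per_turn mean terminated sequences per main-speaker
#'   turn (at least 1).
#' @param p_ts_class probabilities of (simple, complex, stanza).
#' @param p_top,p_apc probability that a non-simple TS carries a Topic /
#'   an Appendix unit.
#' @param mean_ts_words mean semantic words per TS.
#' @param retracing list: `episode_rate` (events per information unit),
#'   `chain_fraction` (events realized as chains), `position_weights`
#'   (start_of_ts, start_of_iu_inside_ts, inside_ts; renormalized over
#'   the positions feasible for each unit).
#' @param pauses list with elements `T`, `UT`, `IU`, each
#'   `list(p = probability of a pause at an opportunity, bin_weights =
#'   4 weights over the duration bins)`. Durations are drawn uniformly
#'   inside each bin, away from the edges so that detection accuracy of
#'   one hop cannot flip the bin.
#' @param audio list: `rate` (Hz, >= 8000), `f0_base` (named, Hz per
#'   speaker), `token_dur_s`, `amp_db` (dBFS), `exc_st` (named nucleus
#'   excursion per unit role, semitones), `slope` (named spectral power
#'   slope exponent per role; larger = steeper = less high-band energy),
#'   `am_db` (named amplitude-modulation depth per role, dB).
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_turns = 12L,
                       speakers = c(PAT = "patient", DOC = "interviewer"),
                       main_speaker = "PAT", interviewer = "DOC",
                       mean_ts_per_turn = 2,
                       p_ts_class = c(simple = 0.5, complex = 0.4,
                                      stanza = 0.1),
                       p_top = 0.5, p_apc = 0.2,
                       mean_ts_words = 6.5,
                       retracing = list(episode_rate = 0.09,
                                        chain_fraction = 0.25,
                                        position_weights =
                                          c(start_of_ts = 0.13,
                                            start_of_iu_inside_ts = 0.47,
                                            inside_ts = 0.40)),
                       pauses = list(
                         T = list(p = 0.5,
                                  bin_weights = c(0.1, 0.3, 0.35, 0.25)),
                         UT = list(p = 0.35,
                                   bin_weights = c(0.2, 0.35, 0.3, 0.15)),
                         IU = list(p = 0.25,
                                   bin_weights = c(0.4, 0.35, 0.2, 0.05))),
                       audio = list(rate = 16000,
                                    f0_base = c(PAT = 110, DOC = 180),
                                    token_dur_s = 0.2,
                                    amp_db = -12,
                                    exc_st = c(COM = 2.5, TOP = 2.5,
                                               other = 0.5),
                                    slope = c(COM = 1.5, TOP = 1.5,
                                              other = 1.5),
                                    am_db = c(COM = 1, TOP = 1,
                                              other = 0.5))) {
  stopifnot(abs(sum(p_ts_class) - 1) < 1e-9,
            all(p_ts_class >= 0), p_top >= 0, p_top <= 1,
            p_apc >= 0, p_apc <= 1)
  if (sum(p_ts_class) <= 0)
    stop_prosopath("degenerate spec: all class probabilities zero",
                   "prosopath_synth_error")
  structure(list(seed = as.integer(seed), n_turns = as.integer(n_turns),
                 speakers = speakers, main_speaker = main_speaker,
                 interviewer = interviewer,
                 mean_ts_per_turn = mean_ts_per_turn,
                 p_ts_class = p_ts_class, p_top = p_top, p_apc = p_apc,
                 mean_ts_words = mean_ts_words, retracing = retracing,
                 pauses = pauses, audio = audio),
            class = "synth_spec")
}

# draw words for one TS so that the expected total equals mean_ts_words
draw_ts_words <- function(n_units, mean_ts_words) {
  extra <- if (mean_ts_words > n_units)
    stats::rpois(1, mean_ts_words - n_units) else 0L
  total <- n_units + extra
  # spread the extras over units, each unit keeps >= 1 word
  alloc <- rep(1L, n_units)
  if (extra > 0L) {
    add <- table(sample.int(n_units, extra, replace = TRUE))
    alloc[as.integer(names(add))] <- alloc[as.integer(names(add))] +
      as.integer(add)
  }
  alloc
}

# build the token df of one unit, planting a retracing event if asked
build_unit_tokens <- function(n_words, plant = NULL) {
  words <- sample(synth_lexicon, n_words, replace = TRUE)
  df <- new_token_df(surface = words,
                     is_retracted = rep(FALSE, n_words),
                     is_fragment = rep(FALSE, n_words),
                     retr_group = rep(NA_integer_, n_words))
  if (is.null(plant)) return(df)
  p <- plant$token_index       # repair token the episodes copy
  n_ep <- plant$n_episodes
  ins <- new_token_df(surface = rep(words[p], n_ep),
                      is_retracted = rep(TRUE, n_ep),
                      is_fragment = rep(FALSE, n_ep),
                      retr_group = seq_len(n_ep))
  out <- rbind(if (p > 1L) df[seq_len(p - 1L), ] else NULL,
               ins, df[p:n_words, ])
  rownames(out) <- NULL
  out
}

#' Generate a synthetic transcript with ground truth
#'
#' @param spec a `synth_spec`.
#' @return list with elements `transcript` (parsed object), `text`
#'   (CHAT-LABLITA lines), and `truth` (list of data.frames: `ts` with
#'   one row per terminated sequence carrying turn index, speaker, class,
#'   semantic words, Topic/Appendix flags; `units` one row per
#'   information unit; `episodes` one row per planted retracing event).
#' @export
gen_transcript <- function(spec) {
  with_seed(spec$seed, gen_transcript_impl(spec))
}

gen_transcript_impl <- function(spec) {
  turns <- list()
  ts_rows <- list(); unit_rows <- list(); ep_rows <- list()
  ts_idx <- 0L
  pw <- spec$retracing$position_weights
  for (ti in seq_len(spec$n_turns)) {
    is_main <- ti %% 2L == 0L
    spk <- if (is_main) spec$main_speaker else spec$interviewer
    n_ts <- if (is_main)
      1L + stats::rpois(1, max(0, spec$mean_ts_per_turn - 1)) else 1L
    seqs <- list()
    for (si in seq_len(n_ts)) {
      ts_idx <- ts_idx + 1L
      if (!is_main) {
        units <- list(new_unit(build_unit_tokens(
          1L + stats::rpois(1, 2)), tag = "COM", tag_explicit = TRUE,
          trailing_boundary = "terminal"))
        cls <- "simple"; has_top <- FALSE; has_apc <- FALSE
      } else {
        cls <- sample(names(spec$p_ts_class), 1, prob = spec$p_ts_class)
        has_top <- FALSE; has_apc <- FALSE
        tags <- switch(cls,
          simple = "COM",
          complex = {
            has_top <- stats::runif(1) < spec$p_top
            has_apc <- stats::runif(1) < spec$p_apc
            tg <- c(if (has_top) "TOP", "COM",
                    if (!has_top && !has_apc) "PAR",
                    if (has_apc) "APC")
            tg
          },
          stanza = {
            has_top <- stats::runif(1) < spec$p_top
            has_apc <- stats::runif(1) < spec$p_apc
            c(if (has_top) "TOP",
              rep("COB", 2L + stats::rpois(1, 1)),
              if (has_apc) "APC")
          })
        alloc <- draw_ts_words(length(tags), spec$mean_ts_words)
        units <- vector("list", length(tags))
        for (ui in seq_along(tags)) {
          plant <- NULL
          if (stats::runif(1) < spec$retracing$episode_rate) {
            feas <- if (ui == 1L) c("start_of_ts", "inside_ts")
                    else c("start_of_iu_inside_ts", "inside_ts")
            if (alloc[ui] < 2L) feas <- setdiff(feas, "inside_ts")
            w <- pw[feas]
            pos <- if (sum(w) > 0) sample(feas, 1, prob = w)
                   else feas[1]
            tok_i <- if (pos == "inside_ts") {
              cand <- 2:alloc[ui]
              cand[sample.int(length(cand), 1)]
            } else 1L
            is_chain <- stats::runif(1) < spec$retracing$chain_fraction
            n_ep <- if (is_chain) 2L + stats::rbinom(1, 1, 0.3) else 1L
            plant <- list(token_index = tok_i, n_episodes = n_ep)
            ep_rows[[length(ep_rows) + 1L]] <- data.frame(
              ts_index = ts_idx, unit_index = ui, position = pos,
              n_episodes = n_ep, is_chain = is_chain,
              stringsAsFactors = FALSE)
          }
          units[[ui]] <- new_unit(
            build_unit_tokens(alloc[ui], plant),
            tag = tags[ui], tag_explicit = TRUE,
            trailing_boundary = if (ui == length(tags)) "terminal"
                                else "non_terminal")
        }
      }
      n_words <- sum(vapply(units, function(u)
        sum(!u$tokens$is_retracted & !u$tokens$is_fragment), integer(1)))
      ts_rows[[ts_idx]] <- data.frame(
        ts_index = ts_idx, turn = ti, speaker = spk, class = cls,
        n_units = length(units), n_words = n_words,
        has_top = has_top, has_apc = has_apc, stringsAsFactors = FALSE)
      for (ui in seq_along(units))
        unit_rows[[length(unit_rows) + 1L]] <- data.frame(
          ts_index = ts_idx, unit_index = ui,
          tag = units[[ui]]$tag,
          n_tokens = nrow(units[[ui]]$tokens), speaker = spk,
          turn = ti, stringsAsFactors = FALSE)
      seqs[[si]] <- new_ts(units, spk)
    }
    turns[[ti]] <- new_turn(spk, seqs)
  }
  tr <- new_transcript(turns, spec$speakers)
  empty_eps <- data.frame(ts_index = integer(), unit_index = integer(),
                          position = character(), n_episodes = integer(),
                          is_chain = logical(), stringsAsFactors = FALSE)
  truth <- list(ts = do.call(rbind, ts_rows),
                units = do.call(rbind, unit_rows),
                episodes = if (length(ep_rows) > 0)
                  do.call(rbind, ep_rows) else empty_eps)
  list(transcript = tr, text = serialize_transcript(tr), truth = truth)
}

draw_gap_ms <- function(bin_weights) {
  # uniform inside the bin, at least two detection hops (20 ms) away from
  # every edge so edge slack cannot flip the assigned bin
  ranges <- list(c(172, 248), c(272, 498), c(522, 998), c(1022, 2200))
  b <- sample.int(4L, 1, prob = bin_weights)
  stats::runif(1, ranges[[b]][1], ranges[[b]][2])
}

render_unit_audio <- function(n_tokens, role, speaker, spec) {
  au <- spec$audio
  sr <- au$rate
  dur <- n_tokens * au$token_dur_s
  n <- round(dur * sr)
  tt <- seq_len(n) / sr
  base <- au$f0_base[[speaker]] * 2^(stats::runif(1, -0.5, 0.5) / 12)
  role_key <- if (role %in% names(au$exc_st)) role else "other"
  exc <- au$exc_st[[role_key]]
  # rise-peak-fall in semitones, minima at the unit edges
  f0_t <- base * 2^(exc * sin(pi * tt / dur) / 12)
  phase <- 2 * pi * cumsum(f0_t) / sr
  alpha <- au$slope[[role_key]]
  amp_k <- (1:5)^(-alpha / 2)
  amp_k <- amp_k / sqrt(sum(amp_k^2))
  sig <- rep(0, n)
  for (k in 1:5) sig <- sig + amp_k[k] * sin(k * phase)
  am <- au$am_db[[role_key]]
  env <- 10^((am * sin(2 * pi * tt / 0.25)) / 20)
  sig <- sig * env * 10^(au$amp_db / 20)
  ramp_n <- min(n %/% 2, round(0.005 * sr))
  if (ramp_n > 0) {
    r <- seq(0, 1, length.out = ramp_n)
    sig[seq_len(ramp_n)] <- sig[seq_len(ramp_n)] * r
    sig[(n - ramp_n + 1L):n] <- sig[(n - ramp_n + 1L):n] * rev(r)
  }
  list(samples = sig, f0_t = f0_t)
}

#' Render synthetic audio, alignment and prominence spans
#'
#' Each information unit becomes a harmonic complex (five partials with
#' the role's spectral slope) carrying a rise-peak-fall f0 contour; one
#' syllable interval is emitted per token. Silent gaps are planted at
#' turn-taking, between terminated sequences and between units according
#' to the spec's pause parameters; the alignment tiers reflect the
#' rendering times exactly.
#'
#' @param spec a `synth_spec`.
#' @param gen output of [gen_transcript()] for the same spec.
#' @return list: `audio` (an `audio_signal`), `alignment` (an
#'   `alignment_tier` with tiers turn/ts/iu plus `syllable` and
#'   `prominence`), `spans` (prominence span table), and `truth`
#'   (data.frames `gaps` - planted and unplanted pause opportunities with
#'   durations - and `spans` with per-span f0 mean/sd ground truth).
#' @export
gen_audio <- function(spec, gen) {
  if (spec$audio$rate < 8000)
    stop_prosopath("audio rate below 8 kHz", "prosopath_synth_error")
  with_seed(spec$seed + 500009L, gen_audio_impl(spec, gen))
}

gen_audio_impl <- function(spec, gen) {
  sr <- spec$audio$rate
  units <- gen$truth$units
  ts_tab <- gen$truth$ts
  chunks <- list()
  cursor <- 0
  push <- function(x) {
    chunks[[length(chunks) + 1L]] <<- x
    cursor <<- cursor + length(x) / sr
  }
  iv <- list()
  add_iv <- function(tier, s, e, label)
    iv[[length(iv) + 1L]] <<- data.frame(tier = tier, start_s = s,
                                         end_s = e, label = label,
                                         stringsAsFactors = FALSE)
  gap_rows <- list(); span_rows <- list(); span_truth <- list()
  tracked <- names(spec$speakers)[spec$speakers != "interviewer"]
  prev_spk <- NULL
  for (ti in sort(unique(units$turn))) {
    tdf <- ts_tab[ts_tab$turn == ti, , drop = FALSE]
    spk <- tdf$speaker[1]
    if (!is.null(prev_spk)) {
      if (spk %in% tracked && prev_spk != spk) {
        planted <- stats::runif(1) < spec$pauses$T$p
        d <- if (planted) draw_gap_ms(spec$pauses$T$bin_weights) else 0
        if (d > 0) push(rep(0, round(d / 1000 * sr)))
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(position = "T", duration_ms = d, speaker = spk,
                     before_s = cursor, stringsAsFactors = FALSE)
      } else {
        push(rep(0, round(0.08 * sr)))  # sub-threshold articulation gap
      }
    }
    turn_start <- cursor
    for (si in seq_len(nrow(tdf))) {
      tsi <- tdf$ts_index[si]
      if (si > 1L) {
        planted <- stats::runif(1) < spec$pauses$UT$p
        d <- if (planted) draw_gap_ms(spec$pauses$UT$bin_weights) else 0
        if (d > 0) push(rep(0, round(d / 1000 * sr)))
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(position = "UT", duration_ms = d, speaker = spk,
                     before_s = cursor, stringsAsFactors = FALSE)
      }
      ts_start <- cursor
      udf <- units[units$ts_index == tsi, , drop = FALSE]
      for (ui in seq_len(nrow(udf))) {
        if (ui > 1L && spk %in% tracked) {
          planted <- stats::runif(1) < spec$pauses$IU$p
          d <- if (planted) draw_gap_ms(spec$pauses$IU$bin_weights) else 0
          if (d > 0) push(rep(0, round(d / 1000 * sr)))
          gap_rows[[length(gap_rows) + 1L]] <-
            data.frame(position = "IU", duration_ms = d, speaker = spk,
                       before_s = cursor, stringsAsFactors = FALSE)
        }
        unit_start <- cursor
        role <- udf$tag[ui]
        ra <- render_unit_audio(udf$n_tokens[ui], role, spk, spec)
        push(ra$samples)
        add_iv("iu", unit_start, cursor, role)
        for (k in seq_len(udf$n_tokens[ui]))
          add_iv("syllable",
                 unit_start + (k - 1L) * spec$audio$token_dur_s,
                 unit_start + k * spec$audio$token_dur_s, "syl")
        if (role %in% c("COM", "TOP") && spk %in% tracked) {
          span_rows[[length(span_rows) + 1L]] <- data.frame(
            speaker = spk, unit_role = role, start_s = unit_start,
            end_s = cursor, n_syllables = udf$n_tokens[ui],
            stringsAsFactors = FALSE)
          span_truth[[length(span_truth) + 1L]] <- data.frame(
            speaker = spk, unit_role = role,
            f0mean_hz = mean(ra$f0_t), f0sd_hz = sd_pop(ra$f0_t),
            stringsAsFactors = FALSE)
          add_iv("prominence", unit_start, cursor,
                 paste0(role, ":", udf$n_tokens[ui]))
        }
      }
      add_iv("ts", ts_start, cursor, tdf$class[si])
    }
    add_iv("turn", turn_start, cursor, spk)
    prev_spk <- spk
  }
  audio <- audio_signal(unlist(chunks), sr)
  align <- alignment_tier(do.call(rbind, iv))
  spans <- if (length(span_rows) > 0) do.call(rbind, span_rows)
           else data.frame(speaker = character(), unit_role = character(),
                           start_s = numeric(), end_s = numeric(),
                           n_syllables = integer())
  truth <- list(
    gaps = if (length(gap_rows) > 0) do.call(rbind, gap_rows)
           else data.frame(position = character(), duration_ms = numeric(),
                           speaker = character(), before_s = numeric()),
    spans = if (length(span_truth) > 0) do.call(rbind, span_truth)
            else data.frame(speaker = character(), unit_role = character(),
                            f0mean_hz = numeric(), f0sd_hz = numeric()))
  list(audio = audio, alignment = align, spans = spans, truth = truth)
}

#' Preset specs emulating the study regimes
#'
#' `"cipps-like"` mirrors the schizophrenic-interview profile: near-even
#' split of simple and complex TSs with few stanzas, shorter utterances,
#' frequent and long turn-taking pauses, elevated retracing with more
#' chains, a flatter Comment nucleus (small excursion, steep spectral
#' slope, shallow intensity modulation) but an effortful Topic.
#' `"control-like"` mirrors the non-pathological profile: more complex
#' TSs and stanzas, longer utterances, rare turn-taking silence, little
#' retracing, and a Comment nucleus livelier than the Topic.
#'
#' @param preset `"cipps-like"` or `"control-like"`.
#' @param seed integer seed.
#' @param n_turns number of turns.
#' @return a `synth_spec`.
#' @export
synth_preset <- function(preset = c("cipps-like", "control-like"),
                         seed = 1L, n_turns = 12L) {
  preset <- match.arg(preset)
  if (preset == "cipps-like") {
    synth_spec(
      seed = seed, n_turns = n_turns,
      speakers = c(PAT = "patient", DOC = "interviewer"),
      main_speaker = "PAT",
      p_ts_class = c(simple = 0.454, complex = 0.409, stanza = 0.137),
      p_top = 0.30, p_apc = 0.14, mean_ts_words = 5.7,
      retracing = list(episode_rate = 0.12, chain_fraction = 0.27,
                       position_weights = c(start_of_ts = 0.13,
                                            start_of_iu_inside_ts = 0.47,
                                            inside_ts = 0.40)),
      pauses = list(
        T = list(p = 0.74, bin_weights = c(0.07, 0.18, 0.30, 0.45)),
        UT = list(p = 0.42, bin_weights = c(0.15, 0.30, 0.35, 0.20)),
        IU = list(p = 0.31, bin_weights = c(0.40, 0.30, 0.20, 0.10))),
      audio = list(rate = 16000, f0_base = c(PAT = 100, DOC = 180),
                   token_dur_s = 0.2, amp_db = -12,
                   exc_st = c(COM = 1.5, TOP = 3.5, other = 0.5),
                   slope = c(COM = 1.9, TOP = 1.1, other = 1.5),
                   am_db = c(COM = 0.5, TOP = 1.2, other = 0.5)))
  } else {
    synth_spec(
      seed = seed, n_turns = n_turns,
      speakers = c(CTL = "control", DOC = "interviewer"),
      main_speaker = "CTL",
      p_ts_class = c(simple = 0.314, complex = 0.464, stanza = 0.222),
      p_top = 0.60, p_apc = 0.09, mean_ts_words = 8.8,
      retracing = list(episode_rate = 0.05, chain_fraction = 0.18,
                       position_weights = c(start_of_ts = 0.13,
                                            start_of_iu_inside_ts = 0.47,
                                            inside_ts = 0.40)),
      pauses = list(
        T = list(p = 0.28, bin_weights = c(0.25, 0.35, 0.30, 0.10)),
        UT = list(p = 0.30, bin_weights = c(0.30, 0.35, 0.25, 0.10)),
        IU = list(p = 0.21, bin_weights = c(0.45, 0.35, 0.15, 0.05))),
      audio = list(rate = 16000, f0_base = c(CTL = 115, DOC = 180),
                   token_dur_s = 0.2, amp_db = -12,
                   exc_st = c(COM = 3.5, TOP = 2.0, other = 0.5),
                   slope = c(COM = 1.1, TOP = 1.6, other = 1.5),
                   am_db = c(COM = 1.5, TOP = 0.8, other = 0.5)))
  }
}

#' Generate a paired patient-like / control-like corpus
#'
#' @param spec_patient,spec_control two `synth_spec`s (defaults: the two
#'   presets with the given seed).
#' @param seed seed used when the default presets are taken.
#' @param with_audio also render audio for both corpora.
#' @return list with elements `patient` and `control`, each the output
#'   of [gen_transcript()] (plus `audio`, `alignment`, `spans`,
#'   `audio_truth` when `with_audio`).
#' @export
gen_patient_vs_control <- function(spec_patient = NULL, spec_control = NULL,
                                   seed = 1L, n_turns = 24L,
                                   with_audio = FALSE) {
  if (is.null(spec_patient))
    spec_patient <- synth_preset("cipps-like", seed = seed,
                                 n_turns = n_turns)
  if (is.null(spec_control))
    spec_control <- synth_preset("control-like", seed = seed + 1L,
                                 n_turns = n_turns)
  out <- list()
  for (side in c("patient", "control")) {
    sp <- if (side == "patient") spec_patient else spec_control
    g <- gen_transcript(sp)
    if (with_audio) {
      a <- gen_audio(sp, g)
      g$audio <- a$audio; g$alignment <- a$alignment
      g$spans <- a$spans; g$audio_truth <- a$truth
    }
    out[[side]] <- g
  }
  out
}
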