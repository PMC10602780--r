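#' @title Prominence acoustics
#'
#' @description
#' The nucleus of a Comment (root contour) or Topic (prefix contour) unit
#' is the minimal rise-peak-fall f0 movement sufficient to perform the
#' unit's information function. Four acoustic indices are computed on
#' each annotated nucleus span: f0 mean and f0 standard deviation (in Hz,
#' and in semitones converted per frame before averaging), spectral
#' emphasis (full-band minus low-band level, a vocal-effort proxy), and
#' the coefficient of intensity variation (100 x sd / mean of the dB
#' intensity contour).
#'
#' @name prominence
NULL

#' Extract an f0 track by autocorrelation
#'
#' Per-frame normalized autocorrelation with parabolic peak
#' interpolation; frames whose peak correlation falls below
#' `voicing_threshold`, whose best candidate lies outside
#' `[floor_hz, ceil_hz]`, or whose energy is negligible are unvoiced.
#'
#' @param audio an `audio_signal`.
#' @param span optional `c(start_s, end_s)` restricting analysis.
#' @param floor_hz,ceil_hz pitch search range in Hz.
#' @param frame_ms analysis window (default three periods of `floor_hz`).
#' @param hop_ms hop in ms.
#' @param voicing_threshold minimum normalized autocorrelation for a
#'   frame to count as voiced.
#' @return data.frame of class `f0_track` with columns `time` (s, frame
#'   centre) and `f0` (Hz, `NA` when unvoiced).
#' @export
extract_f0 <- function(audio, span = NULL, floor_hz = 50, ceil_hz = 300,
                       frame_ms = NULL, hop_ms = 10,
                       voicing_threshold = 0.45) {
  if (!is.null(span)) audio <- audio_slice(audio, span[1], span[2])
  t0 <- if (is.null(span)) 0 else max(0, span[1])
  sr <- audio$rate
  if (is.null(frame_ms)) frame_ms <- 3000 / floor_hz
  flen <- round(frame_ms / 1000 * sr)
  hop <- max(1L, round(hop_ms / 1000 * sr))
  x <- audio$samples
  n <- length(x)
  lag_min <- max(2L, floor(sr / ceil_hz))
  lag_max <- ceiling(sr / floor_hz)
  if (flen <= lag_max + 2L || n < flen)
    return(structure(data.frame(time = numeric(), f0 = numeric()),
                     class = c("f0_track", "data.frame")))
  starts <- seq(1L, n - flen + 1L, by = hop)
  peak_rms <- sqrt(max(0, mean(x^2)))
  times <- (starts - 1L + flen / 2) / sr + t0
  f0 <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    fr <- x[starts[k]:(starts[k] + flen - 1L)]
    fr <- fr - mean(fr)
    e0 <- sum(fr^2)
    if (e0 < (1e-4 * peak_rms)^2 * flen || e0 == 0) next
    # normalized autocorrelation via FFT
    m <- stats::nextn(2L * flen, 2)
    sp <- stats::fft(c(fr, rep(0, m - flen)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / m
    ac <- ac / ac[1]
    lags <- lag_min:min(lag_max, flen - 1L)
    seg <- ac[lags + 1L]
    i <- which.max(seg)
    r <- seg[i]
    if (is.na(r) || r < voicing_threshold) next
    lag <- lags[i]
    # parabolic interpolation around the peak for sub-sample accuracy
    if (lag > lag_min && lag < max(lags)) {
      y1 <- ac[lag]; y2 <- ac[lag + 1L]; y3 <- ac[lag + 2L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) {
        delta <- 0.5 * (y1 - y3) / denom
        if (abs(delta) <= 1) lag <- lag + delta
      }
    }
    cand <- sr / lag
    if (cand >= floor_hz && cand <= ceil_hz) f0[k] <- cand
  }
  structure(data.frame(time = times, f0 = f0),
            class = c("f0_track", "data.frame"))
}

#' Convert frequency to semitones
#'
#' 12 x log2(f / ref): the logarithmic pitch scale with 12 units per
#' octave relative to `ref_hz` (default 1 Hz, so absolute semitones).
#'
#' @param f frequencies in Hz (must be positive).
#' @param ref_hz reference frequency in Hz.
#' @return semitone values.
#' @export
hz_to_semitones <- function(f, ref_hz = 1) {
  if (any(!is.na(f) & f <= 0) || ref_hz <= 0)
    stop_prosopath("frequencies must be positive for semitone conversion",
                   "prosopath_acoustics_error")
  12 * log2(f / ref_hz)
}

smooth_track <- function(f0, hop_s = 0.01, win_s = 0.02) {
  v <- f0
  # 3-point running median (octave-error spikes), then short moving average
  if (length(v) >= 3L)
    v <- stats::runmed(v, 3, endrule = "keep")
  k <- max(1L, round(win_s / hop_s))
  if (k > 1L && length(v) >= k)
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
  out <- as.numeric(v)
  out[is.na(out)] <- f0[is.na(out)]
  out
}

#' Select the nucleus span of a prominence
#'
#' Locates the largest rise-peak-fall movement of the smoothed f0 track
#' (peak = global maximum; rise start = preceding local minimum; fall
#' end = following local minimum) and snaps it to syllable boundaries,
#' optionally padded by up to two syllables on each side - the
#' convention that preserves the semantic unity of the nucleus without
#' extending it past two syllables before the rise or after the fall.
#' A track with no interior peak falls back to the longest voiced run,
#' flagged via the `flagged` attribute.
#'
#' @param f0 an `f0_track`.
#' @param syllables data.frame with columns `start_s`, `end_s`, one row
#'   per syllable, covering the unit.
#' @param pad_syllables extra syllables included on each side (0-2).
#' @return list with `start_s`, `end_s`, `syllable_range` (indices) and
#'   attribute `flagged` (TRUE for the degenerate fallback).
#' @export
select_nucleus_span <- function(f0, syllables, pad_syllables = 0) {
  pad_syllables <- min(2L, max(0L, as.integer(pad_syllables)))
  voiced <- which(!is.na(f0$f0))
  if (length(voiced) == 0L)
    stop_prosopath("no voiced frames in span", "prosopath_acoustics_error")
  hop <- if (nrow(f0) > 1L) stats::median(diff(f0$time)) else 0.01
  sm <- rep(NA_real_, nrow(f0))
  sm[voiced] <- smooth_track(f0$f0[voiced], hop_s = hop)
  peak <- which.max(sm)
  flagged <- FALSE
  # walk outward to the local minima bounding the movement, tolerating
  # estimation ripple: a step counts as descent only when it goes at
  # least `tol` below the running minimum, and the walk gives up after
  # eight frames (80 ms at the default hop) without further descent
  tol <- max(0.3, 0.01 * diff(range(sm, na.rm = TRUE)))
  descend <- function(from, dir) {
    lo <- from; j <- from + dir; stall <- 0L
    while (j >= 1L && j <= length(sm) && !is.na(sm[j]) && stall < 8L) {
      if (sm[j] < sm[lo] - tol) {
        lo <- j; stall <- 0L
      } else {
        stall <- stall + 1L
      }
      j <- j + dir
    }
    lo
  }
  left <- descend(peak, -1L)
  right <- descend(peak, 1L)
  if (left == peak && right == peak) {
    # flat or single-frame track: longest voiced run
    flagged <- TRUE
    r <- rle(!is.na(f0$f0))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    left <- starts[best]; right <- ends[best]
  } else if (left == peak || right == peak) {
    # monotone movement only: take the maximal monotone stretch
    flagged <- TRUE
  }
  t_left <- f0$time[left]; t_right <- f0$time[right]
  syl_of <- function(tt) {
    i <- which(syllables$start_s - 1e-9 <= tt & tt <= syllables$end_s + 1e-9)
    if (length(i) == 0L) i <- which.min(pmin(abs(syllables$start_s - tt),
                                             abs(syllables$end_s - tt)))
    i[1]
  }
  s1 <- max(1L, syl_of(t_left) - pad_syllables)
  s2 <- min(nrow(syllables), syl_of(t_right) + pad_syllables)
  structure(list(start_s = syllables$start_s[s1],
                 end_s = syllables$end_s[s2],
                 syllable_range = c(s1, s2)),
            flagged = flagged)
}

#' Spectral emphasis of a span
#'
#' Full-band minus low-band sound level on the span's power spectrum,
#' with the low band `[0, cutoff]`. The default cutoff follows the
#' f0-proportional convention, 1.43 x the span's median f0, falling back
#' to a fixed 400 Hz when the span is unvoiced. Higher values mean more
#' energy above the voicing fundamental: greater vocal effort.
#'
#' @param audio an `audio_signal`.
#' @param span optional `c(start_s, end_s)`.
#' @param cutoff_policy `"auto"` (f0-proportional) or a fixed frequency
#'   in Hz.
#' @param ... passed to [extract_f0()] when the cutoff is automatic.
#' @return emphasis in dB.
#' @export
spectral_emphasis <- function(audio, span = NULL, cutoff_policy = "auto",
                              ...) {
  if (!is.null(span)) audio <- audio_slice(audio, span[1], span[2])
  x <- audio$samples
  if (sum(x^2) == 0)
    stop_prosopath("silent span has no spectral energy",
                   "prosopath_acoustics_error")
  if (identical(cutoff_policy, "auto")) {
    f0 <- extract_f0(audio, ...)
    med <- stats::median(f0$f0, na.rm = TRUE)
    cutoff <- if (is.na(med)) 400 else 1.43 * med
  } else {
    cutoff <- as.numeric(cutoff_policy)
  }
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1L) / n * audio$rate
  half <- freq <= audio$rate / 2
  p_full <- sum(spec[half])
  p_low <- sum(spec[half & freq <= cutoff])
  p_low <- max(p_low, p_full * 1e-12)
  10 * log10(p_full / p_low)
}

#' Coefficient of intensity variation
#'
#' 100 x population standard deviation / mean of the dB intensity
#' contour over a span. Scale-invariant on the contour; zero for a
#' constant contour; higher values mean a livelier intensity modulation.
#'
#' @param intensity an `intensity_track` (columns `time`, `db`).
#' @param span optional `c(start_s, end_s)`.
#' @return dimensionless coefficient (x100).
#' @export
cv_intensity <- function(intensity, span = NULL) {
  v <- intensity$db
  if (!is.null(span))
    v <- v[intensity$time >= span[1] - 1e-9 & intensity$time <= span[2] + 1e-9]
  if (length(v) < 2L)
    stop_prosopath("need at least two intensity frames in span",
                   "prosopath_acoustics_error")
  m <- mean(v)
  if (m <= 0)
    stop_prosopath("non-positive mean intensity; re-reference the contour",
                   "prosopath_acoustics_error")
  100 * sd_pop(v) / m
}

#' Acoustic profile of one prominence span
#'
#' f0 statistics are computed over voiced frames; Hz statistics on the
#' Hz values and semitone statistics on per-frame converted values (not
#' a conversion of the Hz mean - the two differ whenever f0 varies).
#' Spectral emphasis and the intensity-variation coefficient are always
#' computed, even when the span is unvoiced (f0 fields are then `NA`).
#'
#' @param audio an `audio_signal`.
#' @param span `c(start_s, end_s)` or a list with `start_s`/`end_s`.
#' @param ref_hz semitone reference in Hz.
#' @param cutoff_policy see [spectral_emphasis()].
#' @param floor_hz,ceil_hz pitch range passed to [extract_f0()].
#' @return one-row data.frame of class `prominence_acoustics` with
#'   columns `f0mean_hz`, `f0mean_st`, `f0sd_hz`, `f0sd_st`, `emph_db`,
#'   `cvint`, `n_voiced`.
#' @export
prominence_profile <- function(audio, span, ref_hz = 1,
                               cutoff_policy = "auto",
                               floor_hz = 50, ceil_hz = 300) {
  if (is.list(span)) span <- c(span$start_s, span$end_s)
  f0 <- extract_f0(audio, span, floor_hz = floor_hz, ceil_hz = ceil_hz)
  v <- f0$f0[!is.na(f0$f0)]
  if (length(v) > 0L) {
    st <- hz_to_semitones(v, ref_hz)
    f0mean_hz <- mean(v); f0sd_hz <- sd_pop(v)
    f0mean_st <- mean(st); f0sd_st <- sd_pop(st)
  } else {
    f0mean_hz <- f0sd_hz <- f0mean_st <- f0sd_st <- NA_real_
  }
  emph <- spectral_emphasis(audio, span, cutoff_policy,
                            floor_hz = floor_hz, ceil_hz = ceil_hz)
  itr <- intensity_track(audio_slice(audio, span[1], span[2]))
  cv <- cv_intensity(itr)
  structure(data.frame(f0mean_hz = f0mean_hz, f0mean_st = f0mean_st,
                       f0sd_hz = f0sd_hz, f0sd_st = f0sd_st,
                       emph_db = emph, cvint = cv,
                       n_voiced = length(v)),
            class = c("prominence_acoustics", "data.frame"))
}

#' Profile every annotated prominence span
#'
#' @param audio an `audio_signal`.
#' @param spans data.frame with columns `speaker`, `unit_role`
#'   (`"COM"`/`"TOP"`), `start_s`, `end_s` and optionally `n_syllables`.
#' @param ... passed to [prominence_profile()].
#' @return the spans table with the acoustic columns appended.
#' @export
prominence_profiles <- function(audio, spans, ...) {
  prof <- lapply(seq_len(nrow(spans)), function(i)
    prominence_profile(audio, c(spans$start_s[i], spans$end_s[i]), ...))
  cbind(spans, do.call(rbind, prof))
}

#' Group summary of prominence acoustics
#'
#' Per-speaker and pooled means of the acoustic indices, separately for
#' Comment and Topic prominences. Pooled rows are prominence-weighted
#' (the mean over all prominences, not over speaker means).
#'
#' @param profiles data.frame as returned by [prominence_profiles()].
#' @param groups optional named vector speaker -> group; when given, one
#'   pooled row per group is produced, otherwise a single `ALL` row.
#' @return data.frame with columns `group`, `speaker`, `unit_role`, `n`,
#'   and the mean of each acoustic index.
#' @export
group_summary <- function(profiles, groups = NULL) {
  metrics <- c("f0mean_hz", "f0mean_st", "f0sd_hz", "f0sd_st",
               "emph_db", "cvint")
  if (is.null(groups))
    groups <- stats::setNames(rep("ALL", length(unique(profiles$speaker))),
                              unique(profiles$speaker))
  profiles$group <- unname(groups[profiles$speaker])
  rows <- list()
  summarize <- function(df, group, speaker, role) {
    row <- data.frame(group = group, speaker = speaker, unit_role = role,
                      n = nrow(df))
    for (m in metrics) row[[m]] <- mean(df[[m]], na.rm = TRUE)
    row
  }
  for (role in unique(profiles$unit_role)) {
    pr <- profiles[profiles$unit_role == role, , drop = FALSE]
    for (spk in unique(pr$speaker)) {
      d <- pr[pr$speaker == spk, , drop = FALSE]
      rows[[length(rows) + 1L]] <- summarize(d, d$group[1], spk, role)
    }
    for (g in unique(pr$group)) {
      d <- pr[pr$group == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <- summarize(d, g, "POOLED", role)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
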