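---
title: "Profiling spontaneous speech at the prosody/pragmatics interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling spontaneous speech at the prosody/pragmatics interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosopath)
```

## The analysis model

L-AcT (Language into Act Theory) takes the utterance as the reference
unit of spoken language: a stretch of speech performing one speech act,
delimited by a perceptually terminal prosodic boundary. prosopath
operates on corpora annotated in this frame (CHAT-LABLITA format) and
assumes the segmentation itself — terminal `//` and non-terminal `/`
boundaries, `^TAG^` unit labels, `* … [/]` retracing marks — has been
produced by human annotators. The package never re-derives perceptual
judgments from audio; it quantifies what the annotation plus the
time-aligned signal contain. That division of labour mirrors how such
corpora are actually built: segmentation is perceptual, measurement is
automatic.

The parsed hierarchy is Transcript → Turn → Terminated sequence (TS) →
Information unit → Token. Three parsing conventions deserve note, since
the format leaves them open:

* **Scansion attaches forward.** An untagged `/`-chunk is prosodic
  scansion of the unit that follows; its tokens merge into the next
  explicitly tagged unit. Tags in CHAT-LABLITA are suffixed to the
  boundary that closes the unit, so the text a tag labels precedes it.
* **A TS without an explicit COM/COB gets an inferred Comment.** An
  utterance must carry an illocution, and the unit closed by the
  terminal boundary is its natural bearer. The inferred tag is not
  re-serialized, which keeps parse ∘ serialize an identity on structure.
* **Open tag vocabulary.** COM/COB/TOP/APC are first-class; any other
  label (PAR, INT, …) is preserved untouched, so corpora using the
  fuller L-AcT tagset still parse.

TS classification is: stanza iff the TS contains a Bound Comment (COB);
otherwise simple iff it consists of one tagged unit (absorbed scansion
chunks do not make it complex — units are functional, not
breath-groups); otherwise complex. Stanza takes precedence because the
published count tables treat the three classes as a partition.

MLU counts, by default, the words contributing to semantic content:
retracted tokens and word fragments (leading `&`) are excluded, fillers
kept. The policy is configurable (`"semantic"`, `"non_retracted"`,
`"all"`) because published token totals and MLU values based on the
same material can differ — raw token counts include repairs that a
semantic count drops. Group comparisons use the Kruskal–Wallis mid-rank
test (via `stats::kruskal.test`), reported unadjusted; the degenerate
all-equal case is mapped to H = 0, p = 1.

## Pauses

Silence detection reproduces the Praat sounding/silent recipe: RMS
intensity on 25 ms frames at a 10 ms hop; frames more than 25 dB below
the file's maximum are silent; adjacent silent frames merge; intervals
shorter than 150 ms (about one stop closure) are dropped. Edge accuracy
is one hop per edge, which is why the synthetic generator plants gap
durations at least two hops away from the bin edges 250/500/1000 ms.
Durations are floored to integer ms to match the integer bin
definitions (150–250, 251–500, 501–1000, > 1000). There is no upper
duration cap: clinically interesting pauses can run to tens of seconds.

Position classification assigns a silence by its midpoint to the
annotated gap it falls into: `T` when the gap separates two turns by
different speakers *and* the following turn belongs to a tracked
(non-interviewer) speaker — only the pause before the turn is an index
of the speaker's reaction time, so pauses before interviewer turns are
excluded; `UT` between two TS spans of one turn; `IU` between two unit
spans of one TS; `excluded` otherwise. The midpoint rule makes the
annotated gap, not frame accidents at its edges, decide the class.
`pause_profile()` counts *opportunities* (turn starts, adjacent TS
pairs, adjacent unit pairs), so "no pause" percentages are well defined;
when several detections fall in one gap the longest is taken. A
hand-edited silence table can override detection, standing in for the
manual revision pass such studies apply.

## Retracing

Each `* … [/]` group is one episode; adjacent groups with no
non-retracted token between them form a chain — one restart event whose
members all inherit the first episode's position. Position is
`start_of_ts` (unit 1, token 1), `start_of_iu_inside_ts` (token 1 of a
later unit), else `inside_ts`; the contrast is unit-initial versus
ongoing locution. Kind compares the retracted tokens with the same
number of repair tokens that follow the event: all equal → total
repetition; at least one fragment-stripped token a prefix of its repair
counterpart → partial repetition; otherwise modification. The
prefix-on-any-token rule is deliberate: restarts that share material
mid-sequence ("s' era" → "gl' eran") read as partial repetition, while
a pure morphological swap ("le" → "il") reads as modification.

Rates divide single-episode and chain counts by the number of
information units containing no retracing at all ("not retracted
units"), per TS type; a chain counts once — never additionally as
singles — both here and in the positional distribution. Zero
denominators yield absent (NA) rates rather than zeros.

## Prominence acoustics

f0 is extracted by normalized autocorrelation (window three periods of
the 50 Hz floor, 10 ms hop, parabolic peak interpolation, voicing
threshold 0.45); the biased estimator naturally discounts longer lags,
which suppresses subharmonic octave errors. Accuracy on harmonic
material is well under 2 Hz across 80–250 Hz.

Two conventions are resolved explicitly because published (Hz, st)
value pairs cannot be reproduced by any single conversion of the Hz
mean:

* **Semitones are converted per frame, then averaged**, with a 1 Hz
  reference by default (both configurable). Per-frame conversion and
  conversion-of-the-mean differ whenever f0sd > 0; the per-frame policy
  is the one consistent with scripts that aggregate a semitone track.
* **cvint = 100 · sd/mean** on the dB contour. Verbal descriptions of
  this coefficient sometimes invert the ratio; the conventional
  coefficient of variation places sd in the numerator, and only that
  orientation makes "higher cvint = livelier intensity" read correctly.

Within-span statistics use the population (n) standard deviation: the
frames of a span are the whole population of interest, not a sample.
Spectral emphasis is full-band minus low-band SPL with an
f0-proportional cutoff (1.43 × span median f0), falling back to a fixed
400 Hz on unvoiced spans; it is gain-invariant and non-negative up to
numerical tolerance. Nucleus-span selection smooths the track (3-point
median, then a 20 ms moving average against octave-error spikes), takes
the global maximum as the peak, walks outward to the bounding local
minima — tolerating up to 80 ms of estimation ripple, with a descent
threshold of max(0.3 Hz, 1 % of the track range) — and snaps to
syllable boundaries, with optional padding clamped at two syllables per
side (the convention that preserves the semantic unity of the nucleus).
Monotone or flat tracks fall back, flagged, to the maximal movement or
the longest voiced run. Pooled summary rows are prominence-weighted,
not speaker-weighted: a pooled mean over all measured prominences is
what a flat table of per-prominence measurements aggregates to.

## The synthetic generator

`synth_spec()` fixes the generative truth: TS-class probabilities,
TOP/APC probabilities per non-simple TS, mean words per TS, retracing
episode/chain rates with position weights, per-position pause
probabilities with duration-bin weights, and the rendering parameters
(base f0 per speaker, nucleus excursion in semitones, spectral slope,
amplitude-modulation depth). All draws come from one seeded stream per
corpus; a fixed seed yields byte-identical text, audio and alignment.

Audio is rendered as harmonic complexes — five partials with a
configurable power slope — because every measured quantity (f0, band
energies, intensity contour, silent gaps) is fully determined by that
model; no formant or naturalistic synthesis is attempted. One syllable
interval is emitted per token, avoiding a syllabifier. Units carrying
prominence get a rise–peak–fall contour with minima at the unit edges.

The presets encode the two study regimes. The `"cipps-like"` preset
uses class probabilities (0.454, 0.409, 0.137), shorter utterances
(5.7 words/TS), frequent long turn-taking pauses (pause probability
0.74, mass on the long bins), elevated retracing (0.12 events/unit,
27 % chains), and a flat Comment nucleus (1.5 st excursion, steep
spectral slope, shallow AM) against an effortful Topic. The
`"control-like"` preset inverts each contrast (0.314, 0.464, 0.222;
8.8 words/TS; turn-taking pause probability 0.28; 0.05 events/unit; a
Comment livelier than the Topic). These values were chosen once, to
match the published corpus profiles, and are not tuned.

What passing tests on this material do and do not show: the generator
exercises the full annotation grammar, exact alignment, and clean
harmonic sources, so it validates the *measurement machinery* —
parsing, counting, detection, classification, spectral arithmetic — at
known truth. It does not contain overlapping speech, background noise,
microphone variation, creaky or breathy voice, imperfect alignment, or
annotator disagreement; recovery on synthetic corpora therefore bounds
algorithmic error, not field error on real recordings. Reproducing the
published corpus-level acoustic values would require the original
audio, which is not packaged; those comparisons are deliberately out of
scope, and the package instead verifies the qualitative orderings the
two regimes plant (more turn-taking silence, more chains, weaker
Comment emphasis, Topic > Comment acoustics in the patient-like
corpus).

## Validation sizes and numerical choices

The test suite runs round-trip parsing over 100 seeded corpora,
null-calibrates the Kruskal–Wallis wrapper over 60 seed pairs
(KS test against uniform p-values), recovers planted parameters on a
~2,000-TS corpus (binomial bounds: ±3.5 points on class percentages,
±4 on TOP/APC among their hosts, ±0.3 words on MLU, ±1.5 points on the
episode rate per unit), and checks silence recovery at ±1 hop per edge.
These sizes keep each property comfortably inside its sampling bound
while the whole suite stays fast. Ties in `which.max` resolve to the
earlier index (shorter lag, higher f0); interval membership uses a 1 ns
slack so touching spans never drop a boundary case; percentages are
rounded half-up to one decimal, matching printed-table conventions, and
pooled percentages are recomputed from summed counts rather than
averaged over speakers.

## Known limitations

* The parser accepts-and-preserves unknown bracketed codes and tags
  rather than interpreting them; dependent CHAT tiers (`%mor` etc.) are
  ignored.
* No automatic prosodic segmentation, diarization, filled-pause
  detection, or prominence *detection* from raw audio: spans and
  boundaries are inputs.
* The f0 tracker is tuned for the 50–300 Hz range of adult conversational
  speech; soprano or creaky extremes need the range parameters adjusted.
* Alignment is trusted: misaligned tiers shift pause positions, and the
  package flags only structural violations (overlap, broken nesting),
  not temporal drift.
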