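# prosopath

Corpus-based profiling of spontaneous speech at the prosody/pragmatics
interface, for clinical-linguistics and speech-science researchers who
work with L-AcT (Language into Act Theory) annotated corpora — e.g. when
comparing schizophrenic interview speech with non-pathological controls.

The package covers the four analysis levels such studies run on a
time-aligned CHAT-LABLITA corpus:

1. **Information structure.** The speech flow is segmented into
   *terminated sequences* (TS, ending in a terminal prosodic boundary
   `//`), each split into prosodic/information units (`/` boundaries)
   tagged Comment (COM, the illocution-bearing unit), Topic (TOP),
   Appendix (APC) or Bound Comment (COB). A TS is *simple* (one unit, a
   COM), *complex* (several units, one COM), or a *stanza* (a chain of
   COBs). The package tabulates class proportions, TOP/APC presence,
   and MLU = words per TS, with Kruskal–Wallis group comparisons.
2. **Silent pauses.** Silences are detected with a Praat-style
   sounding/silent criterion (frame intensity below max − 25 dB,
   minimum 150 ms), binned by duration (150–250, 251–500, 501–1000,
   > 1000 ms) and classified by position: `T` at turn-taking (only the
   pause *before* a tracked speaker's turn counts — it indexes reaction
   time), `UT` between two utterances of one turn, `IU` between two
   information units of one utterance.
3. **Retracing.** The `* … [/]` markers yield repair episodes; adjacent
   episodes form chains. Events are classified by position (start of
   TS, start of a non-first unit, inside the ongoing unit) and kind
   (total/partial repetition, modification), and rated against the
   number of retracing-free information units per TS type.
4. **Prominence acoustics.** On each annotated COM/TOP nucleus span the
   package measures f0 mean and standard deviation — in Hz, and in
   semitones (12·log₂(f/ref), converted per frame *before* averaging) —
   spectral emphasis (full-band minus low-band SPL, cutoff 1.43 × median
   f0; a vocal-effort proxy) and cvint = 100·sd/mean of the dB intensity
   contour.

A seeded synthetic-corpus generator (`synth_spec()`, `gen_transcript()`,
`gen_audio()`, presets `"cipps-like"`/`"control-like"`) produces
transcripts and harmonic-complex audio with complete ground truth, so
every stage is testable without access to clinical recordings.

## Worked example

```r
library(prosopath)
lines <- c(
  "@group: DOC interviewer",
  "@group: PAT patient",
  "*DOC:\tcome va il lavoro //",
  "*PAT:\tallora / i' camionista /^TOP^ ho iniziato a venti / tre anni /^COM^ a farlo //^APC^",
  "*PAT:\t*pe' [/] pe' dargli un colore piu uniforme //",
  "*PAT:\tfaccio un po di tutto //")
tr <- parse_transcript(lines)
ts_class_table(tr)
#>   speaker n_ts n_simple n_complex n_stanza pct_simple pct_complex pct_stanza
#> 1     PAT    3        2         1        0       66.7        33.3          0
#> 2     ALL    3        2         1        0       66.7        33.3          0
mlu(tr)[c("speaker", "n_ts", "n_words", "mlu")]
#>   speaker n_ts n_words      mlu
#> 1     PAT    3      22 7.333333
find_episodes(transcript_ts(tr, "PAT")[[2]])
#>   ts_ref unit_ref start_token n_retracted_tokens    position             kind
#> 1      1        1           1                  1 start_of_ts repetition_total
#>   chain_id is_single
#> 1       NA      TRUE
```

The interviewer's turn is parsed but excluded from all per-speaker
metrics. The second PAT line opens with a retracted token (`*pe' [/]`)
that is repeated verbatim by the repair, hence a single
utterance-initial total repetition; the retracted token is excluded from
the MLU word count (22 semantic words over 3 TSs).

For audio work, `detect_silences()` + `classify_pause_position()` +
`pause_profile()` produce the per-position pause tables, and
`prominence_profiles()` + `group_summary()` the per-speaker and pooled
acoustic tables. `run_pipeline()` chains everything from a YAML config;
`inst/cli/prosopath.R` exposes the same stages as a command-line tool.

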