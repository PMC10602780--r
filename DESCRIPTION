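Package: prosopath
Title: Prosody-Pragmatics Profiling of Spontaneous Speech Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corpus-based profiling of spontaneous speech at the
    prosody/pragmatics interface, designed around the Language into Act
    Theory (L-AcT) annotation scheme. Parses CHAT-LABLITA style
    transcripts into a turn / terminated-sequence / information-unit
    hierarchy, classifies terminated sequences (simple, complex, stanza)
    and computes information-structure metrics (MLU, Topic/Appendix
    presence), detects silent pauses in audio and classifies them by
    position (turn-taking, between utterances, between information units)
    and duration bin, mines retracing (repair) episodes and chains with
    their positional typology, and measures prominence acoustics (f0 mean
    and standard deviation in Hz and semitones, spectral emphasis,
    coefficient of intensity variation) on Comment and Topic nuclei. A
    synthetic corpus generator with full ground truth makes every stage
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
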