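# Printed corpus excerpts used across the suite (CHAT-LABLITA lines).
ex_simple <- "*PAT:\tfaccio un po' di tutto //"
ex_two_units <- "*PAT:\te poi / niente //"
ex_complex <- paste0("*PAT:\tallora / i' camionista /^TOP^ ",
                     "ho iniziato a venti / tre anni /^COM^ a farlo //^APC^")
ex_stanza <- paste0("*PAT:\tl' ho fatto per diversi anni /^COB^ ",
                    "poi mi sono messo in proprio /^COB^ ",
                    "s' e' creato una piccola azienda /^COB^ e via //^COB^")
ex_retr_start <- "*PAT:\t*pe' [/] pe' dargli un colore piu' uniforme //"
ex_retr_chain <- paste0("*PAT:\ti' ramo / *&d [/] *&d [/] d' un noce / ",
                        "gl' e' piu' chiaro d' i' fusto //")
ex_retr_inside <- "*PAT:\tha fatto *le [/] il tecnico industriale //"
ex_retr_partial <- paste0("*PAT:\ta casa mia *s' era [/] gl' eran poveri / ",
                          "e quindi 'un c' era / tanto da mangiare //")

first_ts <- function(text, speaker = "PAT") {
  tr <- parse_transcript(text)
  transcript_ts(tr, speaker)[[1]]
}

# harmonic tone with optional partial rolloff; amplitude < 1
tone <- function(dur_s, f0, sr = 16000, partials = 3, amp = 0.4) {
  tt <- seq_len(round(dur_s * sr)) / sr
  x <- 0
  for (k in seq_len(partials)) x <- x + 2^(1 - k) * sin(2 * pi * k * f0 * tt)
  amp * x / partials
}

silence <- function(dur_s, sr = 16000) rep(0, round(dur_s * sr))

# per-speaker class/TOP/APC counts of the published schizophrenic-corpus
# information-structure tables (speakers A-D)
cipps_counts <- data.frame(
  speaker = c("A", "B", "C", "D"),
  n_simple = c(39L, 125L, 86L, 93L),
  n_complex = c(32L, 109L, 84L, 84L),
  n_stanza = c(6L, 40L, 32L, 25L),
  n_with_top = c(6L, 71L, 36L, 24L),
  n_with_apc = c(6L, 17L, 15L, 22L),
  stringsAsFactors = FALSE)
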