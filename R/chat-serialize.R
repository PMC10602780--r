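serialize_unit <- function(unit, last_in_ts) {
  toks <- unit$tokens
  parts <- character()
  prev_group <- NA_integer_
  for (i in seq_len(nrow(toks))) {
    g <- toks$retr_group[i]
    if (!is.na(prev_group) && (is.na(g) || g != prev_group))
      parts <- c(parts, "[/]")
    w <- toks$surface[i]
    if (!is.na(g) && (is.na(prev_group) || g != prev_group))
      w <- paste0("*", w)
    parts <- c(parts, w)
    if (i %in% unit$scansion_breaks) parts <- c(parts, "/")
    prev_group <- g
  }
  if (!is.na(prev_group)) parts <- c(parts, "[/]")
  b <- if (unit$trailing_boundary == "terminal") "//" else "/"
  if (unit$tag_explicit && !is.na(unit$tag))
    b <- paste0(b, "^", unit$tag, "^")
  paste(c(parts, b), collapse = " ")
}

#' Serialize a transcript back to CHAT-LABLITA text
#'
#' Inverse of [parse_transcript()]: emits one `*SPK:` line per terminated
#' sequence, with `@group:` headers for the speaker-group map. Inferred
#' (default) Comment tags are not written, so a parse of the output
#' yields a structurally identical transcript.
#'
#' @param t a `transcript`.
#' @return character vector of lines.
#' @export
serialize_transcript <- function(t) {
  lines <- character()
  for (m in t$metadata) lines <- c(lines, m)
  for (code in names(t$speakers))
    lines <- c(lines, sprintf("@group: %s %s", code, t$speakers[[code]]))
  for (tu in t$turns) {
    for (ts in tu$sequences) {
      units <- vapply(seq_along(ts$units), function(i)
        serialize_unit(ts$units[[i]], i == length(ts$units)), character(1))
      lines <- c(lines,
                 paste0("*", tu$speaker, ":\t", paste(units, collapse = " ")))
    }
  }
  lines
}

#' Write a transcript to a file
#' @param t a `transcript`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(t, path) {
  writeLines(serialize_transcript(t), path, useBytes = TRUE)
  invisible(path)
}
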