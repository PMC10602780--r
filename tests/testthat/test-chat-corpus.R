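test_that("simple and two-unit utterances parse with the default Comment", {
  ts <- first_ts(ex_simple)
  expect_length(ts$units, 1L)
  expect_identical(ts$units[[1]]$tag, "COM")
  expect_false(ts$units[[1]]$tag_explicit)

  ts2 <- first_ts(ex_two_units)
  expect_length(ts2$units, 2L)
  expect_true(is.na(ts2$units[[1]]$tag))
  expect_identical(ts2$units[[2]]$tag, "COM")
  expect_identical(ts2$units[[2]]$trailing_boundary, "terminal")
})

test_that("scansion chunks attach forward to the next tagged unit", {
  ts <- first_ts(ex_complex)
  expect_length(ts$units, 3L)
  expect_identical(vapply(ts$units, `[[`, "", "tag"),
                   c("TOP", "COM", "APC"))
  # "allora /" absorbed by TOP, "ho iniziato a venti /" by COM
  expect_identical(lengths(lapply(ts$units, `[[`, "scansion_breaks")),
                   c(1L, 1L, 0L))
  expect_identical(ts$units[[1]]$tokens$surface,
                   c("allora", "i'", "camionista"))
  expect_identical(ts$units[[2]]$tokens$surface,
                   c("ho", "iniziato", "a", "venti", "tre", "anni"))
})

test_that("retracing markers set token flags and fragments are detected", {
  ts <- first_ts(ex_retr_start)
  tk <- ts$units[[1]]$tokens
  expect_identical(tk$is_retracted, c(TRUE, rep(FALSE, 6)))
  expect_identical(sum(tk$is_retracted), 1L)
  expect_identical(nrow(tk), 7L)

  ts6 <- first_ts(ex_retr_chain)
  tk6 <- ts6$units[[2]]$tokens
  expect_identical(tk6$surface[1:2], c("&d", "&d"))
  expect_true(all(tk6$is_fragment[1:2]))
  expect_true(all(tk6$is_retracted[1:2]))
  expect_identical(tk6$retr_group[1:2], c(1L, 2L))
})

test_that("annotation errors are signalled with line numbers", {
  expect_error(parse_transcript("*PAT:\t*pe' pe' dargli //"),
               "unmatched")
  expect_error(parse_transcript("*PAT:\t/^COM^ toto //"),
               "no preceding text")
  expect_error(parse_transcript("PAT: toto //"), "speaker prefix")
  expect_warning(parse_transcript("*PAT:\te poi / niente"),
                 "terminal boundary")
  lint <- lint_transcript(c("*PAT:\ttoto //", "*PAT:\t*a b //"))
  expect_identical(lint$severity, "error")
  expect_identical(lint$line, 2L)
})

test_that("a line lacking the terminal boundary still yields one TS", {
  tr <- suppressWarnings(parse_transcript("*PAT:\te poi / niente"))
  tss <- transcript_ts(tr, "PAT")
  expect_length(tss, 1L)
  expect_identical(tss[[1]]$units[[2]]$trailing_boundary, "terminal")
})

test_that("consecutive same-speaker lines merge into one turn", {
  tr <- parse_transcript(c("*DOC:\tcome va //", ex_simple, ex_two_units,
                           "*DOC:\tbene //"),
                         groups = c(PAT = "patient", DOC = "interviewer"))
  expect_length(tr$turns, 3L)
  expect_identical(vapply(tr$turns, `[[`, "", "speaker"),
                   c("DOC", "PAT", "DOC"))
  expect_length(tr$turns[[2]]$sequences, 2L)
})

test_that("serialization round-trips the printed examples", {
  for (ex in list(ex_simple, ex_two_units, ex_complex, ex_stanza,
                  ex_retr_start, ex_retr_chain, ex_retr_inside,
                  ex_retr_partial)) {
    tr <- parse_transcript(ex)
    expect_equal(parse_transcript(serialize_transcript(tr)), tr)
  }
  # tagged example re-serializes to the same line modulo whitespace
  body <- sub("^\\*PAT:\\s*", "",
              grep("^\\*PAT", serialize_transcript(parse_transcript(
                ex_complex)), value = TRUE))
  expect_identical(gsub("\\s+", " ", body),
                   gsub("\\s+", " ", sub("^\\*PAT:\\s*", "", ex_complex)))
})

test_that("serialization round-trips 100 seeded synthetic transcripts", {
  for (seed in 1:100) {
    g <- gen_transcript(synth_spec(seed = seed, n_turns = 6))
    reparsed <- parse_transcript(g$text)
    expect_equal(reparsed, g$transcript)
    expect_equal(parse_transcript(serialize_transcript(reparsed)), reparsed)
  }
})

test_that("token conservation and terminal-boundary ordering hold", {
  g <- gen_transcript(synth_spec(seed = 42, n_turns = 20))
  tr <- parse_transcript(g$text)
  total <- 0L
  for (ts in transcript_ts(tr, names(tr$speakers))) {
    tk <- do.call(rbind, lapply(ts$units, `[[`, "tokens"))
    expect_identical(sum(tk$is_retracted) + sum(!tk$is_retracted),
                     nrow(tk))
    total <- total + nrow(tk)
    bounds <- vapply(ts$units, `[[`, "", "trailing_boundary")
    expect_identical(which(bounds == "terminal"), length(bounds))
  }
  expect_identical(total, sum(g$truth$units$n_tokens))
})

test_that("alignment files read, validate nesting, and attach spans", {
  a <- alignment_tier(data.frame(
    tier = c("turn", "ts", "iu", "iu"),
    start_s = c(0, 0, 0, 1), end_s = c(2, 2, 1, 2),
    label = c("PAT", "ts", "u1", "u2")))
  expect_s3_class(a, "alignment_tier")
  # unit crossing a TS boundary
  expect_error(alignment_tier(data.frame(
    tier = c("ts", "ts", "iu"),
    start_s = c(0, 1, 0.5), end_s = c(1, 2, 1.5),
    label = c("a", "b", "u"))), "crosses")
  # overlap within a tier
  expect_error(alignment_tier(data.frame(
    tier = c("iu", "iu"), start_s = c(0, 0.5), end_s = c(1, 1.5),
    label = c("a", "b"))), "overlap")

  tr <- parse_transcript("*PAT:\tuno /^TOP^ due //^COM^")
  tr2 <- attach_alignment(tr, a)
  expect_equal(tr2$turns[[1]]$time_span, c(0, 2))
  expect_equal(tr2$turns[[1]]$sequences[[1]]$units[[2]]$time_span, c(1, 2))
  # count mismatch names the tier
  bad <- alignment_tier(data.frame(
    tier = c("turn", "ts", "iu"), start_s = 0, end_s = 2,
    label = "x"))
  expect_error(attach_alignment(tr, bad), "iu tier")
})

test_that("alignment TSV and TextGrid converters round-trip", {
  g <- gen_transcript(synth_spec(seed = 5, n_turns = 8))
  a <- gen_audio(synth_spec(seed = 5, n_turns = 8), g)$alignment
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(a, tsv)
  a2 <- read_alignment(tsv)
  expect_equal(a2$intervals$start_s, a$intervals$start_s, tolerance = 1e-8)
  expect_identical(a2$intervals$label, a$intervals$label)
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(a, tg)
  a3 <- read_textgrid(tg)
  expect_identical(sort(unique(a3$intervals$tier)),
                   sort(unique(a$intervals$tier)))
  iu <- a3$intervals[a3$intervals$tier == "iu", ]
  iu0 <- a$intervals[a$intervals$tier == "iu", ]
  expect_equal(iu$start_s, iu0$start_s, tolerance = 1e-6)
})

test_that("attached spans nest units within TSs within turns", {
  sp <- synth_spec(seed = 11, n_turns = 10)
  g <- gen_transcript(sp)
  au <- gen_audio(sp, g)
  tr <- attach_alignment(parse_transcript(g$text), au$alignment)
  for (tu in tr$turns) {
    for (ts in tu$sequences) {
      expect_gte(ts$time_span[1], tu$time_span[1] - 1e-9)
      expect_lte(ts$time_span[2], tu$time_span[2] + 1e-9)
      for (u in ts$units) {
        expect_gte(u$time_span[1], ts$time_span[1] - 1e-9)
        expect_lte(u$time_span[2], ts$time_span[2] + 1e-9)
      }
    }
  }
})
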