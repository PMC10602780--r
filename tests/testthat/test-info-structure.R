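test_that("terminated sequences classify as simple, complex, stanza", {
  expect_identical(classify_ts(first_ts(ex_simple)), "simple")
  expect_identical(classify_ts(first_ts(ex_two_units)), "complex")
  expect_identical(classify_ts(first_ts(ex_complex)), "complex")
  expect_identical(classify_ts(first_ts(ex_stanza)), "stanza")
  # stanza precedence when TOP is also present
  expect_identical(classify_ts(first_ts(
    "*PAT:\tlena /^TOP^ toto /^COB^ mira //^COB^")), "stanza")
  # invalid annotation: no illocution-bearing unit
  bad <- first_ts("*PAT:\ttoto //^COM^")
  bad$units[[1]]$tag <- "TOP"
  expect_error(classify_ts(bad), "neither COM nor COB")
})

test_that("class table reproduces the published per-speaker percentages", {
  tr <- counts_to_transcript(cipps_counts)
  tab <- ts_class_table(tr)
  pooled <- tab[tab$speaker == "ALL", ]
  expect_identical(pooled$n_ts, 755L)
  expect_identical(pooled$n_simple, 343L)
  expect_equal(pooled$pct_simple, 45.4)
  expect_equal(pooled$pct_complex, 40.9)
  expect_equal(tab$pct_simple[tab$speaker == "A"], 50.6)
  expect_equal(tab$pct_stanza[tab$speaker == "B"], 14.6)
  # percentages sum to 100 within rounding slack on every row
  expect_true(all(abs(tab$pct_simple + tab$pct_complex +
                        tab$pct_stanza - 100) <= 0.2))
})

test_that("single simple TS gives 100 percent simple", {
  tab <- ts_class_table(parse_transcript(ex_simple))
  expect_equal(tab$pct_simple, c(100, 100))
})

test_that("topic/appendix presence counts TSs once, not units", {
  tr <- counts_to_transcript(cipps_counts)
  tab <- unit_presence_table(tr)
  expect_equal(tab$pct_top[tab$speaker == "B"], 25.9)
  expect_identical(tab$n_with_top[tab$speaker == "ALL"], 137L)
  # two TOPs in one TS still count once
  t2 <- parse_transcript("*PAT:\ta /^TOP^ b /^TOP^ c //^COM^")
  expect_identical(unit_presence_table(t2)$n_with_top[1], 1L)
})

test_that("pooled percentages equal count-weighted speaker means", {
  # two speakers with different class mixes make pooling non-trivial
  g1 <- gen_transcript(synth_spec(seed = 9, n_turns = 60))
  g2 <- gen_transcript(synth_spec(
    seed = 10, n_turns = 60,
    speakers = c(QQ = "patient", DOC = "interviewer"),
    main_speaker = "QQ",
    p_ts_class = c(simple = 0.2, complex = 0.5, stanza = 0.3)))
  tr <- parse_transcript(c(g1$text, g2$text))
  tab <- ts_class_table(tr)
  pooled <- tab[tab$speaker == "ALL", ]
  spk <- tab[tab$speaker != "ALL", ]
  for (cl in c("pct_simple", "pct_complex", "pct_stanza")) {
    weighted <- sum(spk[[cl]] * spk$n_ts) / sum(spk$n_ts)
    expect_lt(abs(pooled[[cl]] - weighted), 0.1)
  }
  expect_identical(sum(spk$n_simple + spk$n_complex + spk$n_stanza),
                   sum(spk$n_ts))
})

test_that("MLU counts semantic words under the default policy", {
  m <- mlu(parse_transcript(ex_two_units))
  expect_identical(m$n_words, 3L)
  expect_equal(m$mlu, 3)
  # retracted token excluded, six semantic words remain
  expect_identical(ts_word_count(first_ts(ex_retr_start)), 6L)
  expect_identical(ts_word_count(first_ts(ex_retr_start), "all"), 7L)
  # retracted fragments excluded under the default policy, kept by "all"
  expect_identical(ts_word_count(first_ts(ex_retr_chain)), 12L)
  expect_identical(ts_word_count(first_ts(ex_retr_chain), "all"), 14L)
})

test_that("adding a word strictly increases a speaker's MLU", {
  base <- c(ex_simple, ex_two_units)
  longer <- c(ex_simple, "*PAT:\te poi / niente davvero //")
  m0 <- mlu(parse_transcript(base))$mlu
  m1 <- mlu(parse_transcript(longer))$mlu
  expect_gt(m1, m0)
})

test_that("synthetic MLU recovers the generator mean length", {
  sp <- synth_spec(seed = 21, n_turns = 120, mean_ts_words = 6.5)
  g <- gen_transcript(sp)
  m <- mlu(parse_transcript(g$text), speakers = "PAT")
  expect_gte(m$n_ts, 100L)
  expect_lt(abs(m$mlu - 6.5), 0.5)
  # parser-side counts agree with generator truth exactly
  truth <- g$truth$ts[g$truth$ts$speaker == "PAT", ]
  expect_identical(m$n_words, sum(truth$n_words))
})

test_that("kruskal_wallis matches a hand-computed rank statistic", {
  # independent oracle: mid-ranks, tie-corrected H, computed directly
  kw_oracle <- function(groups) {
    x <- unlist(groups)
    n <- length(x)
    r <- rank(x)  # mid-ranks
    idx <- rep(seq_along(groups), lengths(groups))
    h <- 12 / (n * (n + 1)) *
      sum(vapply(seq_along(groups), function(i) {
        ri <- r[idx == i]
        length(ri) * (mean(ri) - (n + 1) / 2)^2
      }, numeric(1)))
    ties <- table(x)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    list(H = h, p = stats::pchisq(h, length(groups) - 1,
                                  lower.tail = FALSE))
  }
  cases <- list(list(c(1, 2, 3), c(4, 5, 6)),
                list(c(1, 1, 2, 5), c(2, 2, 3), c(7, 1)),
                list(rnorm(10), rnorm(12), rnorm(8)))
  set.seed(4)
  for (gr in cases) {
    got <- kruskal_wallis(gr)
    want <- kw_oracle(gr)
    expect_equal(got$H, want$H, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)
})

test_that("equal generators yield uniform Kruskal-Wallis p-values", {
  # null calibration: per-TS lengths from identically parameterized
  # corpora; 60 seed pairs
  pvals <- vapply(1:60, function(s) {
    a <- gen_transcript(synth_spec(seed = 1000 + s, n_turns = 16))
    b <- gen_transcript(synth_spec(seed = 5000 + s, n_turns = 16))
    la <- mlu(parse_transcript(a$text))$per_ts_lengths[[1]]
    lb <- mlu(parse_transcript(b$text))$per_ts_lengths[[1]]
    kruskal_wallis(list(la, lb))$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
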