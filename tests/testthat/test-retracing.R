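test_that("printed retracing examples yield the documented labels", {
  # utterance-initial total repetition, single episode
  e5 <- find_episodes(first_ts(ex_retr_start))
  expect_identical(nrow(e5), 1L)
  expect_identical(e5$position, "start_of_ts")
  expect_identical(e5$kind, "repetition_total")
  expect_true(e5$is_single)

  # fragment chain at the start of a non-first unit, partial repetition
  e6 <- find_episodes(first_ts(ex_retr_chain))
  expect_identical(nrow(e6), 2L)
  expect_identical(unique(e6$position), "start_of_iu_inside_ts")
  expect_identical(unique(e6$kind), "repetition_partial")
  expect_false(any(e6$is_single))
  expect_identical(length(unique(e6$chain_id)), 1L)

  # mid-unit modification (gender/number repair), single episode
  e7b <- find_episodes(first_ts(ex_retr_inside))
  expect_identical(e7b$position, "inside_ts")
  expect_identical(e7b$kind, "modification")

  # shared-material restart classifies as partial repetition
  e7a <- find_episodes(first_ts(ex_retr_partial))
  expect_identical(e7a$position, "inside_ts")
  expect_identical(e7a$kind, "repetition_partial")
  expect_identical(e7a$n_retracted_tokens, 2L)
})

test_that("retracted token rate counts fragments and markers correctly", {
  t5 <- parse_transcript(ex_retr_start)
  expect_equal(retracted_token_rate(t5, "PAT"), 100 / 7)
  clean <- parse_transcript(c(ex_simple, ex_two_units))
  expect_equal(retracted_token_rate(clean, "PAT"), 0)
})

test_that("episode rates divide by retracing-free units per TS type", {
  lines <- c(ex_retr_start,  # 1 simple TS, its only unit retracted
             rep("*PAT:\tuno due tre //^COM^", 20))
  tr <- parse_transcript(lines)
  rates <- episode_rates_by_ts_type(tr)
  simple <- rates[rates$ts_type == "simple", ]
  expect_identical(simple$n_single, 1L)
  expect_identical(simple$n_clean_units, 20L)
  expect_equal(simple$single_rate, 5)
  expect_equal(simple$chain_rate, 0)
  # corpus without retracing: defined rates are zero, empty types absent
  r0 <- episode_rates_by_ts_type(parse_transcript(
    rep("*PAT:\tuno due //^COM^", 5)))
  defined <- !is.na(r0$single_rate)
  expect_identical(r0$ts_type[defined], c("all", "simple"))
  expect_true(all(r0$single_rate[defined] == 0))
  expect_true(all(r0$chain_rate[defined] == 0))
})

test_that("zero denominators yield absent rates", {
  # the single unit of the only TS carries retracing: no clean units
  tr <- parse_transcript(ex_retr_start)
  r <- episode_rates_by_ts_type(tr)
  expect_true(is.na(r$single_rate[r$ts_type == "simple"]))
})

test_that("position distribution counts chains once and sums to 100", {
  tr <- parse_transcript(c(ex_retr_start, ex_retr_chain, ex_retr_inside))
  pd <- position_distribution(tr)
  expect_identical(pd$n_events, rep(1L, 3))
  expect_equal(pd$pct, rep(33.3, 3))
  expect_lt(abs(sum(pd$pct) - 100), 0.2)
  # all events utterance-initial
  pd2 <- position_distribution(parse_transcript(rep(ex_retr_start, 4)))
  expect_equal(pd2$pct, c(100, 0, 0))
  # no episodes: empty distribution
  expect_identical(nrow(position_distribution(parse_transcript(ex_simple))),
                   0L)
})

test_that("synthetic corpora recover planted episodes exactly", {
  sp <- synth_spec(seed = 31, n_turns = 200,
                   retracing = list(episode_rate = 0.15,
                                    chain_fraction = 0.3,
                                    position_weights =
                                      c(start_of_ts = 0.13,
                                        start_of_iu_inside_ts = 0.47,
                                        inside_ts = 0.40)))
  g <- gen_transcript(sp)
  tr <- parse_transcript(g$text)
  truth <- g$truth$episodes
  tss <- transcript_ts(tr, "PAT")
  # map generator ts_index (over all speakers) to the PAT-only list
  pat_idx <- g$truth$ts$ts_index[g$truth$ts$speaker == "PAT"]
  found_events <- 0L; found_chains <- 0L
  pos_found <- character()
  for (k in seq_along(tss)) {
    eps <- find_episodes(tss[[k]])
    tri <- truth[truth$ts_index == pat_idx[k], , drop = FALSE]
    expect_identical(nrow(eps), sum(tri$n_episodes))
    n_chain <- length(unique(eps$chain_id[!is.na(eps$chain_id)]))
    expect_identical(n_chain, sum(tri$is_chain))
    found_events <- found_events + sum(eps$is_single) + n_chain
    found_chains <- found_chains + n_chain
    if (nrow(tri) > 0) {
      first_eps <- eps[eps$is_single | !duplicated(eps$chain_id), ]
      expect_setequal(first_eps$position, tri$position)
      pos_found <- c(pos_found, first_eps$position)
    }
  }
  expect_identical(found_events, nrow(truth))
  expect_identical(found_chains, sum(truth$is_chain))
  # chain rate cannot exceed the total event rate in any TS type
  rates <- episode_rates_by_ts_type(tr)
  ok <- !is.na(rates$single_rate)
  expect_true(all(rates$chain_rate[ok] <=
                    rates$single_rate[ok] + rates$chain_rate[ok]))
  # pooled position counts equal the planted ones
  expect_identical(
    as.vector(table(factor(pos_found,
                           c("start_of_ts", "start_of_iu_inside_ts",
                             "inside_ts")))),
    as.vector(table(factor(truth$position,
                           c("start_of_ts", "start_of_iu_inside_ts",
                             "inside_ts")))))
})
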