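test_that("boundary intervals beyond 20 s are disregarded", {
  rec <- session_with_boundaries(c(1, 5, 10, 15, 19, 21, 25, 40))
  iv <- categorize_intervals(parse_sequences(rec))
  b <- iv[iv$category == "BOUNDARY", ]
  cp <- b$value_s[b$boundary_kind == "CHECK_PRESS"]
  expect_setequal(cp, c(1, 5, 10, 15, 19))
  expect_lte(max(b$value_s), 20)
  # filter monotonicity: lowering the cutoff never increases retained count
  n_by_cut <- vapply(c(25, 20, 15, 10, 5), function(cut) {
    sum(categorize_intervals(parse_sequences(rec),
                             max_boundary_s = cut)$category == "BOUNDARY")
  }, 0L)
  expect_true(all(diff(n_by_cut) <= 0))
})

test_that("complete sequences yield paired press-check and check-press records", {
  k <- 5L
  rec <- session_with_boundaries(rep(2, k))
  iv <- categorize_intervals(parse_sequences(rec), max_boundary_s = Inf)
  expect_identical(sum(iv$boundary_kind == "PRESS_CHECK", na.rm = TRUE), k)
  expect_identical(sum(iv$boundary_kind == "CHECK_PRESS", na.rm = TRUE), k)
  # within-records: one per execution press
  expect_identical(sum(iv$category == "WITHIN_SEQUENCE"), k)
  # single length-1 sequence: no within records
  iv1 <- categorize_intervals(parse_sequences(
    ev_df(c(0, 100), c("LP_ACTIVE", "MAG_ENTRY"))))
  expect_identical(sum(iv1$category == "WITHIN_SEQUENCE"), 0L)
})

test_that("check-press intervals span from the last (possibly ignored) check", {
  ev <- ev_df(c(0, 100, 300, 400, 700),
              c("LP_ACTIVE", "MAG_ENTRY", "MAG_ENTRY", "MAG_ENTRY",
                "LP_ACTIVE"))
  iv <- categorize_intervals(parse_sequences(rbind(
    ev, ev_df(800, "MAG_ENTRY"))))
  cp <- iv[!is.na(iv$boundary_kind) & iv$boundary_kind == "CHECK_PRESS", ]
  expect_equal(cp$value_s, 3)  # 400 cs (last ignored check) -> 700 cs press
  # ignored checks never create check-to-check records
  expect_identical(nrow(iv), 3L)  # PRESS_CHECK, CHECK_PRESS, PRESS_CHECK
})

test_that("summed boundary mode adds termination and initiation intervals", {
  rec <- session_with_boundaries(c(2, 3), term_s = 1)
  ivs <- categorize_intervals(parse_sequences(rec), boundary = "summed")
  s <- ivs$value_s[ivs$category == "BOUNDARY"]
  # only the inter-sequence boundary pairs a termination with the next
  # initiation; the session-initial check has no termination to pair
  expect_equal(s, 1 + 3)
  expect_identical(unique(ivs$boundary_kind[ivs$category == "BOUNDARY"]),
                   "SUMMED")
})

test_that("within counts conserve against terminated sequence lengths", {
  sched <- st_schedule(max_time_s = 600)
  for (seed in c(2, 9, 40)) {
    p <- parse_sequences(generate_session(young_like_profile(), sched,
                                          seed = seed)$record)
    iv <- categorize_intervals(p)
    expect_identical(sum(iv$category == "WITHIN_SEQUENCE"),
                     sum(p$length[!p$open] - 1L))
  }
})

test_that("interval summaries restrict to the requested window", {
  rec <- session_with_boundaries(rep(2, 10))
  iv <- categorize_intervals(parse_sequences(rec))
  s_all <- interval_summary(iv)
  expect_identical(s_all$n[s_all$category == "WITHIN_SEQUENCE"], 10L)
  expect_equal(s_all$sd_s[s_all$category == "WITHIN_SEQUENCE"], 0)
  expect_equal(s_all$mean_s[s_all$category == "WITHIN_SEQUENCE"], 0.3)
  # window restriction equals a brute filter on closing-event times
  w <- 15
  s_w <- interval_summary(iv, window_s = w)
  brute <- iv[iv$session_time_cs <= w * 100, ]
  for (categ in s_w$category)
    expect_identical(s_w$n[s_w$category == categ],
                     sum(brute$category == categ))
  expect_identical(nrow(interval_summary(iv, window_s = 0)), 0L)
})

test_that("IPI histograms conserve counts over half-open bins", {
  v <- data.frame(value_s = c(0.005, 0.01, 0.0199, 0.5, 1.999, 2.5))
  h <- ipi_histogram(v)
  expect_identical(sum(h$count), 5L)  # 2.5 s falls outside [0, 2)
  expect_identical(h$count[1], 1L)    # [0, 0.01): the 0.005 value
  expect_identical(h$count[2], 2L)    # [0.01, 0.02): 0.01 and 0.0199
  # uniform synthetic intervals fill bins uniformly (chi-square sanity)
  set.seed(13)
  u <- data.frame(value_s = runif(20000, 0, 2))
  hu <- ipi_histogram(u)
  chi <- sum((hu$count - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 199))
  expect_error(ipi_histogram(v, bin_edges_s = c(0, 0, 1)), "increasing")
})

test_that("chunk scatter transforms to log10 with unit-mass density curves", {
  rec <- session_with_boundaries(rep(c(2, 3, 4), 5))
  iv <- categorize_intervals(parse_sequences(rec))
  iv$value_s[1] <- 1    # exact log10 anchors
  iv$value_s[2] <- 0.1
  cs <- chunk_scatter(iv, seed = 4)
  expect_equal(cs$points$x_log10[1], 0)
  expect_equal(cs$points$x_log10[2], -1)
  expect_true(all(cs$points$y >= 0 & cs$points$y <= 1))
  # y jitter reproducible from the seed
  expect_identical(cs$points$y, chunk_scatter(iv, seed = 4)$points$y)
  # each kernel curve integrates to 1 (trapezoid) within 1e-3
  for (categ in unique(cs$densities$category)) {
    d <- cs$densities[cs$densities$category == categ, ]
    area <- sum(diff(d$x_log10) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_lt(abs(area - 1), 1e-3)
  }
})

test_that("fastest-burst extraction matches a brute-force sort", {
  sched <- st_schedule(max_time_s = 600)
  p <- parse_sequences(generate_session(aged_like_profile(), sched,
                                        seed = 3)$record)
  fb <- fastest_sequences(p, k = 5)
  brute <- p[!is.na(p$speed_pps), ]
  brute <- brute[order(-brute$speed_pps, brute$start_cs), ][1:5, ]
  expect_identical(fb$sequences$seq_index, brute$seq_index)
  expect_equal(fb$mean_speed_pps, mean(brute$speed_pps))
  expect_false(fb$truncated)
  # k beyond availability returns everything, flagged
  few <- parse_sequences(ev_df(c(0, 50, 100, 200),
                               c(rep("LP_ACTIVE", 3), "MAG_ENTRY")))
  fb2 <- fastest_sequences(few, k = 5)
  expect_identical(nrow(fb2$sequences), 1L)
  expect_true(fb2$truncated)
  # equal 0.5-s spacing: burst speed 2 presses/s
  expect_equal(fb2$mean_speed_pps, 2)
})
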