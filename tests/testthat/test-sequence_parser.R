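test_that("element classification follows the interspersal rule", {
  ev <- ev_df(c(0, 50, 100, 200, 250),
              c("LP_ACTIVE", "LP_ACTIVE", "LP_ACTIVE", "MAG_ENTRY",
                "MAG_ENTRY"))
  expect_identical(classify_elements(ev)$label,
                   c("initiation", "execution", "execution", "termination",
                     "ignored"))
  # session-initial checks precede any press and cannot be terminations
  ev2 <- ev_df(c(0, 10, 100), c("MAG_ENTRY", "MAG_ENTRY", "LP_ACTIVE"))
  expect_identical(classify_elements(ev2)$label,
                   c("ignored", "ignored", "initiation"))
  # minimal length-1 sequence
  ev3 <- ev_df(c(0, 10), c("LP_ACTIVE", "MAG_ENTRY"))
  expect_identical(classify_elements(ev3)$label, c("initiation", "termination"))
  # pellets and cues pass through unlabelled and do not break press runs
  ev4 <- ev_df(c(0, 10, 10, 40, 100),
               c("LP_ACTIVE", "CUE_ON", "PELLET", "LP_ACTIVE", "MAG_ENTRY"))
  expect_identical(classify_elements(ev4)$label,
                   c("initiation", NA, NA, "execution", "termination"))
  expect_error(classify_elements(ev_df(c(50, 10), "LP_ACTIVE")), "sorted")
})

test_that("classification equals the independent lag-based oracle", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    ev <- ev_df(cumsum(sample(1:300, n, replace = TRUE)),
                sample(c("LP_ACTIVE", "MAG_ENTRY", "PELLET", "LP_INACTIVE"),
                       n, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1)))
    expect_identical(classify_elements(ev)$label, oracle_classify(ev))
  }
})

test_that("parsing assembles one sequence per initiation", {
  # k repeating P,P,P,M blocks -> k sequences of length 3
  k <- 6L
  base <- rep(c(0, 50, 100, 200), k) + rep((0:(k - 1)) * 1000, each = 4)
  ev <- ev_df(base, rep(c("LP_ACTIVE", "LP_ACTIVE", "LP_ACTIVE",
                          "MAG_ENTRY"), k))
  p <- parse_sequences(ev)
  expect_identical(nrow(p), k)
  expect_identical(unique(p$length), 3L)
  expect_false(any(p$open))
  # partition: sum of lengths = total active presses
  expect_identical(sum(p$length), sum(ev$kind == "LP_ACTIVE"))
  # trailing open sequence is emitted and flagged
  ev2 <- rbind(ev, ev_df(c(6000, 6050), "LP_ACTIVE"))
  p2 <- parse_sequences(ev2)
  expect_identical(nrow(p2), k + 1L)
  expect_true(p2$open[k + 1])
  expect_true(is.na(p2$duration_s[k + 1]))
  # idempotence: re-parsing the labelled table yields identical sequences
  p3 <- parse_sequences(attr(p2, "labelled"))
  expect_identical(as.data.frame(p2), as.data.frame(p3))
})

test_that("reward attribution uses pellet timestamps alone", {
  ev <- ev_df(c(0, 50, 50, 120, 300, 350, 500),
              c("LP_ACTIVE", "LP_ACTIVE", "PELLET", "MAG_ENTRY",
                "LP_ACTIVE", "MAG_ENTRY", "PELLET"))
  p <- parse_sequences(ev)
  expect_identical(p$rewarded, c(TRUE, FALSE))
})

test_that("sequence metrics match hand arithmetic", {
  ev <- ev_df(c(0, 50, 100, 200),
              c("LP_ACTIVE", "LP_ACTIVE", "LP_ACTIVE", "MAG_ENTRY"))
  p <- parse_sequences(ev)
  expect_equal(attr(p, "ipis")[[1]], c(0.5, 0.5))
  expect_equal(p$duration_s, 2.0)
  # 2 inter-press intervals over a 1-s press span: 2 presses per second
  expect_equal(p$speed_pps, 2.0)
  m <- sequence_metrics(p, duration = "press_span")
  expect_equal(m$duration_s, 1.0)
  expect_equal(m$mean_ipi_s, 0.5)
  # length-1 sequence: no IPIs, speed absent
  p1 <- parse_sequences(ev_df(c(0, 10), c("LP_ACTIVE", "MAG_ENTRY")))
  expect_identical(length(attr(p1, "ipis")[[1]]), 0L)
  expect_true(is.na(p1$speed_pps))
  # equal spacing: IPI = c implies speed = 1/c
  evc <- ev_df(c(0, 25, 50, 75, 130), c(rep("LP_ACTIVE", 4), "MAG_ENTRY"))
  expect_equal(parse_sequences(evc)$speed_pps, 4)
})

test_that("session summaries normalise by duration and conserve counts", {
  sched <- st_schedule(max_time_s = 1200)
  g <- generate_session(young_like_profile(), sched, seed = 31)
  p <- parse_sequences(g$record)
  s <- session_summary(g$record, p)
  expect_equal(s$duration_min, 20)
  expect_identical(s$n_initiations + s$n_executions, s$n_presses)
  expect_equal(s$sequence_rate_per_min, sum(!p$open) / 20)
  expect_equal(s$rewards_per_min, s$n_pellets / 20)
  # 20 pellets in 20 minutes -> efficiency 1/min
  ev <- ev_df(seq(100, by = 100, length.out = 20), "PELLET")
  rec <- toy_record(ev, duration_s = 1200)
  expect_equal(session_summary(rec)$rewards_per_min, 1)
  # empty session: all rates zero
  rec0 <- toy_record(ev_df(integer(0), character(0)), duration_s = 600)
  s0 <- session_summary(rec0)
  expect_equal(s0$lp_rate_per_min, 0)
  expect_equal(s0$sequence_rate_per_min, 0)
})

test_that("first-check intervals subtract and censor per pellet", {
  ev <- ev_df(c(100, 180, 500, 900, 950),
              c("PELLET", "MAG_ENTRY", "PELLET", "PELLET", "MAG_ENTRY"))
  rec <- toy_record(ev)
  fc <- first_check_intervals(rec)
  expect_equal(fc$first_check_s, c(0.8, NA, 0.5))
  # magazine generator: constant 1-s reaction yields exactly 1-s intervals
  # for every pellet whose next delivery is more than 1 s away
  rec2 <- generate_magazine_session(
    mean_interval_s = 30, n_pellets = 20,
    reaction_dist = list(family = "constant", value = 1), seed = 8)
  expect_identical(sum(rec2$events$kind == "PELLET"), 20L)
  fc2 <- first_check_intervals(rec2)
  gap_next <- diff(c(fc2$pellet_time_cs, Inf))
  gap_prev <- c(Inf, gap_next[-length(gap_next)])
  clean <- which(gap_next > 100 & gap_prev > 100)  # no pending check nearby
  expect_true(all(abs(fc2$first_check_s[clean] - 1) <= 1e-9))
  expect_lte(nrow(fc2), 20)
})
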