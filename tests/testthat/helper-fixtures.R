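# Shared fixtures and independent oracles for the test suite.

# Build an event data frame from compact (time_cs, kind) pairs.
ev_df <- function(time_cs, kind, hold_cs = NA_integer_) {
  data.frame(time_cs = as.integer(time_cs), kind = as.character(kind),
             hold_cs = rep(as.integer(hold_cs),
                           length.out = length(time_cs)),
             stringsAsFactors = FALSE)
}

# A session record around an event table under a permissive CRF schedule.
toy_record <- function(events, duration_s = NULL) {
  if (is.null(duration_s))
    duration_s <- (max(events$time_cs, 0) + 100) / 100
  session_record("toy", 1L,
                 schedule_descriptor("CRF", max_rewards = 1000L,
                                     max_time_s = duration_s),
                 events, duration_cs = duration_s * 100)
}

# Independent element classifier: vectorised lag over the behavioural
# subsequence (presses and checks only), unlike the package's stateful scan.
oracle_classify <- function(events) {
  beh <- which(events$kind %in% c("LP_ACTIVE", "MAG_ENTRY"))
  k <- events$kind[beh]
  prev <- c("none", k[-length(k)])
  lab <- ifelse(k == "LP_ACTIVE",
                ifelse(prev == "LP_ACTIVE", "execution", "initiation"),
                ifelse(prev == "LP_ACTIVE", "termination", "ignored"))
  out <- rep(NA_character_, nrow(events))
  out[beh] <- lab
  out
}

# Brute-force recount of RR consultations under the sequence-trigger rule:
# walks the element stream keeping an explicit consecutive-press counter.
oracle_st_consults <- function(elements, requirement) {
  count <- 0L; unlocked <- FALSE
  consulted <- logical(length(elements))
  for (i in seq_along(elements)) {
    e <- elements[i]
    if (e == "PRESS") {
      count <- count + 1L
      if (count >= requirement) unlocked <- TRUE
      consulted[i] <- unlocked
    } else {
      count <- 0L; unlocked <- FALSE
    }
  }
  consulted
}

# Random ST element stream: presses with occasional terminations/rewards.
random_element_stream <- function(n) {
  sample(c("PRESS", "TERMINATION", "REWARD"), n, replace = TRUE,
         prob = c(0.75, 0.18, 0.07))
}

# Render Gaussian blobs at given (x, y) positions on a blank canvas;
# independent of generate_section_image().
render_blobs <- function(xs, ys, width, height, sigma = 2, peak = 0.8,
                         noise_sd = 0) {
  img <- matrix(if (noise_sd > 0) stats::rnorm(width * height, sd = noise_sd)
                else 0, width, height)
  half <- ceiling(4 * sigma)
  for (k in seq_along(xs)) {
    gi <- max(1, round(xs[k]) + 1 - half):min(width, round(xs[k]) + 1 + half)
    gj <- max(1, round(ys[k]) + 1 - half):min(height, round(ys[k]) + 1 + half)
    img[gi, gj] <- img[gi, gj] +
      peak * exp(-outer((gi - 1 - xs[k])^2, (gj - 1 - ys[k])^2, "+") /
                   (2 * sigma^2))
  }
  pmin(pmax(img, 0), 1)
}

# A session with sequence boundary intervals at chosen values: each block
# is M(check) ... P P M with the check-press gap taken from `init_s` and a
# fixed press-check gap.
session_with_boundaries <- function(init_s, term_s = 1, ipi_s = 0.3) {
  t <- 0; times <- integer(0); kinds <- character(0)
  push <- function(dt, k) {
    t <<- t + quantize_time(dt)
    times[[length(times) + 1]] <<- t
    kinds[[length(kinds) + 1]] <<- k
  }
  push(1, "MAG_ENTRY")  # session-initial check anchors the first interval
  for (b in init_s) {
    push(b, "LP_ACTIVE")
    push(ipi_s, "LP_ACTIVE")
    push(term_s, "MAG_ENTRY")
  }
  toy_record(ev_df(unlist(times), unlist(kinds)))
}

# Default RR_ST sequencing schedule used across tests.
st_schedule <- function(p = 0.05, st = 7, max_rewards = 1000L,
                        max_time_s = 1200) {
  schedule_descriptor("RR_ST", p_reinforce = p, st_requirement = st,
                      max_rewards = max_rewards, max_time_s = max_time_s)
}

# Small randomised agent profile for parser-oracle sweeps.
random_profile <- function(seed) {
  with_seed(seed, agent_profile(
    name = sprintf("rand%d", seed),
    seq_len_dist = list(family = "nbinom_shifted", size = runif(1, 1, 5),
                        mu = runif(1, 0.5, 6)),
    ipi_dist = list(family = "lognormal", meanlog = log(runif(1, 0.1, 1)),
                    sdlog = runif(1, 0.2, 0.6)),
    term_int_dist = list(family = "lognormal",
                         meanlog = log(runif(1, 0.5, 4)),
                         sdlog = runif(1, 0.2, 0.6)),
    init_int_dist = list(family = "lognormal",
                         meanlog = log(runif(1, 0.5, 6)),
                         sdlog = runif(1, 0.2, 0.7)),
    n_checks_dist = list(family = "poisson_shifted",
                         lambda = runif(1, 0, 1.5)),
    pause_prob = runif(1, 0, 0.2)))
}
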