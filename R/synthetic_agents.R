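#' Evaluate code with a temporary RNG seed
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state,
#' so seeded generators do not perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed and a key
#'
#' Stage- and subject-level seeds are split from one master seed with a
#' small multiplicative hash of the key string, keeping every derived seed
#' in `[1, 2^31 - 2]`. The same (master, key) pair always yields the same
#' child seed, so any stage or subject can be regenerated in isolation.
#'
#' @param master Integer master seed.
#' @param key Character key naming the substream (e.g. `"subject3/day12"`).
#' @return Integer child seed.
#' @export
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647)
  for (c in utf8ToInt(as.character(key)))
    h <- (h * 131 + c) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# Sample n values from a distribution spec: list(family = ..., params...).
# Families cover the generator's needs; all are configurable fixtures.
sample_dist <- function(d, n) {
  if (n == 0) return(numeric(0))
  switch(d$family,
    constant   = rep(d$value, n),
    lognormal  = stats::rlnorm(n, d$meanlog, d$sdlog),
    exponential = stats::rexp(n, 1 / d$mean),
    gamma      = stats::rgamma(n, shape = d$shape, rate = d$rate),
    uniform    = stats::runif(n, d$min, d$max),
    nbinom_shifted = 1 + stats::rnbinom(n, size = d$size, mu = d$mu),
    poisson_shifted = 1 + stats::rpois(n, d$lambda),
    stop("unknown distribution family: ", d$family))
}

# Mean of a distribution spec (used for parameter-recovery checks).
dist_mean <- function(d) {
  switch(d$family,
    constant   = d$value,
    lognormal  = exp(d$meanlog + d$sdlog^2 / 2),
    exponential = d$mean,
    gamma      = d$shape / d$rate,
    uniform    = (d$min + d$max) / 2,
    nbinom_shifted = 1 + d$mu,
    poisson_shifted = 1 + d$lambda,
    stop("unknown distribution family: ", d$family))
}

#' Construct a synthetic-agent profile
#'
#' A profile parameterises the generative model of one behavioural
#' phenotype: the distribution of action-sequence lengths, of
#' within-sequence inter-press intervals (IPIs), of the press-to-check
#' (termination) and check-to-press (initiation) boundary intervals, of
#' the number of consecutive magazine checks after each termination, and
#' of occasional long off-task pauses (> 20 s) that the boundary filter
#' must later discard. Distributions are specs understood by the internal
#' sampler: `list(family = "lognormal", meanlog =, sdlog =)`,
#' `"constant"`, `"exponential"`, `"gamma"`, `"uniform"`,
#' `"nbinom_shifted"`, `"poisson_shifted"`.
#'
#' @param name Profile name.
#' @param seq_len_dist Count distribution of sequence lengths (>= 1).
#' @param ipi_dist Positive-duration distribution of within-sequence IPIs
#'   (seconds).
#' @param term_int_dist Press-to-check boundary interval distribution.
#' @param init_int_dist Check-to-press boundary interval distribution.
#' @param n_checks_dist Count distribution of consecutive magazine checks
#'   per termination (>= 1).
#' @param check_gap_dist Gap between consecutive checks (seconds).
#' @param pause_prob Probability that a given initiation interval is
#'   replaced by a long off-task pause.
#' @param pause_dist Pause duration distribution (seconds; should place
#'   most mass above 20 s).
#' @return An `agent_profile` object.
#' @seealso [young_like_profile()], [aged_like_profile()]
#' @export
agent_profile <- function(name, seq_len_dist, ipi_dist, term_int_dist,
                          init_int_dist,
                          n_checks_dist = list(family = "constant", value = 1),
                          check_gap_dist = list(family = "lognormal",
                                                meanlog = log(1), sdlog = 0.3),
                          pause_prob = 0,
                          pause_dist = list(family = "lognormal",
                                            meanlog = log(45), sdlog = 0.4)) {
  if (pause_prob < 0 || pause_prob > 1) stop("pause_prob must be in [0, 1]")
  structure(list(name = name, seq_len_dist = seq_len_dist,
                 ipi_dist = ipi_dist, term_int_dist = term_int_dist,
                 init_int_dist = init_int_dist,
                 n_checks_dist = n_checks_dist,
                 check_gap_dist = check_gap_dist,
                 pause_prob = pause_prob, pause_dist = pause_dist),
            class = "agent_profile")
}

#' Young-adult-like agent preset
#'
#' Emulates the qualitative structure of well-trained young-adult
#' performance: longer sequences, slower within-sequence pressing, and
#' boundary intervals spread well above the chunking space. Parameter
#' values are generator fixtures, not measured quantities; only the
#' orderings relative to [aged_like_profile()] are contractual (tested).
#'
#' @return An [agent_profile()].
#' @export
young_like_profile <- function() {
  agent_profile(
    name = "young_like",
    seq_len_dist = list(family = "nbinom_shifted", size = 3, mu = 4),
    ipi_dist = list(family = "lognormal", meanlog = log(0.5), sdlog = 0.4),
    term_int_dist = list(family = "lognormal", meanlog = log(2.5), sdlog = 0.5),
    init_int_dist = list(family = "lognormal", meanlog = log(4.5), sdlog = 0.6),
    n_checks_dist = list(family = "poisson_shifted", lambda = 0.8),
    pause_prob = 0.12,
    pause_dist = list(family = "lognormal", meanlog = log(45), sdlog = 0.4))
}

#' Aged-like agent preset
#'
#' Emulates the aged "microchunk" phenotype: shorter and faster sequences
#' produced at a higher rate, with within-sequence IPIs and boundary
#' intervals compressed towards the chunking space. Parameter values are
#' generator fixtures; only the orderings relative to
#' [young_like_profile()] are contractual (tested).
#'
#' @return An [agent_profile()].
#' @export
aged_like_profile <- function() {
  agent_profile(
    name = "aged_like",
    seq_len_dist = list(family = "nbinom_shifted", size = 3, mu = 1.6),
    ipi_dist = list(family = "lognormal", meanlog = log(0.2), sdlog = 0.35),
    term_int_dist = list(family = "lognormal", meanlog = log(1.1), sdlog = 0.4),
    init_int_dist = list(family = "lognormal", meanlog = log(1.6), sdlog = 0.5),
    n_checks_dist = list(family = "poisson_shifted", lambda = 0.5),
    pause_prob = 0.04,
    pause_dist = list(family = "lognormal", meanlog = log(45), sdlog = 0.4))
}

#' Generate one synthetic session with ground truth
#'
#' Simulates a session under an agent profile and a schedule. The agent
#' emits sequences of presses (sampled length and IPIs), a termination
#' magazine check after each sequence (plus possible extra consecutive
#' checks, which the parser must ignore), and a boundary interval before
#' the next sequence (occasionally replaced by a long off-task pause). The
#' schedule is consulted per press (sequence-trigger gate and RR draw
#' where configured); a reinforced press truncates the ongoing sequence —
#' the agent heads to the magazine to collect. Sampled inter-event gaps
#' are quantised to the 10-ms grid with a 1-cs floor, which reproduces the
#' timestamp pile-up artefact at very short intervals.
#'
#' @param profile An [agent_profile()].
#' @param schedule A [schedule_descriptor()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param subject_id,day Metadata stored on the record.
#' @return List with `record` (a [session_record()]) and `truth` (ground
#'   truth: `labels`, a character vector parallel to the event rows with
#'   values initiation/execution/termination/ignored and `NA` for
#'   pellet/cue rows, and `sequences`, a data frame of per-sequence start
#'   and end event-row indices with the realised length and rewarded flag).
#' @export
generate_session <- function(profile, schedule, seed,
                             subject_id = profile$name, day = 1L) {
  stopifnot(inherits(profile, "agent_profile"),
            inherits(schedule, "schedule_descriptor"))
  with_seed(seed, {
    max_cs <- quantize_time(schedule$max_time_s)
    st <- if (schedule$kind == "RR_ST") st_state(schedule$st_requirement)
    use_rr <- schedule$kind %in% c("CRF", "RR", "RR_ST")
    times <- integer(0); kinds <- character(0); labels <- character(0)
    seq_start <- integer(0); seq_end <- integer(0)
    seq_len_out <- integer(0); seq_rew <- logical(0)
    add <- function(t, k, lab) {
      times[[length(times) + 1L]] <<- t
      kinds[[length(kinds) + 1L]] <<- k
      labels[[length(labels) + 1L]] <<- lab
      length(times)
    }
    gap_cs <- function(d) max(1L, quantize_time(sample_dist(d, 1)))
    rewards <- 0L
    now <- 0L
    ended <- FALSE
    repeat {
      # boundary: check-to-press interval (or off-task pause) to next initiation
      dt <- if (stats::runif(1) < profile$pause_prob)
        gap_cs(profile$pause_dist) else gap_cs(profile$init_int_dist)
      now <- now + dt
      if (now > max_cs) { ended <- TRUE; break }
      L <- sample_dist(profile$seq_len_dist, 1)
      first_row <- length(times) + 1L
      reinforced <- FALSE
      emitted <- 0L
      for (i in seq_len(L)) {
        if (i > 1) {
          now <- now + gap_cs(profile$ipi_dist)
          if (now > max_cs) { ended <- TRUE; break }
        }
        add(now, "LP_ACTIVE", if (i == 1) "initiation" else "execution")
        emitted <- emitted + 1L
        if (use_rr) {
          ok <- if (schedule$kind == "RR_ST") {
            g <- st_gate_step(st, "PRESS"); st <- g$state; g$rr_accessible
          } else TRUE
          if (ok && stats::runif(1) < schedule$p_reinforce) {
            reinforced <- TRUE
            rewards <- rewards + 1L
            if (schedule$kind == "RR_ST") st <- st_gate_step(st, "REWARD")$state
            if (schedule$cue_enabled) add(now, "CUE_ON", NA_character_)
            add(now, "PELLET", NA_character_)
            break  # agent stops pressing to collect
          }
        }
      }
      if (emitted > 0L) {
        seq_start[[length(seq_start) + 1L]] <- first_row
        seq_len_out[[length(seq_len_out) + 1L]] <- emitted
        seq_rew[[length(seq_rew) + 1L]] <- reinforced
      }
      if (ended) {
        if (emitted > 0L) seq_end[[length(seq_end) + 1L]] <- length(times)
        break
      }
      # termination check(s)
      now <- now + gap_cs(profile$term_int_dist)
      if (now > max_cs) {
        if (emitted > 0L) seq_end[[length(seq_end) + 1L]] <- length(times)
        break
      }
      if (!reinforced && schedule$kind == "RR_ST")
        st <- st_gate_step(st, "TERMINATION")$state
      row <- add(now, "MAG_ENTRY", "termination")
      if (emitted > 0L) seq_end[[length(seq_end) + 1L]] <- row
      extra <- sample_dist(profile$n_checks_dist, 1) - 1
      for (j in seq_len(extra)) {
        now <- now + gap_cs(profile$check_gap_dist)
        if (now > max_cs) { ended <- TRUE; break }
        add(now, "MAG_ENTRY", "ignored")
      }
      if (ended) break
      if (rewards >= schedule$max_rewards) break
    }
    duration_cs <- if (rewards >= schedule$max_rewards && length(times))
      times[length(times)] else max_cs
    record <- session_record(subject_id, day, schedule,
      data.frame(time_cs = times, kind = kinds, hold_cs = NA_integer_,
                 stringsAsFactors = FALSE),
      duration_cs = duration_cs)
    truth <- list(
      labels = labels,
      sequences = data.frame(
        seq_index = seq_along(seq_start), start_row = seq_start,
        end_row = seq_end, length = seq_len_out, rewarded = seq_rew))
    list(record = record, truth = truth)
  })
}

#' Generate a cohort of synthetic sessions
#'
#' One session per subject and day. Each (subject, day) cell uses an
#' independent seed derived from the master seed via [derive_seed()], so a
#' subject's data do not depend on how many other subjects are generated.
#'
#' @param n_subjects Number of subjects.
#' @param profile An [agent_profile()] (or a function `(subject) ->
#'   profile` for heterogeneous cohorts).
#' @param schedule A [schedule_descriptor()].
#' @param days Number of training days.
#' @param seed Master seed.
#' @return List of session-with-truth lists as returned by
#'   [generate_session()], ordered subject-major.
#' @export
generate_cohort <- function(n_subjects, profile, schedule, days = 1L, seed) {
  out <- vector("list", n_subjects * days)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    prof <- if (is.function(profile)) profile(s) else profile
    for (d in seq_len(days)) {
      k <- k + 1L
      out[[k]] <- generate_session(
        prof, schedule,
        seed = derive_seed(seed, sprintf("subject%d/day%d", s, d)),
        subject_id = sprintf("%s_%02d", prof$name, s), day = d)
    }
  }
  out
}

#' Generate a magazine-training session
#'
#' Pellets are delivered on a random-time schedule (exponential
#' inter-delivery intervals, mean `mean_interval_s`); the simulated mouse
#' checks the magazine after each delivery with a sampled reaction time.
#' A reaction that would land after the next delivery still produces its
#' check (first-check analysis treats the pellet with no check before the
#' next delivery as censored).
#'
#' @param mean_interval_s Mean inter-delivery interval, seconds (RT 60 s
#'   by default).
#' @param n_pellets Number of pellets (20 by default).
#' @param reaction_dist Reaction-time distribution spec (seconds).
#' @param seed Integer seed.
#' @param subject_id,day Metadata.
#' @return A [session_record()] under a MAGAZINE schedule.
#' @export
generate_magazine_session <- function(mean_interval_s = 60, n_pellets = 20,
                                      reaction_dist = list(
                                        family = "lognormal",
                                        meanlog = log(2), sdlog = 0.5),
                                      seed = 1L,
                                      subject_id = "mag", day = 1L) {
  with_seed(seed, {
    pellet_s <- cumsum(magazine_rt_step(mean_interval_s, n_pellets))
    check_s <- pellet_s + sample_dist(reaction_dist, n_pellets)
    ev <- rbind(
      data.frame(time_cs = quantize_time(pellet_s), kind = "PELLET",
                 stringsAsFactors = FALSE),
      data.frame(time_cs = quantize_time(check_s), kind = "MAG_ENTRY",
                 stringsAsFactors = FALSE))
    ev <- ev[order(ev$time_cs), , drop = FALSE]
    dur <- max(ev$time_cs) + 100L
    session_record(subject_id, day,
                   schedule_descriptor("MAGAZINE", max_rewards = n_pellets,
                                       max_time_s = dur / 100),
                   ev, duration_cs = dur)
  })
}
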