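#' Create a random-ratio schedule state
#'
#' @param p_reinforce Per-press reinforcement probability in `[0, 1]`.
#' @return An `rr_state` list with the probability and a reward counter.
#' @export
rr_state <- function(p_reinforce) {
  if (p_reinforce < 0 || p_reinforce > 1) stop("p_reinforce must be in [0, 1]")
  structure(list(p_reinforce = p_reinforce, rewards_delivered = 0L),
            class = "rr_state")
}

#' Advance a random-ratio schedule by one press
#'
#' Each active lever press is reinforced with independent probability
#' `p_reinforce` (the RR-n schedule rewards each press with probability
#' 1/n, e.g. RR5 has p = 0.2 and RR20 has p = 0.05). Draws come from R's
#' global RNG stream; seed it with [set.seed()] for reproducibility.
#'
#' @param state An [rr_state()].
#' @return List with `reinforced` (logical) and the updated `state`.
#' @export
rr_step <- function(state) {
  stopifnot(inherits(state, "rr_state"))
  reinforced <- stats::runif(1) < state$p_reinforce
  if (reinforced)
    state$rewards_delivered <- state$rewards_delivered + 1L
  list(reinforced = reinforced, state = state)
}

#' Create a sequence-trigger gate state
#'
#' The sequence trigger (ST) limits access to the RR program to action
#' sequences initiated with at least `requirement_n` consecutive lever
#' presses (5 from training day 10, 7 from day 13).
#'
#' @param requirement_n Required number of initial consecutive presses.
#' @return An `st_state` list.
#' @export
st_state <- function(requirement_n) {
  if (requirement_n < 1) stop("requirement_n must be >= 1")
  structure(list(requirement_n = as.integer(requirement_n),
                 consecutive_presses = 0L, unlocked = FALSE),
            class = "st_state")
}

#' Advance the sequence-trigger gate by one behavioural element
#'
#' Semantics: a `PRESS` increments the consecutive-press counter; once the
#' counter reaches the requirement the gate unlocks and the RR program is
#' accessible for that press and all later presses of the same sequence. A
#' `TERMINATION` (press followed by magazine check) before unlocking resets
#' the counter with the RR program never consulted for that sequence; a
#' `TERMINATION` after unlocking but before reward resets the RR trial
#' (counter reset, lock re-imposed). A `REWARD` completes the sequence
#' normally: counter reset and lock re-imposed for the next sequence.
#'
#' @param state An [st_state()].
#' @param element One of `"PRESS"`, `"TERMINATION"`, `"REWARD"`.
#' @return List with `rr_accessible` (logical: may the RR program be
#'   consulted for this press) and the updated `state`. `rr_accessible` is
#'   only meaningful for `PRESS` elements and is `FALSE` otherwise.
#' @export
st_gate_step <- function(state, element) {
  stopifnot(inherits(state, "st_state"))
  element <- match.arg(element, c("PRESS", "TERMINATION", "REWARD"))
  rr_accessible <- FALSE
  if (element == "PRESS") {
    state$consecutive_presses <- state$consecutive_presses + 1L
    if (state$consecutive_presses >= state$requirement_n)
      state$unlocked <- TRUE
    rr_accessible <- state$unlocked
  } else {
    # TERMINATION or REWARD: sequence over, reset and re-lock
    state$consecutive_presses <- 0L
    state$unlocked <- FALSE
  }
  list(rr_accessible = rr_accessible, state = state)
}

#' Lever-hold requirement parameters
#'
#' Named presets for the lever-hold (LH) training stages. Hold requirements
#' are drawn fresh each trial from an exponential distribution truncated to
#' hard bounds, with the rate solved so the truncated mean equals the
#' stage's nominal mean. The LH0.3 stage has mean 0.3 s with bounds
#' 0.05–0.88 s; the final LH5 stage averages 5 s with holds as long as
#' 11.7 s. Stage minima and the intermediate-stage maxima are not part of
#' the published parameterisation; defaults keep the 0.05-s floor
#' throughout and scale intermediate maxima by the final-stage max/mean
#' ratio (11.7/5).
#'
#' @param stage One of `"LH0.3"`, `"LH0.8"`, `"LH2"`, `"LH3.2"`, `"LH5"`,
#'   or `NULL` to pass explicit values.
#' @param mean_s,min_s,max_s Explicit mean and bounds in seconds.
#' @return An `lh_params` list with `mean_s`, `min_s`, `max_s` and the
#'   solved truncation `rate`.
#' @export
lh_params <- function(stage = NULL, mean_s = NULL, min_s = 0.05,
                      max_s = NULL) {
  presets <- list(
    "LH0.3" = c(0.3, 0.05, 0.88),
    "LH0.8" = c(0.8, 0.05, 0.8 * 11.7 / 5),
    "LH2"   = c(2,   0.05, 2   * 11.7 / 5),
    "LH3.2" = c(3.2, 0.05, 3.2 * 11.7 / 5),
    "LH5"   = c(5,   0.05, 11.7))
  if (!is.null(stage)) {
    stage <- match.arg(stage, names(presets))
    v <- presets[[stage]]
    mean_s <- v[1]; min_s <- v[2]; max_s <- v[3]
  }
  if (is.null(mean_s) || is.null(max_s))
    stop("supply a stage name or explicit mean_s and max_s")
  if (!(min_s <= mean_s && mean_s <= max_s) || min_s <= 0)
    stop("need 0 < min_s <= mean_s <= max_s")
  structure(list(mean_s = mean_s, min_s = min_s, max_s = max_s,
                 rate = lh_solve_rate(mean_s, min_s, max_s)),
            class = "lh_params")
}

# Mean of Exp(rate) truncated to [a, b]; rate may be negative (density
# increasing towards b), and rate -> 0 recovers the uniform mean (a+b)/2.
lh_trunc_mean <- function(rate, a, b) {
  w <- b - a
  if (abs(rate * w) < 1e-8) return(a + w / 2 - rate * w^2 / 12)
  a + 1 / rate - w / (exp(rate * w) - 1)
}

lh_solve_rate <- function(mean_s, a, b) {
  if (b == a) return(Inf)  # degenerate: every draw equals the bound
  f <- function(r) lh_trunc_mean(r, a, b) - mean_s
  lim <- 1e3 / (b - a)
  stats::uniroot(f, lower = -lim, upper = lim, tol = 1e-12)$root
}

#' Draw lever-hold requirements
#'
#' Draws from the bounded-exponential requirement distribution by inverse
#' CDF; every draw lies within `[min_s, max_s]` and the long-run mean
#' equals `mean_s`.
#'
#' @param params An [lh_params()].
#' @param n Number of draws.
#' @return Numeric vector of required hold durations in seconds.
#' @examples
#' set.seed(1)
#' r <- lh_draw_requirement(lh_params("LH0.3"), 1000)
#' range(r)   # within [0.05, 0.88]
#' mean(r)    # ~0.3
#' @export
lh_draw_requirement <- function(params, n = 1) {
  stopifnot(inherits(params, "lh_params"))
  a <- params$min_s; b <- params$max_s; r <- params$rate
  if (!is.finite(r) || b == a) return(rep(a, n))
  u <- stats::runif(n)
  if (abs(r * (b - a)) < 1e-8) return(a + u * (b - a))
  a - log(1 - u * (1 - exp(-r * (b - a)))) / r
}

#' Judge a lever hold against its drawn requirement
#'
#' The hold is reinforced when it meets or exceeds the requirement
#' (boundary inclusive).
#'
#' @param hold_s Observed hold duration, seconds.
#' @param requirement_s Required hold duration, seconds.
#' @return Logical vector: reinforced?
#' @export
lh_judge <- function(hold_s, requirement_s) {
  if (any(hold_s < 0) || any(requirement_s < 0))
    stop("durations must be >= 0")
  hold_s >= requirement_s
}

#' Draw the next delivery delay of a random-time schedule
#'
#' Random-time (RT) schedules deliver pellets at exponentially distributed
#' intervals independent of behaviour (magazine training uses RT 60 s).
#'
#' @param mean_interval_s Mean inter-delivery interval in seconds.
#' @param n Number of draws.
#' @return Numeric vector of delays in seconds.
#' @export
magazine_rt_step <- function(mean_interval_s, n = 1) {
  if (mean_interval_s <= 0) stop("mean_interval_s must be > 0")
  stats::rexp(n, rate = 1 / mean_interval_s)
}

#' Simulate pellet-drop session durations
#'
#' The pellet-drop procedure activates the dispenser with probability `p`
#' at each 1-second tick and ends when `n_pellets` pellets have been
#' delivered. With the standard p = 0.1 and 10 pellets the expected
#' duration is 100 s (about 1.66 min).
#'
#' @param n_sessions Number of sessions to simulate.
#' @param p Per-second delivery probability.
#' @param n_pellets Pellets per session.
#' @return Numeric vector of session durations in seconds (time of the
#'   final delivery, counting ticks from 1).
#' @export
pellet_drop_session <- function(n_sessions = 1, p = 0.1, n_pellets = 10) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  # duration = sum of n_pellets geometric waiting times (in whole seconds)
  draws <- stats::rgeom(n_sessions * n_pellets, p) + 1
  colSums(matrix(draws, nrow = n_pellets))
}

#' Fixed-rate pressing agent
#'
#' A deterministic agent for driving [run_session()]: presses the active
#' lever every `press_interval_s` seconds and, when a press is reinforced,
#' heads to the magazine `collect_latency_s` later before resuming
#' pressing.
#'
#' @param press_interval_s Interval between presses, seconds.
#' @param collect Collect rewards with a magazine entry?
#' @param collect_latency_s Press-to-magazine latency, seconds.
#' @param hold_s Lever-hold duration attached to each press (LH sessions).
#' @return An agent function for [run_session()].
#' @export
make_fixed_rate_agent <- function(press_interval_s = 2, collect = TRUE,
                                  collect_latency_s = 1, hold_s = NA) {
  force(press_interval_s); force(collect); force(collect_latency_s)
  function(now_cs, last_press_reinforced) {
    if (collect && isTRUE(last_press_reinforced)) {
      list(kind = "MAG_ENTRY", dt_cs = quantize_time(collect_latency_s))
    } else {
      list(kind = "LP_ACTIVE", dt_cs = quantize_time(press_interval_s),
           hold_cs = if (is.na(hold_s)) NA_integer_ else quantize_time(hold_s))
    }
  }
}

#' Run one operant session under a schedule
#'
#' Drives an agent against a schedule state machine and records the event
#' stream. The agent is a function `(now_cs, last_press_reinforced)`
#' returning the next behavioural event as a list with `kind`
#' (`"LP_ACTIVE"`, `"LP_INACTIVE"` or `"MAG_ENTRY"`), `dt_cs` (delay from
#' `now_cs`, at least 1 cs) and optionally `hold_cs`. The engine applies
#' the schedule (RR Bernoulli draw gated by the sequence trigger where
#' configured; lever-hold judgement for LH), emits `PELLET` (and, when the
#' cue is enabled, `CUE_ON`) events at the reinforcing press time, and
#' terminates at the reward cap or the session timeout, whichever first.
#'
#' @param agent Agent function (see above, or [make_fixed_rate_agent()]).
#' @param schedule A [schedule_descriptor()].
#' @param subject_id,day Metadata stored on the record.
#' @return A [session_record()].
#' @export
run_session <- function(agent, schedule, subject_id = "sim", day = 1L) {
  stopifnot(inherits(schedule, "schedule_descriptor"))
  max_cs <- quantize_time(schedule$max_time_s)
  st <- if (schedule$kind == "RR_ST") st_state(schedule$st_requirement)
  lhp <- if (schedule$kind == "LH")
    lh_params(mean_s = schedule$lh_mean_s, min_s = schedule$lh_min_s,
              max_s = schedule$lh_max_s)
  cue_on <- schedule$cue_enabled
  times <- integer(0); kinds <- character(0); holds <- integer(0)
  add <- function(t, k, h = NA_integer_) {
    times[[length(times) + 1L]] <<- t
    kinds[[length(kinds) + 1L]] <<- k
    holds[[length(holds) + 1L]] <<- h
  }
  now <- 0L; rewards <- 0L; last_reinforced <- FALSE
  repeat {
    ev <- agent(now, last_reinforced)
    dt <- max(1L, as.integer(ev$dt_cs))
    t <- now + dt
    if (t > max_cs) { now <- max_cs; break }
    if (t < now + 1L) stop("agent emitted a time-travelling event")
    reinforced <- FALSE
    if (ev$kind == "LP_ACTIVE") {
      consult_rr <- switch(schedule$kind,
        CRF = TRUE, RR = TRUE,
        RR_ST = {
          g <- st_gate_step(st, "PRESS")
          st <- g$state
          g$rr_accessible
        },
        FALSE)
      if (consult_rr)
        reinforced <- stats::runif(1) < schedule$p_reinforce
      if (schedule$kind == "LH") {
        hold_s <- (if (is.null(ev$hold_cs) || is.na(ev$hold_cs)) 0L
                   else ev$hold_cs) / 100
        reinforced <- lh_judge(hold_s, lh_draw_requirement(lhp))
      }
      add(t, "LP_ACTIVE",
          if (is.null(ev$hold_cs)) NA_integer_ else as.integer(ev$hold_cs))
      if (reinforced) {
        rewards <- rewards + 1L
        if (schedule$kind == "RR_ST") st <- st_gate_step(st, "REWARD")$state
        if (cue_on) add(t, "CUE_ON")
        add(t, "PELLET")
      }
      last_reinforced <- reinforced
    } else if (ev$kind == "MAG_ENTRY") {
      if (schedule$kind == "RR_ST") st <- st_gate_step(st, "TERMINATION")$state
      add(t, "MAG_ENTRY")
      last_reinforced <- FALSE
    } else if (ev$kind == "LP_INACTIVE") {
      add(t, "LP_INACTIVE")
    } else stop("agent emitted unknown event kind: ", ev$kind)
    now <- t
    if (rewards >= schedule$max_rewards) break
  }
  session_record(subject_id, day, schedule,
                 data.frame(time_cs = times, kind = kinds, hold_cs = holds,
                            stringsAsFactors = FALSE),
                 duration_cs = if (rewards >= schedule$max_rewards) now
                               else max_cs)
}
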