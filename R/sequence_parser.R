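#' Classify behavioural events into sequence elements
#'
#' Labels each active lever press and magazine entry by its predecessor:
#' an initiation is the first press of the session or a press occurring
#' after a magazine check; an execution is a press occurring after a
#' press; a termination is a magazine check occurring after a press.
#' Consecutive magazine checks produced after the termination of a
#' sequence are ignored, as are checks preceding any press. Pellet, cue
#' and inactive-lever events pass through unlabelled (`NA`) and do not
#' affect the classification.
#'
#' @param events Event data frame (`time_cs`, `kind`, ...) sorted by time,
#'   or a [session_record()].
#' @return The event data frame with an added character column `label`
#'   (`"initiation"`, `"execution"`, `"termination"`, `"ignored"`, or `NA`).
#' @export
classify_elements <- function(events) {
  if (inherits(events, "session_record")) events <- events$events
  if (nrow(events) && is.unsorted(events$time_cs)) stop("events must be sorted")
  label <- rep(NA_character_, nrow(events))
  prev <- "none"  # last behavioural element among press/check
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k == "LP_ACTIVE") {
      label[i] <- if (prev == "press") "execution" else "initiation"
      prev <- "press"
    } else if (k == "MAG_ENTRY") {
      label[i] <- if (prev == "press") "termination" else "ignored"
      prev <- "check"
    }
  }
  events$label <- label
  events
}

#' Parse labelled events into action sequences
#'
#' Assembles one action sequence per initiation press. Each sequence spans
#' its initiation press, any execution presses, and the termination
#' magazine check; a trailing sequence with no termination before the
#' session end is emitted with `open = TRUE`. A sequence is `rewarded`
#' when a pellet event falls between its initiation and termination
#' (inclusive) — attribution uses pellet timestamps only, so parsing works
#' on logs alone.
#'
#' @param labelled Output of [classify_elements()] (a data frame with a
#'   `label` column), or an unlabelled event data frame / [session_record()]
#'   (classified on the fly).
#' @return An object of class `action_sequences`: a data frame with one
#'   row per sequence (`seq_index`, `start_cs`, `end_cs`, `length`,
#'   `duration_s`, `press_span_s`, `speed_pps`, `rewarded`, `open`) and an
#'   attribute `ipis` (list of within-sequence inter-press intervals in
#'   seconds) plus `labelled` (the labelled event table). `end_cs` and
#'   `duration_s` are `NA` for open sequences; `speed_pps` is `NA` for
#'   length-1 sequences.
#' @export
parse_sequences <- function(labelled) {
  if (inherits(labelled, "session_record") || !"label" %in% names(labelled))
    labelled <- classify_elements(labelled)
  lab <- labelled$label
  init_rows <- which(lab == "initiation" & !is.na(lab))
  n <- length(init_rows)
  pellet_t <- labelled$time_cs[labelled$kind == "PELLET"]
  start_cs <- end_cs <- integer(n)
  len <- integer(n); open <- logical(n); rewarded <- logical(n)
  span_s <- dur_s <- speed <- numeric(n)
  ipis <- vector("list", n)
  for (j in seq_len(n)) {
    i0 <- init_rows[j]
    i1 <- if (j < n) init_rows[j + 1] - 1L else nrow(labelled)
    rows <- i0:i1
    press_rows <- rows[lab[rows] %in% c("initiation", "execution")]
    term_row <- rows[which(lab[rows] == "termination")[1]]
    pt <- labelled$time_cs[press_rows]
    start_cs[j] <- pt[1]
    len[j] <- length(pt)
    ipis[[j]] <- diff(pt) / 100
    span_s[j] <- (pt[length(pt)] - pt[1]) / 100
    speed[j] <- if (len[j] >= 2) (len[j] - 1) / span_s[j] else NA_real_
    if (length(term_row) == 1 && !is.na(term_row)) {
      open[j] <- FALSE
      end_cs[j] <- labelled$time_cs[term_row]
      dur_s[j] <- (end_cs[j] - start_cs[j]) / 100
      rewarded[j] <- any(pellet_t >= start_cs[j] & pellet_t <= end_cs[j])
    } else {
      open[j] <- TRUE
      end_cs[j] <- NA_integer_
      dur_s[j] <- NA_real_
      rewarded[j] <- any(pellet_t >= start_cs[j] & pellet_t <= pt[length(pt)])
    }
  }
  out <- data.frame(seq_index = seq_len(n), start_cs = start_cs,
                    end_cs = end_cs, length = len, duration_s = dur_s,
                    press_span_s = span_s, speed_pps = speed,
                    rewarded = rewarded, open = open)
  attr(out, "ipis") <- ipis
  attr(out, "labelled") <- labelled
  class(out) <- c("action_sequences", "data.frame")
  out
}

#' Per-sequence metrics
#'
#' Recomputes the derived metrics of one parsed sequence row. Duration
#' follows the initiation-to-termination convention by default (time from
#' the initiation press to the termination magazine check); the press-span
#' alternative (first press to last press) is available via
#' `duration = "press_span"`. Speed is `(length - 1) / press_span_s`
#' (presses per second; the reciprocal of the mean IPI), undefined for
#' length-1 sequences.
#'
#' @param parsed An `action_sequences` object from [parse_sequences()].
#' @param duration `"init_term"` (default) or `"press_span"`.
#' @return Data frame with `seq_index`, `length`, `duration_s`,
#'   `speed_pps`, `mean_ipi_s`, `rewarded`.
#' @export
sequence_metrics <- function(parsed, duration = c("init_term", "press_span")) {
  duration <- match.arg(duration)
  ipis <- attr(parsed, "ipis")
  data.frame(
    seq_index = parsed$seq_index,
    length = parsed$length,
    duration_s = if (duration == "init_term") parsed$duration_s
                 else parsed$press_span_s,
    speed_pps = parsed$speed_pps,
    mean_ipi_s = vapply(ipis, function(x)
      if (length(x)) mean(x) else NA_real_, 0),
    rewarded = parsed$rewarded)
}

#' Session-level summary of parsed behaviour
#'
#' Rates are normalised by the session duration in minutes: the sequence
#' rate (sequences per minute), lever-press rate, and efficiency (rewards
#' earned per minute). Mean/SD of sequence length, duration and speed are
#' taken over terminated sequences only (an open trailing sequence has no
#' measurable duration and is excluded from all summaries).
#'
#' @param record A [session_record()].
#' @param parsed Optional pre-parsed `action_sequences`; parsed from
#'   `record` if missing.
#' @return One-row data frame of session summaries and element counts.
#' @export
session_summary <- function(record, parsed = NULL) {
  stopifnot(inherits(record, "session_record"))
  if (is.null(parsed)) parsed <- parse_sequences(record)
  lab <- attr(parsed, "labelled")$label
  mins <- record$duration_cs / 100 / 60
  closed <- parsed[!parsed$open, , drop = FALSE]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  data.frame(
    subject_id = record$subject_id, day = record$day,
    duration_min = mins,
    n_sequences = nrow(closed),
    n_presses = sum(record$events$kind == "LP_ACTIVE"),
    n_pellets = sum(record$events$kind == "PELLET"),
    n_initiations = sum(lab == "initiation", na.rm = TRUE),
    n_executions = sum(lab == "execution", na.rm = TRUE),
    n_terminations = sum(lab == "termination", na.rm = TRUE),
    n_ignored_checks = sum(lab == "ignored", na.rm = TRUE),
    sequence_rate_per_min = nrow(closed) / mins,
    lp_rate_per_min = sum(record$events$kind == "LP_ACTIVE") / mins,
    rewards_per_min = sum(record$events$kind == "PELLET") / mins,
    mean_length = if (nrow(closed)) mean(closed$length) else NA_real_,
    sd_length = sd0(closed$length),
    mean_duration_s = if (nrow(closed)) mean(closed$duration_s) else NA_real_,
    sd_duration_s = sd0(closed$duration_s),
    mean_speed_pps = if (any(!is.na(closed$speed_pps)))
      mean(closed$speed_pps, na.rm = TRUE) else NA_real_,
    sd_speed_pps = sd0(closed$speed_pps[!is.na(closed$speed_pps)]),
    stringsAsFactors = FALSE)
}

#' First-check intervals of a magazine session
#'
#' For each pellet delivery, the reaction time to the first magazine check
#' strictly after it. A pellet with no check before the next delivery (or
#' session end) yields a censored entry (`NA`).
#'
#' @param record A magazine-training [session_record()].
#' @return Data frame with `pellet_time_cs` and `first_check_s` (`NA`
#'   when censored).
#' @export
first_check_intervals <- function(record) {
  stopifnot(inherits(record, "session_record"))
  ev <- record$events
  pt <- ev$time_cs[ev$kind == "PELLET"]
  ct <- ev$time_cs[ev$kind == "MAG_ENTRY"]
  nxt <- c(pt[-1], Inf)
  first_check <- vapply(seq_along(pt), function(i) {
    cand <- ct[ct > pt[i] & ct <= nxt[i]]
    if (length(cand)) (cand[1] - pt[i]) / 100 else NA_real_
  }, 0)
  data.frame(pellet_time_cs = pt, first_check_s = first_check)
}
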