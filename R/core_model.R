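#' actionchunks: operant schedules, action-sequence chunking and activation mapping
#'
#' Simulation and analysis of single-lever operant conditioning sessions
#' recorded as time-stamped event streams at 10-ms resolution. The package
#' covers the reinforcement-schedule state machines (CRF, random ratio,
#' sequence-trigger gating, lever hold, random time, pellet drop), a
#' synthetic-agent session generator with ground-truth element labels, the
#' parsing of event streams into action sequences (initiation / execution /
#' termination elements), within-sequence versus sequence-boundary interval
#' analyses of motor chunking, acoustic recovery of true inter-press
#' intervals, and regional activation mapping on section images.
#'
#' Internal time unit is integer centiseconds (1 cs = 10 ms), matching the
#' recording resolution of the behavioural apparatus; seconds appear only
#' at API boundaries.
#'
#' @keywords internal
"_PACKAGE"

#' Event kinds recognised in a session record
#'
#' @format Character vector of the five event kinds: active and inactive
#'   lever presses, magazine entries, pellet deliveries, and cue onsets.
#' @export
EVENT_KINDS <- c("LP_ACTIVE", "LP_INACTIVE", "MAG_ENTRY", "PELLET", "CUE_ON")

#' Quantise a time in seconds to the centisecond grid
#'
#' Event times are recorded on a 10-ms grid. `quantize_time()` maps a
#' non-negative time in seconds to integer centiseconds by flooring, and is
#' idempotent on times already on the grid.
#'
#' @param t_s Numeric vector of non-negative times in seconds.
#' @return Integer vector of centiseconds.
#' @examples
#' quantize_time(1.239)  # 123
#' quantize_time(0.004)  # 0, below the grid resolution
#' @export
quantize_time <- function(t_s) {
  if (!is.numeric(t_s) || any(is.na(t_s)) || any(t_s < 0))
    stop("t_s must be non-negative numeric")
  # +1e-9 guards against 0.29*100 = 28.999... style float representation
  as.integer(floor(t_s * 100 + 1e-9))
}

#' Construct a schedule descriptor
#'
#' A schedule descriptor captures the full parameterisation of one training
#' schedule: the schedule family, the per-press reinforcement probability
#' for the random-ratio (RR) family, the sequence-trigger (ST) press
#' requirement, the lever-hold (LH) requirement distribution bounds, the
#' feedback-cue setting, and the session termination caps.
#'
#' @param kind One of `"MAGAZINE"`, `"CRF"`, `"RR"`, `"RR_ST"`, `"LH"`,
#'   `"PELLET_DROP"`.
#' @param p_reinforce Per-press reinforcement probability in `[0, 1]` (RR
#'   family; CRF is the `p = 1` limit).
#' @param st_requirement Number of initial consecutive presses required to
#'   unlock the RR program (`RR_ST` only), or `NA`.
#' @param lh_mean_s,lh_min_s,lh_max_s Mean and hard bounds (seconds) of the
#'   lever-hold requirement distribution (`LH` only), or `NA`.
#' @param cue_enabled If `TRUE`, the press that triggers reward delivery is
#'   cued (a `CUE_ON` event of `cue_dur_s` seconds is emitted at that press).
#' @param cue_dur_s Cue duration in seconds (default 0.75).
#' @param max_rewards Session ends when this many pellets have been earned
#'   (default 20).
#' @param max_time_s Session ends at this time in seconds (default 1800).
#' @return An object of class `schedule_descriptor`.
#' @examples
#' schedule_descriptor("RR", p_reinforce = 0.2)          # RR5
#' schedule_descriptor("RR_ST", p_reinforce = 0.05, st_requirement = 7)
#' @export
schedule_descriptor <- function(kind,
                                p_reinforce = NA_real_,
                                st_requirement = NA_integer_,
                                lh_mean_s = NA_real_,
                                lh_min_s = NA_real_,
                                lh_max_s = NA_real_,
                                cue_enabled = FALSE,
                                cue_dur_s = 0.75,
                                max_rewards = 20L,
                                max_time_s = 1800) {
  kind <- match.arg(kind,
    c("MAGAZINE", "CRF", "RR", "RR_ST", "LH", "PELLET_DROP"))
  if (kind == "CRF") p_reinforce <- 1
  if (!is.na(p_reinforce) && (p_reinforce < 0 || p_reinforce > 1))
    stop("p_reinforce must lie in [0, 1]")
  if (kind %in% c("RR", "RR_ST") && is.na(p_reinforce))
    stop("RR schedules need p_reinforce")
  if (kind == "RR_ST" && (is.na(st_requirement) || st_requirement < 1))
    stop("RR_ST needs st_requirement >= 1")
  if (kind == "LH") {
    if (any(is.na(c(lh_mean_s, lh_min_s, lh_max_s))))
      stop("LH needs lh_mean_s, lh_min_s and lh_max_s")
    if (!(lh_min_s <= lh_mean_s && lh_mean_s <= lh_max_s))
      stop("need lh_min_s <= lh_mean_s <= lh_max_s")
  }
  if (max_rewards <= 0) stop("max_rewards must be positive")
  if (max_time_s <= 0) stop("max_time_s must be positive")
  structure(
    list(kind = kind, p_reinforce = p_reinforce,
         st_requirement = if (is.na(st_requirement)) NA_integer_
                          else as.integer(st_requirement),
         lh_mean_s = lh_mean_s, lh_min_s = lh_min_s, lh_max_s = lh_max_s,
         cue_enabled = isTRUE(cue_enabled), cue_dur_s = cue_dur_s,
         max_rewards = as.integer(max_rewards), max_time_s = max_time_s),
    class = "schedule_descriptor")
}

#' Construct a session record
#'
#' A session record holds the subject identity, training day, schedule and
#' the time-ordered event stream of one session. Events are stored as a
#' data frame with columns `time_cs` (integer centiseconds), `kind` (one of
#' [EVENT_KINDS]) and `hold_cs` (integer centiseconds, lever-hold sessions
#' only, otherwise `NA`). Ties in `time_cs` keep their supplied order.
#'
#' @param subject_id Subject identifier string.
#' @param day Positive integer training day.
#' @param schedule A [schedule_descriptor()].
#' @param events Data frame with columns `time_cs`, `kind`, and optionally
#'   `hold_cs`.
#' @param duration_cs Session duration in centiseconds; defaults to the
#'   schedule's `max_time_s` or the last event time, whichever is larger.
#' @return An object of class `session_record`.
#' @export
session_record <- function(subject_id, day, schedule, events,
                           duration_cs = NULL) {
  stopifnot(inherits(schedule, "schedule_descriptor"))
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(time_cs = integer(), kind = character(),
                         hold_cs = integer(), stringsAsFactors = FALSE)
  }
  if (!"hold_cs" %in% names(events)) events$hold_cs <- NA_integer_
  events <- events[, c("time_cs", "kind", "hold_cs")]
  events$time_cs <- as.integer(events$time_cs)
  events$hold_cs <- as.integer(events$hold_cs)
  events$kind <- as.character(events$kind)
  bad <- setdiff(unique(events$kind), EVENT_KINDS)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (any(events$time_cs < 0)) stop("event times must be >= 0")
  if (is.unsorted(events$time_cs)) {
    warning("events not sorted by time; repairing with a stable sort")
    events <- events[order(events$time_cs), , drop = FALSE]
  }
  rownames(events) <- NULL
  if (is.null(duration_cs)) {
    duration_cs <- max(quantize_time(schedule$max_time_s),
                       if (nrow(events)) max(events$time_cs) else 0L)
  }
  duration_cs <- as.integer(duration_cs)
  if (nrow(events) && max(events$time_cs) > duration_cs)
    stop("event times exceed duration_cs")
  structure(
    list(subject_id = as.character(subject_id), day = as.integer(day),
         schedule = schedule, events = events, duration_cs = duration_cs),
    class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  n <- table(factor(x$events$kind, levels = EVENT_KINDS))
  cat(sprintf("<session_record> subject %s, day %d, schedule %s\n",
              x$subject_id, x$day, x$schedule$kind))
  cat(sprintf("  %d events over %.1f s (%s)\n", nrow(x$events),
              x$duration_cs / 100,
              paste(sprintf("%s:%d", names(n), n), collapse = " ")))
  invisible(x)
}

schedule_to_list <- function(s) {
  out <- unclass(s)
  out[!vapply(out, function(v) length(v) == 1 && is.na(v), logical(1))]
}

schedule_from_list <- function(l) {
  do.call(schedule_descriptor, l)
}

#' Write a session record to a session-log file
#'
#' The session-log dialect is a UTF-8 text file with a YAML front-matter
#' block (subject id, day, duration and schedule fields) delimited by
#' `---` lines, followed by CSV with header `time_cs,kind,hold_cs`. Output
#' bytes are deterministic for a given record, so logs can be compared
#' verbatim.
#'
#' @param record A [session_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_session_log()]
#' @export
write_session_log <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  hdr <- list(subject_id = record$subject_id, day = record$day,
              duration_cs = record$duration_cs,
              schedule = schedule_to_list(record$schedule))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("---",
               sub("\n$", "", yaml::as.yaml(hdr, precision = 15)),
               "---",
               "time_cs,kind,hold_cs"), con, sep = "\n", useBytes = TRUE)
  if (nrow(record$events)) {
    ev <- record$events
    lines <- sprintf("%d,%s,%s", ev$time_cs, ev$kind,
                     ifelse(is.na(ev$hold_cs), "", ev$hold_cs))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a session record from a session-log file
#'
#' Parses the dialect written by [write_session_log()]. Events tied at the
#' same centisecond keep file order. Unsorted times are repaired with a
#' stable sort and a warning; a malformed event line is an error reporting
#' its line number.
#'
#' @param path Path to a session-log file.
#' @return A [session_record()].
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || lines[1] != "---")
    stop("not a session log (missing YAML front matter): ", path)
  end_hdr <- which(lines == "---")[2]
  if (is.na(end_hdr)) stop("unterminated YAML front matter in ", path)
  hdr <- yaml::yaml.load(paste(lines[2:(end_hdr - 1)], collapse = "\n"))
  body <- lines[(end_hdr + 1):length(lines)]
  if (length(body) == 0 || body[1] != "time_cs,kind,hold_cs")
    stop("missing CSV header in ", path)
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows)) {
    parts <- strsplit(rows, ",", fixed = TRUE)
    nfield <- lengths(parts)
    bad <- which(nfield < 2 | nfield > 3)
    if (length(bad))
      stop(sprintf("malformed event line %d in %s: '%s'",
                   end_hdr + 1 + bad[1], path, rows[bad[1]]))
    events <- data.frame(
      time_cs = as.integer(vapply(parts, `[`, "", 1)),
      kind = vapply(parts, `[`, "", 2),
      hold_cs = as.integer(vapply(parts, function(p)
        if (length(p) >= 3 && nzchar(p[3])) p[3] else NA_character_, "")),
      stringsAsFactors = FALSE)
    if (any(is.na(events$time_cs)))
      stop(sprintf("malformed time on event line %d in %s",
                   end_hdr + 1 + which(is.na(events$time_cs))[1], path))
  } else {
    events <- NULL
  }
  session_record(hdr$subject_id, hdr$day, schedule_from_list(hdr$schedule),
                 events, duration_cs = hdr$duration_cs)
}

#' Compare two session records for equality
#'
#' @param a,b Session records.
#' @return `TRUE` if subject, day, schedule, duration and the full event
#'   table (including tie order) are identical.
#' @export
session_equal <- function(a, b) {
  isTRUE(all.equal(a$subject_id, b$subject_id)) &&
    a$day == b$day && a$duration_cs == b$duration_cs &&
    isTRUE(all.equal(schedule_to_list(a$schedule),
                     schedule_to_list(b$schedule), tolerance = 1e-12)) &&
    identical(dim(a$events), dim(b$events)) &&
    isTRUE(all.equal(a$events, b$events, check.attributes = FALSE))
}
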