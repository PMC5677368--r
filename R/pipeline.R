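#' Resolve a schedule specification from a config list
#'
#' @param sched Named list of [schedule_descriptor()] arguments (a
#'   `schedule_descriptor` passes through).
#' @return A [schedule_descriptor()].
#' @export
resolve_schedule <- function(sched) {
  if (inherits(sched, "schedule_descriptor")) return(sched)
  do.call(schedule_descriptor, sched)
}

resolve_profile <- function(profile) {
  if (inherits(profile, "agent_profile")) return(profile)
  if (is.character(profile))
    return(switch(profile,
                  young_like = young_like_profile(),
                  aged_like = aged_like_profile(),
                  stop("unknown profile preset: ", profile)))
  do.call(agent_profile, profile)
}

#' Run the simulate / parse / chunk (/ acoustic / map) pipeline
#'
#' Orchestrates the full analysis on a synthetic cohort: session
#' generation, sequence parsing, interval categorisation and chunking
#' summaries, and optionally acoustic onset recovery on the fastest
#' sequences and activation mapping on synthetic section images. Every
#' stochastic stage draws its seed from the master seed via
#' [derive_seed()], so identical configs produce identical outputs and
#' any stage can be reproduced in isolation.
#'
#' Config keys (list or YAML file path): `out_dir` (optional; when set,
#' tables are written as CSV and a provenance manifest as JSON), `seed`,
#' `simulate` (`profile` preset name or parameter list, `subjects`,
#' `days`, `schedule` list), `parse` (`duration`: `"init_term"` or
#' `"press_span"`), `chunk` (`max_boundary_s`, `boundary`, `window_s`,
#' `k_fastest`), `acoustic` (`enabled`, `noise_rms`, `sample_rate_hz`),
#' `map` (`enabled`, `density_per_mm2`, `n_animals`).
#'
#' @param config Configuration list or path to a YAML config file.
#' @return Invisibly, a list of result tables (`sequences`, `summary`,
#'   `intervals`, `chunk_summary`, optionally `onsets`,
#'   `activation_table`, `detections`) plus the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "simulate", "parse", "chunk", "acoustic", "map")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config needs an explicit master seed")
  seed <- as.integer(config$seed)
  sim <- config$simulate
  if (is.null(sim)) stop("config needs a simulate stage")
  profile <- resolve_profile(sim$profile %||% "young_like")
  schedule <- resolve_schedule(sim$schedule %||%
    list(kind = "RR_ST", p_reinforce = 0.05, st_requirement = 7,
         max_rewards = 1000L, max_time_s = 1200))
  subjects <- sim$subjects %||% 4L
  days <- sim$days %||% 1L
  duration <- (config$parse$duration) %||% "init_term"
  max_boundary_s <- config$chunk$max_boundary_s %||% 20
  boundary <- config$chunk$boundary %||% "pooled"
  window_s <- config$chunk$window_s %||% 600
  k_fastest <- config$chunk$k_fastest %||% 5

  cohort <- generate_cohort(subjects, profile, schedule, days,
                            seed = derive_seed(seed, "simulate"))
  seq_rows <- list(); sum_rows <- list(); int_rows <- list()
  fast_rows <- list(); onset_rows <- list()
  acoustic_on <- isTRUE(config$acoustic$enabled)
  for (cell in cohort) {
    rec <- cell$record
    parsed <- parse_sequences(rec)
    met <- sequence_metrics(parsed, duration = duration)
    seq_rows[[length(seq_rows) + 1L]] <- data.frame(
      subject = rec$subject_id, day = rec$day,
      start_cs = parsed$start_cs, length = parsed$length,
      duration_s = met$duration_s, speed_pps = parsed$speed_pps,
      rewarded = parsed$rewarded, open = parsed$open,
      stringsAsFactors = FALSE)
    sum_rows[[length(sum_rows) + 1L]] <- session_summary(rec, parsed)
    iv <- categorize_intervals(parsed, max_boundary_s = max_boundary_s,
                               boundary = boundary)
    if (nrow(iv))
      int_rows[[length(int_rows) + 1L]] <- cbind(
        subject = rec$subject_id, day = rec$day, iv,
        stringsAsFactors = FALSE)
    fb <- fastest_sequences(parsed, k = k_fastest)
    fast_rows[[length(fast_rows) + 1L]] <- data.frame(
      subject = rec$subject_id, day = rec$day,
      mean_speed_pps = fb$mean_speed_pps, mean_ipi_s = fb$mean_ipi_s,
      n_bursts = nrow(fb$sequences), stringsAsFactors = FALSE)
    if (acoustic_on && nrow(fb$sequences)) {
      ipis <- attr(parsed, "ipis")
      for (j in seq_len(nrow(fb$sequences))) {
        row <- fb$sequences[j, ]
        press_s <- (row$start_cs / 100) + c(0, cumsum(ipis[[row$seq_index]]))
        trace <- synthesize_session_audio(
          press_s - press_s[1] + 0.1,
          noise_rms = config$acoustic$noise_rms %||% 0.02,
          sample_rate_hz = config$acoustic$sample_rate_hz %||% 22050,
          seed = derive_seed(seed, paste0("acoustic/", rec$subject_id, "/",
                                          rec$day, "/", row$seq_index)))
        det <- detect_press_onsets(trace)
        if (nrow(det) >= 1)
          onset_rows[[length(onset_rows) + 1L]] <- data.frame(
            subject = rec$subject_id, day = rec$day,
            seq_index = row$seq_index, time_s = det$time_s,
            score = det$score, stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(sequences = do.call(rbind, seq_rows),
              summary = do.call(rbind, sum_rows),
              intervals = do.call(rbind, int_rows),
              chunk_summary = do.call(rbind, lapply(seq_along(cohort),
                function(i) {
                  s <- interval_summary(
                    categorize_intervals(parse_sequences(cohort[[i]]$record),
                                         max_boundary_s = max_boundary_s,
                                         boundary = boundary),
                    window_s = window_s)
                  if (nrow(s)) cbind(subject = cohort[[i]]$record$subject_id,
                                     day = cohort[[i]]$record$day, s,
                                     stringsAsFactors = FALSE)
                })),
              fastest = do.call(rbind, fast_rows))
  if (acoustic_on) out$onsets <- do.call(rbind, onset_rows)

  if (isTRUE(config$map$enabled)) {
    n_animals <- config$map$n_animals %||% subjects
    atlas <- synthetic_atlas()
    det_rows <- list(); count_rows <- list()
    for (a in seq_len(n_animals)) {
      sec <- generate_section_image(
        atlas, per_region_density = config$map$density_per_mm2 %||% 800,
        seed = derive_seed(seed, paste0("map/animal", a)))
      det <- assign_regions(detect_somata(sec$image), atlas)
      det_rows[[a]] <- cbind(animal = a, det, stringsAsFactors = FALSE)
      rc <- region_counts(det, atlas)
      count_rows[[a]] <- stats::setNames(rc$count[rc$region != "UNASSIGNED"],
                                         rc$region[rc$region != "UNASSIGNED"])
    }
    out$detections <- do.call(rbind, det_rows)
    out$activation_table <- do.call(rbind, count_rows)
  }

  out$manifest <- list(
    package = "actionchunks",
    version = as.character(utils::packageVersion("actionchunks")),
    master_seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate")),
    profile = profile$name,
    schedule = schedule_to_list(schedule),
    subjects = subjects, days = days,
    parse = list(duration = duration),
    chunk = list(max_boundary_s = max_boundary_s, boundary = boundary,
                 window_s = window_s, k_fastest = k_fastest),
    stages_run = c("simulate", "parse", "chunk",
                   if (acoustic_on) "acoustic",
                   if (isTRUE(config$map$enabled)) "map"),
    stages_skipped = c(if (!acoustic_on) "acoustic",
                       if (!isTRUE(config$map$enabled)) "map"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df))
        utils::write.csv(df, file.path(config$out_dir, name),
                         row.names = FALSE)
    }
    wr(out$sequences, "sequences.csv")
    wr(out$summary, "summary.csv")
    wr(out$intervals, "intervals.csv")
    wr(out$chunk_summary, "chunk_summary.csv")
    wr(out$fastest, "fastest.csv")
    wr(out$onsets, "onsets.csv")
    if (!is.null(out$detections)) wr(out$detections, "detections.csv")
    if (!is.null(out$activation_table))
      utils::write.csv(as.data.frame(out$activation_table),
                       file.path(config$out_dir, "activation_table.csv"),
                       row.names = FALSE)
    jsonlite::write_json(out$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
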