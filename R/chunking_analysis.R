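#' Categorise action intervals into within-sequence and boundary records
#'
#' Within-sequence inter-press intervals (IPIs) are the intervals between
#' presses contained in the same sequence (execution intervals). Sequence
#' boundary intervals pool the press-to-check (termination) and
#' check-to-press (initiation) intervals that lie between sequences.
#' Boundary intervals beyond the cutoff (20 s by default) reflect
#' engagement in other behaviours and are disregarded.
#'
#' A check-to-press interval exists for every initiation press preceded by
#' a magazine check and is measured from the immediately preceding check
#' (the moment the animal leaves the magazine), so trailing ignored checks
#' anchor the interval but never create check-to-check intervals of their
#' own. Within-sequence intervals of an open trailing sequence (no
#' termination before session end) are excluded, matching the exclusion of
#' open sequences from sequence summaries.
#'
#' An alternative reading sums each termination interval with the
#' following initiation interval into one per-boundary value; it is
#' available via `boundary = "summed"`. The pooled form is the default.
#'
#' @param parsed An `action_sequences` object from [parse_sequences()] (or
#'   anything [parse_sequences()] accepts).
#' @param max_boundary_s Boundary-interval exclusion cutoff in seconds.
#' @param boundary `"pooled"` (default) or `"summed"`.
#' @return Data frame of interval records: `value_s`, `category`
#'   (`"WITHIN_SEQUENCE"` / `"BOUNDARY"`), `boundary_kind`
#'   (`"PRESS_CHECK"` / `"CHECK_PRESS"` / `NA`; `"SUMMED"` in summed
#'   mode), `session_time_cs` (time of the interval's closing event) and
#'   `sequence_index`.
#' @export
categorize_intervals <- function(parsed, max_boundary_s = 20,
                                 boundary = c("pooled", "summed")) {
  boundary <- match.arg(boundary)
  if (!inherits(parsed, "action_sequences")) parsed <- parse_sequences(parsed)
  lab_df <- attr(parsed, "labelled")
  lab <- lab_df$label
  t_cs <- lab_df$time_cs
  open_seq <- parsed$seq_index[parsed$open]
  rows <- which(!is.na(lab))
  val <- numeric(0); cat <- bk <- character(0)
  close_cs <- sidx <- integer(0)
  add <- function(v, category, kind, close_t, si) {
    val[[length(val) + 1L]] <<- v
    cat[[length(cat) + 1L]] <<- category
    bk[[length(bk) + 1L]] <<- kind
    close_cs[[length(close_cs) + 1L]] <<- close_t
    sidx[[length(sidx) + 1L]] <<- si
  }
  si <- 0L
  prev_press_cs <- NA_integer_  # time of the latest press
  prev_check_cs <- NA_integer_  # time of the latest check (incl. ignored)
  pending_term <- NULL  # termination interval awaiting its pair (summed mode)
  for (i in rows) {
    lc <- lab[i]
    if (lc == "initiation") {
      si <- si + 1L
      if (!is.na(prev_check_cs)) {
        dt <- (t_cs[i] - prev_check_cs) / 100
        if (boundary == "pooled") {
          add(dt, "BOUNDARY", "CHECK_PRESS", t_cs[i], si)
        } else if (!is.null(pending_term)) {
          add(pending_term$v + dt, "BOUNDARY", "SUMMED", t_cs[i],
              pending_term$si)
          pending_term <- NULL
        }
      }
      prev_press_cs <- t_cs[i]
    } else if (lc == "execution") {
      if (!(si %in% open_seq))
        add((t_cs[i] - prev_press_cs) / 100, "WITHIN_SEQUENCE",
            NA_character_, t_cs[i], si)
      prev_press_cs <- t_cs[i]
    } else if (lc == "termination") {
      dt <- (t_cs[i] - prev_press_cs) / 100
      if (boundary == "pooled") {
        add(dt, "BOUNDARY", "PRESS_CHECK", t_cs[i], si)
      } else pending_term <- list(v = dt, si = si)
      prev_check_cs <- t_cs[i]
    } else if (lc == "ignored") {
      prev_check_cs <- t_cs[i]
    }
  }
  out <- data.frame(value_s = val, category = cat, boundary_kind = bk,
                    session_time_cs = close_cs, sequence_index = sidx,
                    stringsAsFactors = FALSE)
  keep <- out$category != "BOUNDARY" | out$value_s <= max_boundary_s
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise interval records per category
#'
#' Mean, SD and count of interval values per category, optionally
#' restricted to the first `window_s` seconds of the session (the window
#' is applied to the interval's closing-event time).
#'
#' @param records Interval records from [categorize_intervals()].
#' @param window_s Optional window length in seconds from session start.
#' @return Data frame with one row per category present.
#' @export
interval_summary <- function(records, window_s = NULL) {
  if (!is.null(window_s))
    records <- records[records$session_time_cs <= window_s * 100, ,
                       drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(category = character(), mean_s = numeric(),
                      sd_s = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- lapply(split(records$value_s, records$category), function(v)
    data.frame(mean_s = mean(v),
               sd_s = if (length(v) > 1) stats::sd(v) else 0, n = length(v)))
  out <- do.call(rbind, agg)
  out <- cbind(category = rownames(out), out)
  rownames(out) <- NULL
  out$category <- as.character(out$category)
  out
}

#' Frequency distribution of inter-press intervals
#'
#' Counts interval values over half-open bins `[e_i, e_{i+1})`. Default
#' bins are 10-ms wide from 0 to 2 s, matching the timestamp grid
#' resolution at short intervals.
#'
#' @param records Interval records (all categories counted; filter before
#'   calling to restrict, e.g. to within-sequence IPIs).
#' @param bin_edges_s Monotone increasing numeric vector of bin edges in
#'   seconds.
#' @return Data frame with `bin_left_s`, `bin_right_s`, `count`.
#' @export
ipi_histogram <- function(records, bin_edges_s = seq(0, 2, by = 0.01)) {
  if (is.unsorted(bin_edges_s, strictly = TRUE))
    stop("bin_edges_s must be strictly increasing")
  v <- if (is.data.frame(records)) records$value_s else records
  idx <- findInterval(v, bin_edges_s, rightmost.closed = FALSE)
  nb <- length(bin_edges_s) - 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  data.frame(bin_left_s = bin_edges_s[-length(bin_edges_s)],
             bin_right_s = bin_edges_s[-1], count = counts)
}

#' Chunking-space scatter and kernel density curves
#'
#' Produces the scatter representation of interval chunking: x is the
#' log10-transformed interval, y is uniform random jitter in `[0, 1]`
#' (reproducible from `seed`), and one Gaussian kernel density curve per
#' category is estimated over the log10 axis (Silverman's rule bandwidth
#' by default). Each density curve integrates to 1 over its support.
#'
#' @param records Interval records from [categorize_intervals()].
#' @param seed Seed for the y jitter.
#' @param bw Kernel bandwidth on the log10 scale, or `"nrd0"` for
#'   Silverman's rule.
#' @param n_grid Number of density grid points.
#' @return List with `points` (data frame `x_log10`, `y`, `category`) and
#'   `densities` (data frame `category`, `x_log10`, `density`).
#' @export
chunk_scatter <- function(records, seed = 1L, bw = "nrd0", n_grid = 512) {
  if (any(records$value_s <= 0)) stop("interval values must be > 0")
  x <- log10(records$value_s)
  y <- with_seed(seed, stats::runif(length(x)))
  dens_list <- lapply(split(x, records$category), function(xs) {
    if (length(xs) < 2) return(NULL)
    d <- stats::density(xs, bw = bw, n = n_grid)
    data.frame(x_log10 = d$x, density = d$y)
  })
  dens <- do.call(rbind, lapply(names(dens_list), function(nm) {
    if (is.null(dens_list[[nm]])) return(NULL)
    cbind(category = nm, dens_list[[nm]], stringsAsFactors = FALSE)
  }))
  list(points = data.frame(x_log10 = x, y = y, category = records$category,
                           stringsAsFactors = FALSE),
       densities = dens)
}

#' Fastest action sequences of a session
#'
#' Returns the `k` highest-speed sequences (ties broken by earlier start
#' time) with their mean speed and the mean within-burst IPI, mirroring
#' the fastest-burst analysis used to select sequences for acoustic
#' verification.
#'
#' @param parsed An `action_sequences` object.
#' @param k Number of bursts (5 by default).
#' @return List with `sequences` (the selected rows, fastest first),
#'   `mean_speed_pps`, `mean_ipi_s`, and `truncated` (`TRUE` when fewer
#'   than `k` sequences had a defined speed).
#' @export
fastest_sequences <- function(parsed, k = 5) {
  stopifnot(inherits(parsed, "action_sequences"))
  ipis <- attr(parsed, "ipis")
  ok <- which(!is.na(parsed$speed_pps))
  ord <- ok[order(-parsed$speed_pps[ok], parsed$start_cs[ok])]
  sel <- utils::head(ord, k)
  sequences <- parsed[sel, , drop = FALSE]
  list(sequences = sequences,
       mean_speed_pps = if (length(sel)) mean(parsed$speed_pps[sel])
                        else NA_real_,
       mean_ipi_s = if (length(sel)) mean(unlist(ipis[sel])) else NA_real_,
       truncated = length(sel) < k)
}
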