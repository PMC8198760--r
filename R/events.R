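#' Detect mitoses from the APC/C reporter of one cell
#'
#' A mitosis is called at a sample where the APC/C-degron signal falls, within
#' one frame, by at least `drop_fraction` of its trailing peak (the running
#' maximum since the previous detected mitosis), provided that trailing peak
#' is at least `min_peak_au`. When H2B-split flags are supplied, a detection
#' is confirmed only if a flag lies within `match_tolerance_frames` of the
#' drop.
#'
#' @param time_h Sample times (hours), uniformly spaced.
#' @param apc_au APC/C reporter intensities.
#' @param h2b_split_flag Optional 0/1 vector of H2B-split flags.
#' @param drop_fraction Minimum one-frame drop as a fraction of the trailing
#'   peak.
#' @param min_peak_au Minimum trailing peak (a.u.) for a drop to count;
#'   guards against calling mitoses on the noise floor.
#' @param match_tolerance_frames Frame tolerance for H2B confirmation.
#' @return Strictly increasing vector of mitosis times (possibly empty).
#' @export
detect_mitoses <- function(time_h, apc_au, h2b_split_flag = NULL,
                           drop_fraction = 0.5, min_peak_au = 50,
                           match_tolerance_frames = 2L) {
  n <- length(time_h)
  stopifnot(length(apc_au) == n)
  if (n < 2) return(numeric(0))
  dt <- diff(time_h)
  if (any(abs(dt - dt[1]) > 1e-6)) {
    stop("detect_mitoses: sampling must be uniform", call. = FALSE)
  }
  hits <- integer(0)
  trail <- apc_au[1]
  for (k in 2:n) {
    if ((trail - apc_au[k]) >= drop_fraction * trail && trail >= min_peak_au) {
      hits <- c(hits, k)
      trail <- apc_au[k]
    } else {
      trail <- max(trail, apc_au[k])
    }
  }
  if (!is.null(h2b_split_flag) && length(hits) > 0) {
    flags <- which(h2b_split_flag == 1)
    ok <- vapply(hits, function(k) {
      length(flags) > 0 && min(abs(flags - k)) <= match_tolerance_frames
    }, logical(1))
    hits <- hits[ok]
  }
  time_h[hits]
}

#' Segment G1 and S/G2/M intervals of one cell
#'
#' Each G1 starts at a detected mitosis (or at observation start) and ends at
#' the first sample where the APC/C signal exceeds `rise_fraction` of that
#' cycle's eventual peak (and `min_rise_au`); S/G2/M spans from that rise to
#' the next mitosis. A cycle whose reporter never rises above the floor is a
#' single G1; trailing phases not closed by a mitosis within the observation
#' window are flagged censored.
#'
#' @param time_h,apc_au Per-cell series as in [detect_mitoses()].
#' @param mitosis_times Mitosis times from [detect_mitoses()].
#' @param rise_fraction Fraction of the cycle's APC/C peak defining G1 exit.
#' @param min_rise_au Absolute floor (a.u.) the signal must exceed.
#' @return Data frame with columns `phase` (`"G1"`/`"SG2M"`), `start_h`,
#'   `end_h` (half-open intervals) and `censored`.
#' @export
segment_phases <- function(time_h, apc_au, mitosis_times,
                           rise_fraction = 0.02, min_rise_au = 0) {
  if (length(mitosis_times) > 0 && min(mitosis_times) < min(time_h)) {
    stop("segment_phases: mitosis before observation start", call. = FALSE)
  }
  bounds <- c(min(time_h), sort(mitosis_times))
  t_end <- max(time_h)
  out <- vector("list", length(bounds))
  for (j in seq_along(bounds)) {
    b0 <- bounds[j]
    b1 <- if (j < length(bounds)) bounds[j + 1] else t_end
    terminal <- j == length(bounds)
    in_cycle <- time_h >= b0 & time_h < b1
    if (terminal) in_cycle <- time_h >= b0  # include last sample
    if (!any(in_cycle)) next
    peak <- max(apc_au[in_cycle])
    thr <- max(rise_fraction * peak, min_rise_au)
    rise_k <- which(in_cycle & apc_au > thr)
    rise_k <- rise_k[time_h[rise_k] > b0]
    if (length(rise_k) == 0) {
      out[[j]] <- data.frame(phase = "G1", start_h = b0, end_h = b1,
                             censored = terminal)
    } else {
      rise_t <- time_h[rise_k[1]]
      if (rise_t < b0) {
        stop("segment_phases: rise before preceding mitosis", call. = FALSE)
      }
      out[[j]] <- data.frame(phase = c("G1", "SG2M"),
                             start_h = c(b0, rise_t),
                             end_h = c(rise_t, b1),
                             censored = c(FALSE, terminal))
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Compute per-cell cell-cycle event records for a trace set
#'
#' Runs [detect_mitoses()] and [segment_phases()] on every cell of a long
#' trace table.
#'
#' @param traces Long trace table (`cell_id`, `time_h`, `apc_au`,
#'   `h2b_split_flag`).
#' @param use_h2b Confirm drops with H2B-split flags when available.
#' @inheritParams detect_mitoses
#' @inheritParams segment_phases
#' @return An object of class `event_set`: list with `cells` (per cell:
#'   `cell_id`, `n_divisions`, `span_start_h`, `span_end_h`), `mitoses`
#'   (long: `cell_id`, `time_h`) and `intervals` (long: `cell_id`, `phase`,
#'   `start_h`, `end_h`, `censored`).
#' @export
compute_events <- function(traces, use_h2b = TRUE, drop_fraction = 0.5,
                           min_peak_au = 50, match_tolerance_frames = 2L,
                           rise_fraction = 0.02, min_rise_au = 0) {
  ids <- sort(unique(traces$cell_id))
  by_cell <- split(traces, traces$cell_id)
  cells <- vector("list", length(ids))
  mit <- vector("list", length(ids))
  ints <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- by_cell[[as.character(ids[i])]]
    tr <- tr[order(tr$time_h), , drop = FALSE]
    flags <- if (use_h2b && "h2b_split_flag" %in% names(tr)) {
      tr$h2b_split_flag
    } else {
      NULL
    }
    m <- detect_mitoses(tr$time_h, tr$apc_au, flags, drop_fraction,
                        min_peak_au, match_tolerance_frames)
    seg <- segment_phases(tr$time_h, tr$apc_au, m, rise_fraction, min_rise_au)
    cells[[i]] <- data.frame(cell_id = ids[i], n_divisions = length(m),
                             span_start_h = min(tr$time_h),
                             span_end_h = max(tr$time_h))
    if (length(m) > 0) mit[[i]] <- data.frame(cell_id = ids[i], time_h = m)
    seg$cell_id <- ids[i]
    ints[[i]] <- seg[, c("cell_id", "phase", "start_h", "end_h", "censored")]
  }
  keep <- !vapply(mit, is.null, logical(1))
  out <- list(
    cells = do.call(rbind, cells),
    mitoses = if (any(keep)) do.call(rbind, mit[keep]) else
      data.frame(cell_id = integer(0), time_h = numeric(0)),
    intervals = do.call(rbind, ints)
  )
  rownames(out$cells) <- rownames(out$intervals) <- NULL
  class(out) <- "event_set"
  out
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set>", nrow(x$cells), "cells,", nrow(x$mitoses),
      "mitoses,", nrow(x$intervals), "phase intervals\n")
  invisible(x)
}

#' Fraction of cells in S/G2/M over time
#'
#' At each grid time, the fraction of observed cells whose current phase
#' interval is S/G2/M; the denominator is the number of cells observed at
#' that time. Invariant under cell relabeling and uniform intensity
#' rescaling.
#'
#' @param events An [compute_events()] `event_set`.
#' @param time_grid Times (hours) at which to evaluate; must be non-empty.
#' @return Data frame `time_h`, `fraction_sg2m`, `n_observed`.
#' @export
fraction_in_sg2m <- function(events, time_grid) {
  if (length(time_grid) == 0) stop("empty time grid", call. = FALSE)
  num <- numeric(length(time_grid))
  den <- numeric(length(time_grid))
  for (i in seq_len(nrow(events$cells))) {
    obs <- time_grid >= events$cells$span_start_h[i] &
      time_grid <= events$cells$span_end_h[i]
    den <- den + obs
  }
  sg <- events$intervals[events$intervals$phase == "SG2M", , drop = FALSE]
  for (j in seq_len(nrow(sg))) {
    num <- num + (time_grid >= sg$start_h[j] & time_grid < sg$end_h[j])
  }
  data.frame(time_h = time_grid,
             fraction_sg2m = ifelse(den > 0, num / den, NA_real_),
             n_observed = den)
}

#' Classify quiescent cells
#'
#' A cell is quiescent iff it never crossed the commitment threshold (the
#' `crossed` flag is supplied by the caller) and entered no S phase in the
#' window `(refresh_time_h, refresh_time_h + lookahead_h]`. Committed cells
#' without post-refresh cycling are differentiated/post-mitotic, not
#' quiescent.
#'
#' @param events An `event_set`.
#' @param crossed Logical vector aligned with `events$cells$cell_id`.
#' @param refresh_time_h Serum-refresh time (hours).
#' @param lookahead_h Window length after the refresh inspected for S-phase
#'   entries; `Inf` means the rest of the observation. A finite value beyond
#'   the observation end is truncated with a warning.
#' @return Logical vector, one flag per cell in `events$cells` order.
#' @export
classify_quiescent <- function(events, crossed, refresh_time_h = 48,
                               lookahead_h = Inf) {
  stopifnot(length(crossed) == nrow(events$cells))
  horizon <- max(events$cells$span_end_h)
  end <- refresh_time_h + lookahead_h
  if (is.finite(lookahead_h) && end > horizon) {
    warning("lookahead extends beyond the observation window; truncated")
    end <- horizon
  }
  if (!is.finite(end)) end <- horizon
  sg <- events$intervals[events$intervals$phase == "SG2M", , drop = FALSE]
  entries <- split(sg$start_h, sg$cell_id)
  vapply(seq_len(nrow(events$cells)), function(i) {
    if (crossed[i]) return(FALSE)
    e <- entries[[as.character(events$cells$cell_id[i])]]
    is.null(e) || !any(e > refresh_time_h & e <= end)
  }, logical(1))
}
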