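#' Align traces to their commitment-crossing time
#'
#' Re-indexes each committed cell's PPARG series by `t - crossing_time` so
#' that aligned time 0 is the sample at which the cell crossed the threshold.
#' Alignment is a pure shift at frame resolution (no interpolation), so
#' per-cell values are conserved. Cells without a crossing are excluded.
#'
#' @param traces Long trace table.
#' @param crossings Data frame from [detect_crossings()].
#' @param probs Lower/upper percentile pair for the summary band
#'   (default 5th-95th; use `c(0.25, 0.75)` for the interquartile band).
#' @return Object of class `aligned_ensemble`: list with `aligned_time_h`
#'   (grid, spacing = sampling interval), `values` (cells x grid matrix,
#'   `NA` where unobserved), `cell_id`, `crossing_time_h`, and `summary`
#'   (`aligned_time_h`, `median`, `lower`, `upper`, `n`).
#' @export
align_to_crossing <- function(traces, crossings, probs = c(0.05, 0.95)) {
  com <- crossings[!is.na(crossings$crossing_time_h), , drop = FALSE]
  if (nrow(com) == 0) stop("align_to_crossing: no committed cells",
                           call. = FALSE)
  by_cell <- split(traces, traces$cell_id)
  dt <- NULL
  shifted <- lapply(seq_len(nrow(com)), function(i) {
    tr <- by_cell[[as.character(com$cell_id[i])]]
    tr <- tr[order(tr$time_h), ]
    data.frame(cell_id = com$cell_id[i],
               aligned_h = tr$time_h - com$crossing_time_h[i],
               pparg_au = tr$pparg_au)
  })
  shifted <- do.call(rbind, shifted)
  step <- min(diff(sort(unique(traces$time_h))))
  grid <- seq(round(min(shifted$aligned_h) / step),
              round(max(shifted$aligned_h) / step)) * step
  vals <- matrix(NA_real_, nrow(com), length(grid))
  idx <- round(shifted$aligned_h / step) - round(min(shifted$aligned_h) / step) + 1
  row <- match(shifted$cell_id, com$cell_id)
  vals[cbind(row, idx)] <- shifted$pparg_au
  med <- apply(vals, 2, stats::median, na.rm = TRUE)
  lo <- apply(vals, 2, stats::quantile, probs = probs[1], na.rm = TRUE,
              names = FALSE)
  hi <- apply(vals, 2, stats::quantile, probs = probs[2], na.rm = TRUE,
              names = FALSE)
  n_obs <- colSums(!is.na(vals))
  structure(list(
    aligned_time_h = grid,
    values = vals,
    cell_id = com$cell_id,
    crossing_time_h = com$crossing_time_h,
    summary = data.frame(aligned_time_h = grid, median = med,
                         lower = lo, upper = hi, n = n_obs)
  ), class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat("<aligned_ensemble>", length(x$cell_id), "committed cells on [",
      min(x$aligned_time_h), ",", max(x$aligned_time_h), "] h\n")
  invisible(x)
}

#' Per-aligned-time correlation of PPARG with endpoint markers
#'
#' At each aligned time point, the Pearson correlation coefficient between
#' the cells' aligned PPARG values and their endpoint marker values, computed
#' over the cells observed at that time. Times with fewer than `min_n` cells
#' or zero variance are reported as `NA`, not 0.
#'
#' @param aligned An [align_to_crossing()] ensemble.
#' @param endpoint Endpoint marker table with `cell_id` plus marker columns.
#' @param markers Marker column names (default: all non-`cell_id` columns).
#' @param min_n Minimum number of cells per evaluated time.
#' @return Long data frame `aligned_time_h`, `marker`, `r`, `n`.
#' @export
correlation_profile <- function(aligned, endpoint,
                                markers = setdiff(names(endpoint), "cell_id"),
                                min_n = 10) {
  stopifnot(inherits(aligned, "aligned_ensemble"))
  ep <- endpoint[match(aligned$cell_id, endpoint$cell_id), , drop = FALSE]
  out <- lapply(markers, function(m) {
    y <- ep[[m]]
    r <- vapply(seq_along(aligned$aligned_time_h), function(j) {
      x <- aligned$values[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_n) return(NA_real_)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    n <- vapply(seq_along(aligned$aligned_time_h), function(j) {
      sum(!is.na(aligned$values[, j]) & !is.na(y))
    }, numeric(1))
    data.frame(aligned_time_h = aligned$aligned_time_h, marker = m,
               r = r, n = n)
  })
  do.call(rbind, out)
}

#' Scramble crossing times across cells
#'
#' Returns the crossings with the multiset of crossing times uniformly
#' permuted across the committed cells (self-assignment allowed). Aligning to
#' scrambled crossings is the negative control for the correlation profile:
#' the sharp pre/post-crossing change should vanish.
#'
#' @param crossings Data frame from [detect_crossings()]; at least 2 cells
#'   must have crossings.
#' @param seed Integer seed.
#' @return A copy of `crossings` with permuted `crossing_time_h` among the
#'   committed cells.
#' @export
scramble_crossings <- function(crossings, seed = 1L) {
  com <- which(!is.na(crossings$crossing_time_h))
  if (length(com) < 2) stop("scramble_crossings: need >= 2 crossings",
                            call. = FALSE)
  set.seed(seed)
  crossings$crossing_time_h[com] <-
    crossings$crossing_time_h[com][sample.int(length(com))]
  crossings
}

#' Bin cells by a value and summarize per bin
#'
#' Assigns values to half-open bins `[lo, hi)` (last bin closed) — either
#' `n_bins` equal-width bins over the value range or explicit `edges` — and
#' applies a reducer to a statistic vector within each bin. Values outside
#' explicit edges go to an overflow bin.
#'
#' @param values Binning variable (e.g. PPARG at 48 h), non-empty.
#' @param stat Vector to be reduced per bin (defaults to `values`).
#' @param n_bins Number of equal-width bins over `range(values)`.
#' @param edges Explicit bin edges (overrides `n_bins`).
#' @param reducer Function applied to `stat` within each bin.
#' @return Data frame `bin`, `lo`, `hi`, `n`, `stat`; an `"overflow"` row is
#'   appended when explicit edges do not cover all values. Per-bin `n` sums
#'   to `length(values)`.
#' @export
bin_by_level <- function(values, stat = values, n_bins = 10, edges = NULL,
                         reducer = mean) {
  stopifnot(length(values) > 0, length(stat) == length(values))
  if (is.null(edges)) {
    edges <- seq(min(values), max(values), length.out = n_bins + 1)
    if (edges[1] == edges[length(edges)]) {
      edges <- edges + seq(0, 1e-9, length.out = length(edges))
    }
  }
  k <- length(edges) - 1
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx < 1 | idx > k] <- NA  # outside explicit edges
  rows <- lapply(seq_len(k), function(b) {
    sel <- !is.na(idx) & idx == b
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1], n = sum(sel),
               stat = if (any(sel)) reducer(stat[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  n_over <- sum(is.na(idx))
  if (n_over > 0) {
    sel <- is.na(idx)
    out <- rbind(out, data.frame(bin = NA, lo = NA, hi = NA, n = n_over,
                                 stat = reducer(stat[sel])))
    out$overflow <- c(rep(FALSE, k), TRUE)
  }
  out
}

#' Mitosis-to-threshold gaps and their normalized histogram
#'
#' For each committed cell with at least one mitosis, the gap between its
#' crossing time and its last mitosis (negative when the cell crossed while
#' its final S/G2/M was still in progress). The histogram is normalized so
#' that the bars sum to 1.
#'
#' @param crossings Data frame from [detect_crossings()].
#' @param events An `event_set`.
#' @param binwidth_h Histogram bin width (hours).
#' @return List with `gaps` (`cell_id`, `crossing_time_h`,
#'   `last_mitosis_h`, `gap_h`), `histogram` (`mid`, `fraction`; fractions
#'   sum to 1), and `n_no_mitosis` (committed cells with no observed
#'   mitosis, reported separately).
#' @export
mitosis_to_threshold_gaps <- function(crossings, events, binwidth_h = 2) {
  com <- crossings[!is.na(crossings$crossing_time_h), , drop = FALSE]
  last_m <- tapply(events$mitoses$time_h, events$mitoses$cell_id, max)
  lm <- last_m[as.character(com$cell_id)]
  has_m <- !is.na(lm)
  gaps <- data.frame(
    cell_id = com$cell_id[has_m],
    crossing_time_h = com$crossing_time_h[has_m],
    last_mitosis_h = as.vector(lm[has_m]),
    gap_h = com$crossing_time_h[has_m] - as.vector(lm[has_m])
  )
  hist <- NULL
  if (nrow(gaps) > 0) {
    lo <- floor(min(gaps$gap_h) / binwidth_h) * binwidth_h
    hi <- ceiling(max(gaps$gap_h) / binwidth_h) * binwidth_h
    if (hi == lo) hi <- lo + binwidth_h
    breaks <- seq(lo, hi, by = binwidth_h)
    h <- graphics::hist(gaps$gap_h, breaks = breaks, plot = FALSE)
    hist <- data.frame(mid = h$mids, fraction = h$counts / sum(h$counts))
  }
  list(gaps = gaps, histogram = hist,
       n_no_mitosis = sum(!has_m))
}

#' Fraction-of-cells histogram
#'
#' Histogram normalized so that the bars sum to 1 (each bar is the fraction
#' of cells in that bin, not a density).
#'
#' @param x Values (e.g. durations in hours).
#' @param binwidth Bin width, in the units of `x`.
#' @return Data frame `mid`, `fraction`; `sum(fraction) == 1`.
#' @export
normalized_histogram <- function(x, binwidth = 2) {
  stopifnot(length(x) > 0, binwidth > 0)
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi == lo) hi <- lo + binwidth
  h <- graphics::hist(x, breaks = seq(lo, hi, by = binwidth), plot = FALSE)
  data.frame(mid = h$mids, fraction = h$counts / sum(h$counts))
}

#' First-versus-second G1 durations and total G1 time per cell
#'
#' For cells with at least `min_divisions` mitoses, the paired durations of
#' their first and second completed G1 periods; plus, for every cell, the
#' summed duration of all completed (uncensored) G1 intervals.
#'
#' @param events An `event_set`.
#' @param min_divisions Minimum division count for the paired comparison.
#' @return List with `pairs` (`cell_id`, `g1_first_h`, `g1_second_h`) and
#'   `total` (`cell_id`, `total_g1_h`, `n_completed_g1`).
#' @export
g1_duration_stats <- function(events, min_divisions = 3) {
  ints <- events$intervals
  g1 <- ints[ints$phase == "G1" & !ints$censored, , drop = FALSE]
  g1 <- g1[order(g1$cell_id, g1$start_h), ]
  g1$dur <- g1$end_h - g1$start_h
  by_cell <- split(g1$dur, g1$cell_id)
  total <- data.frame(
    cell_id = events$cells$cell_id,
    total_g1_h = vapply(as.character(events$cells$cell_id), function(id) {
      d <- by_cell[[id]]
      if (is.null(d)) 0 else sum(d)
    }, numeric(1), USE.NAMES = FALSE),
    n_completed_g1 = vapply(as.character(events$cells$cell_id), function(id) {
      length(by_cell[[id]])
    }, numeric(1), USE.NAMES = FALSE)
  )
  elig <- events$cells$cell_id[events$cells$n_divisions >= min_divisions]
  pairs <- do.call(rbind, lapply(as.character(elig), function(id) {
    d <- by_cell[[id]]
    if (is.null(d) || length(d) < 2) return(NULL)
    data.frame(cell_id = as.numeric(id), g1_first_h = d[1], g1_second_h = d[2])
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(cell_id = numeric(0), g1_first_h = numeric(0),
                        g1_second_h = numeric(0))
  }
  list(pairs = pairs, total = total)
}

#' Commitment speed as a function of stimulus exposure
#'
#' Bins committed cells by the time of their last mitosis (a proxy for how
#' long they were exposed to the adipogenic stimulus before their final G1)
#' and reports, per bin, the mean last-mitosis time and the mean
#' mitosis-to-threshold gap. With longer exposure the PPARG rate is faster,
#' so the mean gap decreases across later bins.
#'
#' @param crossings,events As in [mitosis_to_threshold_gaps()].
#' @param n_bins Number of equal-count bins over last-mitosis times.
#' @param last_mitosis_max_h Restrict to cells whose last mitosis occurred no
#'   later than this (default: the 48-h stimulus window, within which
#'   exposure accrues at full strength; after stimulus removal the
#'   exposure-speed relation no longer applies).
#' @return Data frame `bin`, `n`, `mean_last_mitosis_h`, `mean_gap_h`
#'   (empty bins are skipped).
#' @export
exposure_binned_commitment <- function(crossings, events, n_bins = 9,
                                       last_mitosis_max_h = 48) {
  g <- mitosis_to_threshold_gaps(crossings, events)$gaps
  g <- g[g$last_mitosis_h <= last_mitosis_max_h, , drop = FALSE]
  if (nrow(g) == 0) stop("no committed cells with a mitosis", call. = FALSE)
  qs <- stats::quantile(g$last_mitosis_h, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs[1] <- qs[1] - 1e-9
  idx <- cut(g$last_mitosis_h, breaks = unique(qs), labels = FALSE)
  agg <- lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin = b, n = sum(sel),
               mean_last_mitosis_h = mean(g$last_mitosis_h[sel]),
               mean_gap_h = mean(g$gap_h[sel]))
  })
  do.call(rbind, agg)
}

#' Median PPARG aligned to the last mitosis, by exposure group
#'
#' Splits committed cells into `n_groups` equal-count groups by the time of
#' their last mitosis, aligns each cell's PPARG series to that mitosis
#' (aligned time 0 = the mitosis sample, which is masked: the nuclear PPARG
#' signal is undefined while the nuclear envelope is broken down), and
#' reports the per-group median over aligned time.
#'
#' @param traces Long trace table.
#' @param crossings,events As above.
#' @param n_groups Number of exposure groups.
#' @param last_mitosis_max_h As in [exposure_binned_commitment()].
#' @return Long data frame `group`, `group_lo_h`, `group_hi_h`,
#'   `aligned_time_h`, `median_pparg`, `n`.
#' @export
exposure_aligned_profiles <- function(traces, crossings, events,
                                      n_groups = 3,
                                      last_mitosis_max_h = 48) {
  g <- mitosis_to_threshold_gaps(crossings, events)$gaps
  g <- g[g$last_mitosis_h <= last_mitosis_max_h, , drop = FALSE]
  if (nrow(g) == 0) stop("no committed cells with a mitosis", call. = FALSE)
  qs <- stats::quantile(g$last_mitosis_h,
                        probs = seq(0, 1, length.out = n_groups + 1),
                        names = FALSE)
  qs[1] <- qs[1] - 1e-9
  grp <- cut(g$last_mitosis_h, breaks = unique(qs), labels = FALSE)
  by_cell <- split(traces, traces$cell_id)
  step <- min(diff(sort(unique(traces$time_h))))
  out <- lapply(sort(unique(grp)), function(b) {
    sel <- which(grp == b)
    rows <- lapply(sel, function(i) {
      tr <- by_cell[[as.character(g$cell_id[i])]]
      al <- tr$time_h - g$last_mitosis_h[i]
      keep <- abs(al) >= step / 2  # mask the mitosis sample itself
      data.frame(aligned = round(al[keep] / step) * step,
                 pparg = tr$pparg_au[keep])
    })
    rows <- do.call(rbind, rows)
    med <- tapply(rows$pparg, rows$aligned, stats::median)
    nn <- tapply(rows$pparg, rows$aligned, length)
    data.frame(group = b,
               group_lo_h = min(g$last_mitosis_h[grp == b]),
               group_hi_h = max(g$last_mitosis_h[grp == b]),
               aligned_time_h = as.numeric(names(med)),
               median_pparg = as.vector(med),
               n = as.vector(nn))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
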