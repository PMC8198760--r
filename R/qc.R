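#' Quality-control configuration for single-cell traces
#'
#' Parameters of the trace filters that remove incomplete or mistracked
#' cells before analysis.
#'
#' @param endpoint_absence_window_h Cells with no record within this many
#'   hours of the last sample time are removed (default 6 h).
#' @param late_start_cutoff_h Cells first appearing later than this many
#'   hours after the global first time point are removed (default 4 h).
#' @param jump_fold_cutoff Maximum tolerated frame-to-frame PPARG fold change;
#'   a ratio outside `[1/cutoff, cutoff]` marks a tracking error. Must be
#'   generous enough to pass the post-threshold amplification phase.
#' @param split_match_tolerance_frames An H2B-split flag must have an APC/C
#'   reporter drop within this many frames (default 2, i.e. 24 min).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(endpoint_absence_window_h = 6,
                      late_start_cutoff_h = 4,
                      jump_fold_cutoff = 3,
                      split_match_tolerance_frames = 2L) {
  stopifnot(endpoint_absence_window_h > 0, late_start_cutoff_h > 0,
            jump_fold_cutoff > 0, split_match_tolerance_frames > 0)
  structure(list(endpoint_absence_window_h = endpoint_absence_window_h,
                 late_start_cutoff_h = late_start_cutoff_h,
                 jump_fold_cutoff = jump_fold_cutoff,
                 split_match_tolerance_frames =
                   as.integer(split_match_tolerance_frames)),
            class = "qc_config")
}

#' Filter incomplete or mistracked traces
#'
#' Removes cells that violate any of four criteria: (a) absent within
#' `endpoint_absence_window_h` of the last sample time of the experiment;
#' (b) first appearing more than `late_start_cutoff_h` after the global first
#' time point; (c) any frame-to-frame PPARG intensity ratio outside
#' `[1/jump_fold_cutoff, jump_fold_cutoff]`; (d) an H2B-split flag with no
#' APC/C-reporter drop within `split_match_tolerance_frames`. Surviving
#' traces are returned unchanged. Filtering is idempotent and partitions the
#' input cells into kept and removed.
#'
#' @param traces Long trace table (`cell_id`, `time_h`, `pparg_au`, `apc_au`,
#'   `h2b_split_flag`, ...).
#' @param qc A [qc_config()].
#' @return List with `traces` (kept rows) and `report`, a per-cell data frame
#'   with columns `cell_id`, `kept` and `violations` (criteria codes
#'   `"endpoint_absence"`, `"late_start"`, `"pparg_jump"`,
#'   `"unmatched_split"`, semicolon-separated; empty iff kept).
#' @export
filter_traces <- function(traces, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  if (nrow(traces) == 0) {
    return(list(traces = traces,
                report = data.frame(cell_id = integer(0), kept = logical(0),
                                    violations = character(0))))
  }
  t_first <- min(traces$time_h)
  t_last <- max(traces$time_h)
  ids <- sort(unique(traces$cell_id))
  split_traces <- split(traces, traces$cell_id)

  report <- lapply(ids, function(id) {
    tr <- split_traces[[as.character(id)]]
    tr <- tr[order(tr$time_h), , drop = FALSE]
    viol <- character(0)
    if (max(tr$time_h) < t_last - qc$endpoint_absence_window_h) {
      viol <- c(viol, "endpoint_absence")
    }
    if (min(tr$time_h) > t_first + qc$late_start_cutoff_h) {
      viol <- c(viol, "late_start")
    }
    p <- tr$pparg_au
    if (length(p) > 1) {
      ratio <- p[-1] / pmax(p[-length(p)], .Machine$double.eps)
      if (any(ratio > qc$jump_fold_cutoff |
              ratio < 1 / qc$jump_fold_cutoff)) {
        viol <- c(viol, "pparg_jump")
      }
    }
    flags <- which(tr$h2b_split_flag == 1)
    if (length(flags) > 0) {
      a <- tr$apc_au
      drop_idx <- which(diff(a) < 0 &
                          (a[-length(a)] - a[-1]) >= 0.5 * a[-length(a)] &
                          a[-length(a)] > 0) + 1L
      tol <- qc$split_match_tolerance_frames
      matched <- vapply(flags, function(f) {
        length(drop_idx) > 0 && min(abs(drop_idx - f)) <= tol
      }, logical(1))
      if (!all(matched)) viol <- c(viol, "unmatched_split")
    }
    data.frame(cell_id = id, kept = length(viol) == 0,
               violations = paste(viol, collapse = ";"))
  })
  report <- do.call(rbind, report)
  kept_ids <- report$cell_id[report$kept]
  out <- traces[traces$cell_id %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  list(traces = out, report = report)
}
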