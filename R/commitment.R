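#' Fit a two-component Gaussian mixture to endpoint PPARG values
#'
#' Maximum-likelihood EM fit with deterministic initialization: component
#' means seeded at the 25th and 75th percentiles, equal weights, pooled
#' standard deviations. Components are reported in ascending mean order, so
#' the low component represents undifferentiated and the high component
#' differentiated cells.
#'
#' @param values Endpoint intensities (a.u.), positive, at least 50.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return Object of class `mixture_model`: list with `weight` (length 2,
#'   sums to 1), `mean` (ascending), `sd`, `loglik`, `n_iter`.
#' @export
fit_endpoint_mixture <- function(values, max_iter = 1000, tol = 1e-10) {
  values <- as.numeric(values)
  if (length(values) < 50) {
    stop("fit_endpoint_mixture: need at least 50 values", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("fit_endpoint_mixture: values must be finite and non-negative",
         call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("fit_endpoint_mixture: degenerate input (all values equal)",
         call. = FALSE)
  }
  mu <- as.numeric(stats::quantile(values, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * stats::sd(values)
  sdev <- rep(stats::sd(values), 2)
  w <- c(0.5, 0.5)
  sd_floor <- 1e-6 * stats::sd(values)
  ll_old <- -Inf
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sdev[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sdev[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    ll <- sum(log(tot))
    n_iter <- it
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
    w <- c(mean(r1), mean(r2))
    mu <- c(sum(r1 * values) / sum(r1), sum(r2 * values) / sum(r2))
    sdev <- c(sqrt(sum(r1 * (values - mu[1])^2) / sum(r1)),
              sqrt(sum(r2 * (values - mu[2])^2) / sum(r2)))
    sdev <- pmax(sdev, sd_floor)
  }
  ord <- order(mu)
  structure(list(weight = w[ord], mean = mu[ord], sd = sdev[ord],
                 loglik = ll_old, n_iter = n_iter),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf(
    "<mixture_model> low: N(%.1f, %.1f) w=%.2f | high: N(%.1f, %.1f) w=%.2f\n",
    x$mean[1], x$sd[1], x$weight[1], x$mean[2], x$sd[2], x$weight[2]))
  invisible(x)
}

#' Classify endpoint values against a fitted mixture
#'
#' Each value is assigned to the component with the higher posterior
#' responsibility; exact ties go to the low (undifferentiated) component.
#'
#' @param values Endpoint intensities.
#' @param model A [fit_endpoint_mixture()] `mixture_model`.
#' @return Character vector, `"differentiated"` or `"undifferentiated"`.
#' @export
classify_endpoint <- function(values, model) {
  stopifnot(inherits(model, "mixture_model"))
  d_lo <- model$weight[1] * stats::dnorm(values, model$mean[1], model$sd[1])
  d_hi <- model$weight[2] * stats::dnorm(values, model$mean[2], model$sd[2])
  ifelse(d_hi > d_lo, "differentiated", "undifferentiated")
}

#' Estimate the commitment threshold under an FPR constraint
#'
#' Scans candidate thresholds over the sorted unique reference-time PPARG
#' values (plus a +Inf sentinel) and returns the smallest threshold such that
#' predicting "differentiated" for cells at or above it yields a false
#' positive rate `FP / (FP + TN) <= max_fpr` against the endpoint labels
#' ("differentiated" is the positive class). Lowering the threshold calls
#' borderline cells differentiated only while the error bound allows.
#' Alternatively (`method = "midpoint"`), the midpoint between the two fitted
#' mixture component means is returned.
#'
#' @param values_at_reference Per-cell PPARG at the reference time (e.g. 48 h,
#'   just before stimulus removal).
#' @param endpoint_labels Per-cell endpoint labels from [classify_endpoint()];
#'   both classes must be present.
#' @param max_fpr Maximum tolerated false positive rate.
#' @param method `"fpr_scan"` (default) or `"midpoint"`.
#' @param mixture `mixture_model`, required for `method = "midpoint"`.
#' @param reference_time_h Stored for bookkeeping (hours).
#' @return Object of class `threshold_result`: `threshold_au`,
#'   `achieved_fpr`, `feasible`, `max_fpr`, `reference_time_h`, `method`,
#'   and `labels` — the reference-time predictions
#'   (`"differentiated"` iff value >= threshold).
#' @export
estimate_threshold <- function(values_at_reference, endpoint_labels,
                               max_fpr = 0.05,
                               method = c("fpr_scan", "midpoint"),
                               mixture = NULL, reference_time_h = 48) {
  method <- match.arg(method)
  stopifnot(length(values_at_reference) == length(endpoint_labels))
  if (length(unique(endpoint_labels)) < 2) {
    stop("estimate_threshold: both endpoint classes must be present",
         call. = FALSE)
  }
  neg <- values_at_reference[endpoint_labels == "undifferentiated"]
  fpr_at <- function(thr) mean(neg >= thr)
  if (method == "midpoint") {
    if (is.null(mixture)) {
      stop("method = \"midpoint\" needs the fitted mixture", call. = FALSE)
    }
    thr <- mean(mixture$mean)
    feasible <- fpr_at(thr) <= max_fpr
  } else {
    cand <- c(sort(unique(values_at_reference)), Inf)
    fprs <- vapply(cand, fpr_at, numeric(1))
    ok <- which(fprs <= max_fpr)
    if (length(ok) > 0) {
      thr <- cand[ok[1]]
      feasible <- TRUE
    } else {
      thr <- cand[which.min(fprs)]
      feasible <- FALSE
    }
  }
  structure(list(
    threshold_au = thr,
    achieved_fpr = fpr_at(thr),
    feasible = feasible,
    max_fpr = max_fpr,
    reference_time_h = reference_time_h,
    method = method,
    labels = ifelse(values_at_reference >= thr,
                    "differentiated", "undifferentiated")
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> threshold %.2f a.u. at %g h (method %s); FPR %.4f (max %.2f)%s\n",
    x$threshold_au, x$reference_time_h, x$method, x$achieved_fpr, x$max_fpr,
    if (x$feasible) "" else " [infeasible]"))
  invisible(x)
}

#' Apply a control-condition threshold to another condition
#'
#' In multi-condition experiments the mixture and threshold are estimated on
#' the negative control only and applied unchanged everywhere else.
#'
#' @param control_result A `threshold_result` fitted on the control.
#' @param values Reference-time PPARG values of the other condition.
#' @return Character labels, `"differentiated"` iff value >= control
#'   threshold.
#' @export
transfer_threshold <- function(control_result, values) {
  stopifnot(inherits(control_result, "threshold_result"))
  ifelse(values >= control_result$threshold_au,
         "differentiated", "undifferentiated")
}

#' Detect the commitment-crossing time of one trace
#'
#' The crossing time is the first sample at which PPARG reaches the threshold
#' and remains at or above it throughout a persistence window, which rejects
#' single-frame noise spikes. A window truncated by the end of observation is
#' evaluated on the available samples.
#'
#' Commitment is a kinetic switch: the crossing coincides with a slope break
#' from slow accumulation to fast self-amplification. With `refine_kink =
#' TRUE` the level-based estimate is refined by fitting a two-segment
#' continuous (hinge) regression in a window around it and snapping to the
#' first sample at or after the fitted breakpoint. On noisy traces that
#' approach the threshold slowly, the level detector's timing error is bounded
#' below by noise/slope, while the slope break stays sharply localized; on
#' noise-free traces both estimates agree.
#'
#' @param time_h,pparg_au Per-cell series.
#' @param threshold_au Commitment threshold (a.u.).
#' @param persistence_h Persistence window (hours); 0 disables the check.
#' @param refine_kink Refine the crossing time by hinge regression.
#' @return Crossing time (hours) or `NA` if the cell never crosses.
#' @export
detect_crossing <- function(time_h, pparg_au, threshold_au,
                            persistence_h = 2, refine_kink = FALSE) {
  ord <- order(time_h)
  time_h <- time_h[ord]
  pparg_au <- pparg_au[ord]
  above <- pparg_au >= threshold_au
  if (!any(above)) return(NA_real_)
  hit <- NA_real_
  for (k in which(above)) {
    win <- which(time_h >= time_h[k] & time_h <= time_h[k] + persistence_h)
    if (all(above[win])) {
      hit <- time_h[k]
      break
    }
  }
  if (is.na(hit) || !refine_kink) return(hit)
  refine_crossing_kink(time_h, pparg_au, hit)
}

## Breakpoint refinement around a candidate crossing: profile a continuous
## segmented regression (linear before the break, quadratic after, to absorb
## the concavity of the saturating amplification) over interior sample times,
## re-center once on the SSE minimizer, and snap to the first sample at or
## after it. Refinement is skipped when the trace's relative frame-to-frame
## noise is negligible (the level rule is already exact) or when too few
## samples follow the candidate to localize a slope break.
refine_crossing_kink <- function(time_h, pparg_au, t0,
                                 window_pre_h = 4, window_post_h = 5,
                                 iterations = 2) {
  rel_step <- abs(diff(pparg_au)) / pmax(pparg_au[-length(pparg_au)], 1)
  if (stats::median(rel_step) < 0.01) return(t0)
  if (sum(time_h > t0) < 5) return(t0)
  ## coarse stage: the self-amplification kink is where the 1-h local slope
  ## of the remaining trace peaks; the level pass may precede it by many
  ## hours when the scan threshold sits below the switch.
  est <- coarse_kink(time_h, pparg_au, t0)
  for (it in seq_len(iterations)) {
    sel <- which(time_h >= est - window_pre_h & time_h <= est + window_post_h)
    if (length(sel) < 10) return(est)
    tt <- time_h[sel]
    yy <- pparg_au[sel]
    cand <- tt[4:(length(tt) - 3)]
    if (length(cand) == 0) return(est)
    sse <- vapply(cand, function(b) {
      h <- pmax(0, tt - b)
      X <- cbind(1, tt, h, h^2)
      sum(stats::lm.fit(X, yy)$residuals^2)
    }, numeric(1))
    est <- cand[which.min(sse)]
  }
  after <- time_h[time_h >= est]
  if (length(after) == 0) t0 else after[1]
}

## locate the sample (>= t0 - 4 h) at which the local 1-h forward slope of
## log-intensity (the relative growth rate) is maximal: self-amplification at
## the commitment switch is the fastest relative growth anywhere on the
## trace, and the log scale keeps plateau-level noise from competing with
## it; returns t0 unchanged when too little data follows
coarse_kink <- function(time_h, pparg_au, t0, slope_window_h = 1) {
  sel <- which(time_h >= t0 - 4)
  if (length(sel) < 10) return(t0)
  lp <- log(pmax(pparg_au, 1e-6))
  slopes <- vapply(sel, function(k) {
    w <- which(time_h >= time_h[k] & time_h <= time_h[k] + slope_window_h)
    if (length(w) < 4) return(-Inf)
    stats::coef(stats::lm.fit(cbind(1, time_h[w]), lp[w]))[2]
  }, numeric(1))
  if (!any(is.finite(slopes))) return(t0)
  time_h[sel[which.max(slopes)]]
}

#' Detect crossing times for all cells of a trace set
#'
#' @param traces Long trace table.
#' @param threshold_au Commitment threshold (a.u.).
#' @inheritParams detect_crossing
#' @return Data frame `cell_id`, `crossing_time_h` (`NA` when never crossed).
#' @export
detect_crossings <- function(traces, threshold_au, persistence_h = 2,
                             refine_kink = FALSE) {
  by_cell <- split(traces, traces$cell_id)
  ids <- sort(unique(traces$cell_id))
  data.frame(
    cell_id = ids,
    crossing_time_h = vapply(as.character(ids), function(id) {
      tr <- by_cell[[id]]
      detect_crossing(tr$time_h, tr$pparg_au, threshold_au, persistence_h,
                      refine_kink)
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Gate detected crossings by endpoint classification
#'
#' Clears the crossing time of every cell whose endpoint label is
#' undifferentiated. The endpoint mixture classification defines *whether* a
#' cell differentiated; the threshold crossing marks *when*. Without gating,
#' cells that creep persistently above the scan threshold but never engage
#' the self-amplifying switch would be counted as committed.
#'
#' @param crossings Data frame from [detect_crossings()].
#' @param cell_ids,endpoint_labels Parallel vectors: cell id and its
#'   [classify_endpoint()] label.
#' @return `crossings` with `crossing_time_h = NA` for
#'   endpoint-undifferentiated cells.
#' @export
gate_crossings <- function(crossings, cell_ids, endpoint_labels) {
  stopifnot(length(cell_ids) == length(endpoint_labels))
  undiff <- cell_ids[endpoint_labels == "undifferentiated"]
  crossings$crossing_time_h[crossings$cell_id %in% undiff] <- NA_real_
  crossings
}

#' Fate census of a cell population
#'
#' Assigns each cell exactly one of three mutually exclusive fates:
#' `differentiated_postmitotic` (crossed the threshold),
#' `undiff_proliferating` (no crossing, entered S phase after the serum
#' refresh) or `undiff_quiescent` (neither). Fractions sum to 1. When traces
#' and a threshold are supplied, the per-time fraction of PPARG-high cells is
#' also computed (cells at or above the threshold among cells observed at
#' that time).
#'
#' @param crossings Data frame from [detect_crossings()].
#' @param events An `event_set` over the same cells.
#' @param refresh_time_h,lookahead_h Passed to [classify_quiescent()].
#' @param traces,threshold_au Optional, for the PPARG-high time series.
#' @return List with `fates` (per-cell `cell_id`, `crossing_time_h`, `fate`),
#'   `counts`, `fractions`, and optionally `pparg_high` (`time_h`,
#'   `fraction_high`, `n_observed`).
#' @export
census <- function(crossings, events, refresh_time_h = 48, lookahead_h = Inf,
                   traces = NULL, threshold_au = NULL) {
  if (!setequal(crossings$cell_id, events$cells$cell_id)) {
    stop("census: crossings and events cover different cell sets",
         call. = FALSE)
  }
  crossings <- crossings[match(events$cells$cell_id, crossings$cell_id), ]
  crossed <- !is.na(crossings$crossing_time_h)
  quiet <- classify_quiescent(events, crossed, refresh_time_h, lookahead_h)
  fate <- ifelse(crossed, "differentiated_postmitotic",
                 ifelse(quiet, "undiff_quiescent", "undiff_proliferating"))
  lv <- c("differentiated_postmitotic", "undiff_proliferating",
          "undiff_quiescent")
  counts <- table(factor(fate, levels = lv))
  out <- list(
    fates = data.frame(cell_id = events$cells$cell_id,
                       crossing_time_h = crossings$crossing_time_h,
                       fate = fate),
    counts = as.vector(counts, mode = "integer") |>
      stats::setNames(lv),
    fractions = as.vector(counts / sum(counts)) |> stats::setNames(lv)
  )
  if (!is.null(traces) && !is.null(threshold_au)) {
    out$pparg_high <- fraction_pparg_high(traces, threshold_au)
  }
  class(out) <- "fate_census"
  out
}

#' @export
print.fate_census <- function(x, ...) {
  cat("<fate_census>",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-time fraction of PPARG-high cells
#'
#' At each sample time, the number of cells at or above the threshold divided
#' by the number of cells observed at that time.
#'
#' @param traces Long trace table.
#' @param threshold_au Commitment threshold (a.u.).
#' @return Data frame `time_h`, `fraction_high`, `n_observed`.
#' @export
fraction_pparg_high <- function(traces, threshold_au) {
  high <- tapply(traces$pparg_au >= threshold_au, traces$time_h, mean)
  n <- tapply(traces$pparg_au, traces$time_h, length)
  data.frame(time_h = as.numeric(names(high)),
             fraction_high = as.vector(high),
             n_observed = as.vector(n),
             row.names = NULL)
}
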