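#' Simulate a mitogen x adipogen stimulus grid and census cell numbers
#'
#' Runs one independent simulation per grid point, scaling the base
#' configuration's stimulus schedule multiplicatively: the mitogen level
#' scales `mitogen_strength` (shortening G1 and increasing the number of
#' divisions) and the adipogen level scales `adipo_strength` (accelerating
#' PPARG accumulation and G1 lengthening). Endpoint cells are labeled by the
#' commitment threshold estimated on the base (control) configuration and
#' transferred unchanged to every condition. Because each simulated trace
#' follows a single lineage, the endpoint population it represents is counted
#' as `2^n_divisions` cells sharing that lineage's endpoint state, so totals
#' grow with proliferation.
#'
#' @param base A [sim_config()]; also defines the control used to fit the
#'   threshold.
#' @param mitogen_levels,adipogen_levels Non-empty numeric vectors of
#'   multiplicative strengths.
#' @param seed Master seed; each grid point gets an independent sub-seed
#'   derived from it.
#' @param max_fpr FPR bound for the control threshold.
#' @return Object of class `grid_result`: data frame `mitogen`, `adipogen`,
#'   `n_progenitor`, `n_differentiated`, `n_total` (one row per condition,
#'   `n_progenitor + n_differentiated == n_total`), with the control
#'   `threshold_result` attached as attribute `"control_threshold"`.
#' @export
run_grid <- function(base, mitogen_levels, adipogen_levels, seed = 1L,
                     max_fpr = 0.05) {
  validate_sim_config(base)
  if (length(mitogen_levels) == 0 || length(adipogen_levels) == 0) {
    stop("run_grid: level lists must be non-empty", call. = FALSE)
  }
  ## control fit on the base configuration
  control <- simulate_population(base)
  mix <- fit_endpoint_mixture(control$endpoint$pparg_end)
  lab <- classify_endpoint(control$endpoint$pparg_end, mix)
  ref <- reference_values(control$traces, base$refresh_time_h)
  thr <- estimate_threshold(ref$pparg_au, lab, max_fpr = max_fpr,
                            reference_time_h = base$refresh_time_h)

  rows <- list()
  ij <- 0
  for (m in mitogen_levels) {
    for (a in adipogen_levels) {
      ij <- ij + 1
      cfg <- base
      ## mitogen: cycle re-entry propensity (inverse G1 duration)
      cfg$stimulus_schedule$mitogen_strength <-
        base$stimulus_schedule$mitogen_strength * m
      ## adipogen: PPARG accumulation rate and G1 lengthening (exposure
      ## accrual itself keeps the control clock)
      cfg$pparg_rate_base <- base$pparg_rate_base * a
      cfg$pparg_rate_accel <- base$pparg_rate_accel * a
      cfg$g1_lengthening_rate <- base$g1_lengthening_rate * a
      cfg$condition <- sprintf("m%g_a%g", m, a)
      cfg$seed <- (base$seed + 1009L * ij) %% .Machine$integer.max
      sim <- simulate_population(cfg)
      end_lab <- transfer_threshold(thr, sim$endpoint$pparg_end)
      w <- 2^sim$ground_truth$cells$n_divisions
      n_diff <- sum(w[end_lab == "differentiated"])
      n_prog <- sum(w[end_lab == "undifferentiated"])
      rows[[ij]] <- data.frame(mitogen = m, adipogen = a,
                               n_progenitor = n_prog,
                               n_differentiated = n_diff,
                               n_total = n_prog + n_diff)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "control_threshold") <- thr
  class(out) <- c("grid_result", "data.frame")
  out
}

## per-cell PPARG at the sample closest to the reference time
reference_values <- function(traces, reference_time_h) {
  tt <- sort(unique(traces$time_h))
  t_ref <- tt[which.min(abs(tt - reference_time_h))]
  ref <- traces[traces$time_h == t_ref, c("cell_id", "pparg_au")]
  ref[order(ref$cell_id), ]
}

#' Iso-progenitor contour of a stimulus grid
#'
#' For each mitogen level, the adipogen level (linear interpolation between
#' grid points) at which the progenitor count crosses `target_count`. Columns
#' where the count never crosses the target are omitted.
#'
#' @param grid A [run_grid()] result.
#' @param target_count Progenitor count defining the contour.
#' @return Data frame `mitogen`, `adipogen` (possibly 0 rows, with a warning
#'   when empty).
#' @export
iso_progenitor_contour <- function(grid, target_count) {
  pts <- list()
  for (m in sort(unique(grid$mitogen))) {
    col <- grid[grid$mitogen == m, , drop = FALSE]
    col <- col[order(col$adipogen), ]
    y <- col$n_progenitor - target_count
    if (all(y > 0) || all(y < 0)) next
    hit <- which(y == 0)
    if (length(hit) > 0) {
      pts[[length(pts) + 1]] <- data.frame(mitogen = m,
                                           adipogen = col$adipogen[hit[1]])
      next
    }
    k <- which(y[-1] * y[-length(y)] < 0)[1]
    frac <- y[k] / (y[k] - y[k + 1])
    pts[[length(pts) + 1]] <- data.frame(
      mitogen = m,
      adipogen = col$adipogen[k] + frac * (col$adipogen[k + 1] - col$adipogen[k])
    )
  }
  if (length(pts) == 0) {
    warning("iso_progenitor_contour: no column crosses the target count")
    return(data.frame(mitogen = numeric(0), adipogen = numeric(0)))
  }
  do.call(rbind, pts)
}
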