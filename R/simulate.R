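#' PPARG accumulation rate law
#'
#' The instantaneous PPARG accumulation rate of a cell during the
#' pre-commitment phase. In G1 the rate is
#' `(pparg_rate_base + pparg_rate_accel * max(0, exposure_h - pparg_lag_h))`
#' scaled by the current adipogenic strength and the per-cell multiplier;
#' outside G1 the same quantity is multiplied by `sg2m_suppression`. The rate
#' is non-decreasing in exposure: the longer a cell has been exposed to the
#' adipogenic stimulus, the faster PPARG accumulates in its next G1.
#'
#' @param exposure_h Accumulated adipogenic exposure (hours, >= 0); vectorized.
#' @param in_g1 Logical: is the cell in G1?
#' @param adipo_strength Current adipogenic strength (>= 0).
#' @param cell_multiplier Per-cell lognormal rate multiplier (>= 0).
#' @param config A [sim_config()] supplying the kinetic constants.
#' @return Rate in a.u./h (vector of `length(exposure_h)`).
#' @export
pparg_rate <- function(exposure_h, in_g1, adipo_strength, cell_multiplier = 1,
                       config = sim_config()) {
  if (any(exposure_h < 0) || any(adipo_strength < 0) ||
      any(cell_multiplier < 0)) {
    stop("pparg_rate: exposure_h, adipo_strength and cell_multiplier must be >= 0",
         call. = FALSE)
  }
  r <- (config$pparg_rate_base +
          config$pparg_rate_accel * pmax(0, exposure_h - config$pparg_lag_h)) *
    adipo_strength * cell_multiplier
  ifelse(rep_len(in_g1, length(r)), r, r * config$sg2m_suppression)
}

#' Draw a G1 duration from the lengthening law
#'
#' Mean G1 duration grows multiplicatively and linearly with accumulated
#' adipogenic exposure at cycle start, is lengthened by p21 and shortened by
#' cyclin D and mitogens:
#' `g1_base_h * (1 + g1_lengthening_rate * E(start)) * p21_scale /
#' (cyclind_scale * mitogen_strength)`, times a mean-one lognormal jitter.
#'
#' @param config A [sim_config()].
#' @param cycle_start_h Time (hours, >= 0) at which this G1 begins.
#' @param n Number of draws.
#' @param jitter If `FALSE`, return the mean duration (no randomness).
#' @param mitogen_strength,p21_scale,cyclind_scale Optional overrides; by
#'   default taken from the stimulus schedule at `cycle_start_h` and from the
#'   config.
#' @return Vector of `n` strictly positive durations (hours). Uses the current
#'   RNG stream when `jitter = TRUE`.
#' @export
draw_g1_duration <- function(config, cycle_start_h, n = 1, jitter = TRUE,
                             mitogen_strength = NULL, p21_scale = NULL,
                             cyclind_scale = NULL) {
  if (cycle_start_h < 0) stop("cycle_start_h must be >= 0", call. = FALSE)
  if (is.null(mitogen_strength)) {
    mitogen_strength <- mitogen_at(config, cycle_start_h)
  }
  if (is.null(p21_scale)) p21_scale <- config$p21_scale
  if (is.null(cyclind_scale)) cyclind_scale <- config$cyclind_scale
  if (mitogen_strength <= 0) stop("mitogen_strength must be > 0", call. = FALSE)
  if (cyclind_scale <= 0) stop("cyclind_scale must be > 0", call. = FALSE)
  mu <- config$g1_base_h *
    (1 + config$g1_lengthening_rate * exposure_at(config, cycle_start_h)) *
    p21_scale / (cyclind_scale * mitogen_strength)
  if (!jitter || config$g1_jitter_cv == 0) return(rep(mu, n))
  mu * rlnorm_mean1(n, config$g1_jitter_cv)
}

## mean-one lognormal draws at a given CV
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

draw_sg2m_duration <- function(config, n = 1) {
  config$sg2m_duration_h * rlnorm_mean1(n, config$sg2m_jitter_cv)
}

#' Simulate a dual-reporter single-cell population
#'
#' Generates `n_cells` trajectories of nuclear PPARG and APC/C-degron reporter
#' intensities over the observation window, together with full ground truth.
#' Each cell starts in G1 at stimulus addition and alternates G1 and S/G2/M
#' phases. G1 durations follow the exposure-dependent lengthening law
#' ([draw_g1_duration()]); S/G2/M durations have a fixed mean. PPARG
#' accumulates at the [pparg_rate()] law, gated to G1 (suppressed in S/G2/M).
#' The first up-crossing of `threshold_true` irreversibly commits the cell:
#' PPARG switches to self-amplification relaxing exponentially toward
#' `pparg_plateau`, and no new cell cycle is entered (an S/G2/M already in
#' progress completes its mitosis). Designated quiescent cells stop entering
#' S phase after a random onset drawn before the serum refresh and have their
#' PPARG drive scaled down, so they typically neither proliferate after the
#' refresh nor differentiate. The APC/C reporter is 0 through G1, rises
#' linearly to a per-cycle peak through S/G2/M, and drops to 0 at anaphase;
#' the H2B-split flag is set at the sample of the drop. Multiplicative
#' lognormal measurement noise is applied last. The run is a pure function of
#' the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population` with elements:
#'   \describe{
#'     \item{traces}{Long data frame: `cell_id`, `time_h`, `pparg_au`,
#'       `apc_au`, `h2b_split_flag`, `condition`.}
#'     \item{ground_truth}{List with `cells` (per-cell: `cell_id`,
#'       `rate_multiplier`, `quiescent_designated`, `quiescence_onset_h`,
#'       `crossing_time_h`, `fate`, `n_divisions`), `mitoses` (long:
#'       `cell_id`, `time_h`) and `phases` (long: `cell_id`, `phase`,
#'       `start_h`, `end_h`, `censored`).}
#'     \item{endpoint}{Per-cell endpoint marker table (`cell_id`, `fabp4`,
#'       `glut4`, `adiponectin`, `lipid`, `p21`, `cyclind1`,
#'       `pparg_end`). Markers are saturating functions of time spent above
#'       the threshold plus noise, so they carry no information about
#'       pre-threshold PPARG.}
#'     \item{config}{The configuration used.}
#'   }
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  dt <- config$sample_interval_h
  times <- seq(0, config$horizon_h, by = dt)
  n_t <- length(times)
  n <- config$n_cells
  kamp <- config$amplification_rate /
    (config$pparg_plateau - config$threshold_true)

  pparg_mat <- matrix(0, n_t, n)
  apc_mat <- matrix(0, n_t, n)
  flag_mat <- matrix(0L, n_t, n)
  gt_cells <- vector("list", n)
  gt_mit <- vector("list", n)
  gt_phase <- vector("list", n)
  ep_rows <- vector("list", n)

  t_mid <- times[-n_t] + dt / 2
  adipo_mid <- adipo_at(config, t_mid)
  expo_mid <- exposure_at(config, t_mid)

  for (i in seq_len(n)) {
    mult <- rlnorm_mean1(1, config$heterogeneity_cv)
    quiescent <- stats::runif(1) < config$quiescent_fraction
    onset <- stats::runif(1, 0, config$refresh_time_h)
    drive <- mult * if (quiescent) config$quiescent_pparg_factor else 1

    ## --- pass 1: cycling phase schedule (pre-commitment) -------------------
    ph_start <- numeric(0); ph_end <- numeric(0); ph_lab <- character(0)
    mitoses <- numeric(0)
    t0 <- 0
    repeat {
      d_g1 <- draw_g1_duration(config, t0)
      g1_end <- t0 + d_g1
      if ((quiescent && g1_end > onset) || g1_end >= config$horizon_h) {
        ph_start <- c(ph_start, t0); ph_end <- c(ph_end, config$horizon_h)
        ph_lab <- c(ph_lab, "G1")
        break
      }
      d_s <- draw_sg2m_duration(config)
      m_t <- g1_end + d_s
      ph_start <- c(ph_start, t0, g1_end)
      ph_end <- c(ph_end, g1_end, min(m_t, config$horizon_h))
      ph_lab <- c(ph_lab, "G1", "SG2M")
      if (m_t <= config$horizon_h) {
        mitoses <- c(mitoses, m_t)
        t0 <- m_t
        if (t0 >= config$horizon_h) break
      } else {
        break
      }
    }

    ## --- pass 2: PPARG integration with phase-overlap weighting ------------
    g1_idx <- which(ph_lab == "G1")
    g1_overlap <- numeric(n_t - 1)
    for (j in g1_idx) {
      g1_overlap <- g1_overlap +
        pmax(0, pmin(times[-1], ph_end[j]) - pmax(times[-n_t], ph_start[j]))
    }
    rate_g1 <- pparg_rate(expo_mid, TRUE, adipo_mid, drive, config)
    dP <- rate_g1 * g1_overlap +
      (rate_g1 * config$sg2m_suppression) * (dt - g1_overlap)
    P <- config$pparg_basal + c(0, cumsum(dP))

    crossing <- NA_real_
    above <- which(P >= config$threshold_true)
    if (length(above) > 0) {
      k <- above[1]
      if (k == 1) {
        crossing <- times[1]
      } else {
        crossing <- times[k - 1] + dt * (config$threshold_true - P[k - 1]) /
          (P[k] - P[k - 1])
      }
      post <- times >= crossing
      P[post] <- config$pparg_plateau -
        (config$pparg_plateau - config$threshold_true) *
        exp(-kamp * (times[post] - crossing))
    }

    ## --- pass 3: commitment truncates the cycling schedule -----------------
    if (!is.na(crossing)) {
      ph_i <- which(ph_start <= crossing & crossing < ph_end)[1]
      trunc_from <- NA_integer_  # index of the first phase to drop
      if (!is.na(ph_i)) {
        if (ph_lab[ph_i] == "G1") {
          trunc_from <- ph_i
        } else if (ph_end[ph_i] < config$horizon_h - 1e-9) {
          ## in-progress S/G2/M completes its mitosis, then terminal G1
          trunc_from <- ph_i + 1L
        }  # censored final S/G2/M: nothing to truncate
      }
      if (!is.na(trunc_from) && trunc_from <= length(ph_lab)) {
        keep <- seq_len(trunc_from - 1L)
        term_start <- if (length(keep) > 0) ph_end[keep[length(keep)]] else 0
        ph_start <- c(ph_start[keep], term_start)
        ph_end <- c(ph_end[keep], config$horizon_h)
        ph_lab <- c(ph_lab[keep], "G1")
        mitoses <- mitoses[mitoses <= term_start + 1e-9]
      }
    }
    censored <- ph_end >= config$horizon_h - 1e-9

    ## --- APC/C reporter -----------------------------------------------------
    apc <- numeric(n_t)
    flags <- integer(n_t)
    sg_idx <- which(ph_lab == "SG2M")
    for (j in sg_idx) {
      peak <- config$apc_peak_au * rlnorm_mean1(1, config$apc_peak_cv)
      s <- ph_start[j]
      e_full <- s + (if (censored[j]) {
        ## censored S/G2/M: rise toward a mitosis beyond the horizon
        draw_sg2m_duration(config)
      } else {
        ph_end[j] - s
      })
      inph <- times >= s & times < ph_end[j]
      apc[inph] <- peak * (times[inph] - s) / (e_full - s)
      if (!censored[j]) {
        k <- which(times >= ph_end[j])[1]
        if (!is.na(k)) flags[k] <- 1L
      }
    }

    ## --- fate ---------------------------------------------------------------
    s_entries <- ph_start[ph_lab == "SG2M"]
    fate <- if (!is.na(crossing)) {
      "differentiated_postmitotic"
    } else if (any(s_entries > config$refresh_time_h)) {
      "undiff_proliferating"
    } else {
      "undiff_quiescent"
    }

    ## --- measurement noise --------------------------------------------------
    if (config$noise_cv > 0) {
      P_obs <- P * rlnorm_mean1(n_t, config$noise_cv)
      apc_obs <- apc * rlnorm_mean1(n_t, config$noise_cv)
    } else {
      P_obs <- P
      apc_obs <- apc
    }

    ## --- endpoint markers ---------------------------------------------------
    above_h <- if (is.na(crossing)) 0 else config$horizon_h - crossing
    sat <- above_h^2 / (above_h^2 + 12^2)
    msd <- 800 * config$noise_cv
    mk_noise <- function() if (msd > 0) stats::rnorm(1, 0, msd) else 0
    ep_rows[[i]] <- data.frame(
      cell_id = i,
      fabp4 = max(0, 1000 * sat + mk_noise()),
      glut4 = max(0, 800 * sat + mk_noise()),
      adiponectin = max(0, 900 * sat + mk_noise()),
      lipid = max(0, 1200 * sat + mk_noise()),
      p21 = max(0, 150 + 850 * sat + mk_noise()),
      cyclind1 = max(0, 400 - 300 * sat + mk_noise() / 2),
      pparg_end = P_obs[n_t]
    )

    pparg_mat[, i] <- P_obs
    apc_mat[, i] <- apc_obs
    flag_mat[, i] <- flags
    gt_cells[[i]] <- data.frame(
      cell_id = i, rate_multiplier = mult, quiescent_designated = quiescent,
      quiescence_onset_h = if (quiescent) onset else NA_real_,
      crossing_time_h = crossing, fate = fate,
      n_divisions = length(mitoses)
    )
    if (length(mitoses) > 0) {
      gt_mit[[i]] <- data.frame(cell_id = i, time_h = mitoses)
    }
    gt_phase[[i]] <- data.frame(
      cell_id = i, phase = ph_lab, start_h = ph_start, end_h = ph_end,
      censored = censored
    )
  }

  traces <- data.frame(
    cell_id = rep(seq_len(n), each = n_t),
    time_h = rep(times, n),
    pparg_au = as.vector(pparg_mat),
    apc_au = as.vector(apc_mat),
    h2b_split_flag = as.vector(flag_mat),
    condition = config$condition
  )
  out <- list(
    traces = traces,
    ground_truth = list(
      cells = do.call(rbind, gt_cells),
      mitoses = if (any(!vapply(gt_mit, is.null, logical(1)))) {
        do.call(rbind, gt_mit[!vapply(gt_mit, is.null, logical(1))])
      } else {
        data.frame(cell_id = integer(0), time_h = numeric(0))
      },
      phases = do.call(rbind, gt_phase)
    ),
    endpoint = do.call(rbind, ep_rows),
    config = config
  )
  class(out) <- "sim_population"
  out
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$ground_truth$cells$fate)
  cat("<sim_population>", x$config$n_cells, "cells x",
      length(unique(x$traces$time_h)), "samples; fates:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Inject tracking artifacts into a trace set
#'
#' Degrades a clean trace table so that quality-control filters have something
#' to catch: some cells lose their tail (absent near the endpoint), some lose
#' their head (late first appearance), and some receive a single-frame PPARG
#' intensity spike.
#'
#' @param traces Long trace table as produced by [simulate_population()].
#' @param n_truncate_end,n_late_start,n_spike Number of distinct cells to
#'   degrade with each artifact.
#' @param truncate_h,late_h Hours removed from the tail / head.
#' @param spike_factor Multiplier applied to one PPARG sample.
#' @param seed Integer seed.
#' @return A degraded copy of `traces` plus an attribute
#'   `degraded_cells` (data frame of `cell_id`, `artifact`).
#' @export
inject_artifacts <- function(traces, n_truncate_end = 0, n_late_start = 0,
                             n_spike = 0, truncate_h = 12, late_h = 6,
                             spike_factor = 10, seed = 1L) {
  set.seed(seed)
  ids <- unique(traces$cell_id)
  n_bad <- n_truncate_end + n_late_start + n_spike
  if (n_bad > length(ids)) stop("more artifacts than cells", call. = FALSE)
  bad <- sample(ids, n_bad)
  grp <- rep(c("truncate_end", "late_start", "spike"),
             c(n_truncate_end, n_late_start, n_spike))
  t_max <- max(traces$time_h)
  t_min <- min(traces$time_h)
  keep <- rep(TRUE, nrow(traces))
  for (j in seq_along(bad)) {
    rows <- traces$cell_id == bad[j]
    if (grp[j] == "truncate_end") {
      keep[rows & traces$time_h > t_max - truncate_h] <- FALSE
    } else if (grp[j] == "late_start") {
      keep[rows & traces$time_h < t_min + late_h] <- FALSE
    } else {
      cand <- which(rows)
      k <- cand[sample.int(length(cand), 1)]
      traces$pparg_au[k] <- traces$pparg_au[k] * spike_factor
    }
  }
  out <- traces[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degraded_cells") <-
    data.frame(cell_id = bad, artifact = grp)
  out
}
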