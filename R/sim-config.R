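#' Build a simulation configuration
#'
#' A `sim_config` fully parameterizes the stochastic dual-reporter population
#' generator: the stimulus schedule, the cell-cycle timing laws, the PPARG
#' accumulation/amplification kinetics, the reporter synthesis model, noise,
#' and the seed. The defaults describe the standard 96-h differentiation
#' protocol: an adipogenic cocktail applied for the first 48 h, then replaced
#' at the 48-h serum refresh by insulin-only medium with a reduced adipogenic
#' drive, while mitogens (serum) are present throughout.
#'
#' Time is in hours with `t = 0` at stimulus addition. Intensities are in
#' arbitrary units (a.u.) matching typical nuclear fluorescence quantification.
#'
#' @param horizon_h Observation span in hours.
#' @param sample_interval_h Sampling interval in hours (default 0.2 h = 12 min).
#' @param stimulus_schedule Data frame with columns `start_h`, `end_h`,
#'   `adipo_strength`, `mitogen_strength`; windows must tile `[0, horizon_h]`.
#' @param n_cells Number of founder cells to simulate.
#' @param quiescent_fraction Probability that a cell is designated quiescent:
#'   it stops entering S phase after a random onset drawn before the serum
#'   refresh and its adipogenic responsiveness is scaled by
#'   `quiescent_pparg_factor`, so it typically neither proliferates after the
#'   refresh nor differentiates.
#' @param g1_base_h Baseline G1 duration (hours) of unstimulated proliferating
#'   cells.
#' @param g1_lengthening_rate Dimensionless increase in mean G1 duration per
#'   hour of accumulated adipogenic exposure.
#' @param g1_jitter_cv Coefficient of variation of the lognormal multiplicative
#'   jitter on each G1 draw (0 disables jitter).
#' @param sg2m_duration_h Mean S/G2/M duration (hours); not
#'   exposure-dependent.
#' @param sg2m_jitter_cv CV of the lognormal jitter on S/G2/M duration.
#' @param pparg_basal Initial PPARG level (a.u.).
#' @param pparg_rate_base Basal PPARG accumulation rate in G1 (a.u./h) at unit
#'   adipogenic strength.
#' @param pparg_rate_accel Increase of the G1 accumulation rate per hour of
#'   adipogenic exposure beyond `pparg_lag_h` (a.u./h per hour).
#' @param pparg_lag_h Exposure lag (hours) before the rate acceleration
#'   engages; cells whose exposure is below the lag accumulate at the basal
#'   rate only.
#' @param sg2m_suppression Multiplier in `[0, 1]` applied to the PPARG rate
#'   outside G1 (near 0: accumulation is suppressed during S/G2/M).
#' @param threshold_true Ground-truth commitment threshold (a.u.); the first
#'   persistent up-crossing irreversibly commits the cell.
#' @param amplification_rate Initial self-amplification rate (a.u./h) at the
#'   moment of crossing; PPARG then relaxes exponentially toward
#'   `pparg_plateau`.
#' @param pparg_plateau Post-commitment PPARG plateau (a.u.).
#' @param p21_scale Multiplier on G1 duration (>1 lengthens G1, as does p21).
#' @param cyclind_scale Divisor-side multiplier on G1 duration (>1 shortens
#'   G1, as does cyclin D).
#' @param quiescent_pparg_factor Multiplier on the PPARG drive of designated
#'   quiescent cells.
#' @param apc_peak_au Mean APC/C-reporter peak intensity reached just before
#'   anaphase (a.u.).
#' @param apc_peak_cv Per-cycle CV of the APC/C peak.
#' @param noise_cv CV of the multiplicative lognormal measurement noise
#'   applied last to both reporters.
#' @param heterogeneity_cv CV of the per-cell lognormal multiplier applied to
#'   PPARG accumulation rates.
#' @param refresh_time_h Time of the serum refresh / stimulus removal (hours).
#' @param condition Condition label stored in the trace table.
#' @param seed Integer seed; identical configs give bit-identical output.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_population()], [apply_perturbation()]
#' @export
sim_config <- function(horizon_h = 96,
                       sample_interval_h = 0.2,
                       stimulus_schedule = NULL,
                       n_cells = 500,
                       quiescent_fraction = 0.1,
                       g1_base_h = 4,
                       g1_lengthening_rate = 0.05,
                       g1_jitter_cv = 0.25,
                       sg2m_duration_h = 8,
                       sg2m_jitter_cv = 0.05,
                       pparg_basal = 100,
                       pparg_rate_base = 2,
                       pparg_rate_accel = 0.8,
                       pparg_lag_h = 12,
                       sg2m_suppression = 0.05,
                       threshold_true = 450,
                       amplification_rate = 300,
                       pparg_plateau = 2000,
                       p21_scale = 1,
                       cyclind_scale = 1,
                       quiescent_pparg_factor = 0.05,
                       apc_peak_au = 500,
                       apc_peak_cv = 0.2,
                       noise_cv = 0.03,
                       heterogeneity_cv = 0.5,
                       refresh_time_h = 48,
                       condition = "control",
                       seed = 1L) {
  if (is.null(stimulus_schedule)) {
    stimulus_schedule <- data.frame(
      start_h = c(0, refresh_time_h),
      end_h = c(refresh_time_h, horizon_h),
      adipo_strength = c(1, 0.05),
      mitogen_strength = c(1, 1)
    )
  }
  cfg <- list(
    horizon_h = horizon_h,
    sample_interval_h = sample_interval_h,
    stimulus_schedule = stimulus_schedule,
    n_cells = as.integer(n_cells),
    quiescent_fraction = quiescent_fraction,
    g1_base_h = g1_base_h,
    g1_lengthening_rate = g1_lengthening_rate,
    g1_jitter_cv = g1_jitter_cv,
    sg2m_duration_h = sg2m_duration_h,
    sg2m_jitter_cv = sg2m_jitter_cv,
    pparg_basal = pparg_basal,
    pparg_rate_base = pparg_rate_base,
    pparg_rate_accel = pparg_rate_accel,
    pparg_lag_h = pparg_lag_h,
    sg2m_suppression = sg2m_suppression,
    threshold_true = threshold_true,
    amplification_rate = amplification_rate,
    pparg_plateau = pparg_plateau,
    p21_scale = p21_scale,
    cyclind_scale = cyclind_scale,
    quiescent_pparg_factor = quiescent_pparg_factor,
    apc_peak_au = apc_peak_au,
    apc_peak_cv = apc_peak_cv,
    noise_cv = noise_cv,
    heterogeneity_cv = heterogeneity_cv,
    refresh_time_h = refresh_time_h,
    condition = condition,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]; on violation an error
#' names the offending field.
#'
#' @param config A `sim_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fail <- function(field, why) {
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(config$sample_interval_h) || config$sample_interval_h <= 0) {
    fail("sample_interval_h", "must be a positive number")
  }
  if (!num1(config$horizon_h) || config$horizon_h <= 0) {
    fail("horizon_h", "must be a positive number")
  }
  n_steps <- config$horizon_h / config$sample_interval_h
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    fail("horizon_h", "must be an integer multiple of sample_interval_h")
  }
  if (!is.numeric(config$n_cells) || config$n_cells < 1) {
    fail("n_cells", "must be a positive count")
  }
  if (!num1(config$quiescent_fraction) || config$quiescent_fraction < 0 ||
      config$quiescent_fraction > 1) {
    fail("quiescent_fraction", "must lie in [0, 1]")
  }
  for (f in c("g1_base_h", "sg2m_duration_h", "pparg_basal", "pparg_rate_base",
              "pparg_rate_accel", "pparg_lag_h", "g1_lengthening_rate",
              "amplification_rate", "pparg_plateau", "apc_peak_au",
              "noise_cv", "heterogeneity_cv", "g1_jitter_cv", "sg2m_jitter_cv",
              "apc_peak_cv", "quiescent_pparg_factor")) {
    if (!num1(config[[f]]) || config[[f]] < 0) fail(f, "must be >= 0")
  }
  if (config$g1_base_h <= 0) fail("g1_base_h", "must be > 0")
  if (config$sg2m_duration_h <= 0) fail("sg2m_duration_h", "must be > 0")
  if (!num1(config$sg2m_suppression) || config$sg2m_suppression < 0 ||
      config$sg2m_suppression > 1) {
    fail("sg2m_suppression", "must lie in [0, 1]")
  }
  if (!num1(config$threshold_true) ||
      config$threshold_true <= config$pparg_basal) {
    fail("threshold_true", "must exceed pparg_basal")
  }
  if (!num1(config$p21_scale) || config$p21_scale <= 0) {
    fail("p21_scale", "must be > 0")
  }
  if (!num1(config$cyclind_scale) || config$cyclind_scale <= 0) {
    fail("cyclind_scale", "must be > 0")
  }
  ss <- config$stimulus_schedule
  if (!is.data.frame(ss) ||
      !all(c("start_h", "end_h", "adipo_strength", "mitogen_strength") %in%
           names(ss))) {
    fail("stimulus_schedule",
         "needs columns start_h, end_h, adipo_strength, mitogen_strength")
  }
  if (any(ss$adipo_strength < 0) || any(ss$mitogen_strength < 0)) {
    fail("stimulus_schedule", "strengths must be >= 0")
  }
  if (any(ss$end_h <= ss$start_h)) {
    fail("stimulus_schedule", "windows must have end_h > start_h")
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cells, "cells,", x$horizon_h, "h sampled every",
      x$sample_interval_h * 60, "min; condition:", x$condition,
      "; seed:", x$seed, "\n")
  invisible(x)
}

## Stimulus strengths at time t (vectorized over t). Outside any window the
## strength is 0 for adipogen and 1 for mitogen (serum assumed present).
adipo_at <- function(config, t) {
  ss <- config$stimulus_schedule
  out <- numeric(length(t))
  for (i in seq_len(nrow(ss))) {
    inw <- t >= ss$start_h[i] & t < ss$end_h[i]
    out[inw] <- ss$adipo_strength[i]
  }
  out
}

mitogen_at <- function(config, t) {
  ss <- config$stimulus_schedule
  out <- rep(1, length(t))
  for (i in seq_len(nrow(ss))) {
    inw <- t >= ss$start_h[i] & t < ss$end_h[i]
    out[inw] <- ss$mitogen_strength[i]
  }
  out
}

## Accumulated adipogenic exposure E(t) = integral_0^t adipo(s) ds, vectorized.
exposure_at <- function(config, t) {
  ss <- config$stimulus_schedule
  out <- numeric(length(t))
  for (i in seq_len(nrow(ss))) {
    lo <- ss$start_h[i]; hi <- ss$end_h[i]
    out <- out + ss$adipo_strength[i] * pmax(0, pmin(t, hi) - lo)
  }
  out
}

#' Apply a named experimental perturbation to a configuration
#'
#' Returns a modified copy of a [sim_config()] reproducing the direction of a
#' canonical perturbation experiment: p21 knockdown shortens G1, p21
#' overexpression lengthens it, cyclin D1 knockdown lengthens G1, MEK
#' inhibition and low serum reduce mitogen strength, and rosiglitazone (a
#' direct PPARG agonist) increases adipogenic strength.
#'
#' @param config A `sim_config`.
#' @param name One of `"control"`, `"sip21"`, `"p21_overexpression"`,
#'   `"sicyclinD1"`, `"mek_inhibitor"`, `"low_serum"`, `"rosiglitazone"`.
#' @return A modified `sim_config` with its `condition` label set to `name`
#'   (the control copy keeps its label).
#' @export
apply_perturbation <- function(config, name) {
  validate_sim_config(config)
  valid <- c("control", "sip21", "p21_overexpression", "sicyclinD1",
             "mek_inhibitor", "low_serum", "rosiglitazone")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown perturbation; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  out <- config
  switch(name,
    control = NULL,
    sip21 = {
      out$p21_scale <- config$p21_scale * 0.5
    },
    p21_overexpression = {
      out$p21_scale <- config$p21_scale * 2
    },
    sicyclinD1 = {
      out$cyclind_scale <- config$cyclind_scale * 0.5
    },
    mek_inhibitor = {
      out$stimulus_schedule$mitogen_strength <-
        config$stimulus_schedule$mitogen_strength * 0.5
    },
    low_serum = {
      out$stimulus_schedule$mitogen_strength <-
        config$stimulus_schedule$mitogen_strength * 0.4
    },
    rosiglitazone = {
      out$stimulus_schedule$adipo_strength <-
        config$stimulus_schedule$adipo_strength * 1.5
    }
  )
  if (name != "control") out$condition <- name
  validate_sim_config(out)
  out
}
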