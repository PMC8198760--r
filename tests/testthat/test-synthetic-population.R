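test_that("config validation names the offending field", {
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(quiescent_fraction = 1.5), "quiescent_fraction")
  expect_error(sim_config(threshold_true = 50, pparg_basal = 100),
               "threshold_true")
  expect_error(sim_config(horizon_h = 96.1), "horizon_h")
  expect_error(sim_config(sg2m_suppression = 2), "sg2m_suppression")
})

test_that("accumulated exposure integrates the stimulus schedule", {
  cfg <- sim_config()
  # full strength for 48 h then 0.05: E(24) = 24, E(48) = 48,
  # E(96) = 48 + 0.05 * 48
  expect_equal(exposure_at(cfg, c(0, 24, 48, 96)),
               c(0, 24, 48, 48 + 0.05 * 48))
})

test_that("a deterministic unstimulated cell divides every 12 hours", {
  cfg <- sim_config(
    n_cells = 1, noise_cv = 0, heterogeneity_cv = 0, g1_jitter_cv = 0,
    sg2m_jitter_cv = 0, apc_peak_cv = 0, quiescent_fraction = 0,
    stimulus_schedule = data.frame(start_h = 0, end_h = 96,
                                   adipo_strength = 0, mitogen_strength = 1),
    seed = 7)
  sim <- simulate_population(cfg)
  expect_equal(sim$ground_truth$mitoses$time_h, seq(12, 96, by = 12))
  expect_equal(sim$ground_truth$cells$n_divisions, 8)
})

test_that("without adipogenic drive no cell ever differentiates", {
  cfg <- sim_config(
    n_cells = 25, noise_cv = 0, heterogeneity_cv = 0,
    quiescent_fraction = 0,
    stimulus_schedule = data.frame(start_h = 0, end_h = 96,
                                   adipo_strength = 0, mitogen_strength = 1),
    seed = 3)
  sim <- simulate_population(cfg)
  expect_true(all(is.na(sim$ground_truth$cells$crossing_time_h)))
  expect_true(all(sim$ground_truth$cells$fate == "undiff_proliferating"))
  # PPARG never moves off basal without drive
  expect_equal(max(sim$traces$pparg_au), cfg$pparg_basal)
})

test_that("simulation is bit-identical for identical configs", {
  cfg <- sim_config(n_cells = 20, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$endpoint, b$endpoint)
})

test_that("every cell gets exactly one fate and counts sum to n_cells", {
  sim <- cohort("noisy")
  fates <- sim$ground_truth$cells$fate
  expect_equal(length(fates), sim$config$n_cells)
  expect_true(all(fates %in% c("differentiated_postmitotic",
                               "undiff_proliferating", "undiff_quiescent")))
  # crossing present iff differentiated
  expect_equal(!is.na(sim$ground_truth$cells$crossing_time_h),
               fates == "differentiated_postmitotic")
})

test_that("ground truth never has a cell-cycle entry after crossing", {
  sim <- cohort("noisy")
  gt <- sim$ground_truth
  for (i in which(!is.na(gt$cells$crossing_time_h))) {
    s_entries <- gt$phases$start_h[gt$phases$cell_id == gt$cells$cell_id[i] &
                                     gt$phases$phase == "SG2M"]
    expect_true(all(s_entries <= gt$cells$crossing_time_h[i] + 1e-9))
  }
})

test_that("PPARG is constant during S/G2/M when suppression is off", {
  cfg <- sim_config(n_cells = 10, noise_cv = 0, sg2m_suppression = 0,
                    threshold_true = 1e6, pparg_plateau = 2e6, seed = 17)
  sim <- simulate_population(cfg)
  ph <- sim$ground_truth$phases
  sg <- ph[ph$phase == "SG2M", ]
  for (j in seq_len(nrow(sg))) {
    tr <- sim$traces[sim$traces$cell_id == sg$cell_id[j], ]
    # strictly interior samples of the S/G2/M interval
    inside <- tr$time_h > sg$start_h[j] + cfg$sample_interval_h &
      tr$time_h < sg$end_h[j] - cfg$sample_interval_h
    if (sum(inside) > 1) {
      expect_equal(diff(range(tr$pparg_au[inside])), 0, tolerance = 1e-9)
    }
  }
})

test_that("PPARG rate law is monotone in exposure and gated by phase", {
  cfg <- sim_config()
  e <- seq(0, 60, by = 5)
  r <- pparg_rate(e, in_g1 = TRUE, adipo_strength = 1, config = cfg)
  expect_true(all(diff(r) >= 0))
  # flat at the basal rate below the lag
  expect_equal(r[e <= cfg$pparg_lag_h], rep(cfg$pparg_rate_base,
                                            sum(e <= cfg$pparg_lag_h)))
  # full suppression outside G1
  cfg0 <- sim_config(sg2m_suppression = 0)
  expect_equal(pparg_rate(30, FALSE, 1, config = cfg0), 0)
  expect_error(pparg_rate(-1, TRUE, 1, config = cfg), ">= 0")
})

test_that("G1 duration law scales as specified", {
  cfg <- sim_config()
  # identity: no jitter, all scales 1, cycle start 0
  expect_equal(draw_g1_duration(cfg, 0, jitter = FALSE, mitogen_strength = 1,
                                p21_scale = 1, cyclind_scale = 1),
               cfg$g1_base_h)
  # Monte-Carlo mean halves when p21_scale halves
  set.seed(1)
  d_half <- draw_g1_duration(cfg, 0, n = 10000, p21_scale = 0.5)
  d_full <- draw_g1_duration(cfg, 0, n = 10000, p21_scale = 1)
  expect_equal(mean(d_half) / mean(d_full), 0.5, tolerance = 0.03)
  # second-cycle G1 under active stimulus is stochastically longer
  set.seed(2)
  first <- draw_g1_duration(cfg, 0, n = 3000)
  second <- draw_g1_duration(cfg, 12, n = 3000)
  expect_gt(median(second), median(first))
  expect_error(draw_g1_duration(cfg, 0, mitogen_strength = 0), "mitogen")
  expect_error(draw_g1_duration(cfg, 0, cyclind_scale = 0), "cyclind")
})

test_that("perturbations modify the configuration in the stated direction", {
  cfg <- sim_config(seed = 12)
  expect_identical(apply_perturbation(cfg, "control"), cfg)
  expect_error(apply_perturbation(cfg, "nonsense"), "valid names")
  expect_lt(apply_perturbation(cfg, "sip21")$p21_scale, cfg$p21_scale)
  expect_gt(apply_perturbation(cfg, "p21_overexpression")$p21_scale,
            cfg$p21_scale)
  expect_lt(apply_perturbation(cfg, "sicyclinD1")$cyclind_scale,
            cfg$cyclind_scale)
  expect_true(all(
    apply_perturbation(cfg, "mek_inhibitor")$stimulus_schedule$mitogen_strength <
      cfg$stimulus_schedule$mitogen_strength))
  expect_true(all(
    apply_perturbation(cfg, "rosiglitazone")$stimulus_schedule$adipo_strength >
      cfg$stimulus_schedule$adipo_strength))
})

test_that("p21 knockdown shortens total G1 time; MEK inhibition trades proliferation for differentiation", {
  base <- sim_config(n_cells = 250, seed = 31)
  ctrl <- simulate_population(base)
  sip21 <- simulate_population(apply_perturbation(base, "sip21"))
  total_g1 <- function(sim) {
    ph <- sim$ground_truth$phases
    g1 <- ph[ph$phase == "G1" & !ph$censored, ]
    sum(g1$end_h - g1$start_h) / sim$config$n_cells
  }
  expect_lt(total_g1(sip21), total_g1(ctrl))
  mek <- simulate_population(apply_perturbation(base, "mek_inhibitor"))
  mean_div <- function(sim) mean(sim$ground_truth$cells$n_divisions)
  frac_crossed <- function(sim) {
    mean(!is.na(sim$ground_truth$cells$crossing_time_h))
  }
  expect_lt(mean_div(mek), mean_div(ctrl))
  expect_gt(frac_crossed(mek), frac_crossed(ctrl))
})

test_that("default endpoint distribution is bimodal with separable components", {
  sim <- cohort("noisy")
  mix <- fit_endpoint_mixture(sim$endpoint$pparg_end)
  # components well separated relative to their spreads
  expect_gt(mix$mean[2] - mix$mean[1], 2 * (mix$sd[1] + mix$sd[2]))
  lab <- classify_endpoint(sim$endpoint$pparg_end, mix)
  gt_crossed <- !is.na(sim$ground_truth$cells$crossing_time_h)
  expect_gte(mean((lab == "differentiated") == gt_crossed), 0.95)
})

test_that("endpoint markers reflect time above threshold only", {
  sim <- cohort("clean")
  gt <- sim$ground_truth$cells
  above_h <- ifelse(is.na(gt$crossing_time_h), 0,
                    sim$config$horizon_h - gt$crossing_time_h)
  # noise-free cohort: markers are exact saturating functions
  expect_equal(sim$endpoint$fabp4, 1000 * above_h^2 / (above_h^2 + 144),
               tolerance = 1e-8)
  expect_true(all(sim$endpoint$fabp4[is.na(gt$crossing_time_h)] == 0))
})

test_that("artifact injection degrades exactly the requested cells", {
  sim <- cohort("clean")
  sub <- sim$traces[sim$traces$cell_id %in% 1:40, ]
  deg <- inject_artifacts(sub, n_truncate_end = 3, n_late_start = 3,
                          n_spike = 3, seed = 4)
  info <- attr(deg, "degraded_cells")
  expect_equal(nrow(info), 9)
  expect_equal(length(unique(info$cell_id)), 9)
})
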