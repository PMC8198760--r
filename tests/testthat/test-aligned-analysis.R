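test_that("alignment is a pure shift that can be inverted", {
  sim <- cohort("clean")
  cr <- detect_crossings(sim$traces, sim$config$threshold_true)
  al <- align_to_crossing(sim$traces, cr)
  # single committed cell: the median equals its own shifted trace
  one_id <- al$cell_id[1]
  one <- sim$traces[sim$traces$cell_id == one_id, ]
  al1 <- align_to_crossing(one, cr[cr$cell_id == one_id, ])
  expect_equal(al1$summary$median[!is.na(al1$summary$median)],
               one$pparg_au)
  expect_equal(al1$aligned_time_h + al1$crossing_time_h[1], one$time_h)
  # de-alignment recovers the original values for every cell
  for (i in seq_len(5)) {
    row <- al$values[i, ]
    t_orig <- al$aligned_time_h[!is.na(row)] + al$crossing_time_h[i]
    orig <- sim$traces[sim$traces$cell_id == al$cell_id[i], ]
    expect_equal(unname(row[!is.na(row)]),
                 orig$pparg_au[match(round(t_orig, 6),
                                     round(orig$time_h, 6))])
  }
  expect_error(align_to_crossing(sim$traces,
                                 data.frame(cell_id = 1,
                                            crossing_time_h = NA_real_)),
               "no committed")
})

test_that("the aligned median switches from a slow to a fast rise at crossing", {
  chain <- commitment_chain("noisy")
  al <- align_to_crossing(chain$sim$traces, chain$crossings)
  sm <- al$summary
  slope <- function(lo, hi) {
    s <- sm$aligned_time_h >= lo & sm$aligned_time_h <= hi & sm$n >= 10
    unname(coef(lm(sm$median[s] ~ sm$aligned_time_h[s]))[2])
  }
  expect_gt(slope(1, 5), slope(-10, -2))
})

test_that("correlation profile equals a direct per-time Pearson recomputation", {
  chain <- commitment_chain("noisy")
  al <- align_to_crossing(chain$sim$traces, chain$crossings)
  ep <- chain$sim$endpoint[, c("cell_id", "glut4", "fabp4")]
  cp <- correlation_profile(al, ep)
  ep_m <- ep[match(al$cell_id, ep$cell_id), ]
  for (m in c("glut4", "fabp4")) {
    sub <- cp[cp$marker == m, ]
    for (j in sample(seq_along(al$aligned_time_h), 25)) {
      x <- al$values[, j]
      ok <- !is.na(x)
      expected <- if (sum(ok) < 10 || sd(x[ok]) == 0) NA_real_ else
        cor(x[ok], ep_m[[m]][ok])
      expect_equal(sub$r[j], expected, tolerance = 1e-12)
    }
  }
})

test_that("hand-computed Pearson values are reproduced", {
  # three cells, all crossing at the same time, marker = 2 x PPARG
  t <- seq(0, 2, 0.2)
  traces <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(cell_id = i, time_h = t, pparg_au = i * (1 + t),
               apc_au = 0, h2b_split_flag = 0, condition = "c")
  }))
  cr <- data.frame(cell_id = 1:3, crossing_time_h = 1)
  al <- align_to_crossing(traces, cr)
  ep <- data.frame(cell_id = 1:3, m = c(2, 4, 6))
  cp <- correlation_profile(al, ep, min_n = 3)
  expect_true(all(abs(cp$r - 1) < 1e-12))
})

test_that("scrambling crossings preserves their multiset and is seeded", {
  chain <- commitment_chain("noisy")
  scr1 <- scramble_crossings(chain$crossings, seed = 7)
  scr2 <- scramble_crossings(chain$crossings, seed = 7)
  expect_identical(scr1, scr2)
  expect_equal(sort(scr1$crossing_time_h), sort(chain$crossings$crossing_time_h))
  expect_equal(is.na(scr1$crossing_time_h), is.na(chain$crossings$crossing_time_h))
  expect_error(scramble_crossings(data.frame(cell_id = 1,
                                             crossing_time_h = 5)), ">= 2")
})

test_that("the pre/post correlation asymmetry vanishes under scrambling", {
  chain <- commitment_chain("noisy")
  ep <- chain$sim$endpoint[, c("cell_id", "glut4")]
  asym <- function(crossings) {
    al <- align_to_crossing(chain$sim$traces, crossings)
    cp <- correlation_profile(al, ep)
    mean(cp$r[cp$aligned_time_h > 4], na.rm = TRUE) -
      mean(cp$r[cp$aligned_time_h < -4], na.rm = TRUE)
  }
  true_asym <- asym(chain$crossings)
  scr_asym <- asym(scramble_crossings(chain$crossings, seed = 11))
  expect_gt(true_asym, 0)
  expect_lt(abs(scr_asym), abs(true_asym))
})

test_that("level binning follows half-open bin arithmetic", {
  # value 50 in 10 equal bins over [0, 100): bin 6
  b <- bin_by_level(c(0, 50, 99.9), n_bins = 10,
                    edges = seq(0, 100, 10))
  expect_equal(b$n[b$bin == 6], 1)
  # explicit 100:100:2500 edges: value 100 goes in the first bin
  edges <- seq(100, 2500, by = 100)
  b2 <- bin_by_level(c(100, 150, 2500), edges = edges)
  expect_equal(b2$n[b2$bin == 1], 2)
  expect_equal(b2$n[b2$bin == 24], 1)  # last bin closed
  # out-of-range values land in a reported overflow bin
  b3 <- bin_by_level(c(50, 150), edges = edges)
  expect_true(any(b3$overflow))
  expect_equal(sum(b3$n), 2)
})

test_that("differentiated fraction increases with the 48-h PPARG level", {
  chain <- commitment_chain("noisy")
  diff_flag <- as.numeric(chain$labels == "differentiated")
  b <- bin_by_level(chain$ref_values, stat = diff_flag, n_bins = 6)
  frac <- b$stat[b$n >= 10]
  expect_true(all(diff(frac) >= 0))
})

test_that("mitosis-to-threshold gaps subtract correctly and normalize", {
  ev <- structure(list(
    cells = data.frame(cell_id = 1, n_divisions = 1,
                       span_start_h = 0, span_end_h = 96),
    mitoses = data.frame(cell_id = 1, time_h = 9),
    intervals = data.frame(cell_id = 1, phase = "G1", start_h = 0,
                           end_h = 96, censored = TRUE)
  ), class = "event_set")
  cr <- data.frame(cell_id = 1, crossing_time_h = 20)
  g <- mitosis_to_threshold_gaps(cr, ev)
  expect_equal(g$gaps$gap_h, 11)
  chain <- commitment_chain("noisy")
  gg <- mitosis_to_threshold_gaps(chain$crossings, chain$events)
  expect_equal(sum(gg$histogram$fraction), 1, tolerance = 1e-9)
})

test_that("G1 statistics pair first and second durations and total them", {
  ev <- structure(list(
    cells = data.frame(cell_id = 1, n_divisions = 3,
                       span_start_h = 0, span_end_h = 96),
    mitoses = data.frame(cell_id = rep(1, 3), time_h = c(10, 25, 50)),
    intervals = data.frame(
      cell_id = 1,
      phase = c("G1", "SG2M", "G1", "SG2M", "G1", "SG2M", "G1"),
      start_h = c(0, 4, 10, 17, 25, 37, 50),
      end_h = c(4, 10, 17, 25, 37, 50, 96),
      censored = c(rep(FALSE, 6), TRUE)
    )
  ), class = "event_set")
  st <- g1_duration_stats(ev)
  expect_equal(st$pairs$g1_first_h, 4)
  expect_equal(st$pairs$g1_second_h, 7)
  expect_equal(st$total$total_g1_h, 4 + 7 + 12)
})

test_that("the second G1 is longer than the first under active stimulus", {
  chain <- commitment_chain("noisy")
  st <- g1_duration_stats(chain$events)
  expect_gt(nrow(st$pairs), 30)
  expect_gt(median(st$pairs$g1_second_h), median(st$pairs$g1_first_h))
})

test_that("p21 knockdown shifts total G1 time down", {
  base <- sim_config(n_cells = 200, seed = 77)
  ctrl <- compute_events(simulate_population(base)$traces)
  kd <- compute_events(
    simulate_population(apply_perturbation(base, "sip21"))$traces)
  t_ctrl <- g1_duration_stats(ctrl)$total$total_g1_h
  t_kd <- g1_duration_stats(kd)$total$total_g1_h
  expect_lt(median(t_kd), median(t_ctrl))
})

test_that("commitment accelerates with stimulus exposure", {
  chain <- commitment_chain("noisy")
  eb <- exposure_binned_commitment(chain$crossings, chain$events, n_bins = 3)
  # a single bin reproduces the global mean gap over the same cells
  g <- mitosis_to_threshold_gaps(chain$crossings, chain$events)$gaps
  g48 <- g[g$last_mitosis_h <= 48, ]
  one <- exposure_binned_commitment(chain$crossings, chain$events, n_bins = 1)
  expect_equal(one$mean_gap_h, mean(g48$gap_h))
  expect_equal(one$n, nrow(g48))
  # later exposure bins commit faster
  expect_true(all(diff(eb$mean_gap_h) < 0))
})

test_that("exposure-aligned medians mask the mitosis frame", {
  chain <- commitment_chain("noisy")
  prof <- exposure_aligned_profiles(chain$sim$traces, chain$crossings,
                                    chain$events, n_groups = 3)
  expect_false(any(abs(prof$aligned_time_h) < 0.1))
  expect_equal(sort(unique(prof$group)), 1:3)
  # later-exposure groups rise faster after their final mitosis
  rise <- vapply(1:3, function(gr) {
    sub <- prof[prof$group == gr & prof$aligned_time_h > 0 &
                  prof$aligned_time_h <= 6 & prof$n >= 10, ]
    unname(coef(lm(sub$median_pparg ~ sub$aligned_time_h))[2])
  }, numeric(1))
  expect_gt(rise[3], rise[1])
})
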