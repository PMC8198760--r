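# Shared simulated cohorts, built once per test run and cached.
.cohorts <- new.env(parent = emptyenv())

cohort <- function(name) {
  if (!exists(name, envir = .cohorts)) {
    sim <- switch(name,
      # noise-free default-condition cohort for exact recovery checks
      clean = simulate_population(
        sim_config(n_cells = 300, noise_cv = 0, seed = 101)),
      # default noisy cohort for analysis-level checks
      noisy = simulate_population(
        sim_config(n_cells = 500, seed = 202)),
      stop("unknown cohort ", name)
    )
    assign(name, sim, envir = .cohorts)
  }
  get(name, envir = .cohorts)
}

# commitment analysis (mixture, threshold, crossings, events) for a cohort,
# cached alongside it
commitment_chain <- function(name) {
  key <- paste0(name, "_chain")
  if (!exists(key, envir = .cohorts)) {
    sim <- cohort(name)
    mix <- fit_endpoint_mixture(sim$endpoint$pparg_end)
    lab <- classify_endpoint(sim$endpoint$pparg_end, mix)
    ref <- sim$traces[sim$traces$time_h == sim$config$refresh_time_h, ]
    ref <- ref[order(ref$cell_id), ]
    thr <- estimate_threshold(ref$pparg_au, lab, mixture = mix)
    crossings <- gate_crossings(
      detect_crossings(sim$traces, thr$threshold_au, refine_kink = TRUE),
      sim$endpoint$cell_id, lab)
    events <- compute_events(sim$traces)
    assign(key, list(sim = sim, mixture = mix, labels = lab,
                     ref_values = ref$pparg_au, threshold = thr,
                     crossings = crossings, events = events),
           envir = .cohorts)
  }
  get(key, envir = .cohorts)
}

# brute-force FPR-scan oracle: try every candidate cut explicitly
brute_force_threshold <- function(values, labels, max_fpr = 0.05) {
  neg <- values[labels == "undifferentiated"]
  cand <- c(sort(unique(values)), Inf)
  best <- NULL
  for (thr in cand) {
    fpr <- sum(neg >= thr) / length(neg)
    if (fpr <= max_fpr) { best <- thr; break }
  }
  best
}
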