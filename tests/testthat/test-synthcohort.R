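test_that("identical seed and config give byte-identical outputs", {
  p <- pip_plan()
  ev1 <- generate_events(p, 5)
  ev2 <- generate_events(p, 5)
  expect_identical(ev1, ev2)
  spec <- make_neuron_spec("u1", "fear", p)
  s1 <- simulate_unit(spec, p, 5, events = ev1, n_snippets = 4)
  s2 <- simulate_unit(spec, p, 5, events = ev2, n_snippets = 4)
  expect_identical(s1, s2)
  r <- default_rat_params("r1", "successful")
  expect_identical(simulate_freezing(r, p, 5), simulate_freezing(r, p, 5))
})

test_that("seed fan-out isolates units: adding one never perturbs another", {
  p <- mini_plan()
  ev <- generate_events(p, 2)
  a0 <- simulate_unit(make_neuron_spec("uA", "non_responsive", p), p, 2,
                      events = ev, n_snippets = 4)
  invisible(simulate_unit(make_neuron_spec("uB", "non_responsive", p), p, 2,
                          events = ev, n_snippets = 4))
  a1 <- simulate_unit(make_neuron_spec("uA", "non_responsive", p), p, 2,
                      events = ev, n_snippets = 4)
  expect_identical(a0, a1)
  expect_true(substream_seed(1, "uA") != substream_seed(1, "uB"))
  expect_identical(substream_seed(42, "x", 3), substream_seed(42, "x", 3))
})

test_that("degenerate rates give an empty spike table without error", {
  p <- mini_plan()
  spec <- make_neuron_spec("u0", "non_responsive", p, baseline_rate_hz = 0)
  sim <- simulate_unit(spec, p, 1, n_snippets = 4)
  expect_equal(nrow(sim$spikes), 0)
  expect_error(make_neuron_spec("u", "fear", p, baseline_rate_hz = -1),
               ">= 0")
})

test_that("simulated spike counts track the planted baseline rate", {
  p <- mini_plan(n_cs = 5)
  spec <- make_neuron_spec("u", "non_responsive", p, baseline_rate_hz = 8)
  sim <- simulate_unit(spec, p, 4, n_snippets = 4, tail_s = 10)
  ev <- generate_events(p, 4)
  t_end <- max(ev$onset_s) + 30 + 10
  expect_equal(nrow(sim$spikes) / t_end, 8, tolerance = 0.1)
})

test_that("evoked elevation lands in the planted response window", {
  p <- pip_plan()
  ev <- generate_events(p, 6)
  spec <- make_neuron_spec("u", "fear", p, response_latency_ms = 40,
                           response_duration_ms = 60)
  sim <- simulate_unit(spec, p, 6, events = ev, n_snippets = 4)
  pips <- ev$onset_s[ev$session == "Ext1" & ev$kind == "pip"]
  ts <- sort(sim$spikes$t_s[sim$spikes$session == "Ext1"])
  inwin <- sum(bin_event_counts(ts, pips, c(40, 100)))
  prewin <- sum(bin_event_counts(ts, pips, c(-60, 0)))
  expect_gt(inwin, 5 * prewin)  # 10x modulation, equal window lengths
})

test_that("freezing targets round-trip through the 2-s scoring rule", {
  p <- mini_plan(n_cs = 1)
  full <- default_rat_params("r", "successful", sd_pct = 0)
  full$targets <- list(Hab = c(100, 100))
  mv <- simulate_freezing(full, p, 1)
  expect_equal(score_freezing(mv$immobile, 0.1, 30), 100)
  full$targets <- list(Hab = c(0, 0))
  mv <- simulate_freezing(full, p, 1)
  expect_equal(score_freezing(mv$immobile, 0.1, 30), 0)
  # sub-criterion targets score 0: a 1.9-s bout never counts
  full$targets <- list(Hab = c(5, 5))   # 1.5 s of a 30-s CS
  mv <- simulate_freezing(full, p, 2)
  expect_equal(score_freezing(mv$immobile, 0.1, 30), 0)
  bad <- full; bad$targets <- list(Hab = c(-5, 20))
  expect_error(simulate_freezing(bad, p, 1), "0, 100")
})

test_that("scored freezing is unbiased at mid-range targets", {
  p <- mini_plan(n_cs = 1)
  rp <- default_rat_params("r", "successful")
  rp$targets <- list(Hab = c(50, 50))
  scores <- vapply(1:500, function(i) {
    rp$rat_id <- paste0("r", i)
    mv <- simulate_freezing(rp, p, seed = 123)
    score_freezing(mv$immobile, 0.1, 30)
  }, 1)
  expect_lt(abs(mean(scores) - 50), 2)
})

test_that("noiseless slice generator round-trips planted values exactly", {
  sd0 <- simulate_slice_data(list(ppr = 0.6, ampa_nmda = 3, ampa_pA = 150),
                             seed = 1, n_sweeps = 2, noise_sd_pA = 0)
  expect_equal(paired_pulse_ratio(sd0$paired_pulse)$ratio, 0.6)
  an <- ampa_nmda_ratio(sd0$neg70, sd0$pos50)
  expect_equal(an$ratio, 3)
  expect_equal(an$ampa_pA, 150)
})

test_that("planted I/O slope is recovered within 10% under noise", {
  sd <- simulate_slice_data(list(io_slope_pA_per_uA = 5, io_intercept_pA = 0),
                            seed = 3, n_sweeps = 5, noise_sd_pA = 5)
  fit <- io_slope(sd$io_series)
  expect_lt(abs(fit$slope_pA_per_uA - 5) / 5, 0.10)
})

test_that("planted minis are detected at the Poisson-consistent count", {
  sd <- simulate_slice_data(list(mini_rate_hz = 1, mini_amp_pA = 30),
                            seed = 8, noise_sd_pA = 2, duration_s = 120)
  det <- detect_minis(sd$continuous$t_ms, sd$continuous$i_pA,
                      threshold_pA = 10)
  band <- qpois(c(0.025, 0.975), 120)
  expect_gte(nrow(det$events), band[1])
  expect_lte(nrow(det$events), band[2])
  expect_equal(det$mean_amplitude_pA, 30, tolerance = 0.15)
})

test_that("planted ratios must be positive", {
  expect_error(simulate_slice_data(list(ppr = -1)), "positive")
  expect_error(simulate_slice_data(list(ampa_nmda = 0)), "positive")
})
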