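# Direct z recomputation from binned counts: the independent oracle for the
# average-then-z contract.
oracle_z <- function(mean_counts, bin_ms, n_base) {
  rate <- mean_counts / (bin_ms / 1000)
  base <- rate[seq_len(n_base)]
  (rate - mean(base)) / sd(base)
}

test_that("tone z-PETH reproduces the hand-computed baseline example", {
  # single trial with baseline bins {2,2,4,4} counts and 6 in bin 0-100 ms
  onset <- 100
  sp <- c(onset - 0.4 + c(0.01, 0.02),          # bin -400..-300: 2
          onset - 0.3 + c(0.01, 0.02),          # bin -300..-200: 2
          onset - 0.2 + c(0.01, 0.02, 0.03, 0.04),
          onset - 0.1 + c(0.01, 0.02, 0.03, 0.04),
          onset + c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06))
  zp <- zscore_tone_peth(sp, onset, t_post_ms = 500)
  expect_false(zp$degenerate)
  expect_equal(zp$z[5], 2.598, tolerance = 1e-3)   # (6-3)/sd({2,2,4,4})
  expect_equal(zp$z[1:4], oracle_z(c(2, 2, 4, 4, 6, 0, 0, 0, 0), 100, 4)[1:4])
})

test_that("baseline with zero variance sets the degenerate flag and masks z", {
  onset <- 50
  sp <- c(onset - 0.35, onset - 0.25, onset - 0.15, onset - 0.05, onset + 0.02)
  zp <- zscore_tone_peth(sp, onset, t_post_ms = 300)
  expect_true(zp$degenerate)
  expect_true(all(is.na(zp$z)))
  expect_true(is.na(window_response(zp, c(0, 300), "mean")))
})

test_that("z is invariant under a uniform time shift", {
  set.seed(51)
  sp <- sort(runif(400, 0, 200))
  on <- c(50, 120)
  z0 <- zscore_tone_peth(sp, on)
  z1 <- zscore_tone_peth(sp + 37.5, on + 37.5)
  expect_equal(z0$z, z1$z)
})

test_that("doubling every spike maps z per the direct formula", {
  set.seed(52)
  sp <- sort(runif(300, 0, 100))
  on <- c(30, 60, 90)
  z2 <- zscore_tone_peth(rep(sp, each = 2), on)
  counts <- colMeans(bin_event_counts(sort(sp), on, seq(-400, 2000, 100)))
  expect_equal(z2$z, oracle_z(2 * counts, 100, 4))
})

test_that("bins are half-open and conserve the in-window spike count", {
  on <- 10
  sp <- c(on - 0.4, on - 0.2, on, on + 0.0999, on + 0.1, on + 1.9999, on + 2)
  counts <- bin_event_counts(sort(sp), on, seq(-400, 2000, 100))
  expect_equal(sum(counts), 6)        # spike at +2 s is outside [-0.4, 2)
  expect_equal(counts[1, 5], 2)       # 0 ms edge belongs to first post bin
  expect_equal(counts[1, 1], 1)
})

test_that("pip z-PETH averages 135 pips and uses the pre-tone baseline", {
  p <- pip_plan()
  ev <- generate_events(p, 7)
  e <- recall_epochs(p)[2, ]          # post-Cond: first 5 CS of Ext1
  pips <- epoch_onsets(ev, e, "pip")
  tones <- epoch_onsets(ev, e, "tone")
  expect_equal(length(pips), 135)
  set.seed(53)
  sp <- sort(runif(5000, min(tones) - 10, max(tones) + 40))
  zp <- zscore_pip_peth(sp, tones, pips)
  expect_equal(zp$n_events, 135)
  expect_equal(zp$baseline_window_ms, c(-500, 0))
  expect_equal(zp$bin_ms, 20)
})

test_that("a silent unit yields a degenerate pip histogram", {
  p <- pip_plan()
  ev <- generate_events(p, 7)
  e <- recall_epochs(p)[1, ]
  zp <- zscore_pip_peth(numeric(0), epoch_onsets(ev, e, "tone"),
                        epoch_onsets(ev, e, "pip"))
  expect_true(zp$degenerate)
})

test_that("pip mode on a tone-only schedule errors", {
  expect_error(zscore_pip_peth(1:10, 5, numeric(0)), "pip schedule")
})

test_that("window statistics use only fully contained bins", {
  zp <- fearext:::new_zpeth("u", "s", c(0, 100, 200, 300), 100,
                            c(1, 2, 3, 4), 0, 1, c(-400, 0), 5, FALSE)
  expect_equal(window_response(zp, c(0, 400), "mean"), 2.5)
  expect_equal(window_response(zp, c(0, 400), "max"), 4)
  expect_equal(window_response(zp, c(0, 350), "max"), 3)   # bin 300-400 excluded
  expect_equal(window_response(zp, c(50, 400), "max"), 4)  # bin 0-100 excluded
  expect_error(window_response(zp, c(150, 190)), "empty window")
})

test_that("null units give near-zero mean post-onset z", {
  p <- mini_plan(n_cs = 5)
  means <- vapply(1:100, function(i) {
    set.seed(substream_seed(60, "nullz", i))
    ev <- generate_events(p, substream_seed(60, "sched", i))
    on <- ev$onset_s[ev$kind == "tone"]
    sp <- sort(runif(rpois(1, 5 * 700), 0, 700))
    zp <- zscore_tone_peth(sp, on)
    mean(zp$z[zp$bin_left_ms >= 0])
  }, 1)
  expect_lt(abs(mean(means)), 0.2)
})

test_that("planted pip responses cross the detection criteria reliably", {
  p <- pip_plan()
  res <- vapply(1:20, function(i) {
    seed <- substream_seed(61, "rec", i)
    ev <- generate_events(p, seed)
    spec <- make_neuron_spec("u", "fear", p, response_latency_ms = 10,
                             response_duration_ms = 50)
    sim <- simulate_unit(spec, p, seed, events = ev, n_snippets = 4)
    e <- recall_epochs(p)[2, ]
    ts <- sort(sim$spikes$t_s[sim$spikes$session == "Ext1"])
    zp <- zscore_pip_peth(ts, epoch_onsets(ev, e, "tone"),
                          epoch_onsets(ev, e, "pip"))
    c(peak = window_response(zp, c(0, 100), "max"),
      mean = window_response(zp, c(0, 100), "mean"))
  }, c(peak = 1, mean = 1))
  # per-bin latency criterion (z >= 3) and typing strength criterion (1.5)
  expect_gte(mean(res["peak", ] >= 3), 0.95)
  expect_gte(mean(res["mean", ] >= 1.5), 0.95)
})
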