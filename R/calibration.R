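#' Null calibration of the CS-responsiveness test
#'
#' Simulates unmodulated (evoked = baseline) units on a habituation-style
#' pip session and measures how often [cs_responsive_test()] rejects at
#' `alpha` — under a well-calibrated test the empirical rate matches the
#' nominal level.
#'
#' @param n_units Number of simulated null units.
#' @param seed Integer seed.
#' @param baseline_rate_hz Baseline rate (default 5 Hz).
#' @param n_cs CS trials in the session (default 5; 27 pips each).
#' @param alpha Nominal level (default 0.05).
#' @param window_ms Response/baseline window (default 100 ms).
#' @return List `rate` (empirical rejection rate), `n_units`, `alpha`.
#' @export
null_calibration <- function(n_units, seed, baseline_rate_hz = 5, n_cs = 5,
                             alpha = 0.05, window_ms = 100) {
  plan <- make_session_plan("recording",
                            list(alignment = "pip", n_cs = list(Hab = n_cs)))
  plan$sessions <- plan$sessions[plan$sessions$label == "Hab", ]
  events <- generate_events(plan, seed)
  onsets <- sort(events$onset_s[events$kind == "pip"])
  t_end <- max(onsets) + 5
  w <- window_ms / 1000
  hits <- logical(n_units)
  for (i in seq_len(n_units)) {
    set.seed(substream_seed(seed, "null", i))
    n <- stats::rpois(1, baseline_rate_hz * t_end)
    ts <- sort(stats::runif(n, 0, t_end))
    resp <- bin_event_counts(ts, onsets, c(0, window_ms))[, 1]
    base <- bin_event_counts(ts, onsets, c(-window_ms, 0))[, 1]
    hits[i] <- cs_responsive_test(resp, base, alpha)$responsive
  }
  list(rate = mean(hits), n_units = n_units, alpha = alpha)
}
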