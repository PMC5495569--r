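# Counts of `spikes` (sorted seconds) in uniform bins relative to each onset.
# Bins are half-open [left, right) in ms relative to the event; returns the
# per-event count matrix (events x bins).
bin_event_counts <- function(spikes, onsets_s, edges_ms) {
  nb <- length(edges_ms) - 1
  out <- matrix(0, nrow = length(onsets_s), ncol = nb)
  lo <- edges_ms[1] / 1000
  hi <- edges_ms[nb + 1] / 1000
  bw_ms <- edges_ms[2] - edges_ms[1]
  for (e in seq_along(onsets_s)) {
    # [onset+lo, onset+hi): spikes exactly on the left edge belong to bin 1
    a <- findInterval(onsets_s[e] + lo - 1e-9, spikes) + 1
    b <- findInterval(onsets_s[e] + hi - 1e-9, spikes)
    if (b >= a) {
      rel_ms <- (spikes[a:b] - onsets_s[e]) * 1000
      # +1e-9 bin fractions absorb round-off so on-edge spikes fall right
      bins <- floor((rel_ms - edges_ms[1]) / bw_ms + 1e-9) + 1
      bins <- bins[bins >= 1 & bins <= nb]
      out[e, ] <- tabulate(bins, nb)
    }
  }
  out
}

new_zpeth <- function(unit_id, session, bin_left_ms, bin_ms, z,
                      baseline_mean_hz, baseline_sd_hz, baseline_window_ms,
                      n_events, degenerate) {
  structure(list(unit_id = unit_id, session = session,
                 bin_left_ms = bin_left_ms, bin_ms = bin_ms, z = z,
                 baseline_mean_hz = baseline_mean_hz,
                 baseline_sd_hz = baseline_sd_hz,
                 baseline_window_ms = baseline_window_ms,
                 n_events = n_events, degenerate = degenerate),
            class = "zpeth")
}

#' @export
print.zpeth <- function(x, ...) {
  cat(sprintf("zpeth: %s / %s, %d events, %g-ms bins [%g, %g) ms%s\n",
              x$unit_id %||% "?", x$session %||% "?", x$n_events, x$bin_ms,
              x$bin_left_ms[1], x$bin_left_ms[length(x$bin_left_ms)] + x$bin_ms,
              if (x$degenerate) " [degenerate: baseline sd = 0]" else ""))
  invisible(x)
}

#' Tone-aligned z-scored peri-event histogram (100-ms dialect)
#'
#' Spike counts are binned relative to each CS (tone) onset, averaged across
#' trials, converted to rates, and z-scored against the mean and sample SD of
#' the `n_baseline_bins` pre-tone bins of the trial-averaged histogram
#' (average-then-z).  If the baseline SD is zero the histogram is flagged
#' degenerate and all z values are masked (`NA`), never epsilon-inflated.
#'
#' @param spikes Numeric vector of spike times (s), sorted.
#' @param onsets_s CS onset times (s) of the trials to average.
#' @param bin_ms Bin width (default 100 ms).
#' @param n_baseline_bins Pre-onset baseline bins (default 4).
#' @param t_post_ms Histogram extent after onset (default 2000 ms).
#' @param unit_id,session Optional labels carried into the result.
#' @return A `zpeth` object; `bin_left_ms` gives half-open bin left edges,
#'   the 0-ms edge belongs to the first post-onset bin.
#' @export
zscore_tone_peth <- function(spikes, onsets_s, bin_ms = 100,
                             n_baseline_bins = 4, t_post_ms = 2000,
                             unit_id = NULL, session = NULL) {
  if (!length(onsets_s)) stop("no events")
  if (bin_ms <= 0) stop("bins must be positive")
  spikes <- sort(spikes)
  edges <- seq(-n_baseline_bins * bin_ms, t_post_ms, by = bin_ms)
  counts <- bin_event_counts(spikes, onsets_s, edges)
  mean_counts <- colMeans(counts)
  rate_hz <- mean_counts / (bin_ms / 1000)
  base <- rate_hz[seq_len(n_baseline_bins)]
  mu <- mean(base)
  sdv <- stats::sd(base)
  degenerate <- sdv == 0
  z <- if (degenerate) rep(NA_real_, length(rate_hz)) else (rate_hz - mu) / sdv
  new_zpeth(unit_id, session, edges[-length(edges)], bin_ms, z, mu, sdv,
            c(-n_baseline_bins * bin_ms, 0), length(onsets_s), degenerate)
}

#' Pip-aligned z-scored peri-event histogram (20-ms dialect)
#'
#' Counts aligned to every pip of the trial set (135 pips for 5 CSs of 27
#' pips each, under the default plan) are averaged across pips and z-scored
#' against baseline statistics taken from the 500 ms preceding each *tone*
#' onset, binned at the same width (25 baseline bins of 20 ms, averaged over
#' the CS trials).
#'
#' @param spikes Numeric vector of spike times (s), sorted.
#' @param tone_onsets_s CS (tone) onset times of the trial set.
#' @param pip_onsets_s Pip onset times of the same trials.
#' @param bin_ms Bin width (default 20 ms).
#' @param baseline_ms Pre-tone baseline extent (default 500 ms).
#' @param t_pre_ms,t_post_ms Pip-aligned histogram extent (defaults 100/200).
#' @param unit_id,session Optional labels.
#' @return A `zpeth` object (pip-aligned bins; baseline provenance recorded
#'   as the pre-tone window).
#' @export
zscore_pip_peth <- function(spikes, tone_onsets_s, pip_onsets_s, bin_ms = 20,
                            baseline_ms = 500, t_pre_ms = 100, t_post_ms = 200,
                            unit_id = NULL, session = NULL) {
  if (!length(pip_onsets_s)) stop("pip schedule absent (tone-only plan?)")
  if (!length(tone_onsets_s)) stop("no events")
  spikes <- sort(spikes)
  base_edges <- seq(-baseline_ms, 0, by = bin_ms)
  base_counts <- bin_event_counts(spikes, tone_onsets_s, base_edges)
  base_rate <- colMeans(base_counts) / (bin_ms / 1000)
  mu <- mean(base_rate)
  sdv <- stats::sd(base_rate)
  edges <- seq(-t_pre_ms, t_post_ms, by = bin_ms)
  counts <- bin_event_counts(spikes, pip_onsets_s, edges)
  rate_hz <- colMeans(counts) / (bin_ms / 1000)
  degenerate <- sdv == 0
  z <- if (degenerate) rep(NA_real_, length(rate_hz)) else (rate_hz - mu) / sdv
  new_zpeth(unit_id, session, edges[-length(edges)], bin_ms, z, mu, sdv,
            c(-baseline_ms, 0), length(pip_onsets_s), degenerate)
}

#' Scalar response statistic over a post-onset window
#'
#' Mean or max of z over the bins fully contained in
#' `[window_ms[1], window_ms[2])`.
#'
#' @param zpeth A `zpeth`.
#' @param window_ms Length-2 window in ms relative to onset (default 0-400).
#' @param stat `"mean"` or `"max"`.
#' @return Scalar z (`NA` if the histogram is degenerate).
#' @export
window_response <- function(zpeth, window_ms = c(0, 400),
                            stat = c("mean", "max")) {
  stat <- match.arg(stat)
  keep <- zpeth$bin_left_ms >= window_ms[1] &
    (zpeth$bin_left_ms + zpeth$bin_ms) <= window_ms[2]
  if (!any(keep)) stop("empty window: no bin fully inside [",
                       window_ms[1], ", ", window_ms[2], ")")
  if (zpeth$degenerate) return(NA_real_)
  if (stat == "mean") mean(zpeth$z[keep]) else max(zpeth$z[keep])
}
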