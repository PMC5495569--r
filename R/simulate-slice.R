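# Bi-exponential synaptic-current kernel normalised to unit peak.
# Support is truncated at `cut_ms` after onset when given, so that
# successive pulses do not ride on each other's decay tails and planted
# ratios round-trip exactly in the noiseless case.
epsc_kernel <- function(t_ms, onset_ms, tau_rise = 1, tau_decay = 8,
                        cut_ms = NULL) {
  s <- t_ms - onset_ms
  y <- ifelse(s >= 0, exp(-s / tau_decay) - exp(-s / tau_rise), 0)
  if (!is.null(cut_ms)) y[s >= cut_ms] <- 0
  pk_t <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  pk <- exp(-pk_t / tau_decay) - exp(-pk_t / tau_rise)
  y / pk
}

new_sweep <- function(sweep_id, kind, holding_mV, stim_ms, t_ms, i_pA,
                      intensity_uA = NA_real_, rs_Mohm = NA_real_) {
  list(sweep_id = sweep_id, kind = kind, holding_mV = holding_mV,
       stim_ms = stim_ms, t_ms = t_ms, i_pA = i_pA,
       intensity_uA = intensity_uA, series_resistance_Mohm = rs_Mohm)
}

#' Simulate patch-clamp sweep sets with planted synaptic metrics
#'
#' Generates the four sweep families consumed by the slice metrics, each
#' encoding a planted ground-truth value recoverable by the corresponding
#' estimator:
#'
#' * `paired_pulse`: two stimuli 50 ms apart; second/first peak equals
#'   `ppr` before noise.
#' * `dual_holding`: EPSC peak `ampa_pA` at -70 mV; slow outward current at
#'   +50 mV scaled so the sample 50 ms post-stimulus equals
#'   `ampa_pA / ampa_nmda`.
#' * `io_series`: one averaged-response sweep per intensity x repetition,
#'   peak amplitude `io_slope_pA_per_uA * intensity + io_intercept_pA`
#'   plus noise.
#' * `continuous`: Poisson-timed inward miniature events of amplitude
#'   `mini_amp_pA` (SD `mini_amp_sd_pA`) at `mini_rate_hz`.
#'
#' @param planted List of planted values; defaults
#'   `list(ppr = 0.6, ampa_nmda = 3, ampa_pA = 150, io_slope_pA_per_uA =
#'   5.28, io_intercept_pA = 0, mini_rate_hz = 1, mini_amp_pA = 30,
#'   mini_amp_sd_pA = 0)` (unspecified entries are filled in).
#' @param seed Integer seed.
#' @param n_sweeps Sweeps per condition (default 20).
#' @param noise_sd_pA Gaussian sample-noise SD (default 2).
#' @param intensities_uA Stimulus intensities for the I/O series.
#' @param duration_s Continuous-trace duration (default 120 s).
#' @param dt_ms Sample step for evoked sweeps (0.1 ms) — the continuous
#'   trace uses 1-ms steps.
#' @return List `paired_pulse`, `neg70`, `pos50`, `io_series` (sweep lists)
#'   and `continuous` (`t_ms`, `i_pA`), plus `planted` as used.
#' @export
simulate_slice_data <- function(planted = list(), seed = 1, n_sweeps = 20,
                                noise_sd_pA = 2,
                                intensities_uA = seq(10, 100, by = 10),
                                duration_s = 120, dt_ms = 0.1) {
  planted <- utils::modifyList(
    list(ppr = 0.6, ampa_nmda = 3, ampa_pA = 150, io_slope_pA_per_uA = 5.28,
         io_intercept_pA = 0, mini_rate_hz = 1, mini_amp_pA = 30,
         mini_amp_sd_pA = 0), planted)
  with(planted, {
    if (ppr <= 0 || ampa_nmda <= 0) stop("planted ratios must be positive")
    if (mini_rate_hz < 0 || mini_amp_pA <= 0) stop("invalid mini parameters")
  })
  if (noise_sd_pA < 0) stop("noise SD must be >= 0")

  out <- list(planted = planted)
  # kernels re-normalised to their on-grid maximum so planted peak
  # amplitudes round-trip exactly in the noiseless case
  grid_kernel <- function(...) {
    y <- epsc_kernel(...)
    y / max(y)
  }
  # paired pulse: stimuli at 100 and 150 ms
  t_pp <- seq(0, 300, by = dt_ms)
  stim <- c(100, 150)
  base_pp <- -planted$ampa_pA * grid_kernel(t_pp, stim[1], cut_ms = diff(stim)) -
    planted$ppr * planted$ampa_pA * grid_kernel(t_pp, stim[2])
  set.seed(substream_seed(seed, "slice", "pp"))
  out$paired_pulse <- lapply(seq_len(n_sweeps), function(i) {
    new_sweep(paste0("pp", i), "paired_pulse", -70, stim, t_pp,
              base_pp + stats::rnorm(length(t_pp), 0, noise_sd_pA),
              rs_Mohm = 10)
  })
  # dual holding potential: stimulus at 100 ms
  t_dh <- seq(0, 400, by = dt_ms)
  ampa_tr <- -planted$ampa_pA * grid_kernel(t_dh, 100)
  nmda_shape <- epsc_kernel(t_dh, 100, tau_rise = 3, tau_decay = 80)
  at50 <- nmda_shape[which.min(abs(t_dh - 150))]
  nmda_tr <- (planted$ampa_pA / planted$ampa_nmda) / at50 * nmda_shape
  set.seed(substream_seed(seed, "slice", "dh"))
  out$neg70 <- lapply(seq_len(n_sweeps), function(i) {
    new_sweep(paste0("ah", i), "dual_holding", -70, 100, t_dh,
              ampa_tr + stats::rnorm(length(t_dh), 0, noise_sd_pA),
              rs_Mohm = 10)
  })
  out$pos50 <- lapply(seq_len(n_sweeps), function(i) {
    new_sweep(paste0("nh", i), "dual_holding", 50, 100, t_dh,
              nmda_tr + stats::rnorm(length(t_dh), 0, noise_sd_pA),
              rs_Mohm = 10)
  })
  # input-output series: stimulus at 50 ms
  t_io <- seq(0, 150, by = dt_ms)
  set.seed(substream_seed(seed, "slice", "io"))
  out$io_series <- list()
  sid <- 0
  for (u in intensities_uA) {
    for (r in seq_len(n_sweeps)) {
      sid <- sid + 1
      amp <- planted$io_slope_pA_per_uA * u + planted$io_intercept_pA +
        stats::rnorm(1, 0, noise_sd_pA)
      out$io_series[[sid]] <- new_sweep(
        paste0("io", sid), "io_series", -70, 50, t_io,
        -amp * grid_kernel(t_io, 50), intensity_uA = u, rs_Mohm = 10)
    }
  }
  # continuous trace with miniature events (1-ms grid)
  set.seed(substream_seed(seed, "slice", "mini"))
  t_ct <- seq(0, duration_s * 1000 - 1, by = 1)
  n_ev <- stats::rpois(1, planted$mini_rate_hz * duration_s)
  ev_t <- sort(stats::runif(n_ev, 20, duration_s * 1000 - 50))
  ev_a <- pmax(1, stats::rnorm(n_ev, planted$mini_amp_pA,
                               planted$mini_amp_sd_pA))
  i_ct <- stats::rnorm(length(t_ct), 0, noise_sd_pA)
  for (k in seq_len(n_ev)) {
    j0 <- max(1L, floor(ev_t[k]) - 1L)
    j1 <- min(length(t_ct), ceiling(ev_t[k]) + 61L)
    i_ct[j0:j1] <- i_ct[j0:j1] -
      ev_a[k] * epsc_kernel(t_ct[j0:j1], ev_t[k], tau_rise = 1,
                            tau_decay = 8, cut_ms = 60)
  }
  out$continuous <- list(t_ms = t_ct, i_pA = i_ct,
                         true_events = data.frame(t_ms = ev_t,
                                                  amplitude_pA = ev_a))
  out
}

#' Flatten sweep lists into the delimited sweeps table
#'
#' @param sweeps List of sweeps (as produced by [simulate_slice_data()]).
#' @return Data frame `sweep_id, kind, holding_mV, t_ms, i_pA`.
#' @export
sweeps_to_table <- function(sweeps) {
  do.call(rbind, lapply(sweeps, function(s) {
    data.frame(sweep_id = s$sweep_id, kind = s$kind, holding_mV = s$holding_mV,
               t_ms = s$t_ms, i_pA = s$i_pA, stringsAsFactors = FALSE)
  }))
}
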