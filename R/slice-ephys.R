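# Average a list of sweeps sharing a time grid; returns list(t_ms, i_pA).
average_sweeps <- function(sweeps) {
  t0 <- sweeps[[1]]$t_ms
  for (s in sweeps) {
    if (length(s$t_ms) != length(t0) || any(s$t_ms != t0)) {
      stop("sweeps must share one uniform time grid")
    }
  }
  i <- rowMeans(vapply(sweeps, function(s) s$i_pA, numeric(length(t0))))
  list(t_ms = t0, i_pA = i)
}

baseline_subtract <- function(avg, stim_ms) {
  pre <- avg$t_ms < min(stim_ms)
  if (!any(pre)) stop("no pre-stimulus samples for baseline")
  avg$i_pA <- avg$i_pA - mean(avg$i_pA[pre])
  avg
}

#' Paired-pulse ratio of evoked EPSCs
#'
#' Sweeps are averaged, baseline-subtracted with the pre-stimulus mean, and
#' the ratio is the absolute peak after the second pulse over the absolute
#' peak after the first, each searched from its stimulus up to the next
#' stimulus (or sweep end).
#'
#' @param sweeps List of `paired_pulse` sweeps (each a list with `t_ms`,
#'   `i_pA`, `stim_ms` of length 2).
#' @param noise_floor_pA First-peak amplitudes at or below this are
#'   unquantifiable (default 5 pA).
#' @return List `ratio`, `peak1_pA`, `peak2_pA`, `reason` (`NULL`, or
#'   `"first_peak_below_noise_floor"` with `ratio = NA`).
#' @export
paired_pulse_ratio <- function(sweeps, noise_floor_pA = 5) {
  if (!length(sweeps)) stop("no sweeps")
  stim <- sweeps[[1]]$stim_ms
  if (length(stim) != 2 || diff(stim) <= 0) stop("need two increasing stimuli")
  avg <- baseline_subtract(average_sweeps(sweeps), stim)
  w1 <- avg$t_ms >= stim[1] & avg$t_ms < stim[2]
  w2 <- avg$t_ms >= stim[2]
  p1 <- max(abs(avg$i_pA[w1]))
  p2 <- max(abs(avg$i_pA[w2]))
  if (p1 <= noise_floor_pA) {
    return(list(ratio = NA_real_, peak1_pA = p1, peak2_pA = p2,
                reason = "first_peak_below_noise_floor"))
  }
  list(ratio = p2 / p1, peak1_pA = p1, peak2_pA = p2, reason = NULL)
}

#' AMPA/NMDA current ratio from dual-holding-potential sweeps
#'
#' The numerator is the absolute peak of the averaged, baseline-subtracted
#' trace at -70 mV (AMPA-dominated); the denominator is the averaged current
#' exactly 50 ms after the stimulus at +50 mV (NMDA-dominated, AMPA decayed).
#'
#' @param sweeps_neg70 Sweeps at -70 mV (each with `t_ms`, `i_pA`, `stim_ms`).
#' @param sweeps_pos50 Sweeps at +50 mV.
#' @param delay_ms Post-stimulus sampling delay for the denominator (50 ms).
#' @param noise_floor_pA Denominators at or below this are unquantifiable.
#' @return List `ratio`, `ampa_pA`, `nmda_pA`, `reason`.
#' @export
ampa_nmda_ratio <- function(sweeps_neg70, sweeps_pos50, delay_ms = 50,
                            noise_floor_pA = 5) {
  if (!length(sweeps_neg70) || !length(sweeps_pos50)) {
    stop("both holding potentials are required")
  }
  stim_a <- sweeps_neg70[[1]]$stim_ms[1]
  stim_n <- sweeps_pos50[[1]]$stim_ms[1]
  a <- baseline_subtract(average_sweeps(sweeps_neg70), stim_a)
  n <- baseline_subtract(average_sweeps(sweeps_pos50), stim_n)
  ampa <- max(abs(a$i_pA[a$t_ms >= stim_a]))
  k <- which.min(abs(n$t_ms - (stim_n + delay_ms)))
  nmda <- abs(n$i_pA[k])
  if (nmda <= noise_floor_pA) {
    return(list(ratio = NA_real_, ampa_pA = ampa, nmda_pA = nmda,
                reason = "nmda_component_below_noise_floor"))
  }
  list(ratio = ampa / nmda, ampa_pA = ampa, nmda_pA = nmda, reason = NULL)
}

#' Detect miniature synaptic events in a continuous trace
#'
#' Events are threshold crossings of the baseline-corrected deflection
#' (baseline = trace median; polarity selectable, inward/negative by
#' default), separated by at least `min_interval_ms`; each event's amplitude
#' is the peak deflection within `min_interval_ms` of its crossing.
#'
#' @param t_ms Time grid (uniform, ms).
#' @param i_pA Current samples.
#' @param threshold_pA Detection threshold (> 0).
#' @param min_interval_ms Refractory separation between events (default 10).
#' @param polarity `"negative"` (inward, default) or `"positive"`.
#' @return List `events` (data frame `t_ms, amplitude_pA`),
#'   `mean_amplitude_pA`, `frequency_hz`, `duration_s`, plus sorted
#'   `amplitudes_pA` and `intervals_s` for cumulative-distribution tests.
#' @export
detect_minis <- function(t_ms, i_pA, threshold_pA, min_interval_ms = 10,
                         polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (threshold_pA <= 0) stop("threshold must be > 0")
  duration_s <- (t_ms[length(t_ms)] - t_ms[1]) / 1000
  if (duration_s * 1000 <= min_interval_ms) {
    stop("trace shorter than min_interval")
  }
  dev <- i_pA - stats::median(i_pA)
  if (polarity == "negative") dev <- -dev
  dt <- t_ms[2] - t_ms[1]
  above <- dev >= threshold_pA
  rising <- which(above & !c(FALSE, above[-length(above)]))
  times <- numeric(0)
  amps <- numeric(0)
  last <- -Inf
  last_pk <- 1L
  k_win <- max(1L, round(min_interval_ms / dt))
  for (i in rising) {
    if (t_ms[i] - last < min_interval_ms) next
    # hysteresis: re-arm only after the trace has fallen below half
    # threshold since the previous event (suppresses decay-tail retriggers)
    if (length(times) && min(dev[last_pk:i]) >= threshold_pA / 2) next
    j <- min(length(dev), i + k_win)
    pk <- which.max(dev[i:j]) + i - 1
    times <- c(times, t_ms[pk])
    amps <- c(amps, dev[pk])
    last <- t_ms[i]
    last_pk <- pk
  }
  list(events = data.frame(t_ms = times, amplitude_pA = amps),
       mean_amplitude_pA = if (length(amps)) mean(amps) else NA_real_,
       frequency_hz = length(amps) / duration_s,
       duration_s = duration_s,
       amplitudes_pA = sort(amps),
       intervals_s = if (length(times) > 1) sort(diff(times)) / 1000
                     else numeric(0))
}

#' Input-output curve and slope of evoked EPSC amplitude
#'
#' Mean absolute EPSC amplitude per stimulus intensity, fitted by ordinary
#' least squares with a free intercept; the slope (pA/uA) indexes synaptic
#' efficacy.
#'
#' @param x Either a data frame `intensity_uA, amplitude_pA` (one row per
#'   sweep) or a list of `io_series` sweeps (each with `t_ms`, `i_pA`,
#'   `stim_ms`, `intensity_uA`), from which peak amplitudes are measured
#'   after baseline subtraction.
#' @return List of class `io_curve`: `points` (mean amplitude per
#'   intensity), `slope_pA_per_uA`, `intercept_pA`.
#' @export
io_slope <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    df <- do.call(rbind, lapply(x, function(s) {
      a <- baseline_subtract(average_sweeps(list(s)), s$stim_ms[1])
      data.frame(intensity_uA = s$intensity_uA,
                 amplitude_pA = max(abs(a$i_pA[a$t_ms >= s$stim_ms[1]])))
    }))
  }
  if (length(unique(df$intensity_uA)) < 2) {
    stop("need >= 2 distinct intensities for a slope")
  }
  pts <- stats::aggregate(amplitude_pA ~ intensity_uA, df, mean)
  fit <- stats::lm(amplitude_pA ~ intensity_uA, pts)
  structure(list(points = pts,
                 slope_pA_per_uA = unname(stats::coef(fit)[2]),
                 intercept_pA = unname(stats::coef(fit)[1])),
            class = "io_curve")
}

#' Series-resistance quality control for a cell
#'
#' A cell's data are discarded when the pipette series resistance changes by
#' more than `max_change` (default 20%, strict) from its initial value at
#' any point in the recording.
#'
#' @param rs_Mohm Series-resistance readings in recording order.
#' @param max_change Maximum tolerated fractional change (default 0.20).
#' @return List `keep` (logical), `max_frac_change`.
#' @examples
#' sweep_qc(c(10, 13))    # 30% change: discard
#' sweep_qc(c(10, 11.9))  # 19%: keep
#' @export
sweep_qc <- function(rs_Mohm, max_change = 0.20) {
  if (length(rs_Mohm) < 2) stop("need >= 2 series-resistance readings")
  if (any(rs_Mohm <= 0)) stop("series resistance must be positive")
  frac <- abs(rs_Mohm - rs_Mohm[1]) / rs_Mohm[1]
  list(keep = !any(frac > max_change), max_frac_change = max(frac))
}
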