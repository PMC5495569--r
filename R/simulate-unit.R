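#' Specify a synthetic neuron's phenotype and rates
#'
#' A neuron is characterised by a baseline firing rate and a per-session
#' evoked rate applied inside a response window after each CS (tone mode) or
#' each pip (pip mode).  The built-in phenotypes mirror the recall-epoch
#' logic of the classifier: a *fear* neuron is CS-responsive when conditioned
#' fear is recalled (elevated throughout Ext1, whose leading CSs form the
#' post-Cond epoch), an *extinction* neuron when extinction is recalled
#' (elevated throughout Ext2 / post-Ext1), and a *session-selective* neuron
#' in exactly one chosen session.
#'
#' @param unit_id Unit identifier.
#' @param phenotype One of `"non_responsive"`, `"fear"`, `"extinction"`,
#'   `"session_selective"`.
#' @param plan A `session_plan` (supplies the session labels).
#' @param baseline_rate_hz Baseline firing rate (default 5 Hz, typical of
#'   amygdala/mPFC principal cells).
#' @param modulation Evoked/baseline rate multiple in active sessions
#'   (default 10).
#' @param target_session Session label for `session_selective`.
#' @param response_latency_ms Response onset after the aligned event.
#'   Defaults: 43.33 ms for pip-aligned plans, 211.1 ms for tone-aligned
#'   plans (the reported mean latencies of the two recording dialects).
#' @param response_duration_ms Response duration. Defaults: 60 ms (pip),
#'   400 ms (tone).
#' @param evoked_rate_hz Optional named vector (one entry per session label)
#'   overriding the phenotype-derived evoked map.
#' @return A `neuron_spec` list.
#' @export
make_neuron_spec <- function(unit_id, phenotype = c("non_responsive", "fear",
                                                    "extinction", "session_selective"),
                             plan, baseline_rate_hz = 5, modulation = 10,
                             target_session = NULL,
                             response_latency_ms = NULL,
                             response_duration_ms = NULL,
                             evoked_rate_hz = NULL) {
  phenotype <- match.arg(phenotype)
  labs <- plan$sessions$label
  if (is.null(response_latency_ms)) {
    response_latency_ms <- if (identical(plan$alignment, "pip")) 43.33 else 211.1
  }
  if (is.null(response_duration_ms)) {
    response_duration_ms <- if (identical(plan$alignment, "pip")) 60 else 400
  }
  if (baseline_rate_hz < 0) stop("baseline_rate_hz must be >= 0")
  if (is.null(evoked_rate_hz)) {
    active <- switch(phenotype,
      non_responsive = character(0),
      fear = "Ext1",
      extinction = "Ext2",
      session_selective = {
        if (is.null(target_session) || !target_session %in% labs) {
          stop("session_selective requires a target_session present in the plan")
        }
        target_session
      })
    evoked_rate_hz <- stats::setNames(rep(baseline_rate_hz, length(labs)), labs)
    evoked_rate_hz[active] <- baseline_rate_hz * modulation
  } else {
    if (!setequal(names(evoked_rate_hz), labs)) {
      stop("evoked_rate_hz must have one entry per session in the plan")
    }
    evoked_rate_hz <- evoked_rate_hz[labs]
  }
  if (any(evoked_rate_hz < 0) || any(!is.finite(evoked_rate_hz))) {
    stop("evoked rates must be finite and >= 0")
  }
  structure(list(unit_id = unit_id, phenotype = phenotype,
                 baseline_rate_hz = baseline_rate_hz,
                 evoked_rate_hz = evoked_rate_hz,
                 response_latency_ms = response_latency_ms,
                 response_duration_ms = response_duration_ms),
            class = "neuron_spec")
}

# Inhomogeneous-Poisson sampler by thinning of a piecewise-constant rate.
# `elev` is a data.frame(start_s, end_s) of disjoint elevated intervals.
thin_poisson <- function(t_end_s, base_hz, evoked_hz, elev) {
  rate_max <- max(base_hz, evoked_hz)
  if (rate_max <= 0 || t_end_s <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * t_end_s)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, 0, t_end_s))
  if (nrow(elev) && evoked_hz != base_hz) {
    idx <- findInterval(cand, elev$start_s)
    inside <- idx >= 1 & cand < elev$end_s[pmax(idx, 1)]
    rate <- ifelse(inside, evoked_hz, base_hz)
  } else {
    rate <- rep(base_hz, n)
  }
  cand[stats::runif(n) <= rate / rate_max]
}

#' Simulate one unit's spike train and per-session waveforms
#'
#' Spikes are drawn from an inhomogeneous Poisson process by thinning of a
#' piecewise-constant rate: the baseline rate everywhere, elevated to the
#' session's evoked rate in `[latency, latency + duration]` after each CS
#' onset (tone alignment) or each pip onset (pip alignment).  Waveform
#' snippets per session are a fixed biphasic template plus seeded Gaussian
#' noise, with configurable inter-session drift along a fixed random
#' direction so that cross-session template correlation can be pushed above
#' or below the stability gate deliberately.
#'
#' @param spec A `neuron_spec`.
#' @param plan A `session_plan`.
#' @param seed Integer seed (fanned out per session via [substream_seed()]).
#' @param events Event table from [generate_events()]; generated from `seed`
#'   when omitted (per-rat cohorts should pass the shared schedule).
#' @param n_snippets Waveform snippets per session (default 80).
#' @param wf_noise_sd Snippet noise SD in microvolts (default 4).
#' @param wf_drift Per-session template drift magnitude (default 0.01; keeps
#'   consecutive-session correlation > 0.99 at the default shape).
#' @param tail_s Recording time simulated after the last event of a session.
#' @return List with `spikes` (data frame `unit_id, session, t_s`) and
#'   `waveforms` (named list of `n_snippets x 32` matrices, one per session).
#' @export
simulate_unit <- function(spec, plan, seed, events = NULL, n_snippets = 80,
                          wf_noise_sd = 4, wf_drift = 0.01, tail_s = 60) {
  if (!nrow(plan$sessions)) stop("empty plan")
  if (is.null(events)) events <- generate_events(plan, seed)
  align_kind <- if (identical(plan$alignment, "pip")) "pip" else "tone"
  lat_s <- spec$response_latency_ms / 1000
  dur_s <- spec$response_duration_ms / 1000

  spikes <- list()
  waveforms <- list()
  base_template <- spike_template()
  drift_dir <- NULL
  for (i in seq_len(nrow(plan$sessions))) {
    lab <- plan$sessions$label[i]
    ev <- events[events$session == lab, ]
    set.seed(substream_seed(seed, "unit", spec$unit_id, lab))
    t_end <- max(ev$onset_s) + plan$sessions$cs_duration_s[i] + tail_s
    on <- ev$onset_s[ev$kind == align_kind]
    elev <- data.frame(start_s = on + lat_s, end_s = on + lat_s + dur_s)
    ts <- thin_poisson(t_end, spec$baseline_rate_hz, spec$evoked_rate_hz[[lab]],
                       elev)
    spikes[[lab]] <- data.frame(unit_id = rep(spec$unit_id, length(ts)),
                                session = rep(lab, length(ts)),
                                t_s = ts, stringsAsFactors = FALSE)
    # session template drifts along a unit-specific fixed direction
    set.seed(substream_seed(seed, "wf", spec$unit_id))
    if (is.null(drift_dir)) {
      drift_dir <- stats::rnorm(length(base_template))
      drift_dir <- drift_dir / sqrt(sum(drift_dir^2))
    }
    set.seed(substream_seed(seed, "wf", spec$unit_id, lab))
    template <- base_template + wf_drift * (i - 1) * max(abs(base_template)) * drift_dir
    snip <- matrix(rep(template, each = n_snippets), nrow = n_snippets) +
      matrix(stats::rnorm(n_snippets * length(template), 0, wf_noise_sd),
             nrow = n_snippets)
    waveforms[[lab]] <- snip
  }
  list(spikes = do.call(rbind, c(spikes, list(make.row.names = FALSE))),
       waveforms = waveforms)
}

# Canonical biphasic extracellular spike shape, 32 samples at 25 us
# (~120 uV negative trough, late positive rebound).
spike_template <- function(n = 32) {
  t <- seq_len(n)
  -120 * exp(-(t - 9)^2 / 8) + 45 * exp(-(t - 17)^2 / 30)
}

#' Construct session templates with an exact planted correlation
#'
#' Used to calibrate the stability gate: given a base template and a target
#' Pearson correlation `r`, each successive template is built in standardised
#' space as `r * previous + sqrt(1 - r^2) * orthogonal`, so consecutive
#' session pairs correlate at exactly `r`.
#'
#' @param base Numeric base template.
#' @param r Target consecutive-session correlation in `[-1, 1]`.
#' @param n_sessions Number of sessions.
#' @param seed Seed for the orthogonal perturbation directions.
#' @return List of templates, length `n_sessions`.
#' @export
drifted_templates <- function(base, r, n_sessions, seed = 1) {
  set.seed(substream_seed(seed, "drift"))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  out <- vector("list", n_sessions)
  out[[1]] <- std(base)
  for (i in seq_len(n_sessions - 1)) {
    prev <- out[[i]]
    raw <- stats::rnorm(length(base))
    raw <- std(raw)
    orth <- raw - sum(raw * prev) / sum(prev * prev) * prev
    orth <- std(orth)
    out[[i + 1]] <- std(r * prev + sqrt(max(0, 1 - r^2)) * orth)
  }
  out
}
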