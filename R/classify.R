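#' Test CS-responsiveness of one unit in one recall epoch
#'
#' Two-sided unpaired (Student) t-test of per-event spike counts in the
#' response window against per-event counts from an equal-duration window
#' immediately before each event (rate-matched baseline).  The response sign
#' is the direction of the mean difference when the test is significant.
#'
#' @param resp_counts Non-negative integer counts, one per event (response
#'   window).
#' @param base_counts Counts from the matched pre-onset windows.
#' @param alpha Significance level (default 0.05).
#' @return List `responsive`, `sign` (`"excitatory"`, `"inhibitory"`,
#'   `"none"`), `p_value`, `tie` (`TRUE` when both samples are constant and
#'   equal, an exact tie that is never responsive).
#' @export
cs_responsive_test <- function(resp_counts, base_counts, alpha = 0.05) {
  if (length(resp_counts) < 2 || length(base_counts) < 2) {
    stop("need >= 2 events on each side")
  }
  if (any(resp_counts < 0) || any(base_counts < 0)) stop("negative counts")
  v1 <- stats::var(resp_counts)
  v2 <- stats::var(base_counts)
  d <- mean(resp_counts) - mean(base_counts)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) {
      return(list(responsive = FALSE, sign = "none", p_value = 1, tie = TRUE))
    }
    # constant but different samples: separation is exact
    p <- 0
  } else {
    p <- stats::t.test(resp_counts, base_counts, var.equal = TRUE)$p.value
  }
  responsive <- p < alpha
  sign <- if (!responsive) "none" else if (d > 0) "excitatory" else "inhibitory"
  list(responsive = responsive, sign = sign, p_value = p, tie = FALSE)
}

#' Build a per-epoch CS-responsiveness profile for one unit
#'
#' For every recall epoch of the plan (Hab, post-Cond, post-Ext1..3) the
#' aligned events are collected (pips in pip mode, tone onsets otherwise),
#' per-event response and matched pre-onset baseline counts are tested with
#' [cs_responsive_test()], and the epoch's mean windowed z is computed from
#' the dialect's z-scored peri-event histogram.  The response window
#' defaults to 0-100 ms after each pip (pip dialect) and 0-400 ms after tone
#' onset (tone dialect).
#'
#' An epoch additionally counts as *strong* when it is responsive and its
#' mean windowed z reaches `strength_z` in magnitude; neuron typing uses the
#' strong flag (the fear/extinction definitions require *strong* responses),
#' while `responsive` alone retains the nominal per-test false-positive rate.
#'
#' @param spikes Spike-time vector (s) for the unit, or its spikes table.
#' @param events Event table from [generate_events()].
#' @param plan A `session_plan`.
#' @param alpha Significance level (default 0.05).
#' @param strength_z Magnitude of mean windowed z required for a response to
#'   count as strong (default 1.5).
#' @param window_ms Response-window length in ms; `NULL` for the dialect
#'   default.
#' @param unit_id Optional label.
#' @return Data frame `unit_id, epoch, responsive, strong, sign, p_value,
#'   mean_window_z`, one row per epoch (class `responsiveness_profile`).
#' @export
build_profile <- function(spikes, events, plan, alpha = 0.05,
                          strength_z = 1.5, window_ms = NULL, unit_id = NA) {
  if (is.data.frame(spikes)) {
    ord <- order(match(spikes$session, plan$sessions$label), spikes$t_s)
    spikes_by_session <- split(spikes$t_s[ord], spikes$session[ord])
  } else {
    stop("spikes must be the unit's spikes table (session clocks differ)")
  }
  pip_mode <- identical(plan$alignment, "pip")
  w <- window_ms %||% if (pip_mode) 100 else 400
  ep <- recall_epochs(plan)
  rows <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    e <- ep[i, ]
    ts <- sort(spikes_by_session[[e$session]] %||% numeric(0))
    onsets <- epoch_onsets(events, e, if (pip_mode) "pip" else "tone")
    tone_onsets <- epoch_onsets(events, e, "tone")
    resp <- bin_event_counts(ts, onsets, c(0, w))[, 1]
    base <- bin_event_counts(ts, onsets, c(-w, 0))[, 1]
    tt <- cs_responsive_test(resp, base, alpha)
    zp <- if (pip_mode) {
      zscore_pip_peth(ts, tone_onsets, onsets, session = e$epoch,
                      unit_id = unit_id)
    } else {
      zscore_tone_peth(ts, tone_onsets, session = e$epoch, unit_id = unit_id)
    }
    mz <- tryCatch(window_response(zp, c(0, w), "mean"),
                   error = function(err) NA_real_)
    rows[[i]] <- data.frame(unit_id = unit_id, epoch = e$epoch,
                            responsive = tt$responsive,
                            strong = tt$responsive && !is.na(mz) &&
                              abs(mz) >= strength_z,
                            sign = tt$sign,
                            p_value = tt$p_value, mean_window_z = mz,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("responsiveness_profile", class(out))
  out
}

#' Type a neuron from its CS-responsiveness profile
#'
#' Typing reads the *strong*-response flags of the profile (significant by
#' the unpaired t-test and with mean windowed z of at least the strength
#' criterion — the fear/extinction phenotypes are defined by strong
#' CS-evoked responses):
#'
#' * **fear**: strong excitatory response at fear recall (post-Cond) and no
#'   strong response in Hab or any post-extinction epoch (response lost with
#'   extinction).
#' * **extinction**: strong excitatory response at extinction recall
#'   (post-Ext1), none in Hab or post-Cond.
#' * **session_selective**: strong response in exactly one epoch, not
#'   matching the above patterns.
#' * **non_responsive** otherwise.
#'
#' @param profile Data frame from [build_profile()] covering epochs Hab,
#'   post-Cond, post-Ext1, post-Ext2, post-Ext3.
#' @return List `unit_id`, `label`, `selective_epoch` (`NA` unless
#'   session-selective).
#' @export
classify_neuron <- function(profile) {
  need <- c("Hab", "post-Cond", "post-Ext1", "post-Ext2", "post-Ext3")
  missing <- setdiff(need, profile$epoch)
  if (length(missing)) stop("profile missing epoch(s): ",
                            paste(missing, collapse = ", "))
  if (is.null(profile$strong)) profile$strong <- profile$responsive
  resp <- stats::setNames(profile$strong, profile$epoch)[need]
  sgn <- stats::setNames(profile$sign, profile$epoch)[need]
  exc <- resp & sgn == "excitatory"
  label <- "non_responsive"
  sel <- NA_character_
  if (exc[["post-Cond"]] && !resp[["Hab"]] &&
      !resp[["post-Ext1"]] && !resp[["post-Ext2"]] && !resp[["post-Ext3"]]) {
    label <- "fear"
  } else if (exc[["post-Ext1"]] && !resp[["Hab"]] && !resp[["post-Cond"]]) {
    label <- "extinction"
  } else if (sum(resp) == 1) {
    label <- "session_selective"
    sel <- need[which(resp)]
  }
  list(unit_id = profile$unit_id[1], label = label, selective_epoch = sel)
}

#' Response latency from a z-scored peri-event histogram
#'
#' The latency is the left edge of the first bin inside the search window
#' whose z meets the criterion; `NA` when no bin crosses it.  With
#' `min_consecutive > 1` the crossing must be sustained over that many
#' consecutive bins — a standard hardening against spurious single-bin
#' crossings when the baseline SD is estimated from few bins (the
#' tone dialect estimates it from 4 bins, i.e. 3 degrees of freedom, so a
#' single underestimated SD inflates every bin of the histogram at once).
#'
#' @param zpeth A non-degenerate `zpeth`.
#' @param criterion_z Detection criterion (default 3).
#' @param window_ms Search window; default 0-100 ms for 20-ms (pip dialect)
#'   bins, 0-400 ms otherwise.
#' @param min_consecutive Number of consecutive bins that must meet the
#'   criterion (default 1: first crossing).
#' @return Latency in ms, or `NA_real_` if no crossing.
#' @export
response_latency <- function(zpeth, criterion_z = 3, window_ms = NULL,
                             min_consecutive = 1) {
  if (zpeth$degenerate) stop("degenerate histogram: baseline sd = 0")
  window_ms <- window_ms %||% if (zpeth$bin_ms <= 20) c(0, 100) else c(0, 400)
  keep <- which(zpeth$bin_left_ms >= window_ms[1] &
                  (zpeth$bin_left_ms + zpeth$bin_ms) <= window_ms[2])
  over <- zpeth$z[keep] >= criterion_z
  if (min_consecutive > 1) {
    r <- rle(over)
    ok <- r$values & r$lengths >= min_consecutive
    if (!any(ok)) return(NA_real_)
    start <- sum(r$lengths[seq_len(which(ok)[1] - 1)]) + 1
    return(zpeth$bin_left_ms[keep[start]])
  }
  hit <- keep[over]
  if (!length(hit)) NA_real_ else zpeth$bin_left_ms[hit[1]]
}

#' Population composition of classified neurons
#'
#' @param labels Character vector of neuron labels (from
#'   [classify_neuron()]) for the classified units.
#' @param n_recorded Total number of recorded units.
#' @param n_responsive Number of CS-responsive units (denominator of the
#'   second percentage); defaults to the number of labels other than
#'   `non_responsive`.
#' @return Data frame `label, n, pct_recorded, pct_responsive` (percentages
#'   to 2 decimals; `NA` with a warning on a zero denominator).
#' @examples
#' cohort_summary(rep(c("fear", "extinction"), c(8, 6)),
#'                n_recorded = 130, n_responsive = 35)
#' @export
cohort_summary <- function(labels, n_recorded, n_responsive = NULL) {
  if (n_recorded < length(labels)) stop("n_recorded < number of labelled units")
  lv <- c("fear", "extinction", "session_selective", "non_responsive")
  counts <- table(factor(labels, levels = lv))
  n_responsive <- n_responsive %||% sum(labels != "non_responsive")
  data.frame(label = lv, n = as.integer(counts),
             pct_recorded = vapply(as.integer(counts), pct, 1, n = n_recorded),
             pct_responsive = vapply(as.integer(counts), pct, 1,
                                     n = n_responsive),
             stringsAsFactors = FALSE)
}
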