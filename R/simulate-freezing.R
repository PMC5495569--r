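#' Default freezing-trajectory parameters for a rat
#'
#' Per-session target freezing (percent of CS time) at the start and end of
#' each session, linearly interpolated across CSs, shaped so that conditioned
#' freezing rises with conditioning and progressively decreases over the
#' three extinction sessions.  Two profiles are provided: a *successful*
#' extinction-recall profile (low freezing at the start of Ext2) and a *poor*
#' one (freezing stays high into Ext2 and beyond).
#'
#' @param rat_id Rat identifier.
#' @param group `"successful"` or `"poor"` recall profile.
#' @param sd_pct Across-CS SD of scored freezing around the target (default 10).
#' @return A list with `rat_id`, `sd_pct` and `targets` (named list of
#'   `c(start, end)` percent pairs per session label).
#' @export
default_rat_params <- function(rat_id, group = c("successful", "poor"),
                               sd_pct = 10) {
  group <- match.arg(group)
  targets <- if (group == "successful") {
    list(Hab = c(5, 5), Cond = c(10, 65), Ext1 = c(70, 35),
         Ext2 = c(30, 15), Ext3 = c(15, 8), Test = c(10, 10))
  } else {
    list(Hab = c(5, 5), Cond = c(10, 70), Ext1 = c(75, 60),
         Ext2 = c(65, 50), Ext3 = c(50, 40), Test = c(45, 45))
  }
  list(rat_id = rat_id, group = group, sd_pct = sd_pct, targets = targets)
}

#' Simulate a binary immobility trace per CS
#'
#' For each CS the scored freezing target is the linear interpolation between
#' the session's start/end targets, plus Gaussian trial noise truncated to
#' `[0, 100]`.  The corresponding immobile time is laid down as a single
#' contiguous bout (always satisfying the minimum-bout rule when non-zero)
#' placed uniformly at random inside the CS window, on a 0.1-s grid so the
#' 2-s rule is exact.  Targets that imply a bout shorter than `min_bout_s`
#' score 0 under the rule and are emitted as fully mobile.
#'
#' @param rat Parameters from [default_rat_params()] (or same shape).
#' @param plan A `session_plan`.
#' @param seed Integer seed.
#' @param dt_s Sampling step (default 0.1 s).
#' @param min_bout_s Minimum immobility bout to count as freezing (default 2).
#' @return Data frame `movement(rat_id, session, cs_index, t_s, immobile)`
#'   with `t_s` relative to CS onset.
#' @export
simulate_freezing <- function(rat, plan, seed, dt_s = 0.1, min_bout_s = 2) {
  tg <- rat$targets
  for (v in tg) {
    if (any(v < 0 | v > 100)) stop("freezing targets must lie in [0, 100]")
  }
  if (rat$sd_pct < 0) stop("sd_pct must be >= 0")
  out <- list()
  for (i in seq_len(nrow(plan$sessions))) {
    lab <- plan$sessions$label[i]
    if (is.null(tg[[lab]])) stop("no freezing target for session ", lab)
    n_cs <- plan$sessions$n_cs[i]
    dur <- plan$sessions$cs_duration_s[i]
    nsteps <- round(dur / dt_s)
    set.seed(substream_seed(seed, "freeze", rat$rat_id, lab))
    target <- if (n_cs == 1) mean(tg[[lab]]) else
      seq(tg[[lab]][1], tg[[lab]][2], length.out = n_cs)
    scored <- pmin(100, pmax(0, stats::rnorm(n_cs, target, rat$sd_pct)))
    for (j in seq_len(n_cs)) {
      k <- round(scored[j] / 100 * dur / dt_s)   # immobile steps
      if (k * dt_s < min_bout_s) k <- 0
      trace <- integer(nsteps)
      if (k > 0) {
        start <- sample.int(nsteps - k + 1, 1) - 1L
        trace[(start + 1):(start + k)] <- 1L
      }
      out[[length(out) + 1]] <- data.frame(
        rat_id = rat$rat_id, session = lab, cs_index = j,
        t_s = (seq_len(nsteps) - 1) * dt_s, immobile = trace,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
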