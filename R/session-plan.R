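#' Build a multi-session conditioning/extinction protocol
#'
#' Returns a `session_plan`: the ordered list of behavioural sessions
#' (habituation, conditioning, extinction sessions, retention test) with CS
#' counts, CS duration, inter-trial-interval range and footshock (US)
#' parameters, plus the CS alignment mode.  Three presets cover the protocol
#' variants used across in vivo recording, ex vivo slice and lesion
#' experiments:
#'
#' * `"recording"`: Hab 5 CS; Cond 5 CS/US pairings (0.5 mA, 0.5 s), ITI
#'   80-120 s; Ext1 20 CS; Ext2/Ext3 20 CS (configurable; only Ext1's count
#'   is protocol-fixed); Test 5 CS.  Tone alignment by default; pip alignment
#'   (27 pips per CS, 200 ms, 0.9 Hz) for basal-amygdala style recordings.
#' * `"slice"`: Cond 3 CS/US pairings (1 mA, 1 s), ITI 100 s; Ext1 20 CS;
#'   Ext2/Ext3 15 CS; retention window 2.
#' * `"lesion"`: Cond 4 CS/US pairings (0.4 mA, 1 s), ITI 100 s; Ext1 20 CS;
#'   Ext2/Ext3 20 CS; Test 5 CS.
#'
#' @param preset One of `"recording"`, `"slice"`, `"lesion"`.
#' @param overrides Named list replacing matching fields only.  Recognised
#'   keys: `alignment` (`"tone"`/`"pip"`), `pip_spec`, `retention_window`,
#'   `n_cs` (named list, e.g. `list(Ext1 = 1)`), `cs_duration_s`,
#'   `iti_s` (named list of length-2 vectors), `us` (named list).
#' @return A `session_plan` object: list with `sessions` (data frame with
#'   columns `label`, `n_cs`, `cs_duration_s`, `iti_min_s`, `iti_max_s`,
#'   `us_mA`, `us_s`), `alignment`, `pip_spec`, `retention_window`.
#' @examples
#' make_session_plan("recording")
#' make_session_plan("recording", list(alignment = "pip"))
#' @export
make_session_plan <- function(preset = c("recording", "slice", "lesion"),
                              overrides = list()) {
  preset <- match.arg(preset)
  sess <- function(label, n_cs, iti, us_mA = NA_real_, us_s = NA_real_,
                   cs_duration_s = 30) {
    data.frame(label = label, n_cs = n_cs, cs_duration_s = cs_duration_s,
               iti_min_s = iti[1], iti_max_s = iti[2],
               us_mA = us_mA, us_s = us_s, stringsAsFactors = FALSE)
  }
  plan <- switch(preset,
    recording = list(
      sessions = rbind(
        sess("Hab",  5, c(80, 120)),
        sess("Cond", 5, c(80, 120), us_mA = 0.5, us_s = 0.5),
        sess("Ext1", 20, c(80, 120)),
        sess("Ext2", 20, c(80, 120)),
        sess("Ext3", 20, c(80, 120)),
        sess("Test", 5, c(80, 120))),
      alignment = "tone", pip_spec = NULL, retention_window = 5L),
    slice = list(
      sessions = rbind(
        sess("Cond", 3, c(100, 100), us_mA = 1, us_s = 1),
        sess("Ext1", 20, c(100, 100)),
        sess("Ext2", 15, c(100, 100)),
        sess("Ext3", 15, c(100, 100))),
      alignment = "tone", pip_spec = NULL, retention_window = 2L),
    lesion = list(
      sessions = rbind(
        sess("Cond", 4, c(100, 100), us_mA = 0.4, us_s = 1),
        sess("Ext1", 20, c(100, 100)),
        sess("Ext2", 20, c(100, 100)),
        sess("Ext3", 20, c(100, 100)),
        sess("Test", 5, c(100, 100))),
      # conditioning has only 4 CSs in this variant, so the recall window
      # cannot exceed 4
      alignment = "tone", pip_spec = NULL, retention_window = 4L))

  known <- c("alignment", "pip_spec", "retention_window", "n_cs",
             "cs_duration_s", "iti_s", "us")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))

  if (!is.null(overrides$alignment)) {
    plan$alignment <- match.arg(overrides$alignment, c("tone", "pip"))
  }
  if (identical(plan$alignment, "pip") && is.null(plan$pip_spec)) {
    plan$pip_spec <- list(n_pips = 27L, pip_duration_ms = 200, pip_rate_hz = 0.9)
  }
  if (!is.null(overrides$pip_spec)) {
    plan$pip_spec <- utils::modifyList(plan$pip_spec %||% list(), overrides$pip_spec)
  }
  if (!is.null(overrides$retention_window)) {
    plan$retention_window <- as.integer(overrides$retention_window)
  }
  if (!is.null(overrides$cs_duration_s)) {
    plan$sessions$cs_duration_s <- overrides$cs_duration_s
  }
  for (lab in names(overrides$n_cs)) {
    i <- match(lab, plan$sessions$label)
    if (is.na(i)) stop("override references unknown session: ", lab)
    plan$sessions$n_cs[i] <- overrides$n_cs[[lab]]
  }
  for (lab in names(overrides$iti_s)) {
    i <- match(lab, plan$sessions$label)
    if (is.na(i)) stop("override references unknown session: ", lab)
    plan$sessions$iti_min_s[i] <- overrides$iti_s[[lab]][1]
    plan$sessions$iti_max_s[i] <- overrides$iti_s[[lab]][2]
  }
  for (lab in names(overrides$us)) {
    i <- match(lab, plan$sessions$label)
    if (is.na(i)) stop("override references unknown session: ", lab)
    plan$sessions$us_mA[i] <- overrides$us[[lab]][["amplitude_mA"]]
    plan$sessions$us_s[i] <- overrides$us[[lab]][["duration_s"]]
  }
  class(plan) <- "session_plan"
  validate_session_plan(plan)
  plan
}

#' Validate a session plan's invariants
#'
#' Checks that every non-habituation session has at least `retention_window`
#' CS presentations, that a pip specification is present exactly when the
#' alignment mode is `"pip"`, and that the footshock appears only in the
#' conditioning session.
#'
#' @param plan A `session_plan`.
#' @return The plan, invisibly; errors on violation.
#' @export
validate_session_plan <- function(plan) {
  s <- plan$sessions
  non_hab <- s$label != "Hab"
  if (any(s$n_cs[non_hab] < plan$retention_window)) {
    stop("n_cs < retention_window in session(s): ",
         paste(s$label[non_hab & s$n_cs < plan$retention_window], collapse = ", "))
  }
  if (identical(plan$alignment, "pip") && is.null(plan$pip_spec)) {
    stop("pip alignment requires pip_spec")
  }
  if (identical(plan$alignment, "tone") && !is.null(plan$pip_spec)) {
    stop("pip_spec present but alignment is tone")
  }
  has_us <- !is.na(s$us_mA)
  if (any(has_us & s$label != "Cond")) stop("US present outside Cond")
  invisible(plan)
}

#' @export
print.session_plan <- function(x, ...) {
  cat("session_plan (", x$alignment, "-aligned, retention window ",
      x$retention_window, " CS)\n", sep = "")
  print(x$sessions, row.names = FALSE)
  if (!is.null(x$pip_spec)) {
    cat(sprintf("pips: %d per CS, %g ms at %g Hz\n", x$pip_spec$n_pips,
                x$pip_spec$pip_duration_ms, x$pip_spec$pip_rate_hz))
  }
  invisible(x)
}

#' Generate the event schedule realised from a session plan
#'
#' Draws inter-trial intervals uniformly in `[iti_min, iti_max]` and lays out
#' CS onsets per session on an absolute within-session clock (sessions have
#' independent clocks).  In pip mode every CS additionally emits its pip
#' onsets (`n_pips` at `pip_rate_hz`); in the conditioning session the
#' footshock co-terminates with the CS.
#'
#' @param plan A `session_plan`.
#' @param seed Integer seed.
#' @param t0_s Time of the first CS onset in each session (default 60 s).
#' @return Data frame `events(session, cs_index, onset_s, kind)` with
#'   `kind` in `tone`, `pip`, `us`.
#' @export
generate_events <- function(plan, seed, t0_s = 60) {
  set.seed(substream_seed(seed, "events"))
  out <- list()
  for (i in seq_len(nrow(plan$sessions))) {
    s <- plan$sessions[i, ]
    iti <- stats::runif(s$n_cs, s$iti_min_s, s$iti_max_s)
    onsets <- t0_s + cumsum(c(0, (s$cs_duration_s + iti)[-s$n_cs]))
    rows <- data.frame(session = s$label, cs_index = seq_len(s$n_cs),
                       onset_s = onsets, kind = "tone",
                       stringsAsFactors = FALSE)
    if (identical(plan$alignment, "pip")) {
      ps <- plan$pip_spec
      pip_rel <- (seq_len(ps$n_pips) - 1) / ps$pip_rate_hz
      pips <- data.frame(
        session = s$label,
        cs_index = rep(seq_len(s$n_cs), each = ps$n_pips),
        onset_s = rep(onsets, each = ps$n_pips) + rep(pip_rel, s$n_cs),
        kind = "pip", stringsAsFactors = FALSE)
      rows <- rbind(rows, pips)
    }
    if (!is.na(s$us_mA)) {
      us <- data.frame(session = s$label, cs_index = seq_len(s$n_cs),
                       onset_s = onsets + s$cs_duration_s - s$us_s,
                       kind = "us", stringsAsFactors = FALSE)
      rows <- rbind(rows, us)
    }
    out[[i]] <- rows[order(rows$onset_s, rows$kind), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recall-epoch table for a session plan
#'
#' The leading `retention_window` CSs of each session are scored as the
#' retention (recall) test of the preceding session's learning: the first CSs
#' of Ext1 probe conditioning (post-Cond), the first CSs of Ext2 probe Ext1
#' (post-Ext1), and so on; a final short Test session probes the last
#' extinction session.  Habituation forms its own epoch.
#'
#' @param plan A `session_plan`.
#' @return Data frame `epochs(epoch, session, cs_from, cs_to)`.
#' @export
recall_epochs <- function(plan) {
  labs <- plan$sessions$label
  rw <- plan$retention_window
  rows <- list()
  if ("Hab" %in% labs) {
    n <- plan$sessions$n_cs[labs == "Hab"]
    rows[[length(rows) + 1]] <- data.frame(
      epoch = "Hab", session = "Hab", cs_from = 1L, cs_to = as.integer(n))
  }
  prev <- NULL
  for (lab in labs) {
    if (lab == "Hab") next
    if (!is.null(prev)) {
      rows[[length(rows) + 1]] <- data.frame(
        epoch = paste0("post-", prev), session = lab,
        cs_from = 1L, cs_to = as.integer(rw))
    }
    prev <- lab
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Event onsets belonging to one recall epoch
#'
#' @param events Event table from [generate_events()].
#' @param epoch_row One row of [recall_epochs()].
#' @param kind `"tone"` or `"pip"`.
#' @return Numeric vector of onset times (seconds, session clock).
#' @export
epoch_onsets <- function(events, epoch_row, kind = "tone") {
  sel <- events$session == epoch_row$session &
    events$cs_index >= epoch_row$cs_from &
    events$cs_index <= epoch_row$cs_to &
    events$kind == kind
  sort(events$onset_s[sel])
}
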