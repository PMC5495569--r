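#' Score freezing from a binary immobility trace
#'
#' An animal counts as frozen during maximal runs of immobility lasting at
#' least `min_bout_s` (no movement except respiration for 2 s, under the
#' default); the total qualifying time is normalised to the CS duration.
#'
#' @param immobile Integer/logical vector of immobility samples covering the
#'   CS window, on a uniform grid.
#' @param dt_s Sampling step in seconds.
#' @param cs_duration_s CS duration in seconds.
#' @param min_bout_s Minimum qualifying bout length (default 2 s).
#' @return Freezing percentage in `[0, 100]`.
#' @examples
#' score_freezing(rep(1, 300), 0.1, 30)          # 100
#' score_freezing(rep(c(1, 0), c(120, 180)), 0.1, 30)  # one 12-s bout: 40
#' @export
score_freezing <- function(immobile, dt_s, cs_duration_s, min_bout_s = 2) {
  n_expected <- round(cs_duration_s / dt_s)
  if (length(immobile) < n_expected) {
    stop("trace (", length(immobile) * dt_s, " s) shorter than CS window (",
         cs_duration_s, " s)")
  }
  immobile <- immobile[seq_len(n_expected)]   # intersect with the CS window
  r <- rle(as.integer(immobile != 0))
  frozen_s <- sum(r$lengths[r$values == 1 & r$lengths * dt_s >= min_bout_s]) * dt_s
  100 * frozen_s / cs_duration_s
}

#' Score freezing for every (rat, session, CS) in a movement table
#'
#' @param movement Data frame `rat_id, session, cs_index, t_s, immobile`
#'   (as emitted by [simulate_freezing()]).
#' @param plan A `session_plan`.
#' @param min_bout_s Minimum qualifying bout (default 2 s).
#' @return Data frame `rat_id, session, cs_index, freezing_pct`.
#' @export
score_freezing_table <- function(movement, plan, min_bout_s = 2) {
  dur <- stats::setNames(plan$sessions$cs_duration_s, plan$sessions$label)
  key <- interaction(movement$rat_id, movement$session, movement$cs_index,
                     drop = TRUE)
  pieces <- split(movement, key)
  rows <- lapply(pieces, function(d) {
    d <- d[order(d$t_s), ]
    dt <- if (nrow(d) > 1) d$t_s[2] - d$t_s[1] else 0.1
    data.frame(rat_id = d$rat_id[1], session = d$session[1],
               cs_index = d$cs_index[1],
               freezing_pct = score_freezing(d$immobile, dt,
                                             dur[[d$session[1]]], min_bout_s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$rat_id, match(res$session, plan$sessions$label),
                   res$cs_index), ]
  rownames(res) <- NULL
  res
}

#' Per-rat freezing during the extinction-recall epoch (post-Ext1)
#'
#' Recall of the first extinction session is probed by the leading
#' `retention_window` CSs of Ext2; each rat's recall freezing is the mean
#' over those CSs.
#'
#' @param freezing Data frame from [score_freezing_table()].
#' @param plan A `session_plan`.
#' @return Named numeric vector of freezing percentages, one per rat.
#' @export
post_ext1_freezing <- function(freezing, plan) {
  ep <- recall_epochs(plan)
  row <- ep[ep$epoch == "post-Ext1", ]
  if (!nrow(row)) stop("plan has no post-Ext1 epoch")
  sel <- freezing$session == row$session &
    freezing$cs_index >= row$cs_from & freezing$cs_index <= row$cs_to
  tapply(freezing$freezing_pct[sel], freezing$rat_id[sel], mean)
}

#' Split rats into successful and poor extinction-recall groups
#'
#' The threshold is the upper bound of the two-sided `level` t-confidence
#' interval for the across-rat mean of post-Ext1 freezing
#' (`mean + t * sd / sqrt(n)`); a rat recalls extinction successfully iff its
#' freezing lies strictly below the threshold.
#'
#' @param post_ext1 Named numeric vector of per-rat recall freezing.
#' @param level Confidence level (default 0.99).
#' @return Data frame `rat_id, freezing_pct, group, threshold_pct` with
#'   `group` in `successful`/`poor`.
#' @examples
#' assign_recall_groups(c(a = 0, b = 0, c = 100))  # threshold ~364: all successful
#' @export
assign_recall_groups <- function(post_ext1, level = 0.99) {
  if (length(post_ext1) < 2) stop("need >= 2 rats to form a confidence interval")
  if (any(!is.finite(post_ext1))) stop("non-finite freezing values")
  thr <- upper_conf_bound(post_ext1, level)
  data.frame(rat_id = names(post_ext1) %||% as.character(seq_along(post_ext1)),
             freezing_pct = as.numeric(post_ext1),
             group = ifelse(post_ext1 < thr, "successful", "poor"),
             threshold_pct = thr, stringsAsFactors = FALSE)
}
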