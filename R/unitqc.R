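#' Cluster-isolation quality in principal-component space
#'
#' Grades how compact and well separated sorted unit clusters are, using the
#' scatter-matrix ratio J3 and the Davies-Bouldin validity index:
#' \deqn{J_1 = \sum_k \sum_{x \in k} \lVert x - m_k \rVert^2, \quad
#'       J_2 = \sum_k n_k \lVert m_k - m \rVert^2, \quad J_3 = J_2 / J_1}
#' \deqn{DB = \frac{1}{K} \sum_k \max_{j \ne k}
#'       \frac{s_k + s_j}{\lVert m_k - m_j \rVert}}
#' with \eqn{s_k} the mean distance of cluster k's points to their centroid.
#' A high J3 and a low DB indicate a compact, well-separated cluster.
#'
#' @param clusters List of numeric matrices (points x dimensions), one per
#'   cluster, all sharing the same dimensionality.
#' @return List `j3`, `db`, `flag` (`NULL`, or `"coincident_centroids"` when
#'   DB is undefined).  `j3` is `Inf` when the within-cluster scatter is 0.
#' @examples
#' a <- rbind(c(0, 0), c(0, 2)); b <- rbind(c(10, 0), c(10, 2))
#' cluster_quality(list(a, b))  # j3 = 25, db = 0.2
#' @export
cluster_quality <- function(clusters) {
  if (length(clusters) < 2) stop("need >= 2 clusters")
  clusters <- lapply(clusters, function(x) {
    x <- as.matrix(x)
    if (!nrow(x)) stop("empty cluster")
    x
  })
  d <- unique(vapply(clusters, ncol, 1L))
  if (length(d) != 1) stop("clusters must share dimensionality")
  centroids <- t(vapply(clusters, colMeans, numeric(d)))
  all_pts <- do.call(rbind, clusters)
  m <- colMeans(all_pts)
  n_k <- vapply(clusters, nrow, 1L)
  j1 <- sum(vapply(seq_along(clusters), function(k) {
    sum(sweep(clusters[[k]], 2, centroids[k, ])^2)
  }, 1))
  j2 <- sum(n_k * rowSums(sweep(centroids, 2, m)^2))
  j3 <- if (j1 == 0) Inf else j2 / j1
  s_k <- vapply(seq_along(clusters), function(k) {
    mean(sqrt(rowSums(sweep(clusters[[k]], 2, centroids[k, ])^2)))
  }, 1)
  dm <- as.matrix(stats::dist(centroids))
  flag <- NULL
  K <- length(clusters)
  ratios <- numeric(K)
  for (k in seq_len(K)) {
    others <- setdiff(seq_len(K), k)
    if (any(dm[k, others] == 0)) {
      flag <- "coincident_centroids"
      ratios[k] <- NA_real_
    } else {
      ratios[k] <- max((s_k[k] + s_k[others]) / dm[k, others])
    }
  }
  db <- if (is.null(flag)) mean(ratios) else NA_real_
  list(j3 = j3, db = db, flag = flag)
}

#' Project waveform snippets of several clusters into PC space
#'
#' Principal components are computed on the pooled snippets (top-`k`
#' components of the pooled covariance) and each cluster's snippets are
#' returned as scores in that shared space, ready for [cluster_quality()].
#'
#' @param snippet_sets List of snippet matrices (spikes x samples).
#' @param k Number of components (default 2).
#' @return List of score matrices (spikes x k).
#' @export
pc_project <- function(snippet_sets, k = 2) {
  pooled <- do.call(rbind, snippet_sets)
  p <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
  idx <- rep(seq_along(snippet_sets), vapply(snippet_sets, nrow, 1L))
  lapply(seq_along(snippet_sets), function(i) scores[idx == i, , drop = FALSE])
}

#' Cross-session template stability of one unit
#'
#' The session template is the mean snippet; stability is judged from the
#' Pearson correlations between templates of consecutive sessions, with the
#' gate `min r > threshold` (default 0.97, strict).
#'
#' @param waveforms_by_session Named list of snippet matrices (spikes x
#'   samples), in chronological session order, equal sample counts.
#' @param threshold Stability gate (default 0.97).
#' @return List `template_r` (named per consecutive pair), `min_r`, `stable`,
#'   `reason` (`NULL`, or `"zero_variance_template"` when a correlation is
#'   undefined; the unit is then unstable).
#' @export
template_stability <- function(waveforms_by_session, threshold = 0.97) {
  if (length(waveforms_by_session) < 2) stop("need >= 2 sessions")
  templates <- lapply(waveforms_by_session, function(w) colMeans(as.matrix(w)))
  len <- unique(lengths(templates))
  if (length(len) != 1) stop("templates must have equal length")
  labs <- names(waveforms_by_session) %||%
    as.character(seq_along(waveforms_by_session))
  n <- length(templates)
  r <- numeric(n - 1)
  reason <- NULL
  for (i in seq_len(n - 1)) {
    a <- templates[[i]]; b <- templates[[i + 1]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r[i] <- NA_real_
      reason <- "zero_variance_template"
    } else {
      r[i] <- stats::cor(a, b)
    }
  }
  names(r) <- paste(labs[-n], labs[-1], sep = ":")
  stable <- is.null(reason) && all(r > threshold)
  list(template_r = r, min_r = if (anyNA(r)) NA_real_ else min(r),
       stable = stable, reason = reason)
}
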