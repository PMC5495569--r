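new_test_result <- function(method, statistic, df, p_value, n) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  stat <- paste(names(x$statistic), signif(unlist(x$statistic), 5),
                sep = " = ", collapse = ", ")
  dfs <- if (length(x$df)) paste0(" (df ", paste(x$df, collapse = ", "), ")")
         else ""
  cat(sprintf("%s: %s%s, p = %.4g, n = %s\n", x$method, stat, dfs,
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Mann-Whitney U test (exact small-sample / tie-corrected normal)
#'
#' Midranks are used for ties; the reported statistic is
#' `U = min(U_x, U_y)`.  The two-sided p-value is exact (equivalent to full
#' enumeration of rank assignments) when `max(n) <= 10` and there are no
#' ties, otherwise a normal approximation with tie correction and continuity
#' correction is used.  `mode` can force either branch.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return A `test_result` with statistic `U`.
#' @examples
#' mann_whitney_u(1:3, 4:6)  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  ties <- length(unique(c(x, y))) < n1 + n2
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = max(n1, n2) <= 10 && !ties)
  if (use_exact && ties) stop("exact p undefined with ties")
  if (use_exact) {
    # U_x has the exact Wilcoxon rank-sum distribution
    p <- 2 * min(stats::pwilcox(ux, n1, n2),
                 1 - stats::pwilcox(ux - 1, n1, n2))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sig2 == 0) {
      p <- 1
    } else {
      z <- (abs(ux - mu) - 0.5) / sqrt(sig2)   # continuity-corrected
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  new_test_result("Mann-Whitney U", list(U = u), integer(0), p, c(n1, n2))
}

#' Kruskal-Wallis H test with tie correction
#'
#' @param groups List of numeric samples (>= 3 groups; use
#'   [mann_whitney_u()] for two).
#' @return A `test_result` with statistic `H`, df `k - 1`, chi-squared p.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.571
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3) {
    stop("need >= 3 groups (use mann_whitney_u for two)")
  }
  n_k <- lengths(groups)
  if (any(n_k < 1)) stop("empty group")
  v <- unlist(groups)
  N <- length(v)
  r <- rank(v)
  idx <- rep(seq_along(groups), n_k)
  R <- tapply(r, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(R^2 / n_k) - 3 * (N + 1)
  tie_tab <- table(v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  h <- if (corr > 0) h / corr else 0
  df <- length(groups) - 1
  new_test_result("Kruskal-Wallis H", list(H = h), df,
                  stats::pchisq(h, df, lower.tail = FALSE), n_k)
}

#' Friedman chi-squared test for repeated measures
#'
#' Rows are blocks (cells, rats), columns treatments (sessions); ranks are
#' midranks within each block and
#' \deqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1).}
#'
#' @param mat Numeric matrix, blocks x treatments, no missing cells.
#' @return A `test_result` with statistic `chisq`, df `k - 1`.
#' @examples
#' friedman_test(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))  # chisq = 6
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 3) stop("need >= 2 blocks and >= 3 treatments")
  if (anyNA(mat)) stop("missing cells")
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  R <- colSums(ranks)
  chisq <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  df <- k - 1
  new_test_result("Friedman chi-squared", list(chisq = chisq), df,
                  stats::pchisq(chisq, df, lower.tail = FALSE), n)
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR decisions
#'
#' The two-stage linear step-up: (1) Benjamini-Hochberg at
#' `q' = q / (1 + q)`; with `r1` rejections, estimate `m0 = m - r1`; (2) if
#' `0 < r1 < m`, rerun BH at `q' * m / m0` and take its decisions (all or
#' none short-circuit otherwise).
#'
#' @param p Raw p-values.
#' @param q FDR level (default 0.05).
#' @return Logical rejection vector, same order as `p`.
#' @export
bky_reject <- function(p, q = 0.05) {
  bh <- function(p, level) {
    m <- length(p)
    o <- order(p)
    thr <- level * seq_len(m) / m
    k <- which(p[o] <= thr)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(bh(p, q1))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

#' Dunn's post-hoc test with two-stage BKY FDR control
#'
#' Pairwise rank comparisons after a Kruskal-Wallis (independent groups) or
#' Friedman (repeated measures) omnibus test.  For independent groups,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac1{n_i} +
#'   \frac1{n_j}\right)}}}
#' with midranks over the pooled data and tie correction; for repeated
#' measures the within-block Friedman rank sums are compared with variance
#' `n k (k+1) / 6`.  Raw two-sided normal p-values are screened with
#' [bky_reject()].
#'
#' @param x List of group samples (`design = "independent"`) or a blocks x
#'   treatments matrix (`design = "repeated"`).
#' @param design `"independent"` or `"repeated"`.
#' @param q FDR level (default 0.05).
#' @return Data frame `pair, z, p_raw, reject` (class `posthoc_table`).
#' @export
dunn_bky <- function(x, design = c("independent", "repeated"), q = 0.05) {
  design <- match.arg(design)
  if (design == "independent") {
    groups <- x
    if (length(groups) < 2) stop("need >= 2 groups")
    n_k <- lengths(groups)
    labs <- names(groups) %||% as.character(seq_along(groups))
    v <- unlist(groups)
    N <- length(v)
    r <- rank(v)
    idx <- rep(seq_along(groups), n_k)
    rbar <- tapply(r, idx, mean)
    tie_tab <- table(v)
    s2 <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
    pairs <- utils::combn(length(groups), 2)
    z <- apply(pairs, 2, function(ij) {
      (rbar[ij[1]] - rbar[ij[2]]) /
        sqrt(s2 * (1 / n_k[ij[1]] + 1 / n_k[ij[2]]))
    })
  } else {
    mat <- as.matrix(x)
    if (ncol(mat) < 2) stop("need >= 2 treatments")
    labs <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
    n <- nrow(mat); k <- ncol(mat)
    R <- colSums(t(apply(mat, 1, rank)))
    pairs <- utils::combn(k, 2)
    z <- apply(pairs, 2, function(ij) {
      (R[ij[1]] - R[ij[2]]) / sqrt(n * k * (k + 1) / 6)
    })
  }
  p_raw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(pair = paste(labs[pairs[1, ]], labs[pairs[2, ]], sep = "-"),
                    z = as.numeric(z), p_raw = p_raw,
                    reject = bky_reject(p_raw, q), stringsAsFactors = FALSE)
  class(out) <- c("posthoc_table", class(out))
  out
}

#' Repeated-measures one-way ANOVA
#'
#' Within-subject design: rows are subjects (cells), columns the repeated
#' factor (sessions).  `F = MS_sessions / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))` after removing the per-subject effect.
#'
#' @param mat Complete numeric matrix, subjects x sessions.
#' @return A `test_result` with statistic `F`, dfs, plus fields
#'   `means`, `ms_error` for Newman-Keuls follow-up.
#' @export
rm_anova1 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 sessions")
  if (anyNA(mat)) stop("missing cells")
  grand <- mean(mat)
  ss_sessions <- n * sum((colMeans(mat) - grand)^2)
  ss_subjects <- k * sum((rowMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_error <- ss_total - ss_sessions - ss_subjects
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_error <- ss_error / df2
  if (ms_error <= 0) {
    res <- new_test_result("RM one-way ANOVA", list(F = NA_real_),
                           c(df1, df2), NA_real_, n)
    res$reason <- "zero_error_variance"
  } else {
    f <- (ss_sessions / df1) / ms_error
    res <- new_test_result("RM one-way ANOVA", list(F = f), c(df1, df2),
                           stats::pf(f, df1, df2, lower.tail = FALSE), n)
  }
  res$means <- colMeans(mat)
  res$ms_error <- ms_error
  res
}

#' Newman-Keuls stepwise post-hoc comparison
#'
#' Studentized-range step-down procedure over the ordered session means:
#' pairs spanning a stretch of `r` ordered means are tested against
#' `q_{alpha, r, df}` (computed numerically from the studentized-range
#' distribution); pairs nested inside a non-significant stretch inherit
#' non-significance without being tested.
#'
#' @param means Session means.
#' @param ms_error Error mean square from [rm_anova1()].
#' @param df_error Error degrees of freedom.
#' @param n Subjects per mean (balanced).
#' @param alpha Familywise level per stretch (default 0.05).
#' @return Data frame `pair, diff, q, p_value, stretch, reject`
#'   (class `posthoc_table`); `p_value` is `NA` for untested nested pairs.
#' @export
newman_keuls <- function(means, ms_error, df_error, n, alpha = 0.05) {
  if (n < 2) stop("need n >= 2 subjects per mean")
  k <- length(means)
  labs <- names(means) %||% as.character(seq_len(k))
  o <- order(means)
  se <- sqrt(ms_error / n)
  sig <- matrix(NA, k, k)   # significance in ordered-index space
  rows <- list()
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      # inherit non-significance from any containing non-significant stretch
      contained_ns <- FALSE
      for (a in seq_len(i)) for (b in j:k) {
        if ((b - a) > (j - i) && isFALSE(sig[a, b])) contained_ns <- TRUE
      }
      if (contained_ns) {
        sig[i, j] <- FALSE
        q_obs <- NA_real_; pv <- NA_real_
      } else {
        q_obs <- (means[o[j]] - means[o[i]]) / se
        pv <- stats::ptukey(q_obs, r, df_error, lower.tail = FALSE)
        sig[i, j] <- pv < alpha
      }
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(labs[o[i]], labs[o[j]], sep = "-"),
        diff = means[o[j]] - means[o[i]], q = q_obs, p_value = pv,
        stretch = r, reject = sig[i, j], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posthoc_table", class(out))
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions over the pooled support; the p-value is the asymptotic
#' Kolmogorov distribution with effective size `n1 n2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples.
#' @return A `test_result` with statistic `D`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  pooled <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  d <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  p <- min(1, max(0, p))
  new_test_result("Kolmogorov-Smirnov", list(D = d), integer(0), p,
                  c(length(x), length(y)))
}

#' Upper bound of the two-sided t confidence interval for a mean
#'
#' `mean + t_{(1 + level)/2, n-1} * sd / sqrt(n)`; used to split animals
#' into successful and poor extinction-recall groups.
#'
#' @param values Numeric sample (n >= 2).
#' @param level Confidence level (default 0.99).
#' @return Scalar upper bound.
#' @examples
#' upper_conf_bound(c(0, 0, 100))  # ~364.2
#' @export
upper_conf_bound <- function(values, level = 0.99) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  mean(values) + stats::qt((1 + level) / 2, n - 1) *
    stats::sd(values) / sqrt(n)
}
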