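# Brute-force two-sided exact Mann-Whitney p by enumerating all rank
# assignments; independent oracle for the exact branch.
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  ux_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(seq_len(n1 + n2)[subsets], nrow = n1)) -
    n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= ux_obs), mean(us >= ux_obs)))
}

test_that("Mann-Whitney exact branch matches full enumeration", {
  expect_equal(mann_whitney_u(1:3, 4:6)$statistic$U, 0)
  expect_equal(mann_whitney_u(1:3, 4:6)$p_value, 0.1)
  set.seed(101)
  for (i in 1:10) {
    x <- sample(100, 5); y <- setdiff(sample(100, 9), x)[1:4]
    expect_equal(mann_whitney_u(x, y)$p_value, enum_mw_p(x, y))
  }
})

test_that("identical samples are maximally non-significant", {
  x <- c(3, 1, 4, 1, 5)
  expect_gte(mann_whitney_u(x, sample(x))$p_value, 0.99)
})

test_that("normal approximation tracks the exact p within 0.02 at n = 8", {
  set.seed(102)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("tied data route to the tie-corrected approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  expect_error(mann_whitney_u(x, y, mode = "exact"), "ties")
  r <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Kruskal-Wallis matches the hand computation and base R", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic$H, 4.571, tolerance = 1e-3)
  expect_equal(r$df, 2)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic$H, 0)
  set.seed(103)
  g <- list(rpois(7, 4), rpois(9, 5), rpois(6, 4), rpois(8, 6))
  ref <- kruskal.test(g)
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic$H, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # rank-based: invariant under monotone transforms
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic$H, mine$statistic$H)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "3 groups")
})

test_that("Friedman matches the closed form and base R", {
  ordered3 <- rbind(c(1, 2, 3), c(4, 5, 6), c(2, 4, 9))
  expect_equal(friedman_test(ordered3)$statistic$chisq, 6)
  flat <- matrix(5, 4, 3)
  expect_equal(friedman_test(flat)$statistic$chisq, 0)
  set.seed(104)
  m <- matrix(rnorm(24), 6, 4)
  ref <- friedman.test(m)
  mine <- friedman_test(m)
  expect_equal(mine$statistic$chisq, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  expect_equal(friedman_test(m[sample(6), ])$statistic$chisq,
               mine$statistic$chisq)
  expect_error(friedman_test(rbind(c(1, NA, 2), c(3, 1, 2))), "missing")
})

test_that("BKY decisions bracket Bonferroni and unadjusted decisions", {
  expect_true(all(bky_reject(rep(0.001, 3), 0.05)))
  expect_false(any(bky_reject(rep(0.9, 3), 0.05)))
  set.seed(105)
  for (i in 1:20) {
    p <- c(runif(6), runif(4, 0, 0.01))
    rej <- bky_reject(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(rej[bonf]))          # never fewer than Bonferroni
    expect_true(all(p[rej] <= 0.05))     # never more than unadjusted
    # oracle: literal two-stage BH via p.adjust
    q1 <- 0.05 / 1.05
    r1 <- sum(p.adjust(p, "BH") <= q1)
    oracle <- if (r1 == 0) rep(FALSE, 10) else if (r1 == 10) rep(TRUE, 10)
              else p.adjust(p, "BH") <= q1 * 10 / (10 - r1)
    expect_equal(rej, oracle)
  }
})

test_that("Dunn post-hoc flags the separated group in both designs", {
  set.seed(106)
  g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 6))
  tab <- dunn_bky(g, "independent")
  expect_equal(tab$reject, c(FALSE, TRUE, TRUE))  # a-b ns; a-c, b-c sig
  # repeated design: one treatment dominates within every block
  m <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 10)
  tabr <- dunn_bky(m, "repeated")
  expect_true(all(tabr$reject[tabr$pair %in% c("a-c", "b-c")]))
  expect_false(tabr$reject[tabr$pair == "a-b"])
  # decisions monotone in raw p
  o <- order(tab$p_raw)
  expect_true(all(diff(as.integer(tab$reject[o])) <= 0))
})

test_that("repeated-measures ANOVA reproduces design dfs and base aov", {
  r <- rm_anova1(matrix(rnorm(56 * 5), 56, 5))
  expect_equal(r$df, c(4, 220))
  r2 <- rm_anova1(rbind(c(1, 2), c(3, 3)))
  expect_equal(r2$statistic$F, 1)
  set.seed(107)
  m <- matrix(rnorm(24, sd = 2), 6, 4)
  mine <- rm_anova1(m)
  d <- data.frame(y = as.vector(m), subj = factor(rep(1:6, 4)),
                  sess = factor(rep(1:4, each = 6)))
  ref <- summary(aov(y ~ sess + Error(subj), d))[["Error: Within"]][[1]]
  expect_equal(mine$statistic$F, ref["sess", "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref["sess", "Pr(>F)"], tolerance = 1e-10)
  # per-subject constants are absorbed by the subject effect
  shifted <- m + matrix(rep(rnorm(6, sd = 9), 4), 6)
  expect_equal(rm_anova1(shifted)$statistic$F, mine$statistic$F)
  expect_equal(rm_anova1(cbind(c(1, 1), c(1, 1)))$reason,
               "zero_error_variance")
})

test_that("Newman-Keuls steps down through the ordered means", {
  nk0 <- newman_keuls(c(a = 3, b = 3, c = 3), ms_error = 1, df_error = 20,
                      n = 8)
  expect_false(any(nk0$reject))
  nk1 <- newman_keuls(c(a = 0, b = 0.1, c = 100), ms_error = 1,
                      df_error = 20, n = 8)
  expect_true(all(nk1$reject[nk1$pair %in% c("a-c", "b-c")]))
  expect_false(nk1$reject[nk1$pair == "a-b"])
  # oracle: direct studentized-range quantile lookups per stretch
  means <- c(a = 0, b = 1.2, c = 2.1)
  nk <- newman_keuls(means, ms_error = 2, df_error = 18, n = 6)
  se <- sqrt(2 / 6)
  for (row in seq_len(nrow(nk))) {
    if (is.na(nk$q[row])) next
    crit <- qtukey(0.95, nk$stretch[row], 18)
    expect_equal(nk$reject[row], nk$q[row] > crit)
  }
  expect_error(newman_keuls(c(1, 2), 1, 10, n = 1), "n >= 2")
})

test_that("KS statistic is the EDF supremum with asymptotic p", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$statistic$D, 0)
  expect_equal(ks_two_sample(x, c(4, 5, 6))$statistic$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic$D, 0.5)
  set.seed(108)
  a <- rnorm(60); b <- rnorm(60, 0.6)
  mine <- ks_two_sample(a, b)
  ref <- ks.test(a, b, exact = FALSE)
  expect_equal(mine$statistic$D, unname(ref$statistic))
  expect_lt(abs(mine$p_value - ref$p.value), 0.02)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("upper confidence bound is the t-interval bound, monotone in level", {
  expect_equal(upper_conf_bound(c(7, 7, 7)), 7)
  expect_equal(upper_conf_bound(c(0, 0, 100)), 364.1614, tolerance = 1e-4)
  set.seed(109)
  v <- rnorm(15, 40, 12)
  expect_equal(upper_conf_bound(v, 0.99), t.test(v, conf.level = 0.99)$conf.int[2])
  lv <- c(0.8, 0.9, 0.95, 0.99)
  expect_true(all(diff(vapply(lv, function(l) upper_conf_bound(v, l), 1)) > 0))
  expect_error(upper_conf_bound(5), "n >= 2")
})

test_that("two-group reductions order like their omnibus analogues", {
  set.seed(110)
  x <- rnorm(9); y <- rnorm(9, 1.2)
  # KW on 2 groups orders with Mann-Whitney (same ranks, chi-square vs U)
  kw2 <- suppressWarnings(kruskal.test(list(x, y)))
  mw <- mann_whitney_u(x, y, mode = "normal")
  expect_lt(abs(kw2$p.value - mw$p_value), 0.03)
})

test_that("battery holds its nominal type-I error under the null", {
  set.seed(111)
  rej_mw <- mean(replicate(2000, {
    mann_whitney_u(rnorm(10), rnorm(10), mode = "normal")$p_value < 0.05
  }))
  expect_gte(rej_mw, 0.03); expect_lte(rej_mw, 0.07)
  rej_kw <- mean(replicate(1000, {
    kruskal_wallis(list(rnorm(8), rnorm(8), rnorm(8)))$p_value < 0.05
  }))
  expect_gte(rej_kw, 0.03); expect_lte(rej_kw, 0.07)
})
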