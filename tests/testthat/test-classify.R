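test_that("CS-responsiveness test matches the unpaired t-test contract", {
  same <- c(2, 3, 2, 3, 2, 3)
  r <- cs_responsive_test(same, same)
  expect_false(r$responsive)
  expect_equal(r$sign, "none")
  # all-zero baseline vs constant response: exact separation
  r <- cs_responsive_test(rep(5, 135), rep(0, 135))
  expect_true(r$responsive)
  expect_equal(r$sign, "excitatory")
  expect_lt(r$p_value, 1e-10)
  r <- cs_responsive_test(c(0, 1, 0, 1, 0, 0), c(4, 5, 4, 5, 4, 5))
  expect_equal(r$sign, "inhibitory")
  # agreement with stats::t.test on generic counts
  set.seed(71)
  a <- rpois(30, 3); b <- rpois(30, 4)
  expect_equal(cs_responsive_test(a, b)$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("exact ties and short samples follow the error contract", {
  tie <- cs_responsive_test(c(2, 2, 2), c(2, 2, 2))
  expect_true(tie$tie)
  expect_false(tie$responsive)
  expect_error(cs_responsive_test(1, c(1, 2)), ">= 2")
  expect_error(cs_responsive_test(c(-1, 2, 1), c(0, 1, 2)), "negative")
})

make_prof <- function(strong, sign) {
  data.frame(unit_id = "u",
             epoch = c("Hab", "post-Cond", "post-Ext1", "post-Ext2",
                       "post-Ext3"),
             responsive = strong, strong = strong, sign = sign,
             p_value = ifelse(strong, 0.001, 0.5),
             mean_window_z = ifelse(strong, 5, 0),
             stringsAsFactors = FALSE)
}

test_that("typing rules reproduce the fear/extinction definitions", {
  f <- make_prof(c(FALSE, TRUE, FALSE, FALSE, FALSE),
                 c("none", "excitatory", "none", "none", "none"))
  expect_equal(classify_neuron(f)$label, "fear")
  e <- make_prof(c(FALSE, FALSE, TRUE, FALSE, FALSE),
                 c("none", "none", "excitatory", "none", "none"))
  expect_equal(classify_neuron(e)$label, "extinction")
  n <- make_prof(rep(FALSE, 5), rep("none", 5))
  expect_equal(classify_neuron(n)$label, "non_responsive")
  s <- make_prof(c(FALSE, FALSE, FALSE, TRUE, FALSE),
                 c("none", "none", "none", "inhibitory", "none"))
  cs <- classify_neuron(s)
  expect_equal(cs$label, "session_selective")
  expect_equal(cs$selective_epoch, "post-Ext2")
  # inhibitory at post-Cond is not a fear neuron
  i <- make_prof(c(FALSE, TRUE, FALSE, FALSE, FALSE),
                 c("none", "inhibitory", "none", "none", "none"))
  expect_equal(classify_neuron(i)$label, "session_selective")
  expect_error(classify_neuron(f[-1, ]), "missing epoch")
})

test_that("typing permutes with its input units (pure function)", {
  profs <- list(
    make_prof(c(FALSE, TRUE, FALSE, FALSE, FALSE),
              c("none", "excitatory", "none", "none", "none")),
    make_prof(c(FALSE, FALSE, TRUE, FALSE, FALSE),
              c("none", "none", "excitatory", "none", "none")),
    make_prof(rep(FALSE, 5), rep("none", 5)))
  fwd <- vapply(profs, function(p) classify_neuron(p)$label, "")
  rev_ <- vapply(rev(profs), function(p) classify_neuron(p)$label, "")
  expect_equal(rev_, rev(fwd))
})

test_that("latency is the first criterion crossing in the window", {
  zp <- fearext:::new_zpeth("u", "s", seq(0, 80, 20), 20,
                            c(0.5, 3.2, 4.0, 1.0, 0.2), 0, 1,
                            c(-500, 0), 135, FALSE)
  expect_equal(response_latency(zp), 20)
  expect_true(is.na(response_latency(zp, criterion_z = 10)))
  # lowering the criterion never increases latency
  lat_hi <- response_latency(zp, criterion_z = 4)
  lat_lo <- response_latency(zp, criterion_z = 1)
  expect_lte(lat_lo, lat_hi)
  zp$degenerate <- TRUE
  expect_error(response_latency(zp), "degenerate")
})

test_that("sustained-crossing latency skips isolated spurious bins", {
  zp <- fearext:::new_zpeth("u", "s", seq(0, 80, 20), 20,
                            c(0.5, 3.2, 1.0, 3.5, 3.6), 0, 1,
                            c(-500, 0), 135, FALSE)
  expect_equal(response_latency(zp), 20)                       # first crossing
  expect_equal(response_latency(zp, min_consecutive = 2), 60)  # sustained run
  expect_true(is.na(response_latency(zp, min_consecutive = 3)))
})

test_that("composition percentages reproduce the reported arithmetic", {
  labs <- rep(c("fear", "extinction", "session_selective"), c(8, 6, 21))
  cs <- cohort_summary(labs, n_recorded = 130)
  expect_equal(cs$pct_recorded[cs$label == "fear"], 6.15)
  expect_equal(cs$pct_recorded[cs$label == "extinction"], 4.62)
  expect_equal(cs$pct_responsive[cs$label == "fear"], 22.86)
  expect_equal(cs$pct_responsive[cs$label == "extinction"], 17.14)
  w <- testthat::capture_warnings(cohort_summary(character(0), n_recorded = 0))
  expect_true(any(grepl("zero denominator", w)))
  expect_error(cohort_summary(labs, n_recorded = 10), "n_recorded")
})

test_that("profiles built from planted units carry coherent flags", {
  p <- pip_plan()
  ev <- generate_events(p, 81)
  spec <- make_neuron_spec("u", "extinction", p)
  sim <- simulate_unit(spec, p, 81, events = ev, n_snippets = 4)
  prof <- build_profile(sim$spikes, ev, p, unit_id = "u")
  expect_equal(prof$epoch, c("Hab", "post-Cond", "post-Ext1", "post-Ext2",
                             "post-Ext3"))
  # sign is none exactly when not responsive
  expect_true(all((prof$sign == "none") == !prof$responsive))
  # strong implies responsive
  expect_true(all(!prof$strong | prof$responsive))
  expect_true(prof$strong[prof$epoch == "post-Ext1"])
  expect_equal(classify_neuron(prof)$label, "extinction")
})
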