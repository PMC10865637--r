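test_that("wilson interval matches the score-test inversion oracle", {
  for (n in c(5, 30, 100, 2950)) {
    for (k in unique(round(c(0, 1, n / 3, n / 2, n - 1, n)))) {
      got <- wilson_interval(k, n)
      want <- wilson_oracle(k / n, n)
      expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-8)
      expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-8)
    }
  }
  # and the base-R score-test interval agrees too
  pt <- prop.test(29, 100, correct = FALSE)
  got <- wilson_interval(29, 100)
  expect_equal(c(got$lower, got$upper), as.numeric(pt$conf.int), tolerance = 1e-9)
})

test_that("wilson interval closed-form values and boundary clipping", {
  w <- wilson_interval(0.5, 100, estimate = TRUE)
  expect_equal(w$lower, 0.404, tolerance = 1e-3)
  expect_equal(w$upper, 0.596, tolerance = 1e-3)
  expect_equal(wilson_interval(0, 50)$lower, 0)
  expect_equal(wilson_interval(50, 50)$upper, 1)
  expect_error(wilson_interval(5, 0), "n must be")
  expect_error(wilson_interval(1.2, 10, estimate = TRUE), "estimate")
  expect_error(wilson_interval(11, 10), "numerator")
})

test_that("wilson interval invariants: containment, n-monotonicity, reflection", {
  for (p in c(0.1, 0.35, 0.5, 0.9)) {
    w30 <- wilson_interval(p, 30, estimate = TRUE)
    w300 <- wilson_interval(p, 300, estimate = TRUE)
    expect_true(w30$lower <= p && p <= w30$upper)
    expect_lt(w300$upper - w300$lower, w30$upper - w30$lower)
    refl <- wilson_interval(1 - p, 30, estimate = TRUE)
    expect_equal(refl$lower, 1 - w30$upper, tolerance = 1e-12)
    expect_equal(refl$upper, 1 - w30$lower, tolerance = 1e-12)
  }
})

test_that("sample-size calculation reproduces known values and is monotone", {
  expect_equal(as.integer(sample_size_sens_spec(0.45, 0.67, 0.14, 0.5)), 97L)
  expect_equal(as.integer(sample_size_sens_spec(0.8, 0.8, 0.1, 0.5)), 123L)
  # algebraic inversion: precision chosen so that n = 200 is recovered
  n <- 200
  prec <- qnorm(0.975) * 0.5 / sqrt(n * 0.5)
  expect_equal(as.integer(sample_size_sens_spec(0.5, 0.5, prec, 0.5)), n)
  # non-increasing in precision, maximal at se = 0.5
  sizes <- vapply(c(0.05, 0.10, 0.14, 0.20), function(pr)
    as.integer(sample_size_sens_spec(0.45, 0.67, pr, 0.5)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  by_se <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(se)
    attr(sample_size_sens_spec(se, 0.5, 0.1, 0.5), "components")[["n_se"]],
    numeric(1))
  expect_equal(which.max(by_se), 3L)
  expect_error(sample_size_sens_spec(0.5, 0.5, 0, 0.5), "strictly")
})

test_that("perfect and inverted predictions bound the accuracy summary", {
  cases <- make_cases(10, 10)
  parts <- make_participants(c("p1", "p2", "p3"),
                             c("resident", "midwife", "obstetrician_gynecologist"),
                             years = c(1, 3, 10))
  perfect <- make_full_study(cases, parts, function(truth, pid) truth)
  for (g in c("none", "profession", "experience_band")) {
    sm <- summarize_performance(perfect, g)
    ok <- sm$n > 0
    expect_true(all(sm$success_rate[ok] == 1))
    expect_true(all(sm$sensitivity[ok] == 1))
    expect_true(all(sm$specificity[ok] == 1))
  }
  inverted <- make_full_study(cases, parts, function(truth, pid) flip(truth))
  sm <- summarize_performance(inverted, "none")
  expect_equal(sm$success_rate, 0)
  expect_equal(sm$sensitivity, 0)
  expect_equal(sm$specificity, 0)
})

test_that("group successes pool to the total for any disjoint grouping", {
  s <- simulate_study(generator_config(seed = 4))
  for (g in c("profession", "experience_band")) {
    sm <- summarize_performance(s, g)
    grp <- sm[sm$group != "total", ]
    tot <- sm[sm$group == "total", ]
    expect_equal(sum(grp$successes), tot$successes)
    expect_equal(sum(grp$n), tot$n)
    # success numerator splits into the two truth strata
    expect_equal(tot$sensitivity * tot$n_hypoxia + tot$specificity * tot$n_normal,
                 tot$successes)
  }
})

test_that("degenerate strata report undefined metrics, not zero", {
  cases <- make_cases(2, 2)
  parts <- make_participants("p1", "midwife")
  hyp_only <- cases$case_id[cases$true_outcome == "hypoxia"]
  ann <- make_annotations("p1", hyp_only, rep("hypoxia", length(hyp_only)))
  sm <- summarize_performance(as_study(cases, parts, ann), "none")
  expect_equal(sm$specificity, NA_real_)
  expect_equal(sm$sensitivity, 1)
})

test_that("confidence-interval overlap flags separate only disjoint groups", {
  cases <- make_cases(25, 25)
  parts <- make_participants(c("p1", "p2"), c("midwife", "resident"))
  # midwife perfect, resident at chance-like 50%
  pred <- function(truth, pid) if (pid == "p1") truth else
    ifelse(seq_along(truth) %% 2 == 0, truth, flip(truth))
  s <- make_full_study(cases, parts, pred)
  sm <- summarize_performance(s, "profession")
  fl <- flag_group_differences(sm, "success_rate")
  row <- fl[fl$group1 == "resident" & fl$group2 == "midwife" |
            fl$group1 == "midwife" & fl$group2 == "resident", ]
  expect_true(row$distinct)  # 1.0 vs 0.5 on n = 50: CIs disjoint
})

test_that("participant operating points count TPR/FPR and apply the >10 filter", {
  cases <- make_cases(10, 10)
  parts <- make_participants(c("p1", "p2", "p3"),
                             c("midwife", "midwife", "resident"))
  ann <- rbind(
    make_annotations("p1", cases$case_id, cases$true_outcome),         # 20, perfect
    # p2: 6/10 hypoxia correct, 7/10 normal correct
    make_annotations("p2", cases$case_id,
                     c(cases$true_outcome[1:6], flip(cases$true_outcome[7:10]),
                       cases$true_outcome[11:17], flip(cases$true_outcome[18:20]))),
    make_annotations("p3", cases$case_id[1:10], cases$true_outcome[1:10])  # exactly 10
  )
  pts <- participant_points(as_study(cases, parts, ann))
  expect_setequal(pts$participant_id, c("p1", "p2"))   # p3 filtered (not > 10)
  expect_equal(pts$tpr[pts$participant_id == "p1"], 1)
  expect_equal(pts$fpr[pts$participant_id == "p1"], 0)
  expect_equal(pts$tpr[pts$participant_id == "p2"], 0.6)
  expect_equal(pts$fpr[pts$participant_id == "p2"], 0.3)
})

test_that("participants with one-sided exposure are omitted with a reason", {
  parts <- make_participants("p1", "resident")
  cases <- make_cases(1, 11)
  nor <- cases$case_id[cases$true_outcome == "normal"]
  ann <- make_annotations("p1", nor, rep("normal", 11))
  pts <- participant_points(as_study(cases, parts, ann))
  expect_equal(nrow(pts), 0)
  om <- attr(pts, "omitted")
  expect_equal(om$participant_id, "p1")
  expect_match(om$reason, "no hypoxic")
})

test_that("pH bins are right-open, contiguous and cover the line", {
  s <- simulate_study(generator_config(seed = 2))
  bins <- success_by_ph_bin(s)
  expect_equal(nrow(bins), 9)
  expect_equal(bins$bin_lower[1], -Inf)
  expect_equal(bins$bin_upper[9], Inf)
  expect_equal(bins$bin_lower[-1], bins$bin_upper[-9])  # contiguous
  expect_equal(sum(bins$n), nrow(s$annotations))        # every annotation binned once
  expect_error(success_by_ph_bin(s, thresholds = c(7.0, 6.9)), "increasing")

  # half-open convention at an edge: 6.98 and 7.0499 share a bin, 7.05 starts the next
  cases <- data.frame(case_id = c("a", "b", "c"), ph = c(6.98, 7.0499, 7.05),
                      stringsAsFactors = FALSE)
  parts <- make_participants("p1", "midwife")
  ann <- make_annotations("p1", cases$case_id, derive_outcome(cases$ph))
  b <- success_by_ph_bin(as_study(cases, parts, ann))
  expect_equal(b$n[b$bin_lower == 6.98], 2)
  expect_equal(b$n[b$bin_lower == 7.05], 1)
})
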