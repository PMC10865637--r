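# A study where three midwives and two residents each annotate the same
# four cases with fixed votes, giving known majorities and one tie for the
# residents.
agreement_fixture <- function() {
  cases <- make_cases(2, 2)
  parts <- make_participants(c("m1", "m2", "m3", "r1", "r2"),
                             c(rep("midwife", 3), rep("resident", 2)))
  votes <- list(
    m1 = c("hypoxia", "hypoxia", "normal", "normal"),
    m2 = c("hypoxia", "normal",  "normal", "normal"),
    m3 = c("normal",  "hypoxia", "normal", "hypoxia"),
    r1 = c("hypoxia", "normal",  "normal", "hypoxia"),
    r2 = c("hypoxia", "hypoxia", "normal", "normal"))
  ann <- do.call(rbind, lapply(names(votes), function(p)
    make_annotations(p, cases$case_id, votes[[p]])))
  as_study(cases, parts, ann)
}

test_that("consensus is the strict per-case majority; ties follow the policy", {
  s <- agreement_fixture()
  mid <- consensus_by_profession(s, "midwife")
  # tallies: c01 2H/1N, c02 2H/1N, c03 0H/3N, c04 1H/2N
  expect_equal(unname(mid$labels[c("c01", "c02", "c03", "c04")]),
               c("hypoxia", "hypoxia", "normal", "normal"))
  expect_length(mid$tie_cases, 0)

  res <- consensus_by_profession(s, "resident")
  # c02 and c04 are 1/1 ties for the residents
  expect_setequal(res$tie_cases, c("c02", "c04"))
  expect_false(any(c("c02", "c04") %in% names(res$labels)))
  expect_equal(unname(res$labels["c01"]), "hypoxia")

  forced <- consensus_by_profession(s, "resident", tie_policy = "hypoxia")
  expect_equal(unname(forced$labels[c("c02", "c04")]), c("hypoxia", "hypoxia"))
  expect_length(forced$tie_cases, 0)

  # a single annotator is a singleton majority
  one <- make_full_study(make_cases(1, 1), make_participants("x", "resident"),
                         function(truth, pid) c("hypoxia", "hypoxia"))
  cv <- consensus_by_profession(one, "resident")
  expect_equal(unname(cv$labels), c("hypoxia", "hypoxia"))
  expect_error(consensus_by_profession(s, "surgeon"), "unknown profession")
})

test_that("proportion of agreement counts label matches on the overlap", {
  v1 <- make_consensus("midwife",
                       setNames(rep(c("hypoxia", "normal"), 50), sprintf("c%03d", 1:100)))
  expect_equal(proportion_agreement(v1, v1)$estimate, 1.0)

  v2 <- v1; v2$profession <- "resident"
  v2$labels[1:18] <- flip(v2$labels[1:18])
  pa <- proportion_agreement(v1, v2)
  expect_equal(pa$estimate, 0.82)
  expect_equal(pa$n, 100)

  v3 <- v1; v3$labels <- flip(v3$labels)
  expect_equal(proportion_agreement(v1, v3)$estimate, 0.0)

  v4 <- make_consensus("resident", setNames("hypoxia", "zzz"))
  expect_warning(out <- proportion_agreement(v1, v4), "no overlapping")
  expect_null(out)
})

test_that("kappa matches the hand formula on a known 2x2 table", {
  # a=40 (both hypoxia), b=10, c=10, d=40 -> p_o=0.8, p_e=0.5, kappa=0.6
  ids <- sprintf("c%03d", 1:100)
  l1 <- setNames(c(rep("hypoxia", 50), rep("normal", 50)), ids)
  l2 <- setNames(c(rep("hypoxia", 40), rep("normal", 10),
                   rep("hypoxia", 10), rep("normal", 40)), ids)
  k <- cohen_kappa(make_consensus("midwife", l1), make_consensus("resident", l2))
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$kappa, kappa_oracle(40, 10, 10, 40))
  expect_true(k$lower <= 0.6 && 0.6 <= k$upper)
})

test_that("kappa limits: perfect agreement, chance, degenerate marginals", {
  ids <- sprintf("c%03d", 1:60)
  l <- setNames(rep(c("hypoxia", "normal"), 30), ids)
  both <- make_consensus("midwife", l)
  expect_equal(cohen_kappa(both, make_consensus("resident", l))$kappa, 1.0)

  # constant vector vs balanced random labels: kappa tends to 0
  n <- 10000
  ids <- sprintf("k%05d", 1:n)
  const <- make_consensus("midwife", setNames(rep("hypoxia", n), ids))
  rnd <- make_consensus("resident",
    setNames(rep(c("hypoxia", "normal"), n / 2), ids))
  expect_lt(abs(cohen_kappa(const, rnd)$kappa), 0.05)

  # both marginals degenerate: chance agreement is 1, kappa undefined
  k <- cohen_kappa(const, make_consensus("resident", setNames(rep("hypoxia", n), ids)))
  expect_true(is.na(k$kappa))
  expect_match(k$reason, "degenerate")
})

test_that("kappa is invariant under simultaneous label swap and <= p_o", {
  set.seed(31)
  for (i in 1:20) {
    ids <- sprintf("c%03d", 1:80)
    l1 <- setNames(sample(c("hypoxia", "normal"), 80, replace = TRUE), ids)
    l2 <- setNames(ifelse(runif(80) < 0.7, l1, flip(l1)), ids)
    v1 <- make_consensus("midwife", l1); v2 <- make_consensus("resident", l2)
    k <- cohen_kappa(v1, v2)
    ks <- cohen_kappa(make_consensus("midwife", flip(l1)),
                      make_consensus("resident", flip(l2)))
    expect_equal(k$kappa, ks$kappa, tolerance = 1e-12)
    expect_lte(k$kappa, k$p_o + 1e-12)
  }
})

test_that("kappa agrees with an independent library computation", {
  skip_if_not_installed("e1071")
  set.seed(99)
  ids <- sprintf("c%03d", 1:90)
  l1 <- setNames(sample(c("hypoxia", "normal"), 90, replace = TRUE), ids)
  l2 <- setNames(ifelse(runif(90) < 0.6, l1, flip(l1)), ids)
  k <- cohen_kappa(make_consensus("midwife", l1), make_consensus("resident", l2))
  expect_equal(k$kappa, e1071::classAgreement(table(l1, l2))$kappa,
               tolerance = 1e-12)
})

test_that("overall agreement is the overlap-weighted mean of pairwise values", {
  pw <- data.frame(profession1 = c("a", "b"), profession2 = c("b", "c"),
                   n_overlap = c(50, 100), pa = c(0.8, 0.9),
                   kappa = c(0.5, 0.7), stringsAsFactors = FALSE)
  ov <- overall_agreement(pw)
  expect_equal(ov$pa, (0.8 * 50 + 0.9 * 100) / 150)
  expect_equal(ov$pa, 0.8667, tolerance = 1e-4)
  expect_equal(ov$kappa, (0.5 * 50 + 0.7 * 100) / 150)
  # single pair: overall equals that pair
  ov1 <- overall_agreement(pw[1, ])
  expect_equal(ov1$pa, 0.8)
  # equal values: weights are immaterial
  pw$pa <- 0.75; pw$kappa <- 0.4
  ov2 <- overall_agreement(pw)
  expect_equal(ov2$pa, 0.75)
  expect_equal(ov2$kappa, 0.4)
})

test_that("verbal scales follow the printed cut-points with no gaps", {
  expect_equal(classify_agreement(0.82, "altman_pa"), "very_good")
  expect_equal(classify_agreement(0.63, "landis_koch_kappa"), "substantial")
  expect_equal(classify_agreement(0.20, "landis_koch_kappa"), "slight")
  expect_equal(classify_agreement(0.21, "landis_koch_kappa"), "fair")
  grid <- seq(-1, 1, by = 0.005)
  for (sc in c("altman_pa", "landis_koch_kappa")) {
    cls <- classify_agreement(grid, sc)
    expect_false(any(is.na(cls)))             # no gaps
    idx <- as.integer(factor(cls, levels = unique(cls)))
    expect_true(all(diff(idx) >= 0))          # classes change monotonically
    expect_length(unique(cls), 5)
  }
})

test_that("full agreement analysis: CIs contain estimates, bootstrap is seeded", {
  s <- simulate_study(generator_config(seed = 6))
  a1 <- agreement_analysis(s, n_boot = 300, seed = 5)
  a2 <- agreement_analysis(s, n_boot = 300, seed = 5)
  expect_equal(a1$overall, a2$overall)
  a3 <- agreement_analysis(s, n_boot = 300, seed = 6)
  expect_false(identical(a1$overall$pa_lower, a3$overall$pa_lower))

  o <- a1$overall
  expect_true(o$pa_lower <= o$pa && o$pa <= o$pa_upper)
  expect_true(o$kappa_lower <= o$kappa && o$kappa <= o$kappa_upper)
  pw <- a1$pairwise
  expect_true(all(pw$pa_significant == (pw$pa_lower >= 0.5)))
  expect_true(all(pw$kappa <= pw$pa + 1e-12))
})
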