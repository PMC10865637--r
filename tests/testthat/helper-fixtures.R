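# Fixtures built in code: small handmade studies and independent oracles.

# A balanced case table with pH values spread around the 7.15 threshold.
make_cases <- function(n_hyp = 5, n_norm = 5) {
  ph <- c(seq(6.90, 7.14, length.out = n_hyp),
          seq(7.16, 7.40, length.out = n_norm))
  ph <- round(ph, 2)
  data.frame(case_id = sprintf("c%02d", seq_along(ph)), ph = ph,
             true_outcome = derive_outcome(ph), stringsAsFactors = FALSE)
}

make_participants <- function(ids, professions,
                              years = rep(5, length(ids))) {
  data.frame(participant_id = ids, profession = professions,
             years_experience = years,
             setting = "university_hospital", country = "France",
             stringsAsFactors = FALSE)
}

# Annotations where participant `pid` labels the given cases with the given
# predictions, indices 1..k in order.
make_annotations <- function(pid, case_ids, predictions) {
  data.frame(participant_id = pid, case_id = case_ids,
             predicted_outcome = predictions,
             presentation_index = seq_along(case_ids),
             stringsAsFactors = FALSE)
}

# Study where every participant annotates every case, predictions supplied
# per participant as a function of the truth.
make_full_study <- function(cases, participants, predict_fun) {
  ann <- do.call(rbind, lapply(participants$participant_id, function(pid) {
    make_annotations(pid, cases$case_id, predict_fun(cases$true_outcome, pid))
  }))
  as_study(cases, participants, ann)
}

# Consensus vector built directly, for agreement unit tests.
make_consensus <- function(profession, labels, ties = character(0)) {
  structure(list(profession = profession, labels = labels, tie_cases = ties),
            class = "ctg_consensus")
}

flip <- function(labels) ifelse(labels == "hypoxia", "normal", "hypoxia")

# Independent Wilson oracle: invert the score test numerically.  The
# bounds are the two roots in p of (phat - p)^2 = z^2 p(1-p)/n.
wilson_oracle <- function(phat, n, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # g vanishes at phat itself, so root-hunt on intervals that exclude it
  lower <- if (phat == 0) 0 else
    uniroot(g, c(0, if (phat == 1) 1 - 1e-6 else phat), tol = 1e-12)$root
  upper <- if (phat == 1) 1 else
    uniroot(g, c(if (phat == 0) 1e-6 else phat, 1), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Independent kappa oracle from a labelled 2x2 table.
kappa_oracle <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

# Exact distribution of the number of successes of independent Bernoulli
# trials with heterogeneous probabilities (Poisson binomial), by dynamic
# programming; oracle for coverage computations.
poisson_binomial_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}
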