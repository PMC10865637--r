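#' @title Synthetic annotator-cohort generator
#' @description Generates studies with the statistical structure a
#'   CTG observer-performance analysis assumes: a balanced case set around
#'   the hypoxia pH threshold, a mixed-profession cohort with heavy-tailed
#'   participation, and annotations drawn from a two-parameter logistic
#'   rater response model in which the probability of a correct call dips
#'   toward chance for pH near the threshold and rises away from it.
#'   Every draw comes from a stream keyed by (seed, entity id), so
#'   generated tables are fully deterministic and any subset reproducible.
#' @name synthetic_cohort
NULL

#' Generator configuration
#'
#' All tunables of the synthetic cohort, with defaults matching a
#' 120-reader, 100-case study: 50/50 hypoxia/normal split at pH 7.15,
#' professions 39 residents / 23 midwives / 58 obstetrician-gynecologists,
#' and a participation mixture (point mass of completers plus a truncated
#' log-normal) giving a median near 11 annotations with quartiles near
#' 5 and 36.
#'
#' @param seed integer master seed; every stream is keyed from it.
#' @param n_cases even number of cases (default 100).
#' @param threshold hypoxia pH threshold (default 7.15).
#' @param ph_mean,ph_sd,ph_range truncated-normal pH distribution
#'   (defaults: mean 7.20, sd 0.12, truncated to \[6.85, 7.47\]), sampled
#'   separately below/above the threshold to force the balanced split.
#' @param n_participants cohort size (default 120).
#' @param profession_counts named integer vector over the three
#'   professions; must sum to \code{n_participants}.
#' @param n_student_midwives midwives flagged as students (stored as
#'   midwives with a provenance flag; default 2).
#' @param experience_probs mixture over the four experience bands.
#' @param bias_mean,bias_sd normal distribution of the rater bias
#'   \code{a} (log-odds offset toward calling hypoxia).
#' @param discrimination_median,discrimination_sdlog log-normal
#'   distribution of the rater discrimination \code{b} (log-odds per pH
#'   unit; defaults: median 8, sdlog 0.5).
#' @param p_complete probability a participant annotates all cases
#'   (default 0.10).
#' @param participation_median,participation_sdlog log-normal number of
#'   annotations for non-completers (defaults: median 9, sdlog 1.1),
#'   truncated to \[1, n_cases - 1\].
#' @param p_university,p_home_country probabilities of a university
#'   setting and of the modal country.
#' @return list of class \code{ctg_gen_config}.
#' @export
generator_config <- function(seed = 1,
                             n_cases = 100,
                             threshold = 7.15,
                             ph_mean = 7.20, ph_sd = 0.12,
                             ph_range = c(6.85, 7.47),
                             n_participants = 120,
                             profession_counts = c(resident = 39, midwife = 23,
                                                   obstetrician_gynecologist = 58),
                             n_student_midwives = 2,
                             experience_probs = c("0-2" = 0.30, "2-4" = 0.20,
                                                  "4-8" = 0.20, ">8" = 0.30),
                             bias_mean = 0, bias_sd = 0.4,
                             discrimination_median = 8,
                             discrimination_sdlog = 0.5,
                             p_complete = 0.10,
                             participation_median = 9,
                             participation_sdlog = 1.1,
                             p_university = 0.84,
                             p_home_country = 0.78) {
  if (n_cases %% 2 != 0) stop("n_cases must be even")
  if (!setequal(names(profession_counts), PROFESSIONS)) {
    stop("profession_counts must be named over: ", paste(PROFESSIONS, collapse = ", "))
  }
  if (sum(profession_counts) != n_participants) {
    stop("profession_counts must sum to n_participants (",
         sum(profession_counts), " != ", n_participants, ")")
  }
  if (ph_range[1] >= threshold || ph_range[2] <= threshold) {
    stop("ph_range must straddle the threshold")
  }
  structure(as.list(environment()), class = "ctg_gen_config")
}

#' Generate a balanced synthetic case set
#'
#' Draws \code{n_cases/2} pH values from the truncated normal restricted
#' below the threshold and \code{n_cases/2} restricted to/above it, so the
#' hypoxia/normal split is exactly balanced.  pH is rounded to 2 decimals
#' (the resolution of cord blood gas reports); rounding never crosses the
#' threshold.
#'
#' @param config a \code{ctg_gen_config}.
#' @return data frame of cases with \code{case_id}, \code{ph},
#'   \code{true_outcome}.
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "ctg_gen_config"))
  half <- config$n_cases / 2
  ph_lo <- with_seed(keyed_seed(config$seed, "cases", "hypoxia"),
    rtruncnorm(half, config$ph_mean, config$ph_sd,
               config$ph_range[1], config$threshold - 1e-9))
  ph_hi <- with_seed(keyed_seed(config$seed, "cases", "normal"),
    rtruncnorm(half, config$ph_mean, config$ph_sd,
               config$threshold, config$ph_range[2]))
  # keep rounded values on their side of the threshold
  ph_lo <- pmin(round(ph_lo, 2), round(config$threshold - 0.01, 2))
  ph_hi <- pmax(round(ph_hi, 2), config$threshold)
  ph <- c(ph_lo, ph_hi)
  data.frame(
    case_id = sprintf("case_%03d", seq_len(config$n_cases)),
    ph = ph,
    true_outcome = derive_outcome(ph, config$threshold),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic participant cohort with latent rater models
#'
#' Professions are assigned to match \code{profession_counts} exactly;
#' each participant receives latent response parameters (bias \code{a},
#' discrimination \code{b}) and a planned number of annotations from the
#' participation mixture: with probability \code{p_complete} all cases,
#' otherwise a truncated log-normal.
#'
#' @param config a \code{ctg_gen_config}.
#' @return list with \code{participants} (a participants table) and
#'   \code{raters} (per participant: \code{a}, \code{b},
#'   \code{planned_annotations}).
#' @export
generate_raters <- function(config) {
  stopifnot(inherits(config, "ctg_gen_config"))
  counts <- config$profession_counts[PROFESSIONS]
  profession <- rep(PROFESSIONS, times = counts)
  n <- config$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  draw <- function(label, expr_fun) {
    vapply(seq_len(n), function(i) {
      with_seed(keyed_seed(config$seed, label, ids[i]), expr_fun())
    }, numeric(1))
  }
  band <- EXPERIENCE_BANDS[vapply(seq_len(n), function(i) {
    with_seed(keyed_seed(config$seed, "band", ids[i]),
              sample.int(4, 1, prob = config$experience_probs[EXPERIENCE_BANDS]))
  }, integer(1))]
  lo <- c(`0-2` = 0, `2-4` = 2, `4-8` = 4, `>8` = 8)[band]
  hi <- c(`0-2` = 2, `2-4` = 4, `4-8` = 8, `>8` = 25)[band]
  years <- round(lo + draw("years", function() stats::runif(1)) * (hi - lo), 1)
  # guard the right-open band edges after rounding
  years <- pmin(years, hi - 0.1)

  a <- draw("bias", function() stats::rnorm(1, config$bias_mean, config$bias_sd))
  b <- draw("disc", function()
    stats::rlnorm(1, log(config$discrimination_median), config$discrimination_sdlog))
  k <- vapply(seq_len(n), function(i) {
    with_seed(keyed_seed(config$seed, "partic", ids[i]), {
      if (stats::runif(1) < config$p_complete) config$n_cases
      else {
        x <- round(stats::rlnorm(1, log(config$participation_median),
                                 config$participation_sdlog))
        min(max(x, 1), config$n_cases - 1)
      }
    })
  }, numeric(1))
  setting <- ifelse(draw("setting", function() stats::runif(1)) < config$p_university,
                    "university_hospital", "general_hospital")
  country <- ifelse(draw("country", function() stats::runif(1)) < config$p_home_country,
                    "France", "other")
  student <- logical(n)
  midwives <- which(profession == "midwife")
  student[utils::head(midwives, config$n_student_midwives)] <- TRUE

  list(
    participants = data.frame(
      participant_id = ids, profession = profession,
      years_experience = years, setting = setting, country = country,
      student_midwife = student, stringsAsFactors = FALSE),
    raters = data.frame(
      participant_id = ids, a = a, b = b,
      planned_annotations = as.integer(k), stringsAsFactors = FALSE))
}

#' Probability a rater calls "hypoxia" on a case
#'
#' The latent response model: \eqn{P(\mathrm{hypoxia}) =
#' \sigma(a + b(\tau - \mathrm{pH}))} with \eqn{\sigma} the standard
#' logistic.  Far below the threshold the call is almost surely hypoxia,
#' far above almost surely normal, and at the threshold it approaches a
#' (bias-shifted) coin flip — reproducing the dip of observed success
#' rates toward chance for cases near the decision boundary.
#'
#' @param ph case pH (vectorized).
#' @param a rater bias (log-odds offset toward hypoxia).
#' @param b rater discrimination (log-odds per pH unit, >= 0).
#' @param threshold pH threshold (default 7.15).
#' @return probability of predicting hypoxia.
#' @export
rater_response <- function(ph, a, b, threshold = 7.15) {
  stats::plogis(a + b * (threshold - ph))
}

#' Simulate annotations for a cohort on a case set
#'
#' Each rater receives the presentation sequence of the shared batch plan
#' truncated to their planned number of annotations, and predicts hypoxia
#' with probability [rater_response()].  The prediction draw for a
#' (participant, case) pair comes from its own keyed stream, so any
#' subset of the table is reproducible.
#'
#' @param cases case table (from [generate_cases()] or a study).
#' @param raters list from [generate_raters()], or a data frame shaped
#'   like its \code{raters} element joined with \code{participants}.
#' @param config a \code{ctg_gen_config} (supplies the seed and
#'   threshold).
#' @return annotations data frame (\code{participant_id}, \code{case_id},
#'   \code{predicted_outcome}, \code{presentation_index}).
#' @export
simulate_annotations <- function(cases, raters, config) {
  stopifnot(inherits(config, "ctg_gen_config"))
  rt <- if (is.data.frame(raters)) raters else raters$raters
  plan <- build_batch_plan(cases, config$seed)
  ph_of <- stats::setNames(cases$ph, cases$case_id)
  out <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    pid <- rt$participant_id[i]
    k <- rt$planned_annotations[i]
    seq_i <- presentation_sequence(plan, pid, k, config$seed)
    u <- vapply(seq_i, function(cid)
      keyed_runif(1, config$seed, "pred", pid, cid), numeric(1))
    p_hyp <- rater_response(ph_of[seq_i], rt$a[i], rt$b[i], config$threshold)
    out[[i]] <- data.frame(
      participant_id = pid, case_id = seq_i,
      predicted_outcome = ifelse(u < p_hyp, "hypoxia", "normal"),
      presentation_index = seq_len(k), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic study
#'
#' Cases, cohort and annotations in one call; the latent rater parameters
#' are attached as attribute \code{"truth"} for parameter-recovery
#' experiments.
#'
#' @param config a \code{ctg_gen_config}; see [generator_config()].
#' @return a \code{ctg_study} with attribute \code{"truth"} (the raters
#'   table of latent parameters).
#' @export
simulate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "ctg_gen_config"))
  cases <- generate_cases(config)
  cohort <- generate_raters(config)
  ann <- simulate_annotations(cases, cohort, config)
  study <- as_study(cases, cohort$participants, ann,
                    threshold = config$threshold)
  attr(study, "truth") <- cohort$raters
  study
}

#' Recover rater parameters from a simulated study
#'
#' Per rater: empirical sensitivity and specificity with Wilson intervals,
#' and — for raters with at least \code{min_fit} annotations — a
#' maximum-likelihood logistic fit of the response model
#' \eqn{\sigma(a + b(\tau - pH))} via \code{glm}.  When the generating
#' parameters are supplied, truth columns are joined in for comparison.
#'
#' @param study a \code{ctg_study}.
#' @param truth optional raters table of generating parameters (columns
#'   \code{participant_id}, \code{a}, \code{b}); defaults to the study's
#'   \code{"truth"} attribute.
#' @param min_fit minimum annotations for the logistic fit (default 30);
#'   raters below it keep \code{NA} fits and are listed in attribute
#'   \code{"not_fitted"}.
#' @param level confidence level for the Wilson intervals.
#' @return data frame, one row per rater: annotation counts, empirical
#'   \code{se}/\code{sp} with CI bounds, fitted \code{a_hat}/\code{b_hat},
#'   and \code{a_true}/\code{b_true} when truth is available.
#' @export
recover_rater_parameters <- function(study, truth = attr(study, "truth"),
                                     min_fit = 30, level = 0.95) {
  stopifnot(inherits(study, "ctg_study"))
  af <- annotation_frame(study)
  tau <- study$threshold
  not_fitted <- character(0)
  rows <- lapply(unique(af$participant_id), function(pid) {
    d <- af[af$participant_id == pid, ]
    hyp <- d[d$true_outcome == "hypoxia", ]
    nor <- d[d$true_outcome == "normal", ]
    se <- prop_row(sum(hyp$correct), nrow(hyp), level)
    sp <- prop_row(sum(nor$correct), nrow(nor), level)
    a_hat <- b_hat <- NA_real_
    if (nrow(d) >= min_fit) {
      fit <- suppressWarnings(stats::glm(
        I(predicted_outcome == "hypoxia") ~ I(tau - ph),
        family = stats::binomial(), data = d))
      a_hat <- unname(stats::coef(fit)[1])
      b_hat <- unname(stats::coef(fit)[2])
    } else {
      not_fitted <<- c(not_fitted, pid)
    }
    data.frame(participant_id = pid, n_annotations = nrow(d),
               n_hypoxia = nrow(hyp), n_normal = nrow(nor),
               se = se$estimate, se_lower = se$lower, se_upper = se$upper,
               sp = sp$estimate, sp_lower = sp$lower, sp_upper = sp$upper,
               a_hat = a_hat, b_hat = b_hat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    m <- match(out$participant_id, truth$participant_id)
    out$a_true <- truth$a[m]
    out$b_true <- truth$b[m]
  }
  rownames(out) <- NULL
  attr(out, "not_fitted") <- not_fitted
  out
}
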