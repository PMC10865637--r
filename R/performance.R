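#' @title Diagnostic accuracy of outcome predictions
#' @description Success rate, sensitivity and specificity of the pooled
#'   annotations, with Wilson score confidence intervals, stratified by
#'   profession or experience band; per-participant TPR/FPR operating
#'   points; success rate by pH range; and the sample-size calculation for
#'   a sensitivity/specificity study.
#' @name performance
NULL

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: with \eqn{z} the standard-normal quantile at
#' \eqn{(1+level)/2}, the interval is centred at
#' \eqn{(\hat p + z^2/2n) / (1 + z^2/n)} with half-width
#' \eqn{z/(1+z^2/n)\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}, clipped to
#' \[0,1\].  Better behaved than the Wald interval at extreme proportions
#' or small n.
#'
#' @param x numerator (count of successes, 0..n), or a proportion in
#'   \[0,1\] when \code{estimate = TRUE}.  Vectorized.
#' @param n number of trials (>= 1).
#' @param level two-sided confidence level, default 0.95.
#' @param estimate if \code{TRUE}, interpret \code{x} as the point
#'   estimate rather than a count.
#' @return data frame of class \code{ctg_prop_ci} with columns
#'   \code{estimate}, \code{numerator}, \code{n}, \code{level},
#'   \code{lower}, \code{upper}.
#' @examples
#' wilson_interval(0.58, n = 2950, estimate = TRUE)  # bounds 0.56-0.60
#' @export
wilson_interval <- function(x, n, level = 0.95, estimate = FALSE) {
  stopifnot(is.numeric(x), is.numeric(n), level > 0, level < 1)
  if (any(n < 1)) stop("n must be >= 1")
  if (estimate) {
    if (any(x < 0 | x > 1)) stop("estimate must lie in [0, 1]")
    p <- x
    num <- rep(NA_real_, length(p))
  } else {
    if (any(x < 0 | x > n)) stop("numerator must lie in 0..n")
    p <- x / n
    num <- x
  }
  z <- stats::qnorm((1 + level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  out <- data.frame(estimate = p, numerator = num, n = n, level = level,
                    lower = pmax(0, centre - half),
                    upper = pmin(1, centre + half))
  class(out) <- c("ctg_prop_ci", "data.frame")
  out
}

prop_row <- function(k, n, level) {
  if (is.na(n) || n == 0) {
    return(data.frame(estimate = NA_real_, numerator = NA_real_, n = 0,
                      level = level, lower = NA_real_, upper = NA_real_))
  }
  as.data.frame(wilson_interval(k, n, level))
}

#' Stratified accuracy summary
#'
#' For each group (or for all annotations pooled): the success rate over
#' all annotations, sensitivity over annotations of truly hypoxic cases,
#' and specificity over annotations of truly normal cases, each with a
#' Wilson interval.  Metrics pool annotations, not participant averages.
#' Strata with no hypoxic (or no normal) annotations report the affected
#' metric as \code{NA}.
#'
#' @param study a \code{ctg_study}.
#' @param grouping one of \code{"none"}, \code{"profession"},
#'   \code{"experience_band"}.
#' @param level confidence level for all intervals.
#' @return data frame of class \code{ctg_performance}, one row per group
#'   plus (for grouped summaries) a pooled \code{"total"} row; columns
#'   \code{group}, then \code{n}/\code{successes}/\code{success_rate}/CI
#'   bounds, and likewise for sensitivity and specificity.
#' @export
summarize_performance <- function(study,
                                  grouping = c("none", "profession", "experience_band"),
                                  level = 0.95) {
  stopifnot(inherits(study, "ctg_study"))
  grouping <- match.arg(grouping)
  af <- annotation_frame(study)
  if (!nrow(af)) stop("study has no annotations")
  groups <- switch(grouping,
    none = list(total = af),
    profession = split(af, factor(af$profession, levels = PROFESSIONS)),
    experience_band = split(af, factor(af$experience_band, levels = EXPERIENCE_BANDS)))
  if (grouping != "none") groups <- c(groups, list(total = af))

  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    hyp <- d[d$true_outcome == "hypoxia", ]
    nor <- d[d$true_outcome == "normal", ]
    sr <- prop_row(sum(d$correct), nrow(d), level)
    se <- prop_row(sum(hyp$correct), nrow(hyp), level)
    sp <- prop_row(sum(nor$correct), nrow(nor), level)
    data.frame(group = g,
               n = nrow(d), successes = sum(d$correct),
               success_rate = sr$estimate, success_lower = sr$lower,
               success_upper = sr$upper,
               n_hypoxia = nrow(hyp),
               sensitivity = se$estimate, sensitivity_lower = se$lower,
               sensitivity_upper = se$upper,
               n_normal = nrow(nor),
               specificity = sp$estimate, specificity_lower = sp$lower,
               specificity_upper = sp$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "grouping") <- grouping
  class(out) <- c("ctg_performance", "data.frame")
  out
}

#' @export
print.ctg_performance <- function(x, digits = 2, ...) {
  cat(sprintf("Accuracy summary (grouping: %s, %g%% Wilson CIs)\n",
              attr(x, "grouping"), 100 * attr(x, "level")))
  fmt <- function(e, l, u) ifelse(is.na(e), "-",
    sprintf("%.*f (%.*f, %.*f)", digits, e, digits, l, digits, u))
  print(data.frame(group = x$group, n = x$n,
                   success = fmt(x$success_rate, x$success_lower, x$success_upper),
                   sensitivity = fmt(x$sensitivity, x$sensitivity_lower, x$sensitivity_upper),
                   specificity = fmt(x$specificity, x$specificity_lower, x$specificity_upper)),
        row.names = FALSE)
  invisible(x)
}

#' Flag pairwise group differences by confidence-interval overlap
#'
#' Two groups are flagged as different on a metric when their confidence
#' intervals do not overlap.  This is the screening heuristic used in
#' observer-performance reports, not a formal hypothesis test.  Groups
#' with an undefined metric are excluded.
#'
#' @param perf a \code{ctg_performance} table from
#'   [summarize_performance()].
#' @param metric one of \code{"success_rate"}, \code{"sensitivity"},
#'   \code{"specificity"}.
#' @return data frame with one row per unordered group pair (the pooled
#'   total row excluded) and a logical column \code{distinct}.
#' @export
flag_group_differences <- function(perf,
                                   metric = c("success_rate", "sensitivity", "specificity")) {
  stopifnot(inherits(perf, "ctg_performance"))
  metric <- match.arg(metric)
  pre <- c(success_rate = "success", sensitivity = "sensitivity",
           specificity = "specificity")[[metric]]
  d <- perf[perf$group != "total" & !is.na(perf[[metric]]), ]
  if (nrow(d) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      distinct = logical()))
  }
  pairs <- utils::combn(seq_len(nrow(d)), 2)
  data.frame(
    group1 = d$group[pairs[1, ]],
    group2 = d$group[pairs[2, ]],
    distinct = d[[paste0(pre, "_lower")]][pairs[1, ]] > d[[paste0(pre, "_upper")]][pairs[2, ]] |
               d[[paste0(pre, "_lower")]][pairs[2, ]] > d[[paste0(pre, "_upper")]][pairs[1, ]],
    stringsAsFactors = FALSE)
}

#' Per-participant operating points (TPR vs FPR)
#'
#' One point per participant with strictly more than \code{min_annotations}
#' annotations: TPR = correct hypoxia calls / hypoxic cases seen, FPR =
#' 1 - correct normal calls / normal cases seen.  Participants who saw no
#' hypoxic (or no normal) case are omitted; their ids and the reason are
#' attached as attribute \code{"omitted"}.
#'
#' @param study a \code{ctg_study}.
#' @param min_annotations inclusion cut-off; a participant is kept only
#'   with more than this many annotations (default 10).
#' @return data frame with columns \code{participant_id}, \code{tpr},
#'   \code{fpr}, \code{n_annotations}.
#' @export
participant_points <- function(study, min_annotations = 10) {
  stopifnot(inherits(study, "ctg_study"))
  af <- annotation_frame(study)
  omitted <- data.frame(participant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (pid in unique(af$participant_id)) {
    d <- af[af$participant_id == pid, ]
    if (nrow(d) <= min_annotations) next
    hyp <- d[d$true_outcome == "hypoxia", ]
    nor <- d[d$true_outcome == "normal", ]
    if (!nrow(hyp) || !nrow(nor)) {
      omitted <- rbind(omitted, data.frame(
        participant_id = pid,
        reason = if (!nrow(hyp)) "no hypoxic case seen" else "no normal case seen",
        stringsAsFactors = FALSE))
      next
    }
    rows[[pid]] <- data.frame(
      participant_id = pid,
      tpr = sum(hyp$correct) / nrow(hyp),
      fpr = 1 - sum(nor$correct) / nrow(nor),
      n_annotations = nrow(d),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), tpr = numeric(),
               fpr = numeric(), n_annotations = integer())
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Success rate by pH range
#'
#' Bins annotations by their case's pH into the half-open ranges
#' \eqn{(-\infty, t_1), [t_1, t_2), \ldots, [t_k, \infty)} and reports the
#' per-bin success rate with a Wilson interval.  The default thresholds
#' are chosen so real-world case sets spread roughly evenly across bins.
#'
#' @param study a \code{ctg_study}.
#' @param thresholds strictly increasing numeric vector of bin edges.
#' @param level confidence level.
#' @return data frame with columns \code{bin_lower}, \code{bin_upper}
#'   (\code{-Inf}/\code{Inf} at the ends), \code{n}, \code{successes},
#'   \code{success_rate}, \code{lower}, \code{upper}.
#' @export
success_by_ph_bin <- function(study,
                              thresholds = c(6.90, 6.98, 7.05, 7.13, 7.20, 7.28, 7.35, 7.43),
                              level = 0.95) {
  stopifnot(inherits(study, "ctg_study"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  af <- annotation_frame(study)
  edges <- c(-Inf, thresholds, Inf)
  # right-open bins: annotation with ph == t_i falls in [t_i, t_{i+1})
  bin <- findInterval(af$ph, thresholds) + 1L
  rows <- lapply(seq_len(length(edges) - 1), function(b) {
    d <- af[bin == b, ]
    pr <- prop_row(sum(d$correct), nrow(d), level)
    data.frame(bin_lower = edges[b], bin_upper = edges[b + 1],
               n = nrow(d), successes = sum(d$correct),
               success_rate = pr$estimate, lower = pr$lower, upper = pr$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample size for a sensitivity/specificity study
#'
#' Buderer-type calculation: the number of cases needed so that the
#' half-width of the usual normal-approximation interval around an
#' anticipated sensitivity (and specificity) does not exceed
#' \code{precision}, given the prevalence of the target condition:
#' \deqn{n_{se} = z^2 se(1-se) / (precision^2 \cdot prevalence), \quad
#'       n_{sp} = z^2 sp(1-sp) / (precision^2 (1-prevalence))}
#' The larger of the two is returned, rounded to the nearest integer.
#'
#' @param se,sp anticipated sensitivity and specificity, in (0,1).
#' @param precision maximum acceptable confidence-interval half-width.
#' @param prevalence expected prevalence of the condition, in (0,1).
#' @param level confidence level, default 0.95.
#' @return integer number of cases; the unrounded per-metric requirements
#'   are attached as attribute \code{"components"}.
#' @examples
#' sample_size_sens_spec(se = 0.45, sp = 0.67, precision = 0.14,
#'                       prevalence = 0.5)  # 97
#' @export
sample_size_sens_spec <- function(se, sp, precision, prevalence, level = 0.95) {
  vals <- c(se = se, sp = sp, precision = precision, prevalence = prevalence)
  if (any(vals <= 0 | vals >= 1)) {
    stop("se, sp, precision and prevalence must all lie strictly in (0, 1)")
  }
  z <- stats::qnorm((1 + level) / 2)
  n_se <- z^2 * se * (1 - se) / (precision^2 * prevalence)
  n_sp <- z^2 * sp * (1 - sp) / (precision^2 * (1 - prevalence))
  structure(as.integer(round(max(n_se, n_sp))),
            components = c(n_se = n_se, n_sp = n_sp))
}
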