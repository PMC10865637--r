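#' @title Consensus-based interobserver agreement and reliability
#' @description Per-profession consensus labels (majority vote), pairwise
#'   proportion of agreement (PA) and Cohen's kappa on overlapping cases,
#'   overlap-weighted overall values with a seeded case-level bootstrap,
#'   and the conventional verbal classifications (Altman for PA,
#'   Landis-Koch for kappa).
#' @name agreement
NULL

#' Majority-vote consensus labels for one profession
#'
#' For every case annotated by at least one participant of the profession,
#' the consensus is the label given by the strict majority of that
#' profession's annotators of the case.  Exact ties are handled by
#' \code{tie_policy}: excluded from the consensus vector (a tie is not a
#' consensus), or resolved to a fixed label.
#'
#' @param study a \code{ctg_study}.
#' @param profession one of \code{"resident"}, \code{"midwife"},
#'   \code{"obstetrician_gynecologist"}.
#' @param tie_policy \code{"exclude"} (default), \code{"hypoxia"} or
#'   \code{"normal"}.
#' @return object of class \code{ctg_consensus}: list with
#'   \code{profession}, \code{labels} (named character vector,
#'   case_id -> label) and \code{tie_cases} (character vector of excluded
#'   tied cases; empty unless \code{tie_policy = "exclude"}).
#' @export
consensus_by_profession <- function(study, profession,
                                    tie_policy = c("exclude", "hypoxia", "normal")) {
  stopifnot(inherits(study, "ctg_study"))
  tie_policy <- match.arg(tie_policy)
  if (!profession %in% PROFESSIONS) {
    stop("unknown profession: ", profession)
  }
  af <- annotation_frame(study)
  d <- af[af$profession == profession, ]
  labels <- character(0)
  ties <- character(0)
  for (cid in unique(d$case_id)) {
    votes <- d$predicted_outcome[d$case_id == cid]
    n_hyp <- sum(votes == "hypoxia")
    n_nor <- length(votes) - n_hyp
    if (n_hyp == n_nor) {
      if (tie_policy == "exclude") {
        ties <- c(ties, cid)
        next
      }
      labels[cid] <- tie_policy
    } else {
      labels[cid] <- if (n_hyp > n_nor) "hypoxia" else "normal"
    }
  }
  structure(list(profession = profession, labels = labels, tie_cases = ties),
            class = "ctg_consensus")
}

overlap_labels <- function(v1, v2) {
  shared <- intersect(names(v1$labels), names(v2$labels))
  list(cases = shared, l1 = unname(v1$labels[shared]), l2 = unname(v2$labels[shared]))
}

#' Proportion of agreement between two consensus vectors
#'
#' The fraction of jointly covered cases on which the two consensus
#' vectors give the same label, with a Wilson interval.
#'
#' @param v1,v2 \code{ctg_consensus} objects (see
#'   [consensus_by_profession()]).
#' @param level confidence level.
#' @return one-row \code{ctg_prop_ci} data frame, or \code{NULL} (with a
#'   warning) when the vectors share no case.
#' @export
proportion_agreement <- function(v1, v2, level = 0.95) {
  ov <- overlap_labels(v1, v2)
  if (!length(ov$cases)) {
    warning("no overlapping cases between ", v1$profession, " and ",
            v2$profession, "; agreement undefined")
    return(NULL)
  }
  wilson_interval(sum(ov$l1 == ov$l2), length(ov$cases), level)
}

# kappa from agreement counts on overlapping cases; a..d is the 2x2 table
# (rows = v1 hypoxia/normal, cols = v2 hypoxia/normal).
kappa_from_table <- function(a, b, c_, d, level) {
  n <- a + b + c_ + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (p_e >= 1) {
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                n = n, p_o = p_o, p_e = p_e,
                reason = "both marginals degenerate (chance agreement 1)"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o)) / ((1 - p_e) * sqrt(n))
  z <- stats::qnorm((1 + level) / 2)
  list(kappa = kappa, lower = max(-1, kappa - z * se),
       upper = min(1, kappa + z * se), n = n, p_o = p_o, p_e = p_e,
       reason = NA_character_)
}

#' Cohen's kappa between two consensus vectors
#'
#' Chance-corrected agreement on the overlapping cases:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} from the 2x2 cross-tabulation,
#' with a large-sample confidence interval using
#' \eqn{SE = \sqrt{p_o(1-p_o)} / ((1-p_e)\sqrt{N})}, clipped to \[-1, 1\].
#' Kappa is sensitive to label prevalence: with rare positives it can be
#' near zero despite high raw agreement.
#'
#' @inheritParams proportion_agreement
#' @return list with \code{kappa}, \code{lower}, \code{upper}, \code{n},
#'   \code{p_o}, \code{p_e}; \code{kappa} is \code{NA} with a
#'   \code{reason} when both marginals are degenerate.
#' @export
cohen_kappa <- function(v1, v2, level = 0.95) {
  ov <- overlap_labels(v1, v2)
  if (!length(ov$cases)) {
    warning("no overlapping cases between ", v1$profession, " and ",
            v2$profession, "; kappa undefined")
    return(NULL)
  }
  kappa_from_table(sum(ov$l1 == "hypoxia" & ov$l2 == "hypoxia"),
                   sum(ov$l1 == "hypoxia" & ov$l2 == "normal"),
                   sum(ov$l1 == "normal" & ov$l2 == "hypoxia"),
                   sum(ov$l1 == "normal" & ov$l2 == "normal"),
                   level)
}

#' Verbal classification of an agreement or reliability value
#'
#' Applies the conventional cut-points: the Altman scale for PA
#' (poor / fair / moderate / good / very good) or the Landis-Koch scale
#' for kappa (slight / fair / moderate / substantial / almost perfect).
#' Both scales change class above 0.20, 0.40, 0.60 and 0.80; values are
#' rounded to 2 decimals before classification so that quantities in the
#' unprinted gaps between ranges (e.g. 0.805) classify deterministically.
#'
#' @param value numeric in \[-1, 1\] (PA values are in \[0, 1\]).
#' @param scale \code{"altman_pa"} or \code{"landis_koch_kappa"}.
#' @return character class label; vectorized over \code{value}.
#' @examples
#' classify_agreement(0.82, "altman_pa")          # "very_good"
#' classify_agreement(0.63, "landis_koch_kappa")  # "substantial"
#' @export
classify_agreement <- function(value, scale = c("altman_pa", "landis_koch_kappa")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(value), all(value >= -1 & value <= 1))
  v <- round(value, 2)
  labels <- switch(scale,
    altman_pa = c("poor", "fair", "moderate", "good", "very_good"),
    landis_koch_kappa = c("slight", "fair", "moderate", "substantial", "almost_perfect"))
  labels[findInterval(v, c(0.21, 0.41, 0.61, 0.81)) + 1L]
}

#' Pairwise agreement and reliability between professions
#'
#' Builds each profession's consensus vector and computes PA and kappa for
#' every unordered pair on their overlapping cases, with verbal classes
#' and the PA significance flag (agreement is regarded as non-significant
#' when the lower bound of the PA interval falls below 0.50).
#'
#' @param study a \code{ctg_study}.
#' @param tie_policy consensus tie handling; see
#'   [consensus_by_profession()].
#' @param level confidence level.
#' @return data frame with one row per profession pair with at least one
#'   overlapping case: \code{profession1}, \code{profession2},
#'   \code{n_overlap}, PA estimate/CI/class/significance and kappa
#'   estimate/CI/class.  The consensus vectors are attached as attribute
#'   \code{"consensus"}.
#' @export
pairwise_agreement <- function(study, tie_policy = "exclude", level = 0.95) {
  stopifnot(inherits(study, "ctg_study"))
  present <- intersect(PROFESSIONS, unique(study$participants$profession))
  cons <- lapply(present, consensus_by_profession, study = study,
                 tie_policy = tie_policy)
  names(cons) <- present
  if (length(present) < 2) stop("need at least two professions with annotations")
  pairs <- utils::combn(present, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    v1 <- cons[[pairs[1, j]]]
    v2 <- cons[[pairs[2, j]]]
    ov <- overlap_labels(v1, v2)
    if (!length(ov$cases)) {
      warning("pair ", v1$profession, "/", v2$profession,
              " shares no case; dropped from the agreement table")
      next
    }
    pa <- proportion_agreement(v1, v2, level)
    ka <- cohen_kappa(v1, v2, level)
    rows[[j]] <- data.frame(
      profession1 = v1$profession, profession2 = v2$profession,
      n_overlap = length(ov$cases),
      pa = pa$estimate, pa_lower = pa$lower, pa_upper = pa$upper,
      pa_class = classify_agreement(pa$estimate, "altman_pa"),
      pa_significant = pa$lower >= 0.50,
      kappa = ka$kappa, kappa_lower = ka$lower, kappa_upper = ka$upper,
      kappa_class = if (is.na(ka$kappa)) NA_character_ else
        classify_agreement(ka$kappa, "landis_koch_kappa"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no profession pair shares any case")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "consensus") <- cons
  attr(out, "level") <- level
  out
}

#' Overlap-weighted overall agreement
#'
#' Pools pairwise PA and kappa values into a single overall value per
#' metric by a weighted average with weights equal to the number of
#' overlapping cases of each pair, so pairs with more shared cases
#' contribute more.
#'
#' @param pairwise data frame from [pairwise_agreement()] (columns
#'   \code{n_overlap}, \code{pa}, \code{kappa}).
#' @return list with \code{pa}, \code{kappa} and the named \code{weights}.
#' @export
overall_agreement <- function(pairwise) {
  stopifnot(is.data.frame(pairwise), nrow(pairwise) >= 1)
  ok <- !is.na(pairwise$pa)
  w <- pairwise$n_overlap[ok]
  weights <- stats::setNames(w, paste(pairwise$profession1[ok],
                                      pairwise$profession2[ok], sep = "-"))
  list(pa = sum(pairwise$pa[ok] * w) / sum(w),
       kappa = if (all(is.na(pairwise$kappa[ok]))) NA_real_ else {
         kk <- !is.na(pairwise$kappa) & ok
         sum(pairwise$kappa[kk] * pairwise$n_overlap[kk]) / sum(pairwise$n_overlap[kk])
       },
       weights = weights)
}

# Recompute pairwise PA/kappa and the weighted overall on a case resample.
overall_on_cases <- function(cons, pairs, case_sample) {
  pa_num <- 0; pa_den <- 0; ka_num <- 0; ka_den <- 0
  for (j in seq_len(ncol(pairs))) {
    l1 <- cons[[pairs[1, j]]]$labels
    l2 <- cons[[pairs[2, j]]]$labels
    shared <- case_sample[case_sample %in% names(l1) & case_sample %in% names(l2)]
    n <- length(shared)
    if (!n) next
    a1 <- l1[shared]; a2 <- l2[shared]
    pa_num <- pa_num + sum(a1 == a2)
    pa_den <- pa_den + n
    ka <- kappa_from_table(sum(a1 == "hypoxia" & a2 == "hypoxia"),
                           sum(a1 == "hypoxia" & a2 == "normal"),
                           sum(a1 == "normal" & a2 == "hypoxia"),
                           sum(a1 == "normal" & a2 == "normal"), 0.95)
    if (!is.na(ka$kappa)) {
      ka_num <- ka_num + ka$kappa * n
      ka_den <- ka_den + n
    }
  }
  c(pa = if (pa_den) pa_num / pa_den else NA_real_,
    kappa = if (ka_den) ka_num / ka_den else NA_real_)
}

#' Full interobserver agreement analysis
#'
#' Runs the whole consensus procedure: per-profession majority consensus,
#' pairwise PA and kappa, overlap-weighted overall values, and a seeded
#' case-level bootstrap (resampling case ids with replacement and
#' recomputing the weighted overall on each resample) for the overall
#' confidence intervals.
#'
#' @inheritParams pairwise_agreement
#' @param n_boot number of bootstrap resamples for the overall CIs
#'   (default 2000).
#' @param seed integer seed for the bootstrap stream.
#' @return object of class \code{ctg_agreement}: list with
#'   \code{pairwise} (see [pairwise_agreement()]), \code{overall} (PA and
#'   kappa point estimates, percentile bootstrap CIs, classes and the PA
#'   significance flag) and \code{consensus}.
#' @export
agreement_analysis <- function(study, tie_policy = "exclude", level = 0.95,
                               n_boot = 2000, seed = 1) {
  pw <- pairwise_agreement(study, tie_policy = tie_policy, level = level)
  cons <- attr(pw, "consensus")
  ov <- overall_agreement(pw)

  pairs <- rbind(pw$profession1, pw$profession2)
  universe <- unique(unlist(lapply(cons, function(v) names(v$labels))))
  boot <- with_seed(keyed_seed(seed, "agreement-bootstrap"), {
    t(replicate(n_boot, overall_on_cases(
      cons, pairs, sample(universe, length(universe), replace = TRUE))))
  })
  alpha <- (1 - level) / 2
  qs <- function(x) stats::quantile(x, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  pa_ci <- qs(boot[, "pa"])
  ka_ci <- qs(boot[, "kappa"])
  overall <- list(
    pa = ov$pa, pa_lower = pa_ci[1], pa_upper = pa_ci[2],
    pa_class = classify_agreement(ov$pa, "altman_pa"),
    pa_significant = pa_ci[1] >= 0.50,
    kappa = ov$kappa, kappa_lower = ka_ci[1], kappa_upper = ka_ci[2],
    kappa_class = if (is.na(ov$kappa)) NA_character_ else
      classify_agreement(ov$kappa, "landis_koch_kappa"),
    weights = ov$weights, n_boot = n_boot, seed = seed)
  structure(list(pairwise = pw, overall = overall, consensus = cons,
                 level = level),
            class = "ctg_agreement")
}

#' @export
print.ctg_agreement <- function(x, digits = 2, ...) {
  cat(sprintf("Interobserver agreement (%g%% CIs; overall CIs: case bootstrap, %d resamples)\n",
              100 * x$level, x$overall$n_boot))
  pw <- x$pairwise
  print(data.frame(
    pair = paste(pw$profession1, pw$profession2, sep = " vs "),
    n = pw$n_overlap,
    PA = sprintf("%.*f (%.*f, %.*f)", digits, pw$pa, digits, pw$pa_lower,
                 digits, pw$pa_upper),
    kappa = sprintf("%.*f (%.*f, %.*f)", digits, pw$kappa, digits,
                    pw$kappa_lower, digits, pw$kappa_upper)),
    row.names = FALSE)
  o <- x$overall
  cat(sprintf("overall: PA %.2f (%.2f, %.2f) [%s], kappa %.2f (%.2f, %.2f) [%s]\n",
              o$pa, o$pa_lower, o$pa_upper, o$pa_class,
              o$kappa, o$kappa_lower, o$kappa_upper, o$kappa_class))
  invisible(x)
}
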