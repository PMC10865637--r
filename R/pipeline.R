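#' @title End-to-end report pipeline
#' @description One call runs the whole analysis on a study directory (or
#'   a freshly simulated cohort) and writes the standard report bundle:
#'   a participation descriptive table, the stratified accuracy table,
#'   the agreement/reliability table, plot-ready per-participant
#'   operating points and the pH success curve, plus a run manifest.
#' @name cli_pipeline
NULL

#' Participation descriptive summary
#'
#' Per profession and in total: number of assessors (and percent of the
#' cohort), number of annotations (and percent of all annotations), and
#' the median (q1, q3) annotations per assessor.  Quartiles use Tukey
#' hinges (median-of-halves) by default; \code{"linear"} selects the
#' interpolation convention of \code{quantile(type = 7)}.
#'
#' @param study a \code{ctg_study}.
#' @param quartile_method \code{"hinges"} (default) or \code{"linear"}.
#' @return data frame, one row per profession plus a total row.
#' @export
participation_summary <- function(study, quartile_method = c("hinges", "linear")) {
  stopifnot(inherits(study, "ctg_study"))
  quartile_method <- match.arg(quartile_method)
  qfun <- if (quartile_method == "hinges") tukey_quartiles else
    function(x) stats::setNames(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7),
                                c("q1", "median", "q3"))
  pp <- study$participants
  counts_ann <- table(study$annotations$participant_id)
  per_assessor <- as.numeric(counts_ann[pp$participant_id])
  per_assessor[is.na(per_assessor)] <- 0
  n_total <- nrow(pp)
  a_total <- nrow(study$annotations)
  one <- function(label, idx) {
    q <- qfun(per_assessor[idx])
    data.frame(profession = label,
               n_assessors = length(idx),
               pct_assessors = 100 * length(idx) / n_total,
               n_annotations = sum(per_assessor[idx]),
               pct_annotations = if (a_total) 100 * sum(per_assessor[idx]) / a_total else NA_real_,
               median_annotations = q[["median"]],
               q1_annotations = q[["q1"]], q3_annotations = q[["q3"]],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(intersect(PROFESSIONS, unique(pp$profession)),
                 function(p) one(p, which(pp$profession == p)))
  out <- rbind(do.call(rbind, rows), one("total", seq_len(n_total)))
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()]; defaults are the standard
#' analysis constants (pH threshold 7.15, the eight pH bin edges, the
#' >10-annotation filter for operating points, 95% intervals).
#'
#' @param study_dir directory with cases/participants/annotations CSVs;
#'   \code{NULL} to simulate a study instead.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed (bootstrap, and the simulated study when
#'   \code{study_dir} is NULL).
#' @param threshold hypoxia pH threshold.
#' @param ph_thresholds bin edges for the pH success curve.
#' @param min_annotations operating-point inclusion cut-off (strictly
#'   more than this many annotations).
#' @param tie_policy consensus tie handling.
#' @param n_boot bootstrap resamples for overall agreement CIs.
#' @param level confidence level.
#' @param quartile_method quartile convention for the participation table.
#' @param generator a \code{ctg_gen_config} used when \code{study_dir} is
#'   \code{NULL}; defaults to \code{generator_config(seed = seed)}.
#' @return list of class \code{ctg_pipeline_config}.
#' @export
pipeline_config <- function(study_dir = NULL, out_dir,
                            seed = 1,
                            threshold = 7.15,
                            ph_thresholds = c(6.90, 6.98, 7.05, 7.13, 7.20, 7.28, 7.35, 7.43),
                            min_annotations = 10,
                            tie_policy = "exclude",
                            n_boot = 2000,
                            level = 0.95,
                            quartile_method = "hinges",
                            generator = NULL) {
  if (is.null(generator)) generator <- generator_config(seed = seed,
                                                        threshold = threshold)
  structure(as.list(environment()), class = "ctg_pipeline_config")
}

write_report <- function(df, out_dir, name, round_cols = NULL, digits = 2) {
  full <- df
  if (!is.null(round_cols)) {
    for (cc in intersect(round_cols, names(df))) df[[cc]] <- round(df[[cc]], digits)
  }
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(full, file.path(out_dir, paste0(name, ".json")),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(name)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a study and writes to \code{out_dir}:
#' \describe{
#'   \item{table1}{participation descriptives per profession}
#'   \item{table2}{success rate / sensitivity / specificity with Wilson
#'     CIs per profession and pooled}
#'   \item{table2_experience}{the same stratified by experience band}
#'   \item{table3}{pairwise and overall PA / kappa with classes}
#'   \item{fig1_data}{per-participant TPR/FPR operating points}
#'   \item{fig2_data}{success rate by pH range}
#'   \item{run_manifest.json}{config echo, seed, package version, row
#'     counts and the md5 of every output file}
#' }
#' Every table is written as CSV (percentages rounded to integers,
#' metrics to 2 decimals) with a full-precision JSON mirror.  Reruns with
#' the same configuration are byte-identical.
#'
#' @param config a \code{ctg_pipeline_config}; see [pipeline_config()].
#' @return invisibly, a list with the loaded \code{study}, the computed
#'   tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ctg_pipeline_config"))
  stage <- "load"
  res <- tryCatch({
    study <- if (is.null(config$study_dir)) {
      simulate_study(config$generator)
    } else {
      read_study_dir(config$study_dir, threshold = config$threshold)
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "table1"
    t1 <- participation_summary(study, config$quartile_method)
    t1c <- t1
    t1c$pct_assessors <- round_half_up(t1c$pct_assessors)
    t1c$pct_annotations <- round_half_up(t1c$pct_annotations)
    write_report(t1c, config$out_dir, "table1")

    stage <- "table2"
    metric_cols <- c("success_rate", "success_lower", "success_upper",
                     "sensitivity", "sensitivity_lower", "sensitivity_upper",
                     "specificity", "specificity_lower", "specificity_upper")
    t2 <- summarize_performance(study, "profession", config$level)
    write_report(as.data.frame(t2), config$out_dir, "table2", metric_cols)
    t2e <- summarize_performance(study, "experience_band", config$level)
    write_report(as.data.frame(t2e), config$out_dir, "table2_experience", metric_cols)

    stage <- "table3"
    agr <- agreement_analysis(study, tie_policy = config$tie_policy,
                              level = config$level, n_boot = config$n_boot,
                              seed = config$seed)
    o <- agr$overall
    t3 <- rbind(agr$pairwise,
                data.frame(profession1 = "overall", profession2 = "overall",
                           n_overlap = sum(agr$pairwise$n_overlap),
                           pa = o$pa, pa_lower = o$pa_lower, pa_upper = o$pa_upper,
                           pa_class = o$pa_class, pa_significant = o$pa_significant,
                           kappa = o$kappa, kappa_lower = o$kappa_lower,
                           kappa_upper = o$kappa_upper, kappa_class = o$kappa_class,
                           stringsAsFactors = FALSE))
    write_report(t3, config$out_dir, "table3",
                 c("pa", "pa_lower", "pa_upper", "kappa", "kappa_lower", "kappa_upper"))

    stage <- "fig1"
    f1 <- participant_points(study, config$min_annotations)
    write_report(f1, config$out_dir, "fig1_data", c("tpr", "fpr"))

    stage <- "fig2"
    f2 <- success_by_ph_bin(study, config$ph_thresholds, config$level)
    write_report(f2, config$out_dir, "fig2_data",
                 c("success_rate", "lower", "upper"))

    stage <- "manifest"
    outputs <- c("table1", "table2", "table2_experience", "table3",
                 "fig1_data", "fig2_data")
    files <- file.path(config$out_dir,
                       c(paste0(outputs, ".csv"), paste0(outputs, ".json")))
    cfg <- config
    cfg$generator <- unclass(cfg$generator)
    manifest <- list(
      package = "ctgobs",
      version = as.character(utils::packageVersion("ctgobs")),
      seed = config$seed,
      config = cfg[setdiff(names(cfg), "out_dir")],
      counts = list(cases = nrow(study$cases),
                    participants = nrow(study$participants),
                    annotations = nrow(study$annotations)),
      outputs = lapply(stats::setNames(files, basename(files)), function(f)
        list(rows = length(readLines(f, warn = FALSE)) - 1L,
             md5 = unname(tools::md5sum(f)))),
      content_hash = unname(tools::md5sum(files))
    )
    manifest$content_hash <- paste(manifest$content_hash, collapse = "")
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    list(study = study, table1 = t1, table2 = t2, table2_experience = t2e,
         table3 = t3, fig1_data = f1, fig2_data = f2, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
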