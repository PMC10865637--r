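#' @title Study container and tabular input/output
#' @description Domain types for an observer-performance annotation study:
#'   a cases table (umbilical cord pH and the derived hypoxia label), a
#'   participants table (profession, experience, setting, country) and an
#'   annotations table (one row per prediction event).
#' @name study
NULL

OUTCOMES <- c("hypoxia", "normal")
PROFESSIONS <- c("resident", "midwife", "obstetrician_gynecologist")
EXPERIENCE_BANDS <- c("0-2", "2-4", "4-8", ">8")
PH_RANGE <- c(6.50, 7.60)

#' Derive the binary fetal outcome from umbilical cord pH
#'
#' A delivery is labelled \code{"hypoxia"} when the umbilical cord blood pH
#' is strictly below the threshold, and \code{"normal"} otherwise; a pH
#' exactly at the threshold is classed as normal.
#'
#' @param ph numeric vector of pH values; must lie in \[6.50, 7.60\].
#' @param threshold hypoxia threshold on the pH scale (default 7.15,
#'   corresponding to moderate fetal hypoxia).
#' @return character vector in \code{c("hypoxia", "normal")}.
#' @examples
#' derive_outcome(c(7.05, 7.15, 7.20))
#' @export
derive_outcome <- function(ph, threshold = 7.15) {
  stopifnot(is.numeric(ph), length(threshold) == 1, is.finite(threshold))
  bad <- which(!is.finite(ph) | ph < PH_RANGE[1] | ph > PH_RANGE[2])
  if (length(bad)) {
    stop("pH outside plausible range [", PH_RANGE[1], ", ", PH_RANGE[2],
         "] at position(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(utils::head(ph[bad], 5), collapse = ", "))
  }
  ifelse(ph < threshold, "hypoxia", "normal")
}

#' Assign an experience band from years since diploma
#'
#' Bands are left-closed, right-open: \[0,2), \[2,4), \[4,8), \[8,Inf).
#'
#' @param years_experience non-negative numeric vector (years since diploma).
#' @return character vector with levels \code{"0-2"}, \code{"2-4"},
#'   \code{"4-8"}, \code{">8"}.
#' @examples
#' assign_experience_band(c(0, 2, 7.9, 8))
#' @export
assign_experience_band <- function(years_experience) {
  stopifnot(is.numeric(years_experience))
  if (any(!is.finite(years_experience) | years_experience < 0)) {
    stop("years_experience must be non-negative and finite")
  }
  EXPERIENCE_BANDS[findInterval(years_experience, c(0, 2, 4, 8))]
}

new_study <- function(cases, participants, annotations, threshold = 7.15) {
  structure(
    list(cases = cases, participants = participants,
         annotations = annotations, threshold = threshold),
    class = "ctg_study")
}

#' Assemble and validate a study from its three component tables
#'
#' Recomputes the ground-truth outcome from pH (validating any stored
#' label), derives experience bands, and enforces referential integrity
#' and uniqueness constraints.
#'
#' @param cases data frame with columns \code{case_id}, \code{ph} and
#'   optionally \code{true_outcome}.
#' @param participants data frame with columns \code{participant_id},
#'   \code{profession}, \code{years_experience}, \code{setting},
#'   \code{country} and optionally \code{student_midwife}.
#' @param annotations data frame with columns \code{participant_id},
#'   \code{case_id}, \code{predicted_outcome}, \code{presentation_index}.
#' @param threshold pH threshold defining hypoxia (default 7.15).
#' @return an object of class \code{ctg_study}: a list with elements
#'   \code{cases}, \code{participants}, \code{annotations},
#'   \code{threshold}.
#' @seealso [read_study()], [write_study()]
#' @export
as_study <- function(cases, participants, annotations, threshold = 7.15) {
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("missing column(s) in ", what, ": ", paste(miss, collapse = ", "))
    }
  }
  req(cases, c("case_id", "ph"), "cases")
  req(participants,
      c("participant_id", "profession", "years_experience", "setting", "country"),
      "participants")
  req(annotations,
      c("participant_id", "case_id", "predicted_outcome", "presentation_index"),
      "annotations")

  cases$case_id <- as.character(cases$case_id)
  if (anyDuplicated(cases$case_id)) {
    stop("duplicate case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))
  }
  recomputed <- derive_outcome(cases$ph, threshold)
  if ("true_outcome" %in% names(cases)) {
    mism <- which(as.character(cases$true_outcome) != recomputed)
    if (length(mism)) {
      stop("stored true_outcome disagrees with the pH-derived label at case row(s) ",
           paste(utils::head(mism, 5), collapse = ", "),
           " (case_id ", paste(utils::head(cases$case_id[mism], 5), collapse = ", "), ")")
    }
  }
  cases$true_outcome <- recomputed

  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(participants$participant_id[duplicated(participants$participant_id)]),
               collapse = ", "))
  }
  badp <- which(!participants$profession %in% PROFESSIONS)
  if (length(badp)) {
    stop("unknown profession at participant row(s) ",
         paste(utils::head(badp, 5), collapse = ", "), ": ",
         paste(utils::head(participants$profession[badp], 5), collapse = ", "))
  }
  participants$experience_band <- assign_experience_band(participants$years_experience)

  annotations$participant_id <- as.character(annotations$participant_id)
  annotations$case_id <- as.character(annotations$case_id)
  if (nrow(annotations)) {
    bada <- which(!annotations$predicted_outcome %in% OUTCOMES)
    if (length(bada)) {
      stop("predicted_outcome must be one of ", paste(OUTCOMES, collapse = "/"),
           "; offending annotation row(s): ",
           paste(utils::head(bada, 5), collapse = ", "))
    }
    dang_c <- which(!annotations$case_id %in% cases$case_id)
    if (length(dang_c)) {
      stop("annotation row(s) ", paste(utils::head(dang_c, 5), collapse = ", "),
           " reference unknown case_id: ",
           paste(utils::head(annotations$case_id[dang_c], 5), collapse = ", "))
    }
    dang_p <- which(!annotations$participant_id %in% participants$participant_id)
    if (length(dang_p)) {
      stop("annotation row(s) ", paste(utils::head(dang_p, 5), collapse = ", "),
           " reference unknown participant_id: ",
           paste(utils::head(annotations$participant_id[dang_p], 5), collapse = ", "))
    }
    key <- paste(annotations$participant_id, annotations$case_id, sep = "\x1f")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("duplicate (participant_id, case_id) pair at annotation row(s) ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
    # each participant's presentation indices must be 1..k with no gaps
    for (pid in unique(annotations$participant_id)) {
      idx <- sort(annotations$presentation_index[annotations$participant_id == pid])
      if (!identical(as.integer(idx), seq_along(idx))) {
        stop("presentation_index for participant ", pid,
             " is not a gap-free 1..k sequence")
      }
    }
  }
  new_study(cases, participants, annotations, threshold)
}

#' Read a study from three CSV files
#'
#' @param cases_path,participants_path,annotations_path paths to the three
#'   comma-separated tables (UTF-8, header row required).
#' @param threshold pH threshold defining hypoxia (default 7.15).
#' @return a validated \code{ctg_study}; see [as_study()] for the checks
#'   applied.
#' @export
read_study <- function(cases_path, participants_path, annotations_path,
                       threshold = 7.15) {
  for (p in c(cases_path, participants_path, annotations_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, encoding = "UTF-8")
  as_study(rd(cases_path), rd(participants_path), rd(annotations_path),
           threshold = threshold)
}

#' Read a study from a directory containing cases.csv, participants.csv
#' and annotations.csv
#' @param dir directory path.
#' @inheritParams read_study
#' @return a validated \code{ctg_study}.
#' @export
read_study_dir <- function(dir, threshold = 7.15) {
  read_study(file.path(dir, "cases.csv"),
             file.path(dir, "participants.csv"),
             file.path(dir, "annotations.csv"),
             threshold = threshold)
}

#' Write a study's three tables to a directory
#'
#' Writes \code{cases.csv}, \code{participants.csv} and
#' \code{annotations.csv} plus JSON mirrors of each table.
#'
#' @param study a \code{ctg_study}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ctg_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(cases = study$cases, participants = study$participants,
               annotations = study$annotations)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(tabs[[nm]], file.path(dir, paste0(nm, ".json")),
                         dataframe = "rows", digits = NA)
  }
  invisible(dir)
}

#' @export
print.ctg_study <- function(x, ...) {
  n_hyp <- sum(x$cases$true_outcome == "hypoxia")
  cat("CTG annotation study\n")
  cat(sprintf("  cases:        %d (%d hypoxia / %d normal at pH < %.2f)\n",
              nrow(x$cases), n_hyp, nrow(x$cases) - n_hyp, x$threshold))
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s %d", names(table(x$participants$profession)),
                            as.integer(table(x$participants$profession))),
                    collapse = ", ")))
  cat(sprintf("  annotations:  %d\n", nrow(x$annotations)))
  invisible(x)
}

# Annotation table joined with case truth and participant strata; the
# working table every analysis operates on.
annotation_frame <- function(study) {
  a <- study$annotations
  ci <- match(a$case_id, study$cases$case_id)
  pi <- match(a$participant_id, study$participants$participant_id)
  data.frame(
    participant_id = a$participant_id,
    case_id = a$case_id,
    predicted_outcome = a$predicted_outcome,
    ph = study$cases$ph[ci],
    true_outcome = study$cases$true_outcome[ci],
    profession = study$participants$profession[pi],
    experience_band = study$participants$experience_band[pi],
    correct = a$predicted_outcome == study$cases$true_outcome[ci],
    stringsAsFactors = FALSE)
}
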