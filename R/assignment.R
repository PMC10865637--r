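#' @title Batched balanced case assignment
#' @description The study's pseudorandom case-presentation scheme: cases are
#'   grouped once into fixed batches of 10 (5 hypoxic, 5 normal) shared by
#'   all participants; each participant walks the batches in order but sees
#'   a private within-batch permutation, so early stopping still yields a
#'   balanced, highly overlapping case set across participants.
#' @name assignment
NULL

BATCH_SIZE <- 10L

#' Build the shared batch plan
#'
#' Shuffles the hypoxia and normal case pools separately (keyed by
#' \code{seed}) and fills each batch with 5 cases from each pool.  The
#' resulting batch sequence is fixed: the same for every participant.
#'
#' @param cases data frame of cases with columns \code{case_id} and
#'   \code{true_outcome} (e.g. \code{study$cases}).
#' @param seed integer seed keying the plan.
#' @return an object of class \code{ctg_batch_plan}: a list with
#'   \code{batches} (list of character vectors of 10 case ids, 5 hypoxic +
#'   5 normal each) and \code{seed}.
#' @export
build_batch_plan <- function(cases, seed) {
  stopifnot(is.data.frame(cases), all(c("case_id", "true_outcome") %in% names(cases)))
  hyp <- cases$case_id[cases$true_outcome == "hypoxia"]
  nor <- cases$case_id[cases$true_outcome == "normal"]
  n <- length(hyp) + length(nor)
  if (length(hyp) != length(nor)) {
    stop("case set must be balanced: ", length(hyp), " hypoxia vs ",
         length(nor), " normal cases")
  }
  if (n %% BATCH_SIZE != 0) {
    stop("total number of cases (", n, ") must be divisible by ", BATCH_SIZE)
  }
  hyp <- hyp[keyed_permutation(length(hyp), seed, "plan", "hypoxia")]
  nor <- nor[keyed_permutation(length(nor), seed, "plan", "normal")]
  half <- BATCH_SIZE / 2
  batches <- lapply(seq_len(n / BATCH_SIZE), function(b) {
    i <- ((b - 1) * half + 1):(b * half)
    c(hyp[i], nor[i])
  })
  structure(list(batches = batches, seed = seed), class = "ctg_batch_plan")
}

#' @export
print.ctg_batch_plan <- function(x, ...) {
  cat(sprintf("Batch plan: %d batches of %d cases (seed %d)\n",
              length(x$batches), BATCH_SIZE, x$seed))
  invisible(x)
}

#' Presentation sequence for one participant
#'
#' Walks the shared batches in plan order; within each batch the order is a
#' permutation drawn from a stream keyed by \code{(seed, participant_id,
#' batch)}, so any participant's sequence is reproducible independently of
#' call order.  The sequence is truncated to the first \code{k} cases; a
#' participant never sees a case from batch i+1 before completing batch i.
#'
#' @param plan a \code{ctg_batch_plan}.
#' @param participant_id identifier keying the participant's private
#'   permutation stream.
#' @param k number of cases to present (1..total cases).
#' @param seed integer seed; defaults to the plan's seed.
#' @return character vector of \code{k} case ids.
#' @export
presentation_sequence <- function(plan, participant_id, k, seed = plan$seed) {
  stopifnot(inherits(plan, "ctg_batch_plan"))
  total <- length(plan$batches) * BATCH_SIZE
  if (k < 1 || k > total) {
    stop("k must be in 1..", total, " (got ", k, ")")
  }
  seq_full <- unlist(lapply(seq_along(plan$batches), function(b) {
    plan$batches[[b]][keyed_permutation(BATCH_SIZE, seed, "order", participant_id, b)]
  }), use.names = FALSE)
  seq_full[seq_len(k)]
}
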