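# Inter-rater reliability of binary expert assessments: Fleiss's kappa,
# majority-vote consensus labels, and the label-quality gate that decides
# which functional-test parameters are eligible for classification.

#' Fleiss's kappa for a binary rating table
#'
#' Chance-corrected agreement among a fixed panel of raters each assigning
#' one of two categories (error present / absent) to every subject:
#' `kappa = (Pbar - Pe) / (1 - Pe)`, where `Pbar` is the mean over subjects
#' of the proportion of agreeing rater pairs and `Pe` the chance agreement
#' from the marginal category proportions. When every rating in the table is
#' identical the formula degenerates to 0/0; the complete-agreement
#' convention returns 1.
#'
#' @param ratings Integer matrix, subjects x raters, values in `{0, 1}`,
#'   no missing cells.
#' @return Scalar kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    ms_stop("missing_ratings", "rating table has missing cells")
  if (!all(ratings %in% c(0, 1)))
    ms_stop("bad_argument", "ratings must be binary (0/1)")
  n <- nrow(ratings); r <- ncol(ratings)
  if (n < 2 || r < 2)
    ms_stop("bad_argument", "need >= 2 subjects and >= 2 raters")
  n1 <- rowSums(ratings)                    # raters voting 1, per subject
  counts <- cbind(r - n1, n1)               # subjects x 2 category counts
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  p <- colSums(counts) / (n * r)
  Pe <- sum(p^2)
  if (abs(1 - Pe) < .Machine$double.eps^0.5) return(1)
  (Pbar - Pe) / (1 - Pe)
}

#' Majority-vote consensus labels
#'
#' @param ratings Binary matrix, subjects x raters; the rater count must be
#'   odd unless a tie rule is supplied.
#' @param tie One of `"error"` (default; even panels are rejected),
#'   `"faulty"` or `"non_faulty"` (tied votes resolve to 1 or 0).
#' @return List with `labels` (per-subject 0/1), `faulty` and `non_faulty`
#'   counts (summing to the subject count).
#' @export
consensus_labels <- function(ratings, tie = c("error", "faulty", "non_faulty")) {
  tie <- match.arg(tie)
  ratings <- as.matrix(ratings)
  r <- ncol(ratings)
  votes <- rowSums(ratings)
  if (r %% 2 == 0) {
    if (tie == "error" && any(votes == r / 2))
      ms_stop("configuration_error",
              "even rater panel with tied votes: configure a tie rule")
    labels <- as.integer(votes > r / 2 | (votes == r / 2 & tie == "faulty"))
  } else {
    labels <- as.integer(votes > r / 2)
  }
  list(labels = labels, faulty = sum(labels == 1), non_faulty = sum(labels == 0))
}

#' Agreement report over all functional-test parameters
#'
#' Computes, per parameter, Fleiss's kappa and the consensus faulty /
#' non-faulty group sizes, and applies the eligibility gate of
#' [select_parameters()].
#'
#' @param ratings Either a 3-d array `subjects x raters x parameters`, or a
#'   long data frame with columns `subject_id`, `rater_id`, `parameter`,
#'   `rating`.
#' @param kappa_min,min_minority Gate thresholds, see [select_parameters()].
#' @return Data frame with columns `parameter`, `kappa`, `faulty`,
#'   `non_faulty`, `eligible`.
#' @export
agreement_report <- function(ratings, kappa_min = 0.41, min_minority = 8) {
  if (is.data.frame(ratings)) {
    need <- c("subject_id", "rater_id", "parameter", "rating")
    if (!all(need %in% names(ratings)))
      ms_stop("format_error", "ratings data frame needs columns %s",
              paste(need, collapse = ", "))
    ratings <- local({
      subj <- sort(unique(ratings$subject_id))
      raters <- sort(unique(ratings$rater_id))
      pars <- unique(ratings$parameter)
      a <- array(NA_real_, c(length(subj), length(raters), length(pars)),
                 dimnames = list(NULL, NULL, pars))
      a[cbind(match(ratings$subject_id, subj), match(ratings$rater_id, raters),
              match(ratings$parameter, pars))] <- ratings$rating
      a
    })
  }
  pars <- dimnames(ratings)[[3]]
  if (is.null(pars)) pars <- sprintf("parameter_%02d", seq_len(dim(ratings)[3]))
  rows <- lapply(seq_len(dim(ratings)[3]), function(p) {
    m <- ratings[, , p]
    cl <- consensus_labels(m)
    data.frame(parameter = pars[p], kappa = fleiss_kappa(m),
               faulty = cl$faulty, non_faulty = cl$non_faulty)
  })
  report <- do.call(rbind, rows)
  report$eligible <- report$parameter %in%
    select_parameters(report, kappa_min, min_minority)
  report
}

#' Gate parameters eligible for classification
#'
#' A functional-test parameter enters classification only when the expert
#' panel agrees well enough to define a reference standard and both consensus
#' groups are large enough to learn from: `kappa >= kappa_min` (0.41, the
#' conventional floor of moderate agreement, inclusive) and
#' `min(faulty, non_faulty) >= min_minority` (default 8).
#'
#' @param report Data frame with columns `parameter`, `kappa`, `faulty`,
#'   `non_faulty` — as from [agreement_report()] or a published summary
#'   table.
#' @param kappa_min Minimum Fleiss kappa (default 0.41).
#' @param min_minority Minimum size of the smaller consensus group
#'   (default 8).
#' @return Character vector of eligible parameter names (possibly empty).
#' @export
select_parameters <- function(report, kappa_min = 0.41, min_minority = 8) {
  if (nrow(report) == 0) return(character(0))
  ok <- report$kappa >= kappa_min &
    pmin(report$faulty, report$non_faulty) >= min_minority
  as.character(report$parameter[ok])
}

#' Reference expert-agreement table for the 46-subject cohort
#'
#' The published per-parameter agreement summary of the three-physiotherapist
#' panel that rated the 46-subject SLST/SDT cohort: Fleiss's kappa and the
#' consensus faulty / non-faulty group sizes for each of the 15 assessed
#' parameters, per test. Shipped as a plain-text fixture (decimal commas as
#' printed; normalized to numeric at ingest).
#'
#' @param test `"SDT"`, `"SLST"`, or `"both"` (default) for the full table.
#' @return Data frame with columns `parameter`, `test`, `kappa`, `faulty`,
#'   `non_faulty`.
#' @export
reference_agreement <- function(test = c("both", "SDT", "SLST")) {
  test <- match.arg(test)
  path <- system.file("extdata", "expert_agreement_46subjects.tsv",
                      package = "motionscreen", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("SDT", "SLST"), function(tt) {
    data.frame(
      parameter = raw$parameter, test = tt,
      kappa = as.numeric(sub(",", ".", raw[[paste0(tolower(tt), "_kappa")]], fixed = TRUE)),
      faulty = raw[[paste0(tolower(tt), "_faulty")]],
      non_faulty = raw[[paste0(tolower(tt), "_non_faulty")]]
    )
  }))
  if (test != "both") long <- long[long$test == test, ]
  rownames(long) <- NULL
  long
}
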