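#' Score and binarize the line bisection test
#'
#' Patients bisect 20 cm lines; the table records the mean deviation from
#' the true midpoint as a signed percentage of line length (positive =
#' rightward). The deviation in mm is \code{pct / 100 * 200}. Clinical
#' cut-offs: deviations strictly larger than +6.5 mm or strictly smaller
#' than −7.3 mm are pathological; boundary values are classified normal.
#'
#' @param mean_deviation_pct signed percent deviation(s); \code{NA} marks a
#'   patient who did not complete the test.
#' @return data frame with columns \code{raw} (deviation in mm),
#'   \code{deficit} (1 = pathological) and \code{performance}
#'   (\code{1 - deficit}); rows with missing input stay \code{NA}.
#' @export
binarize_line_bisection <- function(mean_deviation_pct) {
  if (any(is.infinite(mean_deviation_pct)))
    stop("deviation must be finite")
  mm <- mean_deviation_pct / 100 * 200
  deficit <- ifelse(is.na(mm), NA_integer_,
                    as.integer(mm > 6.5 | mm < -7.3))
  .test_score(mm, deficit)
}

#' Score and binarize the bells cancellation test
#'
#' The laterality score is the difference between bells found on the right
#' side of the sheet (max 15) and on the left side (max 15); absolute scores
#' strictly larger than 2 are pathological.
#'
#' @param left_found,right_found counts of cancelled bells per side, in
#'   [0, 15]; \code{NA} marks a missing test.
#' @return data frame as in [binarize_line_bisection()] with \code{raw} =
#'   \code{right_found - left_found}.
#' @export
binarize_bells <- function(left_found, right_found) {
  .check_counts(left_found, 15, "bells left")
  .check_counts(right_found, 15, "bells right")
  raw <- right_found - left_found
  deficit <- ifelse(is.na(raw), NA_integer_, as.integer(abs(raw) > 2))
  .test_score(raw, deficit)
}

#' Score and binarize the letter cancellation test
#'
#' The laterality score is computed on omissions: the number of "A" targets
#' omitted on the right side minus the number omitted on the left side
#' (30 targets per side); absolute scores strictly larger than 2 are
#' pathological.
#'
#' @param left_found,right_found counts of cancelled targets per side, in
#'   [0, 30]; \code{NA} marks a missing test.
#' @return data frame as in [binarize_line_bisection()] with \code{raw} =
#'   \code{(30 - right_found) - (30 - left_found)}.
#' @export
binarize_letter <- function(left_found, right_found) {
  .check_counts(left_found, 30, "letter left")
  .check_counts(right_found, 30, "letter right")
  raw <- (30 - right_found) - (30 - left_found)
  deficit <- ifelse(is.na(raw), NA_integer_, as.integer(abs(raw) > 2))
  .test_score(raw, deficit)
}

.check_counts <- function(x, max, what) {
  bad <- which(!is.na(x) & (x < 0 | x > max | x != floor(x)))
  if (length(bad))
    stop(what, " count out of [0,", max, "] at position(s) ",
         paste(bad, collapse = ", "))
}

.test_score <- function(raw, deficit) {
  data.frame(raw = raw, deficit = deficit,
             performance = invert_score(deficit))
}

#' Invert a deficit score into a performance score
#'
#' MSA requires a score representing behavioral ability, so the binary
#' deficit coding (1 = pathological) is inverted: performance =
#' \code{1 - deficit} (1 = normal performance).
#'
#' @param deficit vector with values in {0, 1} (NA allowed for missing).
#' @return \code{1 - deficit}.
#' @export
invert_score <- function(deficit) {
  if (!all(deficit %in% c(0, 1) | is.na(deficit)))
    stop("deficit scores must be binary")
  1L - as.integer(deficit)
}

#' Behavioral scores for a whole cohort
#'
#' Applies the three test rules to a patient table and returns the long
#' score table used to assemble per-test graded datasets. Patients missing a
#' test keep an \code{NA} row (they are excluded from that test's subcohort
#' downstream, never dropped from the table).
#'
#' @param records a patient table from [read_patient_table()] (or any data
#'   frame with its columns).
#' @return data frame with columns \code{id}, \code{test}
#'   (\code{"line_bisection"}, \code{"bells"}, \code{"letter"}), \code{raw},
#'   \code{deficit}, \code{performance}.
#' @export
score_cohort <- function(records) {
  bis <- binarize_line_bisection(records$line_bisection_pct)
  bel <- binarize_bells(records$bells_left, records$bells_right)
  let <- binarize_letter(records$letter_left, records$letter_right)
  out <- rbind(
    cbind(id = records$id, test = "line_bisection", bis),
    cbind(id = records$id, test = "bells", bel),
    cbind(id = records$id, test = "letter", let))
  rownames(out) <- NULL
  out
}

#' Assemble the per-test graded dataset
#'
#' Pairs the intactness rows of the patients who completed a test with their
#' binary performance labels — the original-graded dataset on which the
#' predictor is trained.
#'
#' @param intact patients-by-players intactness matrix (rows aligned with
#'   \code{records}).
#' @param scores long score table from [score_cohort()].
#' @param test one of \code{"line_bisection"}, \code{"bells"},
#'   \code{"letter"}.
#' @param ids patient identifiers aligned with the rows of \code{intact};
#'   default \code{rownames(intact)}.
#' @return list of class \code{"graded_dataset"}: \code{X} (intactness),
#'   \code{y} (1 = normal performance), \code{patient_ids}, \code{test}.
#' @export
graded_dataset <- function(intact, scores, test, ids = rownames(intact)) {
  stopifnot(test %in% c("line_bisection", "bells", "letter"))
  intact <- as.matrix(intact)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(intact)))
  sc <- scores[scores$test == test, ]
  sc <- sc[match(ids, as.character(sc$id)), ]
  keep <- !is.na(sc$performance)
  structure(list(X = intact[keep, , drop = FALSE],
                 y = sc$performance[keep],
                 patient_ids = ids[keep], test = test),
            class = "graded_dataset")
}

#' @export
print.graded_dataset <- function(x, ...) {
  cat(sprintf("Graded dataset [%s]: %d patients x %d players (%d normal, %d pathological)\n",
              x$test, nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}
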