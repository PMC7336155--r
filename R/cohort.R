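#' Read a patient table
#'
#' Reads the cohort CSV whose columns mirror the published layout: one row
#' per patient with sex, age, days since stroke onset, stroke etiology,
#' visual-field status, the mean line-bisection deviation (signed percent of
#' a 20 cm line), and "left/right" found-target cells for the bells (max
#' 15/15) and letter (max 30/30) cancellation tests. Missing entries are
#' encoded as \code{"-"} (an en-dash is also accepted) or an empty cell and
#' are parsed as \code{NA} — never as 0.
#'
#' @param path CSV file with a header row.
#' @return data frame of class \code{"patient_table"} with columns
#'   \code{id}, \code{sex}, \code{age}, \code{onset_days}, \code{etiology},
#'   \code{visual_field}, \code{line_bisection_pct}, \code{bells_left},
#'   \code{bells_right}, \code{letter_left}, \code{letter_right}.
#' @export
read_patient_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  need <- c("id", "sex", "age", "onset_days", "visual_field",
            "line_bisection_pct", "bells", "letter")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("patient table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$id))
    stop("duplicate patient id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))

  bells <- .parse_pair(raw$bells, 15, "bells", raw$id)
  letter <- .parse_pair(raw$letter, 30, "letter", raw$id)
  out <- data.frame(
    id = raw$id,
    sex = raw$sex,
    age = .parse_num(raw$age),
    onset_days = .parse_num(raw$onset_days),
    etiology = if ("etiology" %in% names(raw)) raw$etiology else NA_character_,
    visual_field = raw$visual_field,
    line_bisection_pct = .parse_num(raw$line_bisection_pct),
    bells_left = bells$left, bells_right = bells$right,
    letter_left = letter$left, letter_right = letter$right,
    stringsAsFactors = FALSE)
  bad_age <- which(!is.na(out$age) & out$age <= 0)
  if (length(bad_age))
    stop("non-positive age for patient(s) ",
         paste(out$id[bad_age], collapse = ", "))
  bad_on <- which(!is.na(out$onset_days) & out$onset_days <= 0)
  if (length(bad_on))
    stop("non-positive onset for patient(s) ",
         paste(out$id[bad_on], collapse = ", "))
  class(out) <- c("patient_table", "data.frame")
  out
}

.is_missing_cell <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | x == "-" | x == "–" | x == "—"
}

.parse_num <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !.is_missing_cell(x)
  out[ok] <- as.numeric(gsub(",", "", sub("^\\+", "", trimws(x[ok]))))
  if (anyNA(out[ok])) stop("unparseable numeric cell(s)")
  out
}

.parse_pair <- function(x, max, what, ids) {
  left <- right <- rep(NA_integer_, length(x))
  ok <- which(!.is_missing_cell(x))
  parts <- strsplit(trimws(x[ok]), "/", fixed = TRUE)
  bad <- ok[lengths(parts) != 2]
  if (length(bad))
    stop("malformed ", what, " cell for patient(s) ",
         paste(ids[bad], collapse = ", "))
  l <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  r <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  out_of_range <- is.na(l) | is.na(r) | l < 0 | l > max | r < 0 | r > max
  if (any(out_of_range))
    stop(what, " counts outside [0,", max, "] for patient(s) ",
         paste(ids[ok[out_of_range]], collapse = ", "))
  left[ok] <- l; right[ok] <- r
  list(left = left, right = right)
}

#' Write a patient table
#'
#' Inverse of [read_patient_table()]: left/right counts are rejoined into
#' "l/r" cells and missing values written as \code{"-"}, so a round trip
#' preserves every field including missingness.
#'
#' @param x a \code{"patient_table"} data frame.
#' @param path output CSV path.
#' @export
write_patient_table <- function(x, path) {
  fmt_pair <- function(l, r) ifelse(is.na(l) | is.na(r), "-",
                                    paste0(l, "/", r))
  fmt_num <- function(v) ifelse(is.na(v), "-", format(v, trim = TRUE))
  out <- data.frame(id = x$id, sex = x$sex, age = fmt_num(x$age),
                    onset_days = fmt_num(x$onset_days),
                    etiology = ifelse(is.na(x$etiology), "-", x$etiology),
                    visual_field = x$visual_field,
                    line_bisection_pct = fmt_num(x$line_bisection_pct),
                    bells = fmt_pair(x$bells_left, x$bells_right),
                    letter = fmt_pair(x$letter_left, x$letter_right),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Path to the bundled reference cohort table
#'
#' The package ships the published table of 25 right-hemisphere stroke
#' patients with hemispatial neglect (demographics, onset, visual field and
#' raw scores of the three visuospatial tests) used throughout the examples.
#'
#' @return file path of the bundled CSV.
#' @export
reference_cohort_path <- function() {
  system.file("extdata", "neglect_cohort.csv", package = "lesionmsa",
              mustWork = TRUE)
}

#' Descriptive statistics of a cohort
#'
#' Arithmetic means, SDs (n−1 denominator) and ranges of age and days since
#' onset, the male count, and per-test completion counts (patients with a
#' non-missing score set). With a single patient the SD is reported as
#' missing rather than 0.
#'
#' @param records a \code{"patient_table"} data frame.
#' @return list of class \code{"cohort_summary"}.
#' @export
summarize_cohort <- function(records) {
  if (NROW(records) == 0) stop("empty patient table")
  sd1 <- function(v) if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE)
                     else NA_real_
  n_complete <- c(
    line_bisection = sum(!is.na(records$line_bisection_pct)),
    bells = sum(!is.na(records$bells_left) & !is.na(records$bells_right)),
    letter = sum(!is.na(records$letter_left) & !is.na(records$letter_right)))
  structure(list(
    n = nrow(records),
    n_male = sum(records$sex == "M", na.rm = TRUE),
    age_mean = mean(records$age, na.rm = TRUE),
    age_sd = sd1(records$age),
    age_min = min(records$age, na.rm = TRUE),
    age_max = max(records$age, na.rm = TRUE),
    onset_mean = mean(records$onset_days, na.rm = TRUE),
    onset_sd = sd1(records$onset_days),
    onset_min = min(records$onset_days, na.rm = TRUE),
    onset_max = max(records$onset_days, na.rm = TRUE),
    n_complete = n_complete), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Cohort of %d patients (%d men)\n",
    "  age   mean %.2f y, SD %s, range %g-%g\n",
    "  onset mean %.2f d, SD %s, range %g-%g\n",
    "  completed tests: line bisection %d, bells %d, letter %d\n"),
    x$n, x$n_male, x$age_mean, .fmt_sd(x$age_sd), x$age_min, x$age_max,
    x$onset_mean, .fmt_sd(x$onset_sd), x$onset_min, x$onset_max,
    x$n_complete["line_bisection"], x$n_complete["bells"],
    x$n_complete["letter"]))
  invisible(x)
}

.fmt_sd <- function(s) if (is.na(s)) "undefined (n = 1)" else sprintf("%.2f", s)
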