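#' Construct a cohort of patients and follow-up evaluations
#'
#' @param patients data.frame with columns `id` (unique), `age` (years),
#'   `sex` (`"female"`/`"male"`).
#' @param followups data.frame with columns `id`, `time_months` (>= 0,
#'   fractional allowed), `grade` (integer 0-3, CTCAE dry mouth).
#' @return an object of class `"xero_cohort"`.
#' @export
cohort <- function(patients, followups) {
  patients <- as.data.frame(patients)
  followups <- as.data.frame(followups)
  if (anyDuplicated(patients$id)) stop("patient ids must be unique")
  if (!all(followups$id %in% patients$id))
    stop("follow-ups reference unknown patient ids")
  if (any(followups$time_months < 0)) stop("follow-up times must be >= 0")
  if (!all(followups$grade %in% 0:3)) stop("grades must be integers 0-3")
  structure(list(patients = patients, followups = followups),
            class = "xero_cohort")
}

#' @export
print.xero_cohort <- function(x, ...) {
  cat(sprintf("<xero_cohort> %d patients, %d follow-up evaluations\n",
              nrow(x$patients), nrow(x$followups)))
  invisible(x)
}

#' Time windows of the time-specific endpoints (months)
#'
#' Early 0-6, late 6-15, long-term 15-24 months after radiotherapy. Windows
#' are half-open `(lo, hi]`: a visit at exactly 6 months belongs to the
#' early window.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
endpoint_windows <- function() {
  list(early = c(0, 6), late = c(6, 15), long_term = c(15, 24))
}

#' Aggregate follow-up grades within a time window
#'
#' Arithmetic mean of the grades observed in the window, rounded to the
#' nearest integer with `x.5` rounded up. `NA` when no visit falls in the
#' window.
#'
#' @param times,grades follow-up times (months) and grades for one patient.
#' @param window `c(lo, hi)`; visits with `lo < time <= hi` are used.
#' @return integer grade or `NA`.
#' @export
aggregate_window <- function(times, grades, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing (lo, hi) interval")
  sel <- times > window[1] & times <= window[2]
  if (!any(sel)) return(NA_integer_)
  as.integer(floor(mean(grades[sel]) + 0.5))
}

#' Binarize a toxicity grade
#'
#' Moderate-to-severe xerostomia: 1 iff grade >= 2.
#'
#' @param grade integer grade(s) in 0-3.
#' @return 0/1 integer label(s).
#' @export
binarize_grade <- function(grade) {
  if (any(!grade %in% 0:3)) stop("grade out of range 0-3")
  as.integer(grade >= 2)
}

#' Build the three time-specific endpoint datasets
#'
#' For each of the early/late/long-term windows, averages each patient's
#' grades in the window (mean, half-up rounding), binarizes at grade >= 2,
#' and excludes patients without a visit in the window. Patients with zero
#' follow-ups are excluded from every endpoint with a warning.
#'
#' @param x a [cohort()].
#' @return named list of data.frames `(id, grade, label)`, one per window,
#'   each carrying its window as attribute `"window"`.
#' @export
build_time_specific <- function(x) {
  stopifnot(inherits(x, "xero_cohort"))
  no_fu <- setdiff(x$patients$id, x$followups$id)
  if (length(no_fu))
    warning(length(no_fu), " patient(s) without follow-up excluded")
  lapply(endpoint_windows(), function(w) {
    rows <- lapply(x$patients$id, function(pid) {
      fu <- x$followups[x$followups$id == pid, ]
      g <- aggregate_window(fu$time_months, fu$grade, w)
      if (is.na(g)) return(NULL)
      data.frame(id = pid, grade = g, label = binarize_grade(g),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(id = character(0), grade = integer(0),
                        label = integer(0))
    attr(out, "window") <- w
    out
  })
}

#' Build the longitudinal endpoint dataset
#'
#' One observation per follow-up evaluation: the label derives only from that
#' visit's grade, and the time after treatment is carried as a model
#' covariate.
#'
#' @param x a [cohort()].
#' @return data.frame `(id, time_months, grade, label)`.
#' @export
build_longitudinal <- function(x) {
  stopifnot(inherits(x, "xero_cohort"))
  fu <- x$followups
  data.frame(id = fu$id, time_months = fu$time_months, grade = fu$grade,
             label = binarize_grade(fu$grade), stringsAsFactors = FALSE)
}
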