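#' Construct a limited-proteolysis time course
#'
#' Band densitometry for one condition: at each sampling time, the
#' integrated densities of the full-length band and of the cleaved band.
#'
#' @param time Sampling times (min), strictly increasing, first must be 0.
#' @param full_length Full-length band densities (AU), >= 0.
#' @param cleaved Cleaved band densities (AU), >= 0; `full_length + cleaved`
#'   must be > 0 at every time.
#' @param label Condition label.
#' @return An object of class `digestion_timecourse` (a data frame with
#'   columns `time_min`, `full_length_AU`, `cleaved_AU`).
#' @export
digestion_timecourse <- function(time, full_length, cleaved, label = "") {
  if (length(time) < 2L) stop("a time course needs >= 2 time points")
  if (length(full_length) != length(time) || length(cleaved) != length(time))
    stop("all columns must have the same length")
  if (time[1] != 0) stop("the first time point must be 0")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(full_length < 0) || any(cleaved < 0))
    stop("band densities must be >= 0")
  if (any(full_length + cleaved <= 0))
    stop("both bands zero at some time point")
  structure(data.frame(time_min = as.numeric(time),
                       full_length_AU = as.numeric(full_length),
                       cleaved_AU = as.numeric(cleaved)),
            class = c("digestion_timecourse", "data.frame"),
            label = as.character(label))
}

#' Relative abundance of the full-length band
#'
#' Two-band normalization: `100 * full_length / (full_length + cleaved)` in
#' percent, which is invariant to uniform gel-loading or staining rescaling.
#'
#' @param full_length,cleaved Band densities (AU), vectors of equal length.
#' @return Percentages in `[0, 100]`.
#' @export
relative_abundance <- function(full_length, cleaved) {
  tot <- full_length + cleaved
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("undefined abundance: both bands are zero")
  100 * full_length / tot
}

#' Digestion midpoint of a proteolysis time course
#'
#' The time at which the relative abundance of the full-length band first
#' crosses 50%, found by linear interpolation between the bracketing
#' samples. If the abundance never reaches 50% the midpoint is
#' right-censored at the last sampling time; if the t = 0 abundance is
#' already at or below 50% the course is flagged as pre-digested and the
#' midpoint is 0.
#'
#' @param tc A [digestion_timecourse()].
#' @return A list of class `digestion_midpoint`: `midpoint` (min),
#'   `censored` (logical; `TRUE` means the value is a lower bound),
#'   `bracket` (the two sampling times enclosing the crossing, or `NA`).
#' @export
digestion_midpoint <- function(tc) {
  stopifnot(inherits(tc, "digestion_timecourse"))
  ab <- relative_abundance(tc$full_length_AU, tc$cleaved_AU)
  t <- tc$time_min
  out <- function(mid, cens, bracket) {
    structure(list(midpoint = mid, censored = cens, bracket = bracket),
              class = "digestion_midpoint")
  }
  if (ab[1] <= 50) {
    warning("pre-digested: relative abundance already <= 50% at t = 0")
    return(out(0, FALSE, c(NA_real_, NA_real_)))
  }
  below <- which(ab <= 50)
  if (length(below) == 0L)
    return(out(t[length(t)], TRUE, c(NA_real_, NA_real_)))
  i <- below[1]
  t_mid <- t[i - 1] + (ab[i - 1] - 50) / (ab[i - 1] - ab[i]) *
    (t[i] - t[i - 1])
  out(t_mid, FALSE, c(t[i - 1], t[i]))
}

#' @export
print.digestion_midpoint <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Digestion midpoint: > %g min (right-censored)\n", x$midpoint))
  } else {
    cat(sprintf("Digestion midpoint: %g min (bracket %g-%g min)\n",
                x$midpoint, x$bracket[1], x$bracket[2]))
  }
  invisible(x)
}

#' Protection factor between two proteolysis conditions
#'
#' Ratio of digestion midpoints, protected over reference; values above 1
#' mean the second condition (e.g. + adaptor protein) slows digestion. If
#' the protected course is right-censored the ratio is only a lower bound
#' and is flagged as such.
#'
#' @param reference,protected [digestion_timecourse()] objects.
#' @return A list of class `protection_factor`: `factor` (dimensionless) and
#'   `lower_bound` (logical).
#' @export
protection_factor <- function(reference, protected) {
  m_ref <- digestion_midpoint(reference)
  m_prot <- digestion_midpoint(protected)
  if (m_ref$censored)
    stop("reference midpoint is right-censored; protection factor undefined")
  structure(list(factor = m_prot$midpoint / m_ref$midpoint,
                 lower_bound = m_prot$censored),
            class = "protection_factor")
}

#' @export
print.protection_factor <- function(x, ...) {
  cat(sprintf("Protection factor: %s%.3g\n",
              if (x$lower_bound) ">= " else "", x$factor))
  invisible(x)
}
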