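# Tilt-scheme generation and electron-exposure weighting.

#' Dose-symmetric tilt scheme with pretilt and grouping
#'
#' Generates the acquisition order of a dose-symmetric tilt series: start at
#' the lamella pretilt, then alternate sides in blocks of `group` consecutive
#' steps, covering `pretilt +/- span`. Low tilts are acquired first and so
#' receive the least accumulated dose. The returned angle set is always
#' `{pretilt + k*step : k = -span/step .. +span/step}`; `group` only changes
#' the order.
#'
#' @param pretilt_deg lamella pretilt (degrees); acquisition starts here.
#' @param step_deg tilt increment (degrees, > 0).
#' @param group number of consecutive same-side tilts per block (>= 1).
#' @param span_deg half-range about the pretilt; must be a positive multiple
#'   of `step_deg`.
#' @param positive_first whether the first block after the start goes to the
#'   positive side (default `TRUE`; the convention is not fixed by the
#'   scheme itself).
#' @param dose_per_tilt optional electron exposure per projection
#'   (e-/Angstrom^2); if given, cumulative dose is attached.
#' @return a `tilt_scheme`: list with `angles_deg` (acquisition order),
#'   `pretilt_deg`, `step_deg`, `group`, `span_deg`, and (if dosed)
#'   `dose_per_tilt` and `cumulative_dose` (dose accumulated before each
#'   tilt).
#' @examples
#' dose_symmetric_scheme(8, 2, 2, 60)   # 61 projections, -52 to +68 degrees
#' @export
dose_symmetric_scheme <- function(pretilt_deg = 8, step_deg = 2, group = 2L,
                                  span_deg = 60, positive_first = TRUE,
                                  dose_per_tilt = NULL) {
  stopifnot(step_deg > 0, group >= 1, span_deg > 0)
  m <- span_deg / step_deg
  if (abs(m - round(m)) > 1e-9)
    stop("span_deg (", span_deg, ") must be a multiple of step_deg (", step_deg, ")")
  m <- as.integer(round(m))
  ks <- 0L
  pos <- 0L; neg <- 0L
  side_pos <- positive_first
  while (pos < m || neg < m) {
    if (side_pos && pos < m) {
      take <- seq(pos + 1L, min(pos + group, m))
      ks <- c(ks, take)
      pos <- take[length(take)]
    } else if (!side_pos && neg < m) {
      take <- seq(neg + 1L, min(neg + group, m))
      ks <- c(ks, -take)
      neg <- take[length(take)]
    }
    side_pos <- !side_pos
  }
  scheme <- structure(list(
    angles_deg = pretilt_deg + ks * step_deg,
    pretilt_deg = pretilt_deg, step_deg = step_deg,
    group = as.integer(group), span_deg = span_deg,
    positive_first = positive_first
  ), class = "tilt_scheme")
  if (!is.null(dose_per_tilt)) scheme <- cumulative_dose(scheme, dose_per_tilt)
  scheme
}

#' Accumulated dose per tilt
#'
#' With a constant per-tilt exposure, the dose accumulated before the i-th
#' acquired projection is `(i - 1) * dose_per_tilt` and the series total is
#' `n * dose_per_tilt`.
#'
#' @param scheme a `tilt_scheme`.
#' @param dose_per_tilt exposure per projection (e-/Angstrom^2, > 0).
#' @return the scheme with `dose_per_tilt`, `cumulative_dose` (before each
#'   tilt, acquisition order) and `total_dose` fields.
#' @export
cumulative_dose <- function(scheme, dose_per_tilt) {
  stopifnot(inherits(scheme, "tilt_scheme"), dose_per_tilt > 0)
  n <- length(scheme$angles_deg)
  scheme$dose_per_tilt <- dose_per_tilt
  scheme$cumulative_dose <- (seq_len(n) - 1L) * dose_per_tilt
  scheme$total_dose <- n * dose_per_tilt
  scheme
}

#' @export
print.tilt_scheme <- function(x, ...) {
  n <- length(x$angles_deg)
  cat(sprintf(
    "Dose-symmetric tilt scheme: %d projections, pretilt %+g deg, step %g deg, group %d\n",
    n, x$pretilt_deg, x$step_deg, x$group))
  cat(sprintf("  angles %g to %g deg; order: %s ...\n",
              min(x$angles_deg), max(x$angles_deg),
              paste(utils::head(x$angles_deg, 7L), collapse = ", ")))
  if (!is.null(x$total_dose))
    cat(sprintf("  dose %g e-/A^2 per tilt, %g e-/A^2 total\n",
                x$dose_per_tilt, x$total_dose))
  invisible(x)
}

#' @export
as.data.frame.tilt_scheme <- function(x, ...) {
  data.frame(order = seq_along(x$angles_deg),
             angle_deg = x$angles_deg,
             dose_before = if (is.null(x$cumulative_dose)) NA_real_
                           else x$cumulative_dose)
}

#' Write a tilt scheme as a rawtlt-style angle file
#'
#' One angle per line, acquisition order; optionally a CSV with cumulative
#' dose alongside.
#'
#' @param scheme a `tilt_scheme`.
#' @param path output angle-file path.
#' @param dose_csv optional path for a CSV with order, angle and prior dose.
#' @return `path`, invisibly.
#' @export
write_tilt_scheme <- function(scheme, path, dose_csv = NULL) {
  stopifnot(inherits(scheme, "tilt_scheme"))
  writeLines(format(scheme$angles_deg, trim = TRUE), path)
  if (!is.null(dose_csv))
    utils::write.csv(as.data.frame(scheme), dose_csv, row.names = FALSE)
  invisible(path)
}

#' Critical-exposure dose weight
#'
#' Frequency-dependent attenuation of signal by accumulated electron
#' exposure: `weight = exp(-dose / (2 * Ne(f)))` with critical exposure
#' `Ne(f) = a * f^b + c`. The default constants (a = 0.245, b = -1.665,
#' c = 2.81, f in 1/Angstrom, dose in e-/Angstrom^2) are the published
#' single-particle critical-exposure calibration and are configurable.
#'
#' @param freq_invA spatial frequency (1/Angstrom, > 0).
#' @param accumulated_dose exposure before this image (e-/Angstrom^2, >= 0).
#' @param a,b,c critical-exposure model constants.
#' @return weights in (0, 1], vectorised over `freq_invA` and/or
#'   `accumulated_dose`.
#' @export
exposure_weight <- function(freq_invA, accumulated_dose,
                            a = 0.245, b = -1.665, c = 2.81) {
  stopifnot(all(freq_invA > 0), all(accumulated_dose >= 0))
  ne <- a * freq_invA^b + c
  exp(-accumulated_dose / (2 * ne))
}
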