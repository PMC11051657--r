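# Resolution estimation: Fourier shell correlation between half-maps and
# Rosenthal-Henderson B-factor fits of resolution against particle number.

#' Fourier shell correlation between two half-maps
#'
#' Computes, per radial shell of one Fourier-voxel width,
#' `FSC(s) = Re sum(F_a * Conj(F_b)) / sqrt(sum|F_a|^2 * sum|F_b|^2)`
#' after optional voxelwise masking. Shell frequency is assigned at the shell
#' centre, `s / (box * pixel_size)` in 1/Angstrom, up to Nyquist.
#'
#' @param map_a,map_b 3D numeric arrays of equal cubic dimensions, or
#'   `mrc_volume` objects (then `pixel_size` is taken from the header and
#'   must agree).
#' @param mask optional 3D array with values in \[0, 1\], applied voxelwise
#'   to both maps.
#' @param pixel_size Angstrom per voxel (required for plain arrays).
#' @return an `fsc_curve`: data.frame with `shell_freq` (1/A), `fsc`, and
#'   `n_voxels` per shell; attributes `box_size` and `pixel_size`.
#' @export
compute_fsc <- function(map_a, map_b, mask = NULL, pixel_size = NULL) {
  get_px <- function(m) if (inherits(m, "mrc_volume")) m$pixel_size else NULL
  pxa <- get_px(map_a); pxb <- get_px(map_b)
  if (inherits(map_a, "mrc_volume")) map_a <- map_a$data
  if (inherits(map_b, "mrc_volume")) map_b <- map_b$data
  if (!is.null(pxa) && !is.null(pxb) && abs(pxa - pxb) > 1e-6 * pxa)
    stop("half-maps have different pixel sizes: ", pxa, " vs ", pxb)
  if (is.null(pixel_size)) pixel_size <- if (!is.null(pxa)) pxa else pxb
  if (is.null(pixel_size)) stop("pixel_size required")
  da <- dim(map_a); db <- dim(map_b)
  if (!identical(da, db)) stop("half-maps have different dimensions")
  if (length(da) != 3L || length(unique(da)) != 1L)
    stop("maps must be cubic 3D volumes")
  n <- da[[1L]]
  if (!is.null(mask)) {
    if (!identical(dim(mask), da)) stop("mask dimensions do not match the maps")
    if (min(mask) < 0 || max(mask) > 1) stop("mask values must lie in [0, 1]")
    map_a <- map_a * mask
    map_b <- map_b * mask
  }
  fa <- stats::fft(map_a)
  fb <- stats::fft(map_b)
  shell <- fourier_shell_index(n)
  nmax <- n %/% 2L
  keep <- shell >= 1L & shell <= nmax
  sh <- shell[keep]
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- as.vector(rowsum(cross, sh))
  den <- sqrt(as.vector(rowsum(pa, sh)) * as.vector(rowsum(pb, sh)))
  fsc <- ifelse(den > 0, num / den, 0)
  curve <- data.frame(
    shell_freq = seq_len(nmax) / (n * pixel_size),
    fsc = fsc,
    n_voxels = as.vector(table(factor(sh, levels = seq_len(nmax))))
  )
  structure(curve, class = c("fsc_curve", "data.frame"),
            box_size = n, pixel_size = pixel_size)
}

# Integer radial shell index for an n^3 FFT grid (0 = DC), n even or odd.
fourier_shell_index <- function(n) {
  k <- c(0:(n %/% 2L), if (n > 1L) -((n - n %/% 2L - 1L):1L)) # FFT frequency order
  k2 <- k^2
  r2 <- outer(outer(k2, k2, `+`), k2, `+`)
  as.integer(round(sqrt(r2)))
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC curve: box %d, pixel size %.3f A, %d shells\n",
              attr(x, "box_size"), attr(x, "pixel_size"), nrow(x)))
  for (thr in c(0.5, 0.143)) {
    r <- resolution_at(x, thr)
    cat(sprintf("  resolution at FSC = %.3f: %.2f A%s\n", thr, r,
                if (isTRUE(attr(r, "no_crossing"))) " (no crossing; Nyquist)" else ""))
  }
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, thresholds = c(0.143, 0.5), ...) {
  graphics::plot(x$shell_freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = thresholds, lty = 3, col = "grey40")
  invisible(x)
}

#' Threshold-crossing resolution of an FSC curve
#'
#' Finds the first shell where the curve falls below `threshold`, linearly
#' interpolates the crossing frequency between the bracketing shells, and
#' returns `1 / frequency` in Angstrom. A curve that never crosses returns
#' the Nyquist resolution with attribute `no_crossing = TRUE`.
#'
#' @param curve an `fsc_curve` (or data.frame with `shell_freq` and `fsc`).
#' @param threshold FSC threshold in (0, 1); 0.143 for the gold-standard
#'   half-map criterion, 0.5 for the stricter classical one.
#' @return resolution in Angstrom (length-1 numeric).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(threshold > 0, threshold < 1)
  if (nrow(curve) == 0L) stop("empty FSC curve")
  f <- curve$shell_freq
  v <- curve$fsc
  below <- which(v < threshold)
  if (length(below) == 0L)
    return(structure(1 / f[length(f)], no_crossing = TRUE))
  i <- below[[1L]]
  if (i == 1L) return(structure(1 / f[[1L]], extrapolated = TRUE))
  # linear interpolation between shells i-1 (>= thr) and i (< thr)
  frac <- (v[[i - 1L]] - threshold) / (v[[i - 1L]] - v[[i]])
  fc <- f[[i - 1L]] + frac * (f[[i]] - f[[i - 1L]])
  1 / fc
}

#' Rosenthal-Henderson B-factor fit
#'
#' Fits `1/d^2 = (2/B) * ln(N) + intercept` by ordinary least squares to a
#' series of (particle count, resolution) points: in the regime where
#' alignment is signal-limited, squared inverse resolution grows linearly in
#' the log particle number and the slope gives the overall B-factor
#' `B = 2/slope` (Angstrom^2). Points whose resolution has hit the Nyquist
#' ceiling carry no slope information and are excluded from the default fit
#' range.
#'
#' @param n particle counts.
#' @param d resolutions in Angstrom.
#' @param nyquist_res optional Nyquist resolution (A) of the source maps;
#'   points with `d` within one shell of it are excluded from the fit.
#' @param shell_width_res optional width (A) of the exclusion band around
#'   Nyquist; defaults to 5 percent of `nyquist_res`.
#' @param fit_range optional logical/integer index of points to fit,
#'   overriding the Nyquist rule.
#' @return an `rh_fit`: list with `B` (A^2), `intercept`, `points`
#'   (data.frame with `n`, `d`, `inv_d2`, `used`), and the underlying slope.
#' @export
rosenthal_henderson_fit <- function(n, d, nyquist_res = NULL,
                                    shell_width_res = NULL, fit_range = NULL) {
  stopifnot(length(n) == length(d), all(n >= 1), all(d > 0))
  used <- rep(TRUE, length(n))
  if (!is.null(fit_range)) {
    used <- rep(FALSE, length(n))
    used[fit_range] <- TRUE
  } else if (!is.null(nyquist_res)) {
    if (is.null(shell_width_res)) shell_width_res <- 0.05 * nyquist_res
    used <- d > nyquist_res + shell_width_res
  }
  if (sum(used) < 2L || length(unique(n[used])) < 2L)
    stop("no valid fit: need at least 2 points with distinct N off the Nyquist ceiling")
  x <- log(n[used])
  y <- 1 / d[used]^2
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  if (slope <= 0)
    stop("no valid fit: non-positive slope (resolution does not improve with N)")
  structure(list(B = 2 / slope, intercept = intercept, slope = slope,
                 points = data.frame(n = n, d = d, inv_d2 = 1 / d^2, used = used)),
            class = "rh_fit")
}

#' @export
print.rh_fit <- function(x, ...) {
  cat(sprintf("Rosenthal-Henderson fit: B = %.1f A^2 (slope %.4g, intercept %.4g)\n",
              x$B, x$slope, x$intercept))
  cat(sprintf("  %d/%d points in the linear regime\n",
              sum(x$points$used), nrow(x$points)))
  invisible(x)
}

#' @export
coef.rh_fit <- function(object, ...) {
  c(B = object$B, slope = object$slope, intercept = object$intercept)
}

#' @rdname rosenthal_henderson_fit
#' @param object an `rh_fit`.
#' @param newdata optional vector of particle counts to predict for.
#' @param ... unused.
#' @return `predict.rh_fit`: predicted resolutions (Angstrom) at the given
#'   particle counts.
#' @export
predict.rh_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$points$n else newdata
  inv_d2 <- object$slope * log(n) + object$intercept
  ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
}

#' @export
plot.rh_fit <- function(x, ...) {
  p <- x$points
  graphics::plot(log(p$n), p$inv_d2, pch = ifelse(p$used, 19, 1),
                 xlab = "ln(number of particles)",
                 ylab = expression(1 / d^2 ~ (ring(A)^-2)), ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}
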