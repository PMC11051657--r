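# Ion-damage quantification from template-matching cross-correlation scores.
#
# Gallium implantation and collision cascades during FIB milling degrade a
# layer under each lamella surface. Per-tomogram-normalised CC scores
# (CC/CCmax) rise with depth through that layer and level off to a plateau;
# the levelling-off point is estimated explicitly with a hinge (ramp-plateau)
# regression and a bootstrap confidence interval.

#' Normalise CC scores per tomogram
#'
#' Adds `cc_norm = cc / max(cc within the same tomogram)`, so each
#' tomogram's maximum is exactly 1 and the scores are comparable across
#' tomograms (the CC/CCmax metric).
#'
#' @param table particle table with `tomo` and `cc` columns.
#' @return `table` with a `cc_norm` column.
#' @export
normalize_cc <- function(table) {
  check_particle_table(table, need = c("tomo", "cc"))
  mx <- tapply(table$cc, table$tomo, max)
  bad <- names(mx)[mx <= 0]
  if (length(bad))
    stop("nonpositive maximum CC score in tomogram(s): ", paste(bad, collapse = ", "))
  table$cc_norm <- table$cc / as.vector(mx[as.character(table$tomo)])
  table
}

# Hinge-model least squares at a fixed breakpoint: cc = a + b * min(d, db)/db,
# with a = c_surface and a + b = c_plateau. Returns c(a, b, sse).
hinge_ls <- function(depth, cc, d_break) {
  u <- pmin(depth, d_break) / d_break
  mu <- mean(u); mc <- mean(cc)
  su <- sum((u - mu)^2)
  if (su < .Machine$double.eps) {            # all depths beyond the break
    a <- mc
    return(c(a = a, b = 0, sse = sum((cc - a)^2)))
  }
  b <- sum((u - mu) * (cc - mc)) / su
  a <- mc - b * mu
  r <- cc - a - b * u
  c(a = a, b = b, sse = sum(r * r))
}

#' Estimate the ion-damage layer depth by hinge regression
#'
#' Fits the ramp-plateau model
#' `cc(d) = c_surface + (c_plateau - c_surface) * min(d, d_break) / d_break`
#' to per-particle normalised CC score versus depth. The breakpoint
#' `d_break` is scanned on a grid (default 1-nm steps over 5-80 nm), the two
#' linear parameters are solved in closed form at each grid point, and the
#' SSE-minimising triple is returned with a percentile bootstrap confidence
#' interval for the breakpoint. If the hinge does not beat a constant fit by
#' the F-like criterion `f_min`, a `no_damage` flag is set and `d_break`
#' reported at the grid minimum.
#'
#' @param depth_nm particle depths (nm).
#' @param cc_norm normalised CC scores.
#' @param grid_nm breakpoint grid (nm), default `seq(5, 80, by = 1)`.
#' @param n_boot bootstrap resamples for the CI (default 200).
#' @param seed seed for the bootstrap.
#' @param f_min minimum F-like statistic
#'   `((SSE0 - SSE) / 2) / (SSE / (n - 3))` for the hinge to count as real
#'   damage (default 4).
#' @param conf confidence level of the bootstrap interval (default 0.95).
#' @return a `damage_fit`: list with `d_break_nm`, `c_plateau`, `c_surface`,
#'   `ci` (bootstrap interval for the breakpoint, nm), `no_damage`,
#'   `f_stat`, `rms` residual, `n`, and the scan `profile` (grid, SSE).
#' @export
estimate_damage_depth <- function(depth_nm, cc_norm, grid_nm = seq(5, 80, by = 1),
                                  n_boot = 200L, seed = 1L, f_min = 4,
                                  conf = 0.95) {
  stopifnot(length(depth_nm) == length(cc_norm), length(grid_nm) >= 1)
  ok <- is.finite(depth_nm) & is.finite(cc_norm)
  depth_nm <- depth_nm[ok]; cc_norm <- cc_norm[ok]
  n <- length(depth_nm)
  if (n < 50L)
    stop("need at least 50 particles to estimate the damage depth, got ", n)
  scan_fit <- function(d, cc) {
    fits <- vapply(grid_nm, function(db) hinge_ls(d, cc, db), numeric(3))
    i <- which.min(fits["sse", ])
    c(d_break = grid_nm[[i]], a = unname(fits["a", i]),
      b = unname(fits["b", i]), sse = unname(fits["sse", i]))
  }
  best <- scan_fit(depth_nm, cc_norm)
  sse0 <- sum((cc_norm - mean(cc_norm))^2)
  f_stat <- ((sse0 - best[["sse"]]) / 2) / (best[["sse"]] / max(n - 3L, 1L))
  no_damage <- !is.finite(f_stat) || f_stat < f_min
  if (no_damage) best[["d_break"]] <- grid_nm[[1L]]
  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (!no_damage && n_boot > 0L) {
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(n, n, replace = TRUE)
      scan_fit(depth_nm[j], cc_norm[j])[["d_break"]]
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 1))
  }
  structure(list(
    d_break_nm = unname(best[["d_break"]]),
    c_surface = unname(best[["a"]]),
    c_plateau = unname(best[["a"]] + best[["b"]]),
    ci = ci, no_damage = no_damage, f_stat = unname(f_stat),
    rms = sqrt(best[["sse"]] / n), n = n,
    grid_nm = grid_nm, n_boot = if (no_damage) 0L else n_boot, seed = seed,
    boot = boot
  ), class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  if (x$no_damage) {
    cat(sprintf("No damage layer detected (F = %.2f below criterion); n = %d\n",
                x$f_stat, x$n))
  } else {
    cat(sprintf(
      "Damage-layer depth: %.0f nm (bootstrap %d%% CI %.0f-%.0f nm, %d resamples)\n",
      x$d_break_nm, round(100 * 0.95), x$ci[[1L]], x$ci[[2L]], x$n_boot))
    cat(sprintf("  CC/CCmax: %.3f at surface -> plateau %.3f; residual RMS %.4f, n = %d\n",
                x$c_surface, x$c_plateau, x$rms, x$n))
  }
  invisible(x)
}

#' @export
coef.damage_fit <- function(object, ...) {
  c(d_break_nm = object$d_break_nm, c_surface = object$c_surface,
    c_plateau = object$c_plateau)
}

#' @rdname estimate_damage_depth
#' @param object a `damage_fit`.
#' @param newdata depths (nm) to evaluate the fitted CC model at.
#' @param ... unused.
#' @return `predict.damage_fit`: fitted CC/CCmax at the given depths.
#' @export
predict.damage_fit <- function(object, newdata, ...) {
  object$c_surface + (object$c_plateau - object$c_surface) *
    pmin(newdata, object$d_break_nm) / object$d_break_nm
}

#' @export
plot.damage_fit <- function(x, depth_nm = NULL, cc_norm = NULL, ...) {
  if (!is.null(depth_nm)) {
    graphics::plot(depth_nm, cc_norm, pch = 16, cex = 0.4,
                   col = grDevices::grey(0.5, 0.4),
                   xlab = "depth from lamella surface (nm)",
                   ylab = "CC / CCmax", ...)
  } else {
    graphics::plot(NA, xlim = range(x$grid_nm), ylim = c(x$c_surface, x$c_plateau),
                   xlab = "depth from lamella surface (nm)",
                   ylab = "CC / CCmax", ...)
  }
  dd <- seq(min(x$grid_nm) / 5, max(x$grid_nm) * 1.2, length.out = 200)
  graphics::lines(dd, predict(x, dd), col = "red", lwd = 2)
  graphics::abline(v = x$d_break_nm, lty = 2)
  invisible(x)
}

#' Ordinary least-squares linear trend
#'
#' Slope, intercept and Pearson correlation of `y` against `x`; used e.g.
#' for the linear dependence of CTF-fit resolution on local lamella
#' thickness.
#'
#' @param x,y numeric vectors of equal length, at least two distinct `x`.
#' @return named numeric `c(slope, intercept, r)`.
#' @export
fit_linear_trend <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2L) stop("degenerate x: all values identical")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- if (stats::var(y) > 0) stats::cor(x, y) else 0
  c(slope = slope, intercept = intercept, r = r)
}
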