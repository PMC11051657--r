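# Lamella geometry: in-silico straightening of template-matching coordinates.
#
# FIB-milled lamellae are tilted and offset relative to the tomogram frame
# (pretilt, stage loading offset, non-flatness), so particle Z coordinates do
# not directly measure distance to the milled surfaces. The fix: fit a plane
# through the raw template-match coordinates of each tomogram, subtract it so
# the slab is flat and centred on z = 0, read the two surfaces off the
# flattened-Z histogram, and measure each particle's depth as the distance to
# the closest surface.
#
# Internal canonical unit is nm; STAR coordinates are voxels and are
# converted with the per-tomogram pixel size (Angstrom per voxel):
# nm = voxel * pixel_size / 10.

#' Least-squares reference plane through particle coordinates
#'
#' Fits `z = a*x + b*y + c` by ordinary least squares through a cloud of
#' particle coordinates (normal equations; no outlier rejection, matching the
#' use of raw, pre-classification template matches). Optionally an
#' iteratively-reweighted (Tukey bisquare) robust fit.
#'
#' @param coords matrix or data.frame with columns `x`, `y`, `z` (voxels; any
#'   consistent length unit works, the plane is unit-agnostic).
#' @param robust if `TRUE`, iterate Tukey-bisquare reweighting (off by
#'   default: the straightening uses plain OLS on raw matches).
#' @param tomo tomogram identifier used in error messages.
#' @return numeric vector `c(a, b, c)`.
#' @examples
#' xy <- expand.grid(x = 0:9, y = 0:9)
#' fit_reference_plane(cbind(xy, z = 0.1 * xy$x + 0.2 * xy$y + 50))
#' @export
fit_reference_plane <- function(coords, robust = FALSE, tomo = NULL) {
  coords <- as.data.frame(coords)
  check_particle_table(coords, need = c("x", "y", "z"))
  n <- nrow(coords)
  who <- if (is.null(tomo)) "" else paste0(" (tomogram ", tomo, ")")
  if (n < 3L)
    stop("degenerate geometry", who, ": need at least 3 points, got ", n)
  X <- cbind(coords$x, coords$y, 1)
  if (qr(X)$rank < 3L)
    stop("degenerate geometry", who, ": (x, y) support is collinear")
  w <- rep(1, n)
  for (it in seq_len(if (robust) 20L else 1L)) {
    beta <- solve(crossprod(X * sqrt(w)), crossprod(X * w, coords$z))
    r <- coords$z - X %*% beta
    if (!robust) break
    s <- stats::median(abs(r)) / 0.6745
    if (s == 0) break
    u <- pmin(abs(r) / (4.685 * s), 1)
    w_new <- as.vector((1 - u^2)^2)
    if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
    w <- w_new
  }
  stats::setNames(as.vector(beta), c("a", "b", "c"))
}

#' Subtract the fitted plane from particle Z coordinates
#'
#' Adds a `z_flat` column: `z_flat = z - (a*x + b*y + c)`, leaving the slab
#' roughly centred on zero. Over the support used for the fit, `z_flat` has
#' mean zero by the OLS normal equations.
#'
#' @param table particle table with `x`, `y`, `z` (voxels).
#' @param plane numeric `c(a, b, c)` from [fit_reference_plane()].
#' @return `table` with a `z_flat` column (voxels).
#' @export
flatten_z <- function(table, plane) {
  check_particle_table(table, need = c("x", "y", "z"))
  stopifnot(length(plane) == 3L, all(is.finite(plane)))
  table$z_flat <- table$z - (plane[[1L]] * table$x + plane[[2L]] * table$y + plane[[3L]])
  table
}

#' Estimate the two lamella surfaces from flattened Z coordinates
#'
#' Converts flattened Z to nm, histograms it with `bin_width_nm` bins, and
#' places each surface where the particle count drops off sharply: the
#' plateau level is the median count over the occupied interior bins, and
#' scanning outward from the centre each edge is the outer boundary of the
#' outermost bin whose count still reaches `dropoff_fraction * plateau`
#' (so a single noisy interior dip cannot truncate the slab).
#'
#' @param z_flat flattened Z coordinates, voxels.
#' @param pixel_size Angstrom per voxel.
#' @param bin_width_nm histogram bin width, nm (default 5, the granularity of
#'   the downstream depth analysis).
#' @param dropoff_fraction fraction of the plateau count below which a bin
#'   counts as fallen off (default 0.5).
#' @param min_support minimum number of particles required (default 100).
#' @return numeric `c(z_bottom_nm, z_top_nm)`.
#' @export
estimate_surfaces <- function(z_flat, pixel_size, bin_width_nm = 5,
                              dropoff_fraction = 0.5, min_support = 100L) {
  stopifnot(pixel_size > 0, bin_width_nm > 0,
            dropoff_fraction > 0, dropoff_fraction < 1)
  z_nm <- z_flat * pixel_size / 10
  z_nm <- z_nm[is.finite(z_nm)]
  if (length(z_nm) < min_support)
    stop("insufficient support for surface estimation: ", length(z_nm),
         " particles (need ", min_support, ")")
  lo <- floor(min(z_nm) / bin_width_nm) * bin_width_nm
  hi <- ceiling(max(z_nm) / bin_width_nm) * bin_width_nm
  if (hi <= lo) hi <- lo + bin_width_nm
  breaks <- seq(lo, hi, by = bin_width_nm)
  counts <- graphics::hist(z_nm, breaks = breaks, plot = FALSE)$counts
  occ <- which(counts > 0L)
  interior <- occ[occ > occ[[1L]] & occ < occ[[length(occ)]]]
  if (length(interior) == 0L) interior <- occ
  plateau <- stats::median(counts[interior])
  thr <- dropoff_fraction * plateau
  qual <- which(counts >= thr)
  if (length(qual) == 0L)
    stop("degenerate histogram: no bin reaches the plateau criterion")
  c(z_bottom_nm = breaks[min(qual)], z_top_nm = breaks[max(qual) + 1L])
}

#' Distance from a particle to the closest lamella surface
#'
#' No distinction is made between the top and bottom surfaces. Particles
#' lying outside the estimated slab get a negative depth (kept, not dropped,
#' so surface-estimation error stays inspectable downstream).
#'
#' @param z_flat_nm flattened Z in nm.
#' @param z_bottom_nm,z_top_nm surface offsets in nm (`z_bottom_nm < z_top_nm`).
#' @return numeric vector of depths (nm); negative means outside the slab.
#' @export
particle_depth <- function(z_flat_nm, z_bottom_nm, z_top_nm) {
  stopifnot(z_bottom_nm < z_top_nm)
  pmin(z_flat_nm - z_bottom_nm, z_top_nm - z_flat_nm)
}

#' @title Per-tomogram lamella frame
#' @description Bundle of the fitted plane and estimated surfaces for one
#'   tomogram: the straightening result. Created by [straighten()].
#' @param plane numeric `c(a, b, c)`, voxel units.
#' @param z_bottom_nm,z_top_nm surface offsets in flattened coordinates (nm).
#' @param pixel_size Angstrom per voxel.
#' @param bin_width_nm histogram bin width used (nm).
#' @param n_support number of coordinates used for the fit.
#' @param tomo tomogram identifier.
#' @return an object of class `lamella_frame`.
#' @export
lamella_frame <- function(plane, z_bottom_nm, z_top_nm, pixel_size,
                          bin_width_nm = 5, n_support = NA_integer_,
                          tomo = NA_character_) {
  stopifnot(z_top_nm > z_bottom_nm)
  structure(list(tomo = tomo, plane = plane,
                 z_bottom_nm = z_bottom_nm, z_top_nm = z_top_nm,
                 thickness_nm = z_top_nm - z_bottom_nm,
                 pixel_size = pixel_size, bin_width_nm = bin_width_nm,
                 n_support = n_support),
            class = "lamella_frame")
}

#' @export
print.lamella_frame <- function(x, ...) {
  cat("Lamella frame", if (!is.na(x$tomo)) paste0("for tomogram ", x$tomo), "\n")
  cat(sprintf("  plane z = %.5g*x + %.5g*y + %.5g (voxels, n = %s)\n",
              x$plane[[1L]], x$plane[[2L]], x$plane[[3L]], x$n_support))
  cat(sprintf("  surfaces: %.1f / %.1f nm -> local thickness %.1f nm\n",
              x$z_bottom_nm, x$z_top_nm, x$thickness_nm))
  invisible(x)
}

#' Local lamella thickness of a frame
#' @param frame a `lamella_frame`.
#' @return thickness in nm.
#' @export
local_thickness <- function(frame) {
  stopifnot(inherits(frame, "lamella_frame"))
  frame$thickness_nm
}

#' Front-to-back thickness profile of a lamella
#'
#' Orders per-tomogram frames by a front-to-back position label and returns
#' the thickness series: the milling geometry makes lamellae wedge-shaped,
#' thinner at the front than at the back.
#'
#' @param frames list of `lamella_frame` objects.
#' @param position numeric front-to-back position of each frame (nm or any
#'   monotone label).
#' @return `data.frame` with `position` and `thickness_nm`, sorted by position.
#' @export
wedge_profile <- function(frames, position = seq_along(frames)) {
  stopifnot(length(frames) == length(position))
  th <- vapply(frames, local_thickness, numeric(1))
  o <- order(position)
  data.frame(position = position[o], thickness_nm = th[o])
}

#' Straighten a particle table and derive per-particle depth
#'
#' The full in-silico straightening, per tomogram: fit the reference plane
#' through all template-match coordinates, flatten Z, estimate the two
#' surfaces from the flattened-Z histogram, and attach `depth_nm` (distance
#' to the closest surface, negative outside the slab), `outside_slab`, and
#' `thickness_nm` (the tomogram's local thickness) to every particle.
#'
#' @param table particle table (coordinates in voxels).
#' @param meta per-tomogram metadata with `tomo` and `pixel_size` columns, or
#'   a single pixel size applied to all tomograms.
#' @param bin_width_nm,dropoff_fraction,min_support see [estimate_surfaces()].
#' @param robust robust plane fit, see [fit_reference_plane()].
#' @return list with `particles` (the annotated table) and `frames` (named
#'   list of `lamella_frame`, one per tomogram), classed `straightening`.
#' @export
straighten <- function(table, meta, bin_width_nm = 5, dropoff_fraction = 0.5,
                       min_support = 100L, robust = FALSE) {
  check_particle_table(table)
  if (is.numeric(meta) && length(meta) == 1L) {
    meta <- data.frame(tomo = unique(table$tomo), pixel_size = meta)
  }
  stopifnot(all(c("tomo", "pixel_size") %in% names(meta)))
  table$depth_nm <- NA_real_
  table$thickness_nm <- NA_real_
  table$outside_slab <- NA
  frames <- list()
  for (tm in unique(table$tomo)) {
    sel <- table$tomo == tm
    px <- meta$pixel_size[match(tm, meta$tomo)]
    if (is.na(px)) stop("no pixel size in metadata for tomogram ", tm)
    sub <- table[sel, , drop = FALSE]
    plane <- fit_reference_plane(sub, robust = robust, tomo = tm)
    sub <- flatten_z(sub, plane)
    surf <- estimate_surfaces(sub$z_flat, px, bin_width_nm = bin_width_nm,
                              dropoff_fraction = dropoff_fraction,
                              min_support = min_support)
    fr <- lamella_frame(plane, surf[[1L]], surf[[2L]], px,
                        bin_width_nm = bin_width_nm,
                        n_support = nrow(sub), tomo = tm)
    d <- particle_depth(sub$z_flat * px / 10, surf[[1L]], surf[[2L]])
    table$depth_nm[sel] <- d
    table$thickness_nm[sel] <- fr$thickness_nm
    table$outside_slab[sel] <- d < 0
    frames[[tm]] <- fr
  }
  structure(list(particles = table, frames = frames), class = "straightening")
}

#' @export
print.straightening <- function(x, ...) {
  th <- vapply(x$frames, local_thickness, numeric(1))
  cat(sprintf("Straightened %d particles across %d tomogram(s)\n",
              nrow(x$particles), length(x$frames)))
  cat(sprintf("  local thickness %.0f-%.0f nm; %d particle(s) outside slab\n",
              min(th), max(th), sum(x$particles$outside_slab)))
  invisible(x)
}

#' @export
summary.straightening <- function(object, ...) {
  data.frame(
    tomo = names(object$frames),
    thickness_nm = vapply(object$frames, local_thickness, numeric(1)),
    n = as.vector(table(factor(object$particles$tomo, names(object$frames)))),
    row.names = NULL
  )
}
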