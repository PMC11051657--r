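# Synthetic data: tilted wedge-shaped lamella particle sets with ground
# truth, damage-modulated CC scores, and half-map pairs with a prescribed
# spectral SNR. Everything downstream of template matching can be exercised
# on these without any real tomograms.

#' Describe a synthetic lamella scenario
#'
#' A scenario fixes the geometry and score model of a simulated dataset:
#' `n_tomograms` tomograms spaced front-to-back along one wedge-shaped
#' lamella whose thickness grows linearly from `thickness_front_nm` at rate
#' `wedge_slope` (nm thickness per nm of front-back position), each tomogram
#' a square field of view of `extent_nm`, the slab tilted by the plane
#' `z = a*x + b*y + c` (voxels), particles uniform inside the slab with the
#' given density, and CC scores drawn from a near-surface damage model.
#' Defaults echo a FIB-milled lamella dataset: local thickness spanning
#' roughly 43-255 nm across tomograms, reconstruction pixel size 4.9 A,
#' a ramp damage layer ending at 30 nm with CC/CCmax rising 0.6 -> 0.95.
#'
#' @param n_tomograms number of tomograms along the lamella.
#' @param thickness_front_nm slab thickness at the front edge (nm).
#' @param wedge_slope thickness increase per nm of front-back position.
#' @param plane numeric `c(a, b, c)`: slab mid-plane in voxel units.
#' @param density_per_100nm3 expected particles per (100 nm)^3 of slab.
#' @param damage list: `kind` ("ramp" or "exponential"), `d_break_nm` (ramp)
#'   or `lambda_nm` (exponential), `c_surface`, `c_plateau`, `noise_sd`.
#' @param pixel_size Angstrom per voxel of the exported coordinates.
#' @param extent_nm side length of each tomogram's field of view (nm).
#' @param seed integer seed (mandatory; every draw derives from it).
#' @return a `lamella_scenario` list.
#' @export
lamella_scenario <- function(n_tomograms = 12L,
                             thickness_front_nm = 43,
                             wedge_slope = 0.0221,
                             plane = c(0.08, -0.05, 120),
                             density_per_100nm3 = 8,
                             damage = list(kind = "ramp", d_break_nm = 30,
                                           c_surface = 0.6, c_plateau = 0.95,
                                           noise_sd = 0.05),
                             pixel_size = 4.9,
                             extent_nm = 800,
                             seed = 1L) {
  stopifnot(n_tomograms >= 1, thickness_front_nm > 0, density_per_100nm3 > 0,
            pixel_size > 0, extent_nm > 0, !is.null(seed))
  structure(list(n_tomograms = as.integer(n_tomograms),
                 thickness_front_nm = thickness_front_nm,
                 wedge_slope = wedge_slope, plane = plane,
                 density_per_100nm3 = density_per_100nm3,
                 damage = damage, pixel_size = pixel_size,
                 extent_nm = extent_nm, seed = as.integer(seed)),
            class = "lamella_scenario")
}

#' Simulate template-match particle coordinates in a wedge-shaped lamella
#'
#' Tomograms are laid out front (position 0) to back along the lamella; the
#' slab thickness at front-back position `p` (nm) is
#' `thickness_front_nm + wedge_slope * p`. Within each tomogram, particle
#' counts are Poisson with mean `density * extent^2 * mean thickness`,
#' positions uniform in `{(x,y,z): |z - plane(x,y)| <= t(x)/2}` where `x`
#' also advances the local front-back position. Coordinates are exported in
#' voxels at the scenario pixel size; ground truth carries the true depth,
#' local thickness and plane of every particle.
#'
#' @param scenario a [lamella_scenario()].
#' @return list with `particles` (particle table: `tomo`, `x`, `y`, `z`
#'   voxels, angles, `cc`), `truth` (per-particle `depth_nm`,
#'   `thickness_nm`, front-back `position_nm`), `frames` (per-tomogram true
#'   plane, surfaces and thickness), and `meta` (tomogram metadata table).
#' @export
simulate_lamella_particles <- function(scenario) {
  stopifnot(inherits(scenario, "lamella_scenario"))
  set.seed(scenario$seed)
  px_nm <- scenario$pixel_size / 10     # nm per voxel
  ext <- scenario$extent_nm
  dens <- scenario$density_per_100nm3 / 1e6   # per nm^3
  parts <- list(); truths <- list(); frames <- list()
  for (t in seq_len(scenario$n_tomograms)) {
    tomo <- sprintf("tomo_%03d", t)
    pos0 <- (t - 1L) * ext              # front-back offset of this tomogram
    t_front <- scenario$thickness_front_nm + scenario$wedge_slope * pos0
    t_mean <- t_front + scenario$wedge_slope * ext / 2
    n <- stats::rpois(1L, dens * ext^2 * t_mean)
    if (n == 0L)
      stop("zero expected particle count in tomogram ", tomo,
           "; raise density or extent")
    x_nm <- stats::runif(n, 0, ext)
    y_nm <- stats::runif(n, 0, ext)
    thick <- t_front + scenario$wedge_slope * x_nm
    zc_nm <- (scenario$plane[[1L]] * (x_nm / px_nm) +
              scenario$plane[[2L]] * (y_nm / px_nm) +
              scenario$plane[[3L]]) * px_nm
    z_nm <- zc_nm + stats::runif(n, -0.5, 0.5) * thick
    depth <- pmin(z_nm - (zc_nm - thick / 2), (zc_nm + thick / 2) - z_nm)
    parts[[t]] <- data.frame(
      tomo = tomo,
      x = x_nm / px_nm, y = y_nm / px_nm, z = z_nm / px_nm,
      rot = stats::runif(n, -180, 180),
      tilt = stats::runif(n, 0, 180),
      psi = stats::runif(n, -180, 180)
    )
    truths[[t]] <- data.frame(
      tomo = tomo, depth_nm = depth, thickness_nm = thick,
      position_nm = pos0 + x_nm
    )
    frames[[tomo]] <- list(plane = scenario$plane,
                           thickness_front_nm = t_front,
                           thickness_mean_nm = t_mean,
                           position_nm = pos0)
  }
  particles <- do.call(rbind, parts)
  truth <- do.call(rbind, truths)
  particles$cc <- simulate_cc_scores(truth$depth_nm, scenario$damage,
                                     seed = scenario$seed + 1L)
  meta <- data.frame(tomo = names(frames),
                     pixel_size = scenario$pixel_size,
                     thickness_nm = vapply(frames, `[[`, numeric(1),
                                           "thickness_mean_nm"),
                     position = vapply(frames, `[[`, numeric(1), "position_nm"))
  list(particles = particles, truth = truth, frames = frames, meta = meta)
}

#' Simulate damage-modulated CC scores
#'
#' Ramp model: `cc = c_surface + (c_plateau - c_surface) * min(d, d_break) /
#' d_break + noise`. Exponential model: `cc = c_plateau * (1 - kappa *
#' exp(-d / lambda)) + noise` with `kappa = 1 - c_surface / c_plateau`.
#' Noise is Gaussian, resampled where necessary so that all scores stay
#' positive.
#'
#' @param depth_nm particle depths (nm).
#' @param damage damage-model list, see [lamella_scenario()].
#' @param seed integer seed.
#' @return numeric vector of CC scores, all > 0.
#' @export
simulate_cc_scores <- function(depth_nm, damage, seed = 1L) {
  set.seed(seed)
  d <- pmax(depth_nm, 0)
  base <- switch(damage$kind,
    ramp = damage$c_surface + (damage$c_plateau - damage$c_surface) *
             pmin(d, damage$d_break_nm) / damage$d_break_nm,
    exponential = {
      kappa <- 1 - damage$c_surface / damage$c_plateau
      damage$c_plateau * (1 - kappa * exp(-d / damage$lambda_nm))
    },
    stop("unknown damage model kind: ", damage$kind)
  )
  if (is.null(damage$noise_sd) || damage$noise_sd == 0) return(base)
  cc <- base + stats::rnorm(length(base), 0, damage$noise_sd)
  bad <- which(cc <= 0)
  while (length(bad)) {                 # truncate noise: keep cc > 0
    cc[bad] <- base[bad] + stats::rnorm(length(bad), 0, damage$noise_sd)
    bad <- bad[cc[bad] <= 0]
  }
  cc
}

#' Simulate a half-map pair with a prescribed spectral SNR
#'
#' A band-unlimited random "structure" is drawn once in Fourier space with
#' per-shell amplitude `sqrt(SNR(k))` against unit-variance noise, where
#' `SNR(k) = scale * n_particles * exp(-B * k^2 / 2)` (k in 1/Angstrom).
#' Each half-map is the structure plus independent white noise, so the
#' expected FSC per shell is `SNR / (1 + SNR)`. This operates purely in the
#' Fourier-shell SNR domain: no projection physics, no missing wedge.
#'
#' @param box cube side in voxels (even, >= 32).
#' @param pixel_size Angstrom per voxel.
#' @param n_particles nominal particle count N entering the SNR model.
#' @param B Gaussian falloff parameter (Angstrom^2).
#' @param scale SNR prefactor per particle (default 0.05).
#' @param seed integer seed.
#' @return list with `map_a`, `map_b` (`mrc_volume`), and `expected_fsc`
#'   (data.frame `shell_freq`, `fsc` for shells 1..box/2).
#' @export
simulate_halfmaps <- function(box = 64L, pixel_size = 4.0, n_particles = 1000,
                              B = 300, scale = 0.05, seed = 1L) {
  stopifnot(box >= 32L, box %% 2L == 0L, pixel_size > 0, B > 0, scale > 0)
  set.seed(seed)
  shell <- fourier_shell_index(box)
  freq <- shell / (box * pixel_size)
  snr <- scale * n_particles * exp(-B * freq^2 / 2)
  amp <- array(sqrt(snr), dim = c(box, box, box))
  # real-space white noise -> FFT keeps Hermitian symmetry after shell scaling
  f_sig <- stats::fft(array(stats::rnorm(box^3), dim = c(box, box, box))) * amp
  mk_half <- function() {
    noise <- stats::fft(array(stats::rnorm(box^3), dim = c(box, box, box)))
    Re(stats::fft(f_sig + noise, inverse = TRUE)) / box^3
  }
  map_a <- mk_half()
  map_b <- mk_half()
  nmax <- box %/% 2L
  sfreq <- seq_len(nmax) / (box * pixel_size)
  ssnr <- scale * n_particles * exp(-B * sfreq^2 / 2)
  list(
    map_a = structure(list(data = map_a, pixel_size = pixel_size),
                      class = "mrc_volume"),
    map_b = structure(list(data = map_b, pixel_size = pixel_size),
                      class = "mrc_volume"),
    expected_fsc = data.frame(shell_freq = sfreq, fsc = ssnr / (1 + ssnr))
  )
}
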