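# End-to-end analyses: thickness stratification + Rosenthal-Henderson,
# depth/damage profiling, and the high-quality-versus-random comparison.
# Each run_* function takes a straightened particle table (depth_nm and
# thickness_nm present), does one analysis, and optionally writes STAR/CSV
# reports stamped with the seed and a config hash.

# md5 of a config list, for stamping outputs
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

stamp_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Thickness-stratified resolution analysis
#'
#' Splits the particles into `k` equal-count local-thickness groups, draws
#' nested random subsets inside each group (checked for unbiased thickness
#' distribution), and — via simulated half-map pairs whose spectral SNR
#' scales with particle count — computes an FSC resolution per subset and a
#' Rosenthal-Henderson B-factor fit per group.
#'
#' @param particles straightened particle table (`thickness_nm` present).
#' @param k number of thickness groups (default 3).
#' @param subset_sizes nested subset sizes; capped at the group size.
#' @param seed integer seed.
#' @param box,map_pixel_size,B,scale half-map simulation parameters, see
#'   [simulate_halfmaps()].
#' @param out_dir optional directory for STAR files and the CSV manifest.
#' @return list with `boundaries`, per-group `subsets` checks, `rh_table`
#'   (group, n, resolution), and `rh_fits` (one `rh_fit` per group, `NULL`
#'   where no linear regime exists); classed `thickness_report`.
#' @export
run_thickness_analysis <- function(particles, k = 3L,
                                   subset_sizes = c(250, 500, 1000, 2000,
                                                    4000, 8000, 16114),
                                   seed = 1L, box = 48L, map_pixel_size = 1.2,
                                   B = 300, scale = 0.05, out_dir = NULL) {
  check_particle_table(particles, need = "thickness_nm")
  config <- list(analysis = "thickness", k = k, subset_sizes = subset_sizes,
                 box = box, map_pixel_size = map_pixel_size, B = B, scale = scale)
  hash <- config_hash(config)
  split <- split_equal_count(particles, "thickness_nm", k)
  rh_rows <- list()
  rh_fits <- vector("list", k)
  checks <- list()
  for (g in seq_len(k)) {
    grp <- split$groups[[g]]
    sizes <- subset_sizes[subset_sizes <= nrow(grp)]
    if (length(sizes) == 0L) sizes <- nrow(grp)
    subs <- random_subsets(grp, sizes, seed = seed + g,
                           match_key = "thickness_nm")
    checks[[g]] <- cbind(group = g, subs$checks)
    res <- vapply(seq_along(sizes), function(i) {
      hm <- simulate_halfmaps(box = box, pixel_size = map_pixel_size,
                              n_particles = sizes[[i]], B = B, scale = scale,
                              seed = seed + 100L * g + i)
      resolution_at(compute_fsc(hm$map_a, hm$map_b), 0.143)
    }, numeric(1))
    rh_rows[[g]] <- data.frame(group = g, n = sizes, resolution_A = res)
    nyq <- 2 * map_pixel_size
    rh_fits[[g]] <- tryCatch(
      rosenthal_henderson_fit(sizes, res, nyquist_res = nyq),
      error = function(e) NULL)     # no linear regime: flagged, not forced
  }
  report <- structure(list(
    boundaries = split$boundaries,
    subset_checks = do.call(rbind, checks),
    rh_table = do.call(rbind, rh_rows),
    rh_fits = rh_fits, seed = seed, config_hash = hash
  ), class = "thickness_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in seq_len(k))
      write_particle_star(split$groups[[g]],
                          file.path(out_dir, sprintf("thickness_group%d.star", g)))
    stamp_csv(report$boundaries, file.path(out_dir, "thickness_groups.csv"),
              seed, hash)
    stamp_csv(report$rh_table, file.path(out_dir, "rh_points.csv"), seed, hash)
  }
  report
}

#' @export
print.thickness_report <- function(x, ...) {
  cat("Thickness analysis:", nrow(x$boundaries), "equal-count groups\n")
  print(x$boundaries)
  for (g in seq_along(x$rh_fits)) {
    if (is.null(x$rh_fits[[g]])) cat(sprintf("  group %d: no linear regime\n", g))
    else cat(sprintf("  group %d: B = %.0f A^2\n", g, x$rh_fits[[g]]$B))
  }
  invisible(x)
}

#' Depth-resolved damage analysis
#'
#' Restricts the particles to a local-thickness window (so thickness effects
#' do not confound the depth signal), selects fixed-size particle groups at
#' 5-nm depth centres, normalises CC scores per tomogram, and estimates the
#' damage-layer depth by hinge regression with a bootstrap CI.
#'
#' @param particles straightened particle table with `depth_nm`,
#'   `thickness_nm`, `tomo`, `cc`.
#' @param thickness_window inclusive local-thickness window in nm (default
#'   `c(140, 190)`).
#' @param centers,per_center_n depth-group layout, see [select_depth_bins()].
#' @param grid_nm,n_boot,seed damage-fit controls, see
#'   [estimate_damage_depth()].
#' @param out_dir optional output directory.
#' @return list with `damage` (a `damage_fit`), `groups`, `overlap`,
#'   `profile` (per-centre mean CC/CCmax), `n_window`; classed
#'   `depth_report`.
#' @export
run_depth_analysis <- function(particles, thickness_window = c(140, 190),
                               centers = seq(5, 50, by = 5),
                               per_center_n = 1000L,
                               grid_nm = seq(5, 80, by = 1), n_boot = 200L,
                               seed = 1L, out_dir = NULL) {
  check_particle_table(particles, need = c("depth_nm", "thickness_nm",
                                           "tomo", "cc"))
  config <- list(analysis = "depth", thickness_window = thickness_window,
                 centers = centers, per_center_n = per_center_n)
  hash <- config_hash(config)
  win <- particles$thickness_nm >= thickness_window[[1L]] &
         particles$thickness_nm <= thickness_window[[2L]]
  tab <- particles[win, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no particles with local thickness in [", thickness_window[[1L]],
         ", ", thickness_window[[2L]], "] nm")
  tab <- normalize_cc(tab)
  per_center_n <- min(per_center_n, nrow(tab))
  bins <- select_depth_bins(tab, centers, per_center_n)
  profile <- data.frame(
    center_nm = centers,
    mean_cc_norm = vapply(bins$groups, function(g) mean(g$cc_norm), numeric(1)),
    mean_depth_nm = vapply(bins$groups, function(g) mean(g$depth_nm), numeric(1))
  )
  dmg <- estimate_damage_depth(tab$depth_nm, tab$cc_norm, grid_nm = grid_nm,
                               n_boot = n_boot, seed = seed)
  report <- structure(list(damage = dmg, groups = bins$groups,
                           overlap = bins$overlap, profile = profile,
                           n_window = nrow(tab), seed = seed,
                           config_hash = hash), class = "depth_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bins$groups))
      write_particle_star(bins$groups[[nm]],
                          file.path(out_dir, paste0(nm, ".star")))
    stamp_csv(profile, file.path(out_dir, "depth_profile.csv"), seed, hash)
    stamp_csv(data.frame(d_break_nm = dmg$d_break_nm,
                         c_plateau = dmg$c_plateau, c_surface = dmg$c_surface,
                         ci_low = dmg$ci[[1L]], ci_high = dmg$ci[[2L]],
                         n = dmg$n),
              file.path(out_dir, "damage_fit.csv"), seed, hash)
  }
  report
}

#' @export
print.depth_report <- function(x, ...) {
  cat(sprintf("Depth analysis: %d particles in the thickness window\n",
              x$n_window))
  print(x$damage)
  invisible(x)
}

#' High-quality versus random particle comparison
#'
#' Selects the high-quality set (thin lamellae, outside the damage zone),
#' then two size-matched random comparison sets: one drawn particle-wise
#' from the whole table, one drawn whole-tomogram-wise. Reports paired
#' summary statistics (mean depth, thickness, CC/CCmax) for the three sets.
#'
#' @param particles straightened particle table.
#' @param thickness_max_nm,depth_min_nm high-quality thresholds, see
#'   [select_high_quality()].
#' @param seed integer seed for the random comparison draws.
#' @param out_dir optional output directory.
#' @return list with `high_quality`, `random_particles`, `random_tomograms`
#'   (tables) and `summary` (data.frame); classed `quality_report`.
#' @export
run_quality_comparison <- function(particles, thickness_max_nm = 180,
                                   depth_min_nm = 30, seed = 1L,
                                   out_dir = NULL) {
  check_particle_table(particles, need = c("depth_nm", "thickness_nm",
                                           "tomo", "cc"))
  config <- list(analysis = "quality", thickness_max_nm = thickness_max_nm,
                 depth_min_nm = depth_min_nm)
  hash <- config_hash(config)
  particles <- normalize_cc(particles)
  hq <- select_high_quality(particles, thickness_max_nm, depth_min_nm)
  if (nrow(hq) == 0L) stop("high-quality filter retained no particles")
  rnd_p <- random_subsets(particles, nrow(hq), seed = seed,
                          match_key = "thickness_nm")$subsets[[1L]]
  rnd_t <- select_by_tomogram(particles, nrow(hq), seed = seed)
  summarise <- function(tab, label) data.frame(
    set = label, n = nrow(tab),
    mean_depth_nm = mean(tab$depth_nm),
    mean_thickness_nm = mean(tab$thickness_nm),
    mean_cc_norm = mean(tab$cc_norm)
  )
  summary <- rbind(summarise(hq, "high_quality"),
                   summarise(rnd_p, "random_particles"),
                   summarise(rnd_t, "random_tomograms"))
  report <- structure(list(high_quality = hq, random_particles = rnd_p,
                           random_tomograms = rnd_t, summary = summary,
                           seed = seed, config_hash = hash),
                      class = "quality_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_particle_star(hq, file.path(out_dir, "high_quality.star"))
    write_particle_star(rnd_p, file.path(out_dir, "random_particles.star"))
    write_particle_star(rnd_t, file.path(out_dir, "random_tomograms.star"))
    stamp_csv(summary, file.path(out_dir, "quality_summary.csv"), seed, hash)
  }
  report
}

#' @export
print.quality_report <- function(x, ...) {
  cat("High-quality vs random comparison:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a wedge-shaped multi-tomogram lamella dataset, straightens it,
#' and runs all three analyses (thickness stratification with
#' Rosenthal-Henderson fits, depth/damage profiling, high-quality-vs-random
#' comparison) at desk scale. Group and subset sizes are capped to what the
#' simulated dataset supports.
#'
#' @param seed integer seed driving the whole run.
#' @param scenario a [lamella_scenario()]; defaults to the standard scenario
#'   reseeded with `seed`.
#' @param per_center_n particles per depth group (default 200, sized to the
#'   simulated dataset).
#' @param subset_sizes nested subset sizes for the thickness analysis.
#' @param n_boot bootstrap resamples for the damage CI.
#' @param out_dir optional output directory for all reports.
#' @return list with `straightening`, `thickness`, `depth`, `quality`, and
#'   the `scenario`; classed `lamella_demo`.
#' @export
run_demo <- function(seed = 1L, scenario = lamella_scenario(seed = seed),
                     per_center_n = 200L,
                     subset_sizes = c(250, 500, 1000, 2000),
                     n_boot = 100L, out_dir = NULL) {
  sim <- simulate_lamella_particles(scenario)
  st <- straighten(sim$particles, sim$meta)
  p <- st$particles
  thick <- run_thickness_analysis(p, subset_sizes = subset_sizes,
                                  seed = seed,
                                  out_dir = if (is.null(out_dir)) NULL
                                            else file.path(out_dir, "thickness"))
  depth <- run_depth_analysis(p, per_center_n = per_center_n, n_boot = n_boot,
                              seed = seed,
                              out_dir = if (is.null(out_dir)) NULL
                                        else file.path(out_dir, "depth"))
  quality <- run_quality_comparison(p, seed = seed,
                                    out_dir = if (is.null(out_dir)) NULL
                                              else file.path(out_dir, "quality"))
  structure(list(straightening = st, thickness = thick, depth = depth,
                 quality = quality, scenario = scenario, seed = seed),
            class = "lamella_demo")
}

#' @export
print.lamella_demo <- function(x, ...) {
  cat("Synthetic lamella demonstration (seed ", x$seed, ")\n\n", sep = "")
  print(x$straightening); cat("\n")
  print(x$thickness); cat("\n")
  print(x$depth); cat("\n")
  print(x$quality)
  invisible(x)
}
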