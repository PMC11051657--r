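# Particle curation: stratification by thickness, depth-bin selection,
# the high-quality filter, and random comparison subsets.

#' Split a particle table into equal-count groups
#'
#' Groups are contiguous blocks in sorted key order (stable sort, so ties
#' keep input order). Sizes differ by at most one; when the count is not
#' divisible by `k` the extra particles go to the lowest-key groups. This is
#' how the dataset's three thickness tertiles (thin / middle / thick) are
#' formed.
#'
#' @param table particle table.
#' @param key name of the numeric column to stratify on (e.g.
#'   `"thickness_nm"`).
#' @param k number of groups (>= 2).
#' @return list with `groups` (list of `k` data.frames in ascending key
#'   order), `boundaries` (data.frame of per-group key min/max and size), and
#'   `label` (group index per input row).
#' @export
split_equal_count <- function(table, key, k = 3L) {
  check_particle_table(table, need = key)
  n <- nrow(table)
  if (n == 0L) stop("empty particle table")
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of particles (", n, ")")
  o <- order(table[[key]])            # stable radix/shell order
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  grp_sorted <- rep(seq_len(k), times = sizes)
  label <- integer(n)
  label[o] <- grp_sorted
  groups <- lapply(seq_len(k), function(g) table[label == g, , drop = FALSE])
  boundaries <- data.frame(
    group = seq_len(k),
    n = sizes,
    key_min = vapply(groups, function(g) min(g[[key]]), numeric(1)),
    key_max = vapply(groups, function(g) max(g[[key]]), numeric(1))
  )
  list(groups = groups, boundaries = boundaries, label = label)
}

#' Select fixed-size particle groups centred on target depths
#'
#' For each depth centre `c`, picks the `per_center_n` particles with the
#' smallest `|depth_nm - c|` (ties broken by stable input order). Groups may
#' overlap between neighbouring centres when too few particles sit close to
#' the surface; the pairwise overlap of consecutive groups is reported.
#'
#' @param table particle table with a `depth_nm` column.
#' @param centers depth centres in nm (default 5 to 50 nm in 5-nm steps).
#' @param per_center_n particles per group (default 1000).
#' @return list with `groups` (named list of data.frames), `overlap`
#'   (data.frame of consecutive-centre overlap fractions), and `index`
#'   (list of row indices per centre).
#' @export
select_depth_bins <- function(table, centers = seq(5, 50, by = 5),
                              per_center_n = 1000L) {
  check_particle_table(table, need = "depth_nm")
  n <- nrow(table)
  if (per_center_n > n)
    stop("per_center_n (", per_center_n, ") exceeds available particles (", n, ")")
  idx <- lapply(centers, function(cc) {
    o <- order(abs(table$depth_nm - cc))
    sort(o[seq_len(per_center_n)])
  })
  names(idx) <- paste0("depth_", centers, "nm")
  overlap <- if (length(centers) > 1L) {
    data.frame(
      center_a = centers[-length(centers)],
      center_b = centers[-1L],
      overlap_fraction = vapply(seq_len(length(centers) - 1L), function(i)
        length(intersect(idx[[i]], idx[[i + 1L]])) / per_center_n, numeric(1))
    )
  } else {
    data.frame(center_a = numeric(), center_b = numeric(),
               overlap_fraction = numeric())
  }
  list(groups = lapply(idx, function(i) table[i, , drop = FALSE]),
       overlap = overlap, index = idx)
}

#' High-quality particle filter
#'
#' Keeps particles from tomograms with local lamella thickness strictly below
#' `thickness_max_nm` and located strictly deeper than `depth_min_nm` from
#' the closest lamella surface, i.e. outside the ion-damage zone. Defaults
#' (<180 nm, >30 nm) are the thresholds at which neither thickness nor
#' surface damage measurably costs resolution.
#'
#' @param table particle table with `depth_nm` and `thickness_nm`.
#' @param thickness_max_nm strict upper bound on local thickness (nm).
#' @param depth_min_nm strict lower bound on depth (nm).
#' @return the filtered table, with a `per_tomogram` attribute giving the
#'   retained count per tomogram.
#' @export
select_high_quality <- function(table, thickness_max_nm = 180, depth_min_nm = 30) {
  check_particle_table(table, need = c("depth_nm", "thickness_nm"))
  keep <- table$thickness_nm < thickness_max_nm & table$depth_nm > depth_min_nm
  out <- table[keep, , drop = FALSE]
  attr(out, "per_tomogram") <-
    if ("tomo" %in% names(out)) table(out$tomo) else NULL
  out
}

#' Nested random particle subsets
#'
#' Draws subsets of the requested sizes by sequential random reduction, so
#' each smaller subset is contained in the next larger one (as when a
#' starfile is repeatedly thinned). Each subset's `match_key` distribution is
#' compared to the full table with a two-sample Kolmogorov-Smirnov test; a
#' subset with p below `p_threshold` triggers a warning (biased draw).
#'
#' @param table particle table.
#' @param sizes ascending subset sizes; the largest must not exceed the table.
#' @param seed integer seed; recorded on the result.
#' @param match_key column whose distribution must stay unbiased (default
#'   `"thickness_nm"`; `NULL` skips the check).
#' @param p_threshold KS p-value below which a warning is raised (default 0.01).
#' @return list with `subsets` (named list, one data.frame per size) and
#'   `checks` (data.frame of sizes and KS p-values); seed kept as attribute.
#' @export
random_subsets <- function(table, sizes, seed, match_key = "thickness_nm",
                           p_threshold = 0.01) {
  check_particle_table(table, need = character())
  stopifnot(!is.unsorted(sizes), max(sizes) <= nrow(table), all(sizes >= 1))
  set.seed(seed)
  perm <- sample.int(nrow(table), max(sizes))
  subsets <- lapply(sizes, function(s) table[sort(perm[seq_len(s)]), , drop = FALSE])
  names(subsets) <- paste0("n", sizes)
  pvals <- rep(NA_real_, length(sizes))
  if (!is.null(match_key)) {
    check_particle_table(table, need = match_key)
    full <- table[[match_key]]
    for (i in seq_along(sizes)) {
      p <- suppressWarnings(
        stats::ks.test(subsets[[i]][[match_key]], full)$p.value)
      pvals[i] <- p
      if (is.finite(p) && p < p_threshold)
        warning("subset of size ", sizes[i], " has a biased '", match_key,
                "' distribution (KS p = ", signif(p, 3), ")")
    }
  }
  structure(list(subsets = subsets,
                 checks = data.frame(size = sizes, ks_p = pvals)),
            seed = seed)
}

#' Random selection by whole tomograms
#'
#' Adds complete tomograms in random order until the cumulative particle
#' count first reaches `n_target`, then randomly trims particles from the
#' last tomogram added to hit `n_target` exactly. Selecting tomograms rather
#' than particles keeps many particles per tilt series, which is what
#' multiparticle refinement benefits from.
#'
#' @param table particle table with a `tomo` column.
#' @param n_target number of particles to select.
#' @param seed integer seed.
#' @return the selected particle table; attributes `tomograms` (selection
#'   order) and `seed`.
#' @export
select_by_tomogram <- function(table, n_target, seed) {
  check_particle_table(table, need = "tomo")
  stopifnot(n_target >= 1, n_target <= nrow(table))
  set.seed(seed)
  tomos <- sample(unique(table$tomo))
  chosen <- character()
  total <- 0L
  for (tm in tomos) {
    chosen <- c(chosen, tm)
    total <- total + sum(table$tomo == tm)
    if (total >= n_target) break
  }
  idx <- which(table$tomo %in% chosen)
  excess <- total - n_target
  if (excess > 0L) {
    last <- which(table$tomo == chosen[length(chosen)])
    drop <- sample(last, excess)
    idx <- setdiff(idx, drop)
  }
  out <- table[sort(idx), , drop = FALSE]
  attr(out, "tomograms") <- chosen
  attr(out, "seed") <- seed
  out
}
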