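# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive results by the most literal route available (lm(), explicit
# scans, brute-force sorts) so they stay independent of the package's own
# code paths.

# Literal histogram-scan surface oracle: bin in nm, plateau = median count of
# occupied non-extreme bins, edge = outer boundary of outermost bin >= thr.
oracle_surfaces <- function(z_nm, bin = 5, frac = 0.5) {
  breaks <- seq(floor(min(z_nm) / bin) * bin, ceiling(max(z_nm) / bin) * bin,
                by = bin)
  cnt <- hist(z_nm, breaks = breaks, plot = FALSE)$counts
  occ <- which(cnt > 0)
  inner <- setdiff(occ, range(occ))
  if (!length(inner)) inner <- occ
  thr <- frac * median(cnt[inner])
  q <- which(cnt >= thr)
  c(breaks[min(q)], breaks[max(q) + 1])
}

# Brute-force nearest-by-|depth - center| selection.
oracle_depth_bin <- function(depth, center, n) {
  sort(order(abs(depth - center))[seq_len(n)])
}

# Small synthetic particle table with known depth/thickness labels.
make_table <- function(n = 100, seed = 1) {
  set.seed(seed)
  data.frame(
    tomo = sample(paste0("t", 1:4), n, replace = TRUE),
    x = runif(n, 0, 500), y = runif(n, 0, 500), z = runif(n, 0, 200),
    rot = runif(n, -180, 180), tilt = runif(n, 0, 180),
    psi = runif(n, -180, 180),
    cc = runif(n, 0.1, 1),
    depth_nm = runif(n, 0, 90),
    thickness_nm = runif(n, 43, 255)
  )
}
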