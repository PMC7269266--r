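# Independent oracles and small fixture builders used across the suite.

# Logical disk mask of radius r px centred at (cx, cy) in an h x w raster
# (pixel-centre inclusion rule).
disk_mask <- function(h, w, cy, cx, r) {
  (outer(seq_len(h), rep(1, w)) - cy)^2 +
    (outer(rep(1, h), seq_len(w)) - cx)^2 <= r^2
}

# Brute-force Otsu: exhaustive search of 256 candidate thresholds for the
# maximum between-class variance. The objective is exactly flat across any
# data-free gap between the classes; ties are resolved to the centre of the
# maximizing plateau, matching what histogram implementations converge to.
otsu_bruteforce <- function(x) {
  rng <- range(x)
  cand <- seq(rng[1], rng[2], length.out = 256L)[-256]
  v <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  mean(range(cand[v >= max(v) - 1e-9 * max(v)]))
}

# Second, independently coded histogram density (used against
# size_distributions): simple loop over bins.
histogram_density_oracle <- function(values, weights, edges) {
  dens <- numeric(length(edges) - 1L)
  for (b in seq_along(dens)) {
    inside <- values > edges[b] & values <= edges[b + 1L]
    if (b == 1L) inside <- inside | values <= edges[1L]
    dens[b] <- sum(weights[inside])
  }
  dens / (sum(weights) * diff(edges))
}

# Match measured objects to truth rows by nearest centroid; returns a data
# frame of per-truth-object matches (NA where nothing within max_dist px).
match_truth <- function(measurements, truth, max_dist = 10) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    d2 <- (measurements$centroid_x_px - truth$center_x_px[i])^2 +
      (measurements$centroid_y_px - truth$center_y_px[i])^2
    j <- which.min(d2)
    if (!length(j) || sqrt(d2[j]) > max_dist)
      return(data.frame(truth_id = truth$id[i], matched = FALSE,
                        measured_d = NA_real_, true_d = truth$true_equivalent_diameter_um[i]))
    data.frame(truth_id = truth$id[i], matched = TRUE,
               measured_d = measurements$equivalent_diameter_um[j],
               true_d = truth$true_equivalent_diameter_um[i])
  })
  do.call(rbind, out)
}

# Build a pulse profile on an integer position grid from channel vectors,
# defaulting unspecified channels to zero.
make_profile <- function(position, fsc = NULL, ssc = NULL, flg = NULL,
                         flr = NULL, saturation_mv = Inf, trigger_mv = 200,
                         stained = TRUE) {
  z <- numeric(length(position))
  pulse_profile(position, fsc %||% z, ssc %||% z, flg %||% z, flr %||% z,
                saturation_mv = saturation_mv, trigger_mv = trigger_mv,
                stained = stained)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Rectangle channel: `height` on [from, to] (inclusive of grid points),
# zero elsewhere.
rect_channel <- function(position, from, to, height) {
  ifelse(position >= from & position <= to, height, 0)
}
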