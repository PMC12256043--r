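# Brute-force grid-search oracle for Michaelis-Menten least squares,
# independent of the package's optimiser: evaluates the residual sum of
# squares over a log-spaced (Km, Vmax) grid and returns the best grid point.
mm_grid_oracle <- function(S, v, km_range, vmax_range, n = 400) {
  km_grid <- exp(seq(log(km_range[1]), log(km_range[2]), length.out = n))
  vmax_grid <- exp(seq(log(vmax_range[1]), log(vmax_range[2]), length.out = n))
  best_km <- NA_real_
  best_vmax <- NA_real_
  best_sse <- Inf
  vv <- sum(v^2)
  for (km in km_grid) {
    pred <- S / (km + S)
    sse <- vv - 2 * vmax_grid * sum(v * pred) + vmax_grid^2 * sum(pred^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best_km <- km
      best_vmax <- vmax_grid[j]
    }
  }
  list(km = best_km, vmax = best_vmax, sse = best_sse,
       km_step = km_grid[2] / km_grid[1], vmax_step = vmax_grid[2] / vmax_grid[1])
}

# Noiseless Michaelis-Menten rate table at the default substrate series.
mm_rates <- function(km, vmax, S = default_substrate_series()) {
  tibble::tibble(substrate_uM = S, rate_uM_per_s = vmax * S / (km + S))
}
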