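#' Estimate melting temperatures from thermofluor melt curves
#'
#' Estimates the unfolding midpoint (Tm) of each melt curve in a long-format
#' table, either by non-linear least-squares fit of the two-state model
#' (linear pre-transition baseline + sigmoidal transition + linear
#' post-transition decay; `method = "boltzmann"`) or from the maximum of the
#' smoothed first derivative restricted to the rising phase
#' (`method = "derivative"`). The Boltzmann fit is initialised from the
#' derivative estimate.
#'
#' A transition is declared absent when the (fitted or apparent) amplitude
#' does not exceed `max(3 * fit RMSE, 5%` of the fluorescence range`)`, or
#' when the midpoint lands within 2 degC of either end of the temperature
#' range; such curves get `transition_detected = FALSE` and `tm_C = NA`.
#'
#' @param curves Data frame with columns `condition_id`, `protein_id`,
#'   `temperature_C`, `fluorescence` (one or more curves; each curve needs
#'   >= 10 strictly increasing temperatures).
#' @param method `"boltzmann"` (default) or `"derivative"`.
#' @return A tibble with one row per curve: `condition_id`, `protein_id`,
#'   `tm_C` (NA when no transition), `method`, `amplitude_AU`, `fit_rmse`,
#'   `transition_detected`.
#' @export
#' @examples
#' sim <- gen_melt_curve(tm_C = 70, noise_sd = 0)
#' estimate_tm(sim$curve)
estimate_tm <- function(curves, method = c("boltzmann", "derivative")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(curves))
  req <- c("condition_id", "protein_id", "temperature_C", "fluorescence")
  if (!all(req %in% names(curves)))
    abort(paste0("`curves` must have columns: ", paste(req, collapse = ", ")))
  curves |>
    dplyr::group_by(.data$condition_id, .data$protein_id) |>
    dplyr::group_modify(function(df, key) {
      estimate_tm_one(df$temperature_C, df$fluorescence, method)
    }) |>
    dplyr::ungroup()
}

estimate_tm_one <- function(T, f, method) {
  if (length(T) < 10) abort("Each melt curve needs at least 10 points.")
  if (any(diff(T) <= 0)) abort("Temperatures must be strictly increasing.")
  f_range <- diff(range(f))

  ## smoothed first derivative, restricted to the rising phase
  smoothed <- if (length(f) >= 5) signal::sgolayfilt(f, p = 2, n = 5) else f
  deriv <- c(NA, diff(smoothed, lag = 2) / diff(T, lag = 2), NA)
  i_max <- which.max(smoothed)
  rising <- seq_len(i_max)
  d_rise <- deriv[rising]
  i_tm <- if (all(is.na(d_rise))) NA_integer_ else which.max(d_rise)
  tm_deriv <- if (is.na(i_tm)) NA_real_ else T[i_tm]
  smooth_rmse <- sqrt(mean((f - smoothed)^2))

  if (method == "derivative") {
    amp <- if (is.na(i_tm)) 0 else smoothed[i_max] - min(smoothed[seq_len(max(i_tm, 1))])
    detected <- !is.na(tm_deriv) &&
      amp > max(3 * smooth_rmse, 0.05 * f_range) &&
      tm_deriv > min(T) + 2 && tm_deriv < max(T) - 2
    return(tibble::tibble(
      tm_C = if (detected) tm_deriv else NA_real_, method = "derivative",
      amplitude_AU = amp, fit_rmse = smooth_rmse,
      transition_detected = detected
    ))
  }

  ## Boltzmann two-state fit, initialised from the derivative estimate
  tm0 <- if (is.na(tm_deriv)) stats::median(T) else tm_deriv
  pre <- T < tm0 - 5
  if (sum(pre) < 3) pre <- seq_along(T) <= 5
  base_fit <- lm(f[pre] ~ T[pre])
  start <- list(
    baseline = unname(coef(base_fit)[1]),
    slope_pre = unname(coef(base_fit)[2]),
    amplitude = max(f_range, 1e-6), tm_C = tm0, steepness = 2,
    slope_post = -1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ melt_model(T, baseline, slope_pre, amplitude, tm_C, steepness,
                     slope_post),
      start = start,
      lower = c(-Inf, -Inf, 0, min(T), 0.1, -Inf),
      upper = c(Inf, Inf, Inf, max(T), 30, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(tm_C = NA_real_, method = "boltzmann",
                          amplitude_AU = 0, fit_rmse = NA_real_,
                          transition_detected = FALSE))
  }
  cf <- coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  detected <- cf[["amplitude"]] > max(3 * rmse, 0.05 * f_range) &&
    cf[["tm_C"]] > min(T) + 2 && cf[["tm_C"]] < max(T) - 2
  tibble::tibble(
    tm_C = if (detected) cf[["tm_C"]] else NA_real_, method = "boltzmann",
    amplitude_AU = cf[["amplitude"]], fit_rmse = rmse,
    transition_detected = detected
  )
}

#' Thermal shift relative to a reference condition
#'
#' `compute_delta_tm()` is the elementwise difference
#' `tm_condition_C - tm_reference_C`; an absent Tm (no transition, `NA`)
#' propagates to an absent shift.
#'
#' @param tm_condition_C,tm_reference_C Melting temperatures in degC
#'   (vectorised; `NA` = no measurable transition).
#' @return Numeric vector of thermal shifts in degC.
#' @export
#' @examples
#' compute_delta_tm(83.18, 76.46)
compute_delta_tm <- function(tm_condition_C, tm_reference_C) {
  tm_condition_C - tm_reference_C
}

#' Tabulate thermal shifts against the water-control reference
#'
#' Joins each condition's Tm with the per-protein reference (water-control)
#' Tm and computes the shift and the stabilisation flag (strictly greater
#' than `threshold`).
#'
#' @param tm_results Output of [estimate_tm()] for a full screen (must
#'   include the reference condition for every protein).
#' @param reference_id Condition id of the water control.
#' @param threshold Stabilisation threshold in degC (strict inequality).
#' @return A tibble: `condition_id`, `protein_id`, `tm_C`, `delta_tm_C`,
#'   `stabilising`, `no_transition`.
#' @export
delta_tm_table <- function(tm_results, reference_id = "water_control",
                           threshold = 4) {
  refs <- tm_results |>
    dplyr::filter(.data$condition_id == reference_id) |>
    dplyr::select("protein_id", ref_tm_C = "tm_C")
  if (nrow(refs) == 0)
    abort(paste0("No reference condition '", reference_id, "' in results."))
  tm_results |>
    dplyr::filter(.data$condition_id != reference_id) |>
    dplyr::left_join(refs, by = "protein_id") |>
    dplyr::mutate(
      delta_tm_C = compute_delta_tm(.data$tm_C, .data$ref_tm_C),
      stabilising = !is.na(.data$delta_tm_C) & .data$delta_tm_C > threshold,
      no_transition = is.na(.data$tm_C)
    ) |>
    dplyr::select("condition_id", "protein_id", "tm_C", "delta_tm_C",
                  "stabilising", "no_transition")
}

#' Rank buffer conditions by median thermal shift across proteins
#'
#' For each condition, takes the median shift across proteins (conditions
#' with no measurable transition are excluded from that condition's median,
#' with the exclusion count reported) and flags conditions whose median
#' shift exceeds the stabilisation threshold (strictly). The table is
#' sorted by descending median shift with a deterministic tie-break on
#' condition id.
#'
#' @param delta_entries Tibble with `condition_id`, `protein_id`,
#'   `delta_tm_C` (NA = no transition), as from [delta_tm_table()].
#' @param threshold Stabilisation threshold in degC.
#' @return A tibble: `condition_id`, `median_delta_tm_C`, `n_proteins`,
#'   `n_no_transition`, `stabilising`.
#' @export
rank_buffers <- function(delta_entries, threshold = 4) {
  if (!is.data.frame(delta_entries) || nrow(delta_entries) == 0)
    abort("`delta_entries` must be a non-empty data frame.")
  delta_entries |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      median_delta_tm_C = median(.data$delta_tm_C, na.rm = TRUE),
      n_proteins = dplyr::n(),
      n_no_transition = sum(is.na(.data$delta_tm_C)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      median_delta_tm_C = dplyr::if_else(is.nan(.data$median_delta_tm_C),
                                         NA_real_, .data$median_delta_tm_C),
      stabilising = !is.na(.data$median_delta_tm_C) &
        .data$median_delta_tm_C > threshold
    ) |>
    dplyr::arrange(dplyr::desc(.data$median_delta_tm_C), .data$condition_id)
}

#' Most stabilising condition per protein
#'
#' Picks, for each protein, the screen condition with the largest thermal
#' shift (ties broken towards the lexicographically lower condition id).
#' Proteins with no detected transition in any condition are flagged
#' `"none"`.
#'
#' @param delta_entries Tibble as from [delta_tm_table()] (needs `tm_C`).
#' @return A tibble: `protein_id`, `best_condition`, `tm_C`, `delta_tm_C`.
#' @export
best_condition_per_protein <- function(delta_entries) {
  delta_entries |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- df[!is.na(df$delta_tm_C), ]
      if (nrow(ok) == 0)
        return(tibble::tibble(best_condition = "none", tm_C = NA_real_,
                              delta_tm_C = NA_real_))
      ok <- ok[order(-ok$delta_tm_C, ok$condition_id), ]
      tibble::tibble(best_condition = ok$condition_id[1], tm_C = ok$tm_C[1],
                     delta_tm_C = ok$delta_tm_C[1])
    }) |>
    dplyr::ungroup()
}

#' Default buffer/pH systems of the stability screen
#'
#' Eight buffer/pH systems spanning pH 5.5-9.0, commonly used for terpene
#' synthase storage-buffer screening.
#'
#' @return A tibble with columns `buffer`, `pH`.
#' @export
default_screen_buffers <- function() {
  tibble::tibble(
    buffer = c("MES", "Bis-Tris", "HEPES", "HEPES", "Tris", "Tris", "Tris",
               "CAPS"),
    pH = c(5.5, 6.0, 7.0, 7.5, 7.5, 8.0, 8.5, 9.0)
  )
}

#' Enumerate a thermofluor buffer-screen design
#'
#' Cross-product enumeration of buffer/pH systems with salt additives:
#' buffer-major order; within each buffer, the no-salt condition first, then
#' each salt in the configured order at ascending concentrations. The
#' default design is 8 buffer/pH systems x (1 no-salt + 3 salts x 3
#' concentrations) = 80 conditions.
#'
#' @param buffers Tibble with columns `buffer`, `pH` (pairs must be unique).
#' @param salts Character vector of salt names.
#' @param salt_mM Numeric vector of salt concentrations, mM (ascending use).
#' @param buffer_mM Buffer concentration, mM.
#' @return A tibble: `condition_id`, `buffer`, `buffer_mM`, `pH`, `salt`
#'   (NA for no-salt), `salt_mM` (0 for no-salt).
#' @export
#' @examples
#' nrow(make_buffer_screen())  # 80
make_buffer_screen <- function(buffers = default_screen_buffers(),
                               salts = c("NaCl", "KCl", "MgCl2"),
                               salt_mM = c(50, 100, 200), buffer_mM = 200) {
  if (nrow(buffers) == 0) abort("`buffers` must be non-empty.")
  if (any(buffer_mM < 0) || any(salt_mM < 0))
    abort("Concentrations must be non-negative.")
  if (anyDuplicated(buffers[c("buffer", "pH")]))
    abort("Duplicate buffer/pH pairs in `buffers`.")
  salt_block <- dplyr::bind_rows(
    tibble::tibble(salt = NA_character_, salt_mM = 0),
    tidyr::expand_grid(salt = salts, salt_mM = sort(salt_mM))
  )
  design <- tidyr::expand_grid(buffers, salt_block) |>
    dplyr::mutate(buffer_mM = buffer_mM,
                  condition_id = sprintf("C%03d", dplyr::row_number())) |>
    dplyr::select("condition_id", "buffer", "buffer_mM", "pH", "salt",
                  "salt_mM")
  design
}
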