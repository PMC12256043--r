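#' Fit a phosphate standard curve
#'
#' Ordinary least-squares calibration line `A = slope * c + intercept` for
#' malachite-green endpoint absorbance against Pi (or PPi) concentration.
#'
#' @param concentrations_uM Analyte concentrations, uM (>= 3 distinct
#'   values).
#' @param absorbances_AU Endpoint absorbances at 623 nm, AU.
#' @param analyte `"Pi"` or `"PPi"`.
#' @return A `standard_curve` object: list with `analyte`, `slope`,
#'   `intercept`, `r_squared`, and the input `data` tibble.
#' @export
#' @examples
#' fit_standard_curve(c(1, 2, 4, 8), 0.05 + 0.012 * c(1, 2, 4, 8))
fit_standard_curve <- function(concentrations_uM, absorbances_AU,
                               analyte = c("Pi", "PPi")) {
  analyte <- match.arg(analyte)
  if (length(concentrations_uM) != length(absorbances_AU))
    abort("Concentration and absorbance vectors must have equal length.")
  if (length(concentrations_uM) < 3)
    abort("A standard curve needs at least 3 points.")
  if (length(unique(concentrations_uM)) < 2)
    abort("Standard-curve concentrations are degenerate (all equal).")
  fit <- lm(absorbances_AU ~ concentrations_uM)
  ss_tot <- sum((absorbances_AU - mean(absorbances_AU))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(analyte = analyte,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2,
         data = tibble::tibble(concentration_uM = concentrations_uM,
                               absorbance_AU = absorbances_AU)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: A = %.5f * c + %.5f (R^2 = %.5f, n = %d)\n",
              x$analyte, x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Convert endpoint absorbance to an initial rate
#'
#' Reverses the malachite-green calibration:
#' `Pi = max(0, (A - background - intercept)) / slope` and
#' `rate = Pi / (pi_per_turnover * incubation_s)`. With pyrophosphatase in
#' the assay each substrate turnover releases one PPi hydrolysed to two Pi,
#' hence the default `pi_per_turnover = 2`. Negative net absorbances are
#' floored at zero with a warning.
#'
#' @param absorbance Endpoint absorbance, AU (vectorised).
#' @param background Background absorbance to subtract, AU (net of the
#'   standard-curve intercept).
#' @param curve A [fit_standard_curve()] object.
#' @param incubation_s Endpoint incubation time, s (> 0).
#' @param pi_per_turnover Pi released per turnover (>= 1).
#' @return Initial rates in uM/s.
#' @export
#' @examples
#' sc <- fit_standard_curve(c(1, 2, 4), 0.01 * c(1, 2, 4))
#' absorbance_to_rate(0.036, 0, sc, incubation_s = 1800)
absorbance_to_rate <- function(absorbance, background, curve, incubation_s,
                               pi_per_turnover = 2) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) abort("Standard-curve slope must be positive.")
  if (incubation_s <= 0) abort("`incubation_s` must be > 0.")
  if (pi_per_turnover < 1) abort("`pi_per_turnover` must be >= 1.")
  net <- absorbance - background - curve$intercept
  if (any(net < -1e-12, na.rm = TRUE))
    warn("Negative net absorbance(s) floored to rate 0.")
  pi_uM <- pmax(0, net) / curve$slope
  pi_uM / (pi_per_turnover * incubation_s)
}

#' Fit the Michaelis-Menten model
#'
#' Non-linear least squares for `v = Vmax * S / (Km + S)`, initialised with
#' `Vmax0 = 1.2 * max(v)` and `Km0 =` the substrate level whose rate is
#' nearest `max(v) / 2`, with positivity enforced via box constraints.
#' Standard errors come from the curvature (Fisher information) at the
#' optimum.
#'
#' @param data Data frame with columns `substrate_uM` and `rate_uM_per_s`
#'   (>= 5 substrate levels), optionally `enzyme_id`, `substrate`,
#'   `enzyme_conc_uM`.
#' @param enzyme_conc Effective enzyme concentration used for the kcat
#'   conversion (same concentration unit as Vmax); default 10, the value
#'   that reproduces the reference panel's printed turnover numbers.
#' @return An `mm_fit` object: list with `km_uM`, `vmax_uM_per_s`,
#'   `kcat_per_s`, `km_se`, `vmax_se`, `converged`, `enzyme_conc`, `data`,
#'   plus identifiers when present. Has [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' S <- default_substrate_series()
#' d <- data.frame(substrate_uM = S,
#'                 rate_uM_per_s = 0.2038 * S / (7.809 + S))
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, enzyme_conc = 10) {
  stopifnot(is.data.frame(data))
  if (!all(c("substrate_uM", "rate_uM_per_s") %in% names(data)))
    abort("`data` needs columns `substrate_uM` and `rate_uM_per_s`.")
  S <- data$substrate_uM
  v <- data$rate_uM_per_s
  if (any(S <= 0)) abort("Substrate concentrations must be strictly positive.")
  if (any(v < 0)) abort("Rates must be non-negative.")
  if (length(unique(S)) < 5)
    abort("Need at least 5 distinct substrate levels.")
  if (all(v == 0)) abort("All rates are zero; nothing to fit.")

  vmax0 <- 1.2 * max(v)
  km0 <- S[which.min(abs(v - max(v) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * S / (km + S),
      start = list(vmax = vmax0, km = km0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- list(km_uM = km0, vmax_uM_per_s = vmax0, kcat_per_s = NA_real_,
                km_se = NA_real_, vmax_se = NA_real_, converged = FALSE,
                enzyme_conc = enzyme_conc,
                enzyme_id = data$enzyme_id[1] %||% NA_character_,
                substrate = data$substrate[1] %||% NA_character_,
                data = tibble::as_tibble(data))
    return(structure(res, class = "mm_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  res <- list(
    km_uM = unname(cf[["km"]]), vmax_uM_per_s = unname(cf[["vmax"]]),
    kcat_per_s = unname(cf[["vmax"]]) / enzyme_conc,
    km_se = unname(se[["km"]]), vmax_se = unname(se[["vmax"]]),
    converged = fit$convInfo$isConv %||% TRUE,
    enzyme_conc = enzyme_conc,
    enzyme_id = if ("enzyme_id" %in% names(data)) data$enzyme_id[1] else NA_character_,
    substrate = if ("substrate" %in% names(data)) data$substrate[1] else NA_character_,
    data = tibble::as_tibble(data)
  )
  structure(res, class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g uM, Vmax = %.4g uM/s, kcat = %.4f 1/s (E0 = %g)%s\n",
              x$km_uM, x$vmax_uM_per_s, round_half_up(x$kcat_per_s, 4),
              x$enzyme_conc,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Turnover number from a maximal rate
#'
#' `kcat = Vmax / E0`. The default effective enzyme concentration of 10
#' (in Vmax's concentration unit) reproduces the reference panel's printed
#' turnover numbers; it is configurable for assays with a known molar
#' enzyme concentration.
#'
#' @param vmax_uM_per_s Maximal rate, uM/s.
#' @param enzyme_conc Effective enzyme concentration E0 (> 0).
#' @param digits Decimal places for the reported value (half-away-from-zero
#'   rounding); use `NULL` for full precision.
#' @return kcat in 1/s.
#' @export
#' @examples
#' compute_kcat(0.2038)  # 0.0204
compute_kcat <- function(vmax_uM_per_s, enzyme_conc = 10, digits = 4) {
  if (any(enzyme_conc <= 0)) abort("`enzyme_conc` must be > 0.")
  kcat <- vmax_uM_per_s / enzyme_conc
  if (is.null(digits)) kcat else round_half_up(kcat, digits)
}

#' Process a malachite-green plate into a rate dataset
#'
#' Fits the Pi standard curve from the plate's standard wells, averages the
#' substrate-free background wells (net of the fitted intercept), converts
#' sample absorbances to rates with [absorbance_to_rate()], and averages
#' replicates per substrate level.
#'
#' @param plate Plate tibble with columns `role` (`sample`/`standard`/
#'   `background`), `substrate_uM`, `analyte_uM`, `absorbance`, `replicate`,
#'   as produced by [gen_kinetics_plate()] or read from a plate CSV.
#' @param incubation_s Endpoint incubation time, s.
#' @param pi_per_turnover Pi released per turnover.
#' @return A list with `rates` (tibble: `substrate_uM`, `rate_uM_per_s`
#'   plus identifiers) and `standard_curve`.
#' @export
process_kinetics_plate <- function(plate, incubation_s = 1800,
                                   pi_per_turnover = 2) {
  stopifnot(is.data.frame(plate))
  std <- plate[plate$role == "standard", ]
  if (nrow(std) < 3) abort("Plate has no usable standard-curve block.")
  sc <- fit_standard_curve(std$analyte_uM, std$absorbance)
  bg_wells <- plate[plate$role == "background", ]
  background <- if (nrow(bg_wells)) mean(bg_wells$absorbance) - sc$intercept else 0
  samples <- plate[plate$role == "sample", ]
  rates <- samples |>
    dplyr::mutate(rate_uM_per_s = absorbance_to_rate(
      .data$absorbance, background, sc, incubation_s, pi_per_turnover
    )) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("enzyme_id", "substrate",
                                                  "substrate_uM")))) |>
    dplyr::summarise(rate_uM_per_s = mean(.data$rate_uM_per_s),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$substrate_uM))
  list(rates = rates, standard_curve = sc)
}

#' Summarise a panel of Michaelis-Menten fits
#'
#' Collates enzyme x substrate kinetic parameters into one table and
#' reports the minimum and maximum turnover number across converged fits.
#'
#' @param fits A list of [fit_michaelis_menten()] objects.
#' @param digits Decimal places for the reported kcat.
#' @return A list with `table` (tibble: `enzyme_id`, `substrate`, `km_uM`,
#'   `km_se`, `vmax_uM_per_s`, `vmax_se`, `kcat_per_s`, `converged`),
#'   `kcat_min`, `kcat_max`, and `n_converged`. When no fit converged, the
#'   extremes are `NA` and `note = "no converged fits"`.
#' @export
summarize_panel <- function(fits, digits = 4) {
  if (length(fits) == 0) abort("`fits` must contain at least one fit.")
  stopifnot(all(vapply(fits, inherits, logical(1), "mm_fit")))
  tab <- purrr::map(fits, function(f) {
    tibble::tibble(
      enzyme_id = f$enzyme_id, substrate = f$substrate, km_uM = f$km_uM,
      km_se = f$km_se, vmax_uM_per_s = f$vmax_uM_per_s, vmax_se = f$vmax_se,
      kcat_per_s = round_half_up(f$kcat_per_s, digits),
      converged = isTRUE(f$converged)
    )
  }) |> purrr::list_rbind()
  ok <- tab[tab$converged, ]
  if (nrow(ok) == 0) {
    list(table = tab, kcat_min = NA_real_, kcat_max = NA_real_,
         n_converged = 0L, note = "no converged fits")
  } else {
    list(table = tab, kcat_min = min(ok$kcat_per_s),
         kcat_max = max(ok$kcat_per_s), n_converged = nrow(ok))
  }
}
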