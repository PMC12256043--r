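#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("km_uM", "vmax_uM_per_s"),
    estimate = c(x$km_uM, x$vmax_uM_per_s),
    std.error = c(x$km_se, x$vmax_se)
  )
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `enzyme_id`, `substrate`, `km_uM`,
#'   `vmax_uM_per_s`, `kcat_per_s`, `enzyme_conc`, `converged`, `nobs`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    enzyme_id = x$enzyme_id, substrate = x$substrate, km_uM = x$km_uM,
    vmax_uM_per_s = x$vmax_uM_per_s, kcat_per_s = x$kcat_per_s,
    enzyme_conc = x$enzyme_conc, converged = x$converged,
    nobs = nrow(x$data)
  )
}

#' Tidy a standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return A one-row tibble: `analyte`, `slope`, `intercept`, `r_squared`,
#'   `nobs`.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(analyte = x$analyte, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 nobs = nrow(x$data))
}

#' Tidy a product profile
#'
#' @param x A `product_profile` object.
#' @param ... Unused.
#' @return The composition tibble with sample identifiers prepended.
#' @export
tidy.product_profile <- function(x, ...) {
  if (nrow(x$composition) == 0) {
    return(tibble::tibble(sample_id = character(), substrate = character(),
                          compound = character(), percent = numeric(),
                          putative = logical()))
  }
  dplyr::mutate(x$composition, sample_id = x$sample_id,
                substrate = x$substrate, .before = 1)
}

#' Tidy a frequency report
#'
#' @param x A `frequency_report` object.
#' @param ... Unused.
#' @return A long tibble: `category`, `name`, `n`, `percent`.
#' @export
tidy.frequency_report <- function(x, ...) {
  cats <- c("buffer_pct", "ph_bin_pct", "salt_pct", "precipitant_pct",
            "peg_subtype_pct")
  purrr::map(cats, function(ct) {
    dplyr::mutate(x[[ct]], category = sub("_pct$", "", ct), .before = 1)
  }) |> purrr::list_rbind()
}
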