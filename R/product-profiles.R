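#' Subtract boiled-enzyme control peaks from a sample peak table
#'
#' Implements the background rule for GC-MS assays with boiled-enzyme
#' controls: a sample peak whose retention time matches a control peak
#' within `rt_tol_min` is removed entirely when its area is at most twice
#' the control peak's area (indistinguishable from background), and
#' otherwise retained with the control area subtracted (floored at zero).
#'
#' @param sample,control Peak tables (tibbles with at least `rt_min`,
#'   `area`). An empty control is valid and leaves the sample unchanged.
#' @param rt_tol_min Retention-time matching tolerance in minutes (> 0).
#' @return The corrected sample peak table.
#' @export
subtract_background <- function(sample, control, rt_tol_min = 0.10) {
  stopifnot(is.data.frame(sample), is.data.frame(control))
  if (rt_tol_min <= 0) abort("`rt_tol_min` must be > 0.")
  if (nrow(control) == 0 || nrow(sample) == 0) return(sample)
  keep <- logical(nrow(sample))
  area <- sample$area
  for (i in seq_len(nrow(sample))) {
    j <- which(abs(control$rt_min - sample$rt_min[i]) <= rt_tol_min)
    if (length(j) == 0) {
      keep[i] <- TRUE
      next
    }
    ctrl_area <- max(control$area[j])
    if (area[i] <= 2 * ctrl_area) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      area[i] <- max(0, area[i] - ctrl_area)
    }
  }
  out <- sample
  out$area <- area
  out[keep, , drop = FALSE]
}

#' Classify peaks by compound class
#'
#' Assigns each peak a class (`monoterpene`, `sesquiterpene`,
#' `internal_standard`, `non_terpene` or `unknown`) and a putative flag
#' (library-match-only identification) from the compound lexicon. The
#' internal standard (isobutylbenzene) is recognised by name.
#'
#' @param peaks Peak table with a `compound` column.
#' @param lexicon Compound lexicon, as from [terpene_lexicon()].
#' @return The peak table with `klass` and `putative` columns (re)assigned.
#' @export
#' @examples
#' classify_peaks(tibble::tibble(compound = "β-myrcene", rt_min = 14.2,
#'                               area = 100))$klass
classify_peaks <- function(peaks, lexicon = terpene_lexicon()) {
  stopifnot(is.data.frame(peaks), "compound" %in% names(peaks))
  peaks$klass <- NULL
  peaks$putative <- NULL
  peaks$parent <- NULL
  peaks |>
    dplyr::left_join(
      lexicon |> dplyr::select("compound", "klass", "putative", "parent"),
      by = "compound"
    ) |>
    dplyr::mutate(
      klass = dplyr::coalesce(.data$klass, "unknown"),
      putative = dplyr::coalesce(.data$putative, FALSE)
    )
}

#' Percent-of-total terpene composition of a sample
#'
#' Computes the percent composition over peaks classified as monoterpene or
#' sesquiterpene: the denominator is their summed area, and internal
#' standard, non-terpene and unknown peaks are excluded (listed with
#' reasons). A sample with no terpene peaks (e.g. a GGPP assay of a
#' mono/sesqui synthase) is reported inactive with an empty composition.
#'
#' @param peaks A classified peak table (see [classify_peaks()]); peaks must
#'   carry non-negative areas.
#' @param alias_parent Report thermal-degradation artefacts under their
#'   parent compound name (e.g. elemol as hedycaryol) when `TRUE`.
#' @param digits Decimal places for percentages.
#' @return A `product_profile` object: list with `sample_id`, `substrate`,
#'   `composition` (tibble: `compound`, `percent`, `putative`), `excluded`
#'   (tibble: `compound`, `reason`) and `active`.
#' @export
#' @examples
#' pk <- gen_peak_table(c("β-myrcene" = 100))$peaks
#' percent_composition(classify_peaks(pk))
percent_composition <- function(peaks, alias_parent = FALSE, digits = 2) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("compound", "area", "klass") %in% names(peaks)))
    abort("`peaks` must be classified first (needs compound, area, klass).")
  if (any(peaks$area < 0)) abort("Peak areas must be non-negative.")
  if (!"putative" %in% names(peaks)) peaks$putative <- FALSE
  terp <- peaks[peaks$klass %in% c("monoterpene", "sesquiterpene"), ]
  excl <- peaks[!peaks$klass %in% c("monoterpene", "sesquiterpene"), ]
  denominator <- sum(terp$area)
  if (alias_parent && "parent" %in% names(terp)) {
    terp$compound <- dplyr::coalesce(terp$parent, terp$compound)
  }
  composition <- if (denominator > 0) {
    terp |>
      dplyr::group_by(.data$compound) |>
      dplyr::summarise(area = sum(.data$area),
                       putative = any(.data$putative),
                       .groups = "drop") |>
      dplyr::mutate(percent = round_half_up(100 * .data$area / denominator,
                                            digits)) |>
      dplyr::arrange(dplyr::desc(.data$percent), .data$compound) |>
      dplyr::select("compound", "percent", "putative")
  } else {
    tibble::tibble(compound = character(), percent = numeric(),
                   putative = logical())
  }
  structure(
    list(
      sample_id = if ("sample_id" %in% names(peaks)) peaks$sample_id[1] else NA_character_,
      substrate = if ("substrate" %in% names(peaks)) peaks$substrate[1] else NA_character_,
      composition = composition,
      excluded = tibble::tibble(
        compound = excl$compound,
        reason = dplyr::case_match(excl$klass,
                                   "internal_standard" ~ "internal standard",
                                   "non_terpene" ~ "not a mono-/sesquiterpene",
                                   .default = "unidentified compound")
      ),
      active = denominator > 0
    ),
    class = "product_profile"
  )
}

#' @export
print.product_profile <- function(x, ...) {
  cat(sprintf("<product_profile> %s + %s (%s)\n", x$sample_id, x$substrate,
              if (x$active) "active" else "inactive"))
  if (x$active) print(x$composition)
  if (nrow(x$excluded))
    cat("excluded:", paste(x$excluded$compound, collapse = ", "), "\n")
  invisible(x)
}

#' Substrate-activity classification of an enzyme panel
#'
#' Labels each enzyme by the substrates on which it yielded an active
#' product profile: `"Mono"` (GPP only), `"Sesqui"` (FPP only),
#' `"Mono/Sesqui"` (both) or `"inactive"`. GGPP activity (diterpene
#' formation) is reported in its own column; none of the characterised
#' panel enzymes shows it.
#'
#' @param profiles A list of [percent_composition()] results; `sample_id`
#'   is taken as the enzyme identifier.
#' @return A tibble: `enzyme_id`, `active_GPP`, `active_FPP`, `active_GGPP`,
#'   `tps_type`.
#' @export
substrate_activity_matrix <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "product_profile")))
  purrr::map(profiles, function(p) {
    tibble::tibble(enzyme_id = p$sample_id, substrate = p$substrate,
                   active = p$active)
  }) |>
    purrr::list_rbind() |>
    dplyr::group_by(.data$enzyme_id) |>
    dplyr::summarise(
      active_GPP = any(.data$active[.data$substrate == "GPP"]),
      active_FPP = any(.data$active[.data$substrate == "FPP"]),
      active_GGPP = any(.data$active[.data$substrate == "GGPP"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(tps_type = dplyr::case_when(
      .data$active_GPP & .data$active_FPP ~ "Mono/Sesqui",
      .data$active_GPP ~ "Mono",
      .data$active_FPP ~ "Sesqui",
      .default = "inactive"
    ))
}

#' Spectral match score between two binned mass spectra
#'
#' A transparent stand-in for a spectral-library match score: 1000 times
#' the squared cosine similarity of square-root-scaled intensities.
#' Symmetric in its arguments and invariant to intensity scaling.
#'
#' @param query,reference Non-negative intensity vectors over the same m/z
#'   binning.
#' @return A score in \[0, 1000\].
#' @export
#' @examples
#' match_spectrum(c(1, 0, 2), c(2, 0, 4))  # 1000
match_spectrum <- function(query, reference) {
  if (length(query) != length(reference))
    abort("Spectra must share the same m/z binning.")
  if (any(query < 0) || any(reference < 0))
    abort("Intensities must be non-negative.")
  q <- sqrt(query)
  r <- sqrt(reference)
  if (sum(q) == 0 || sum(r) == 0) {
    warn("All-zero spectrum; returning score 0.")
    return(0)
  }
  cosine <- sum(q * r) / sqrt(sum(q^2) * sum(r^2))
  1000 * cosine^2
}
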