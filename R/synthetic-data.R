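#' Ground truth attached to synthetic datasets
#'
#' Every generator returns, alongside its dataset, a `ground_truth` object
#' recording the generator kind, the full generative parameter set and the
#' seed, so the dataset can be re-simulated bit-identically with
#' [regenerate()].
#'
#' @param kind One of `"melt"`, `"melt_screen"`, `"kinetics"`, `"peaks"`,
#'   `"corpus"`.
#' @param params Named list of generative parameters.
#' @param seed Integer seed (or `NULL` for deterministic generators).
#' @return A `ground_truth` object (a list with elements `kind`, `params`,
#'   `seed`).
#' @export
new_ground_truth <- function(kind, params, seed = NULL) {
  kind <- match.arg(kind, c("melt", "melt_screen", "kinetics", "peaks", "corpus"))
  structure(list(kind = kind, params = params, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$kind, "seed:", x$seed %||% NA_integer_, "\n")
  cat("  params:", paste(names(x$params), collapse = ", "), "\n")
  invisible(x)
}

#' Re-simulate a dataset from its ground truth
#'
#' Calls the generator named by `truth$kind` with the recorded parameters
#' and seed; the result is bit-identical to the original dataset.
#'
#' @param truth A [new_ground_truth()] object.
#' @return The regenerated dataset (same shape as the original generator
#'   output).
#' @export
regenerate <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  fn <- switch(truth$kind,
    melt = gen_melt_curve,
    melt_screen = gen_buffer_screen_dataset,
    kinetics = gen_kinetics_plate,
    peaks = gen_peak_table,
    corpus = gen_condition_corpus
  )
  do.call(fn, c(truth$params, list(seed = truth$seed)))
}

## two-state thermofluor model: linear pre-transition baseline, sigmoidal
## unfolding transition, linear post-transition decay (dye dissociation)
melt_model <- function(T, a_pre, slope_pre, amplitude, tm_C, steepness, slope_post) {
  a_pre + slope_pre * T +
    amplitude / (1 + exp((tm_C - T) / steepness)) +
    slope_post * pmax(T - tm_C, 0)
}

#' Simulate a thermofluor melt curve
#'
#' Generates a single differential-scanning-fluorimetry trace over
#' 20-95 degC in 1 degC steps (76 points) from a two-state unfolding model:
#' a linear pre-transition baseline, a sigmoidal transition of the given
#' amplitude and midpoint, and a linear post-transition decay representing
#' dye dissociation, plus optional Gaussian noise.
#'
#' @param tm_C Generative melting temperature, strictly inside (20, 95) degC.
#' @param amplitude Transition amplitude in fluorescence AU (> 0).
#' @param slope_pre Pre-transition baseline slope, AU per degC.
#' @param slope_post Post-transition decay slope, AU per degC (usually
#'   negative).
#' @param baseline Baseline fluorescence at 0 degC, AU.
#' @param steepness Transition width parameter in degC.
#' @param noise_sd Gaussian noise standard deviation, AU (>= 0).
#' @param no_transition If `TRUE`, emit a flat (baseline-only) curve; the
#'   ground truth marks the transition as absent.
#' @param condition_id,protein_id Identifiers carried into the curve table.
#' @param seed Integer seed; `NULL` is fine when `noise_sd = 0`.
#' @return A list with `curve` (tibble: `condition_id`, `protein_id`,
#'   `temperature_C`, `fluorescence`) and `truth` (a [new_ground_truth()]).
#' @export
#' @examples
#' sim <- gen_melt_curve(tm_C = 83.18, noise_sd = 0)
#' estimate_tm(sim$curve)$tm_C
gen_melt_curve <- function(tm_C, amplitude = 1000, slope_pre = 1.5,
                           slope_post = -12, baseline = 500, steepness = 1.5,
                           noise_sd = 0, no_transition = FALSE,
                           condition_id = "cond1", protein_id = "protein1",
                           seed = NULL) {
  if (!is_scalar_number(tm_C) || tm_C <= 20 || tm_C >= 95)
    abort("`tm_C` must lie strictly inside (20, 95) degC.")
  if (!is_scalar_number(amplitude) || amplitude < 0 ||
      (amplitude == 0 && !no_transition))
    abort("`amplitude` must be positive (use `no_transition = TRUE` for a flat curve).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  temperature_C <- seq(20, 95, by = 1)
  f <- if (no_transition) {
    baseline + slope_pre * temperature_C
  } else {
    melt_model(temperature_C, baseline, slope_pre, amplitude, tm_C,
               steepness, slope_post)
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed %||% 1L),
                              rnorm(length(f), sd = noise_sd))
    f <- f + noise
  }
  curve <- tibble::tibble(
    condition_id = condition_id, protein_id = protein_id,
    temperature_C = temperature_C, fluorescence = f
  )
  truth <- new_ground_truth(
    "melt",
    params = list(tm_C = tm_C, amplitude = amplitude, slope_pre = slope_pre,
                  slope_post = slope_post, baseline = baseline,
                  steepness = steepness, noise_sd = noise_sd,
                  no_transition = no_transition, condition_id = condition_id,
                  protein_id = protein_id),
    seed = seed
  )
  list(curve = curve, truth = truth)
}

#' Simulate a full buffer-screen thermofluor dataset
#'
#' Generates one melt curve per screen condition with generative midpoint
#' `ref_tm_C + delta_tm`, plus a water-control reference curve at
#' `ref_tm_C`. Per-curve sub-seeds are derived deterministically from
#' `seed`.
#'
#' @param delta_tm_map Named numeric vector: condition id -> thermal shift
#'   in degC.
#' @param ref_tm_C Water-control melting temperature, degC.
#' @param noise_sd Per-curve Gaussian noise, AU.
#' @param protein_id Identifier carried into the curves.
#' @param reference_id Condition id used for the water control.
#' @param seed Integer seed.
#' @inheritParams gen_melt_curve
#' @return A list with `curves` (one long tibble of all curves) and `truth`.
#' @export
gen_buffer_screen_dataset <- function(delta_tm_map, ref_tm_C, noise_sd = 0,
                                      protein_id = "protein1",
                                      reference_id = "water_control",
                                      amplitude = 1000, seed = 1L) {
  if (is.null(names(delta_tm_map)) || anyDuplicated(names(delta_tm_map)))
    abort("`delta_tm_map` must be a uniquely named numeric vector.")
  if (ref_tm_C <= 20 || ref_tm_C >= 95)
    abort("`ref_tm_C` must lie strictly inside (20, 95) degC.")
  mids <- ref_tm_C + delta_tm_map
  bad <- names(mids)[mids <= 20 | mids >= 95]
  if (length(bad))
    abort(paste0("Generated midpoint outside (20, 95) degC for condition(s): ",
                 paste(bad, collapse = ", ")))

  ids <- c(reference_id, names(delta_tm_map))
  tms <- c(ref_tm_C, mids)
  sub_seeds <- derive_seeds(seed, length(ids))
  curves <- purrr::map2(ids, seq_along(ids), function(id, i) {
    gen_melt_curve(tm_C = tms[[i]], amplitude = amplitude,
                   noise_sd = noise_sd, condition_id = id,
                   protein_id = protein_id, seed = sub_seeds[[i]])$curve
  }) |> purrr::list_rbind()
  truth <- new_ground_truth(
    "melt_screen",
    params = list(delta_tm_map = delta_tm_map, ref_tm_C = ref_tm_C,
                  noise_sd = noise_sd, protein_id = protein_id,
                  reference_id = reference_id, amplitude = amplitude),
    seed = seed
  )
  list(curves = curves, truth = truth)
}

#' Default substrate dilution series
#'
#' Thirteen descending 2-fold dilutions from 100 uM (lowest ~0.0244 uM),
#' the series used for steady-state kinetics of prenyl-diphosphate
#' substrates.
#'
#' @param top Highest concentration, uM.
#' @param n Number of levels.
#' @return Numeric vector of concentrations in uM, descending.
#' @export
default_substrate_series <- function(top = 100, n = 13) top / 2^(seq_len(n) - 1)

#' Simulate a malachite-green kinetics plate
#'
#' Generates endpoint 623 nm absorbances for a substrate dilution series
#' from Michaelis-Menten initial rates: each turnover releases one PPi,
#' hydrolysed by pyrophosphatase to `pi_per_turnover` Pi, so
#' `Pi = pi_per_turnover * v(S) * incubation_s` and
#' `A = std_intercept + std_slope * Pi`, scaled by multiplicative Gaussian
#' noise of coefficient `noise_cv`. The plate also carries a Pi
#' standard-curve block (2-fold series from 50 uM, 13 levels) and
#' substrate-free background wells.
#'
#' @param km_uM Generative Michaelis constant, uM (> 0).
#' @param vmax_uM_per_s Generative maximal rate, uM/s (> 0).
#' @param substrate_series Substrate concentrations, uM (strictly positive).
#' @param incubation_s Endpoint incubation time, s.
#' @param std_slope,std_intercept Pi standard-curve slope (AU/uM) and
#'   intercept (AU).
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param replicates Replicate wells per level.
#' @param pi_per_turnover Pi released per substrate turnover (2 with
#'   pyrophosphatase).
#' @param enzyme_id,substrate Identifiers carried into the plate.
#' @param seed Integer seed.
#' @return A list with `plate` (tibble: `well`, `role`, `substrate_uM`,
#'   `analyte_uM`, `absorbance`, `replicate`, `enzyme_id`, `substrate`)
#'   and `truth`.
#' @export
#' @examples
#' sim <- gen_kinetics_plate(km_uM = 7.809, vmax_uM_per_s = 0.2038,
#'                           noise_cv = 0, replicates = 1)
#' head(sim$plate)
gen_kinetics_plate <- function(km_uM, vmax_uM_per_s,
                               substrate_series = default_substrate_series(),
                               incubation_s = 1800, std_slope = 0.012,
                               std_intercept = 0.05, noise_cv = 0,
                               replicates = 3, pi_per_turnover = 2,
                               enzyme_id = "enzyme1", substrate = "GPP",
                               seed = NULL) {
  if (km_uM <= 0 || vmax_uM_per_s <= 0)
    abort("`km_uM` and `vmax_uM_per_s` must be positive.")
  if (any(substrate_series <= 0))
    abort("`substrate_series` must be strictly positive.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")

  std_series <- 50 / 2^(0:12)
  v <- vmax_uM_per_s * substrate_series / (km_uM + substrate_series)
  pi_uM <- pi_per_turnover * v * incubation_s

  samples <- tidyr::expand_grid(
    substrate_uM = substrate_series, replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(role = "sample", analyte_uM = NA_real_,
                  absorbance = std_intercept +
                    std_slope * rep(pi_uM, each = replicates))
  standards <- tidyr::expand_grid(
    analyte_uM = std_series, replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(role = "standard", substrate_uM = NA_real_,
                  absorbance = std_intercept + std_slope * .data$analyte_uM)
  background <- tibble::tibble(
    replicate = seq_len(replicates), role = "background",
    substrate_uM = 0, analyte_uM = NA_real_, absorbance = std_intercept
  )
  plate <- dplyr::bind_rows(samples, standards, background)
  if (noise_cv > 0) {
    eps <- withr::with_seed(as.integer(seed %||% 1L),
                            rnorm(nrow(plate), sd = noise_cv))
    plate$absorbance <- plate$absorbance * (1 + eps)
  }
  plate <- plate |>
    dplyr::mutate(well = sprintf("W%03d", dplyr::row_number()),
                  enzyme_id = enzyme_id, substrate = substrate) |>
    dplyr::select("well", "role", "substrate_uM", "analyte_uM", "absorbance",
                  "replicate", "enzyme_id", "substrate")
  truth <- new_ground_truth(
    "kinetics",
    params = list(km_uM = km_uM, vmax_uM_per_s = vmax_uM_per_s,
                  substrate_series = substrate_series,
                  incubation_s = incubation_s, std_slope = std_slope,
                  std_intercept = std_intercept, noise_cv = noise_cv,
                  replicates = replicates, pi_per_turnover = pi_per_turnover,
                  enzyme_id = enzyme_id, substrate = substrate),
    seed = seed
  )
  list(plate = plate, truth = truth)
}

#' Simulate a GC-MS peak table
#'
#' Builds a chromatographic peak table realising a target percent-of-total
#' terpene product profile: one peak per profile compound with area
#' `percent/100 * total_terpene_area`, an isobutylbenzene internal-standard
#' peak, and optional non-terpene peaks. Retention times come from the
#' built-in [terpene_lexicon()].
#'
#' @param profile Named numeric vector of percentages (must sum to
#'   100 +/- 0.05) over compounds known to the lexicon.
#' @param total_terpene_area Total terpene peak area, AU (> 0).
#' @param is_area Internal-standard peak area, AU.
#' @param extra_nonterpene Named numeric vector of additional peak areas for
#'   non-terpene compounds (e.g. `c("geranyl methyl ether" = 500)`).
#' @param sample_id,substrate Identifiers carried into the table.
#' @param seed Integer seed for match-score jitter.
#' @return A list with `peaks` (tibble: `sample_id`, `substrate`, `rt_min`,
#'   `area`, `compound`, `match_score`, plus the ground-truth `klass`) and
#'   `truth`.
#' @export
#' @examples
#' gen_peak_table(c("β-myrcene" = 100))$peaks
gen_peak_table <- function(profile, total_terpene_area = 1e6,
                           is_area = 2.5e5, extra_nonterpene = NULL,
                           sample_id = "sample1", substrate = "GPP",
                           seed = 1L) {
  if (total_terpene_area <= 0) abort("`total_terpene_area` must be > 0.")
  if (any(profile < 0)) abort("Profile percentages must be >= 0.")
  if (abs(sum(profile) - 100) > 0.05)
    abort(sprintf("Profile percentages sum to %.3f, not 100 +/- 0.05.",
                  sum(profile)))
  lex <- terpene_lexicon()
  known <- c(names(profile), names(extra_nonterpene))
  missing <- setdiff(known, lex$compound)
  if (length(missing))
    abort(paste0("Compound(s) not in the retention-time lexicon: ",
                 paste(missing, collapse = ", ")))

  rows <- tibble::tibble(
    compound = c(names(profile), "isobutylbenzene", names(extra_nonterpene)),
    area = c(unname(profile) / 100 * total_terpene_area, is_area,
             unname(extra_nonterpene) %||% numeric())
  ) |>
    dplyr::left_join(lex, by = "compound")
  scores <- withr::with_seed(as.integer(seed),
                             round(runif(nrow(rows), 850, 990)))
  peaks <- rows |>
    dplyr::mutate(
      sample_id = sample_id, substrate = substrate,
      match_score = dplyr::if_else(.data$putative, as.numeric(scores), NA_real_)
    ) |>
    dplyr::arrange(.data$rt_min) |>
    dplyr::select("sample_id", "substrate", "rt_min", "area", "compound",
                  "match_score", "klass")
  truth <- new_ground_truth(
    "peaks",
    params = list(profile = profile, total_terpene_area = total_terpene_area,
                  is_area = is_area, extra_nonterpene = extra_nonterpene,
                  sample_id = sample_id, substrate = substrate),
    seed = seed
  )
  list(peaks = peaks, truth = truth)
}

## iterative proportional fitting of a joint buffer x pH-bin table to the
## target marginals, restricted to each buffer's plausible buffering range
buffer_ph_joint <- function(buffer_pct, ph_bin_pct) {
  ranges <- list(
    "Bis-Tris" = c(5.5, 7.5), "Tris" = c(7.0, 9.0), "HEPES" = c(6.8, 8.2),
    "MES" = c(5.0, 6.7), "sodium citrate" = c(3.0, 6.2),
    "sodium acetate" = c(3.6, 5.6), "sodium cacodylate" = c(5.0, 7.4),
    "imidazole" = c(6.2, 7.8), "Bicine" = c(7.6, 9.0), "CAPS" = c(9.0, 11.0)
  )
  bins <- names(ph_bin_pct)
  lo <- as.numeric(substr(bins, 1, 3))
  mask <- vapply(bins, function(b) {
    i <- match(b, bins)
    vapply(names(buffer_pct), function(bf) {
      r <- ranges[[bf]] %||% c(3, 11)
      lo[i] + 0.9 >= r[1] && lo[i] <= r[2]
    }, logical(1))
  }, logical(length(buffer_pct)))
  joint <- outer(unname(buffer_pct), unname(ph_bin_pct)) * mask
  for (it in 1:200) {
    joint <- joint * (buffer_pct / pmax(rowSums(joint), 1e-12))
    joint <- t(t(joint) * (ph_bin_pct / pmax(colSums(joint), 1e-12)))
  }
  dimnames(joint) <- list(names(buffer_pct), bins)
  joint / sum(joint)
}

## render one parsed component as free text, with seeded spelling/case/unit
## perturbations to exercise the parser
render_component <- function(chemical, conc, unit, ph = NA, lex) {
  syns <- lex$synonyms[[match(chemical, lex$chemical)]]
  syns <- syns[!grepl(",", syns)]
  name <- sample(c(chemical, syns), 1)
  name <- switch(sample(3, 1), toupper(name), tolower(name), name)
  if (unit == "M" && runif(1) < 0.4) {
    conc <- conc * 1000
    unit <- "mM"
  }
  qty <- if (startsWith(unit, "%")) {
    paste0(format(conc, trim = TRUE), sample(c("%", "% w/v", " % w/v"), 1))
  } else {
    paste(format(conc, trim = TRUE), unit)
  }
  txt <- paste(qty, name)
  if (!is.na(ph)) {
    ph_txt <- format(ph, nsmall = 1)
    txt <- if (runif(1) < 0.5) paste0(txt, " (pH ", ph_txt, ")")
           else paste0(txt, " pH ", ph_txt)
  }
  txt
}

#' Simulate a crystallisation-condition corpus
#'
#' Emits free-text crystallisation-condition records whose component
#' frequencies follow a target frequency report: every published record has
#' a buffer with pH (buffer and pH bin sampled jointly so that each buffer
#' stays inside its plausible buffering range while both marginals match the
#' target), an optional salt and an optional precipitant. Spellings, case
#' and concentration units are perturbed per record to exercise the parser;
#' `n_missing` records carry an empty condition string (unpublished
#' conditions).
#'
#' @param n_entries Number of records.
#' @param n_missing Number of records with no published condition.
#' @param freq_spec Frequency target, as from
#'   [reference_condition_frequencies()].
#' @param seed Integer seed.
#' @return A list with `corpus` (tibble: `entry_id`, `condition`) and
#'   `truth`.
#' @export
#' @examples
#' gen_condition_corpus(n_entries = 10, n_missing = 2, seed = 1)$corpus
gen_condition_corpus <- function(n_entries = 120, n_missing = 16,
                                 freq_spec = reference_condition_frequencies(),
                                 seed = 1L) {
  if (n_missing < 0 || n_missing > n_entries)
    abort("`n_missing` must lie in [0, n_entries].")
  for (cat in c("buffer_pct", "ph_bin_pct", "salt_pct", "precipitant_pct")) {
    if (abs(sum(freq_spec[[cat]]) - 100) > 1)
      abort(sprintf("freq_spec$%s must sum to 100 +/- 1.", cat))
  }
  lex <- crystallisation_lexicon()
  unknown <- setdiff(
    c(names(freq_spec$buffer_pct), names(freq_spec$salt_pct),
      names(freq_spec$precipitant_pct)),
    lex$chemical
  )
  if (length(unknown))
    abort(paste0("freq_spec names unknown chemical(s): ",
                 paste(unknown, collapse = ", ")))

  joint <- buffer_ph_joint(freq_spec$buffer_pct, freq_spec$ph_bin_pct)
  cells <- which(joint > 0, arr.ind = TRUE)

  corpus <- withr::with_seed(as.integer(seed), {
    n_pub <- n_entries - n_missing
    texts <- character(n_pub)
    if (n_pub > 0) {
      idx <- sample(nrow(cells), n_pub, replace = TRUE,
                    prob = joint[cells])
      for (i in seq_len(n_pub)) {
        buffer <- rownames(joint)[cells[idx[i], 1]]
        bin_lo <- as.numeric(substr(colnames(joint)[cells[idx[i], 2]], 1, 3))
        ph <- round(runif(1, bin_lo, bin_lo + 0.9), 1)
        parts <- render_component(buffer, sample(c(0.05, 0.1, 0.2), 1), "M",
                                  ph, lex)
        if (runif(1) < freq_spec$p_precipitant) {
          prec <- sample(names(freq_spec$precipitant_pct), 1,
                         prob = freq_spec$precipitant_pct)
          parts <- c(parts, if (grepl("^PEG", prec)) {
            render_component(prec, sample(seq(5, 35, 5), 1), "%w/v", NA, lex)
          } else if (prec == "MPD") {
            render_component(prec, sample(seq(10, 30, 5), 1), "%w/v", NA, lex)
          } else if (prec == "ammonium sulfate") {
            render_component(prec, sample(seq(1, 2, 0.2), 1), "M", NA, lex)
          } else {
            render_component(prec, sample(seq(0.8, 1.6, 0.2), 1), "M", NA, lex)
          })
        }
        if (runif(1) < freq_spec$p_salt) {
          salt <- sample(names(freq_spec$salt_pct), 1,
                         prob = freq_spec$salt_pct)
          parts <- c(parts,
                     render_component(salt, sample(seq(0.05, 0.4, 0.05), 1),
                                      "M", NA, lex))
        }
        texts[i] <- paste(parts, collapse = ", ")
      }
    }
    cond <- c(texts, rep("", n_missing))
    tibble::tibble(
      entry_id = sprintf("ENT%04d", seq_len(n_entries)),
      condition = sample(cond)
    )
  })
  truth <- new_ground_truth(
    "corpus",
    params = list(n_entries = n_entries, n_missing = n_missing,
                  freq_spec = freq_spec),
    seed = seed
  )
  list(corpus = corpus, truth = truth)
}
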