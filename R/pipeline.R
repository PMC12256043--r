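#' Validate a stage input file
#'
#' Checks headers, column types and basic invariants of one of the
#' pipeline's CSV/JSONL input formats and returns per-row diagnostics
#' rather than failing at first error.
#'
#' @param path Input file.
#' @param schema One of `"melt"` (long melt-curve CSV), `"plate"`
#'   (malachite-green plate CSV), `"peaks"` (GC-MS peak CSV), `"corpus"`
#'   (condition corpus JSONL/CSV).
#' @return A list with `ok` (logical), `problems` (tibble: `row`,
#'   `message`; row `NA` for file-level problems) and `data` (the parsed
#'   table when readable).
#' @export
validate_inputs <- function(path, schema = c("melt", "plate", "peaks",
                                             "corpus")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  problems <- tibble::tibble(row = integer(), message = character())
  add <- function(row, msg) {
    problems <<- dplyr::bind_rows(problems,
                                  tibble::tibble(row = row, message = msg))
  }
  data <- NULL
  if (schema == "corpus") {
    data <- tryCatch(read_condition_corpus(path), error = function(e) NULL)
    if (is.null(data)) add(NA_integer_, "corpus not readable as JSONL/CSV")
  } else {
    data <- readr::read_csv(path, show_col_types = FALSE)
    required <- switch(schema,
      melt = c("condition_id", "protein_id", "temperature_C", "fluorescence"),
      plate = c("well", "role", "substrate_uM", "analyte_uM", "absorbance",
                "replicate"),
      peaks = c("sample_id", "substrate", "rt_min", "area", "compound",
                "match_score")
    )
    missing <- setdiff(required, names(data))
    if (length(missing)) {
      add(NA_integer_, paste0("missing column(s): ",
                              paste(missing, collapse = ", ")))
    } else if (schema == "melt") {
      bad <- data |>
        dplyr::group_by(.data$condition_id, .data$protein_id) |>
        dplyr::summarise(
          monotone = all(diff(.data$temperature_C) > 0),
          n = dplyr::n(), in_range = all(.data$temperature_C >= 0 &
                                           .data$temperature_C <= 120),
          .groups = "drop"
        )
      for (i in which(!bad$monotone))
        add(NA_integer_, paste0("non-monotone temperatures in curve ",
                                bad$condition_id[i]))
      for (i in which(bad$n < 10))
        add(NA_integer_, paste0("fewer than 10 points in curve ",
                                bad$condition_id[i]))
      for (i in which(!bad$in_range))
        add(NA_integer_, paste0("temperatures outside [0, 120] in curve ",
                                bad$condition_id[i]))
    } else if (schema == "plate") {
      bad_role <- which(!data$role %in% c("sample", "standard", "background"))
      for (i in bad_role) add(i, paste0("unknown role: ", data$role[i]))
      neg <- which(!is.na(data$substrate_uM) & data$role == "sample" &
                     data$substrate_uM <= 0)
      for (i in neg) add(i, "non-positive sample substrate concentration")
    } else if (schema == "peaks") {
      for (i in which(data$area < 0)) add(i, "negative peak area")
      for (i in which(data$rt_min < 0)) add(i, "negative retention time")
    }
  }
  list(ok = nrow(problems) == 0, problems = problems, data = data)
}

#' Read a long-format melt-curve CSV
#'
#' @param path CSV with columns `condition_id`, `protein_id`,
#'   `temperature_C`, `fluorescence`.
#' @return A tibble.
#' @export
read_melt_curves <- function(path) {
  v <- validate_inputs(path, "melt")
  if (!v$ok)
    abort(paste0("Invalid melt-curve file: ",
                 paste(v$problems$message, collapse = "; ")))
  v$data
}

known_config_keys <- c(
  "out_dir", "seed", "stages", "melt_csv", "plate_csv", "peaks_csv",
  "control_csv", "corpus_path", "method", "stabilising_threshold_C",
  "enzyme_conc", "pi_per_turnover", "incubation_s", "noise_cv", "noise_sd",
  "rt_tol_min", "n_entries", "n_missing", "reference_id"
)

#' Run the characterisation pipeline end to end
#'
#' Executes the requested stages in order (thermal stability, kinetics,
#' product profiles, screen design), writes per-stage CSVs plus a Markdown
#' report and a provenance block (config hash, seed, package version) into
#' `config$out_dir`. Any stage whose input file is not supplied runs on
#' synthetic data generated from the reference panels with the configured
#' seed, so the default configuration produces a complete ten-enzyme
#' report without any instrument files.
#'
#' @param config Named list of options; unknown keys are fatal. Keys:
#'   `out_dir` (required), `seed` (default 1), `stages` (subset of
#'   `c("thermal", "kinetics", "profiles", "screen")`), optional input
#'   paths `melt_csv`, `plate_csv`, `peaks_csv`, `control_csv`,
#'   `corpus_path`, and stage parameters `method`,
#'   `stabilising_threshold_C`, `enzyme_conc`, `pi_per_turnover`,
#'   `incubation_s`, `noise_cv`, `noise_sd`, `rt_tol_min`, `n_entries`,
#'   `n_missing`, `reference_id`.
#' @return A list of stage results (invisibly also written to disk):
#'   `thermal` (tm, delta, ranking, best), `kinetics` (panel summary),
#'   `profiles` (profile tibble, activity matrix), `screen` (report,
#'   selection, spec), plus `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown))
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  if (is.null(config$out_dir)) abort("`config$out_dir` is required.")
  stages <- config$stages %||% c("thermal", "kinetics", "profiles", "screen")
  if (length(stages) == 0) abort("Nothing to do: no stages enabled.")
  bad <- setdiff(stages, c("thermal", "kinetics", "profiles", "screen"))
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub_seeds <- derive_seeds(seed, 4)
  results <- list(paths = character())
  report <- c("# Terpene synthase characterisation report", "")
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    results$paths <<- c(results$paths, p)
  }

  if ("thermal" %in% stages) {
    curves <- if (!is.null(config$melt_csv)) {
      read_melt_curves(config$melt_csv)
    } else {
      simulate_reference_screen(noise_sd = config$noise_sd %||% 0,
                                seed = sub_seeds[1])
    }
    tm <- estimate_tm(curves, method = config$method %||% "boltzmann")
    delta <- delta_tm_table(tm,
                            reference_id = config$reference_id %||% "water_control",
                            threshold = config$stabilising_threshold_C %||% 4)
    ranking <- rank_buffers(delta,
                            threshold = config$stabilising_threshold_C %||% 4)
    best <- best_condition_per_protein(delta)
    emit(tm, "tm.csv"); emit(delta, "delta_tm.csv")
    emit(ranking, "buffer_ranking.csv"); emit(best, "best_conditions.csv")
    results$thermal <- list(tm = tm, delta = delta, ranking = ranking,
                            best = best)
    report <- c(report, "## Thermal stability", "",
                sprintf("- %d curves analysed across %d proteins",
                        nrow(tm), dplyr::n_distinct(tm$protein_id)),
                sprintf("- most stabilising condition overall: %s (median shift %.2f degC)",
                        ranking$condition_id[1], ranking$median_delta_tm_C[1]),
                "")
  }

  if ("kinetics" %in% stages) {
    fits <- if (!is.null(config$plate_csv)) {
      plate <- validate_inputs(config$plate_csv, "plate")$data
      rates <- process_kinetics_plate(
        plate, incubation_s = config$incubation_s %||% 1800,
        pi_per_turnover = config$pi_per_turnover %||% 2
      )$rates
      list(fit_michaelis_menten(rates,
                                enzyme_conc = config$enzyme_conc %||% 10))
    } else {
      simulate_reference_kinetics(noise_cv = config$noise_cv %||% 0.05,
                                  seed = sub_seeds[2],
                                  incubation_s = config$incubation_s %||% 1800,
                                  pi_per_turnover = config$pi_per_turnover %||% 2,
                                  enzyme_conc = config$enzyme_conc %||% 10)
    }
    panel <- summarize_panel(fits)
    emit(panel$table, "kinetics.csv")
    results$kinetics <- panel
    report <- c(report, "## Steady-state kinetics", "",
                sprintf("- %d enzyme/substrate fits (%d converged)",
                        nrow(panel$table), panel$n_converged),
                sprintf("- turnover numbers span %.4f to %.4f per second",
                        panel$kcat_min, panel$kcat_max),
                "")
  }

  if ("profiles" %in% stages) {
    profiles <- if (!is.null(config$peaks_csv)) {
      peaks <- validate_inputs(config$peaks_csv, "peaks")$data
      if (!is.null(config$control_csv)) {
        ctrl <- validate_inputs(config$control_csv, "peaks")$data
        peaks <- subtract_background(peaks, ctrl,
                                     rt_tol_min = config$rt_tol_min %||% 0.10)
      }
      peaks |>
        dplyr::group_by(.data$sample_id, .data$substrate) |>
        dplyr::group_split() |>
        purrr::map(function(df) percent_composition(classify_peaks(df)))
    } else {
      simulate_reference_profiles(seed = sub_seeds[3])
    }
    prof_tab <- purrr::map(profiles, tidy) |> purrr::list_rbind()
    activity <- substrate_activity_matrix(profiles)
    emit(prof_tab, "profiles.csv"); emit(activity, "activity.csv")
    results$profiles <- list(profiles = profiles, table = prof_tab,
                             activity = activity)
    report <- c(report, "## Product profiles", "",
                sprintf("- %d active profiles across %d enzymes",
                        sum(purrr::map_lgl(profiles, "active")),
                        dplyr::n_distinct(activity$enzyme_id)),
                "")
  }

  if ("screen" %in% stages) {
    corpus <- if (!is.null(config$corpus_path)) {
      read_condition_corpus(config$corpus_path)
    } else {
      gen_condition_corpus(n_entries = config$n_entries %||% 120,
                           n_missing = config$n_missing %||% 16,
                           seed = sub_seeds[4])$corpus
    }
    parsed <- parse_corpus(corpus)
    published <- filter_published(parsed)
    stats <- frequency_stats(published)
    selection <- select_components(stats)
    spec <- generate_screen(selection)
    emit(tidy(stats), "screen_stats.csv")
    export_screen(spec, file.path(out_dir, "tps_screen.csv"))
    results$paths <- c(results$paths, file.path(out_dir, "tps_screen.csv"))
    results$screen <- list(report = stats, selection = selection, spec = spec)
    report <- c(report, "## Crystallisation screen", "",
                sprintf("- corpus: %d records, %d published",
                        attr(published, "n_before"), attr(published, "n_after")),
                sprintf("- generated screen: %d conditions", nrow(spec)),
                "")
  }

  provenance <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("tpskit"))),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", rlang::hash(config)),
    sprintf("stages: %s", paste(stages, collapse = ","))
  )
  writeLines(c(report, "## Provenance", "", paste0("    ", provenance)),
             file.path(out_dir, "report.md"))
  results$paths <- c(results$paths, file.path(out_dir, "report.md"))
  invisible(results)
}

#' Simulate a buffer-screen thermofluor dataset for the reference panel
#'
#' For each panel protein, generates melt curves for its best screen
#' condition (at the recorded thermal shift) and a small set of comparison
#' conditions, plus the water control at 76.46 degC.
#'
#' @param noise_sd Per-curve noise, AU.
#' @param seed Integer seed.
#' @param panel Reference panel tibble (see [tps_reference_stability()]).
#' @return A long melt-curve tibble.
#' @export
simulate_reference_screen <- function(noise_sd = 0, seed = 1L,
                                      panel = tps_reference_stability()) {
  ref_tm <- unique(round(panel$tm_C - panel$delta_tm_C, 2))[1]
  conditions <- panel |>
    dplyr::mutate(condition_id = sprintf("%s_pH%.1f_%s%d", .data$buffer,
                                         .data$pH, .data$salt, .data$salt_mM))
  sub_seeds <- derive_seeds(seed, nrow(panel))
  purrr::map(seq_len(nrow(panel)), function(i) {
    protein <- panel$protein_id[i]
    ## the protein's own best condition plus every other panel condition at
    ## a modest shift, emulating a reduced screen
    shifts <- setNames(rep(1.5, nrow(conditions)), conditions$condition_id)
    shifts[conditions$condition_id[i]] <- panel$delta_tm_C[i]
    gen_buffer_screen_dataset(shifts[!duplicated(names(shifts))], ref_tm,
                              noise_sd = noise_sd, protein_id = protein,
                              seed = sub_seeds[i])$curves
  }) |> purrr::list_rbind()
}

#' Simulate and fit reference kinetics plates
#'
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param incubation_s,pi_per_turnover,enzyme_conc Assay parameters.
#' @param panel Reference kinetic panel (see [tps_reference_kinetics()]).
#' @return A list of `mm_fit` objects, one per panel row.
#' @export
simulate_reference_kinetics <- function(noise_cv = 0.05, seed = 1L,
                                        incubation_s = 1800,
                                        pi_per_turnover = 2,
                                        enzyme_conc = 10,
                                        panel = tps_reference_kinetics()) {
  sub_seeds <- derive_seeds(seed, nrow(panel))
  purrr::map(seq_len(nrow(panel)), function(i) {
    sim <- gen_kinetics_plate(
      km_uM = panel$km_uM[i], vmax_uM_per_s = panel$vmax_uM_per_s[i],
      incubation_s = incubation_s, noise_cv = noise_cv,
      pi_per_turnover = pi_per_turnover, enzyme_id = panel$enzyme_id[i],
      substrate = panel$substrate[i], seed = sub_seeds[i]
    )
    rates <- process_kinetics_plate(sim$plate, incubation_s = incubation_s,
                                    pi_per_turnover = pi_per_turnover)$rates
    fit_michaelis_menten(rates, enzyme_conc = enzyme_conc)
  })
}

#' Simulate and quantify reference product profiles
#'
#' Generates a peak table per enzyme/substrate from the reference profile
#' panel (renormalised to exactly 100), classifies it and computes percent
#' compositions; also emits inactive GGPP assays for every enzyme.
#'
#' @param seed Integer seed.
#' @param profiles Reference profile tibble (see [tps_reference_profiles()]).
#' @return A list of `product_profile` objects.
#' @export
simulate_reference_profiles <- function(seed = 1L,
                                        profiles = tps_reference_profiles()) {
  groups <- profiles |>
    dplyr::group_by(.data$enzyme_id, .data$substrate) |>
    dplyr::group_split()
  sub_seeds <- derive_seeds(seed, length(groups))
  active <- purrr::map(seq_along(groups), function(i) {
    g <- groups[[i]]
    prof <- setNames(g$percent / sum(g$percent) * 100, g$compound)
    sim <- gen_peak_table(prof, sample_id = g$enzyme_id[1],
                          substrate = g$substrate[1], seed = sub_seeds[i])
    percent_composition(classify_peaks(sim$peaks))
  })
  inactive <- purrr::map(unique(profiles$enzyme_id), function(e) {
    pk <- tibble::tibble(sample_id = character(), substrate = character(),
                         rt_min = numeric(), area = numeric(),
                         compound = character(), match_score = numeric())
    p <- percent_composition(classify_peaks(pk))
    p$sample_id <- e
    p$substrate <- "GGPP"
    p
  })
  c(active, inactive)
}
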