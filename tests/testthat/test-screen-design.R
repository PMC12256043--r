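test_that("parse_condition handles units, synonyms, case and pH notations", {
  rec <- parse_condition(
    "0.1 M Bis-Tris (pH 7.0), 25% PEG-3350, 0.2 M NaCl, 0.2 M MgCl2")
  expect_s3_class(rec, "condition_record")
  expect_true(rec$published)
  comp <- rec$components
  expect_equal(nrow(comp), 4)
  expect_equal(comp$role, c("buffer", "precipitant", "salt", "salt"))
  expect_equal(comp$chemical,
               c("Bis-Tris", "PEG-3350", "sodium chloride",
                 "magnesium chloride"))
  expect_equal(comp$pH[1], 7.0)
  expect_equal(comp$concentration, c(0.1, 25, 0.2, 0.2))

  # synonym + case + unit variants land on the same canonical components
  variants <- c(
    "100 mM BIS-TRIS pH 7.0; 25 % w/v polyethylene glycol 3350",
    "0.1 M bis-tris (pH 7.0), 25% PEG-3,350"
  )
  for (v in variants) {
    cv <- parse_condition(v)$components
    expect_equal(cv$chemical, c("Bis-Tris", "PEG-3350"))
    expect_equal(cv$role, c("buffer", "precipitant"))
    expect_equal(cv$pH[1], 7.0)
  }
  # mM and M representations agree after unit normalisation
  a <- parse_condition("100 mM Tris pH 8.0")$components
  b <- parse_condition("0.1 M Tris pH 8.0")$components
  expect_equal(a$concentration * 1e-3, b$concentration)
})

test_that("ammonium sulfate switches role at the 0.8 M threshold", {
  lo <- parse_condition("0.2 M ammonium sulfate")$components
  hi <- parse_condition("1.5 M ammonium sulfate")$components
  at <- parse_condition("0.8 M ammonium sulfate")$components
  mm <- parse_condition("800 mM ammonium sulphate")$components
  expect_equal(lo$role, "salt")
  expect_equal(hi$role, "precipitant")
  expect_equal(at$role, "precipitant")
  expect_equal(mm$role, "precipitant")
})

test_that("parser totality: junk is kept as 'other', all-junk errors", {
  expect_warning(
    rec <- parse_condition("0.1 M HEPES pH 7.5, reservoir solution B2"),
    "other"
  )
  expect_equal(rec$components$role, c("buffer", "other"))
  expect_equal(rec$components$raw_fragment[2], "reservoir solution B2")
  expect_error(suppressWarnings(parse_condition("complete nonsense here")),
               "No parseable")
  # empty / NA conditions are unpublished records, not errors
  expect_false(parse_condition("")$published)
  expect_false(parse_condition(NA_character_)$published)
  expect_equal(nrow(parse_condition("")$components), 0)
})

test_that("format_condition round-trips through parse_condition", {
  texts <- c(
    "0.1 M Bis-Tris (pH 6.5), 25% w/v PEG 3350, 0.2 M sodium chloride",
    "1.6 M ammonium sulfate; 0.1 M HEPES pH 7.5",
    "20% w/v PEG 400, 0.2 M magnesium chloride, 0.1 M Tris (pH 8.5)"
  )
  for (t in texts) {
    rec <- parse_condition(t)
    rendered <- format_condition(rec)
    again <- parse_condition(rendered)
    expect_equal(again$components, rec$components |>
                   dplyr::mutate(raw_fragment = again$components$raw_fragment))
  }
  # unpublished record renders as the empty string
  expect_identical(format_condition(parse_condition("")), "")
})

test_that("parse_corpus matches record-by-record parsing and filters missing", {
  sim <- gen_condition_corpus(n_entries = 60, n_missing = 8, seed = 31)
  parsed <- parse_corpus(sim$corpus)
  expect_equal(nrow(parsed), 60)
  expect_equal(sum(parsed$published), 52)
  # list-column agrees with the scalar parser on every record
  for (i in c(1, 17, 42, 60)) {
    one <- parse_condition(sim$corpus$condition[i],
                           entry_id = sim$corpus$entry_id[i])
    expect_equal(parsed$components[[i]], one$components)
  }
  pub <- filter_published(parsed)
  expect_equal(nrow(pub), 52)
  expect_equal(attr(pub, "n_before"), 60)
  expect_equal(attr(pub, "n_after"), 52)
  # the generator's corpus parses without any 'other' fragments
  roles <- unlist(purrr::map(pub$components, "role"))
  expect_false("other" %in% roles)
})

test_that("frequency percentages are conserved within each category", {
  sim <- gen_condition_corpus(n_entries = 200, n_missing = 20, seed = 8)
  rep_ <- frequency_stats(filter_published(parse_corpus(sim$corpus)))
  expect_s3_class(rep_, "frequency_report")
  for (cat in c("buffer_pct", "ph_bin_pct", "salt_pct", "precipitant_pct",
                "peg_subtype_pct")) {
    expect_equal(sum(rep_[[cat]]$percent), 100, tolerance = 0.5)
  }
  # every record has a buffer with pH; salts/precipitants are optional
  expect_equal(unname(rep_$denominators[["buffer"]]), 180)
  expect_equal(unname(rep_$denominators[["ph"]]), 180)
  expect_lte(rep_$denominators[["salt"]], 180)
  expect_lte(rep_$denominators[["peg"]], rep_$denominators[["precipitant"]])
})

test_that("select_components applies the pH-ladder and top-k rules", {
  sim <- gen_condition_corpus(n_entries = 3000, n_missing = 0, seed = 13)
  rep_ <- frequency_stats(filter_published(parse_corpus(sim$corpus)))
  sel <- select_components(rep_)
  expect_equal(nrow(sel$buffers), 6)
  expect_equal(length(sel$precipitants), 2)
  expect_equal(length(sel$salts), 2)
  # ladder is contiguous in 0.5 steps, each buffer holding 3 levels
  expect_equal(diff(sel$buffers$pH), rep(0.5, 5))
  expect_equal(as.integer(table(sel$buffers$buffer)), c(3L, 3L))
  # the lower-pH buffer gets the lower half of the ladder
  med <- dplyr::filter(rep_$buffer_ph_median,
                       .data$buffer %in% sel$buffers$buffer)
  expect_equal(sel$buffers$buffer[1], med$buffer[which.min(med$median_pH)])
  expect_equal(sel$buffers$buffer[1:3], rep(sel$buffers$buffer[1], 3))
  # under-diverse corpora are rejected with an informative error
  spec <- reference_condition_frequencies()
  spec$buffer_pct <- c("Bis-Tris" = 100)
  mono <- gen_condition_corpus(50, 0, freq_spec = spec, seed = 2)
  mono_rep <- frequency_stats(filter_published(parse_corpus(mono$corpus)))
  expect_error(select_components(mono_rep), "distinct buffers")
})

test_that("a large corpus recovers the reference screen selection exactly", {
  sim <- gen_condition_corpus(n_entries = 10000, n_missing = 0, seed = 1)
  sel <- parse_corpus(sim$corpus) |>
    filter_published() |>
    frequency_stats() |>
    select_components()
  expect_identical(sel, reference_screen_selection())
})

test_that("generate_screen is the ordered cross-product with fixed additives", {
  sel <- reference_screen_selection()
  scr <- generate_screen(sel)
  expect_s3_class(scr, "screen_spec")
  expect_equal(nrow(scr),
               nrow(sel$buffers) * length(sel$precipitants) *
                 length(sel$concentrations_pct_wv))
  expect_equal(scr$index, 1:48)
  expect_true(all(scr$buffer_mM == 100))
  expect_true(all(scr$salt1_mM == 200 & scr$salt2_mM == 200))
  # buffer-major, then precipitant, then ascending concentration
  expect_equal(scr$precipitant_pct_wv[1:4], sort(sel$concentrations_pct_wv))
  expect_equal(unique(scr$buffer[1:24]), sel$buffers$buffer[1])
  # all rows unique
  expect_equal(nrow(dplyr::distinct(scr[-1])), 48)
  # cardinality scales with the selection
  sel2 <- sel
  sel2$concentrations_pct_wv <- c(10, 20)
  expect_equal(nrow(generate_screen(sel2)), 6 * 2 * 2)
  sel3 <- sel
  sel3$salts <- sel$salts[1]
  expect_error(generate_screen(sel3), "Empty selection")
})

test_that("screen generation is deterministic from corpus to conditions", {
  run <- function() {
    gen_condition_corpus(n_entries = 400, n_missing = 40, seed = 99)$corpus |>
      parse_corpus() |>
      filter_published() |>
      frequency_stats() |>
      select_components() |>
      generate_screen()
  }
  expect_identical(run(), run())
})

test_that("screen and corpus files round-trip", {
  dir <- withr::local_tempdir()
  scr <- generate_screen(reference_screen_selection())
  csv <- file.path(dir, "screen.csv")
  export_screen(scr, csv)
  expect_true(file.exists(csv))
  sheet <- file.path(dir, "screen_sheet.txt")
  expect_true(file.exists(sheet))
  expect_length(grep("^== ", readLines(sheet)), 6)
  back <- read_screen(csv)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(scr))
  expect_error(export_screen(scr[0, ], file.path(dir, "empty.csv")),
               "empty")

  corpus <- gen_condition_corpus(n_entries = 20, n_missing = 3,
                                 seed = 5)$corpus
  jl <- file.path(dir, "corpus.jsonl")
  write_condition_corpus(corpus, jl)
  expect_equal(read_condition_corpus(jl), corpus)
})
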