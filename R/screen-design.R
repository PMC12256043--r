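## synonym -> canonical lookup built from the crystallisation lexicon
lexicon_lookup <- function(lexicon) {
  tibble::tibble(
    key = unlist(lexicon$synonyms),
    chemical = rep(lexicon$chemical, lengths(lexicon$synonyms))
  ) |>
    dplyr::bind_rows(tibble::tibble(key = tolower(lexicon$chemical),
                                    chemical = lexicon$chemical)) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
}

normalise_unit <- function(u) {
  u <- gsub("\\s+", "", u)
  dplyr::case_match(u, "M" ~ "M", "mM" ~ "mM", "%v/v" ~ "%v/v",
                    .default = "%w/v")
}

## vectorised fragment parser shared by parse_condition and parse_corpus
parse_fragments_vec <- function(fragments, lookup, lexicon) {
  m <- stringr::str_match(fragments, FRAGMENT_RE)
  conc <- as.numeric(m[, 2])
  unit <- normalise_unit(m[, 3])
  name <- stringr::str_squish(m[, 4])
  ph <- as.numeric(m[, 5])
  hit <- match(tolower(name), lookup$key)
  chemical <- lookup$chemical[hit]
  role <- lexicon$role[match(chemical, lexicon$chemical)]
  unparsed <- is.na(m[, 1]) | is.na(hit)
  role[unparsed] <- "other"
  chemical[unparsed] <- ifelse(is.na(m[unparsed, 1]), NA_character_,
                               name[unparsed])
  conc[is.na(m[, 1])] <- NA_real_
  unit[is.na(m[, 1])] <- NA_character_
  ## dual-role override: ammonium sulfate is a precipitant at >= 0.8 M
  amso4 <- !is.na(chemical) & chemical == "ammonium sulfate"
  if (any(amso4)) {
    conc_M <- ifelse(unit[amso4] == "mM", conc[amso4] / 1000, conc[amso4])
    role[amso4] <- ifelse(!is.na(conc_M) & conc_M >= 0.8, "precipitant",
                          "salt")
  }
  tibble::tibble(role = role, chemical = chemical, concentration = conc,
                 unit = unit, pH = ph, raw_fragment = fragments)
}

## fragment grammar: [number unit] chemical [(pH x)]
FRAGMENT_RE <- paste0(
  "^\\s*(\\d+(?:\\.\\d+)?)\\s*",
  "(mM|M|%(?:\\s*[wv]/v)?)\\s*",
  "(.+?)\\s*",
  "(?:\\(?\\s*[pP][hH]\\s*(\\d+(?:\\.\\d+)?)\\s*\\)?)?\\s*$"
)

#' Parse a free-text crystallisation condition
#'
#' Splits a condition string on semicolons and on commas followed by
#' whitespace (so numbers like "PEG-3,350" survive), parses each fragment
#' as `[number unit] chemical [(pH x)]`, normalises chemical names through
#' the lexicon's synonym table (case-insensitive) and assigns roles
#' (buffer/salt/precipitant) from the lexicon, with ammonium sulfate
#' switching from salt to precipitant at 0.8 M. Unparseable fragments are
#' retained with `role = "other"` and a warning. An empty string yields an
#' unpublished record.
#'
#' @param raw_text The condition string.
#' @param lexicon Chemical lexicon, as from [crystallisation_lexicon()].
#' @param entry_id Identifier carried into the record.
#' @return A `condition_record`: list with `entry_id`, `raw_text`,
#'   `published` and `components` (tibble: `role`, `chemical`,
#'   `concentration`, `unit`, `pH`, `raw_fragment`).
#' @export
#' @examples
#' rec <- parse_condition(
#'   "0.1 M Bis-Tris (pH 7.0), 25% PEG-3350, 0.2 M NaCl, 0.2 M MgCl2")
#' rec$components
parse_condition <- function(raw_text, lexicon = crystallisation_lexicon(),
                            entry_id = NA_character_, lookup = NULL) {
  stopifnot(is.character(raw_text), length(raw_text) == 1)
  empty_components <- tibble::tibble(
    role = character(), chemical = character(), concentration = numeric(),
    unit = character(), pH = numeric(), raw_fragment = character()
  )
  if (is.na(raw_text) || !nzchar(stringr::str_trim(raw_text))) {
    return(structure(list(entry_id = entry_id, raw_text = "",
                          published = FALSE, components = empty_components),
                     class = "condition_record"))
  }
  lookup <- lookup %||% lexicon_lookup(lexicon)
  fragments <- stringr::str_split_1(raw_text, ";|,(?=\\s)") |>
    stringr::str_squish()
  fragments <- fragments[nzchar(fragments)]
  components <- parse_fragments_vec(fragments, lookup, lexicon)
  if (nrow(components) > 0 && all(components$role == "other"))
    abort(paste0("No parseable fragment in condition: ",
                 paste(fragments, collapse = " | ")))
  if (any(components$role == "other"))
    warn(paste0("Unparseable fragment(s) kept as role 'other': ",
                paste(components$raw_fragment[components$role == "other"],
                      collapse = " | ")))
  structure(list(entry_id = entry_id, raw_text = raw_text, published = TRUE,
                 components = components),
            class = "condition_record")
}

#' @export
print.condition_record <- function(x, ...) {
  cat("<condition_record>", x$entry_id,
      if (x$published) "" else "(unpublished)", "\n")
  if (x$published) print(x$components)
  invisible(x)
}

#' Render a parsed condition back to canonical free text
#'
#' Inverse of [parse_condition()] up to canonical spelling: reparsing the
#' rendered text reproduces the same components.
#'
#' @param record A `condition_record`.
#' @return A single condition string.
#' @export
format_condition <- function(record) {
  stopifnot(inherits(record, "condition_record"))
  if (!record$published) return("")
  comp <- record$components
  txt <- purrr::pmap_chr(comp, function(role, chemical, concentration, unit,
                                        pH, raw_fragment) {
    if (role == "other") return(raw_fragment)
    qty <- if (startsWith(unit, "%")) {
      paste0(format(concentration, trim = TRUE), unit)
    } else {
      paste(format(concentration, trim = TRUE), unit)
    }
    out <- paste(qty, chemical)
    if (!is.na(pH)) out <- paste0(out, " (pH ", format(pH, nsmall = 1), ")")
    out
  })
  paste(txt, collapse = ", ")
}

#' Parse a whole condition corpus
#'
#' @param corpus Tibble with columns `entry_id`, `condition` (free text),
#'   as from [gen_condition_corpus()] or [read_condition_corpus()].
#' @param lexicon Chemical lexicon.
#' @return A nested tibble: `entry_id`, `raw_text`, `published`,
#'   `components` (list-column of component tibbles).
#' @export
parse_corpus <- function(corpus, lexicon = crystallisation_lexicon()) {
  stopifnot(is.data.frame(corpus),
            all(c("entry_id", "condition") %in% names(corpus)))
  lookup <- lexicon_lookup(lexicon)
  conds <- corpus$condition
  conds[is.na(conds)] <- ""
  published <- nzchar(stringr::str_trim(conds))
  empty_components <- tibble::tibble(
    role = character(), chemical = character(), concentration = numeric(),
    unit = character(), pH = numeric(), raw_fragment = character()
  )
  components <- rep(list(empty_components), nrow(corpus))
  if (any(published)) {
    frag_list <- stringr::str_split(conds[published], ";|,(?=\\s)")
    frags <- stringr::str_squish(unlist(frag_list))
    idx <- rep(which(published), lengths(frag_list))
    keep <- nzchar(frags)
    parsed <- parse_fragments_vec(frags[keep], lookup, lexicon)
    if (any(parsed$role == "other"))
      warn(sprintf("%d fragment(s) kept as role 'other'.",
                   sum(parsed$role == "other")))
    components[unique(idx[keep])] <-
      split(parsed, factor(idx[keep], levels = unique(idx[keep])))
  }
  tibble::tibble(
    entry_id = corpus$entry_id,
    raw_text = conds,
    published = published,
    components = components
  )
}

#' Drop records without published crystallisation conditions
#'
#' @param parsed A parsed corpus from [parse_corpus()].
#' @return The published records only, with attributes `n_before` and
#'   `n_after` recording the filtering.
#' @export
#' @examples
#' corpus <- gen_condition_corpus(n_entries = 12, n_missing = 2, seed = 1)$corpus
#' nrow(filter_published(parse_corpus(corpus)))
filter_published <- function(parsed) {
  stopifnot(is.data.frame(parsed), "published" %in% names(parsed))
  out <- parsed[parsed$published, , drop = FALSE]
  attr(out, "n_before") <- nrow(parsed)
  attr(out, "n_after") <- nrow(out)
  out
}

ph_bin_label <- function(ph) sprintf("%.1f-%.1f", floor(ph), floor(ph) + 0.9)

pct_table <- function(counts, denominator) {
  tibble::tibble(name = names(counts),
                 n = as.integer(counts),
                 percent = 100 * as.integer(counts) / denominator) |>
    dplyr::arrange(dplyr::desc(.data$percent), .data$name)
}

#' Corpus-level component frequency statistics
#'
#' Computes the frequency report used to drive screen design: buffer usage
#' (over records with a buffer component), pH by integer decade bin (over
#' records reporting a pH), salt and precipitant usage (denominators are
#' the records reporting at least one component of that category), and the
#' PEG-subtype breakdown within PEG-containing records. Also records each
#' buffer's median observed pH, used to order buffers along the screen's pH
#' ladder.
#'
#' @param parsed A published, parsed corpus (see [filter_published()]).
#' @return A `frequency_report`: list of tibbles `buffer_pct`,
#'   `ph_bin_pct`, `salt_pct`, `precipitant_pct`, `peg_subtype_pct` (each
#'   `name`/`n`/`percent`), a `buffer_ph_median` tibble and a named
#'   `denominators` vector.
#' @export
frequency_stats <- function(parsed) {
  stopifnot(is.data.frame(parsed))
  if (nrow(parsed) == 0) abort("Empty corpus: nothing to summarise.")
  comp <- parsed |>
    dplyr::mutate(entry = dplyr::row_number()) |>
    dplyr::select("entry", "components") |>
    tidyr::unnest("components")

  per_record <- function(role_name) {
    comp |>
      dplyr::filter(.data$role == role_name) |>
      dplyr::distinct(.data$entry, .data$chemical)
  }
  buf <- per_record("buffer")
  salt <- per_record("salt")
  prec <- per_record("precipitant")
  ph <- comp |>
    dplyr::filter(!is.na(.data$pH)) |>
    dplyr::distinct(.data$entry, .keep_all = TRUE)

  n_buf <- dplyr::n_distinct(buf$entry)
  n_salt <- dplyr::n_distinct(salt$entry)
  n_prec <- dplyr::n_distinct(prec$entry)
  n_ph <- nrow(ph)

  peg <- prec |> dplyr::filter(startsWith(.data$chemical, "PEG"))
  n_peg <- dplyr::n_distinct(peg$entry)

  buffer_ph_median <- comp |>
    dplyr::filter(.data$role == "buffer", !is.na(.data$pH)) |>
    dplyr::group_by(buffer = .data$chemical) |>
    dplyr::summarise(median_pH = median(.data$pH), .groups = "drop")

  structure(list(
    buffer_pct = pct_table(table(buf$chemical), n_buf),
    ph_bin_pct = pct_table(table(ph_bin_label(ph$pH)), n_ph),
    salt_pct = pct_table(table(salt$chemical), n_salt),
    precipitant_pct = pct_table(table(prec$chemical), n_prec),
    peg_subtype_pct = pct_table(table(peg$chemical), n_peg),
    buffer_ph_median = buffer_ph_median,
    denominators = c(corpus = nrow(parsed), buffer = n_buf, ph = n_ph,
                     salt = n_salt, precipitant = n_prec, peg = n_peg)
  ), class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat("<frequency_report> denominators:",
      paste(names(x$denominators), x$denominators, sep = "=",
            collapse = ", "), "\n")
  cat("top buffers:\n")
  print(head(x$buffer_pct, 4))
  invisible(x)
}

#' Select screen components from a frequency report
#'
#' Applies the family-directed selection rules: the top `n_buffers` buffers
#' by usage; a contiguous pH ladder of `n_buffers * ph_levels_per_buffer`
#' steps of `ph_step` starting at the lower edge of the modal pH bin, with
#' consecutive level triples assigned to the selected buffers in order of
#' their median observed pH; the top `n_precipitants` PEG subtypes; the top
#' `n_salts` salts; and the configured precipitant concentration ladder.
#'
#' @param report A [frequency_stats()] report.
#' @param n_buffers,n_precipitants,n_salts Component counts to select.
#' @param ph_levels_per_buffer pH levels per buffer.
#' @param ph_step pH ladder step.
#' @param concentrations_pct_wv Precipitant concentrations, % w/v.
#' @return A selection list with `buffers` (tibble `buffer`, `pH`),
#'   `precipitants`, `concentrations_pct_wv`, `salts` — the same shape as
#'   [reference_screen_selection()].
#' @export
select_components <- function(report, n_buffers = 2, n_precipitants = 2,
                              n_salts = 2, ph_levels_per_buffer = 3,
                              ph_step = 0.5,
                              concentrations_pct_wv = c(5, 15, 25, 35)) {
  stopifnot(inherits(report, "frequency_report"))
  if (nrow(report$buffer_pct) < n_buffers)
    abort(sprintf("Need %d distinct buffers; corpus has %d.", n_buffers,
                  nrow(report$buffer_pct)))
  if (nrow(report$peg_subtype_pct) < n_precipitants)
    abort(sprintf("Need %d distinct PEG subtypes; corpus has %d.",
                  n_precipitants, nrow(report$peg_subtype_pct)))
  if (nrow(report$salt_pct) < n_salts)
    abort(sprintf("Need %d distinct salts; corpus has %d.", n_salts,
                  nrow(report$salt_pct)))

  top_buffers <- report$buffer_pct$name[seq_len(n_buffers)]
  modal_bin <- report$ph_bin_pct$name[1]
  ladder_start <- as.numeric(sub("-.*", "", modal_bin))
  levels <- ladder_start + ph_step * (seq_len(n_buffers * ph_levels_per_buffer) - 1)
  ordering <- report$buffer_ph_median |>
    dplyr::filter(.data$buffer %in% top_buffers) |>
    dplyr::arrange(.data$median_pH)
  buffers <- tibble::tibble(
    buffer = rep(ordering$buffer, each = ph_levels_per_buffer),
    pH = levels
  )
  list(
    buffers = buffers,
    precipitants = report$peg_subtype_pct$name[seq_len(n_precipitants)],
    concentrations_pct_wv = sort(concentrations_pct_wv),
    salts = report$salt_pct$name[seq_len(n_salts)]
  )
}

#' Generate the family-directed crystallisation screen
#'
#' Deterministic cross-product enumeration of a component selection:
#' buffer/pH combinations in listed order (major), then precipitants in
#' listed order, then ascending precipitant concentration. Every condition
#' carries the buffer at 100 mM and both fixed salts at 200 mM. The default
#' reference selection yields 48 conditions.
#'
#' @param selection A selection list, as from [select_components()] or
#'   [reference_screen_selection()].
#' @param buffer_mM Buffer concentration, mM.
#' @param salt_mM Fixed salt concentration, mM.
#' @return A tibble (`screen_spec`): `index`, `buffer`, `buffer_mM`, `pH`,
#'   `precipitant`, `precipitant_pct_wv`, `salt1`, `salt1_mM`, `salt2`,
#'   `salt2_mM`.
#' @export
#' @examples
#' nrow(generate_screen(reference_screen_selection()))  # 48
generate_screen <- function(selection, buffer_mM = 100, salt_mM = 200) {
  needed <- c("buffers", "precipitants", "concentrations_pct_wv", "salts")
  if (!all(needed %in% names(selection)))
    abort("`selection` must have buffers, precipitants, concentrations_pct_wv, salts.")
  if (nrow(selection$buffers) == 0 || length(selection$precipitants) == 0 ||
      length(selection$concentrations_pct_wv) == 0 ||
      length(selection$salts) < 2)
    abort("Empty selection category: cannot generate a screen.")
  spec <- tidyr::expand_grid(
    selection$buffers,
    precipitant = selection$precipitants,
    precipitant_pct_wv = sort(selection$concentrations_pct_wv)
  ) |>
    dplyr::mutate(
      index = dplyr::row_number(), buffer_mM = buffer_mM,
      salt1 = selection$salts[1], salt1_mM = salt_mM,
      salt2 = selection$salts[2], salt2_mM = salt_mM
    ) |>
    dplyr::select("index", "buffer", "buffer_mM", "pH", "precipitant",
                  "precipitant_pct_wv", "salt1", "salt1_mM", "salt2",
                  "salt2_mM")
  class(spec) <- c("screen_spec", class(spec))
  spec
}

#' Export a crystallisation screen
#'
#' Writes the screen as CSV and, alongside it, a human-readable sheet
#' grouped by buffer (same path with a `_sheet.txt` suffix).
#'
#' @param spec A [generate_screen()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_screen <- function(spec, path) {
  if (!is.data.frame(spec) || nrow(spec) == 0)
    abort("Refusing to write an empty screen.")
  readr::write_csv(as.data.frame(spec), path)
  sheet <- paste0(sub("\\.csv$", "", path), "_sheet.txt")
  lines <- spec |>
    dplyr::group_by(.data$buffer, .data$pH) |>
    dplyr::group_map(function(df, key) {
      c(sprintf("== %d mM %s pH %.1f (+ %d mM %s, %d mM %s) ==",
                df$buffer_mM[1], key$buffer, key$pH, df$salt1_mM[1],
                df$salt1[1], df$salt2_mM[1], df$salt2[1]),
        sprintf("  [%02d] %g%% w/v %s", df$index, df$precipitant_pct_wv,
                df$precipitant))
    }) |>
    unlist()
  writeLines(lines, sheet)
  invisible(path)
}

#' Read a crystallisation screen CSV
#'
#' @param path CSV written by [export_screen()].
#' @return A `screen_spec` tibble.
#' @export
read_screen <- function(path) {
  spec <- readr::read_csv(path, show_col_types = FALSE)
  class(spec) <- c("screen_spec", class(spec))
  spec
}

#' Read a crystallisation-condition corpus
#'
#' Accepts JSONL (one `{"entry_id": ..., "condition": ...}` object per
#' line) or a two-column CSV.
#'
#' @param path Corpus file (`.jsonl`/`.json` or `.csv`).
#' @return A tibble with columns `entry_id`, `condition`.
#' @export
read_condition_corpus <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(stringr::str_trim(lines))]
    purrr::map(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      tibble::tibble(entry_id = as.character(x$entry_id),
                     condition = as.character(x$condition %||% ""))
    }) |> purrr::list_rbind()
  } else {
    readr::read_csv(path, col_types = "cc", na = character()) |>
      setNames(c("entry_id", "condition"))
  }
}

#' Write a crystallisation-condition corpus as JSONL
#'
#' @param corpus Tibble with `entry_id`, `condition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_corpus <- function(corpus, path) {
  lines <- purrr::map2_chr(corpus$entry_id, corpus$condition, function(id, cond) {
    jsonlite::toJSON(list(entry_id = id, condition = cond), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
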