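#' Reference thermal-stability panel for ten cannabis terpene synthases
#'
#' Best-condition melting temperatures and thermal shifts from a thermofluor
#' buffer screen of ten recombinant *Cannabis sativa* terpene synthases.
#' Every row satisfies `tm_C - delta_tm_C = 76.46`, the melting temperature
#' of the water-control reference, so the panel doubles as a set of
#' generative midpoints for synthetic melt curves.
#'
#' @return A tibble with columns `protein_id`, `buffer`, `buffer_mM`, `pH`,
#'   `salt`, `salt_mM`, `tm_C`, `delta_tm_C`.
#' @export
#' @examples
#' tps_reference_stability()
tps_reference_stability <- function() {
  tibble::tribble(
    ~protein_id, ~buffer, ~pH, ~salt, ~tm_C, ~delta_tm_C,
    "CsTPS3FN",  "Tris",  8.0, "NaCl", 81.13, 4.67,
    "CsTPS1SK",  "HEPES", 7.5, "KCl",  80.20, 3.74,
    "CsTPS5FN",  "HEPES", 7.0, "KCl",  81.89, 5.43,
    "CsTPS37FN", "Tris",  8.0, "NaCl", 81.25, 4.79,
    "CsTPS9FN",  "HEPES", 7.5, "KCl",  83.18, 6.72,
    "CsTPS16CC", "HEPES", 7.5, "KCl",  79.36, 2.90,
    "CsTPS20CT", "HEPES", 7.0, "NaCl", 80.20, 3.74,
    "CsTPS19BL", "Tris",  8.0, "NaCl", 80.57, 4.11,
    "CsTPS12PK", "Tris",  8.0, "KCl",  81.03, 4.57,
    "CsTPS13PK", "HEPES", 7.5, "KCl",  81.67, 5.21
  ) |>
    dplyr::mutate(buffer_mM = 200, salt_mM = 100, .after = "pH")
}

#' Reference steady-state kinetic panel
#'
#' Michaelis-Menten parameters for a panel of cannabis terpene synthases
#' assayed with the malachite-green phosphate-release assay: Km (uM),
#' Vmax (uM/s) and kcat (1/s, Vmax over the effective enzyme concentration
#' of 10 in Vmax's concentration unit). Used as generative ground truth for
#' synthetic kinetics plates. The `kcat_per_s` column keeps the values as
#' published; for one row (CsTPS19BL with FPP) the published 0.0011 is
#' inconsistent with its published Vmax, which gives 0.0010 at 4 decimal
#' places.
#'
#' @return A tibble with columns `enzyme_id`, `substrate`, `km_uM`,
#'   `km_se_uM`, `vmax_uM_per_s`, `vmax_se_uM_per_s`, `kcat_per_s`.
#' @export
#' @examples
#' tps_reference_kinetics()
tps_reference_kinetics <- function() {
  tibble::tribble(
    ~enzyme_id,  ~substrate, ~km_uM, ~km_se_uM, ~vmax_uM_per_s, ~vmax_se_uM_per_s, ~kcat_per_s,
    "CsTPS3FN",  "GPP",  4.569, 0.411, 0.0196, 0.0005, 0.0020,
    "CsTPS9FN",  "FPP", 41.700, 3.730, 0.1127, 0.0047, 0.0113,
    "CsTPS16CC", "FPP", 38.430, 2.830, 0.1895, 0.0063, 0.0190,
    "CsTPS20CT", "FPP", 16.860, 6.420, 0.0144, 0.0022, 0.0014,
    "CsTPS1SK",  "GPP",  7.809, 0.678, 0.2038, 0.0053, 0.0204,
    "CsTPS5FN",  "GPP", 23.300, 1.340, 0.0300, 0.0007, 0.0030,
    "CsTPS19BL", "GPP", 48.450, 4.390, 0.0129, 0.0006, 0.0013,
    "CsTPS19BL", "FPP", 17.320, 5.230, 0.0102, 0.0002, 0.0011,
    "CsTPS12PK", "GPP", 41.850, 8.290, 0.0119, 0.0011, 0.0012,
    "CsTPS13PK", "GPP", 12.960, 1.230, 0.0918, 0.0029, 0.0092,
    "CsTPS37FN", "GPP", 27.710, 1.920, 0.0884, 0.0025, 0.0088
  )
}

#' Terpene compound lexicon
#'
#' Classification lexicon for the compounds seen in GC-MS assays of mono-
#' and sesquiterpene synthases: compound class (monoterpene, sesquiterpene,
#' non_terpene, internal_standard), whether identification is putative
#' (spectral-library match only, no authentic standard), a fixed reference
#' retention time (synthetic values; only their ordering is meaningful), and
#' an optional parent alias for thermal-degradation artefacts (elemol is the
#' GC artefact of hedycaryol).
#'
#' @return A tibble with columns `compound`, `klass`, `putative`, `rt_min`,
#'   `parent`.
#' @export
#' @examples
#' terpene_lexicon()
terpene_lexicon <- function() {
  tibble::tribble(
    ~compound,               ~klass,              ~putative, ~rt_min,
    "isobutylbenzene",       "internal_standard", FALSE,     11.20,
    "α-pinene",         "monoterpene",       FALSE,     12.35,
    "camphene",              "monoterpene",       FALSE,     12.90,
    "sabinene",              "monoterpene",       FALSE,     13.55,
    "β-pinene",         "monoterpene",       FALSE,     13.80,
    "β-myrcene",        "monoterpene",       FALSE,     14.25,
    "α-phellandrene",   "monoterpene",       FALSE,     14.80,
    "delta-3-carene",        "monoterpene",       FALSE,     15.05,
    "α-terpinene",      "monoterpene",       FALSE,     15.35,
    "limonene",              "monoterpene",       FALSE,     15.75,
    "β-phellandrene",   "monoterpene",       TRUE,      15.95,
    "(Z)-β-ocimene",    "monoterpene",       FALSE,     16.30,
    "(E)-β-ocimene",    "monoterpene",       FALSE,     16.65,
    "γ-terpinene",      "monoterpene",       FALSE,     17.10,
    "terpinolene",           "monoterpene",       FALSE,     17.85,
    "linalool",              "monoterpene",       FALSE,     18.30,
    "allo-ocimene",          "monoterpene",       TRUE,      18.75,
    "α-ocimene",        "monoterpene",       FALSE,     18.95,
    "fenchol",               "monoterpene",       TRUE,      19.20,
    "pinene hydrate",        "non_terpene",       TRUE,      19.60,
    "β-terpineol",      "monoterpene",       TRUE,      20.05,
    "α-terpineol",      "monoterpene",       FALSE,     20.70,
    "geranyl methyl ether",  "non_terpene",       TRUE,      21.15,
    "geraniol",              "monoterpene",       FALSE,     21.80,
    "δ-elemene",        "sesquiterpene",     TRUE,      25.40,
    "β-elemene",        "sesquiterpene",     TRUE,      26.10,
    "γ-elemene",        "sesquiterpene",     TRUE,      26.55,
    "germacrene B",          "sesquiterpene",     TRUE,      27.05,
    "β-caryophyllene",  "sesquiterpene",     FALSE,     27.50,
    "humulene",              "sesquiterpene",     FALSE,     28.20,
    "epi-β-caryophyllene", "sesquiterpene",  TRUE,      28.65,
    "alloaromadendrene",     "sesquiterpene",     TRUE,      29.10,
    "germacrene D",          "sesquiterpene",     TRUE,      29.55,
    "nerolidol",             "sesquiterpene",     FALSE,     30.40,
    "hedycaryol",            "sesquiterpene",     TRUE,      30.80,
    "elemol",                "sesquiterpene",     TRUE,      30.95,
    "germacrene-D",          "sesquiterpene",     TRUE,      29.55,
    "farnesol",              "sesquiterpene",     TRUE,      31.60,
    "guaiol",                "sesquiterpene",     TRUE,      32.15,
    "globulol",              "sesquiterpene",     TRUE,      32.70,
    "γ-eudesmol",       "sesquiterpene",     TRUE,      33.25,
    "α-eudesmol",       "sesquiterpene",     TRUE,      33.80
  ) |>
    dplyr::distinct(.data$compound, .keep_all = TRUE) |>
    dplyr::mutate(parent = dplyr::if_else(.data$compound == "elemol",
                                          "hedycaryol", NA_character_))
}

#' Crystallisation chemical lexicon
#'
#' Canonical names, synonym patterns and default roles for the buffers,
#' salts and precipitants used when parsing free-text crystallisation
#' conditions. Ammonium sulfate is dual-role: it is counted as a salt below
#' 0.8 M and as a precipitant at or above 0.8 M.
#'
#' @return A tibble with columns `chemical`, `role` and `synonyms`
#'   (a list-column of lower-case alternative spellings).
#' @export
#' @examples
#' crystallisation_lexicon()
crystallisation_lexicon <- function() {
  entry <- function(chemical, role, ...) {
    tibble::tibble(chemical = chemical, role = role,
                   synonyms = list(unique(c(tolower(chemical), ...))))
  }
  dplyr::bind_rows(
    entry("Bis-Tris", "buffer", "bis tris", "bistris", "bis-tris propane free"),
    entry("Tris", "buffer", "tris-hcl", "tris hcl", "tris hydrochloride"),
    entry("HEPES", "buffer", "hepes sodium", "na-hepes", "sodium hepes"),
    entry("MES", "buffer", "mes monohydrate", "mes-naoh"),
    entry("CAPS", "buffer"),
    entry("Bicine", "buffer"),
    entry("imidazole", "buffer"),
    entry("sodium acetate", "buffer", "na acetate", "naoac"),
    entry("sodium citrate", "buffer", "na citrate", "tri-sodium citrate",
          "trisodium citrate"),
    entry("sodium cacodylate", "buffer", "na cacodylate", "cacodylate"),
    entry("magnesium chloride", "salt", "mgcl2", "mgcl-2", "mgcl_2",
          "magnesium chloride hexahydrate"),
    entry("sodium chloride", "salt", "nacl"),
    entry("potassium chloride", "salt", "kcl"),
    entry("calcium chloride", "salt", "cacl2", "calcium chloride dihydrate"),
    entry("lithium sulfate", "salt", "li2so4", "lithium sulphate"),
    entry("lithium chloride", "salt", "licl"),
    entry("ammonium acetate", "salt", "nh4 acetate", "nh4oac"),
    entry("magnesium acetate", "salt", "mg acetate"),
    entry("sodium formate", "salt", "na formate"),
    entry("zinc acetate", "salt", "zn acetate", "zinc acetate dihydrate"),
    entry("ammonium sulfate", "salt", "ammonium sulphate", "(nh4)2so4",
          "nh42so4", "amso4"),
    entry("PEG-3350", "precipitant", "peg 3350", "peg3350",
          "polyethylene glycol 3350", "peg-3,350", "peg 3,350"),
    entry("PEG-8000", "precipitant", "peg 8000", "peg8000",
          "polyethylene glycol 8000", "peg-8,000", "peg 8,000"),
    entry("PEG-4000", "precipitant", "peg 4000", "peg4000",
          "polyethylene glycol 4000"),
    entry("PEG-6000", "precipitant", "peg 6000", "peg6000",
          "polyethylene glycol 6000"),
    entry("PEG-400", "precipitant", "peg 400", "peg400",
          "polyethylene glycol 400"),
    entry("PEG MME 2000", "precipitant", "peg mme 2000", "peg-mme-2000",
          "polyethylene glycol monomethyl ether 2000"),
    entry("MPD", "precipitant", "2-methyl-2,4-pentanediol"),
    entry("sodium malonate", "precipitant", "na malonate"),
    entry("glycerol", "precipitant"),
    entry("ethanol", "precipitant"),
    entry("isopropanol", "precipitant", "2-propanol")
  )
}

#' Reference crystallisation-condition frequency target
#'
#' Category frequencies (percent) describing a corpus of 104 published
#' crystallisation conditions for terpene synthases and related proteins:
#' buffer usage, pH decade bins, salts (among the 50 salt-reporting
#' conditions) and precipitants (among the 62 precipitant-reporting
#' conditions). The headline components (Bis-Tris 24.6, Tris 19.7;
#' pH 6.0-6.9 34.4, 7.0-7.9 23.4; magnesium chloride 26, sodium chloride 12;
#' PEG-3350 30.6, PEG-8000 19.4, ammonium sulfate 8) reflect the mined
#' corpus; the remaining mass across minor components is synthetic filler
#' chosen to be realistic, since the corpus itself is summarised only at
#' this level. Used as the generative target of [gen_condition_corpus()].
#'
#' @return A list with numeric percent vectors `buffer_pct`, `ph_bin_pct`,
#'   `salt_pct`, `precipitant_pct`, and scalars `p_salt`, `p_precipitant`
#'   (probabilities that a record reports that category).
#' @export
#' @examples
#' reference_condition_frequencies()
reference_condition_frequencies <- function() {
  list(
    buffer_pct = c(
      "Bis-Tris" = 24.6, "Tris" = 19.7, "HEPES" = 14.8, "MES" = 11.5,
      "sodium citrate" = 8.2, "sodium acetate" = 6.6,
      "sodium cacodylate" = 5.7, "imidazole" = 4.1, "Bicine" = 2.5,
      "CAPS" = 2.3
    ),
    ph_bin_pct = c(
      "3.0-3.9" = 1.5, "4.0-4.9" = 4.7, "5.0-5.9" = 17.2, "6.0-6.9" = 34.4,
      "7.0-7.9" = 23.4, "8.0-8.9" = 14.1, "9.0-9.9" = 4.7
    ),
    salt_pct = c(
      "magnesium chloride" = 26, "sodium chloride" = 12,
      "ammonium sulfate" = 10, "potassium chloride" = 8,
      "calcium chloride" = 8, "lithium sulfate" = 8,
      "magnesium acetate" = 6, "ammonium acetate" = 6,
      "sodium formate" = 6, "lithium chloride" = 6, "zinc acetate" = 4
    ),
    precipitant_pct = c(
      "PEG-3350" = 30.6, "PEG-8000" = 19.4, "PEG-4000" = 12.9,
      "PEG-6000" = 8.1, "PEG-400" = 6.5, "PEG MME 2000" = 6.4,
      "ammonium sulfate" = 8.0, "MPD" = 4.9, "sodium malonate" = 3.2
    ),
    p_salt = 50 / 104,
    p_precipitant = 62 / 104
  )
}

#' Reference screen-component selection
#'
#' The published component selection behind the 48-condition family-directed
#' crystallisation screen: six buffer/pH combinations (Bis-Tris at pH 6.0,
#' 6.5, 7.0 and Tris at pH 7.5, 8.0, 8.5), PEG-3350 and PEG-8000 as
#' precipitants at 5/15/25/35 % w/v, and magnesium chloride plus sodium
#' chloride as fixed 200 mM counter-ion salts.
#'
#' @return A list with tibble `buffers` (columns `buffer`, `pH`), character
#'   vector `precipitants`, numeric `concentrations_pct_wv`, and character
#'   vector `salts`.
#' @export
#' @examples
#' reference_screen_selection()
reference_screen_selection <- function() {
  list(
    buffers = tibble::tibble(
      buffer = rep(c("Bis-Tris", "Tris"), each = 3),
      pH = c(6.0, 6.5, 7.0, 7.5, 8.0, 8.5)
    ),
    precipitants = c("PEG-3350", "PEG-8000"),
    concentrations_pct_wv = c(5, 15, 25, 35),
    salts = c("magnesium chloride", "sodium chloride")
  )
}

#' Reference terpene product profiles
#'
#' Percent-of-total terpene compositions for the characterised enzyme
#' panel, per enzyme and substrate, as determined by GC-MS with an
#' isobutylbenzene internal standard and boiled-enzyme controls.
#' Hedycaryol appears under its GC artefact name elemol. One profile
#' (CsTPS16CC/FPP) sums to 98.66 as printed; simulation helpers renormalise
#' profiles to 100 before generating peak tables.
#'
#' @return A tibble with columns `enzyme_id`, `substrate`, `compound`,
#'   `percent`.
#' @export
#' @examples
#' tps_reference_profiles()
tps_reference_profiles <- function() {
  tibble::tribble(
    ~enzyme_id, ~substrate, ~compound, ~percent,
    "CsTPS3FN", "GPP", "β-myrcene", 100.00,
    "CsTPS1SK", "GPP", "α-pinene", 2.98,
    "CsTPS1SK", "GPP", "camphene", 0.98,
    "CsTPS1SK", "GPP", "β-myrcene", 2.25,
    "CsTPS1SK", "GPP", "β-pinene", 5.18,
    "CsTPS1SK", "GPP", "limonene", 74.72,
    "CsTPS1SK", "GPP", "terpinolene", 1.53,
    "CsTPS1SK", "GPP", "fenchol", 3.55,
    "CsTPS1SK", "GPP", "β-terpineol", 2.30,
    "CsTPS1SK", "GPP", "α-terpineol", 4.83,
    "CsTPS1SK", "GPP", "geraniol", 1.69,
    "CsTPS12PK", "GPP", "α-terpinene", 29.50,
    "CsTPS12PK", "GPP", "limonene", 33.36,
    "CsTPS12PK", "GPP", "γ-terpinene", 24.89,
    "CsTPS12PK", "GPP", "β-myrcene", 12.25,
    "CsTPS13PK", "GPP", "(E)-β-ocimene", 79.52,
    "CsTPS13PK", "GPP", "allo-ocimene", 1.80,
    "CsTPS13PK", "GPP", "(Z)-β-ocimene", 18.68,
    "CsTPS37FN", "GPP", "α-pinene", 3.03,
    "CsTPS37FN", "GPP", "β-phellandrene", 2.17,
    "CsTPS37FN", "GPP", "β-myrcene", 2.16,
    "CsTPS37FN", "GPP", "β-pinene", 4.77,
    "CsTPS37FN", "GPP", "delta-3-carene", 3.67,
    "CsTPS37FN", "GPP", "α-terpinene", 2.86,
    "CsTPS37FN", "GPP", "limonene", 1.96,
    "CsTPS37FN", "GPP", "γ-terpinene", 1.13,
    "CsTPS37FN", "GPP", "terpinolene", 70.69,
    "CsTPS37FN", "GPP", "linalool", 2.95,
    "CsTPS37FN", "GPP", "geraniol", 4.61,
    "CsTPS9FN", "FPP", "β-caryophyllene", 2.76,
    "CsTPS9FN", "FPP", "humulene", 4.49,
    "CsTPS9FN", "FPP", "epi-β-caryophyllene", 67.30,
    "CsTPS9FN", "FPP", "germacrene D", 15.26,
    "CsTPS9FN", "FPP", "globulol", 10.19,
    "CsTPS16CC", "FPP", "β-elemene", 1.05,
    "CsTPS16CC", "FPP", "γ-elemene", 3.82,
    "CsTPS16CC", "FPP", "germacrene B", 92.73,
    "CsTPS16CC", "FPP", "alloaromadendrene", 1.06,
    "CsTPS19BL", "GPP", "linalool", 100.00,
    "CsTPS19BL", "FPP", "nerolidol", 100.00,
    "CsTPS5FN", "GPP", "α-pinene", 23.00,
    "CsTPS5FN", "GPP", "β-myrcene", 37.00,
    "CsTPS5FN", "GPP", "β-pinene", 8.00,
    "CsTPS5FN", "GPP", "limonene", 17.00,
    "CsTPS5FN", "GPP", "sabinene", 15.00,
    "CsTPS5FN", "FPP", "farnesol", 100.00,
    "CsTPS20CT", "GPP", "β-myrcene", 7.89,
    "CsTPS20CT", "GPP", "limonene", 12.72,
    "CsTPS20CT", "GPP", "(Z)-β-ocimene", 2.64,
    "CsTPS20CT", "GPP", "terpinolene", 7.74,
    "CsTPS20CT", "GPP", "α-terpineol", 26.06,
    "CsTPS20CT", "GPP", "geraniol", 42.95,
    "CsTPS20CT", "FPP", "elemol", 31.42,
    "CsTPS20CT", "FPP", "guaiol", 19.96,
    "CsTPS20CT", "FPP", "γ-eudesmol", 20.51,
    "CsTPS20CT", "FPP", "α-eudesmol", 28.11
  )
}
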