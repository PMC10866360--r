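#' @title File I/O, configuration and campaign reporting
#' @description
#' Line-oriented .smi reading/writing with per-line error records, property
#' CSV round trips, JSON run configuration, and the INVEST-counting
#' heuristics used in campaign reports.
#' @name interfaces-reporting
NULL

#' Read a .smi file
#'
#' One SMILES per line, optional whitespace-separated name. Every input is
#' canonicalized; malformed lines are collected as error rows, never
#' silently dropped.
#'
#' @param path input file
#' @return data.frame with `smiles` (as read), `name`, `canonical` (NA for
#'   malformed), `ok`; attribute "errors" holds the malformed subset
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  df <- data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    name = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1)),
    stringsAsFactors = FALSE
  )
  df$canonical <- if (nrow(df) > 0) chem_canonical(df$smiles) else character(0)
  df$ok <- !is.na(df$canonical)
  attr(df, "errors") <- df[!df$ok, , drop = FALSE]
  df
}

#' Write a .smi file
#' @param smiles character vector
#' @param path output file
#' @param names optional molecule names
#' @return the path, invisibly
#' @export
write_smi <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names)
  writeLines(lines, path)
  invisible(path)
}

#' Property table round trip
#'
#' CSV with columns canonical, stg, os, vee (energies in eV, OS
#' dimensionless).
#'
#' @param path file path
#' @return data.frame
#' @export
read_property_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("canonical", "stg", "os", "vee")
  if (!all(need %in% names(df))) {
    stop("property CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_property_csv
#' @param table data.frame with the property columns
#' @export
write_property_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration round trip (JSON)
#'
#' Serializes every field of a [run_config()] including the RNG seed, so a
#' reloaded config reproduces the run bit-identically.
#'
#' @param cfg a `run_config`
#' @param path file path
#' @return the path, invisibly
#' @export
save_config <- function(cfg, path) {
  ser <- list(
    seed_smiles = cfg$seed_smiles, n_generations = cfg$n_generations,
    population_cap = cfg$population_cap, elite_fraction = cfg$elite_fraction,
    classifier_training_generation = cfg$classifier_training_generation,
    mode = cfg$mode$mode, core_pattern = cfg$mode$core_pattern,
    fitness = unclass(cfg$fitness), filter_cfg = unclass(cfg$filter_cfg),
    rng_seed = cfg$rng_seed, seed_substituent = cfg$seed_substituent,
    attempt_factor = cfg$attempt_factor
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  s <- jsonlite::fromJSON(path)
  fit <- do.call(fitness_spec, lapply(s$fitness, function(x)
    if (is.null(x)) NA_real_ else x))
  fc <- s$filter_cfg
  filt <- pi_filter_config(
    required_charge = fc$required_charge,
    required_radical_electrons = fc$required_radical_electrons,
    max_bridgehead_atoms = fc$max_bridgehead_atoms,
    max_spiro_atoms = fc$max_spiro_atoms,
    min_aromaticity_degree = fc$min_aromaticity_degree,
    min_conjugation_degree = fc$min_conjugation_degree,
    ring_size_range = fc$ring_size_range,
    forbidden_substructures = fc$forbidden_substructures %||% character(),
    max_total_atoms = fc$max_total_atoms
  )
  run_config(
    seed_smiles = s$seed_smiles, n_generations = s$n_generations,
    population_cap = s$population_cap, elite_fraction = s$elite_fraction,
    classifier_training_generation = s$classifier_training_generation %||% NA_integer_,
    mode = substitution_mode(s$mode, core_pattern = s$core_pattern),
    fitness = fit, filter_cfg = filt, rng_seed = s$rng_seed,
    seed_substituent = s$seed_substituent, attempt_factor = s$attempt_factor
  )
}

#' Campaign presets
#'
#' Configurations mirroring the six reference experiments (seed, fitness,
#' constraint mode, generation count) with desk-scale population caps and
#' the synthetic oracle in mind. Run 1: methane seed, free mode, threshold
#' 0.6, 11 generations. Runs 2-4: triazaazulene seed, azulene-likeness
#' required. Run 5: identical 1,6-substitution. Run 6: symmetric
#' 4,8-substitution on the fixed 2,5,7 core.
#'
#' @param run integer 1..6
#' @param population_cap desk-scale cap (default 200; full scale 10000)
#' @param rng_seed RNG seed
#' @param classifier_training_generation NA disables the classifier stage
#' @return a [run_config()]
#' @export
campaign_preset <- function(run, population_cap = 200L, rng_seed = 1L,
                            classifier_training_generation = NA_integer_) {
  stopifnot(run %in% 1:6)
  core <- pattern_to_molecule(c(2L, 5L, 7L))$smiles
  mode <- switch(run,
                 substitution_mode("free"),
                 substitution_mode("azulene_required"),
                 substitution_mode("azulene_required"),
                 substitution_mode("azulene_required"),
                 substitution_mode("identical_1_6"),
                 substitution_mode("symmetric_4_8_fixed_core"))
  run_config(
    seed_smiles = if (run == 1) "C" else core,
    n_generations = if (run == 1) 11L else 15L,
    population_cap = population_cap,
    classifier_training_generation = classifier_training_generation,
    mode = mode, fitness = fitness_spec_for_run(run), rng_seed = rng_seed
  )
}

#' INVEST candidate counts
#'
#' Counting heuristics for likely inverted-gap molecules: STG strictly
#' below `stg_cutoff` (0.36 eV), and additionally OS strictly above
#' `os_cutoff` (0.05).
#'
#' @param records data.frame with `stg` and `os` columns
#' @param stg_cutoff STG heuristic cutoff (default [INVEST_STG_CUTOFF])
#' @param os_cutoff OS cutoff (default [INVEST_OS_CUTOFF])
#' @return named integer vector `n_invest`, `n_invest_with_os`
#' @export
count_invest_candidates <- function(records, stg_cutoff = INVEST_STG_CUTOFF,
                                    os_cutoff = INVEST_OS_CUTOFF) {
  ok <- !is.na(records$stg) & !is.na(records$os)
  inv <- ok & records$stg < stg_cutoff
  c(n_invest = sum(inv), n_invest_with_os = sum(inv & records$os > os_cutoff))
}

#' Campaign report
#'
#' Totals, per-generation summaries and INVEST counts for a finished
#' campaign.
#'
#' @param campaign result of [run_campaign()]
#' @return a `campaign_report` list
#' @export
campaign_report <- function(campaign) {
  all <- do.call(rbind, campaign$logs)
  all <- all[!duplicated(all$canonical), , drop = FALSE]
  evaluated <- all[all$status == "ok", , drop = FALSE]
  counts <- count_invest_candidates(evaluated)
  structure(list(
    n_generated = nrow(all),
    n_evaluated = nrow(evaluated),
    n_failed = nrow(all) - nrow(evaluated),
    invest = counts,
    per_generation = campaign$summary,
    best = utils::head(rank_population(evaluated), 10L),
    backend = campaign$backend
  ), class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("<campaign_report>\n",
      "  molecules generated: ", x$n_generated, "\n",
      "  evaluated:           ", x$n_evaluated, "\n",
      "  oracle failures:     ", x$n_failed, "\n",
      "  likely INVEST (stg < 0.36):          ", x$invest["n_invest"], "\n",
      "  ... with appreciable OS (os > 0.05): ", x$invest["n_invest_with_os"],
      "\n", sep = "")
  invisible(x)
}
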