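#' @title Fitness components and property oracles
#' @description
#' Fitness is the sum of three components built from the singlet-triplet
#' gap (STG, eV), the oscillator strength (OS, dimensionless) and the
#' vertical excitation energy (VEE, eV). Properties carrying units are
#' formally divided by unity in the same unit, so all components are
#' dimensionless. A component whose minimum requirement is violated is
#' assigned the penalty constant -1e6; penalties accumulate additively, so
#' any penalized molecule ranks below every unpenalized one.
#'
#' The quantum-chemistry property oracle of the original workflow is
#' abstracted behind a pluggable contract: an oracle is a function taking a
#' character vector of canonical SMILES and returning a data.frame with
#' columns `canonical, stg, os, vee, status` (status "ok" or a failure
#' code; failed molecules are excluded from ranking, never given a fake
#' fitness).
#' @name fitness
NULL

#' Penalty constant
#' @export
FITNESS_PENALTY <- -1e6

#' Post-hoc INVEST counting heuristics (reporting constants)
#'
#' Molecules with STG below 0.36 eV are counted as likely INVEST; those
#' additionally with OS above 0.05 have appreciable fluorescence. The blue
#' target VEE is 3.2 eV on the fitness scale and 2.83 eV on the
#' lead-validation scale.
#' @export
INVEST_STG_CUTOFF <- 0.36
#' @rdname INVEST_STG_CUTOFF
#' @export
INVEST_OS_CUTOFF <- 0.05
#' @rdname INVEST_STG_CUTOFF
#' @export
BLUE_VEE_TARGET <- 3.2
#' @rdname INVEST_STG_CUTOFF
#' @export
BLUE_VEE_TARGET_VALIDATION <- 2.83

#' Fitness specification
#'
#' @param stg_threshold STG threshold in eV, or NA to disable the STG
#'   requirement entirely (0.6 in run 1, 0.3 in runs 2-6)
#' @param use_stg_term include the linear STG term `threshold - stg` in the
#'   fitness? Run 3 keeps the threshold requirement (the penalty gate) but
#'   zero weight.
#' @param os_weight 1 to add the OS term, 0 to drop it
#' @param vee_target target VEE in eV for the `-|vee - target|` term, or NA
#'   to disable (3.2 in run 4)
#' @param penalty penalty constant (default -1e6)
#' @return a `fitness_spec`
#' @export
fitness_spec <- function(stg_threshold = 0.3, use_stg_term = TRUE,
                         os_weight = 1, vee_target = NA_real_,
                         penalty = FITNESS_PENALTY) {
  stopifnot(is.na(stg_threshold) || stg_threshold > 0,
            os_weight %in% c(0, 1), penalty < 0)
  structure(list(stg_threshold = stg_threshold, use_stg_term = use_stg_term,
                 os_weight = os_weight, vee_target = vee_target,
                 penalty = penalty),
            class = "fitness_spec")
}

#' Per-run fitness presets
#'
#' The six artificial-design experiments: run 1 uses threshold 0.6 with the
#' linear STG term and the OS term; runs 2, 5 and 6 use threshold 0.3 with
#' both terms; run 3 keeps the 0.3 threshold requirement but zero STG
#' weight; run 4 adds the blue-light VEE term targeting 3.2 eV.
#'
#' @param run integer 1..6
#' @return a [fitness_spec()]
#' @export
fitness_spec_for_run <- function(run) {
  stopifnot(run %in% 1:6)
  switch(run,
    fitness_spec(stg_threshold = 0.6),
    fitness_spec(stg_threshold = 0.3),
    fitness_spec(stg_threshold = 0.3, use_stg_term = FALSE),
    fitness_spec(stg_threshold = 0.3, vee_target = 3.2),
    fitness_spec(stg_threshold = 0.3),
    fitness_spec(stg_threshold = 0.3)
  )
}

#' STG fitness component
#'
#' `threshold - stg` when non-negative, else the penalty. With
#' `use_stg_term = FALSE` the threshold requirement is still enforced (the
#' penalty branch) but the satisfied component contributes 0.
#'
#' @param stg numeric vector of singlet-triplet gaps (eV)
#' @param spec a [fitness_spec()]
#' @return numeric vector
#' @export
stg_component <- function(stg, spec) {
  if (is.na(spec$stg_threshold)) return(rep(0, length(stg)))
  raw <- spec$stg_threshold - stg
  sat <- if (spec$use_stg_term) raw else rep(0, length(stg))
  ifelse(raw < 0, spec$penalty, sat)
}

#' OS fitness component
#'
#' `os` itself when non-negative and weighted, the penalty when negative,
#' 0 when the weight is 0 (the non-negativity requirement still applies).
#'
#' @param os numeric vector of oscillator strengths
#' @param spec a [fitness_spec()]
#' @return numeric vector
#' @export
os_component <- function(os, spec) {
  ifelse(os < 0, spec$penalty, spec$os_weight * os)
}

#' VEE fitness component
#'
#' Negative VEEs are penalized in every run; otherwise `-|vee - target|`
#' when a target is set, else 0.
#'
#' @param vee numeric vector of vertical excitation energies (eV)
#' @param spec a [fitness_spec()]
#' @return numeric vector
#' @export
vee_component <- function(vee, spec) {
  base <- if (is.na(spec$vee_target)) 0 else -abs(vee - spec$vee_target)
  ifelse(vee < 0, spec$penalty, base)
}

#' Total fitness
#'
#' Sum of the three components; penalties accumulate.
#'
#' @param props data.frame with columns `stg`, `os`, `vee`
#' @param spec a [fitness_spec()]
#' @return numeric vector
#' @export
total_fitness <- function(props, spec) {
  stg_component(props$stg, spec) + os_component(props$os, spec) +
    vee_component(props$vee, spec)
}

#' Deterministic synthetic property oracle
#'
#' A desk-scale stand-in for the quantum-chemistry oracle: a closed form on
#' graph descriptors chosen so that azulene-like, nitrogen-rich,
#' medium-sized molecules reach gap inversion (minimum STG = -0.13 at
#' azulene-like, >= 6 aromatic ring nitrogens, 22 heavy atoms), making the
#' optimization behaviour of the whole loop testable. With H = heavy atoms,
#' nN = aromatic ring nitrogens, D = H-bond donors, C = conjugation degree,
#' azu = azulene-likeness indicator:
#' \deqn{stg = 0.9 - 0.55 azu - 0.08 min(nN, 6) + 0.015 |H - 22|}
#' \deqn{os = 0.02 + 0.08 min(D, 4) + 0.3 C azu min(H, 40)/40}
#' \deqn{vee = 1.8 + 0.04 min(H, 40)}
#'
#' @param smiles character vector
#' @return oracle result data.frame (`canonical, stg, os, vee, status`)
#' @export
synthetic_oracle <- function(smiles) {
  d <- chem_describe(smiles)
  synthetic_oracle_from_description(d)
}

#' @rdname synthetic_oracle
#' @param described a [chem_describe()] table
#' @export
synthetic_oracle_from_description <- function(described) {
  d <- described
  azu <- as.numeric(d$azulene_like)
  stg <- 0.9 - 0.55 * azu - 0.08 * pmin(d$n_arom_n, 6) +
    0.015 * abs(d$heavy - 22)
  os <- 0.02 + 0.08 * pmin(d$h_donors, 4) +
    0.3 * d$conj_deg * azu * pmin(d$heavy, 40) / 40
  vee <- 1.8 + 0.04 * pmin(d$heavy, 40)
  status <- ifelse(d$ok, "ok", "parse_failure")
  data.frame(canonical = d$canonical, stg = ifelse(d$ok, stg, NA_real_),
             os = ifelse(d$ok, os, NA_real_),
             vee = ifelse(d$ok, vee, NA_real_),
             status = status, stringsAsFactors = FALSE)
}

#' Lookup oracle from a property table
#'
#' Returns the stored property triple for molecules present in the table
#' and a "missing" status otherwise (by contract, not an exception).
#'
#' @param table data.frame with columns `canonical, stg, os, vee` (extra
#'   columns ignored); canonical forms are re-canonicalized on construction
#' @return an oracle function(character) -> result data.frame
#' @export
lookup_oracle <- function(table) {
  stopifnot(nrow(table) >= 1, all(c("canonical", "stg", "os", "vee") %in%
                                    names(table)))
  key <- chem_canonical(table$canonical)
  function(smiles) {
    canon <- chem_canonical(smiles)
    idx <- match(canon, key)
    data.frame(
      canonical = canon,
      stg = table$stg[idx],
      os = table$os[idx],
      vee = table$vee[idx],
      status = ifelse(is.na(idx), "missing", "ok"),
      stringsAsFactors = FALSE
    )
  }
}

#' The seed molecule property row
#'
#' 2,5,7-triazaazulene with its reference property triple on the fitness
#' scale: STG 0.24 eV, OS 0.005, VEE 2.71 eV.
#'
#' @return one-row data.frame usable with [lookup_oracle()]
#' @export
seed_property_row <- function() {
  core <- pattern_to_molecule(c(2L, 5L, 7L))
  data.frame(canonical = core$smiles, stg = 0.24, os = 0.005, vee = 2.71,
             stringsAsFactors = FALSE)
}
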