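#' @title Pi-system admissibility filters
#' @description
#' The domain-knowledge filter suite used both in virtual screening and
#' inside the genetic operators: neutral closed-shell molecules, no
#' bridgehead or spiro atoms, at least half the heavy atoms aromatic, at
#' least 70% of heavy-heavy bonds conjugated, every ring of size 4-8, no
#' forbidden substructures, and at most 70 atoms including hydrogens.
#' Acyclic molecules fail the ring rules by convention (the target subset is
#' cyclic pi-systems). Aromaticity and conjugation follow the toolkit's
#' default perception.
#' @name chem-filters
NULL

#' Filter configuration
#'
#' @param required_charge exact total formal charge (default 0)
#' @param required_radical_electrons exact radical electron count (default 0)
#' @param max_bridgehead_atoms maximum bridgehead atoms (default 0)
#' @param max_spiro_atoms maximum spiro atoms (default 0)
#' @param min_aromaticity_degree minimum fraction of aromatic heavy atoms
#'   (default 0.5, compared with >=)
#' @param min_conjugation_degree minimum fraction of conjugated heavy-heavy
#'   bonds (default 0.7, compared with >=)
#' @param ring_size_range inclusive bounds applied to both the smallest and
#'   the largest ring (default c(4, 8))
#' @param forbidden_substructures character vector of SMARTS patterns
#'   (default empty; the list is deferred to run configuration)
#' @param max_total_atoms atom cap including implicit hydrogens (default 70)
#' @return a `pi_filter_config`
#' @export
pi_filter_config <- function(required_charge = 0L,
                             required_radical_electrons = 0L,
                             max_bridgehead_atoms = 0L,
                             max_spiro_atoms = 0L,
                             min_aromaticity_degree = 0.5,
                             min_conjugation_degree = 0.7,
                             ring_size_range = c(4L, 8L),
                             forbidden_substructures = character(),
                             max_total_atoms = 70L) {
  stopifnot(length(ring_size_range) == 2, ring_size_range[1] <= ring_size_range[2],
            min_aromaticity_degree >= 0, min_aromaticity_degree <= 1,
            min_conjugation_degree >= 0, min_conjugation_degree <= 1,
            max_total_atoms >= 1)
  structure(list(
    required_charge = as.integer(required_charge),
    required_radical_electrons = as.integer(required_radical_electrons),
    max_bridgehead_atoms = as.integer(max_bridgehead_atoms),
    max_spiro_atoms = as.integer(max_spiro_atoms),
    min_aromaticity_degree = min_aromaticity_degree,
    min_conjugation_degree = min_conjugation_degree,
    ring_size_range = as.integer(ring_size_range),
    forbidden_substructures = as.character(forbidden_substructures),
    max_total_atoms = as.integer(max_total_atoms)
  ), class = "pi_filter_config")
}

#' Aromaticity degree
#'
#' Fraction of non-hydrogen atoms flagged aromatic by the toolkit.
#'
#' @param smiles character vector
#' @return numeric vector in [0, 1]; errors if any molecule is unparsable or
#'   has no heavy atoms
#' @export
aromaticity_degree <- function(smiles) {
  d <- chem_describe(smiles)
  if (any(!d$ok)) stop("invalid molecule(s): ", paste(d$input[!d$ok], collapse = ", "))
  d$arom_deg
}

#' Conjugation degree
#'
#' Fraction of heavy-heavy bonds flagged conjugated by the toolkit.
#' Molecules without heavy-heavy bonds (e.g. methane) return 0 by convention.
#'
#' @param smiles character vector
#' @return numeric vector in [0, 1]
#' @export
conjugation_degree <- function(smiles) {
  d <- chem_describe(smiles)
  if (any(!d$ok)) stop("invalid molecule(s): ", paste(d$input[!d$ok], collapse = ", "))
  d$conj_deg
}

#' Smallest and largest ring sizes
#'
#' Sizes over the smallest set of smallest rings.
#'
#' @param smiles a single SMILES
#' @return integer vector c(min, max), or NULL for acyclic molecules
#' @export
ring_size_extrema <- function(smiles) {
  d <- chem_describe(smiles)
  if (!d$ok[1]) stop("invalid molecule: ", smiles)
  if (is.na(d$ring_min[1])) return(NULL)
  c(as.integer(d$ring_min[1]), as.integer(d$ring_max[1]))
}

#' Structural counts
#'
#' @param smiles a single SMILES
#' @return named numeric vector: formal charge, radical electrons,
#'   bridgehead atoms, spiro atoms, total atoms including hydrogens
#' @export
structural_counts <- function(smiles) {
  d <- chem_describe(smiles)
  if (!d$ok[1]) stop("invalid molecule: ", smiles)
  c(charge = d$charge[1], radicals = d$radicals[1],
    bridgehead = d$bridgehead[1], spiro = d$spiro[1],
    total_atoms = d$total_atoms[1])
}

#' Apply the filter suite to described molecules
#'
#' Vectorized core of [apply_pi_filters()]: takes a description table from
#' [chem_describe()] (computed with the config's forbidden patterns) and
#' evaluates every rule for every row. Unparsable rows fail all rules.
#'
#' @param described data.frame from [chem_describe()]
#' @param cfg a [pi_filter_config()]
#' @return data.frame of per-rule logicals plus a `passed` column
#' @export
pi_filter_table <- function(described, cfg = pi_filter_config()) {
  d <- described
  lo <- cfg$ring_size_range[1]; hi <- cfg$ring_size_range[2]
  rules <- data.frame(
    charge = d$ok & d$charge == cfg$required_charge,
    radicals = d$ok & d$radicals == cfg$required_radical_electrons,
    bridgehead = d$ok & d$bridgehead <= cfg$max_bridgehead_atoms,
    spiro = d$ok & d$spiro <= cfg$max_spiro_atoms,
    aromaticity = d$ok & d$arom_deg >= cfg$min_aromaticity_degree,
    conjugation = d$ok & d$conj_deg >= cfg$min_conjugation_degree,
    ring_min = d$ok & !is.na(d$ring_min) & d$ring_min >= lo & d$ring_min <= hi,
    ring_max = d$ok & !is.na(d$ring_max) & d$ring_max >= lo & d$ring_max <= hi,
    substructures = d$ok & !d$forbidden_hit,
    atom_cap = d$ok & d$total_atoms <= cfg$max_total_atoms
  )
  rules[is.na(rules)] <- FALSE
  rules$passed <- Reduce(`&`, rules)
  rules
}

#' Apply the pi-system filters to one molecule
#'
#' @param smiles a single SMILES
#' @param cfg a [pi_filter_config()]
#' @return a `filter_verdict`: list with `passed` and `per_rule`, a named
#'   list of `list(passed =, observed =)` entries covering every rule
#' @export
apply_pi_filters <- function(smiles, cfg = pi_filter_config()) {
  d <- chem_describe(smiles, forbidden = cfg$forbidden_substructures)
  if (!d$ok[1]) stop("invalid molecule: ", smiles)
  rules <- pi_filter_table(d, cfg)
  observed <- list(
    charge = d$charge[1], radicals = d$radicals[1],
    bridgehead = d$bridgehead[1], spiro = d$spiro[1],
    aromaticity = d$arom_deg[1], conjugation = d$conj_deg[1],
    ring_min = d$ring_min[1], ring_max = d$ring_max[1],
    substructures = d$forbidden_hit[1], atom_cap = d$total_atoms[1]
  )
  per_rule <- lapply(names(observed), function(nm)
    list(passed = rules[[nm]][1], observed = observed[[nm]]))
  names(per_rule) <- names(observed)
  structure(list(passed = rules$passed[1], per_rule = per_rule,
                 canonical = d$canonical[1]),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat("<filter_verdict> passed:", x$passed, "\n")
  for (nm in names(x$per_rule)) {
    pr <- x$per_rule[[nm]]
    cat(sprintf("  %-14s %-5s (observed: %s)\n", nm, pr$passed,
                format(pr$observed)))
  }
  invisible(x)
}

#' Batch-filter a .smi file
#'
#' Reads a line-oriented SMILES file, evaluates every rule for every
#' molecule and writes a CSV with one row per input: the input, canonical
#' form, every observed value, every rule outcome, and the verdict.
#' Malformed lines are kept as rows with `ok = FALSE`.
#'
#' @param input path to a .smi file
#' @param output path for the CSV report
#' @param cfg a [pi_filter_config()]
#' @return the report data.frame, invisibly
#' @export
filter_smi_file <- function(input, output, cfg = pi_filter_config()) {
  smi <- read_smi(input)
  d <- chem_describe(smi$smiles, forbidden = cfg$forbidden_substructures)
  rules <- pi_filter_table(d, cfg)
  names(rules) <- paste0("rule_", names(rules))
  names(rules)[names(rules) == "rule_passed"] <- "passed"
  rep <- cbind(name = smi$name, d, rules)
  utils::write.csv(rep, output, row.names = FALSE)
  invisible(rep)
}
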