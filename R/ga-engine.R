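#' @title Campaign engine
#' @description
#' The generation loop: seed mutation for generation 1, fitness ranking,
#' top-20% elitism, replacement of the rest by filter- and
#' constraint-satisfying offspring, the population cap, optional surrogate
#' classifier training at a configured generation followed by gated
#' generation, and per-generation logging. Entire campaigns are
#' reproducible from the configured RNG seed.
#' @name ga-engine
NULL

#' Run configuration
#'
#' @param seed_smiles the seed molecule (methane in run 1, the
#'   2,5,7-triazaazulene core in runs 2-6)
#' @param n_generations number of generations (11 for run 1, 15 otherwise)
#' @param population_cap molecules per generation cap (full scale 10000;
#'   desk-scale campaigns use a few hundred)
#' @param elite_fraction fraction propagated unchanged (0.2)
#' @param classifier_training_generation generation after which the
#'   classifier is trained and the gate installed, or NA for no classifier
#'   (11 in the reference protocol)
#' @param mode a [substitution_mode()]
#' @param fitness a [fitness_spec()]
#' @param filter_cfg a [pi_filter_config()]
#' @param rng_seed integer seed for all randomness in the run
#' @param seed_substituent token string seeding the substituent genome in
#'   the attachment modes (the seed molecule there is the bare core, whose
#'   genome cannot seed substituent evolution); default a single carbon
#' @param attempt_factor attempt budget per generation as a multiple of the
#'   offspring deficit (default 20)
#' @return a `run_config`
#' @export
run_config <- function(seed_smiles, n_generations = 15L,
                       population_cap = 10000L, elite_fraction = 0.2,
                       classifier_training_generation = NA_integer_,
                       mode = substitution_mode("free"),
                       fitness = fitness_spec(),
                       filter_cfg = pi_filter_config(),
                       rng_seed = 1L,
                       seed_substituent = "[C]",
                       attempt_factor = 20L) {
  stopifnot(elite_fraction > 0, elite_fraction < 1, population_cap >= 2,
            n_generations >= 1)
  if (!is.na(classifier_training_generation)) {
    stopifnot(classifier_training_generation < n_generations)
  }
  structure(list(seed_smiles = seed_smiles, n_generations = as.integer(n_generations),
                 population_cap = as.integer(population_cap),
                 elite_fraction = elite_fraction,
                 classifier_training_generation = as.integer(classifier_training_generation),
                 mode = mode, fitness = fitness, filter_cfg = filter_cfg,
                 rng_seed = as.integer(rng_seed),
                 seed_substituent = seed_substituent,
                 attempt_factor = as.integer(attempt_factor)),
            class = "run_config")
}

#' Rank molecules by fitness
#'
#' Descending fitness; ties broken by canonical form lexicographically
#' (fixed C collation) so rankings are deterministic across runs.
#'
#' @param records data.frame with columns `canonical` and `fitness`
#' @return the data.frame reordered
#' @export
rank_population <- function(records) {
  if (any(is.na(records$fitness))) {
    stop("all records must carry a fitness (exclude failures first)")
  }
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  records[order(-records$fitness, records$canonical), , drop = FALSE]
}

#' Select the elite block
#'
#' The first `max(1, floor(fraction * N))` records of a ranked population.
#'
#' @param ranked ranked data.frame (from [rank_population()])
#' @param fraction elite fraction (default 0.2)
#' @return the elite rows
#' @export
select_elites <- function(ranked, fraction = 0.2) {
  stopifnot(nrow(ranked) >= 1)
  n <- max(1L, floor(fraction * nrow(ranked)))
  ranked[seq_len(n), , drop = FALSE]
}

# assemble the per-generation record table
make_records <- function(genomes, oracle_res, fitness_vals, generation) {
  if (length(genomes) == 0) {
    return(data.frame(generation = integer(), canonical = character(),
                      smiles_tokens = character(), operator = character(),
                      parent_ids = character(), stg = numeric(),
                      os = numeric(), vee = numeric(), status = character(),
                      fitness = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    generation = generation,
    canonical = oracle_res$canonical,
    smiles_tokens = vapply(genomes, function(g) paste(g$tokens, collapse = ""),
                           character(1)),
    operator = vapply(genomes, function(g) g$operator, character(1)),
    parent_ids = vapply(genomes, function(g)
      paste(g$parent_ids, collapse = ";"), character(1)),
    stg = oracle_res$stg, os = oracle_res$os, vee = oracle_res$vee,
    status = oracle_res$status, fitness = fitness_vals,
    stringsAsFactors = FALSE
  )
}

#' Collect classifier training data from generation logs
#'
#' One labeled example per unique evaluated molecule; labels follow the
#' good/bad rule ([label_example()]) computed from stored properties,
#' independent of the fitness spec.
#'
#' @param logs list of generation record data.frames
#' @return data.frame with `canonical, stg, os, label`
#' @export
collect_training_data <- function(logs) {
  all <- do.call(rbind, logs)
  all <- all[all$status == "ok", , drop = FALSE]
  all <- all[!duplicated(all$canonical), , drop = FALSE]
  lab <- label_example(all$stg, all$os)
  out <- data.frame(canonical = all$canonical, stg = all$stg, os = all$os,
                    label = lab, stringsAsFactors = FALSE)
  if (length(unique(out$label)) < 2) {
    attr(out, "degenerate") <- TRUE
    warning("training data contains a single class; classifier untrainable")
  }
  out
}

#' Run an artificial-design campaign
#'
#' Generation 1 consists of unique, constraint-passing mutants of the seed
#' (the seed itself is evaluated but exempt from the filters, since e.g.
#' methane fails the pi-filters by design). Every later generation is the
#' elite block plus offspring from [propose_offspring()], up to the
#' population cap. Every new molecule is property-evaluated by the oracle
#' and fitness-scored; oracle failures are excluded from ranking. When a
#' `classifier_trainer` is supplied and the configured training generation
#' completes, all molecules evaluated so far become training data, and the
#' trained gate filters offspring for the remaining generations.
#'
#' @param cfg a [run_config()]
#' @param oracle property oracle: function(character) -> data.frame
#'   (`canonical, stg, os, vee, status`)
#' @param classifier_trainer optional function(training_data_frame) ->
#'   model; the model is used via [gate_candidates()]
#' @param checkpoint_dir optional directory; per-generation JSON checkpoints
#'   and the uniqueness registry are written there
#' @param verbose print per-generation summaries
#' @return list with `logs` (per-generation record data.frames), `summary`
#'   (per-generation stats data.frame), `classifier` (model or NULL),
#'   `registry`, and `config`
#' @export
run_campaign <- function(cfg, oracle, classifier_trainer = NULL,
                         checkpoint_dir = NULL, verbose = FALSE) {
  set.seed(cfg$rng_seed)
  registry <- new_registry()
  memo <- new.env(parent = emptyenv())
  attach_mode <- !is.null(cfg$mode$attach_positions)
  # seed genome: in attachment modes the genetic operators act on the
  # substituent string; otherwise on the whole molecule
  seed_genome <- if (attach_mode) {
    new_genome(cfg$seed_substituent, operator = "seed")
  } else {
    smiles_to_genome(cfg$seed_smiles, operator = "seed")
  }
  seed_canonical <- chem_canonical(cfg$seed_smiles)
  registry_add(registry, seed_canonical)

  gate_fun <- NULL
  model <- NULL
  logs <- list()
  summaries <- list()
  elites_genomes <- list(seed_genome)
  prev_records <- NULL

  for (gen in seq_len(cfg$n_generations)) {
    target <- if (gen == 1L) cfg$population_cap - 1L else
      cfg$population_cap - nrow(prev_records)
    offspring <- propose_offspring(
      elites_genomes, max(1L, target), cfg = cfg$filter_cfg, mode = cfg$mode,
      registry = registry, gate = gate_fun,
      attempt_budget = cfg$attempt_factor * max(1L, target), memo = memo,
      edit_range = if (gen == 1L) 1:30 else 1:3
    )
    new_smiles <- vapply(offspring, function(g) g$canonical, character(1))
    if (gen == 1L) {
      # evaluate the seed alongside its mutants
      eval_genomes <- c(list(seed_genome), offspring)
      eval_smiles <- c(seed_canonical, new_smiles)
    } else {
      eval_genomes <- offspring
      eval_smiles <- new_smiles
    }
    if (length(eval_smiles) == 0 && gen == 1L) {
      stop("empty first generation: attempt budget exhausted")
    }
    props <- oracle(eval_smiles)
    fit <- rep(NA_real_, nrow(props))
    ok <- props$status == "ok"
    fit[ok] <- total_fitness(props[ok, , drop = FALSE], cfg$fitness)
    recs <- make_records(eval_genomes, props, fit, gen)
    gen_records <- if (gen == 1L) recs else rbind(prev_records, recs)
    gen_records$generation <- gen
    logs[[gen]] <- gen_records

    scored <- gen_records[gen_records$status == "ok", , drop = FALSE]
    if (nrow(scored) == 0) stop("no scorable molecules in generation ", gen)
    ranked <- rank_population(scored)
    elites <- select_elites(ranked, cfg$elite_fraction)
    # elites re-used without re-evaluation; genome lookup by canonical form
    genome_pool <- c(elites_genomes, eval_genomes)
    pool_keys <- vapply(genome_pool, function(g) g$canonical, character(1))
    idx <- match(elites$canonical, pool_keys)
    elites_genomes <- genome_pool[idx[!is.na(idx)]]
    if (length(elites_genomes) == 0) elites_genomes <- list(seed_genome)
    prev_records <- elites

    gate_frac <- NA_real_
    if (!is.null(gate_fun)) {
      lab <- label_example(recs$stg[recs$status == "ok"],
                           recs$os[recs$status == "ok"])
      gate_frac <- mean(lab == "good")
    }
    summaries[[gen]] <- data.frame(
      generation = gen, n_molecules = nrow(gen_records),
      n_new = length(eval_smiles), n_failed = sum(!ok),
      best_fitness = ranked$fitness[1],
      median_fitness = stats::median(ranked$fitness),
      attempts = attr(offspring, "attempts") %||% NA_integer_,
      gated = !is.null(gate_fun), good_fraction_new = gate_frac
    )
    if (verbose) {
      message(sprintf("gen %2d: %4d molecules, best fitness %.4f",
                      gen, nrow(gen_records), ranked$fitness[1]))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(gen_records,
                       file.path(checkpoint_dir, sprintf("generation_%02d.csv", gen)),
                       row.names = FALSE)
      registry_save(registry, file.path(checkpoint_dir, "registry.txt"))
    }

    if (!is.null(classifier_trainer) &&
        !is.na(cfg$classifier_training_generation) &&
        gen == cfg$classifier_training_generation) {
      train_df <- collect_training_data(logs)
      if (!isTRUE(attr(train_df, "degenerate"))) {
        model <- classifier_trainer(train_df)
        gate_fun <- function(smiles) gate_candidates(model, smiles)
      }
    }
  }
  list(logs = logs, summary = do.call(rbind, summaries), classifier = model,
       registry = registry, config = cfg,
       backend = chem_backend_info())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
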