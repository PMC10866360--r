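#' @title Genetic operators on robust token strings
#' @description
#' STONED-style structure generation: random token edits (insertion,
#' deletion, replacement) and string interpolation between two parents,
#' operating on the robust representation so every proposal decodes to a
#' valid molecule. Offspring are accepted only if they satisfy the
#' pi-system filters, the active structural constraint mode, the 70-atom
#' cap, uniqueness across the whole run, and (when installed) the surrogate
#' classifier gate.
#' @name genetic-operators
NULL

#' Uniqueness registry
#'
#' Append-only set of canonical forms encountered during a run; offspring
#' already present are rejected so every molecule in a campaign is unique
#' across all generations.
#'
#' @return a `uniqueness_registry`
#' @export
new_registry <- function() {
  env <- new.env(parent = emptyenv())
  structure(list(env = env), class = "uniqueness_registry")
}

#' @rdname new_registry
#' @param reg a registry
#' @param canonical character vector of canonical forms
#' @export
registry_has <- function(reg, canonical) {
  vapply(canonical, function(k) nzchar(k) && !is.null(reg$env[[k]]),
         logical(1), USE.NAMES = FALSE)
}

#' @rdname new_registry
#' @export
registry_add <- function(reg, canonical) {
  for (k in canonical) reg$env[[k]] <- TRUE
  invisible(reg)
}

#' @rdname new_registry
#' @export
registry_size <- function(reg) length(ls(reg$env))

#' @rdname new_registry
#' @param path file path; the registry persists as a sorted text file of
#'   canonical forms for run resumption
#' @export
registry_save <- function(reg, path) {
  writeLines(sort(ls(reg$env)), path)
  invisible(path)
}

#' @rdname new_registry
#' @export
registry_load <- function(path) {
  reg <- new_registry()
  registry_add(reg, readLines(path))
  reg
}

mutate_tokens <- function(tokens, n_mutations) {
  alphabet <- RTS_ALPHABET
  for (k in seq_len(n_mutations)) {
    type <- sample(c("insert", "delete", "replace"), 1L)
    n <- length(tokens)
    if (type == "insert" || n == 0L) {
      pos <- sample.int(n + 1L, 1L)
      tok <- sample(alphabet, 1L)
      tokens <- append(tokens, tok, after = pos - 1L)
    } else if (type == "delete") {
      tokens <- tokens[-sample.int(n, 1L)]
    } else {
      tokens[sample.int(n, 1L)] <- sample(alphabet, 1L)
    }
  }
  tokens
}

#' Random string mutations
#'
#' Applies `n_mutations` random token edits (insertion, deletion,
#' replacement chosen uniformly) to a genome. The robust representation
#' guarantees the result decodes to a valid molecule; edit sequences that
#' leave no atom token (possible through deletions) are redrawn internally.
#' Randomness comes from R's RNG: seed with [set.seed()] for reproducibility.
#'
#' @param genome a `candidate_genome`
#' @param n_mutations number of token edits, >= 1
#' @return a new `candidate_genome` with operator "mutation"
#' @export
random_string_mutations <- function(genome, n_mutations = 1L) {
  stopifnot(n_mutations >= 1L)
  for (attempt in 1:50) {
    tokens <- mutate_tokens(genome$tokens, n_mutations)
    smi <- rts_to_smiles(tokens)
    if (!is.na(smi)) {
      return(new_genome(tokens, canonical = chem_canonical(smi),
                        operator = "mutation", parent_ids = genome$canonical))
    }
  }
  stop("mutation failed to produce a decodable string after 50 attempts")
}

#' String interpolation between two parents
#'
#' Pads the shorter token string with `[nop]`, then forms hybrids from a
#' prefix of one parent and the suffix of the other at random crossover
#' points. Identical parents yield an empty list.
#'
#' @param a,b parent `candidate_genome`s
#' @param n_offspring number of crossover draws (default 8)
#' @return list of token vectors (possibly fewer after deduplication)
#' @export
interpolate <- function(a, b, n_offspring = 8L) {
  if (identical(a$tokens, b$tokens)) return(list())
  len <- max(length(a$tokens), length(b$tokens))
  pad <- function(x) c(x, rep("[nop]", len - length(x)))
  ta <- pad(a$tokens); tb <- pad(b$tokens)
  if (len < 2L) return(list())
  out <- list()
  seen <- character(0)
  for (k in seq_len(n_offspring)) {
    cut <- sample.int(len - 1L, 1L)
    child <- if (sample.int(2L, 1L) == 1L) {
      c(ta[1:cut], tb[(cut + 1L):len])
    } else {
      c(tb[1:cut], ta[(cut + 1L):len])
    }
    child <- child[child != "[nop]"]
    key <- paste(child, collapse = "")
    if (length(child) > 0 && !(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- child
    }
  }
  out
}

# Generate raw candidate token strings from elite genomes.
# mutation : interpolation is an even split; edit counts drawn from
# edit_range (1..3 in steady state; generation 1 uses a wide "seed burst"
# so small seeds can reach ring-containing structures at all).
generate_raw_tokens <- function(elites, n, edit_range = 1:3) {
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    use_interp <- length(elites) >= 2L && stats::runif(1) < 0.5
    if (use_interp) {
      pick <- sample.int(length(elites), 2L)
      kids <- interpolate(elites[[pick[1]]], elites[[pick[2]]], n_offspring = 2L)
      for (kid in kids) {
        if (i > n) break
        out[[i]] <- list(tokens = kid, operator = "interpolation",
                         parents = c(elites[[pick[1]]]$canonical,
                                     elites[[pick[2]]]$canonical))
        i <- i + 1L
      }
    } else {
      p <- sample.int(length(elites), 1L)
      n_edit <- if (length(edit_range) == 1L) edit_range else
        sample(edit_range, 1L)
      toks <- mutate_tokens(elites[[p]]$tokens, n_edit)
      out[[i]] <- list(tokens = toks, operator = "mutation",
                       parents = elites[[p]]$canonical)
      i <- i + 1L
    }
  }
  out
}

#' Propose filter- and constraint-satisfying offspring
#'
#' Draws parents uniformly from the elites, applies mutation or
#' interpolation (50/50), and -- in the substituent-attachment modes --
#' treats the generated structure as a substituent attached to the fixed
#' azulene core at the mode's positions. A candidate is accepted only if it
#' decodes validly, respects the atom cap and the full pi-filter suite,
#' satisfies the constraint mode, is new to the registry, and (when a gate
#' is installed) is classified good. Accepted candidates are registered
#' immediately.
#'
#' @param elites list of `candidate_genome`s (non-empty)
#' @param target_count number of offspring wanted, >= 1
#' @param cfg a [pi_filter_config()]
#' @param mode a [substitution_mode()]
#' @param registry a [new_registry()]
#' @param gate optional classifier gate: a function(canonical_smiles) ->
#'   logical vector (TRUE = good)
#' @param attempt_budget max raw proposals before giving up (default
#'   20 * target_count); shortfall returns a partial list with a warning
#' @param edit_range integer range the per-mutation edit count is drawn
#'   from (default 1:3; the campaign engine widens this for generation 1
#'   seeding so small seeds can reach cyclic structures)
#' @param memo optional environment memoizing decoded-structure verdicts
#'   across calls (the campaign engine shares one per run); mutation
#'   operators frequently regenerate the same structure, and memoized
#'   structures skip the perception round trip
#' @return list of accepted `candidate_genome`s; attribute "attempts" holds
#'   the number of raw proposals consumed
#' @export
propose_offspring <- function(elites, target_count, cfg = pi_filter_config(),
                              mode = substitution_mode("free"),
                              registry = new_registry(), gate = NULL,
                              attempt_budget = 20L * target_count,
                              memo = new.env(parent = emptyenv()),
                              edit_range = 1:3) {
  stopifnot(length(elites) >= 1L, target_count >= 1L)
  accepted <- list()
  attempts <- 0L
  batch_seen <- character(0)
  while (length(accepted) < target_count && attempts < attempt_budget) {
    chunk <- min(attempt_budget - attempts,
                 max(64L, 2L * (target_count - length(accepted))))
    raw <- generate_raw_tokens(elites, chunk, edit_range = edit_range)
    attempts <- attempts + chunk
    smi <- vapply(raw, function(r) {
      s <- rts_to_smiles(r$tokens)
      if (is.na(s)) NA_character_ else s
    }, character(1))
    keep <- !is.na(smi)
    raw <- raw[keep]; smi <- smi[keep]
    if (length(smi) == 0) next
    hit <- vapply(smi, function(s) !is.null(memo[[s]]), logical(1),
                  USE.NAMES = FALSE)
    canon <- character(length(smi))
    pass <- logical(length(smi))
    for (k in which(hit)) {
      mv <- memo[[smi[k]]]
      canon[k] <- mv$canonical
      pass[k] <- mv$pass
    }
    new_idx <- which(!hit)
    # a raw structure may repeat within the chunk: perceive each once
    if (length(new_idx) > 0) {
      uniq <- !duplicated(smi[new_idx])
      probe_idx <- new_idx[uniq]
      if (!is.null(mode$attach_positions)) {
        att <- chem_attach(mode$core_pattern, smi[probe_idx],
                           mode$attach_positions)
        full_smi <- att$smiles
      } else {
        full_smi <- smi[probe_idx]
      }
      usable <- !is.na(full_smi)
      d <- chem_describe(full_smi[usable],
                         forbidden = cfg$forbidden_substructures)
      rules <- pi_filter_table(d, cfg)
      ok <- rules$passed & d$total_atoms <= cfg$max_total_atoms
      if (mode$mode != "free") ok <- ok & !is.na(d$azulene_like) & d$azulene_like
      ok[is.na(ok)] <- FALSE
      probe_can <- rep(NA_character_, length(probe_idx))
      probe_ok <- rep(FALSE, length(probe_idx))
      probe_can[usable] <- d$canonical
      probe_ok[usable] <- ok
      for (j in seq_along(probe_idx)) {
        memo[[smi[probe_idx[j]]]] <- list(
          canonical = if (is.na(probe_can[j])) "" else probe_can[j],
          pass = probe_ok[j] && !is.na(probe_can[j])
        )
      }
      for (k in new_idx) {
        mv <- memo[[smi[k]]]
        canon[k] <- mv$canonical
        pass[k] <- mv$pass
      }
    }
    ok <- pass & !registry_has(registry, canon) & !(canon %in% batch_seen)
    idx <- which(ok)
    idx <- idx[!duplicated(canon[idx])]
    if (length(idx) > 0 && !is.null(gate)) {
      good <- gate(canon[idx])
      idx <- idx[good]
    }
    for (k in idx) {
      if (length(accepted) >= target_count) break
      g <- new_genome(raw[[k]]$tokens, canonical = canon[k],
                      operator = if (!is.null(mode$attach_positions))
                        "substituent_attachment" else raw[[k]]$operator,
                      parent_ids = raw[[k]]$parents)
      accepted[[length(accepted) + 1L]] <- g
      registry_add(registry, canon[k])
      batch_seen <- c(batch_seen, canon[k])
    }
  }
  if (length(accepted) < target_count) {
    warning("attempt budget exhausted: ", length(accepted), "/", target_count,
            " offspring accepted")
  }
  attr(accepted, "attempts") <- attempts
  accepted
}
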