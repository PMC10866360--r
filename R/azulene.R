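#' @title Azulene scaffold enumeration and constraints
#' @description
#' Symmetry-aware handling of nitrogen-substituted azulene cores. Azulene is
#' numbered by IUPAC convention: positions 1-3 on the five-membered ring,
#' 4-8 on the seven-membered ring, with the fusion carbons 3a/8a never
#' substituted. The molecular mirror plane induces the position permutation
#' sigma = (1 3)(4 8)(5 7), so nitrogen-substitution patterns are orbits of
#' subsets of {1..8} under sigma: (2^8 + 2^5)/2 = 144 distinct cores by
#' Burnside's lemma.
#' @name azulene-scaffolds
NULL

AZULENE_MIRROR <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 8L,
                    `5` = 7L, `6` = 6L, `7` = 5L, `8` = 4L)

#' Mirror image of a substitution pattern
#'
#' Applies the mirror permutation sigma position-wise.
#'
#' @param positions integer vector of nitrogen positions (subset of 1..8)
#' @return sorted integer vector of mirrored positions
#' @export
mirror_image <- function(positions) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > 8L)) {
    stop("positions must lie in 1..8")
  }
  sort(unname(AZULENE_MIRROR[as.character(positions)]))
}

#' Canonical form of a substitution pattern
#'
#' The lexicographically smaller of the sorted pattern and its mirror image
#' (comparison on the serialized position string). Idempotent.
#'
#' @param positions integer vector of nitrogen positions
#' @return sorted integer vector, canonical under the mirror symmetry
#' @export
canonical_pattern <- function(positions) {
  a <- sort(as.integer(unique(positions)))
  if (any(a < 1L | a > 8L)) stop("positions must lie in 1..8")
  b <- mirror_image(a)
  ka <- pattern_key(a); kb <- pattern_key(b)
  if (kb < ka) b else a
}

#' Serialize a pattern
#' @param positions integer vector
#' @return comma-joined sorted positions ("" for the empty pattern)
#' @export
pattern_key <- function(positions) {
  paste(sort(as.integer(positions)), collapse = ",")
}

#' Human-readable pattern label
#' @param positions integer vector
#' @return e.g. "aza-2,5,7", or "azulene" for the empty pattern
#' @export
pattern_label <- function(positions) {
  if (length(positions) == 0) return("azulene")
  paste0("aza-", pattern_key(canonical_pattern(positions)))
}

#' Enumerate all symmetry-distinct core patterns
#'
#' Every subset of the eight CH positions, deduplicated under the mirror
#' symmetry; exactly 144 patterns.
#'
#' @return list of sorted integer vectors (canonical patterns), ordered by
#'   nitrogen count then lexicographically
#' @export
enumerate_core_patterns <- function() {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:255) {
    pos <- which(bitwAnd(mask, bitwShiftL(1L, 0:7)) != 0L)
    p <- canonical_pattern(pos)
    k <- pattern_key(p)
    if (is.null(seen[[paste0("k", k)]])) {
      seen[[paste0("k", k)]] <- TRUE
      out[[length(out) + 1L]] <- p
    }
  }
  ord <- order(vapply(out, length, integer(1)),
               vapply(out, pattern_key, character(1)))
  out[ord]
}

#' Build the molecule for a core pattern
#'
#' The fully conjugated azaazulene with nitrogen at the given positions and
#' CH elsewhere. If the toolkit's aromaticity model rejects a pattern the
#' localized Kekule form is used and flagged.
#'
#' @param positions integer vector of nitrogen positions
#' @return list with `smiles` (canonical) and `kekule_fallback` flag
#' @export
pattern_to_molecule <- function(positions) {
  positions <- sort(as.integer(unique(positions)))
  if (any(positions < 1L | positions > 8L)) stop("positions must lie in 1..8")
  chem_build_core(positions)
}

#' Azulene-likeness
#'
#' TRUE iff the molecule contains a fused bicyclic 5-7 ring system, fully
#' conjugated, whose ring atoms are all carbon or nitrogen. Pentalene (5-5),
#' heptalene (7-7) and naphthalene (6-6) do not match.
#'
#' @param smiles character vector
#' @return logical vector (NA for unparsable input)
#' @export
is_azulene_like <- function(smiles) {
  chem_describe(smiles)$azulene_like
}

#' Attach identical substituents to a core
#'
#' Bonds the same substituent at both given positions of the azaazulene
#' core, replacing one hydrogen at each. For positions (4,8) on a
#' mirror-symmetric core the product has a plane of symmetry through the
#' azulene core. The substituent's attachment point is the first atom of
#' its SMILES, which must have a free valence.
#'
#' @param core_positions nitrogen positions of the core pattern
#' @param substituent SMILES of the substituent (first atom = attachment)
#' @param positions attachment position pair, c(1,6) or c(4,8)
#' @return canonical SMILES of the product
#' @export
attach_identical_substituents <- function(core_positions, substituent,
                                          positions = c(4L, 8L)) {
  positions <- sort(as.integer(positions))
  if (!identical(positions, c(1L, 6L)) && !identical(positions, c(4L, 8L))) {
    stop("positions must be (1,6) or (4,8)")
  }
  core_positions <- sort(as.integer(unique(core_positions)))
  if (any(positions %in% core_positions)) {
    stop("attachment position occupied by a ring nitrogen")
  }
  res <- chem_attach(core_positions, substituent, positions)
  if (!is.na(res$error[1])) stop("attachment failed: ", res$error[1])
  res$smiles[1]
}

#' Substitution mode for constrained generation
#'
#' @param mode one of "free", "azulene_required", "identical_1_6",
#'   "symmetric_4_8_fixed_core"
#' @param core_pattern nitrogen positions of the fixed core used in the
#'   attachment modes; must be c(2,5,7) for symmetric_4_8_fixed_core
#'   (defaults: c(2,5,7) in both attachment modes)
#' @return a `substitution_mode`
#' @export
substitution_mode <- function(mode = c("free", "azulene_required",
                                       "identical_1_6",
                                       "symmetric_4_8_fixed_core"),
                              core_pattern = NULL) {
  mode <- match.arg(mode)
  if (mode == "symmetric_4_8_fixed_core") {
    if (is.null(core_pattern)) core_pattern <- c(2L, 5L, 7L)
    if (!identical(sort(as.integer(core_pattern)), c(2L, 5L, 7L))) {
      stop("symmetric_4_8_fixed_core requires the 2,5,7 core")
    }
  } else if (mode == "identical_1_6") {
    if (is.null(core_pattern)) core_pattern <- c(2L, 5L, 7L)
    core_pattern <- sort(as.integer(core_pattern))
    if (any(c(1L, 6L) %in% core_pattern)) {
      stop("identical_1_6 requires carbon at positions 1 and 6")
    }
  } else {
    core_pattern <- NULL
  }
  structure(list(mode = mode, core_pattern = core_pattern,
                 attach_positions = switch(mode,
                                           identical_1_6 = c(1L, 6L),
                                           symmetric_4_8_fixed_core = c(4L, 8L),
                                           NULL)),
            class = "substitution_mode")
}

#' Write the 144 cores to a .smi file
#'
#' One line per core: canonical SMILES and the pattern label.
#'
#' @param path output file
#' @return the data.frame written, invisibly
#' @export
write_core_library <- function(path) {
  pats <- enumerate_core_patterns()
  rows <- lapply(pats, function(p) {
    m <- pattern_to_molecule(p)
    data.frame(smiles = m$smiles, name = pattern_label(p),
               kekule_fallback = m$kekule_fallback, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  writeLines(paste(df$smiles, df$name), path)
  invisible(df)
}
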