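# Shared fixtures: small molecules with hand-checkable structure.
AZULENE <- "C1=CC2=CC=CC=CC2=C1"
NAPHTHALENE <- "c1ccc2ccccc2c1"
BENZENE <- "c1ccccc1"
STYRENE <- "C=Cc1ccccc1"
BUTADIENE <- "C=CC=C"
ETHANE <- "CC"
HEXANE <- "CCCCCC"
CYCLOPROPANE <- "C1CC1"
SPIROPENTANE <- "C1CC12CC2"
ACETATE <- "CC(=O)[O-]"

triaza_core <- function() pattern_to_molecule(c(2L, 5L, 7L))$smiles

# a small corpus of valid molecules spanning the filter rules
corpus_smiles <- function() {
  c(AZULENE, NAPHTHALENE, BENZENE, STYRENE, BUTADIENE, ETHANE, HEXANE,
    CYCLOPROPANE, SPIROPENTANE, "c1ccncc1", "c1ccc2[nH]ccc2c1", "C1=CC=CC1",
    "C#Cc1ccccc1", "OC=O", "N#Cc1ccccc1", triaza_core())
}

# random decodable genomes under a fixed seed
random_genomes <- function(n, len = 20L) {
  lapply(seq_len(n), function(i) {
    repeat {
      toks <- sample(rts_alphabet(), sample.int(len, 1L), replace = TRUE)
      if (!is.na(rts_to_smiles(toks))) return(toks)
    }
  })
}

# brute-force comparator-based ordering oracle for the hierarchical ranking:
# independent of the recursive implementation in the package
chimera_bruteforce <- function(points, spec) {
  vals <- sapply(spec$objectives, function(o) {
    v <- if (is.null(o$transform)) points[[o$name]] else o$transform(points)
    if (o$goal == "maximize") -v else v
  })
  vals <- matrix(vals, nrow = nrow(points))
  tol <- sapply(spec$objectives, function(o)
    if (o$goal == "maximize") -o$tolerance else o$tolerance)
  tie <- if ("canonical" %in% names(points)) points$canonical
         else sprintf("%09d", seq_len(nrow(points)))
  nlev <- ncol(vals)
  # returns TRUE if point i ranks strictly before point j
  before <- function(i, j) {
    for (l in seq_len(nlev)) {
      fi <- vals[i, l] <= tol[l]
      fj <- vals[j, l] <= tol[l]
      if (fi && !fj) return(TRUE)
      if (!fi && fj) return(FALSE)
      if (!fi && !fj) {
        if (vals[i, l] != vals[j, l]) return(vals[i, l] < vals[j, l])
        return(tie[i] < tie[j])
      }
      if (l == nlev) {
        if (vals[i, l] != vals[j, l]) return(vals[i, l] < vals[j, l])
        return(tie[i] < tie[j])
      }
    }
    tie[i] < tie[j]
  }
  ord <- seq_len(nrow(points))
  # insertion sort with the comparator
  for (k in seq_along(ord)[-1]) {
    x <- ord[k]
    pos <- k
    while (pos > 1 && before(x, ord[pos - 1])) {
      ord[pos] <- ord[pos - 1]
      pos <- pos - 1
    }
    ord[pos] <- x
  }
  ord
}
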