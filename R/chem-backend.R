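#' @title RDKit perception backend
#' @description
#' All chemical perception (sanitization, canonical SMILES, aromaticity,
#' conjugation, ring analysis, bridgehead/spiro counting, Morgan
#' fingerprints, substructure matching) is delegated to RDKit, which runs as
#' a persistent worker process speaking line-oriented JSON over stdin/stdout.
#' Degrees of aromaticity and conjugation are model-dependent quantities, so
#' the RDKit version in use is exposed via [chem_backend_info()] for run logs.
#' @name chem-backend
NULL

.chem <- new.env(parent = emptyenv())

chem_worker_path <- function() {
  path <- system.file("python", "chem_worker.py", package = "investga")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- file.path("inst", "python", "chem_worker.py")
  }
  if (!file.exists(path)) stop("chem_worker.py not found")
  path
}

chem_start <- function() {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) stop("no python interpreter on PATH (required for RDKit backend)")
  proc <- processx::process$new(
    python, c("-u", chem_worker_path()),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .chem$proc <- proc
  .chem$buf <- ""
  .chem$counter <- 0L
  info <- chem_request("ping")
  .chem$rdkit_version <- info$rdkit
  invisible(proc)
}

chem_proc <- function() {
  if (is.null(.chem$proc) || !.chem$proc$is_alive()) chem_start()
  .chem$proc
}

#' Backend information
#'
#' Returns the perception model in use (RDKit version). Recorded in campaign
#' logs because aromaticity and conjugation degrees depend on it.
#' @return list with element `rdkit`
#' @export
chem_backend_info <- function() {
  chem_proc()
  list(rdkit = .chem$rdkit_version)
}

#' Stop the perception worker
#' @return invisibly TRUE
#' @export
chem_stop <- function() {
  if (!is.null(.chem$proc) && .chem$proc$is_alive()) {
    try(.chem$proc$kill(), silent = TRUE)
  }
  .chem$proc <- NULL
  invisible(TRUE)
}

chem_request <- function(op, payload = list(), timeout_s = 300) {
  proc <- chem_proc()
  .chem$counter <- .chem$counter + 1L
  payload$op <- op
  payload$id <- .chem$counter
  line <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  proc$write_input(paste0(line, "\n"))
  deadline <- Sys.time() + timeout_s
  repeat {
    nl <- regexpr("\n", .chem$buf, fixed = TRUE)
    if (nl > 0) {
      line <- substr(.chem$buf, 1L, nl - 1L)
      .chem$buf <- substr(.chem$buf, nl + 1L, nchar(.chem$buf))
      resp <- jsonlite::fromJSON(line, simplifyVector = FALSE)
      if (!is.null(resp$error)) stop("chem worker error: ", resp$error)
      return(resp)
    }
    if (!proc$is_alive()) {
      err <- paste(proc$read_all_error_lines(), collapse = "\n")
      .chem$proc <- NULL
      stop("chem worker died: ", err)
    }
    if (Sys.time() > deadline) stop("chem worker timeout on op '", op, "'")
    proc$poll_io(200)
    .chem$buf <- paste0(.chem$buf, proc$read_output())
  }
}

#' Describe molecules
#'
#' Batch perception call: parses each SMILES and returns one row per input
#' with the quantities used by the pi-system filters, the azulene-likeness
#' test and the synthetic property oracle.
#'
#' @param smiles character vector of SMILES
#' @param forbidden character vector of SMARTS patterns; a match sets
#'   `forbidden_hit`
#' @return data.frame with columns `ok, input, canonical, heavy, total_atoms,
#'   charge, radicals, bridgehead, spiro, arom_deg, conj_deg, ring_min,
#'   ring_max, azulene_like, n_arom_n, h_donors, forbidden_hit`; unparsable
#'   inputs have `ok = FALSE` and NA elsewhere. `total_atoms` includes
#'   implicit hydrogens; `ring_min`/`ring_max` are NA for acyclic molecules.
#' @export
chem_describe <- function(smiles, forbidden = character()) {
  if (length(smiles) == 0) return(.empty_describe())
  out <- vector("list", length(smiles))
  # chunk large batches to keep individual JSON lines modest
  chunks <- split(seq_along(smiles), ceiling(seq_along(smiles) / 2000))
  for (idx in chunks) {
    resp <- chem_request("describe", list(smiles = as.list(smiles[idx]),
                                          forbidden = as.list(forbidden)))
    out[idx] <- resp$records
  }
  recs <- out
  get_num <- function(field) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  get_chr <- function(field) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  get_lgl <- function(field) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA else as.logical(v)
    }, logical(1))
  }
  data.frame(
    ok = get_lgl("ok"),
    input = smiles,
    canonical = get_chr("canonical"),
    heavy = get_num("heavy"),
    total_atoms = get_num("total_atoms"),
    charge = get_num("charge"),
    radicals = get_num("radicals"),
    bridgehead = get_num("bridgehead"),
    spiro = get_num("spiro"),
    arom_deg = get_num("arom_deg"),
    conj_deg = get_num("conj_deg"),
    ring_min = get_num("ring_min"),
    ring_max = get_num("ring_max"),
    azulene_like = get_lgl("azulene_like"),
    n_arom_n = get_num("n_arom_n"),
    h_donors = get_num("h_donors"),
    forbidden_hit = get_lgl("forbidden_hit"),
    stringsAsFactors = FALSE
  )
}

.empty_describe <- function() {
  data.frame(ok = logical(), input = character(), canonical = character(),
             heavy = numeric(), total_atoms = numeric(), charge = numeric(),
             radicals = numeric(), bridgehead = numeric(), spiro = numeric(),
             arom_deg = numeric(), conj_deg = numeric(), ring_min = numeric(),
             ring_max = numeric(), azulene_like = logical(),
             n_arom_n = numeric(), h_donors = numeric(),
             forbidden_hit = logical(), stringsAsFactors = FALSE)
}

#' Canonical SMILES
#' @param smiles character vector
#' @return character vector (NA where unparsable)
#' @export
chem_canonical <- function(smiles) {
  chem_describe(smiles)$canonical
}

#' Morgan fingerprints
#'
#' Binary Morgan (circular) fingerprints, folded to `nbits`.
#'
#' @param smiles character vector
#' @param radius Morgan radius (default 2)
#' @param nbits fingerprint length in bits (default 1024)
#' @return list of integer vectors of 1-based on-bit positions; NULL entries
#'   for unparsable SMILES
#' @export
chem_fingerprints <- function(smiles, radius = 2L, nbits = 1024L) {
  if (length(smiles) == 0) return(list())
  out <- vector("list", length(smiles))
  chunks <- split(seq_along(smiles), ceiling(seq_along(smiles) / 2000))
  for (idx in chunks) {
    resp <- chem_request("fingerprint", list(smiles = as.list(smiles[idx]),
                                             radius = radius, nbits = nbits))
    out[idx] <- lapply(resp$bits, function(b) {
      if (is.null(b)) NULL else as.integer(unlist(b)) + 1L
    })
  }
  out
}

chem_graphs <- function(smiles) {
  resp <- chem_request("graph", list(smiles = as.list(smiles)))
  lapply(resp$graphs, function(g) {
    if (is.null(g)) return(NULL)
    bonds <- if (length(g$bonds) == 0) {
      matrix(integer(), ncol = 3)
    } else {
      do.call(rbind, lapply(g$bonds, function(b) as.integer(unlist(b))))
    }
    list(atoms = as.character(unlist(g$atoms)), bonds = bonds)
  })
}

chem_build_core <- function(npos) {
  resp <- chem_request("core", list(npos = as.list(as.integer(npos))))
  list(smiles = resp$smiles, kekule_fallback = isTRUE(resp$kekule_fallback))
}

chem_attach <- function(npos, subs, positions) {
  if (length(subs) == 0) return(data.frame(smiles = character(), error = character()))
  resp <- chem_request("attach", list(npos = as.list(as.integer(npos)),
                                      subs = as.list(subs),
                                      positions = as.list(as.integer(positions))))
  data.frame(
    smiles = vapply(resp$attached, function(a)
      if (is.null(a$smiles)) NA_character_ else a$smiles, character(1)),
    error = vapply(resp$attached, function(a)
      if (is.null(a$error)) NA_character_ else a$error, character(1)),
    stringsAsFactors = FALSE
  )
}

chem_match <- function(smiles, smarts) {
  if (length(smiles) == 0) return(logical())
  resp <- chem_request("match", list(smiles = as.list(smiles), smarts = smarts))
  vapply(resp$matches, function(m) if (is.null(m)) NA else as.logical(m), logical(1))
}
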