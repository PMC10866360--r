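#' @title Robust molecular token strings
#' @description
#' A SELFIES-style robust string representation over a 16-token alphabet of
#' C/N/O/S atoms (with bond-order prefixes), branches and ring closures.
#' Decoding is a valence-constrained derivation, so *every* token sequence
#' containing at least one atom token decodes to a chemically valid molecule
#' -- the property that makes random string edits and string interpolation
#' viable genetic operators. Valence caps are C:4, N:3, O:2, S:2 and decoded
#' molecules are neutral closed-shell Kekule structures; aromaticity is
#' perceived downstream by the chemical toolkit.
#'
#' Branch and ring tokens consume the following token(s) as a base-16 digit
#' (the token's alphabet index): `[Branch1]`/`[Ring1]` read one digit,
#' `[Branch2]`/`[Ring2]` read two. `[nop]` is ignored (used as padding by
#' the interpolation operator). Tokens that cannot be applied in the current
#' derivation state are skipped, never an error.
#' @name robust-string
NULL

RTS_ALPHABET <- c("[C]", "[=C]", "[#C]", "[N]", "[=N]", "[#N]",
                  "[O]", "[=O]", "[S]", "[Branch1]", "[Branch2]",
                  "[Ring1]", "[=Ring1]", "[#Ring1]", "[Ring2]", "[nop]")

RTS_MAXVAL <- c(C = 4L, N = 3L, O = 2L, S = 2L)

.rts_atom_info <- local({
  tok <- c("[C]", "[=C]", "[#C]", "[N]", "[=N]", "[#N]", "[O]", "[=O]", "[S]")
  el  <- c("C", "C", "C", "N", "N", "N", "O", "O", "S")
  ord <- c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 1L)
  data.frame(token = tok, element = el, order = ord, stringsAsFactors = FALSE)
})

#' Token alphabet
#' @return character vector of the 16 tokens
#' @export
rts_alphabet <- function() RTS_ALPHABET

rts_index <- function(tokens) {
  idx <- match(tokens, RTS_ALPHABET)
  if (anyNA(idx)) stop("unknown token(s): ", paste(tokens[is.na(idx)], collapse = " "))
  idx - 1L
}

#' Decode a token sequence to a molecular graph
#'
#' @param tokens character vector of alphabet tokens
#' @return list with `atoms` (element symbols) and `bonds` (matrix i,j,order),
#'   or NULL when the derivation places no atom (e.g. all-[nop] strings)
#' @export
rts_decode <- function(tokens) {
  st <- new.env(parent = emptyenv())
  st$el <- character(0)
  st$rem <- integer(0)
  st$bonds <- list()
  walk <- function(toks, cur) {
    i <- 1L
    n <- length(toks)
    while (i <= n) {
      t <- toks[i]
      if (t == "[nop]") { i <- i + 1L; next }
      ai <- match(t, .rts_atom_info$token)
      if (!is.na(ai)) {
        el <- .rts_atom_info$element[ai]
        maxv <- RTS_MAXVAL[[el]]
        if (is.na(cur)) {
          st$el <- c(st$el, el)
          st$rem <- c(st$rem, maxv)
          cur <- length(st$el)
        } else {
          if (st$rem[cur] <= 0L) break  # derivation halts on exhausted valence
          o <- min(.rts_atom_info$order[ai], st$rem[cur], maxv)
          st$el <- c(st$el, el)
          new <- length(st$el)
          st$rem[cur] <- st$rem[cur] - o
          st$rem <- c(st$rem, maxv - o)
          st$bonds[[length(st$bonds) + 1L]] <- c(cur, new, o)
          cur <- new
        }
        i <- i + 1L
        next
      }
      if (t %in% c("[Branch1]", "[Branch2]")) {
        ndig <- if (t == "[Branch1]") 1L else 2L
        if (i + ndig > n) break
        digits <- rts_index(toks[(i + 1L):(i + ndig)])
        q <- sum(digits * 16L^rev(seq_along(digits) - 1L))
        len <- q + 1L
        i <- i + 1L + ndig
        if (!is.na(cur) && st$rem[cur] >= 2L && i <= n) {
          sub <- toks[i:min(n, i + len - 1L)]
          walk(sub, cur)
        }
        i <- i + len
        next
      }
      if (t %in% c("[Ring1]", "[=Ring1]", "[#Ring1]", "[Ring2]")) {
        ndig <- if (t == "[Ring2]") 2L else 1L
        if (i + ndig > n) break
        digits <- rts_index(toks[(i + 1L):(i + ndig)])
        q <- sum(digits * 16L^rev(seq_along(digits) - 1L))
        look <- q + 1L
        i <- i + 1L + ndig
        if (is.na(cur)) next
        target <- cur - look
        o <- switch(t, "[=Ring1]" = 2L, "[#Ring1]" = 3L, 1L)
        if (target >= 1L && target != cur) {
          dup <- any(vapply(st$bonds, function(b)
            (b[1] == cur && b[2] == target) || (b[1] == target && b[2] == cur),
            logical(1)))
          o <- min(o, st$rem[cur], st$rem[target])
          if (!dup && o >= 1L) {
            st$bonds[[length(st$bonds) + 1L]] <- c(target, cur, o)
            st$rem[cur] <- st$rem[cur] - o
            st$rem[target] <- st$rem[target] - o
          }
        }
        next
      }
      stop("unknown token: ", t)
    }
  }
  walk(tokens, NA_integer_)
  if (length(st$el) == 0) return(NULL)
  bonds <- if (length(st$bonds) == 0) matrix(integer(), ncol = 3) else
    do.call(rbind, st$bonds)
  list(atoms = st$el, bonds = bonds)
}

#' Write a molecular graph as Kekule SMILES
#'
#' Hydrogens are implicit: valences stay within the default valence of each
#' element, so the toolkit infers hydrogen counts on parsing.
#'
#' @param graph list with `atoms` and `bonds` as returned by [rts_decode()]
#' @return a SMILES string
#' @export
graph_to_smiles <- function(graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- length(atoms)
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  bsym <- c("", "=", "#")
  visited <- rep(FALSE, n)
  ring_labels <- vector("list", n)  # per atom: list of c(label, order)
  ring_n <- 0L
  # first pass: DFS to find tree edges and assign ring-closure labels
  tree_children <- vector("list", n)
  stack_parent <- rep(NA_integer_, n)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  dfs1 <- function(a, parent) {
    visited[a] <<- TRUE
    nb <- adj[[a]]
    if (!is.null(nb)) {
      ord <- order(nb[, 1])
      for (r in ord) {
        b <- nb[r, 1]; o <- nb[r, 2]
        key <- ekey(a, b)
        if (!is.null(edge_used[[key]])) next
        if (!visited[b]) {
          edge_used[[key]] <- "tree"
          tree_children[[a]] <<- rbind(tree_children[[a]], c(b, o))
          dfs1(b, a)
        } else {
          edge_used[[key]] <- "ring"
          ring_n <<- ring_n + 1L
          lab <- ring_n
          ring_labels[[a]] <<- c(ring_labels[[a]], list(c(lab, o)))
          ring_labels[[b]] <<- c(ring_labels[[b]], list(c(lab, o)))
        }
      }
    }
  }
  roots <- integer(0)
  for (a in seq_len(n)) {
    if (!visited[a]) { roots <- c(roots, a); dfs1(a, NA) }
  }
  lab_str <- function(lab) if (lab < 10) as.character(lab) else sprintf("%%%02d", lab)
  emit <- function(a, bond_in) {
    s <- paste0(bsym[bond_in], atoms[a])
    for (rl in ring_labels[[a]]) {
      s <- paste0(s, bsym[rl[2]], lab_str(rl[1]))
    }
    ch <- tree_children[[a]]
    if (!is.null(ch) && nrow(ch) > 0) {
      for (r in seq_len(nrow(ch))) {
        sub <- emit(ch[r, 1], ch[r, 2])
        if (r < nrow(ch)) s <- paste0(s, "(", sub, ")") else s <- paste0(s, sub)
      }
    }
    s
  }
  paste(vapply(roots, function(a) {
    # re-emit bond_in = 1 -> empty symbol for roots
    sub <- emit(a, 1L)
    sub
  }, character(1)), collapse = ".")
}

#' Decode tokens directly to SMILES
#' @param tokens character vector of alphabet tokens
#' @return SMILES string, or NA if the derivation places no atom
#' @export
rts_to_smiles <- function(tokens) {
  g <- rts_decode(tokens)
  if (is.null(g)) return(NA_character_)
  graph_to_smiles(g)
}

.rts_digit <- function(q, ndig) {
  stopifnot(q >= 0, q < 16^ndig)
  d <- integer(ndig)
  for (k in ndig:1) { d[k] <- q %% 16L; q <- q %/% 16L }
  RTS_ALPHABET[d + 1L]
}

.rts_atom_token <- function(element, order) {
  hit <- .rts_atom_info$token[.rts_atom_info$element == element &
                                .rts_atom_info$order == order]
  if (length(hit) != 1) {
    stop("cannot encode bond of order ", order, " to element ", element)
  }
  hit
}

#' Encode a molecular graph as a token sequence
#'
#' Inverse of [rts_decode()] up to canonicalization: the round trip
#' `rts_decode(rts_encode(g))` reproduces the same molecule. Supported
#' elements: C, N, O, S; neutral, closed-shell, Kekule bond orders.
#'
#' @param graph list with `atoms` and `bonds`
#' @return character vector of tokens
#' @export
rts_encode <- function(graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- length(atoms)
  bad <- setdiff(unique(atoms), names(RTS_MAXVAL))
  if (length(bad) > 0) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  visited <- rep(FALSE, n)
  place <- rep(NA_integer_, n)   # placement order in the decoded derivation
  counter <- 0L
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  encode_atom <- function(a, bond_in) {
    visited[a] <<- TRUE
    counter <<- counter + 1L
    place[a] <<- counter
    toks <- .rts_atom_token(atoms[a], bond_in)
    ring_toks <- character(0)
    subtrees <- list()
    nb <- adj[[a]]
    if (!is.null(nb)) {
      # neighbors processed in index order; recursion happens immediately so
      # an edge is a ring closure iff its far atom was placed earlier (in
      # token order), matching the decoder's placement-order lookback
      for (r in order(nb[, 1])) {
        b <- nb[r, 1]; o <- nb[r, 2]
        key <- ekey(a, b)
        if (!is.null(edge_used[[key]])) next
        edge_used[[key]] <- TRUE
        if (visited[b]) {
          look <- place[a] - place[b]
          rt <- switch(as.character(o), "1" = "[Ring1]", "2" = "[=Ring1]",
                       "3" = "[#Ring1]", stop("bad ring order"))
          if (look <= 16L) {
            ring_toks <- c(ring_toks, rt, .rts_digit(look - 1L, 1L))
          } else {
            if (o != 1L) stop("long ring closure with order > 1 not encodable")
            ring_toks <- c(ring_toks, "[Ring2]", .rts_digit(look - 1L, 2L))
          }
        } else {
          subtrees[[length(subtrees) + 1L]] <- encode_atom(b, o)
        }
      }
    }
    toks <- c(toks, ring_toks)
    if (length(subtrees) > 0) {
      for (ci in seq_along(subtrees)) {
        sub <- subtrees[[ci]]
        if (ci < length(subtrees)) {
          len <- length(sub)
          if (len <= 16L) {
            toks <- c(toks, "[Branch1]", .rts_digit(len - 1L, 1L), sub)
          } else if (len <= 256L) {
            toks <- c(toks, "[Branch2]", .rts_digit(len - 1L, 2L), sub)
          } else {
            stop("branch too long to encode")
          }
        } else {
          toks <- c(toks, sub)
        }
      }
    }
    toks
  }
  out <- character(0)
  for (a in seq_len(n)) {
    if (!visited[a]) {
      if (length(out) > 0) stop("disconnected graphs are not encodable")
      out <- encode_atom(a, 1L)
    }
  }
  out
}

#' Build a genome from a SMILES string
#'
#' Uses the toolkit to parse and kekulize, then encodes the graph. The
#' genome's canonical form is the toolkit's canonical SMILES.
#'
#' @param smiles a SMILES string
#' @param operator provenance tag
#' @param parent_ids character vector of parent canonical forms
#' @return a `candidate_genome` (list with `tokens`, `canonical`,
#'   `parent_ids`, `operator`)
#' @export
smiles_to_genome <- function(smiles, operator = "seed", parent_ids = character()) {
  g <- chem_graphs(smiles)[[1]]
  if (is.null(g)) stop("cannot derive a neutral Kekule graph from: ", smiles)
  tokens <- rts_encode(g)
  canonical <- chem_canonical(smiles)
  new_genome(tokens, canonical, operator = operator, parent_ids = parent_ids)
}

#' Construct a candidate genome
#' @param tokens token vector
#' @param canonical canonical form (computed from tokens when NULL)
#' @param operator provenance tag (seed, seed_mutation, mutation,
#'   interpolation, substituent_attachment)
#' @param parent_ids parent canonical forms
#' @return a `candidate_genome`
#' @export
new_genome <- function(tokens, canonical = NULL, operator = "seed",
                       parent_ids = character()) {
  if (is.null(canonical)) {
    smi <- rts_to_smiles(tokens)
    if (is.na(smi)) stop("token sequence decodes to no molecule")
    canonical <- chem_canonical(smi)
  }
  structure(list(tokens = tokens, canonical = canonical,
                 operator = operator, parent_ids = parent_ids),
            class = "candidate_genome")
}

#' @export
print.candidate_genome <- function(x, ...) {
  cat("<candidate_genome> ", x$canonical, "\n  ",
      length(x$tokens), " tokens, operator: ", x$operator, "\n", sep = "")
  invisible(x)
}
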