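# Internal molecular-graph model.
#
# Molecules are parsed from OpenBabel *canonical* SMILES into a light graph
# structure (atoms, bonds, adjacency, smallest-set-of-smallest-rings). All
# structural queries and edits in the package operate on this graph; atom ids
# are 1-based positions in the canonical SMILES atom order, so they are stable
# across serializations of the same molecule.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# data.frame constructor without the validation overhead (hot path)
fast_df <- function(a1, a2, order) {
  structure(list(a1 = a1, a2 = a2, order = order),
            class = "data.frame", row.names = .set_row_names(length(a1)))
}

# default valences used for implicit-H assignment (neutral organic subset)
DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

new_mol <- function(elem, arom, charge, iso, nH, bonds, smiles = NA_character_) {
  n <- length(elem)
  if (nrow(bonds)) {
    m <- nrow(bonds)
    ends <- factor(c(bonds$a1, bonds$a2), levels = seq_len(n))
    adj <- split(c(bonds$a2, bonds$a1), ends)
    badj <- split(rep(seq_len(m), 2L), ends)
    names(adj) <- NULL; names(badj) <- NULL
  } else {
    adj <- rep(list(integer(0)), n)
    badj <- rep(list(integer(0)), n)
  }
  structure(
    list(
      n = n, elem = elem, arom = arom, charge = charge, iso = iso, nH = nH,
      bonds = bonds, adj = adj, badj = badj, smiles = smiles, rings = NULL
    ),
    class = "borysite_mol"
  )
}

#' @export
print.borysite_mol <- function(x, ...) {
  cat("<mol> ", x$smiles, "  (", x$n, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

smiles_tokenize_error <- function(smiles, where) {
  stop(sprintf("cannot parse SMILES '%s' (near position %d)", smiles, where),
       call. = FALSE)
}

# Parse a (canonical) SMILES string into the internal graph. Supports the
# dialect OpenBabel emits: organic subset + bracket atoms, ring closures
# (incl. %nn), branches, bond symbols -=#:$/\ and dots. Stereo marks are
# accepted and discarded (sites are stereochemistry-agnostic).
parse_smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  np <- length(chars)
  if (np == 0L) smiles_tokenize_error(smiles, 1L)

  elem <- character(0); arom <- logical(0); charge <- integer(0)
  iso <- integer(0); nH <- integer(0); nH_explicit <- logical(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- numeric(0)

  prev <- NA_integer_          # previous atom for next bond
  stack <- integer(0)          # branch stack
  pending_bond <- NA_real_     # NA = unspecified
  ring_open <- list()          # digit -> list(atom, bond)

  add_atom <- function(e, ar, ch, is, h, h_exp) {
    elem <<- c(elem, e); arom <<- c(arom, ar); charge <<- c(charge, ch)
    iso <<- c(iso, is); nH <<- c(nH, h); nH_explicit <<- c(nH_explicit, h_exp)
    length(elem)
  }
  add_bond <- function(a, b, ord) {
    b_a1 <<- c(b_a1, a); b_a2 <<- c(b_a2, b); b_ord <<- c(b_ord, ord)
  }
  close_atom <- function(id) {
    if (!is.na(prev)) {
      add_bond(prev, id, if (is.na(pending_bond)) 0 else pending_bond)
    }
    prev <<- id
    pending_bond <<- NA_real_
  }
  handle_ring <- function(digit, i) {
    key <- as.character(digit)
    if (is.na(prev)) smiles_tokenize_error(smiles, i)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond)
    } else {
      op <- ring_open[[key]]
      ord <- if (!is.na(pending_bond)) pending_bond
             else if (!is.na(op$bond)) op$bond else 0
      add_bond(op$atom, prev, ord)
      ring_open[[key]] <<- NULL
    }
    pending_bond <<- NA_real_
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) smiles_tokenize_error(smiles, i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2}|@TH[12]?)?(H[0-9]*)?(\\+{1,}[0-9]*|-{1,}[0-9]*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L || m[1] != body) smiles_tokenize_error(smiles, i)
      isot <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      sym <- m[3]
      ar <- sym == tolower(sym) && sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      e <- if (ar) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      hh <- 0L
      if (nzchar(m[5])) {
        hh <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      }
      chg <- 0L
      if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[6])
        chg <- if (nzchar(digits)) sgn * as.integer(digits)
               else sgn * nchar(m[6])
      }
      id <- add_atom(e, ar, chg, isot, hh, TRUE)
      close_atom(id)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < np && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      id <- add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, 0L, NA_integer_, FALSE)
      close_atom(id)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      id <- add_atom(ch, FALSE, 0L, 0L, NA_integer_, FALSE)
      close_atom(id)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      id <- add_atom(toupper(ch), TRUE, 0L, 0L, NA_integer_, FALSE)
      close_atom(id)
      i <- i + 1L
    } else if (ch == "-") { pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") { pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") { pending_bond <- 3; i <- i + 1L
    } else if (ch == "$") { pending_bond <- 4; i <- i + 1L
    } else if (ch == ":") { pending_bond <- 1.5; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pending_bond <- 1; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_tokenize_error(smiles, i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) smiles_tokenize_error(smiles, i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      handle_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > np) smiles_tokenize_error(smiles, i)
      handle_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1L
    } else {
      smiles_tokenize_error(smiles, i)
    }
  }
  if (length(ring_open)) {
    stop(sprintf("cannot parse SMILES '%s': unmatched ring bond", smiles),
         call. = FALSE)
  }
  if (length(stack)) {
    stop(sprintf("cannot parse SMILES '%s': unclosed branch", smiles),
         call. = FALSE)
  }

  n <- length(elem)
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord)

  # Resolve unspecified bond orders: between two aromatic atoms an
  # unspecified bond is aromatic when it lies in a cycle (ring bond),
  # single otherwise (e.g. the biaryl bond of biphenyl).
  unspec <- which(bonds$order == 0)
  if (length(unspec)) {
    for (k in unspec) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      if (arom[a] && arom[b] && bond_in_cycle(n, bonds, k)) {
        bonds$order[k] <- 1.5
      } else {
        bonds$order[k] <- 1
      }
    }
  }

  # implicit hydrogens for organic-subset atoms
  for (a in which(!nH_explicit)) {
    conn <- sum(ifelse(bonds$order[b_a1 == a | b_a2 == a] == 1.5, 1,
                       bonds$order[b_a1 == a | b_a2 == a]))
    vals <- DEFAULT_VALENCES[[elem[a]]]
    if (is.null(vals)) {
      nH[a] <- 0L
    } else if (arom[a]) {
      nH[a] <- max(0L, as.integer(min(vals) - conn - 1L))
    } else {
      fit <- vals[vals >= conn]
      nH[a] <- if (length(fit)) as.integer(fit[1] - conn) else 0L
    }
  }

  mol <- new_mol(elem, arom, charge, iso, nH, bonds, smiles)
  mol$rings <- sssr(mol)
  mol
}

# TRUE if bond k is part of some cycle (i.e. its endpoints stay connected
# when the bond is removed).
bond_in_cycle <- function(n, bonds, k) {
  src <- bonds$a1[k]; dst <- bonds$a2[k]
  adj <- rep(list(integer(0)), n)
  for (j in seq_len(nrow(bonds))) {
    if (j == k) next
    adj[[bonds$a1[j]]] <- c(adj[[bonds$a1[j]]], bonds$a2[j])
    adj[[bonds$a2[j]]] <- c(adj[[bonds$a2[j]]], bonds$a1[j])
  }
  seen <- logical(n); seen[src] <- TRUE; queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (w == dst) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  FALSE
}

# Smallest set of smallest rings: candidate cycles are, for each ring bond,
# the shortest cycle through it; candidates are added smallest-first while
# linearly independent over GF(2) in edge space, until the cycle-space
# dimension (m - n + components) is reached.
sssr <- function(mol) {
  m <- nrow(mol$bonds)
  if (m == 0L) return(list())
  comp <- mol_components(mol)
  dim_cycle <- m - mol$n + length(unique(comp))
  if (dim_cycle <= 0L) return(list())

  candidates <- list()
  for (k in seq_len(m)) {
    path <- shortest_path_avoiding_bond(mol, k)
    if (!is.null(path)) candidates[[length(candidates) + 1L]] <- path
  }
  if (!length(candidates)) return(list())
  sizes <- vapply(candidates, length, integer(1))
  keys <- vapply(candidates, function(r) paste(sort(r), collapse = ","),
                 character(1))
  ord <- order(sizes, keys)
  candidates <- candidates[ord]
  keys <- keys[ord]
  candidates <- candidates[!duplicated(keys)]

  basis <- matrix(0L, nrow = 0, ncol = m)
  rings <- list()
  bond_key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                    pmax(mol$bonds$a1, mol$bonds$a2))
  for (ring in candidates) {
    if (length(rings) == dim_cycle) break
    vec <- integer(m)
    len <- length(ring)
    for (i in seq_len(len)) {
      a <- ring[i]; b <- ring[if (i == len) 1L else i + 1L]
      vec[match(paste(min(a, b), max(a, b)), bond_key)] <- 1L
    }
    # Gaussian elimination over GF(2)
    v <- vec
    indep <- TRUE
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1]
        if (v[piv] == 1L) v <- (v + basis[r, ]) %% 2L
      }
    }
    if (!any(v == 1L)) indep <- FALSE
    if (indep) {
      basis <- rbind(basis, v)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

mol_components <- function(mol) {
  comp <- integer(mol$n)
  cur <- 0L
  for (s in seq_len(mol$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in mol$adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# Shortest path between the endpoints of bond k avoiding the bond itself;
# returned as the atom cycle (path + bond) or NULL if the bond is a bridge.
shortest_path_avoiding_bond <- function(mol, k) {
  src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
  prev <- integer(mol$n)
  seen <- logical(mol$n); seen[src] <- TRUE
  queue <- src
  found <- FALSE
  while (length(queue) && !found) {
    v <- queue[1]; queue <- queue[-1]
    nb <- mol$adj[[v]]; bb <- mol$badj[[v]]
    for (j in seq_along(nb)) {
      if (bb[j] == k) next
      w <- nb[j]
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == dst) { found <- TRUE; break }
        queue <- c(queue, w)
      }
    }
  }
  if (!found) return(NULL)
  path <- dst
  while (path[1] != src) path <- c(prev[path[1]], path)
  path
}

# rings (from SSSR) that are fully aromatic
aromatic_rings <- function(mol) {
  Filter(function(r) all(mol$arom[r]), mol$rings)
}

bond_between <- function(mol, a, b) {
  hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
               (mol$bonds$a1 == b & mol$bonds$a2 == a))
  if (length(hit)) hit[1] else NA_integer_
}
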