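# Differential reaction fingerprints, built from scratch: circular
# substructure shingles of every molecule on each side of a reaction, the
# symmetric set difference between the two sides, hashed onto a fixed-length
# bit vector with a platform-independent 32-bit string hash (FNV-1a).

#' FNV-1a 32-bit string hash
#'
#' Deterministic, platform-independent hash used to map shingles to
#' fingerprint bits (offset basis 2166136261, prime 16777619). Implemented
#' in vectorized integer-safe arithmetic so fingerprints are bit-exact
#' across machines and processes.
#'
#' @param strings character vector.
#' @return numeric vector of hash values in [0, 2^32).
#' @export
fnv1a32 <- function(strings) {
  stopifnot(is.character(strings))
  ns <- length(strings)
  if (!ns) return(numeric(0))
  bytes <- lapply(strings, utf8ToInt)
  lens <- lengths(bytes)
  maxlen <- max(lens, 0L)
  h <- rep(2166136261, ns)
  two32 <- 4294967296
  for (pos in seq_len(maxlen)) {
    active <- which(lens >= pos)
    b <- vapply(bytes[active], `[[`, numeric(1), pos)
    ha <- h[active]
    lo <- ha %% 256
    ha <- ha - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply by the FNV prime 2^24 + 2^8 + 0x93 modulo 2^32, split so every
    # intermediate stays below 2^53
    ha <- ((ha * 147) %% two32 +
           ((ha %% 16777216) * 256) %% two32 +
           ((ha %% 256) * 16777216)) %% two32
    h[active] <- ha
  }
  h
}

# BFS distances from one atom (molecules are small; plain R is fine)
atom_distances <- function(mol, from) {
  d <- rep(NA_integer_, mol$n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in mol$adj[[v]]) {
      if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
    }
  }
  d
}

# Canonical ranks of a (sub)molecule's atoms by iterated Weisfeiler-Lehman
# refinement with content-ordered relabeling; used to write fragment strings
# in an input-order-independent way.
wl_ranks <- function(mol) {
  lab <- paste(mol$elem, mol$arom, mol$charge, mol$iso)
  lab <- match(lab, sort(unique(lab)))
  n <- mol$n
  if (n <= 1L || !nrow(mol$bonds)) return(lab)
  # half-edge representation: one vectorized pass per refinement round
  he_a <- c(mol$bonds$a1, mol$bonds$a2)
  he_n <- c(mol$bonds$a2, mol$bonds$a1)
  he_o <- rep(mol$bonds$order, 2L)
  he_oc <- as.character(he_o * 2)
  fa <- factor(he_a, levels = seq_len(n))
  key_base <- (he_a * 8L + match(he_o, c(1, 1.5, 2, 3, 4))) * (n + 1L)
  for (iter in seq_len(n)) {
    o <- order(key_base + lab[he_n])
    pieces <- paste(he_oc[o], lab[he_n[o]])
    nbrs <- vapply(split(pieces, fa[o]), paste, character(1), collapse = "|")
    nxt <- paste(lab, nbrs)
    new_lab <- match(nxt, sort(unique(nxt)))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

frag_string <- function(mol, atoms) {
  sub <- induced_submol(mol, atoms)
  write_smiles(sub, rank = wl_ranks(sub), style = "shingle")
}

.shingle_cache <- new.env(parent = emptyenv())

#' Circular-substructure shingles of a molecule
#'
#' For every atom and every radius 0..`radius`, the canonical fragment
#' string of the atom's circular environment (all atoms within that graph
#' distance), plus the canonical string of every smallest ring. Duplicates
#' collapse: the result is a set.
#'
#' @param smiles a single SMILES string.
#' @param radius maximum environment radius in bonds (default 3).
#' @return character vector of unique shingle strings.
#' @examples
#' extract_shingles("C", radius = 0)    # "C"
#' @export
extract_shingles <- function(smiles, radius = 3) {
  stopifnot(radius >= 0)
  can <- canonicalize1(smiles)
  key <- paste0(radius, "|", can)
  hit <- .shingle_cache[[key]]
  if (!is.null(hit)) return(hit)
  mol <- get_mol(can)
  shingles <- character(0)
  seen_balls <- new.env(parent = emptyenv())
  add_ball <- function(ball) {
    bkey <- paste(ball, collapse = ",")
    if (is.null(seen_balls[[bkey]])) {
      seen_balls[[bkey]] <- TRUE
      shingles <<- c(shingles, frag_string(mol, ball))
    }
  }
  for (a in seq_len(mol$n)) {
    d <- atom_distances(mol, a)
    prev_size <- -1L
    for (r in 0:radius) {
      ball <- which(!is.na(d) & d <= r)
      if (length(ball) == prev_size) break   # environment stopped growing
      prev_size <- length(ball)
      add_ball(ball)
    }
  }
  for (ring in mol$rings) {
    add_ball(sort(ring))
  }
  out <- unique(shingles)
  .shingle_cache[[key]] <- out
  out
}

side_shingles <- function(field, radius) {
  if (!nzchar(field)) return(character(0))
  mols <- strsplit(field, ".", fixed = TRUE)[[1]]
  unique(unlist(lapply(mols, extract_shingles, radius = radius)))
}

#' Differential reaction fingerprint
#'
#' The symmetric set difference between the shingle sets of the reactant
#' side and the product side of a reaction, hashed to a fixed-length binary
#' vector: each surviving shingle sets bit `fnv1a32(shingle) mod n_bits`.
#' Agents (the middle reaction-SMILES field) are ignored, and the
#' fingerprint is invariant to reaction direction.
#'
#' @param rxn_smiles character vector of reaction SMILES
#'   (`reactants>agents>products`).
#' @param n_bits fingerprint length (default 256).
#' @param radius shingle radius (default 3).
#' @return a 0/1 integer matrix with `length(rxn_smiles)` rows and `n_bits`
#'   columns.
#' @examples
#' sum(drfp("CC>>CC"))   # identity reaction: empty difference, all zeros
#' @export
drfp <- function(rxn_smiles, n_bits = 256, radius = 3) {
  stopifnot(is.character(rxn_smiles), n_bits >= 1)
  out <- matrix(0L, nrow = length(rxn_smiles), ncol = n_bits)
  for (i in seq_along(rxn_smiles)) {
    rxn <- rxn_smiles[i]
    nsep <- lengths(regmatches(rxn, gregexpr(">", rxn, fixed = TRUE)))
    if (nsep != 2L) {
      stop(sprintf("reaction SMILES '%s' must contain exactly two '>' separators",
                   rxn), call. = FALSE)
    }
    parts <- strsplit(rxn, ">", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 3L - length(parts)))[1:3]
    left <- side_shingles(parts[1], radius)
    right <- side_shingles(parts[3], radius)
    diff <- c(setdiff(left, right), setdiff(right, left))
    if (length(diff)) {
      bits <- unique(fnv1a32(diff) %% n_bits) + 1
      out[i, bits] <- 1L
    }
  }
  out
}

#' Featurize site reactions into a fingerprint matrix
#'
#' @param sites tibble with a `site_reaction` column (from
#'   [enumerate_sites()] / [build_site_dataset()]), or a character vector of
#'   reaction SMILES.
#' @param n_bits,radius fingerprint parameters, see [drfp()].
#' @return 0/1 integer matrix, rows aligned with the input order.
#' @export
featurize_sites <- function(sites, n_bits = 256, radius = 3) {
  rxns <- if (is.character(sites)) sites else sites$site_reaction
  drfp(rxns, n_bits = n_bits, radius = radius)
}
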