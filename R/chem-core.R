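#' Canonicalize SMILES strings
#'
#' Converts SMILES to their unique canonical form via OpenBabel. The result
#' is idempotent: canonicalizing a canonical SMILES returns it unchanged.
#' All structural reasoning in the package (site identity, product matching,
#' deduplication) happens on these canonical strings, with atom ids defined
#' as 1-based positions in the canonical SMILES atom order.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize("C1=CC=CC=C1")
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, canonicalize1, character(1), USE.NAMES = FALSE)
}

.canon_cache <- new.env(parent = emptyenv())
.mol_cache <- new.env(parent = emptyenv())

canonicalize1 <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    stop("cannot canonicalize an empty SMILES string", call. = FALSE)
  }
  hit <- .canon_cache[[s]]
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = s),
    error = function(e) ""
  )
  out <- sub("[ \t\r\n].*$", "", out)
  if (!nzchar(out)) {
    stop(sprintf("cannot parse SMILES '%s'", s), call. = FALSE)
  }
  .canon_cache[[s]] <- out
  .canon_cache[[out]] <- out
  out
}

# Parsed-molecule accessor with memoization; always operates on the
# canonical form so atom ids are serialization-independent.
get_mol <- function(smiles) {
  can <- canonicalize1(smiles)
  hit <- .mol_cache[[can]]
  if (!is.null(hit)) return(hit)
  mol <- parse_smiles_graph(can)
  .mol_cache[[can]] <- mol
  mol
}

#' Summarize molecules
#'
#' @param smiles character vector of SMILES.
#' @return a tibble with columns `smiles` (canonical), `atom_count` (heavy
#'   atoms) and `aromatic_ring_count`.
#' @export
molecule_info <- function(smiles) {
  tibble::tibble(
    smiles = canonicalize(smiles),
    atom_count = vapply(smiles, function(s) get_mol(s)$n, integer(1),
                        USE.NAMES = FALSE),
    aromatic_ring_count = count_aromatic_rings(smiles)
  )
}

#' Count aromatic rings
#'
#' Number of rings in the smallest set of smallest rings whose atoms are all
#' aromatic. Used, e.g., to stratify substrates into single-ring and
#' multi-ring subsets.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector.
#' @examples
#' count_aromatic_rings(c("c1ccccc1", "c1ccc2ccccc2c1"))
#' @export
count_aromatic_rings <- function(smiles) {
  vapply(smiles, function(s) length(aromatic_rings(get_mol(s))), integer(1),
         USE.NAMES = FALSE)
}

#' Test whether an atom sits on a heterocyclic aromatic ring
#'
#' TRUE when at least one smallest aromatic ring containing the atom has a
#' non-carbon ring member. Used to assign reactions to the heterocycle /
#' carbocycle subsets by their reactive site.
#'
#' @param smiles a single SMILES string.
#' @param atom_id 1-based atom index into the canonical atom ordering.
#' @return logical scalar.
#' @export
ring_is_heterocyclic <- function(smiles, atom_id) {
  mol <- get_mol(smiles)
  stopifnot(length(atom_id) == 1L, atom_id >= 1L, atom_id <= mol$n)
  rings <- aromatic_rings(mol)
  mine <- Filter(function(r) atom_id %in% r, rings)
  if (!length(mine)) {
    stop(sprintf("atom %d of '%s' is not part of any aromatic ring",
                 atom_id, mol$smiles), call. = FALSE)
  }
  any(vapply(mine, function(r) any(mol$elem[r] != "C"), logical(1)))
}

#' Graph-symmetry classes of a molecule's atoms
#'
#' Partitions atoms into orbits of the molecular graph's automorphism group
#' (computed exactly with BLISS via igraph, on a graph whose vertices are
#' colored by element, aromaticity, charge, isotope and hydrogen count and
#' whose bonds are typed). Substitution at any two atoms of the same class
#' yields the same product, so enumeration works per class.
#'
#' @param smiles a single SMILES string.
#' @return integer vector of class labels (contiguous from 0) indexed by
#'   canonical atom id.
#' @examples
#' symmetry_classes("c1ccccc1")      # all carbons equivalent
#' symmetry_classes("c1cccnc1")      # pyridine: 2/6, 3/5, 4 + N
#' @export
symmetry_classes <- function(smiles) {
  mol <- get_mol(smiles)
  classes <- atom_orbits(mol)
  relabel_classes(classes)
}

relabel_classes <- function(classes) {
  first_seen <- unique(classes)
  match(classes, first_seen) - 1L
}

# Automorphism orbits of the heavy-atom graph with atom and bond colors.
# Bond types are encoded by subdividing each bond with a colored vertex,
# which reduces edge-colored to vertex-colored automorphism.
atom_orbits <- function(mol) {
  n <- mol$n
  if (n <= 1L) return(rep(1L, n))
  atom_key <- paste(mol$elem, mol$arom, mol$charge, mol$iso, mol$nH)
  atom_col <- match(atom_key, unique(atom_key))
  m <- nrow(mol$bonds)
  if (m == 0L) {
    return(match(atom_col, unique(atom_col)))
  }
  bond_col <- max(atom_col) + match(mol$bonds$order, unique(mol$bonds$order))
  edges <- integer(0)
  for (k in seq_len(m)) {
    bv <- n + k
    edges <- c(edges, mol$bonds$a1[k], bv, bv, mol$bonds$a2[k])
  }
  g <- igraph::make_graph(edges, n = n + m, directed = FALSE)
  gens <- igraph::automorphism_group(g, colors = c(atom_col, bond_col))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (perm in gens) {
    p <- as.integer(perm)
    for (i in seq_len(n)) {
      ri <- find(i); rj <- find(p[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Parse reaction SMILES into a tidy table
#'
#' Splits `reactants>agents>products` strings, canonicalizes every component
#' and picks the borylation substrate: the reactant-field molecule with the
#' most heavy atoms after excluding boron-containing reagents (falling back
#' to the largest reactant when all contain boron).
#'
#' @param rxn_smiles character vector of reaction SMILES.
#' @param yield_percent optional numeric vector of percent yields in [0, 100].
#' @param id optional character vector of provenance ids.
#' @return a tibble with columns `id`, `rxn_smiles`, `substrate`,
#'   `reactants`, `agents`, `products` (the last three are list-columns of
#'   canonical SMILES) and `yield_percent`.
#' @export
parse_reactions <- function(rxn_smiles, yield_percent = NULL, id = NULL) {
  stopifnot(is.character(rxn_smiles))
  nr <- length(rxn_smiles)
  if (is.null(yield_percent)) yield_percent <- rep(NA_real_, nr)
  if (is.null(id)) id <- paste0("rxn", seq_len(nr))
  stopifnot(length(yield_percent) == nr, length(id) == nr)
  bad_yield <- !is.na(yield_percent) & (yield_percent < 0 | yield_percent > 100)
  if (any(bad_yield)) {
    stop("yield_percent must lie in [0, 100]", call. = FALSE)
  }
  parsed <- lapply(rxn_smiles, parse_reaction1)
  tibble::tibble(
    id = as.character(id),
    rxn_smiles = rxn_smiles,
    substrate = vapply(parsed, `[[`, character(1), "substrate"),
    reactants = lapply(parsed, `[[`, "reactants"),
    agents = lapply(parsed, `[[`, "agents"),
    products = lapply(parsed, `[[`, "products"),
    yield_percent = as.numeric(yield_percent)
  )
}

parse_reaction1 <- function(rxn) {
  parts <- strsplit(rxn, ">", fixed = TRUE)[[1]]
  nsep <- lengths(regmatches(rxn, gregexpr(">", rxn, fixed = TRUE)))
  if (nsep != 2L) {
    stop(sprintf("reaction SMILES '%s' must contain exactly two '>' separators",
                 rxn), call. = FALSE)
  }
  parts <- c(parts, rep("", 3L - length(parts)))[1:3]
  split_field <- function(x) {
    if (!nzchar(x)) return(character(0))
    canonicalize(strsplit(x, ".", fixed = TRUE)[[1]])
  }
  reactants <- split_field(parts[1])
  agents <- split_field(parts[2])
  products <- split_field(parts[3])
  if (!length(reactants) || !length(products)) {
    stop(sprintf("reaction SMILES '%s' needs at least one reactant and one product",
                 rxn), call. = FALSE)
  }
  list(
    reactants = reactants, agents = agents, products = products,
    substrate = pick_substrate(reactants)
  )
}

pick_substrate <- function(reactants) {
  has_boron <- vapply(reactants, function(s) any(get_mol(s)$elem == "B"),
                      logical(1))
  pool <- if (all(has_boron)) reactants else reactants[!has_boron]
  sizes <- vapply(pool, function(s) get_mol(s)$n, integer(1))
  pool[which.max(sizes)]
}

contains_element <- function(smiles, element) {
  any(get_mol(smiles)$elem == element)
}
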