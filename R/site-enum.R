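# Candidate-site enumeration: one substrate -> its ensemble of hypothetical
# monoborylation reactions, one per symmetry-distinct C-H position.

BPIN_SMILES <- "B1OC(C)(C)C(C)(C)O1"

# Splice a fragment (parsed from frag_smiles) onto `site`: both the site atom
# and the fragment attachment atom give up one hydrogen for the new bond.
glue_fragment <- function(mol, site, frag_smiles, frag_attach = 1L) {
  frag <- parse_smiles_graph(frag_smiles)
  if (mol$nH[site] < 1L) {
    stop(sprintf("atom %d of '%s' carries no hydrogen", site, mol$smiles),
         call. = FALSE)
  }
  if (frag$nH[frag_attach] < 1L) {
    stop("fragment attachment atom carries no hydrogen", call. = FALSE)
  }
  off <- mol$n
  elem <- c(mol$elem, frag$elem)
  arom <- c(mol$arom, frag$arom)
  charge <- c(mol$charge, frag$charge)
  iso <- c(mol$iso, frag$iso)
  nH <- c(mol$nH, frag$nH)
  nH[site] <- nH[site] - 1L
  nH[off + frag_attach] <- nH[off + frag_attach] - 1L
  bonds <- rbind(
    mol$bonds,
    data.frame(a1 = frag$bonds$a1 + off, a2 = frag$bonds$a2 + off,
               order = frag$bonds$order),
    data.frame(a1 = site, a2 = off + frag_attach, order = 1)
  )
  new_mol(elem, arom, charge, iso, nH, bonds)
}

#' Attach a pinacol boronate group at a C-H site
#'
#' Replaces one hydrogen on the given carbon by Bpin
#' (4,4,5,5-tetramethyl-1,3,2-dioxaborolan-2-yl) and returns the canonical
#' SMILES of the monoborylation product.
#'
#' @param smiles substrate SMILES (a single string).
#' @param site_atom 1-based atom index into the canonical atom ordering;
#'   must be a carbon bearing at least one hydrogen.
#' @return canonical SMILES of the site product.
#' @examples
#' attach_boron("c1ccccc1", 1)
#' @export
attach_boron <- function(smiles, site_atom) {
  mol <- get_mol(smiles)
  stopifnot(length(site_atom) == 1L, site_atom >= 1L, site_atom <= mol$n)
  if (mol$elem[site_atom] != "C") {
    stop(sprintf("atom %d of '%s' is not a carbon", site_atom, mol$smiles),
         call. = FALSE)
  }
  product <- glue_fragment(mol, site_atom, BPIN_SMILES, frag_attach = 1L)
  canonicalize1(write_smiles(product))
}

#' Enumerate candidate monoborylation sites
#'
#' Generates the ensemble of hypothetical site reactions for each substrate:
#' one `substrate>>site_product` reaction per symmetry class of eligible
#' carbons. In `aromatic_CH` mode eligible carbons are aromatic C-H
#' positions; `nonquaternary_C` mode admits any carbon with a hydrogen.
#'
#' @param smiles character vector of substrate SMILES.
#' @param mode `"aromatic_CH"` (default) or `"nonquaternary_C"`.
#' @param collapse_symmetry collapse symmetry-equivalent positions to one
#'   site per unique product (default TRUE). When FALSE every raw atom
#'   position becomes a row (its class is still reported).
#' @return a tibble with columns `substrate` (canonical SMILES), `site_atom`
#'   (class representative: lowest canonical atom id), `symmetry_class`,
#'   `n_equivalent`, `site_product` and `site_reaction`. Substrates with no
#'   eligible carbon contribute no rows.
#' @examples
#' enumerate_sites("c1cccnc1")   # pyridine: three distinct sites
#' @export
enumerate_sites <- function(smiles, mode = c("aromatic_CH", "nonquaternary_C"),
                            collapse_symmetry = TRUE) {
  mode <- match.arg(mode)
  out <- lapply(unique(canonicalize(smiles)), enumerate_sites1,
                mode = mode, collapse_symmetry = collapse_symmetry)
  dplyr::bind_rows(out)
}

enumerate_sites1 <- function(substrate, mode, collapse_symmetry) {
  mol <- get_mol(substrate)
  eligible <- which(mol$elem == "C" & mol$nH >= 1L &
                    (if (mode == "aromatic_CH") mol$arom else TRUE))
  if (!length(eligible)) {
    return(tibble::tibble(
      substrate = character(0), site_atom = integer(0),
      symmetry_class = integer(0), n_equivalent = integer(0),
      site_product = character(0), site_reaction = character(0)
    ))
  }
  classes <- symmetry_classes(substrate)
  cls <- classes[eligible]
  if (collapse_symmetry) {
    reps <- vapply(split(eligible, cls), min, integer(1))
    counts <- vapply(split(eligible, cls), length, integer(1))
    site_atoms <- as.integer(reps)
    n_eq <- as.integer(counts)
    site_cls <- as.integer(names(reps))
    ord <- order(site_atoms)
    site_atoms <- site_atoms[ord]; n_eq <- n_eq[ord]; site_cls <- site_cls[ord]
  } else {
    site_atoms <- eligible
    n_eq <- rep(1L, length(eligible))
    site_cls <- cls
  }
  products <- vapply(site_atoms, function(a) attach_boron(substrate, a),
                     character(1))
  tibble::tibble(
    substrate = substrate,
    site_atom = site_atoms,
    symmetry_class = site_cls,
    n_equivalent = n_eq,
    site_product = products,
    site_reaction = paste0(substrate, ">>", products)
  )
}

#' Label enumerated sites against experimental outcomes
#'
#' Compares every candidate site product with the experimentally observed
#' product(s) of its substrate: a site gets label 1 (reactive) when its
#' product canonically equals an observed product, 0 otherwise; observed
#' yields are carried over to the matching site. Mixtures produce several
#' label-1 sites on one substrate.
#'
#' @param sites tibble from [enumerate_sites()].
#' @param outcomes tibble with columns `substrate`, `product` and optionally
#'   `yield_percent`.
#' @return `sites` with `label` (0/1 integer) and `yield_label` columns.
#'   Observed products that no enumerated site can generate are attached as
#'   the `unmatched` attribute and reported with a warning.
#' @export
label_sites <- function(sites, outcomes) {
  stopifnot(all(c("substrate", "product") %in% names(outcomes)))
  if (!"yield_percent" %in% names(outcomes)) {
    outcomes$yield_percent <- NA_real_
  }
  outcomes <- dplyr::mutate(
    outcomes,
    substrate = canonicalize(.data$substrate),
    product = canonicalize(.data$product)
  )
  key_site <- paste(sites$substrate, sites$site_product)
  key_out <- paste(outcomes$substrate, outcomes$product)
  hit <- match(key_site, key_out)
  labeled <- dplyr::mutate(
    sites,
    label = as.integer(!is.na(hit)),
    yield_label = outcomes$yield_percent[hit]
  )
  unmatched <- outcomes[!(key_out %in% key_site), , drop = FALSE]
  if (nrow(unmatched)) {
    warning(sprintf(
      "%d experimental product(s) cannot be generated from their substrate by monoborylation",
      nrow(unmatched)), call. = FALSE)
  }
  attr(labeled, "unmatched") <- tibble::as_tibble(unmatched)
  labeled
}

#' Build a labeled site dataset from curated reactions
#'
#' Expands curated reaction records (substrate, observed borylation product,
#' optional yield) into the full per-site classification dataset: every
#' symmetry-distinct candidate site of every substrate, labeled reactive or
#' unreactive against the observed products.
#'
#' @param reactions tibble with columns `substrate`, `product` and optionally
#'   `yield_percent` (e.g. the output of [curate_reactions()]).
#' @param mode site-eligibility mode passed to [enumerate_sites()].
#' @return labeled site tibble (see [label_sites()]).
#' @export
build_site_dataset <- function(reactions, mode = "aromatic_CH") {
  sites <- enumerate_sites(unique(reactions$substrate), mode = mode)
  label_sites(sites, reactions)
}
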