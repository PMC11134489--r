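# Curation of raw reaction SMILES into a clean aromatic C-H borylation set:
# a cheap C-H/C-B screen, then product fragmentation along C-B bonds with
# fragment-vs-substrate matching (which rejects Miyaura-type C-X borylations),
# SMILES validity, optional yield presence, and the iridium + aromatic-site
# requirement.

#' Naive C-H / C-B screen
#'
#' First-stage filter: the substrate must have at least one carbon bearing a
#' hydrogen and at least one product must contain a carbon-boron bond.
#'
#' @param substrate substrate SMILES.
#' @param products character vector of product SMILES.
#' @return logical scalar.
#' @export
naive_filter <- function(substrate, products) {
  mol <- get_mol(substrate)
  has_ch <- any(mol$elem == "C" & mol$nH >= 1L)
  has_cb <- any(vapply(products, function(p) length(cb_bonds(get_mol(p))) > 0,
                       logical(1)))
  has_ch && has_cb
}

# indices of carbon-boron bonds in a molecule
cb_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(integer(0))
  e1 <- mol$elem[mol$bonds$a1]; e2 <- mol$elem[mol$bonds$a2]
  which((e1 == "C" & e2 == "B") | (e1 == "B" & e2 == "C"))
}

induced_submol <- function(mol, atoms) {
  atoms <- sort(atoms)
  map <- integer(mol$n); map[atoms] <- seq_along(atoms)
  keep <- map[mol$bonds$a1] > 0L & map[mol$bonds$a2] > 0L
  bonds <- fast_df(map[mol$bonds$a1[keep]], map[mol$bonds$a2[keep]],
                   mol$bonds$order[keep])
  new_mol(mol$elem[atoms], mol$arom[atoms], mol$charge[atoms],
          mol$iso[atoms], mol$nH[atoms], bonds)
}

component_of <- function(mol, start, skip_bond) {
  seen <- logical(mol$n); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- mol$adj[[v]]; bb <- mol$badj[[v]]
    for (j in seq_along(nb)) {
      if (bb[j] == skip_bond) next
      if (!seen[nb[j]]) { seen[nb[j]] <- TRUE; queue <- c(queue, nb[j]) }
    }
  }
  which(seen)
}

#' Match a borylation product back to its substrate by C-B fragmentation
#'
#' For each carbon-boron bond of the product (in canonical bond order): cut
#' the bond, discard the boron-containing fragment, cap the carbon with one
#' hydrogen and canonicalize. If the capped fragment equals the reactant the
#' reaction is a genuine C-H borylation and the borylated carbon is returned
#' as an atom id in the reactant's canonical ordering (the lowest id of its
#' symmetry class). Aryl-halide (Miyaura-type) borylations fail the match
#' because the capped fragment lacks the halide.
#'
#' @param reactant substrate SMILES.
#' @param product product SMILES; must contain at least one C-B bond.
#' @return the matched site atom id, or `NA_integer_` when no cleavage
#'   reproduces the reactant.
#' @examples
#' fragment_match("c1ccccc1", "CC1(C)OB(OC1(C)C)c1ccccc1")   # a site id
#' fragment_match("Brc1ccccc1", "CC1(C)OB(OC1(C)C)c1ccccc1") # NA
#' @export
fragment_match <- function(reactant, product) {
  rcan <- canonicalize1(reactant)
  pmol <- get_mol(product)
  kk <- cb_bonds(pmol)
  if (!length(kk)) {
    stop(sprintf("product '%s' contains no carbon-boron bond", pmol$smiles),
         call. = FALSE)
  }
  for (k in kk) {
    carbon <- if (pmol$elem[pmol$bonds$a1[k]] == "C") pmol$bonds$a1[k]
              else pmol$bonds$a2[k]
    comp <- component_of(pmol, carbon, skip_bond = k)
    boron <- if (carbon == pmol$bonds$a1[k]) pmol$bonds$a2[k] else pmol$bonds$a1[k]
    if (boron %in% comp) next   # C-B bond inside a ring: not cleavable
    frag <- induced_submol(pmol, comp)
    cidx <- match(carbon, sort(comp))
    frag$nH[cidx] <- frag$nH[cidx] + 1L
    capped <- tryCatch(canonicalize1(write_smiles(frag)), error = function(e) NA)
    if (is.na(capped) || capped != rcan) next
    # locate the site in the reactant's canonical ordering: re-borylate the
    # capped fragment at the known carbon and find the reactant site class
    # producing the same molecule
    target <- canonicalize1(write_smiles(glue_fragment(frag, cidx, BPIN_SMILES)))
    rmol <- get_mol(rcan)
    classes <- symmetry_classes(rcan)
    cand <- which(rmol$elem == "C" & rmol$nH >= 1L)
    reps <- vapply(split(cand, classes[cand]), min, integer(1))
    for (r in as.integer(reps)) {
      if (attach_boron(rcan, r) == target) return(r)
    }
  }
  NA_integer_
}

#' Iridium-catalysis and aromatic-site filter
#'
#' TRUE when some agent molecule contains iridium and the matched site
#' carbon is aromatic in the reactant.
#'
#' @param substrate substrate SMILES.
#' @param agents character vector of agent SMILES (may be empty).
#' @param site_atom matched site atom id in the substrate.
#' @param require_ir require an iridium-containing agent (default TRUE).
#' @return logical scalar.
#' @export
iridium_aromatic_filter <- function(substrate, agents, site_atom,
                                    require_ir = TRUE) {
  has_ir <- length(agents) > 0 &&
    any(vapply(agents, contains_element, logical(1), element = "Ir"))
  site_arom <- get_mol(substrate)$arom[site_atom]
  (!require_ir || has_ir) && isTRUE(site_arom)
}

#' Curate raw borylation reactions
#'
#' Runs the full filtering funnel over a table of raw reaction SMILES:
#' naive C-H/C-B screen, C-B fragment matching against the substrate,
#' SMILES validity, optional yield presence, and the iridium + aromatic-site
#' requirement; retained records are deduplicated by canonical
#' (substrate, product) pair, ignoring agents. Records that fail to parse
#' are dropped at the validity stage and logged by id.
#'
#' @param reactions data frame with columns `rxn_smiles` and optionally
#'   `yield` (or `yield_percent`) and `id`.
#' @param require_yield drop records without a reported yield (default FALSE).
#' @param require_ir require an iridium-containing agent (default TRUE).
#' @return an object of class `borysite_curation`: a list with `reactions`
#'   (tibble of retained records: `id`, `substrate`, `product`, `site_atom`,
#'   `yield_percent`, `agents`) and `report` (per-stage pass counts forming
#'   the filtering funnel).
#' @export
curate_reactions <- function(reactions, require_yield = FALSE,
                             require_ir = TRUE) {
  stopifnot("rxn_smiles" %in% names(reactions))
  ycol <- intersect(c("yield_percent", "yield"), names(reactions))[1]
  yields <- if (!is.na(ycol)) as.numeric(reactions[[ycol]]) else
    rep(NA_real_, nrow(reactions))
  ids <- if ("id" %in% names(reactions)) as.character(reactions$id) else
    paste0("rxn", seq_len(nrow(reactions)))

  n <- nrow(reactions)
  parsed <- vector("list", n)
  ok_parse <- logical(n)
  for (i in seq_len(n)) {
    parsed[[i]] <- tryCatch(parse_reaction1(reactions$rxn_smiles[i]),
                            error = function(e) NULL)
    ok_parse[i] <- !is.null(parsed[[i]])
  }

  # unparseable records cannot be assessed by the structure filters; they are
  # carried to the validity stage and dropped there (logged below)
  naive_pass <- ok_parse
  site <- rep(NA_integer_, n)
  product <- rep(NA_character_, n)
  for (i in which(ok_parse)) {
    naive_pass[i] <- naive_filter(parsed[[i]]$substrate, parsed[[i]]$products)
  }
  frag_pass <- naive_pass
  for (i in which(ok_parse & naive_pass)) {
    for (p in parsed[[i]]$products) {
      if (!length(cb_bonds(get_mol(p)))) next
      s <- fragment_match(parsed[[i]]$substrate, p)
      if (!is.na(s)) { site[i] <- s; product[i] <- p; break }
    }
    frag_pass[i] <- !is.na(site[i])
  }
  stage_naive <- !ok_parse | naive_pass
  stage_frag <- !ok_parse | frag_pass
  valid_pass <- ok_parse & frag_pass
  dropped_invalid <- ids[stage_frag & !ok_parse]
  if (length(dropped_invalid)) {
    message(sprintf("dropped %d unparseable record(s): %s",
                    length(dropped_invalid),
                    paste(utils::head(dropped_invalid, 5), collapse = ", ")))
  }
  yield_pass <- valid_pass & (!require_yield | !is.na(yields))
  ir_pass <- yield_pass
  for (i in which(yield_pass)) {
    ir_pass[i] <- iridium_aromatic_filter(parsed[[i]]$substrate,
                                          parsed[[i]]$agents, site[i],
                                          require_ir = require_ir)
  }

  kept <- which(ir_pass)
  out <- tibble::tibble(
    id = ids[kept],
    substrate = vapply(parsed[kept], `[[`, character(1), "substrate"),
    product = product[kept],
    site_atom = site[kept],
    yield_percent = yields[kept],
    agents = lapply(parsed[kept], `[[`, "agents")
  )
  dup <- duplicated(paste(out$substrate, out$product))
  out <- out[!dup, , drop = FALSE]

  report <- tibble::tibble(
    stage = c("input", "naive_CH_CB_pass", "fragment_match_pass",
              "valid_species_pass", "with_yield", "ir_aromatic_pass",
              "retained_unique"),
    passed = c(n, sum(stage_naive), sum(stage_frag), sum(valid_pass),
               sum(yield_pass), sum(ir_pass), nrow(out))
  )
  structure(list(reactions = out, report = report),
            class = "borysite_curation")
}

#' @export
print.borysite_curation <- function(x, ...) {
  cat("C-H borylation curation funnel\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @rdname curate_reactions
#' @param x a `borysite_curation` object.
#' @param ... unused.
#' @export
tidy.borysite_curation <- function(x, ...) x$report

#' Funnel plot of the curation stages
#'
#' @param object a `borysite_curation` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.borysite_curation <- function(object, ...) {
  df <- dplyr::mutate(object$report,
                      stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$passed, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$passed), hjust = -0.15) +
    ggplot2::labs(x = "records passing", y = NULL,
                  title = "Borylation curation funnel") +
    ggplot2::theme_minimal()
}
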