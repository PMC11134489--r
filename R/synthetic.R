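# Seeded generator of synthetic borylation reaction sets. Substrates are
# assembled from the aromatic ring systems most common in real borylation
# data (benzenes, thiophenes, pyridines, indoles, quinolines, ...) decorated
# with typical substituents; their regioselectivity follows an explicit
# additive rule score encoding the field's qualitative guidelines: borylation
# avoids positions next to ortho substituents and next to basic (pyridine-
# type) nitrogens, five-membered heteroarenes react preferentially, and
# N-heteroarenes beat plain arenes. The numeric constants are generator
# design choices (the guidelines are ordinal, not quantitative).

RING_VOCABULARY <- tibble::tibble(
  name = c("benzene", "thiophene", "furan", "pyridine", "pyrazole",
           "indole", "quinoline", "benzothiophene", "benzofuran"),
  smiles = c("c1ccccc1", "c1ccsc1", "c1ccoc1", "c1ccncc1", "c1cc[nH]n1",
             "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1", "c1ccc2sccc2c1",
             "c1ccc2occc2c1"),
  weight = c(8, 3, 1.5, 3, 1.5, 2, 2, 1, 1)
)

SUBSTITUENTS <- list(
  Me = list(smiles = "C", attach = 1L),
  OMe = list(smiles = "OC", attach = 1L),
  F = list(smiles = "F", attach = 1L),
  Cl = list(smiles = "Cl", attach = 1L),
  CF3 = list(smiles = "C(F)(F)F", attach = 1L),
  CN = list(smiles = "C#N", attach = 1L),
  CO2Me = list(smiles = "C(=O)OC", attach = 1L)
)

aromatic_ch_atoms <- function(smiles) {
  mol <- get_mol(smiles)
  which(mol$elem == "C" & mol$arom & mol$nH >= 1L)
}

# same, but on the string as written (fragment attachment ids index the raw
# parse, not the canonical ordering)
aromatic_ch_atoms_raw <- function(smiles) {
  mol <- parse_smiles_graph(smiles)
  which(mol$elem == "C" & mol$arom & mol$nH >= 1L)
}

attach_substituent <- function(smiles, site, frag_smiles, frag_attach = 1L) {
  canonicalize1(write_smiles(
    glue_fragment(get_mol(smiles), site, frag_smiles, frag_attach)))
}

#' Generate synthetic borylation substrates
#'
#' Assembles `n` unique aromatic substrates by drawing a ring system from
#' the vocabulary (optionally linked to a second ring system as a biaryl)
#' and decorating it with 0-3 substituents (Me, OMe, F, Cl, CF3, CN, CO2Me)
#' at random aromatic C-H positions. Every substrate is valid, unique, and
#' keeps at least one aromatic C-H. Deterministic for a given seed.
#'
#' @param n number of substrates.
#' @param seed RNG seed.
#' @return character vector of `n` canonical SMILES.
#' @export
generate_substrates <- function(n, seed = 1) {
  stopifnot(n >= 1)
  local_seed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 60L * n) {
      guard <- guard + 1L
      s <- sample(RING_VOCABULARY$smiles, 1, prob = RING_VOCABULARY$weight)
      if (stats::runif(1) < 0.15) {
        other <- sample(RING_VOCABULARY$smiles, 1,
                        prob = RING_VOCABULARY$weight)
        site <- resample(aromatic_ch_atoms(s), 1)
        oa <- resample(aromatic_ch_atoms_raw(other), 1)
        s <- attach_substituent(s, site, other, oa)
      }
      for (k in seq_len(sample(0:3, 1))) {
        ch <- aromatic_ch_atoms(s)
        if (length(ch) <= 1L) break   # keep at least one aromatic C-H
        sub <- SUBSTITUENTS[[sample(length(SUBSTITUENTS), 1)]]
        s <- attach_substituent(s, resample(ch, 1), sub$smiles, sub$attach)
      }
      if (!length(aromatic_ch_atoms(s))) next
      if (!(s %in% out)) out <- c(out, s)
    }
    if (length(out) < n) {
      stop("could not assemble enough unique substrates", call. = FALSE)
    }
    out
  })
}

resample <- function(x, size) x[sample.int(length(x), size)]

#' Rule-based site selectivity score
#'
#' Scores every symmetry-distinct aromatic C-H site of a substrate with the
#' additive selectivity rule used by the synthetic generator:
#' base 2.0 on a five-membered heteroaromatic ring, 1.5 on a six-membered
#' N-heteroaromatic ring, 1.0 on a carbocyclic aromatic ring;
#' -1.5 per flanking ring atom that carries a substituent (or ring fusion);
#' -2.0 per adjacent pyridine-type (two-connected, H-free aromatic)
#' nitrogen. The rule-reactive sites of a substrate are the score maxima.
#'
#' @param smiles substrate SMILES (single string).
#' @return tibble with one row per candidate site: `substrate`, `site_atom`,
#'   `symmetry_class`, `base`, `ortho_penalty`, `basic_n_penalty`, `total`.
#' @examples
#' rule_score("c1ccncc1")   # pyridine: sites next to N score lowest
#' @export
rule_score <- function(smiles) {
  sites <- enumerate_sites(smiles, mode = "aromatic_CH")
  if (!nrow(sites)) {
    stop(sprintf("'%s' has no enumerable aromatic C-H site", smiles),
         call. = FALSE)
  }
  mol <- get_mol(sites$substrate[1])
  arings <- aromatic_rings(mol)
  score1 <- function(a) {
    mine <- Filter(function(r) a %in% r, arings)
    five_het <- any(vapply(mine, function(r)
      length(r) == 5 && any(mol$elem[r] != "C"), logical(1)))
    six_n <- any(vapply(mine, function(r)
      length(r) == 6 && any(mol$elem[r] == "N"), logical(1)))
    base <- if (five_het) 2.0 else if (six_n) 1.5 else 1.0
    nb <- mol$adj[[a]]
    ring_nb <- nb[mol$arom[nb]]
    ortho <- -1.5 * sum(lengths(mol$adj[ring_nb]) >= 3L)
    basic_n <- -2.0 * sum(mol$elem[nb] == "N" & mol$arom[nb] &
                          mol$nH[nb] == 0L & lengths(mol$adj[nb]) == 2L)
    c(base = base, ortho_penalty = ortho, basic_n_penalty = basic_n)
  }
  parts <- t(vapply(sites$site_atom, score1, numeric(3)))
  dplyr::mutate(
    sites[, c("substrate", "site_atom", "symmetry_class")],
    base = unname(parts[, "base"]),
    ortho_penalty = unname(parts[, "ortho_penalty"]),
    basic_n_penalty = unname(parts[, "basic_n_penalty"]),
    total = .data$base + .data$ortho_penalty + .data$basic_n_penalty
  )
}

SYNTH_AGENTS <- c("CC1(C)OB(OC1(C)C)B1OC(C)(C)C(C)(C)O1", "[Ir]")

#' Synthesize a borylation reaction dataset
#'
#' For each of `n` generated substrates, the rule-maximal site(s) react
#' (ties produce product mixtures); with probability `noise` the reactive
#' site is instead reassigned uniformly at random among the substrate's
#' candidate sites (label noise). Products are built by Bpin attachment;
#' the major product's yield is drawn from N(70, 15) clipped to [5, 99] and
#' rounded, minor mixture components from N(30, 10) clipped to [5, 60].
#' Agents include B2pin2 and an iridium species, so the full set passes
#' curation. Deterministic per seed.
#'
#' @param n number of substrates.
#' @param seed RNG seed.
#' @param noise label-noise fraction in [0, 0.5).
#' @return tibble with columns `id`, `rxn_smiles`, `yield` (one row per
#'   product; mixtures give several rows per substrate).
#' @export
synthesize_dataset <- function(n, seed = 1, noise = 0) {
  stopifnot(noise >= 0, noise < 0.5)
  substrates <- generate_substrates(n, seed)
  agent_field <- paste(SYNTH_AGENTS, collapse = ".")
  local_seed(seed + 1000003L, {
    rows <- vector("list", length(substrates))
    for (i in seq_along(substrates)) {
      s <- substrates[i]
      scores <- rule_score(s)
      reactive <- scores$site_atom[scores$total >= max(scores$total) - 1e-9]
      if (noise > 0 && stats::runif(1) < noise) {
        reactive <- resample(scores$site_atom, 1)
      }
      k <- length(reactive)
      yields <- numeric(k)
      yields[1] <- round(min(99, max(5, stats::rnorm(1, 70, 15))))
      if (k > 1) {
        yields[-1] <- round(pmin(60, pmax(5, stats::rnorm(k - 1, 30, 10))))
      }
      products <- vapply(reactive, function(a) attach_boron(s, a), character(1))
      rows[[i]] <- tibble::tibble(
        id = sprintf("synth%05d_%d", i, seq_len(k)),
        rxn_smiles = paste0(s, ">", agent_field, ">", products),
        yield = yields
      )
    }
    dplyr::bind_rows(rows)
  })
}
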