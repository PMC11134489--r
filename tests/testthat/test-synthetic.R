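test_that("substrate generation is deterministic, unique and always enumerable", {
  a <- generate_substrates(25, seed = 1)
  b <- generate_substrates(25, seed = 1)
  expect_equal(a, b)
  expect_length(unique(a), 25)
  expect_false(identical(a, generate_substrates(25, seed = 2)))
  # all parse, all have at least one aromatic C-H site
  expect_true(all(vapply(a, function(s) nrow(enumerate_sites(s)) > 0,
                         logical(1))))
  # both single- and multi-ring substrates occur
  rings <- count_aromatic_rings(generate_substrates(60, seed = 3))
  expect_true(any(rings == 1) && any(rings > 1))
})

test_that("the rule score reproduces each selectivity guideline in isolation", {
  # pyridine: sites adjacent to the basic nitrogen are never maximal
  py <- rule_score(PYRIDINE)
  can <- canonicalize(PYRIDINE)
  mol <- borysite:::get_mol(can)
  nidx <- which(mol$elem == "N")
  next_to_n <- py$site_atom %in% mol$adj[[nidx]]
  expect_true(any(next_to_n))
  expect_lt(max(py$total[next_to_n]), max(py$total))
  expect_equal(py$basic_n_penalty[next_to_n], rep(-2, sum(next_to_n)))

  # m-xylene: ortho-substituted sites are never maximal
  mx <- rule_score("Cc1cccc(C)c1")
  ortho <- mx$ortho_penalty < 0
  expect_true(any(ortho))
  expect_lt(max(mx$total[ortho]), max(mx$total))

  # 2-phenylthiophene: the best site sits on the thiophene ring
  pt <- canonicalize("c1ccc(-c2cccs2)cc1")
  sc <- rule_score(pt)
  best <- sc$site_atom[which.max(sc$total)]
  molp <- borysite:::get_mol(pt)
  sidx <- which(molp$elem == "S")
  thiophene_ring <- Filter(function(r) sidx %in% r,
                           borysite:::aromatic_rings(molp))[[1]]
  expect_true(best %in% thiophene_ring)
  # benzene reference: uniform base scores
  expect_equal(rule_score(BENZENE)$total, 1.0)
})

test_that("synthesized reactions hit rule-maximal sites with yields in range", {
  rxns <- synthesize_dataset(12, seed = 9, noise = 0)
  expect_true(all(rxns$yield >= 5 & rxns$yield <= 99))
  parsed <- parse_reactions(rxns$rxn_smiles, rxns$yield, rxns$id)
  for (i in seq_len(nrow(parsed))) {
    sc <- rule_score(parsed$substrate[i])
    best <- sc$site_atom[sc$total >= max(sc$total) - 1e-9]
    hit <- fragment_match(parsed$substrate[i], parsed$products[[i]][1])
    expect_true(hit %in% best)
  }
  # determinism of the full record set
  expect_equal(rxns, synthesize_dataset(12, seed = 9, noise = 0))
})

test_that("label noise reassigns roughly the requested fraction of substrates", {
  n <- 250
  rxns0 <- synthesize_dataset(n, seed = 19, noise = 0)
  rxns1 <- synthesize_dataset(n, seed = 19, noise = 0.1)
  p0 <- parse_reactions(rxns0$rxn_smiles)
  p1 <- parse_reactions(rxns1$rxn_smiles)
  # compare the product set per substrate between the clean and noisy runs
  set0 <- tapply(vapply(p0$products, `[[`, character(1), 1), p0$substrate,
                 function(x) paste(sort(unique(x)), collapse = "|"))
  set1 <- tapply(vapply(p1$products, `[[`, character(1), 1), p1$substrate,
                 function(x) paste(sort(unique(x)), collapse = "|"))
  shared <- intersect(names(set0), names(set1))
  frac <- mean(set0[shared] != set1[shared])
  # binomial band around 0.1 at n = 250 (3+ standard deviations), allowing
  # for noise draws that land on the rule site by chance
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.18)
})

test_that("agents always include an iridium species so curation passes", {
  rxns <- synthesize_dataset(5, seed = 23)
  parsed <- parse_reactions(rxns$rxn_smiles)
  for (ag in parsed$agents) {
    expect_true(any(grepl("Ir", ag)))
  }
})
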