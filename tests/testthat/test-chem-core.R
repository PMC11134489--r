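test_that("canonicalization maps Kekule input to the canonical aromatic form and is idempotent", {
  expect_equal(canonicalize("C1=CC=CC=C1"), "c1ccccc1")
  # idempotence over a mixed corpus
  corpus <- c(BENZENE, PYRIDINE, TOLUENE, INDOLE, PHBPIN, "O=[N+]([O-])c1ccccc1",
              "FC(F)(F)c1ccc(C#N)cc1", "COC(=O)c1ccsc1", substrate_panel(10))
  can <- canonicalize(corpus)
  expect_equal(canonicalize(can), can)
})

test_that("unparseable SMILES raise an error naming the input", {
  expect_error(canonicalize("c1ccccc"), "c1ccccc")
  expect_error(canonicalize(""), "empty")
  expect_error(canonicalize("notasmiles"), "notasmiles")
})

test_that("canonical form is invariant to the input atom ordering", {
  variants <- list(
    c("c1ccncc1", "n1ccccc1", "C1=CC=NC=C1"),
    c("Cc1ccccc1", "c1ccccc1C"),
    c("c1ccc2[nH]ccc2c1", "c1cc2cc[nH]c2cc1")
  )
  for (v in variants) {
    expect_length(unique(canonicalize(v)), 1)
  }
})

test_that("reaction SMILES parse into substrate, agents and products", {
  tbl <- parse_reactions("c1ccccc1>>CC1(C)OB(OC1(C)C)c1ccccc1")
  expect_equal(tbl$substrate, "c1ccccc1")
  expect_length(tbl$agents[[1]], 0)
  expect_length(tbl$products[[1]], 1)

  tbl2 <- parse_reactions("c1ccccc1.O>[Ir]>CC1(C)OB(OC1(C)C)c1ccccc1")
  expect_length(tbl2$reactants[[1]], 2)
  expect_equal(tbl2$agents[[1]], "[Ir]")
  expect_equal(tbl2$substrate, "c1ccccc1")   # largest reactant wins
})

test_that("malformed reaction strings and out-of-range yields are rejected", {
  expect_error(parse_reactions("c1ccccc1>"), "separator")
  expect_error(parse_reactions("a>b>c>d"), "separator")
  expect_error(parse_reactions("c1ccccc1>>CC", yield_percent = 120), "0, 100")
})

test_that("the substrate is the largest non-boron reactant", {
  tbl <- parse_reactions(paste0(B2PIN2, ".c1ccncc1>>CC1(C)OB(OC1(C)C)c1ccncc1"))
  expect_equal(tbl$substrate, canonicalize("c1ccncc1"))
})

test_that("aromatic ring counting follows the smallest-set-of-smallest-rings", {
  expect_equal(count_aromatic_rings(BENZENE), 1L)
  expect_equal(count_aromatic_rings(BIPHENYL), 2L)
  expect_equal(count_aromatic_rings("c1ccc2ccccc2c1"), 2L)   # naphthalene
  expect_equal(count_aromatic_rings("C1CCCCC1"), 0L)
  # invariant to serialization
  expect_equal(count_aromatic_rings("c2ccc1ccccc1c2"), 2L)
})

test_that("heterocycle membership is resolved per smallest ring", {
  expect_false(ring_is_heterocyclic(BENZENE, 1))
  can <- canonicalize(INDOLE)
  mol <- borysite:::get_mol(can)
  # the pyrrole-ring carbons (sharing a ring with N) are heterocyclic, the
  # non-fused benzo carbons are not
  nidx <- which(mol$elem == "N")
  pyrrole_c <- intersect(mol$adj[[nidx]], which(mol$elem == "C"))
  expect_true(all(vapply(pyrrole_c, function(a) ring_is_heterocyclic(can, a),
                         logical(1))))
  benzo_only <- setdiff(which(mol$elem == "C" & mol$nH == 1), unlist(
    Filter(function(r) nidx %in% r, borysite:::aromatic_rings(mol))))
  benzo_only <- benzo_only[vapply(benzo_only, function(a) {
    rs <- Filter(function(r) a %in% r, borysite:::aromatic_rings(mol))
    all(vapply(rs, function(r) !nidx %in% r, logical(1)))
  }, logical(1))]
  expect_true(length(benzo_only) > 0)
  expect_false(any(vapply(benzo_only, function(a) ring_is_heterocyclic(can, a),
                          logical(1))))
  expect_error(ring_is_heterocyclic("CC", 1), "aromatic")
})

test_that("symmetry classes agree with unique-product counting", {
  # benzene fully symmetric
  expect_length(unique(symmetry_classes(BENZENE)), 1)
  # pyridine: three carbon classes (2/6, 3/5, 4) plus N
  can <- canonicalize(PYRIDINE)
  mol <- borysite:::get_mol(can)
  cls <- symmetry_classes(can)
  expect_length(unique(cls[mol$elem == "C"]), 3)
  # thiophene: two carbon classes
  can2 <- canonicalize(THIOPHENE)
  mol2 <- borysite:::get_mol(can2)
  expect_length(unique(symmetry_classes(can2)[mol2$elem == "C"]), 2)
  # class counts equal brute-force unique-product counts
  for (s in c(BENZENE, PYRIDINE, THIOPHENE, TOLUENE, INDOLE)) {
    expect_length(brute_force_products(s),
                  nrow(enumerate_sites(s)))
  }
})
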