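test_that("the naive C-H/C-B screen checks both reaction sides", {
  expect_true(naive_filter(BENZENE, PHBPIN))
  expect_false(naive_filter(BENZENE, BENZENE))               # no C-B made
  expect_false(naive_filter("Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl",  # no C-H
                            PHBPIN))
})

test_that("fragment matching recovers the borylated carbon and rejects Miyaura-type reactions", {
  site <- fragment_match(BENZENE, PHBPIN)
  expect_false(is.na(site))
  expect_equal(attach_boron(BENZENE, site), canonicalize(PHBPIN))
  # bromobenzene did not lose an H: capping gives benzene, not bromobenzene
  expect_true(is.na(fragment_match("Brc1ccccc1", PHBPIN)))
  expect_error(fragment_match(BENZENE, BENZENE), "carbon-boron")
})

test_that("every enumerated site reaction round-trips through fragment matching", {
  for (s in substrate_panel(12, seed = 11)) {
    sites <- enumerate_sites(s)
    for (i in seq_len(nrow(sites))) {
      expect_equal(fragment_match(sites$substrate[i], sites$site_product[i]),
                   sites$site_atom[i])
    }
  }
})

test_that("the iridium/aromatic filter needs both an Ir agent and an aromatic site", {
  expect_true(iridium_aromatic_filter(BENZENE, "[Ir]", 1))
  expect_false(iridium_aromatic_filter(BENZENE, character(0), 1))
  expect_false(iridium_aromatic_filter(BENZENE, "CCO", 1))
  # cyclohexane borylation: site not aromatic
  expect_false(iridium_aromatic_filter("C1CCCCC1", "[Ir]", 1))
  # without the Ir requirement, aromaticity still decides
  expect_true(iridium_aromatic_filter(BENZENE, character(0), 1,
                                      require_ir = FALSE))
})

test_that("the curation funnel is monotone, deduplicates and records drops", {
  df <- data.frame(
    rxn_smiles = c(
      borylation_rxn(BENZENE, PHBPIN),
      "Brc1ccccc1>>CC1(C)OB(OC1(C)C)c1ccccc1",           # Miyaura decoy
      paste0(BENZENE, ">[Ir]>", PHBPIN),                 # duplicate pair
      "badsmiles>>alsobad",                              # validity drop
      "C1CCCCC1>[Ir]>CC1(C)OB(OC1(C)C)C1CCCCC1",         # aliphatic site
      paste0(BENZENE, ">>", PHBPIN)                      # no Ir agent
    ),
    yield = c(80, NA, 75, NA, 50, 60)
  )
  cur <- suppressMessages(curate_reactions(df))
  counts <- cur$report$passed
  expect_equal(counts[1], nrow(df))
  expect_true(all(diff(counts) <= 0))
  expect_equal(cur$report$passed[cur$report$stage == "retained_unique"], 1)
  expect_equal(cur$reactions$substrate, BENZENE)
  expect_equal(cur$reactions$site_atom, fragment_match(BENZENE, PHBPIN))

  # requiring yields drops yield-less records
  df2 <- df[c(1, 3), ]; df2$yield <- c(80, NA)
  cur2 <- curate_reactions(df2, require_yield = TRUE)
  expect_equal(cur2$report$passed[cur2$report$stage == "with_yield"], 1)
})

test_that("curation output is independent of record order", {
  rxns <- synthesize_dataset(8, seed = 3)
  a <- curate_reactions(rxns)
  b <- curate_reactions(rxns[rev(seq_len(nrow(rxns))), ])
  key <- function(x) sort(paste(x$reactions$substrate, x$reactions$product,
                                x$reactions$site_atom))
  expect_equal(key(a), key(b))
  expect_equal(sort(a$report$passed), sort(b$report$passed))
})

test_that("synthetic reaction sets survive the full funnel without drops", {
  rxns <- synthesize_dataset(15, seed = 5)
  cur <- curate_reactions(rxns, require_yield = TRUE, require_ir = TRUE)
  expect_true(all(cur$report$passed[-length(cur$report$passed)] == nrow(rxns)))
})
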