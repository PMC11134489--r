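small_labeled_set <- function(n = 40, seed = 31) {
  rxns <- synthesize_dataset(n, seed = seed)
  build_site_dataset(curate_reactions(rxns)$reactions)
}

test_that("the classifier interpolates separable training data and is seed-deterministic", {
  sites <- small_labeled_set()
  m1 <- fit_site_model(sites, "classify", seed = 7)
  p1 <- predict(m1, sites)
  expect_gt(mean(p1$label == p1$pred), 0.95)
  m2 <- fit_site_model(sites, "classify", seed = 7)
  expect_equal(predict(m2, sites)$prob, p1$prob)
  m3 <- fit_site_model(sites, "classify", seed = 8)
  expect_false(identical(predict(m3, sites)$prob, p1$prob))
})

test_that("single-class training labels are rejected for classification", {
  sites <- small_labeled_set(8, seed = 41)
  sites$label <- 0L
  expect_error(fit_site_model(sites, "classify"), "both site classes")
})

test_that("feature width must match the model fingerprint length", {
  sites <- small_labeled_set(10, seed = 43)
  m <- fit_site_model(sites, "classify", n_bits = 128, seed = 1)
  bad <- featurize_sites(sites, n_bits = 64)
  expect_error(predict(m, sites, features = bad), "n_bits")
})

test_that("regressor training excludes reactive sites with missing yields", {
  sites <- small_labeled_set(25, seed = 47)
  sites$yield_label[which(sites$label == 1)[1:3]] <- NA
  m <- fit_site_model(sites, "yield", seed = 5)
  expect_equal(m$n_train, nrow(sites) - 3L)
  pr <- predict(m, sites)
  # predicted class is the documented >= threshold rule
  expect_equal(pr$pred, as.integer(pr$yield_pred >= 5))
})

test_that("molecule-level prediction aggregates sites and flags no-reaction substrates", {
  sites <- small_labeled_set()
  m <- fit_site_model(sites, "classify", seed = 7)
  # no aromatic C-H at all -> no reaction, no sites
  hexaF <- "Fc1c(F)c(F)c(F)c(F)c1F"
  out <- predict_molecule(m, hexaF)
  expect_true(out$no_reaction)
  expect_equal(out$n_sites, 0L)
  expect_length(out$reactive_sites[[1]], 0)

  # a training substrate with a clear rule site is recovered
  sub <- sites$substrate[which(sites$label == 1)[1]]
  out2 <- predict_molecule(m, sub)
  expect_false(out2$no_reaction)
  truth <- sites[sites$substrate == sub, ]
  expect_setequal(out2$reactive_sites[[1]],
                  truth$site_atom[truth$label == 1])
  # prediction is invariant to substrate serialization
  mol <- borysite:::get_mol(sub)
  scrambled <- borysite:::write_smiles(mol, rank = rev(seq_len(mol$n)))
  expect_equal(predict_molecule(m, scrambled), out2)
})

test_that("the no-reaction flag mirrors an empty reactive set", {
  sites <- small_labeled_set(15, seed = 53)
  m <- fit_site_model(sites, "classify", seed = 7)
  for (s in unique(sites$substrate)[1:5]) {
    out <- predict_molecule(m, s)
    expect_equal(out$no_reaction, length(out$reactive_sites[[1]]) == 0)
    if (!out$no_reaction) {
      expect_true(out$major_site %in% out$reactive_sites[[1]])
    }
  }
})

test_that("the substrate-substructure post-filter keeps only true super-structures", {
  pyr3 <- attach_boron(PYRIDINE, enumerate_sites(PYRIDINE)$site_atom[1])
  expect_equal(substructure_postfilter(PYRIDINE, c(pyr3, PHBPIN)), pyr3)
  expect_equal(substructure_postfilter(BENZENE, PHBPIN), PHBPIN)
  expect_equal(substructure_postfilter(BENZENE, character(0)), character(0))
  # every enumerated product contains its own substrate
  for (s in substrate_panel(8, seed = 61)) {
    prods <- enumerate_sites(s)$site_product
    expect_equal(substructure_postfilter(s, prods), prods)
  }
  # order preserved
  both <- c(PHBPIN, attach_boron(TOLUENE, 1))
  expect_equal(substructure_postfilter(BENZENE, both), both)
})

test_that("model summaries expose the pinned hyperparameters", {
  sites <- small_labeled_set(10, seed = 67)
  m <- fit_site_model(sites, "classify", seed = 2)
  g <- glance(m)
  expect_equal(g$num_trees, 500)
  expect_equal(g$mtry, 16)         # floor(sqrt(256))
  expect_equal(g$n_bits, 256)
  expect_equal(g$seed, 2)
})
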