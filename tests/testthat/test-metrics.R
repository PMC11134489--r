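test_that("MCC follows the closed form with the zero-denominator convention", {
  expect_equal(mcc(tp = 5, fp = 0, tn = 5, fn = 0), 1)
  expect_equal(mcc(tp = 0, fp = 0, tn = 8, fn = 2), 0)   # nothing predicted positive
  # denominator (3+1)(3+1)(5+1)(5+1) = 576; cross-checked against cor() below
  expect_equal(mcc(tp = 3, fp = 1, tn = 5, fn = 1), 14 / sqrt(576))
  expect_equal(mcc(confusion_counts(c(1, 0), c(0, 1))), -1)
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    lab <- rbinom(n, 1, 0.4)
    pred <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2 || length(unique(pred)) < 2) next
    expect_equal(mcc(confusion_counts(lab, pred)),
                 suppressWarnings(cor(lab, pred)), tolerance = 1e-12)
  }
})

test_that("site metrics match a hand-evaluated confusion table", {
  m <- site_metrics(c(1, 0, 0, 1), c(1, 1, 0, 0))
  expect_equal(m$site_accuracy, 0.5)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_equal(m$mcc, 0)
  perfect <- site_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  expect_error(site_metrics(c(1, 0), c(1, 0, 0)), "length")
})

test_that("site metrics are invariant under joint permutation", {
  set.seed(7)
  lab <- rbinom(40, 1, 0.3); pred <- rbinom(40, 1, 0.4)
  p <- sample(40)
  expect_equal(site_metrics(lab, pred), site_metrics(lab[p], pred[p]))
})

test_that("molecule-level accuracy requires every site to be correct", {
  sub <- c("a", "a", "b", "b")
  expect_equal(molecule_accuracy(sub, c(1, 0, 1, 0), c(1, 0, 1, 1)), 0.5)
  expect_equal(molecule_accuracy(sub, c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_error(molecule_accuracy(character(0), integer(0), integer(0)),
               "no substrates")
  # molecule accuracy is bounded by the mean per-molecule site accuracy
  set.seed(11)
  for (i in 1:20) {
    sub <- rep(letters[1:6], each = 4)
    lab <- rbinom(24, 1, 0.3); pred <- rbinom(24, 1, 0.3)
    per_mol <- tapply(lab == pred, sub, mean)
    expect_lte(molecule_accuracy(sub, lab, pred), mean(per_mol))
  }
})

test_that("major-product accuracy handles ties and unlabeled substrates", {
  sub <- c("a", "a", "b", "b", "c")
  ylab <- c(70, NA, 40, 40, NA)      # c has no labeled site
  ypred <- c(60, 10, 5, 30, 50)
  acc <- major_product_accuracy(sub, ylab, ypred)
  expect_equal(as.numeric(acc), 1)   # a: correct; b: tie, either counts
  expect_equal(attr(acc, "n_excluded"), 1L)
  expect_equal(as.numeric(major_product_accuracy(c("a", "a"), c(70, 30),
                                                 c(10, 20))), 0)
})

test_that("regression metrics match hand evaluation and flag constant targets", {
  r <- regression_metrics(c(0, 0, 50, 100), c(0, 0, 60, 90))
  expect_equal(r$mae, 5)
  expect_equal(r$rmse, sqrt(50))
  expect_equal(r$r2, 1 - 200 / sum((c(0, 0, 50, 100) - 37.5)^2))
  perfect <- regression_metrics(c(0, 10, 80), c(0, 10, 80))
  expect_equal(perfect[, c("r2", "mae", "rmse", "outcome_mcc")],
               tibble::tibble(r2 = 1, mae = 0, rmse = 0, outcome_mcc = 1))
  expect_equal(regression_metrics(c(0, 10), c(10, 0))$outcome_mcc, -1)
  expect_warning(out <- regression_metrics(c(5, 5), c(4, 6)), "undefined")
  expect_true(is.nan(out$r2))
})

test_that("regression metrics agree with independent computations on random data", {
  set.seed(23)
  for (i in 1:30) {
    y <- runif(50, 0, 100); yhat <- pmax(0, y + rnorm(50, 0, 15))
    r <- regression_metrics(y, yhat)
    fit_resid <- y - yhat
    expect_equal(r$mae, mean(abs(fit_resid)), tolerance = 1e-12)
    expect_equal(r$rmse, sqrt(mean(fit_resid^2)), tolerance = 1e-12)
    expect_equal(r$r2, 1 - sum(fit_resid^2) / ((50 - 1) * var(y)),
                 tolerance = 1e-12)
    succ_y <- as.numeric(y >= 5); succ_p <- as.numeric(yhat >= 5)
    if (var(succ_y) > 0 && var(succ_p) > 0) {
      expect_equal(r$outcome_mcc, cor(succ_y, succ_p), tolerance = 1e-12)
    }
  }
})
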