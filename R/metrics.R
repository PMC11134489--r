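# Site- and molecule-level evaluation. Site classification is imbalanced
# (most candidate sites are unreactive), so the headline site metric is the
# Matthews correlation coefficient; molecule-level accuracy requires the
# entire reactivity pattern of a substrate to be correct.

#' Confusion counts for binary site predictions
#'
#' @param labels,predictions aligned 0/1 vectors.
#' @return one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  check_binary_pair(labels, predictions)
  tibble::tibble(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0)
  )
}

check_binary_pair <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be 0/1", call. = FALSE)
  }
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0 when
#' any factor of the denominator is zero.
#'
#' @param tp,fp,tn,fn confusion counts; alternatively pass a one-row data
#'   frame from [confusion_counts()] as `tp`.
#' @return numeric scalar in [-1, 1].
#' @examples
#' mcc(tp = 3, fp = 1, tn = 5, fn = 1)   # 14 / sqrt(768)
#' @export
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Site-level classification metrics
#'
#' Accuracy, positive predictive value (precision), recall, F1 and MCC over
#' aligned binary site labels and predictions. PPV, recall and F1 fall back
#' to 0 in their degenerate cases.
#'
#' @param labels,predictions aligned 0/1 vectors.
#' @return one-row tibble with `n`, `tp`, `fp`, `tn`, `fn`, `site_accuracy`,
#'   `ppv`, `recall`, `f1`, `mcc`.
#' @export
site_metrics <- function(labels, predictions) {
  cc <- confusion_counts(labels, predictions)
  ppv <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
  f1 <- if (ppv + recall == 0) 0 else 2 * ppv * recall / (ppv + recall)
  dplyr::mutate(
    cc,
    n = .data$tp + .data$fp + .data$tn + .data$fn,
    site_accuracy = (.data$tp + .data$tn) / .data$n,
    ppv = ppv, recall = recall, f1 = f1,
    mcc = mcc(cc),
    .before = 1
  )
}

#' Molecule-level all-sites accuracy
#'
#' Fraction of substrates whose complete site-reactivity pattern is
#' predicted correctly (every candidate site of the molecule classified
#' right).
#'
#' @param substrate grouping vector (one entry per site).
#' @param labels,predictions aligned 0/1 vectors.
#' @return numeric scalar in [0, 1].
#' @export
molecule_accuracy <- function(substrate, labels, predictions) {
  check_binary_pair(labels, predictions)
  if (!length(substrate)) stop("no substrates to evaluate", call. = FALSE)
  stopifnot(length(substrate) == length(labels))
  ok <- tapply(labels == predictions, substrate, all)
  mean(ok)
}

#' Major-product accuracy of a yield regressor
#'
#' Fraction of substrates where the site with the highest predicted yield is
#' the experimentally major site (highest observed yield). Experimental ties
#' count as correct for any tied site; substrates without any labeled
#' reactive site are excluded (their count is reported as an attribute).
#'
#' @param substrate grouping vector (one entry per site).
#' @param yield_label observed per-site yields (NA for unreactive sites).
#' @param yield_pred predicted per-site yields.
#' @return numeric scalar, with attribute `n_excluded`.
#' @export
major_product_accuracy <- function(substrate, yield_label, yield_pred) {
  stopifnot(length(substrate) == length(yield_label),
            length(substrate) == length(yield_pred))
  groups <- split(seq_along(substrate), substrate)
  correct <- logical(0)
  excluded <- 0L
  for (idx in groups) {
    y <- yield_label[idx]
    if (all(is.na(y))) { excluded <- excluded + 1L; next }
    best_pred <- idx[which.max(yield_pred[idx])]
    top <- max(y, na.rm = TRUE)
    majors <- idx[!is.na(y) & y == top]
    correct <- c(correct, best_pred %in% majors)
  }
  if (!length(correct)) stop("no substrate has a labeled site", call. = FALSE)
  structure(mean(correct), n_excluded = excluded)
}

#' Parity plot for site-yield predictions
#'
#' Observed versus predicted per-site yields, with the identity line and the
#' reaction-success threshold marked on both axes.
#'
#' @param y,yhat aligned numeric vectors (observed / predicted yields).
#' @param success_threshold success cutoff drawn as dashed lines (default 5).
#' @return a ggplot.
#' @export
plot_parity <- function(y, yhat, success_threshold = 5) {
  df <- tibble::tibble(observed = y, predicted = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = success_threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_vline(xintercept = success_threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(alpha = 0.4, color = "steelblue") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "observed yield / %", y = "predicted yield / %") +
    ggplot2::theme_minimal()
}

#' Regression metrics for site-yield prediction
#'
#' Coefficient of determination, MAE and RMSE, plus the reaction-outcome MCC
#' obtained by thresholding observed and predicted yields at the reaction
#' success cutoff (default 5 percent).
#'
#' @param y,yhat aligned numeric vectors (observed / predicted yields).
#' @param success_threshold yield at or above which a reaction counts as
#'   successful (default 5).
#' @return one-row tibble with `r2`, `mae`, `rmse`, `outcome_mcc`.
#' @export
regression_metrics <- function(y, yhat, success_threshold = 5) {
  stopifnot(length(y) == length(yhat))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant observed yields: R^2 undefined", call. = FALSE)
    NaN
  } else {
    1 - sum((y - yhat)^2) / ss_tot
  }
  cc <- confusion_counts(as.integer(y >= success_threshold),
                         as.integer(yhat >= success_threshold))
  tibble::tibble(
    r2 = r2,
    mae = mean(abs(y - yhat)),
    rmse = sqrt(mean((y - yhat)^2)),
    outcome_mcc = mcc(cc)
  )
}
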