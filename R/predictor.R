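# Random-forest site models on DRFP features: a reactivity classifier and a
# yield regressor, molecule-level aggregation of per-site predictions, and
# the substrate-substructure post-filter for candidate products.

#' Fit a site-reactivity classifier or site-yield regressor
#'
#' Trains a random forest (ranger) on the differential reaction fingerprints
#' of labeled site reactions. Hyperparameters are pinned in the returned
#' model object so "default hyperparameters" cannot drift: 500 trees, Gini
#' splitting with mtry = floor(sqrt(p)) for classification, variance
#' splitting with mtry = p (all features, the default convention of the
#' toolkit family the fingerprint baseline comes from) for regression, one
#' thread, seeded.
#'
#' For the yield task the response is the observed per-site yield with
#' unreactive sites (label 0) set to 0; reactive sites with unreported
#' yields are excluded from training rather than imputed, since reported
#' yields are biased upward.
#'
#' @param sites labeled site tibble from [build_site_dataset()] (columns
#'   `site_reaction`, `label`, and `yield_label` for the yield task).
#' @param task `"classify"` or `"yield"`.
#' @param n_bits,radius fingerprint parameters (must be reused at
#'   prediction time; they are stored in the model).
#' @param num_trees number of trees (default 500).
#' @param seed RNG seed controlling forest growth.
#' @param features optional precomputed fingerprint matrix, row-aligned with
#'   `sites`.
#' @return an object of class `site_model`.
#' @export
fit_site_model <- function(sites, task = c("classify", "yield"),
                           n_bits = 256, radius = 3, num_trees = 500,
                           seed = 1, features = NULL) {
  task <- match.arg(task)
  stopifnot("label" %in% names(sites))
  if (is.null(features)) {
    features <- featurize_sites(sites, n_bits = n_bits, radius = radius)
  }
  stopifnot(nrow(features) == nrow(sites), ncol(features) == n_bits)
  colnames(features) <- paste0("b", seq_len(n_bits))

  if (task == "classify") {
    if (length(unique(sites$label)) < 2L) {
      stop("classifier training needs both site classes present", call. = FALSE)
    }
    y <- factor(sites$label, levels = c(0, 1))
    mtry <- max(1L, floor(sqrt(n_bits)))
    fit <- ranger::ranger(
      x = features, y = y, probability = TRUE, num.trees = num_trees,
      mtry = mtry, splitrule = "gini", seed = seed, num.threads = 1,
      verbose = FALSE
    )
    n_used <- nrow(features)
  } else {
    if (!"yield_label" %in% names(sites)) {
      stop("yield task needs a yield_label column", call. = FALSE)
    }
    y <- ifelse(sites$label == 0, 0, sites$yield_label)
    keep <- !is.na(y)
    if (!any(keep)) stop("no usable yield labels", call. = FALSE)
    mtry <- n_bits
    fit <- ranger::ranger(
      x = features[keep, , drop = FALSE], y = y[keep],
      num.trees = num_trees, mtry = mtry, splitrule = "variance",
      seed = seed, num.threads = 1, verbose = FALSE
    )
    n_used <- sum(keep)
  }

  structure(
    list(
      task = task, fit = fit, n_bits = n_bits, radius = radius,
      num_trees = num_trees, mtry = mtry, seed = seed, n_train = n_used,
      dataset_hash = fnv1a32(paste(sites$site_reaction, sites$label,
                                   collapse = ";"))
    ),
    class = "site_model"
  )
}

#' Predict reactivity or yield for site reactions
#'
#' @param object a `site_model`.
#' @param sites site tibble (or character vector of site reaction SMILES).
#' @param success_threshold yield at or above which a site counts as
#'   reactive for the yield task (default 5 percent).
#' @param features optional precomputed fingerprint matrix; its width must
#'   match the model's `n_bits`.
#' @param ... unused.
#' @return the input sites with `prob` (classifier) or `yield_pred`
#'   (regressor) and a 0/1 `pred` column.
#' @export
predict.site_model <- function(object, sites, success_threshold = 5,
                               features = NULL, ...) {
  if (is.character(sites)) sites <- tibble::tibble(site_reaction = sites)
  if (is.null(features)) {
    features <- featurize_sites(sites, n_bits = object$n_bits,
                                radius = object$radius)
  }
  if (ncol(features) != object$n_bits) {
    stop(sprintf("feature width %d does not match model n_bits %d",
                 ncol(features), object$n_bits), call. = FALSE)
  }
  colnames(features) <- paste0("b", seq_len(object$n_bits))
  pr <- stats::predict(object$fit, data = features, num.threads = 1)
  if (object$task == "classify") {
    prob <- pr$predictions[, "1"]
    dplyr::mutate(sites, prob = prob, pred = as.integer(prob >= 0.5))
  } else {
    dplyr::mutate(sites, yield_pred = pr$predictions,
                  pred = as.integer(pr$predictions >= success_threshold))
  }
}

#' Molecule-level borylation prediction
#'
#' Enumerates the substrate's candidate sites, predicts each, and aggregates:
#' the reactive set (classifier: class-1 sites; regressor: sites with
#' predicted yield at or above the success threshold), the major site
#' (highest probability or predicted yield, ties to the lowest canonical
#' atom id), and a no-reaction flag when no site is predicted reactive (or
#' the molecule has no enumerable site at all).
#'
#' @param model a `site_model`.
#' @param smiles substrate SMILES (single string).
#' @param mode site-eligibility mode, see [enumerate_sites()].
#' @param success_threshold reaction-success yield cutoff (default 5).
#' @return a one-row tibble: `substrate`, `n_sites`, `reactive_sites`
#'   (list-column of atom ids), `major_site`, `no_reaction`, `sites`
#'   (list-column with the per-site predictions).
#' @export
predict_molecule <- function(model, smiles, mode = "aromatic_CH",
                             success_threshold = 5) {
  substrate <- canonicalize1(smiles)
  sites <- enumerate_sites(substrate, mode = mode)
  if (!nrow(sites)) {
    return(tibble::tibble(
      substrate = substrate, n_sites = 0L,
      reactive_sites = list(integer(0)), major_site = NA_integer_,
      no_reaction = TRUE, sites = list(sites)
    ))
  }
  scored <- predict(model, sites, success_threshold = success_threshold)
  score <- if (model$task == "classify") scored$prob else scored$yield_pred
  reactive <- scored$site_atom[scored$pred == 1]
  tibble::tibble(
    substrate = substrate,
    n_sites = nrow(scored),
    reactive_sites = list(reactive),
    major_site = if (length(reactive)) scored$site_atom[which.max(score)]
                 else NA_integer_,
    no_reaction = length(reactive) == 0L,
    sites = list(scored)
  )
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf(
    "site_model (%s): %d trees, mtry %d, %d-bit DRFP (radius %d), n_train %d\n",
    x$task, x$num_trees, x$mtry, x$n_bits, x$radius, x$n_train))
  invisible(x)
}

#' @rdname fit_site_model
#' @param x a `site_model`.
#' @param ... unused.
#' @export
glance.site_model <- function(x, ...) {
  tibble::tibble(
    task = x$task, num_trees = x$num_trees, mtry = x$mtry,
    n_bits = x$n_bits, radius = x$radius, seed = x$seed,
    n_train = x$n_train, oob_error = x$fit$prediction.error,
    dataset_hash = x$dataset_hash
  )
}

#' Filter candidate products by the substrate-substructure rule
#'
#' In C-H functionalization the substrate is always a substructure of a true
#' product, so candidates that do not contain the substrate (graph
#' monomorphism with element-, aromaticity-, charge- and bond-type-aware
#' matching) can be discarded. Order is preserved.
#'
#' @param substrate substrate SMILES.
#' @param candidates character vector of candidate product SMILES.
#' @return the subset of `candidates` containing the substrate.
#' @export
substructure_postfilter <- function(substrate, candidates) {
  if (!length(candidates)) return(character(0))
  pat <- get_mol(substrate)
  keep <- vapply(candidates, function(cand)
    has_substructure(pat, get_mol(cand)), logical(1))
  candidates[keep]
}

# Typed subgraph monomorphism via LAD on bond-subdivided graphs: every bond
# becomes a vertex, so bond-type compatibility is expressed through vertex
# domains alongside atom compatibility.
has_substructure <- function(pat, tgt) {
  if (pat$n > tgt$n || nrow(pat$bonds) > nrow(tgt$bonds)) return(FALSE)
  g_p <- subdivided_graph(pat)
  g_t <- subdivided_graph(tgt)
  doms <- vector("list", pat$n + nrow(pat$bonds))
  for (a in seq_len(pat$n)) {
    ok <- which(tgt$elem == pat$elem[a] & tgt$arom == pat$arom[a] &
                tgt$charge == pat$charge[a] &
                lengths(tgt$adj) >= length(pat$adj[[a]]))
    if (!length(ok)) return(FALSE)
    doms[[a]] <- ok
  }
  for (k in seq_len(nrow(pat$bonds))) {
    ok <- which(tgt$bonds$order == pat$bonds$order[k]) + tgt$n
    if (!length(ok)) return(FALSE)
    doms[[pat$n + k]] <- ok
  }
  doms <- lapply(doms, function(d) igraph::V(g_t)[d])
  igraph::subgraph_isomorphic(g_p, g_t, method = "lad", induced = FALSE,
                              domains = doms)
}

subdivided_graph <- function(mol) {
  m <- nrow(mol$bonds)
  edges <- integer(0)
  for (k in seq_len(m)) {
    bv <- mol$n + k
    edges <- c(edges, mol$bonds$a1[k], bv, bv, mol$bonds$a2[k])
  }
  igraph::make_graph(edges, n = mol$n + m, directed = FALSE)
}
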