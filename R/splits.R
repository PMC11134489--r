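# Dataset splits. All splitting is by unique substrate, never by reaction
# record or site, so the same molecule can never leak between train and test.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split a site dataset by substrate
#'
#' Three splitting schemes:
#' \describe{
#'   \item{random}{seeded substrate-level shuffle with a held-out test
#'     fraction (default 10 percent); returns `train` / `test` subsets.}
#'   \item{ring_type}{`HET` / `CARB` partition by whether the substrate's
#'     experimentally reactive site(s) sit on a heterocyclic aromatic ring.
#'     Substrates reacting at both ring kinds go to `HET` with a warning;
#'     substrates with no reactive site go to `CARB`.}
#'   \item{ring_count}{`ONE` / `MULT` partition by whether the substrate has
#'     exactly one aromatic ring.}
#' }
#'
#' @param sites labeled site tibble (see [build_site_dataset()]); `ring_type`
#'   requires the `label` column.
#' @param kind `"random"`, `"ring_type"` or `"ring_count"`.
#' @param seed RNG seed for the random split.
#' @param test_fraction held-out fraction of substrates for the random split.
#' @return an object of class `borysite_split`: list with `assignment`
#'   (tibble `substrate`, `subset`) and `subsets` (named list of site
#'   tibbles).
#' @export
split_sites <- function(sites, kind = c("random", "ring_type", "ring_count"),
                        seed = 1, test_fraction = 0.1) {
  kind <- match.arg(kind)
  subs <- unique(sites$substrate)
  assignment <- switch(
    kind,
    random = {
      n_test <- max(1L, round(length(subs) * test_fraction))
      test <- local_seed(seed, sample(subs, n_test))
      tibble::tibble(
        substrate = subs,
        subset = ifelse(subs %in% test, "test", "train")
      )
    },
    ring_type = {
      if (!"label" %in% names(sites)) {
        stop("ring_type split needs labeled sites", call. = FALSE)
      }
      subset <- vapply(subs, function(s) {
        rows <- sites$substrate == s & sites$label == 1
        if (!any(rows)) return("CARB")
        het <- vapply(sites$site_atom[rows], function(a)
          ring_is_heterocyclic(s, a), logical(1))
        if (any(het) && any(!het)) {
          warning(sprintf(
            "substrate '%s' reacts at both ring kinds; assigned HET", s),
            call. = FALSE)
        }
        if (any(het)) "HET" else "CARB"
      }, character(1))
      tibble::tibble(substrate = subs, subset = unname(subset))
    },
    ring_count = tibble::tibble(
      substrate = subs,
      subset = ifelse(count_aromatic_rings(subs) == 1, "ONE", "MULT")
    )
  )
  subsets <- lapply(
    split(assignment$substrate, assignment$subset),
    function(members) sites[sites$substrate %in% members, , drop = FALSE]
  )
  structure(list(kind = kind, assignment = assignment, subsets = subsets),
            class = "borysite_split")
}

#' @export
print.borysite_split <- function(x, ...) {
  cat("substrate split (", x$kind, "):\n", sep = "")
  print(table(x$assignment$subset))
  invisible(x)
}
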