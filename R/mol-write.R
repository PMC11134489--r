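# SMILES writer for the internal graph. Output is not canonical by itself —
# molecule-level strings are re-canonicalized through OpenBabel; fragment
# (shingle) strings get their atom order from the package's own canonical
# ranking, which makes the written string deterministic.

# What a SMILES reader would infer for a bare (non-bracket) atom token.
inferred_hydrogens <- function(mol, a) {
  ords <- mol$bonds$order[mol$badj[[a]]]
  conn <- sum(ifelse(ords == 1.5, 1, ords))
  vals <- DEFAULT_VALENCES[[mol$elem[a]]]
  if (is.null(vals)) return(0L)
  if (mol$arom[a]) return(max(0L, as.integer(min(vals) - conn - 1L)))
  fit <- vals[vals >= conn]
  if (length(fit)) as.integer(fit[1] - conn) else 0L
}

atom_token <- function(mol, a, style = "smiles") {
  sym <- if (mol$arom[a]) tolower(mol$elem[a]) else mol$elem[a]
  organic <- mol$elem[a] %in% ORGANIC_SUBSET
  if (style == "shingle") {
    # hydrogen counts deliberately omitted from shingles
    if (mol$charge[a] == 0L && mol$iso[a] == 0L && organic) return(sym)
    chg <- format_charge(mol$charge[a])
    iso <- if (mol$iso[a] > 0L) mol$iso[a] else ""
    return(paste0("[", iso, sym, chg, "]"))
  }
  needs_bracket <- mol$charge[a] != 0L || mol$iso[a] > 0L || !organic ||
    inferred_hydrogens(mol, a) != mol$nH[a]
  if (!needs_bracket) return(sym)
  h <- if (mol$nH[a] == 0L) "" else if (mol$nH[a] == 1L) "H" else paste0("H", mol$nH[a])
  iso <- if (mol$iso[a] > 0L) mol$iso[a] else ""
  paste0("[", iso, sym, h, format_charge(mol$charge[a]), "]")
}

format_charge <- function(chg) {
  if (chg == 0L) ""
  else if (chg == 1L) "+"
  else if (chg == -1L) "-"
  else if (chg > 1L) paste0("+", chg)
  else paste0("-", abs(chg))
}

# bond symbols for all bonds at once; single bonds between two aromatic
# atoms need an explicit "-" so they do not read back as aromatic
bond_tokens <- function(mol) {
  ord <- mol$bonds$order
  tok <- rep("", length(ord))
  tok[ord == 2] <- "="
  tok[ord == 3] <- "#"
  tok[ord == 4] <- "$"
  tok[ord == 1 & mol$arom[mol$bonds$a1] & mol$arom[mol$bonds$a2]] <- "-"
  tok
}

# rank: integer vector, lower = visited earlier (both DFS roots and branches)
write_smiles <- function(mol, rank = seq_len(mol$n), style = "smiles") {
  n <- mol$n
  if (n == 0L) return("")
  visited <- logical(n)
  ring_digit <- new.env(parent = emptyenv())  # bond index -> digit
  digit_free <- rep(TRUE, 99)

  # adjacency pre-sorted by visit priority, one order() pass for the graph
  if (nrow(mol$bonds)) {
    he_a <- c(mol$bonds$a1, mol$bonds$a2)
    he_n <- c(mol$bonds$a2, mol$bonds$a1)
    he_b <- rep(seq_len(nrow(mol$bonds)), 2L)
    o <- order((he_a * (n + 1L) + rank[he_n]) * (n + 1L) + he_n)
    fa <- factor(he_a[o], levels = seq_len(n))
    sadj <- split(he_n[o], fa)
    sbadj <- split(he_b[o], fa)
  } else {
    sadj <- rep(list(integer(0)), n)
    sbadj <- rep(list(integer(0)), n)
  }
  btok <- bond_tokens(mol)

  # pass 1: find ring-closure (back) edges under the same DFS order
  tree_edge <- logical(nrow(mol$bonds))
  back_edges_at <- rep(list(integer(0)), n)
  seen <- logical(n)
  dfs_mark <- function(a, from_bond) {
    seen[a] <<- TRUE
    nb <- sadj[[a]]; bb <- sbadj[[a]]
    for (j in seq_along(nb)) {
      k <- bb[j]; w <- nb[j]
      if (k == from_bond) next
      if (!seen[w]) {
        tree_edge[k] <<- TRUE
        dfs_mark(w, k)
      } else if (!tree_edge[k] && !(k %in% back_edges_at[[a]]) &&
                 !(k %in% back_edges_at[[w]])) {
        back_edges_at[[a]] <<- c(back_edges_at[[a]], k)
        back_edges_at[[w]] <<- c(back_edges_at[[w]], k)
      }
    }
  }

  emit <- function(a, from_bond) {
    visited[a] <<- TRUE
    out <- atom_token(mol, a, style)
    # ring closures at this atom
    for (k in back_edges_at[[a]]) {
      key <- as.character(k)
      if (is.null(ring_digit[[key]])) {
        d <- which(digit_free)[1]
        digit_free[d] <<- FALSE
        ring_digit[[key]] <- d
      } else {
        d <- ring_digit[[key]]
        digit_free[d] <<- TRUE
      }
      dtok <- if (d < 10) as.character(d) else paste0("%", d)
      out <- paste0(out, btok[k], dtok)
    }
    nb <- sadj[[a]]; bb <- sbadj[[a]]
    kids <- list()
    for (j in seq_along(nb)) {
      k <- bb[j]; w <- nb[j]
      if (k == from_bond || !tree_edge[k] || visited[w]) next
      kids[[length(kids) + 1L]] <- paste0(btok[k], emit(w, k))
    }
    if (length(kids)) {
      if (length(kids) > 1L) {
        for (i in seq_len(length(kids) - 1L)) {
          out <- paste0(out, "(", kids[[i]], ")")
        }
      }
      out <- paste0(out, kids[[length(kids)]])
    }
    out
  }

  roots <- order(rank, seq_len(n))
  parts <- character(0)
  if (nrow(mol$bonds) < n) {
    # forest: every edge is a tree edge, no ring closures
    tree_edge[] <- TRUE
    seen[] <- TRUE
  } else {
    for (r in roots) {
      if (seen[r]) next
      dfs_mark(r, 0L)
    }
  }
  for (r in roots) {
    if (visited[r]) next
    parts <- c(parts, emit(r, 0L))
  }
  paste(parts, collapse = ".")
}
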