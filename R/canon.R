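# Canonical labeling of (rooted) vertex-colored molecular graphs -------------
#
# Atomic signatures are compared as strings, so rooted fragments that are
# isomorphic as rooted graphs must serialize identically.  We use iterative
# color refinement with individualization on ties: refinement colors are
# re-ranked from sorted signature strings each round (making color ids
# isomorphism-invariant); whenever the partition is not discrete, every
# vertex of the first non-singleton cell is individualized in turn and the
# lexicographically smallest serialization wins.  Fragments are small (a
# radius-2 ball), so the branching is negligible in practice.

atom_token <- function(element, charge, aromatic, nH, root = FALSE) {
  el <- if (aromatic) {
    paste0(tolower(substr(element, 1, 1)), substring(element, 2))
  } else {
    element
  }
  h <- if (nH > 0) paste0("H", nH) else ""
  chg <- if (charge > 0) {
    paste0("+", charge)
  } else if (charge < 0) {
    paste0("-", -charge)
  } else {
    ""
  }
  paste0("[", el, h, chg, if (root) ":1", "]")
}

parse_atom_token <- function(tok) {
  m <- regmatches(
    tok,
    regexec(
      "^\\[([A-Za-z][a-z]?)(?:H([0-9]+))?(?:([+-])([0-9]+)?)?(:1)?\\]$",
      tok
    )
  )[[1]]
  if (length(m) == 0) stop("bad atom token: ", tok)
  raw_el <- m[2]
  aromatic <- substr(raw_el, 1, 1) %in% letters
  element <- paste0(toupper(substr(raw_el, 1, 1)), substring(raw_el, 2))
  nH <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  charge <- if (nzchar(m[4])) {
    sign <- if (m[4] == "+") 1L else -1L
    sign * if (nzchar(m[5])) as.integer(m[5]) else 1L
  } else {
    0L
  }
  list(
    element = element, charge = charge, aromatic = aromatic, nH = nH,
    root = nzchar(m[6])
  )
}

# Adjacency list: for vertex v, adj[[v]] = data frame (nbr, order).
build_adj <- function(n, bonds) {
  adj <- rep(list(list(nbr = integer(), order = character())), n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
      adj[[i]]$order <- c(adj[[i]]$order, o)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
      adj[[j]]$order <- c(adj[[j]]$order, o)
    }
  }
  adj
}

refine_colors <- function(colors, adj) {
  n <- length(colors)
  repeat {
    # zero-padded ids keep string order equal to numeric order, so the
    # smallest class (the root, when rooted) stays rank 1 through rounds
    pad <- formatC(colors, width = 8, flag = "0")
    sigs <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      if (length(nb$nbr) == 0) {
        return(paste0(pad[v], "|"))
      }
      paste0(
        pad[v], "|",
        paste(sort(paste0(nb$order, ":", pad[nb$nbr])), collapse = ",")
      )
    }, "")
    new_colors <- match(sigs, sort(unique(sigs)))
    if (identical(new_colors, colors)) return(colors)
    if (length(unique(new_colors)) == length(unique(colors)) &&
        identical(
          match(new_colors, unique(new_colors)),
          match(colors, unique(colors))
        )) {
      return(new_colors)
    }
    colors <- new_colors
  }
}

serialize_ordering <- function(atoms, bonds, perm_pos, root_pos) {
  n <- nrow(atoms)
  ord <- order(perm_pos)
  toks <- vapply(ord, function(v) {
    atom_token(
      atoms$element[v], atoms$charge[v], atoms$aromatic[v], atoms$nH[v],
      root = !is.na(root_pos) && perm_pos[v] == root_pos
    )
  }, "")
  if (nrow(bonds) > 0) {
    bi <- perm_pos[bonds$a1] - 1L
    bj <- perm_pos[bonds$a2] - 1L
    lo <- pmin(bi, bj); hi <- pmax(bi, bj)
    key <- order(lo, hi, bonds$order)
    btxt <- paste(
      paste0(lo[key], "-", hi[key], "(", bonds$order[key], ")"),
      collapse = ","
    )
  } else {
    btxt <- ""
  }
  paste0(paste(toks, collapse = ""), "|", btxt)
}

canon_search <- function(colors, adj, atoms, bonds, rooted) {
  colors <- refine_colors(colors, adj)
  tab <- table(colors)
  non_singleton <- as.integer(names(tab)[tab > 1])
  if (length(non_singleton) == 0) {
    perm_pos <- rank(colors, ties.method = "first")
    return(serialize_ordering(
      atoms, bonds, perm_pos,
      root_pos = if (rooted) 1L else NA_integer_
    ))
  }
  cell <- which(colors == non_singleton[1])
  best <- NULL
  for (v in cell) {
    colors2 <- colors * 2L
    colors2[v] <- colors2[v] - 1L
    cand <- canon_search(colors2, adj, atoms, bonds, rooted)
    if (is.null(best) || cand < best) best <- cand
  }
  best
}

#' Canonical string of a (rooted) molecular graph
#'
#' @param atoms data frame with `element`, `charge`, `aromatic`, `nH`.
#' @param bonds data frame with `a1`, `a2` (1-based), `order`.
#' @param root 1-based root vertex index, or `NULL` for an unrooted graph.
#' @return canonical string; rooted graphs carry exactly one `:1` tag.
#' @keywords internal
canon_string <- function(atoms, bonds, root = NULL) {
  n <- nrow(atoms)
  stopifnot(n >= 1)
  adj <- build_adj(n, bonds)
  init <- vapply(seq_len(n), function(v) {
    paste0(
      if (!is.null(root) && v == root) "0|" else "1|",
      atoms$element[v], "/", atoms$charge[v], "/",
      as.integer(atoms$aromatic[v]), "/", atoms$nH[v]
    )
  }, "")
  colors <- match(init, sort(unique(init)))
  canon_search(colors, adj, atoms, bonds, rooted = !is.null(root))
}

#' Parse a canonical fragment string back into a graph
#'
#' Inverse of the serialization used by [canon_string()]: returns the atom
#' table, bond table and the root index (or `NA` if untagged).
#'
#' @param fragment canonical fragment string.
#' @return list with `atoms`, `bonds`, `root`.
#' @keywords internal
parse_fragment <- function(fragment) {
  parts <- strsplit(fragment, "|", fixed = TRUE)[[1]]
  atom_part <- parts[1]
  bond_part <- if (length(parts) > 1) parts[2] else ""
  toks <- regmatches(atom_part, gregexpr("\\[[^]]*\\]", atom_part))[[1]]
  recs <- lapply(toks, parse_atom_token)
  atoms <- data.frame(
    element = vapply(recs, `[[`, "", "element"),
    charge = vapply(recs, `[[`, 0L, "charge"),
    aromatic = vapply(recs, `[[`, TRUE, "aromatic"),
    nH = vapply(recs, `[[`, 0L, "nH"),
    stringsAsFactors = FALSE
  )
  root <- which(vapply(recs, `[[`, TRUE, "root"))
  if (nzchar(bond_part)) {
    btoks <- strsplit(bond_part, ",", fixed = TRUE)[[1]]
    m <- regmatches(
      btoks, regexec("^([0-9]+)-([0-9]+)\\(([^)]+)\\)$", btoks)
    )
    bonds <- data.frame(
      a1 = vapply(m, function(x) as.integer(x[2]), 0L) + 1L,
      a2 = vapply(m, function(x) as.integer(x[3]), 0L) + 1L,
      order = vapply(m, function(x) x[4], ""),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(
      a1 = integer(), a2 = integer(), order = character(),
      stringsAsFactors = FALSE
    )
  }
  list(
    atoms = atoms, bonds = bonds,
    root = if (length(root) == 1) root else NA_integer_
  )
}
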