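# Atomic and molecular signatures; consistency and graphicality checks -------

#' Atomic signature object
#'
#' The atomic signature of atom `x` at radius `r` is the subgraph of the
#' molecule induced by all atoms at graph distance at most `r` from `x`
#' (including ring-closure bonds between frontier atoms), written as a
#' canonical rooted fragment string with the root tagged `:1`.
#' Stereochemistry is excluded.  The object also carries the root atom's
#' attributes, its degree in the parent molecule, and one boundary bond
#' descriptor per bond incident to the root: `(source, order, target)` where
#' `source`/`target` are the radius-`(r-1)` signatures of the two endpoints.
#'
#' @name atomic_sig
#' @keywords internal
NULL

new_atomic_sig <- function(fragment, radius, root, degree, boundary) {
  structure(
    list(
      fragment = fragment, radius = as.integer(radius), root = root,
      degree = as.integer(degree), boundary = boundary
    ),
    class = "atomic_sig"
  )
}

#' @export
print.atomic_sig <- function(x, ...) {
  cat("<atomic_sig r=", x$radius, "> ", x$fragment, "\n", sep = "")
  invisible(x)
}

empty_boundary <- function() {
  data.frame(
    source = character(), order = character(), target = character(),
    stringsAsFactors = FALSE
  )
}

# distances from root, capped at `radius`; Inf for out-of-ball atoms
ball_distances <- function(n, adj, root, radius) {
  dist <- rep(Inf, n)
  dist[root] <- 0
  frontier <- root
  d <- 0
  while (length(frontier) > 0 && d < radius) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, function(v) adj[[v]]$nbr)))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

fragment_string <- function(mol, adj, root, radius) {
  dist <- ball_distances(nrow(mol$atoms), adj, root, radius)
  keep <- which(is.finite(dist))
  sub_atoms <- mol$atoms[keep, , drop = FALSE]
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  sub_bonds <- mol$bonds[bsel, , drop = FALSE]
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  sub_bonds$a1 <- remap[sub_bonds$a1]
  sub_bonds$a2 <- remap[sub_bonds$a2]
  canon_string(sub_atoms, sub_bonds, root = remap[root])
}

#' Atomic signature of one atom
#'
#' @param mol a `sig_mol`.
#' @param atom 1-based heavy-atom index.
#' @param radius environment radius (default 2).
#' @return an `atomic_sig` object.
#' @export
atomic_signature <- function(mol, atom, radius = 2L) {
  stopifnot(inherits(mol, "sig_mol"))
  n <- n_atoms(mol)
  if (!(atom %in% seq_len(n))) stop("atom index out of range")
  adj <- build_adj(n, mol$bonds)
  atomic_signature_impl(mol, adj, atom, radius)
}

atomic_signature_impl <- function(mol, adj, atom, radius,
                                  sub_cache = NULL) {
  frag <- fragment_string(mol, adj, atom, radius)
  nb <- adj[[atom]]
  if (radius >= 1 && length(nb$nbr) > 0) {
    sub_of <- function(v) {
      if (!is.null(sub_cache)) {
        sub_cache[[v]]
      } else {
        fragment_string(mol, adj, v, radius - 1L)
      }
    }
    src <- sub_of(atom)
    boundary <- data.frame(
      source = rep(src, length(nb$nbr)),
      order = nb$order,
      target = vapply(nb$nbr, sub_of, ""),
      stringsAsFactors = FALSE
    )
    ord <- order(boundary$target, boundary$order)
    boundary <- boundary[ord, , drop = FALSE]
    rownames(boundary) <- NULL
  } else {
    boundary <- empty_boundary()
  }
  new_atomic_sig(
    fragment = frag, radius = radius,
    root = as.list(mol$atoms[atom, c("element", "charge", "aromatic", "nH")]),
    degree = length(nb$nbr),
    boundary = boundary
  )
}

#' Rebuild an atomic signature object from its fragment string
#'
#' The boundary descriptors and root attributes are fully determined by the
#' fragment: the radius-`(r-1)` ball of the root and of each root neighbor
#' lie inside the radius-`r` ball, so they are recomputed within the parsed
#' fragment graph.
#'
#' @param fragment canonical rooted fragment string (with `:1` tag).
#' @param radius the radius the fragment was extracted at.
#' @return an `atomic_sig`.
#' @export
atomic_sig_from_fragment <- function(fragment, radius = 2L) {
  g <- parse_fragment(fragment)
  if (is.na(g$root)) stop("fragment has no :1 root tag")
  mol <- new_sig_mol(g$atoms, g$bonds, smiles = NA_character_)
  adj <- build_adj(nrow(g$atoms), g$bonds)
  sig <- atomic_signature_impl(mol, adj, g$root, radius)
  # fragment string must round-trip (the parsed graph is the whole ball)
  stopifnot(identical(sig$fragment, fragment))
  sig
}

#' Molecular signature of a molecule
#'
#' The multiset of atomic signatures of all heavy atoms, one member per
#' atom.
#'
#' @param mol a `sig_mol`.
#' @param radius environment radius (default 2).
#' @return a `mol_sig` object: list with `members` (list of `atomic_sig`)
#'   and `radius`.
#' @export
molecular_signature <- function(mol, radius = 2L) {
  stopifnot(inherits(mol, "sig_mol"))
  n <- n_atoms(mol)
  adj <- build_adj(n, mol$bonds)
  sub_cache <- if (radius >= 1) {
    lapply(seq_len(n), function(v) fragment_string(mol, adj, v, radius - 1L))
  } else {
    NULL
  }
  members <- lapply(seq_len(n), function(v) {
    atomic_signature_impl(mol, adj, v, radius, sub_cache = sub_cache)
  })
  structure(list(members = members, radius = as.integer(radius)),
            class = "mol_sig")
}

#' @export
print.mol_sig <- function(x, ...) {
  cat("<mol_sig r=", x$radius, "> ", length(x$members), " members\n",
      sep = "")
  tab <- sort(table(vapply(x$members, `[[`, "", "fragment")),
              decreasing = TRUE)
  for (i in seq_along(tab)) {
    cat("  ", tab[[i]], "x ", names(tab)[i], "\n", sep = "")
  }
  invisible(x)
}

#' Canonical key of a molecular signature
#'
#' Sorted member fragments joined by newlines; two molecular signatures are
#' equal as multisets iff their keys are equal.
#'
#' @param sig a `mol_sig`.
#' @return character key.
#' @export
sig_key <- function(sig) {
  paste(sort(vapply(sig$members, `[[`, "", "fragment")), collapse = "\n")
}

boundary_tally <- function(members, weights) {
  tal <- new.env(parent = emptyenv())
  for (i in seq_along(members)) {
    w <- weights[i]
    if (w == 0) next
    b <- members[[i]]$boundary
    if (nrow(b) == 0) next
    for (k in seq_len(nrow(b))) {
      key <- paste(b$source[k], b$order[k], b$target[k], sep = "\r")
      tal[[key]] <- (if (is.null(tal[[key]])) 0 else tal[[key]]) + w
    }
  }
  tal
}

#' Consistency equations (CE)
#'
#' A weighted multiset of atomic signatures is bond-consistent iff for every
#' directed boundary descriptor `(p, order, q)` the weighted count equals
#' the weighted count of the reversed descriptor `(q, order, p)`, and the
#' count of every self-paired descriptor `(p, order, p)` is even.
#'
#' @param members list of `atomic_sig`.
#' @param weights non-negative integer multiplicities (default all 1).
#' @return `TRUE` or `FALSE`.
#' @export
ce_holds <- function(members, weights = rep(1L, length(members))) {
  stopifnot(length(weights) == length(members), all(weights >= 0))
  tal <- boundary_tally(members, weights)
  for (key in ls(tal)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    if (parts[1] == parts[3]) {
      if (tal[[key]] %% 2 != 0) return(FALSE)
    } else {
      rev_key <- paste(parts[3], parts[2], parts[1], sep = "\r")
      rc <- if (is.null(tal[[rev_key]])) 0 else tal[[rev_key]]
      if (tal[[key]] != rc) return(FALSE)
    }
  }
  TRUE
}

#' Graphicality equation (GE)
#'
#' With `n_i` the weighted number of members whose root degree is `i`, a
#' connected graph can exist only if
#' `sum_{i>=2} (i - 2) n_i - n_1 + 2` is an even non-negative integer.
#'
#' @inheritParams ce_holds
#' @return `TRUE` or `FALSE`.
#' @export
ge_holds <- function(members, weights = rep(1L, length(members))) {
  stopifnot(length(weights) == length(members), all(weights >= 0))
  deg <- vapply(members, `[[`, 0L, "degree")
  n1 <- sum(weights[deg == 1])
  high <- deg >= 2
  value <- sum((deg[high] - 2) * weights[high]) - n1 + 2
  value >= 0 && value %% 2 == 0
}

#' Write / read molecular signatures as text
#'
#' One member class per line, `count<TAB>fragment`, preceded by a header
#' line `# radius=<r>`.
#'
#' @param sig a `mol_sig`.
#' @param path file path.
#' @return `path` invisibly / a `mol_sig`.
#' @export
write_mol_sig <- function(sig, path) {
  frags <- vapply(sig$members, `[[`, "", "fragment")
  tab <- table(frags)
  lines <- c(
    paste0("# radius=", sig$radius),
    paste0(as.integer(tab), "\t", names(tab))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mol_sig
#' @export
read_mol_sig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  radius <- as.integer(sub("^# radius=", "", lines[1]))
  members <- list()
  for (line in lines[-1]) {
    if (!nzchar(line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    cnt <- as.integer(parts[1])
    sig <- atomic_sig_from_fragment(parts[2], radius)
    members <- c(members, rep(list(sig), cnt))
  }
  structure(list(members = members, radius = radius), class = "mol_sig")
}
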