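# End-to-end inversion: ECFP -> molecular signatures -> flat graphs ->
# stereoisomers -> exact-fingerprint matches ---------------------------------

#' Reconstruction thresholds
#'
#' @param T step cap for the backtracking reconstruction (a step is one
#'   attempted bond placement).
#' @param restarts randomized restarts (with permuted node/pairing order)
#'   attempted when the step cap is hit.
#' @param stereo_cap_total total stereoisomer budget, divided evenly over
#'   the flat molecules of a query (minimum 1 each).
#' @return a `recon_thresholds` list.
#' @export
recon_thresholds <- function(T = 2e5, restarts = 10L,
                             stereo_cap_total = 2e5) {
  stopifnot(T >= 1, restarts >= 1, stereo_cap_total >= 1)
  structure(
    list(
      T = T, restarts = as.integer(restarts),
      stereo_cap_total = stereo_cap_total
    ),
    class = "recon_thresholds"
  )
}

#' Enumerate molecular signatures compatible with a fingerprint
#'
#' Restricts the alphabet to the candidate set for the query, builds the
#' Diophantine system, solves it, and emits one molecular signature per
#' surviving solution vector (candidate `j` with multiplicity `n_j`),
#' deduplicated as multisets.
#'
#' @param fp query `counted_fp`.
#' @param alphabet a `sig_alphabet` with matching generator settings.
#' @param thresholds a [solver_thresholds()].
#' @return list with `signatures` (list of `mol_sig`), `cap_hit` flag, and
#'   `solver` (the raw [solve_system()] result, with `n_candidates`).
#' @export
enumerate_signatures <- function(fp, alphabet,
                                 thresholds = solver_thresholds()) {
  cands <- candidates(alphabet, fp)
  if (length(cands) == 0 || length(fp$counts) == 0) {
    return(list(
      signatures = list(), cap_hit = FALSE,
      solver = list(
        solutions = list(), n_pe_solutions = 0L,
        orbit_sizes = integer(), truncated = FALSE, n_candidates = 0L
      )
    ))
  }
  system <- dio_system(cands, fp)
  res <- solve_system(system, thresholds)
  res$n_candidates <- length(cands)
  seen <- character()
  sigs <- list()
  for (v in res$solutions) {
    members <- list()
    for (j in which(v > 0)) {
      members <- c(members, rep(list(cands[[j]]$sig), v[j]))
    }
    ms <- structure(
      list(members = members, radius = alphabet$radius),
      class = "mol_sig"
    )
    key <- sig_key(ms)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      sigs[[length(sigs) + 1L]] <- ms
    }
  }
  list(signatures = sigs, cap_hit = res$truncated, solver = res)
}

# --- backtracking reconstruction over bond-descriptor pairings -------------

desc_keys <- function(sig) {
  b <- sig$boundary
  if (nrow(b) == 0) return(character())
  sort(paste(b$source, b$order, b$target, sep = "\r"))
}

reverse_key <- function(key) {
  p <- strsplit(key, "\r", fixed = TRUE)[[1]]
  paste(p[3], p[2], p[1], sep = "\r")
}

key_order <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]][2]

# Enumerate all connected graphs realizing the signature; returns raw
# graphs (atoms/bonds data frames).  A step is one attempted bond
# placement; exceeding `T` aborts the attempt.
reconstruct_graphs <- function(sig, thresholds = recon_thresholds()) {
  members <- sig$members
  n <- length(members)
  if (!ce_holds(members) || !ge_holds(members)) {
    stop("input molecular signature violates CE or GE")
  }
  atoms <- data.frame(
    element = vapply(members, function(m) m$root$element, ""),
    charge = vapply(members, function(m) m$root$charge, 0L),
    aromatic = vapply(members, function(m) m$root$aromatic, TRUE),
    nH = vapply(members, function(m) m$root$nH, 0L),
    stringsAsFactors = FALSE
  )
  frag_of <- vapply(members, `[[`, "", "fragment")
  target_key <- sig_key(sig)

  if (n == 1) {
    if (members[[1]]$degree != 0) {
      return(list(graphs = list(), cap_hit = FALSE))
    }
    g <- list(atoms = atoms, bonds = data.frame(
      a1 = integer(), a2 = integer(), order = character(),
      stringsAsFactors = FALSE
    ))
    return(list(graphs = list(g), cap_hit = FALSE))
  }

  found <- new.env(parent = emptyenv())
  steps <- 0L
  cap_hit_any <- FALSE

  attempt <- function(node_perm) {
    remaining0 <- lapply(members, desc_keys)[node_perm]
    frag_p <- frag_of[node_perm]
    atoms_p <- atoms[node_perm, , drop = FALSE]
    rownames(atoms_p) <- NULL
    aborted <- FALSE

    search <- function(remaining, edges, adj) {
      if (aborted) return()
      open_nodes <- which(lengths(remaining) > 0)
      if (length(open_nodes) == 0) {
        bonds <- if (length(edges) > 0) {
          do.call(rbind, lapply(edges, function(e) {
            data.frame(
              a1 = e[[1]], a2 = e[[2]], order = e[[3]],
              stringsAsFactors = FALSE
            )
          }))
        } else {
          data.frame(
            a1 = integer(), a2 = integer(), order = character(),
            stringsAsFactors = FALSE
          )
        }
        g <- list(atoms = atoms_p, bonds = bonds)
        if (!graph_connected(n, bonds)) return()
        gm <- new_sig_mol(g$atoms, g$bonds, smiles = NA_character_)
        if (!identical(sig_key(molecular_signature(gm, sig$radius)),
                       target_key)) {
          return()
        }
        ckey <- canon_string(g$atoms, g$bonds, root = NULL)
        if (is.null(found[[ckey]])) found[[ckey]] <- g
        return()
      }
      # fail-first: the open node with the fewest legal partners for its
      # first unconsumed descriptor
      partner_sets <- lapply(open_nodes, function(u) {
        d <- remaining[[u]][1]
        rk <- reverse_key(d)
        vs <- open_nodes[vapply(open_nodes, function(v) {
          v != u && !(v %in% adj[[u]]) && rk %in% remaining[[v]]
        }, TRUE)]
        vs
      })
      pick <- which.min(lengths(partner_sets))
      u <- open_nodes[pick]
      partners <- partner_sets[[pick]]
      if (length(partners) == 0) return()
      d <- remaining[[u]][1]
      rk <- reverse_key(d)
      ord <- key_order(d)
      # interchangeability pruning: untouched partners with identical
      # fragment and identical remaining multiset are symmetric; keep one
      sig_seen <- character()
      for (v in partners) {
        if (length(adj[[v]]) == 0) {
          vsig <- paste(frag_p[v], paste(remaining[[v]], collapse = ","))
          if (vsig %in% sig_seen) next
          sig_seen <- c(sig_seen, vsig)
        }
        steps <<- steps + 1L
        if (steps > thresholds$T) {
          aborted <<- TRUE
          return()
        }
        rem2 <- remaining
        rem2[[u]] <- rem2[[u]][-1]
        vi <- match(rk, rem2[[v]])
        rem2[[v]] <- rem2[[v]][-vi]
        adj2 <- adj
        adj2[[u]] <- c(adj2[[u]], v)
        adj2[[v]] <- c(adj2[[v]], u)
        search(rem2, c(edges, list(list(min(u, v), max(u, v), ord))), adj2)
        if (aborted) return()
      }
    }
    search(remaining0, list(), rep(list(integer()), n))
    aborted
  }

  perm <- seq_len(n)
  for (try in seq_len(thresholds$restarts)) {
    steps <- 0L
    aborted <- attempt(perm)
    if (!aborted) break
    cap_hit_any <- TRUE
    set.seed(try)
    perm <- sample.int(n)
  }

  graphs <- as.list(found)
  names(graphs) <- NULL
  list(graphs = graphs, cap_hit = cap_hit_any && aborted)
}

graph_connected <- function(n, bonds) {
  if (n == 1) return(TRUE)
  if (nrow(bonds) == 0) return(FALSE)
  adj <- build_adj(n, bonds)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]$nbr
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

graphs_to_molecules <- function(graphs) {
  if (length(graphs) == 0) return(list())
  payload <- lapply(graphs, function(g) {
    list(
      atoms = lapply(seq_len(nrow(g$atoms)), function(i) {
        list(
          element = g$atoms$element[i], charge = g$atoms$charge[i],
          aromatic = g$atoms$aromatic[i], nH = g$atoms$nH[i]
        )
      }),
      bonds = lapply(seq_len(nrow(g$bonds)), function(k) {
        list(
          a1 = g$bonds$a1[k] - 1L, a2 = g$bonds$a2[k] - 1L,
          order = g$bonds$order[k]
        )
      })
    )
  })
  res <- bridge_call(list(list(op = "mol_from_graph", graphs = payload)))[[1]]
  smiles <- vapply(res, function(r) {
    if (isTRUE(r$ok)) r$smiles else NA_character_
  }, "")
  ok <- !is.na(smiles)
  keep <- ok & !duplicated(smiles)
  parse_smiles(smiles[keep])
}

#' Reconstruct flat molecules from a molecular signature
#'
#' Instantiates one node per signature member (element, charge, aromaticity
#' and hydrogen count taken from the root atom), derives the allowed bonds
#' from matching boundary descriptors (`u`--`v` with order `b` is allowed
#' iff `u` carries descriptor `(sigma_u, b, sigma_v)` and `v` the reverse),
#' and backtracks over descriptor pairings.  Accepted graphs are connected
#' and have a radius-`r` molecular signature exactly equal to the input;
#' results are deduplicated by canonical form.
#'
#' @param sig a `mol_sig` satisfying CE and GE.
#' @param thresholds a [recon_thresholds()].
#' @return list with `molecules` (list of flat `sig_mol`) and `cap_hit`
#'   flag.
#' @export
reconstruct_molecules <- function(sig, thresholds = recon_thresholds()) {
  res <- reconstruct_graphs(sig, thresholds)
  list(
    molecules = graphs_to_molecules(res$graphs),
    cap_hit = res$cap_hit
  )
}

#' Expand flat molecules into stereoisomers
#'
#' Enumerates the stereoisomers over unassigned stereocenters of each flat
#' molecule, up to `ceiling(stereo_cap_total / n_flats)` isomers each
#' (minimum 1), and deduplicates by canonical isomeric SMILES.
#'
#' @param flats list of flat `sig_mol` (deduplicated).
#' @param thresholds a [recon_thresholds()].
#' @return list with `molecules` (list of `sig_mol`) and `cap_hit` flag.
#' @export
expand_stereo <- function(flats, thresholds = recon_thresholds()) {
  if (length(flats) == 0) return(list(molecules = list(), cap_hit = FALSE))
  cap <- max(1, ceiling(thresholds$stereo_cap_total / length(flats)))
  res <- bridge_call(list(list(
    op = "stereo_enum",
    smiles = json_vec(vapply(flats, canonicalize, "")),
    max_isomers = cap, only_unassigned = TRUE
  )))[[1]]
  cap_hit <- any(vapply(res, function(r) length(r$isomers) >= cap, TRUE))
  smiles <- unique(unlist(lapply(res, function(r) unlist(r$isomers))))
  list(molecules = parse_smiles(smiles), cap_hit = cap_hit)
}

#' Invert a counted ECFP into molecules
#'
#' Full pipeline: signature enumeration (Diophantine solving), graph
#' reconstruction, stereoisomer expansion, and exact counted-fingerprint
#' matching.  Deterministic whenever no cap flag is raised.
#'
#' @param fp query `counted_fp`.
#' @param alphabet a `sig_alphabet` with matching generator settings.
#' @param solver a [solver_thresholds()].
#' @param recon a [recon_thresholds()].
#' @return list with `signatures`, `flat_molecules`, `stereo_molecules`,
#'   `matched` (each fingerprint-exact match, canonical), and `status`
#'   (flags `partition_cap_hit`, `reconstruction_cap_hit`,
#'   `stereo_cap_hit`).
#' @export
invert_ecfp <- function(fp, alphabet, solver = solver_thresholds(),
                        recon = recon_thresholds()) {
  enum <- enumerate_signatures(fp, alphabet, solver)
  recon_cap <- FALSE
  graphs <- list()
  for (ms in enum$signatures) {
    r <- reconstruct_graphs(ms, recon)
    recon_cap <- recon_cap || r$cap_hit
    graphs <- c(graphs, r$graphs)
  }
  flats <- graphs_to_molecules(graphs)
  st <- expand_stereo(flats, recon)
  matched <- list()
  if (length(st$molecules) > 0) {
    fps <- counted_ecfp(
      st$molecules, fp$radius, fp$nbits, fp$chirality
    )
    hit <- vapply(fps, function(x) fp_equal(x, fp), TRUE)
    matched <- st$molecules[hit]
  }
  list(
    signatures = enum$signatures,
    flat_molecules = flats,
    stereo_molecules = st$molecules,
    matched = matched,
    status = list(
      partition_cap_hit = enum$cap_hit,
      reconstruction_cap_hit = recon_cap,
      stereo_cap_hit = st$cap_hit
    )
  )
}
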