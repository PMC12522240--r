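# Linear Diophantine solver: per-bit integer partitions, orbit decomposition,
# compatibility-checked combination, CE/GE filtering ------------------------

#' Solver thresholds
#'
#' `T` bounds the search per equation: at most `T / 100` integer partitions
#' are kept per partition equation (smallest solution norms first) and at
#' most `T` candidate-assignment expansions are generated per partition.
#' When any bound truncates the search the solver flags the run as possibly
#' incomplete.
#'
#' @param T master threshold (default `2e5`).
#' @return a `solver_thresholds` list with `partitions_cap` and
#'   `permutations_cap`.
#' @export
solver_thresholds <- function(T = 2e5) {
  stopifnot(T >= 100)
  structure(
    list(
      T = T,
      partitions_cap = max(1L, as.integer(T / 100)),
      permutations_cap = max(1L, as.integer(T))
    ),
    class = "solver_thresholds"
  )
}

#' Integer partitions with restricted parts
#'
#' Enumerates the partitions of `n` into parts drawn from `allowed_parts`
#' (unbounded multiplicity), as non-increasing integer vectors.  With all
#' parts `1..n` this enumerates the unrestricted partition function `p(n)`.
#' When `cap` truncates the output, partitions with fewer parts (smaller
#' solution norm) are kept first.
#'
#' @param n non-negative integer to partition.
#' @param allowed_parts positive integer part values (duplicates ignored).
#' @param cap maximum number of partitions returned (`Inf` for all).
#' @return list with `partitions` (list of integer vectors; `n = 0` yields
#'   one empty partition) and `truncated` flag.
#' @export
integer_partitions <- function(n, allowed_parts = seq_len(max(n, 1)),
                               cap = Inf) {
  stopifnot(n >= 0)
  parts <- sort(unique(as.integer(allowed_parts)), decreasing = TRUE)
  stopifnot(all(parts >= 1) || n == 0)
  acc <- list()
  recurse <- function(remaining, max_part_idx, prefix) {
    if (remaining == 0) {
      acc[[length(acc) + 1L]] <<- prefix
      return()
    }
    for (k in seq_along(parts)) {
      if (k < max_part_idx) next
      p <- parts[k]
      if (p > remaining) next
      recurse(remaining - p, k, c(prefix, p))
    }
  }
  recurse(n, 1L, integer())
  truncated <- FALSE
  if (is.finite(cap) && length(acc) > cap) {
    acc <- acc[order(lengths(acc))][seq_len(cap)]
    truncated <- TRUE
  }
  list(partitions = acc, truncated = truncated)
}

#' Diophantine system over atomic signature candidates
#'
#' Binds a candidate list (alphabet entries) to a target fingerprint: the
#' coefficient of candidate `j` at bit `i` is the number of times bit `i`
#' occurs in the candidate's bit multiset, and one partition equation is
#' instantiated per non-zero bit of the target.
#'
#' @param cands list of alphabet entries (see [candidates()]).
#' @param fp target `counted_fp`.
#' @return a `dio_system`: list with `cands`, `fp`, `pe_bits` (0-based bit
#'   indices), `coef` (dense matrix, candidates x equations).
#' @export
dio_system <- function(cands, fp) {
  pe_bits <- fp_support(fp)
  l <- length(cands)
  coef <- matrix(
    0L, nrow = l, ncol = length(pe_bits),
    dimnames = list(NULL, as.character(pe_bits))
  )
  for (j in seq_len(l)) {
    tb <- table(cands[[j]]$bits)
    if (!all(names(tb) %in% colnames(coef))) {
      stop(
        "candidate ", j, " carries bits outside the target support; ",
        "apply candidates() before building the system"
      )
    }
    coef[j, names(tb)] <- as.integer(tb)
  }
  structure(
    list(cands = cands, fp = fp, pe_bits = pe_bits, coef = coef),
    class = "dio_system"
  )
}

#' Solutions of a single partition equation
#'
#' Solves `sum_j n_j * c_j = target` over non-negative integers with
#' `n_j = 0` forced for candidates inactive at the bit, by enumerating
#' integer partitions of the target into the active coefficient values and
#' then distributing the parts of each partition over the candidates that
#' carry each value in all distinct ways.
#'
#' @param system a `dio_system`.
#' @param bit 0-based bit index (must be one of the system's equations).
#' @param thresholds a [solver_thresholds()].
#' @return list with `solutions` (list of length-`l` integer vectors) and
#'   `truncated` flag.
#' @export
solve_pe <- function(system, bit, thresholds = solver_thresholds()) {
  col <- as.character(bit)
  stopifnot(col %in% colnames(system$coef))
  target <- unname(system$fp$counts[[col]])
  cvec <- system$coef[, col]
  active <- which(cvec > 0)
  l <- nrow(system$coef)
  if (length(active) == 0) {
    return(list(solutions = list(), truncated = FALSE))
  }
  values <- unique(cvec[active])
  pp <- integer_partitions(target, values, cap = thresholds$partitions_cap)
  truncated <- pp$truncated
  solutions <- list()
  for (lambda in pp$partitions) {
    mult <- table(lambda)
    # distribute m identical parts of value v over the candidates with
    # coefficient v: all weak compositions
    per_value <- lapply(names(mult), function(v) {
      js <- active[cvec[active] == as.integer(v)]
      compositions_of(as.integer(mult[[v]]), length(js), js)
    })
    expanded <- Reduce(
      function(a, b) {
        out <- list()
        for (x in a) for (y in b) out[[length(out) + 1L]] <- c(x, y)
        out
      },
      per_value,
      accumulate = FALSE
    )
    if (length(solutions) + length(expanded) > thresholds$permutations_cap) {
      keep <- max(0L, thresholds$permutations_cap - length(solutions))
      expanded <- expanded[seq_len(keep)]
      truncated <- TRUE
    }
    for (assign in expanded) {
      v <- integer(l)
      v[as.integer(names(assign))] <- unname(assign)
      solutions[[length(solutions) + 1L]] <- v
    }
    if (truncated && length(solutions) >= thresholds$permutations_cap) break
  }
  list(solutions = solutions, truncated = truncated)
}

# all weak compositions of m into k named slots; returns list of named
# integer vectors (names = slot ids)
compositions_of <- function(m, k, ids) {
  if (k == 1) {
    return(list(stats::setNames(m, ids)))
  }
  out <- list()
  for (first in 0:m) {
    rest <- compositions_of(m - first, k - 1L, ids[-1])
    for (r in rest) {
      out[[length(out) + 1L]] <- c(stats::setNames(first, ids[1]), r)
    }
  }
  out
}

#' Orbit decomposition of a Diophantine system
#'
#' Candidates `j`, `k` are linked whenever some bit has non-zero
#' coefficients for both; the transitive closure (union-find) partitions
#' the candidate indices into orbits.  Partition equations couple only
#' within an orbit.
#'
#' @param system a `dio_system`.
#' @return list of orbits, each a list with `indices` (candidate indices)
#'   and `bits` (0-based bit indices active in the orbit).
#' @export
orbits <- function(system) {
  l <- nrow(system$coef)
  parent <- seq_len(l)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  for (col in seq_len(ncol(system$coef))) {
    act <- which(system$coef[, col] > 0)
    if (length(act) > 1) {
      for (k in act[-1]) union_(act[1], k)
    }
  }
  roots <- vapply(seq_len(l), find, 0L)
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    cols <- which(colSums(system$coef[idx, , drop = FALSE] > 0) > 0)
    list(
      indices = idx,
      bits = as.integer(colnames(system$coef)[cols])
    )
  })
}

#' Combine per-bit solutions within one orbit
#'
#' Folds the orbit's bits in ascending order.  Two partial vectors are
#' compatible when they agree on every candidate constrained by both sides;
#' compatible pairs merge by elementwise maximum.  The fold is associative
#' and order-independent.
#'
#' @param per_bit named list (names = bit indices as characters) of per-bit
#'   solution lists as returned by [solve_pe()]`$solutions`.
#' @param orbit one element of [orbits()].
#' @param coef the system coefficient matrix.
#' @return list of length-`l` integer vectors satisfying all the orbit's
#'   equations.
#' @export
combine_within_orbit <- function(per_bit, orbit, coef) {
  bits <- sort(orbit$bits)
  acc <- NULL       # list of list(vec, fixed)
  for (bit in bits) {
    col <- as.character(bit)
    active <- coef[, col] > 0
    incoming <- lapply(per_bit[[col]], function(v) {
      list(vec = v, fixed = active)
    })
    if (is.null(acc)) {
      acc <- incoming
      next
    }
    merged <- list()
    for (u in acc) {
      for (v in incoming) {
        both <- u$fixed & v$fixed
        if (any(both) && !all(u$vec[both] == v$vec[both])) next
        merged[[length(merged) + 1L]] <- list(
          vec = pmax(u$vec, v$vec),
          fixed = u$fixed | v$fixed
        )
      }
    }
    acc <- merged
    if (length(acc) == 0) break
  }
  if (is.null(acc)) acc <- list()
  lapply(acc, `[[`, "vec")
}

#' Combine orbit solution sets across orbits
#'
#' Orbits have disjoint candidate supports, so no compatibility check is
#' needed: the result is the Cartesian combination by elementwise maximum,
#' and its size is the product of the orbit set sizes.
#'
#' @param orbit_sets list of solution lists, one per orbit.
#' @return list of combined solution vectors (empty if any set is empty).
#' @export
combine_across_orbits <- function(orbit_sets) {
  if (length(orbit_sets) == 0) return(list())
  Reduce(
    function(a, b) {
      out <- list()
      for (u in a) for (v in b) out[[length(out) + 1L]] <- pmax(u, v)
      out
    },
    orbit_sets
  )
}

#' Filter partition-equation solutions by CE and GE
#'
#' Keeps the solution vectors whose weighted candidate multisets satisfy
#' the consistency equations and the graphicality equation.
#'
#' @param sols list of solution vectors.
#' @param system a `dio_system`.
#' @return list of surviving solution vectors.
#' @export
filter_solutions <- function(sols, system) {
  members <- lapply(system$cands, `[[`, "sig")
  Filter(
    function(v) ce_holds(members, v) && ge_holds(members, v),
    sols
  )
}

#' Solve the full (PE, CE, GE) system
#'
#' Runs the staged pipeline: per-bit partition solving, orbit
#' decomposition, within-orbit compatibility folding, across-orbit
#' combination, and CE/GE filtering.  Every returned vector is
#' re-substituted into all partition equations as a defensive check.
#'
#' @param system a `dio_system`.
#' @param thresholds a [solver_thresholds()].
#' @return list with `solutions` (list of integer vectors over candidates),
#'   `n_pe_solutions` (size of the PE solution set before CE/GE),
#'   `orbit_sizes` (per-orbit solution counts), `truncated` flag.
#' @export
solve_system <- function(system, thresholds = solver_thresholds()) {
  l <- nrow(system$coef)
  if (length(system$pe_bits) == 0 || l == 0) {
    return(list(
      solutions = list(), n_pe_solutions = 0L, orbit_sizes = integer(),
      truncated = FALSE
    ))
  }
  # a bit with no active candidate is unsatisfiable
  if (any(colSums(system$coef > 0) == 0)) {
    return(list(
      solutions = list(), n_pe_solutions = 0L, orbit_sizes = integer(),
      truncated = FALSE
    ))
  }
  truncated <- FALSE
  per_bit <- stats::setNames(
    vector("list", length(system$pe_bits)),
    as.character(system$pe_bits)
  )
  for (bit in system$pe_bits) {
    res <- solve_pe(system, bit, thresholds)
    truncated <- truncated || res$truncated
    per_bit[[as.character(bit)]] <- res$solutions
  }
  orbs <- orbits(system)
  orbit_sets <- lapply(orbs, function(o) {
    combine_within_orbit(per_bit, o, system$coef)
  })
  pe_sols <- combine_across_orbits(orbit_sets)
  # defensive re-substitution: every PE must hold exactly
  ok <- vapply(pe_sols, function(v) {
    all(as.integer(v %*% system$coef) == unname(system$fp$counts))
  }, TRUE)
  stopifnot(all(ok))
  list(
    solutions = filter_solutions(pe_sols, system),
    n_pe_solutions = length(pe_sols),
    orbit_sizes = lengths(orbit_sets),
    truncated = truncated
  )
}
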