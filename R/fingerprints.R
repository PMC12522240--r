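# Counted Morgan/ECFP fingerprints and per-atom bit attribution --------------

#' Counted extended-connectivity fingerprint
#'
#' A `counted_fp` stores the sparse non-negative integer count vector of a
#' counted ECFP: `counts` is a named integer vector (names are 0-based bit
#' indices, values are counts > 0), plus the generator settings `radius`,
#' `nbits`, `chirality`.
#'
#' @param counts named integer vector of positive counts; names are 0-based
#'   bit indices in `[0, nbits)`.
#' @param radius,nbits,chirality generator settings.
#' @return A `counted_fp` object.
#' @export
counted_fp <- function(counts, radius = 2L, nbits = 2048L,
                       chirality = TRUE) {
  counts <- counts[order(as.integer(names(counts)))]
  storage.mode(counts) <- "integer"
  stopifnot(
    all(counts > 0) || length(counts) == 0,
    all(as.integer(names(counts)) >= 0),
    all(as.integer(names(counts)) < nbits)
  )
  structure(
    list(
      counts = counts, radius = as.integer(radius),
      nbits = as.integer(nbits), chirality = isTRUE(chirality)
    ),
    class = "counted_fp"
  )
}

#' @export
print.counted_fp <- function(x, ...) {
  cat(
    "<counted_fp> r=", x$radius, " nbits=", x$nbits,
    if (x$chirality) " chiral" else "",
    ": ", length(x$counts), " non-zero bits, total ", fp_total(x), "\n",
    sep = ""
  )
  invisible(x)
}

#' Support and total of a counted fingerprint
#'
#' `fp_support()` returns the 0-based indices with positive count,
#' `fp_total()` the sum of all counts.
#'
#' @param fp a `counted_fp`.
#' @return integer vector / integer.
#' @export
fp_support <- function(fp) as.integer(names(fp$counts))

#' @rdname fp_support
#' @export
fp_total <- function(fp) sum(fp$counts)

fp_meta_equal <- function(a, b) {
  a$radius == b$radius && a$nbits == b$nbits && a$chirality == b$chirality
}

fp_equal <- function(a, b) {
  fp_meta_equal(a, b) && identical(a$counts, b$counts)
}

counts_from_bridge <- function(lst) {
  if (length(lst) == 0) {
    return(stats::setNames(integer(), character()))
  }
  stats::setNames(
    vapply(lst, as.integer, 0L),
    names(lst)
  )
}

#' Counted ECFP of molecules
#'
#' Computes the counted Morgan/extended-connectivity fingerprint: each heavy
#' atom hashes its circular environments of radius 0..`radius` into bit
#' indices; the count vector accumulates one unit per surviving environment
#' (structurally duplicated environments within a molecule are emitted only
#' once, so the total can be less than `(radius + 1) * n_atoms`).
#'
#' @param mols list of `sig_mol` (or a single one).
#' @param radius environment radius (default 2, i.e. ECFP4).
#' @param nbits fingerprint length (default 2048).
#' @param chirality include stereochemistry in the hashed invariants
#'   (default `TRUE`).
#' @return list of `counted_fp` (a single input returns a single
#'   `counted_fp`).
#' @export
counted_ecfp <- function(mols, radius = 2L, nbits = 2048L, chirality = TRUE) {
  single <- inherits(mols, "sig_mol")
  if (single) mols <- list(mols)
  if (length(mols) == 0) return(list())
  res <- bridge_call(list(list(
    op = "fingerprint",
    smiles = json_vec(vapply(mols, canonicalize, "")),
    radius = radius, nbits = nbits, chirality = chirality
  )))[[1]]
  out <- lapply(res, function(rec) {
    if (!isTRUE(rec$ok)) stop("fingerprint failed: invalid molecule")
    counted_fp(counts_from_bridge(rec$counts), radius, nbits, chirality)
  })
  if (single) out[[1]] else out
}

#' Per-atom Morgan bit attribution
#'
#' For each heavy atom, the multiset of bit indices generated by that atom's
#' environments (with multiplicity).  The generator deduplicates structurally
#' identical environments within a molecule, attributing each surviving
#' environment to exactly one root atom, so summing the per-atom multisets
#' reproduces the molecule fingerprint exactly (the partition-equation
#' identity).
#'
#' @inheritParams counted_ecfp
#' @return list (one per molecule) of lists with elements `fp` (the
#'   `counted_fp`) and `per_atom` (list over atoms; each element an integer
#'   vector of 0-based bit indices, repeated by multiplicity, ascending).  A
#'   single `sig_mol` input returns a single attribution record.
#' @export
attribute_bits <- function(mols, radius = 2L, nbits = 2048L,
                           chirality = TRUE) {
  single <- inherits(mols, "sig_mol")
  if (single) mols <- list(mols)
  if (length(mols) == 0) return(list())
  res <- bridge_call(list(list(
    op = "fingerprint",
    smiles = json_vec(vapply(mols, canonicalize, "")),
    radius = radius, nbits = nbits, chirality = chirality, bitinfo = TRUE
  )))[[1]]
  out <- lapply(seq_along(res), function(i) {
    rec <- res[[i]]
    if (!isTRUE(rec$ok)) stop("fingerprint failed: invalid molecule")
    fp <- counted_fp(counts_from_bridge(rec$counts), radius, nbits, chirality)
    per_atom <- vector("list", n_atoms(mols[[i]]))
    for (k in seq_along(per_atom)) per_atom[[k]] <- integer()
    for (bit in names(rec$bitinfo)) {
      for (hit in rec$bitinfo[[bit]]) {
        a <- as.integer(hit[[1]]) + 1L
        per_atom[[a]] <- c(per_atom[[a]], as.integer(bit))
      }
    }
    per_atom <- lapply(per_atom, sort)
    n_attr <- sum(lengths(per_atom))
    if (n_attr != fp_total(fp)) {
      stop("bit attribution does not conserve the fingerprint total")
    }
    list(fp = fp, per_atom = per_atom)
  })
  if (single) out[[1]] else out
}

#' Fingerprint text rendering
#'
#' A counted fingerprint is rendered as the whitespace-separated list of its
#' non-zero bit positions in ascending order, each repeated according to its
#' count; the empty fingerprint renders as the empty string.
#'
#' @param fp a `counted_fp`.
#' @return character string.
#' @export
fp_to_string <- function(fp) {
  stopifnot(inherits(fp, "counted_fp"))
  paste(rep(fp_support(fp), times = fp$counts), collapse = " ")
}

#' @rdname fp_to_string
#' @param text whitespace-separated bit indices (repeated by count).
#' @param radius,nbits,chirality generator settings of the rendered
#'   fingerprint.
#' @export
fp_from_string <- function(text, radius = 2L, nbits = 2048L,
                           chirality = TRUE) {
  toks <- strsplit(trimws(text), "[ \t]+")[[1]]
  toks <- toks[nzchar(toks)]
  idx <- suppressWarnings(as.integer(toks))
  if (any(is.na(idx))) stop("fingerprint string contains non-integer tokens")
  if (any(idx < 0 | idx >= nbits)) {
    stop("fingerprint string contains out-of-range bit indices")
  }
  tab <- table(idx)
  counted_fp(
    stats::setNames(as.integer(tab), names(tab)),
    radius, nbits, chirality
  )
}

#' Sparse JSON interchange form of a fingerprint
#'
#' @param fp a `counted_fp`.
#' @return JSON string `{"nbits":...,"radius":...,"chirality":...,
#'   "counts":{"bit":count,...}}`.
#' @export
fp_to_json <- function(fp) {
  jsonlite::toJSON(
    list(
      nbits = fp$nbits, radius = fp$radius, chirality = fp$chirality,
      counts = as.list(fp$counts)
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname fp_to_json
#' @param json JSON string produced by [fp_to_json()].
#' @export
fp_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  counted_fp(
    stats::setNames(as.integer(obj$counts), names(obj$counts)),
    obj$radius, obj$nbits, obj$chirality
  )
}
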