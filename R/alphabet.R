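# Alphabet: (Morgan-bit multiset, atomic signature) tuples -------------------

entry_key <- function(bits, fragment) {
  paste(fragment, paste(bits, collapse = " "), sep = "\r")
}

new_alphabet <- function(entries, radius, nbits, chirality, n_molecules) {
  structure(
    list(
      entries = entries, radius = as.integer(radius),
      nbits = as.integer(nbits), chirality = isTRUE(chirality),
      n_molecules = as.integer(n_molecules)
    ),
    class = "sig_alphabet"
  )
}

#' @export
print.sig_alphabet <- function(x, ...) {
  cat(
    "<sig_alphabet> ", length(x$entries), " entries (r=", x$radius,
    ", nbits=", x$nbits, if (x$chirality) ", chiral", ") from ",
    x$n_molecules, " molecules\n",
    sep = ""
  )
  invisible(x)
}

sort_entries <- function(entries) {
  frag <- vapply(entries, function(e) e$sig$fragment, "")
  bits <- vapply(entries, function(e) paste(e$bits, collapse = " "), "")
  entries[order(frag, bits)]
}

#' Build an alphabet from molecules
#'
#' For every heavy atom of every molecule, pairs the multiset of Morgan bits
#' that atom generates (with multiplicity, after within-molecule environment
#' deduplication) with the atom's canonical radius-`r` atomic signature.
#' Occurrence counts accumulate over atoms; entries are unique by
#' (bit multiset, signature) and sorted deterministically, so building twice
#' from the same input yields identical files.
#'
#' @param mols list of sanitized `sig_mol`.
#' @param radius,nbits,chirality fingerprint generator settings.
#' @return a `sig_alphabet`.
#' @export
build_alphabet <- function(mols, radius = 2L, nbits = 2048L,
                           chirality = TRUE) {
  if (inherits(mols, "sig_mol")) mols <- list(mols)
  reg <- new.env(parent = emptyenv())
  if (length(mols) > 0) {
    attrib <- attribute_bits(mols, radius, nbits, chirality)
    for (i in seq_along(mols)) {
      ms <- molecular_signature(mols[[i]], radius)
      per_atom <- attrib[[i]]$per_atom
      for (a in seq_along(per_atom)) {
        sig <- ms$members[[a]]
        bits <- per_atom[[a]]
        key <- entry_key(bits, sig$fragment)
        cur <- reg[[key]]
        if (is.null(cur)) {
          reg[[key]] <- list(bits = bits, sig = sig, n = 1L)
        } else {
          cur$n <- cur$n + 1L
          reg[[key]] <- cur
        }
      }
    }
  }
  entries <- sort_entries(as.list(reg))
  names(entries) <- NULL
  new_alphabet(entries, radius, nbits, chirality, length(mols))
}

#' Merge two alphabets
#'
#' Union of entries with summed occurrence counts; generator settings must
#' agree.
#'
#' @param a,b `sig_alphabet` objects with identical radius, nbits and
#'   chirality settings.
#' @return a `sig_alphabet`.
#' @export
merge_alphabets <- function(a, b) {
  stopifnot(inherits(a, "sig_alphabet"), inherits(b, "sig_alphabet"))
  if (a$radius != b$radius || a$nbits != b$nbits ||
      a$chirality != b$chirality) {
    stop("alphabet generator settings mismatch")
  }
  reg <- new.env(parent = emptyenv())
  for (e in c(a$entries, b$entries)) {
    key <- entry_key(e$bits, e$sig$fragment)
    cur <- reg[[key]]
    if (is.null(cur)) {
      reg[[key]] <- e
    } else {
      cur$n <- cur$n + e$n
      reg[[key]] <- cur
    }
  }
  entries <- sort_entries(as.list(reg))
  names(entries) <- NULL
  new_alphabet(entries, a$radius, a$nbits, a$chirality,
               a$n_molecules + b$n_molecules)
}

#' Atomic signature candidates for a query fingerprint
#'
#' Restricts an alphabet to the candidate set for a query: first to entries
#' whose counted bit multiset fits elementwise under the query counts, then
#' iteratively removes entries having any boundary bond descriptor whose
#' reversed descriptor appears in no remaining entry, until a fixed point.
#' The result is the unique maximal subset with the reverse-closure
#' property.
#'
#' @param alphabet a `sig_alphabet`.
#' @param fp a `counted_fp` with matching generator settings.
#' @return list of entries (possibly empty), in the alphabet's order.
#' @export
candidates <- function(alphabet, fp) {
  stopifnot(inherits(alphabet, "sig_alphabet"), inherits(fp, "counted_fp"))
  if (alphabet$radius != fp$radius || alphabet$nbits != fp$nbits ||
      alphabet$chirality != fp$chirality) {
    stop("fingerprint and alphabet generator settings mismatch")
  }
  fits <- vapply(alphabet$entries, function(e) {
    tb <- table(e$bits)
    have <- fp$counts[names(tb)]
    !anyNA(have) && all(as.integer(tb) <= have)
  }, TRUE)
  kept <- alphabet$entries[fits]
  repeat {
    present <- unique(unlist(lapply(kept, function(e) {
      b <- e$sig$boundary
      if (nrow(b) == 0) character() else
        paste(b$source, b$order, b$target, sep = "\r")
    })))
    ok <- vapply(kept, function(e) {
      b <- e$sig$boundary
      if (nrow(b) == 0) return(TRUE)
      all(paste(b$target, b$order, b$source, sep = "\r") %in% present)
    }, TRUE)
    if (all(ok)) break
    kept <- kept[ok]
  }
  kept
}

#' Pielou's evenness of an alphabet
#'
#' Normalized Shannon entropy `J = -sum(p_k log p_k) / log(S)` of the entry
#' occurrence frequencies, with `S` the number of entries; `J = 1` for a
#' single entry by convention.
#'
#' @param alphabet a non-empty `sig_alphabet`.
#' @return numeric in `[0, 1]`.
#' @export
pielou_evenness <- function(alphabet) {
  stopifnot(inherits(alphabet, "sig_alphabet"))
  s <- length(alphabet$entries)
  if (s == 0) stop("empty alphabet")
  if (s == 1) return(1)
  n <- vapply(alphabet$entries, `[[`, 0L, "n")
  p <- n / sum(n)
  -sum(p * log(p)) / log(s)
}

# per-molecule entry keys, computed once (shared by growth_curve)
molecule_entry_keys <- function(mols, radius, nbits, chirality) {
  attrib <- attribute_bits(mols, radius, nbits, chirality)
  lapply(seq_along(mols), function(i) {
    ms <- molecular_signature(mols[[i]], radius)
    vapply(seq_along(attrib[[i]]$per_atom), function(a) {
      entry_key(attrib[[i]]$per_atom[[a]], ms$members[[a]]$fragment)
    }, "")
  })
}

#' Alphabet growth curve under subsampling
#'
#' For each step size, draws `repeats` random subsamples of the molecule
#' list (seeded) and records the mean number of distinct alphabet entries;
#' the marginal rate column reports new entries per additional molecule
#' between consecutive steps.
#'
#' @param mols list of sanitized `sig_mol`.
#' @param step_sizes increasing sample sizes (each `<= length(mols)`).
#' @param repeats subsamples per step.
#' @param seed integer RNG seed.
#' @param radius,nbits,chirality fingerprint generator settings.
#' @return data frame with `n_molecules`, `mean_alphabet_size`,
#'   `new_entries_per_molecule`.
#' @export
growth_curve <- function(mols, step_sizes, repeats = 3L, seed = 1L,
                         radius = 2L, nbits = 2048L, chirality = TRUE) {
  stopifnot(all(step_sizes >= 1), all(step_sizes <= length(mols)))
  keys <- molecule_entry_keys(mols, radius, nbits, chirality)
  mean_sizes <- vapply(step_sizes, function(s) {
    sizes <- vapply(seq_len(repeats), function(rep) {
      set.seed(seed * 10000L + s + rep)
      idx <- sample.int(length(mols), s)
      length(unique(unlist(keys[idx])))
    }, 0)
    mean(sizes)
  }, 0)
  rate <- diff(c(0, mean_sizes)) / diff(c(0, step_sizes))
  data.frame(
    n_molecules = step_sizes,
    mean_alphabet_size = mean_sizes,
    new_entries_per_molecule = rate
  )
}

#' Descriptor duplication histogram
#'
#' Groups molecules by identical descriptor value (molecular signature key
#' or counted-ECFP string) and tabulates group sizes: how many descriptor
#' classes are shared by exactly `k` molecules.
#'
#' @param mols list of sanitized, deduplicated `sig_mol`.
#' @param descriptor `"signature"` or `"ecfp"`.
#' @param radius,nbits,chirality descriptor settings (`nbits`/`chirality`
#'   apply to `"ecfp"` only).
#' @return data frame with `duplication` (group size) and `frequency`
#'   (number of descriptor classes of that size).
#' @export
duplication_histogram <- function(mols, descriptor = c("signature", "ecfp"),
                                  radius = 2L, nbits = 2048L,
                                  chirality = TRUE) {
  descriptor <- match.arg(descriptor)
  vals <- if (descriptor == "signature") {
    vapply(mols, function(m) sig_key(molecular_signature(m, radius)), "")
  } else {
    vapply(counted_ecfp(mols, radius, nbits, chirality), fp_to_string, "")
  }
  sizes <- table(table(vals))
  data.frame(
    duplication = as.integer(names(sizes)),
    frequency = as.integer(sizes)
  )
}

#' Write / read an alphabet as JSON lines
#'
#' First line is a metadata header; each following line is one entry
#' `{"bits":[...],"sig":"<fragment>","n":<occurrences>}` with bits sorted
#' ascending and repeated by count.  Entries are written in the alphabet's
#' deterministic sort order, so identical alphabets produce byte-identical
#' files.
#'
#' @param alphabet a `sig_alphabet`.
#' @param path file path (`.jsonl`).
#' @return `path` invisibly / a `sig_alphabet`.
#' @export
write_alphabet <- function(alphabet, path) {
  header <- jsonlite::toJSON(
    list(
      format = "sigenum-alphabet", version = 1L,
      radius = alphabet$radius, nbits = alphabet$nbits,
      chirality = alphabet$chirality, n_molecules = alphabet$n_molecules
    ),
    auto_unbox = TRUE
  )
  lines <- vapply(alphabet$entries, function(e) {
    as.character(jsonlite::toJSON(
      list(bits = I(e$bits), sig = e$sig$fragment, n = e$n),
      auto_unbox = TRUE
    ))
  }, "")
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_alphabet
#' @export
read_alphabet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "sigenum-alphabet")) {
    stop("not a sigenum alphabet file")
  }
  entries <- lapply(lines[-1], function(line) {
    obj <- jsonlite::fromJSON(line)
    list(
      bits = as.integer(obj$bits),
      sig = atomic_sig_from_fragment(obj$sig, header$radius),
      n = as.integer(obj$n)
    )
  })
  new_alphabet(
    entries, header$radius, header$nbits, header$chirality,
    header$n_molecules
  )
}

#' Export an alphabet as TSV
#'
#' Columns: space-separated bit multiset, fragment string, occurrences.
#'
#' @param alphabet a `sig_alphabet`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_alphabet_tsv <- function(alphabet, path) {
  df <- data.frame(
    bits = vapply(alphabet$entries, function(e) {
      paste(e$bits, collapse = " ")
    }, ""),
    signature = vapply(alphabet$entries, function(e) e$sig$fragment, ""),
    occurrences = vapply(alphabet$entries, `[[`, 0L, "n")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
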