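# Molecule objects, sanitization, canonicalization ---------------------------

#' Molecule object
#'
#' A `sig_mol` is a light heavy-atom graph: an `atoms` data frame (`element`,
#' `charge`, `aromatic`, `nH` = total hydrogen count), a `bonds` data frame
#' (`a1`, `a2` 1-based atom indices, `order` in `"1"`, `"2"`, `"3"`, `"ar"`),
#' and the canonical isomeric SMILES string in `smiles`.  Stereochemistry
#' lives only in the SMILES; the graph carries the flat connectivity used by
#' atomic signatures.
#'
#' @param atoms,bonds,smiles components as described above.
#' @return An object of class `sig_mol`.
#' @keywords internal
new_sig_mol <- function(atoms, bonds, smiles) {
  structure(
    list(atoms = atoms, bonds = bonds, smiles = smiles),
    class = "sig_mol"
  )
}

sig_mol_from_bridge <- function(rec) {
  atoms <- data.frame(
    element = vapply(rec$atoms, function(a) a$element, ""),
    charge = vapply(rec$atoms, function(a) as.integer(a$charge), 0L),
    aromatic = vapply(rec$atoms, function(a) isTRUE(a$aromatic), TRUE),
    nH = vapply(rec$atoms, function(a) as.integer(a$nH), 0L),
    stringsAsFactors = FALSE
  )
  if (length(rec$bonds) > 0) {
    bonds <- data.frame(
      a1 = vapply(rec$bonds, function(b) as.integer(b$a1), 0L) + 1L,
      a2 = vapply(rec$bonds, function(b) as.integer(b$a2), 0L) + 1L,
      order = vapply(rec$bonds, function(b) b$order, ""),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(
      a1 = integer(), a2 = integer(), order = character(),
      stringsAsFactors = FALSE
    )
  }
  new_sig_mol(atoms, bonds, rec$smiles)
}

#' @export
print.sig_mol <- function(x, ...) {
  cat(
    "<sig_mol> ", x$smiles, " (", nrow(x$atoms), " heavy atoms, ",
    nrow(x$bonds), " bonds)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of heavy atoms of a molecule
#' @param mol a `sig_mol`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Parse SMILES strings into molecule objects
#'
#' Parses without applying any acceptance rules (isotopes are still cleared,
#' as the canonical form is isotope-free by convention).  Unparseable inputs
#' yield `NULL` entries.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of `sig_mol` (or `NULL` for unparseable input).
#' @export
parse_smiles <- function(smiles) {
  if (length(smiles) == 0) return(list())
  res <- bridge_call(list(list(op = "parse", smiles = json_vec(smiles))))[[1]]
  lapply(res, function(rec) {
    if (!isTRUE(rec$ok)) NULL else sig_mol_from_bridge(rec)
  })
}

#' Sanitization configuration
#'
#' Acceptance rules applied when preparing a molecule collection: molecules
#' must be fully connected, weigh strictly less than `mw_max` daltons (set
#' `mw_max = NULL` to disable the weight rule), and contain no wildcard
#' (unspecified-element) atoms.  Isotope labels are always cleared.  With
#' `complete_stereo = TRUE`, molecules with unassigned stereocenters are
#' completed by deterministically selecting one full stereoisomer.
#'
#' @param mw_max maximum molecular weight in daltons (strict upper bound),
#'   or `NULL` for no weight restriction.
#' @param require_connected reject multi-fragment inputs.
#' @param forbid_wildcards reject molecules containing atoms of unspecified
#'   element (atomic number 0).
#' @param complete_stereo complete partially specified stereochemistry.
#' @param stereo_seed integer seed controlling which stereoisomer is chosen.
#' @return A `sanitize_config` list.
#' @export
sanitize_config <- function(mw_max = 500, require_connected = TRUE,
                            forbid_wildcards = TRUE, complete_stereo = FALSE,
                            stereo_seed = 0L) {
  if (!is.null(mw_max)) stopifnot(mw_max > 0)
  structure(
    list(
      mw_max = mw_max,
      require_connected = isTRUE(require_connected),
      forbid_wildcards = isTRUE(forbid_wildcards),
      complete_stereo = isTRUE(complete_stereo),
      stereo_seed = as.integer(stereo_seed)
    ),
    class = "sanitize_config"
  )
}

#' Sanitize SMILES inputs
#'
#' Applies the dataset-preparation rules of [sanitize_config()] to a batch of
#' SMILES strings.  Accepted molecules are returned canonicalized; rejected
#' ones are reported with a machine-readable reason code (`parse_error`,
#' `multi_fragment`, `overweight`, `wildcard`).
#'
#' @param smiles character vector of SMILES strings.
#' @param config a [sanitize_config()].
#' @return list with `molecules` (list of accepted `sig_mol`), `accepted`
#'   (logical vector over inputs) and `rejections` (data frame `input`,
#'   `reason`).
#' @export
sanitize <- function(smiles, config = sanitize_config()) {
  stopifnot(inherits(config, "sanitize_config"))
  if (length(smiles) == 0) {
    return(list(
      molecules = list(), accepted = logical(),
      rejections = data.frame(
        input = character(), reason = character(), stringsAsFactors = FALSE
      )
    ))
  }
  res <- bridge_call(list(list(op = "parse", smiles = json_vec(smiles))))[[1]]
  reason <- character(length(smiles))
  for (i in seq_along(res)) {
    rec <- res[[i]]
    reason[i] <- if (!isTRUE(rec$ok)) {
      "parse_error"
    } else if (config$require_connected && rec$n_frags > 1) {
      "multi_fragment"
    } else if (config$forbid_wildcards && isTRUE(rec$has_wildcard)) {
      "wildcard"
    } else if (!is.null(config$mw_max) && rec$mw >= config$mw_max) {
      "overweight"
    } else {
      ""
    }
  }
  accepted <- !nzchar(reason)
  mols <- lapply(which(accepted), function(i) sig_mol_from_bridge(res[[i]]))
  if (config$complete_stereo) {
    needs <- vapply(
      which(accepted),
      function(i) res[[i]]$n_unassigned_stereo > 0, TRUE
    )
    if (any(needs)) {
      mols[needs] <- complete_stereo(mols[needs], seed = config$stereo_seed)
    }
  }
  list(
    molecules = mols,
    accepted = accepted,
    rejections = data.frame(
      input = smiles[!accepted],
      reason = reason[!accepted],
      stringsAsFactors = FALSE
    )
  )
}

#' Canonical isomeric SMILES of a molecule
#'
#' Deterministic: identical graphs with identical stereochemistry yield
#' identical strings, and the function is idempotent through reparsing.
#'
#' @param mol a `sig_mol`.
#' @return character canonical SMILES.
#' @export
canonicalize <- function(mol) {
  stopifnot(inherits(mol, "sig_mol"))
  mol$smiles
}

#' Complete unassigned stereocenters
#'
#' Molecules with partially or fully unassigned stereocenters are completed
#' by enumerating the stereoisomers of the unassigned centers, sorting their
#' canonical SMILES, and picking the entry indexed by the seed.  Fully
#' assigned (or achiral) molecules are returned unchanged.
#'
#' @param mols list of `sig_mol` (or a single one).
#' @param seed integer; the same seed always selects the same isomer.
#' @return list of `sig_mol` of the same length (a single input returns a
#'   single `sig_mol`).
#' @export
complete_stereo <- function(mols, seed = 0L) {
  single <- inherits(mols, "sig_mol")
  if (single) mols <- list(mols)
  if (length(mols) == 0) return(mols)
  smiles <- vapply(mols, canonicalize, "")
  res <- bridge_call(list(list(
    op = "stereo_enum", smiles = json_vec(smiles),
    max_isomers = 1024, only_unassigned = TRUE
  )))[[1]]
  chosen <- vapply(seq_along(res), function(i) {
    iso <- unlist(res[[i]]$isomers)
    if (length(iso) <= 1) return(smiles[i])
    iso[(as.integer(seed) %% length(iso)) + 1L]
  }, "")
  changed <- chosen != smiles
  out <- mols
  if (any(changed)) out[changed] <- parse_smiles(chosen[changed])
  if (single) out[[1]] else out
}

#' Read a SMILES file
#'
#' One molecule per line; an optional whitespace-separated identifier after
#' the SMILES is ignored.  Blank lines are skipped.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smiles <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[[`, "", 1)
}

#' Write molecules to a SMILES file
#' @param mols list of `sig_mol` or character vector of SMILES.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(mols, path) {
  smiles <- if (is.character(mols)) mols else vapply(mols, canonicalize, "")
  writeLines(smiles, path)
  invisible(path)
}

#' Write a rejection report as TSV
#' @param rejections data frame with `input` and `reason` columns.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rejections <- function(rejections, path) {
  utils::write.table(
    rejections, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
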