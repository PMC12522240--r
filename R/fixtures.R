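# Deterministic fixture molecules and round-trip evaluation ------------------

#' The packaged worked example
#'
#' The 2-methyl-1,8-octanediol molecule used throughout the documentation,
#' with its milestone constants: number of non-zero fingerprint components,
#' fingerprint total, number of partition equations, molecular signature
#' size, stereoisomer count of the flat skeleton, and number of exact
#' fingerprint matches.
#'
#' @return list with `smiles` and `expected` (named list of constants).
#' @export
worked_example <- function() {
  list(
    smiles = "C[C@H](CO)CCCCCCO",
    expected = list(
      nonzero = 18L, total = 30L, pe_count = 18L, sig_size = 11L,
      stereo_count = 2L, matched = 1L
    )
  )
}

#' Fixture generation parameters
#'
#' Controls the built-in fragment grammar: chain lengths, the fraction of
#' ring-bearing molecules, the fraction of deliberately repetitive
#' (symmetric / near-linear) molecules that stress the multi-solution
#' cases, and the heteroatom menu.
#'
#' @param chain_range min/max heavy-chain length.
#' @param ring_fraction fraction of molecules grown from a ring template.
#' @param symmetric_fraction fraction of plain unbranched chains (repeated
#'   local environments).
#' @param heteroatoms substituent atom menu.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(chain_range = c(3L, 8L), ring_fraction = 0.3,
                         symmetric_fraction = 0.2,
                         heteroatoms = c("O", "N", "S")) {
  structure(
    list(
      chain_range = as.integer(chain_range),
      ring_fraction = ring_fraction,
      symmetric_fraction = symmetric_fraction,
      heteroatoms = heteroatoms
    ),
    class = "fixture_spec"
  )
}

ring_templates <- c(
  "C1CCCCC1", "C1CCCC1", "c1ccccc1", "C1CCOC1", "C1CCNC1", "C1CCCCO1",
  "c1ccncc1", "C1CCSC1"
)

random_smiles <- function(spec) {
  hetero <- spec$heteroatoms
  sub_menu <- c(hetero, "C", "C(C)C", "C=C", "CO", "CN", "C(=O)O", "C#N")
  u <- stats::runif(1)
  if (u < spec$symmetric_fraction) {
    # plain chain, optionally heteroatom-terminated on both ends
    len <- sample(seq(spec$chain_range[1], spec$chain_range[2] + 2), 1)
    ends <- sample(c("", hetero), 2, replace = TRUE)
    return(paste0(ends[1], strrep("C", len), ends[2]))
  }
  if (u < spec$symmetric_fraction + spec$ring_fraction) {
    ring <- sample(ring_templates, 1)
    n_sub <- sample(0:2, 1)
    if (n_sub == 0) return(ring)
    subs <- sample(sub_menu, n_sub, replace = TRUE)
    # attach substituents after the ring-opening atom
    core <- sub("1", paste0("1(", subs[1], ")"), ring)
    if (n_sub == 2) core <- paste0(core, subs[2])
    return(core)
  }
  len <- sample(seq(spec$chain_range[1], spec$chain_range[2]), 1)
  atoms <- sample(c(rep("C", 6), hetero), len, replace = TRUE)
  smi <- atoms[1]
  for (i in seq_len(len - 1)) {
    branch <- stats::runif(1) < 0.25 && atoms[i] == "C"
    if (branch) {
      smi <- paste0(smi, "(", sample(sub_menu, 1), ")")
    }
    bond <- if (stats::runif(1) < 0.1 && atoms[i] == "C" &&
                atoms[i + 1] == "C") "=" else ""
    smi <- paste0(smi, bond, atoms[i + 1])
  }
  smi
}

#' Generate a deterministic fixture set
#'
#' Assembles candidate SMILES from a seeded fragment grammar (alkyl chains,
#' small rings, heteroatom substituents), filters them through [sanitize()]
#' with default rules plus stereo completion, and deduplicates by canonical
#' form until `n` molecules are collected.  Regeneration with the same seed
#' and spec is byte-identical.
#'
#' @param n number of molecules.
#' @param seed integer RNG seed.
#' @param spec a [fixture_spec()].
#' @return a `fixture_set`: list with `molecules` (list of `sig_mol`),
#'   `smiles`, `seed`, `spec`.
#' @export
generate_fixture_set <- function(n, seed = 1L, spec = fixture_spec()) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  cfg <- sanitize_config(complete_stereo = TRUE, stereo_seed = seed)
  mols <- list()
  seen <- character()
  rounds <- 0L
  while (length(mols) < n) {
    rounds <- rounds + 1L
    if (rounds > 200L) {
      stop("fixture grammar could not produce ", n, " unique molecules")
    }
    batch_n <- max(16L, 2L * (n - length(mols)))
    raw <- vapply(seq_len(batch_n), function(i) random_smiles(spec), "")
    sz <- sanitize(raw, cfg)
    for (m in sz$molecules) {
      if (length(mols) >= n) break
      if (!(m$smiles %in% seen)) {
        seen <- c(seen, m$smiles)
        mols[[length(mols) + 1L]] <- m
      }
    }
  }
  structure(
    list(
      molecules = mols,
      smiles = vapply(mols, canonicalize, ""),
      seed = as.integer(seed), spec = spec
    ),
    class = "fixture_set"
  )
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("<fixture_set> ", length(x$molecules), " molecules (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Round-trip recovery over a fixture set
#'
#' Builds the alphabet from the fixture molecules themselves, inverts each
#' member's counted fingerprint, and marks a member recovered iff its
#' canonical form appears among the exact-fingerprint matches.  The
#' pipeline is staged so that toolkit calls are batched across queries.
#'
#' @param fixture a `fixture_set` (or plain list of `sig_mol`).
#' @param radius,nbits,chirality fingerprint generator settings.
#' @param solver a [solver_thresholds()].
#' @param recon a [recon_thresholds()].
#' @param alphabet optional prebuilt `sig_alphabet`; defaults to the
#'   alphabet of the fixture itself.
#' @return list with `rate` (recovered fraction) and `per_molecule` data
#'   frame (`smiles`, `recovered`, `n_matched`, `n_signatures`, `n_flats`,
#'   and the three cap flags).
#' @export
roundtrip_recovery <- function(fixture, radius = 2L, nbits = 2048L,
                               chirality = TRUE,
                               solver = solver_thresholds(),
                               recon = recon_thresholds(),
                               alphabet = NULL) {
  mols <- if (inherits(fixture, "fixture_set")) fixture$molecules else fixture
  stopifnot(length(mols) >= 1)
  if (is.null(alphabet)) {
    alphabet <- build_alphabet(mols, radius, nbits, chirality)
  }
  fps <- counted_ecfp(mols, radius, nbits, chirality)

  # stage 1: R-side signature enumeration + graph reconstruction
  n <- length(mols)
  all_graphs <- list()
  graph_query <- integer()
  n_sigs <- integer(n)
  part_cap <- logical(n)
  recon_cap <- logical(n)
  for (i in seq_len(n)) {
    enum <- enumerate_signatures(fps[[i]], alphabet, solver)
    n_sigs[i] <- length(enum$signatures)
    part_cap[i] <- enum$cap_hit
    for (ms in enum$signatures) {
      r <- reconstruct_graphs(ms, recon)
      recon_cap[i] <- recon_cap[i] || r$cap_hit
      if (length(r$graphs) > 0) {
        all_graphs <- c(all_graphs, r$graphs)
        graph_query <- c(graph_query, rep(i, length(r$graphs)))
      }
    }
  }

  # stage 2: graphs -> canonical flat SMILES (one bridge call)
  flat_smiles_all <- rep(NA_character_, length(all_graphs))
  if (length(all_graphs) > 0) {
    payload <- lapply(all_graphs, function(g) {
      list(
        atoms = lapply(seq_len(nrow(g$atoms)), function(k) {
          list(
            element = g$atoms$element[k], charge = g$atoms$charge[k],
            aromatic = g$atoms$aromatic[k], nH = g$atoms$nH[k]
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
    res <- bridge_call(list(list(op = "mol_from_graph",
                                 graphs = payload)))[[1]]
    flat_smiles_all <- vapply(res, function(r) {
      if (isTRUE(r$ok)) r$smiles else NA_character_
    }, "")
  }
  flats_by_query <- lapply(seq_len(n), function(i) {
    unique(stats::na.omit(flat_smiles_all[graph_query == i]))
  })
  n_flats <- lengths(flats_by_query)

  # stage 3: stereo expansion of the unique flat molecules (one call)
  uniq_flats <- unique(unlist(flats_by_query))
  stereo_cap <- logical(n)
  iso_by_flat <- list()
  if (length(uniq_flats) > 0) {
    cap <- max(1, ceiling(recon$stereo_cap_total / max(1, max(n_flats))))
    res <- bridge_call(list(list(
      op = "stereo_enum", smiles = json_vec(uniq_flats),
      max_isomers = cap, only_unassigned = TRUE
    )))[[1]]
    iso_by_flat <- stats::setNames(
      lapply(res, function(r) unlist(r$isomers)),
      uniq_flats
    )
    hit_cap_flat <- vapply(res, function(r) length(r$isomers) >= cap, TRUE)
    for (i in seq_len(n)) {
      stereo_cap[i] <- any(hit_cap_flat[match(flats_by_query[[i]],
                                              uniq_flats)])
    }
  }

  # stage 4: fingerprints of all unique isomers (one call)
  uniq_iso <- unique(unlist(iso_by_flat))
  iso_fp_str <- character(0)
  if (length(uniq_iso) > 0) {
    res <- bridge_call(list(list(
      op = "fingerprint", smiles = json_vec(uniq_iso),
      radius = radius, nbits = nbits, chirality = chirality
    )))[[1]]
    iso_fp_str <- vapply(res, function(r) {
      fp_to_string(counted_fp(counts_from_bridge(r$counts),
                              radius, nbits, chirality))
    }, "")
    names(iso_fp_str) <- uniq_iso
  }

  # stage 5: per-query exact matching and recovery
  query_smiles <- vapply(mols, canonicalize, "")
  recovered <- logical(n)
  n_matched <- integer(n)
  for (i in seq_len(n)) {
    isomers <- unique(unlist(iso_by_flat[flats_by_query[[i]]]))
    if (length(isomers) == 0) next
    matched <- isomers[iso_fp_str[isomers] == fp_to_string(fps[[i]])]
    n_matched[i] <- length(matched)
    recovered[i] <- query_smiles[i] %in% matched
  }
  list(
    rate = mean(recovered),
    per_molecule = data.frame(
      smiles = query_smiles,
      recovered = recovered,
      n_matched = n_matched,
      n_signatures = n_sigs,
      n_flats = n_flats,
      partition_cap_hit = part_cap,
      reconstruction_cap_hit = recon_cap,
      stereo_cap_hit = stereo_cap,
      stringsAsFactors = FALSE
    )
  )
}
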