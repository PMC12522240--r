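test_that("signature enumeration recovers the self-consistent signature", {
  enum <- enumerate_signatures(worked_fp(), worked_alphabet())
  expect_false(enum$cap_hit)
  expect_equal(length(enum$signatures), 1L)
  expect_equal(length(enum$signatures[[1]]$members), 11L)
  expect_equal(
    sig_key(enum$signatures[[1]]),
    sig_key(molecular_signature(worked_mol()))
  )
})

test_that("an all-zero fingerprint enumerates nothing", {
  empty <- counted_fp(stats::setNames(integer(), character()))
  enum <- enumerate_signatures(empty, worked_alphabet())
  expect_equal(length(enum$signatures), 0L)
})

test_that("reconstruction returns exactly the generating skeletons", {
  methane <- parse_smiles("C")[[1]]
  rec <- reconstruct_molecules(molecular_signature(methane))
  expect_equal(vapply(rec$molecules, canonicalize, ""), "C")

  flat <- reconstruct_molecules(molecular_signature(worked_mol()))
  expect_false(flat$cap_hit)
  expect_equal(length(flat$molecules), 1L)
  expect_equal(canonicalize(flat$molecules[[1]]), "CC(CO)CCCCCCO")

  benzene <- parse_smiles("c1ccccc1")[[1]]
  rb <- reconstruct_molecules(molecular_signature(benzene))
  expect_equal(vapply(rb$molecules, canonicalize, ""), "c1ccccc1")
})

test_that("reconstructed graphs reproduce the input signature exactly", {
  for (m in fixture_small()$molecules[1:10]) {
    ms <- molecular_signature(m)
    rec <- reconstruct_molecules(ms)
    expect_gte(length(rec$molecules), 1L)
    for (flat in rec$molecules) {
      expect_equal(sig_key(molecular_signature(flat)), sig_key(ms))
    }
  }
})

test_that("reconstruction rejects CE/GE-violating input", {
  ethanol <- parse_smiles("CCO")[[1]]
  broken <- molecular_signature(ethanol)
  broken$members <- broken$members[1]
  expect_error(reconstruct_graphs(broken), "CE or GE")
})

test_that("stereo expansion enumerates unassigned centers and dedups", {
  worked_flat <- parse_smiles("CC(CO)CCCCCCO")
  st <- expand_stereo(worked_flat)
  expect_equal(length(st$molecules), 2L)
  expect_false(any(duplicated(vapply(st$molecules, canonicalize, ""))))

  achiral <- parse_smiles("CCO")
  expect_equal(
    vapply(expand_stereo(achiral)$molecules, canonicalize, ""), "CCO"
  )

  two_centers <- parse_smiles("CC(O)C(N)C")
  expect_equal(length(expand_stereo(two_centers)$molecules), 4L)
})

test_that("stereo caps divide the budget and raise the flag", {
  two_centers <- parse_smiles("CC(O)C(N)C")
  st <- expand_stereo(two_centers, recon_thresholds(stereo_cap_total = 2))
  expect_equal(length(st$molecules), 2L)
  expect_true(st$cap_hit)
})

test_that("full inversion returns the query and only the query", {
  res <- invert_ecfp(worked_fp(), worked_alphabet())
  expect_equal(length(res$signatures), 1L)
  expect_equal(length(res$flat_molecules), 1L)
  expect_equal(length(res$stereo_molecules), 2L)
  expect_equal(length(res$matched), 1L)
  expect_equal(canonicalize(res$matched[[1]]), worked_example()$smiles)
  expect_false(any(unlist(res$status)))
})

test_that("matches are sound: every matched fingerprint equals the query", {
  mols <- fixture_small()$molecules[1:8]
  a <- build_alphabet(mols)
  fps <- counted_ecfp(mols)
  for (i in seq_along(mols)) {
    res <- invert_ecfp(fps[[i]], a)
    for (m in res$matched) {
      expect_true(fp_equal(counted_ecfp(m), fps[[i]]))
    }
    expect_true(canonicalize(mols[[i]]) %in%
                  vapply(res$matched, canonicalize, ""))
  }
})

test_that("an incomplete alphabet yields no matches", {
  a <- worked_alphabet()
  # drop the methyl entry: the candidate closure collapses
  drop <- vapply(a$entries, function(e) e$sig$degree == 1L, TRUE)
  a$entries <- a$entries[!drop]
  res <- invert_ecfp(worked_fp(), a)
  expect_equal(length(res$matched), 0L)
})
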