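test_that("rooted fragments carry exactly one root tag", {
  m <- worked_mol()
  for (a in seq_len(n_atoms(m))) {
    frag <- atomic_signature(m, a, 2L)$fragment
    expect_equal(lengths(regmatches(frag, gregexpr(":1", frag, fixed = TRUE))),
                 1L)
  }
})

test_that("single-atom and symmetric environments canonicalize as expected", {
  methane <- parse_smiles("C")[[1]]
  expect_equal(atomic_signature(methane, 1, 2L)$fragment, "[CH4:1]|")
  ethane <- parse_smiles("CC")[[1]]
  expect_equal(
    atomic_signature(ethane, 1, 1L)$fragment,
    atomic_signature(ethane, 2, 1L)$fragment
  )
})

test_that("identical local environments match across molecules", {
  # terminal CH3 next to CH2 looks the same in butane and hexane at r=1
  butane <- parse_smiles("CCCC")[[1]]
  hexane <- parse_smiles("CCCCCC")[[1]]
  expect_equal(
    atomic_signature(butane, 1, 1L)$fragment,
    atomic_signature(hexane, 1, 1L)$fragment
  )
  # and the hydroxyl environment in two different parents at r=2
  # (atom order is canonical, so locate the oxygen explicitly)
  a <- parse_smiles("OCCCC")[[1]]
  b <- parse_smiles("OCCCN")[[1]]
  expect_equal(
    atomic_signature(a, which(a$atoms$element == "O"), 2L)$fragment,
    atomic_signature(b, which(b$atoms$element == "O"), 2L)$fragment
  )
})

test_that("atomic signatures are invariant under atom relabeling", {
  forms <- parse_smiles(c("C[C@H](CO)CCCCCCO", "OCCCCCC[C@@H](C)CO"))
  expect_equal(
    sig_key(molecular_signature(forms[[1]])),
    sig_key(molecular_signature(forms[[2]]))
  )
})

test_that("molecular signatures have one member per heavy atom", {
  expect_equal(length(molecular_signature(worked_mol())$members), 11L)
  benzene <- parse_smiles("c1ccccc1")[[1]]
  frags <- vapply(molecular_signature(benzene)$members, `[[`, "", "fragment")
  expect_equal(length(frags), 6L)
  expect_equal(length(unique(frags)), 1L)
  for (m in fixture_small()$molecules[1:15]) {
    expect_equal(length(molecular_signature(m)$members), n_atoms(m))
  }
})

test_that("every real molecular signature satisfies CE and GE", {
  for (m in fixture_small()$molecules) {
    ms <- molecular_signature(m)
    expect_true(ce_holds(ms$members))
    expect_true(ge_holds(ms$members))
  }
})

test_that("an unmatched boundary bond violates CE", {
  ethanol <- parse_smiles("CCO")[[1]]
  lone <- molecular_signature(ethanol)$members[1]
  expect_false(ce_holds(lone))
})

test_that("CE agrees with a brute-force tally under random multiplicities", {
  mols <- fixture_small()$molecules[1:8]
  set.seed(5)
  for (m in mols) {
    ms <- molecular_signature(m)
    cands <- lapply(ms$members, function(s) list(sig = s))
    for (k in 1:5) {
      w <- sample(0:3, length(ms$members), replace = TRUE)
      expect_equal(ce_holds(ms$members, w), oracle_ce(cands, w))
    }
  }
})

test_that("GE follows the degree-sequence parity formula", {
  fake <- function(deg) {
    structure(
      list(fragment = "x", radius = 2L, root = NULL,
           degree = as.integer(deg),
           boundary = data.frame(source = character(), order = character(),
                                 target = character())),
      class = "atomic_sig"
    )
  }
  # two degree-1 roots: 0 - 2 + 2 = 0, even -> constructible
  expect_true(ge_holds(list(fake(1), fake(1))))
  # three degree-1 roots only: -1 -> impossible
  expect_false(ge_holds(list(fake(1), fake(1), fake(1))))
  # isolated single atom: +2 -> fine
  expect_true(ge_holds(list(fake(0))))
})

test_that("radius-(r-1) data is recoverable from the fragment string", {
  for (m in list(worked_mol(), parse_smiles("c1ccncc1O")[[1]])) {
    ms <- molecular_signature(m)
    for (s in ms$members) {
      rebuilt <- atomic_sig_from_fragment(s$fragment, s$radius)
      expect_identical(rebuilt$boundary, s$boundary)
      expect_identical(rebuilt$degree, s$degree)
      expect_identical(rebuilt$root, s$root)
    }
  }
})

test_that("molecular signature files round-trip", {
  path <- withr::local_tempfile(fileext = ".sig")
  ms <- molecular_signature(worked_mol())
  write_mol_sig(ms, path)
  back <- read_mol_sig(path)
  expect_equal(sig_key(back), sig_key(ms))
  expect_equal(back$radius, ms$radius)
})
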