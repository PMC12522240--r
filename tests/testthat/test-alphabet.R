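test_that("a single-molecule alphabet pairs its atoms' bits and signatures", {
  a <- worked_alphabet()
  expect_gte(length(a$entries), 1L)
  expect_lte(length(a$entries), 11L)
  expect_equal(sum(vapply(a$entries, `[[`, 0L, "n")), 11L)
  support <- fp_support(worked_fp())
  for (e in a$entries) {
    expect_true(all(e$bits %in% support))
    expect_lte(length(e$bits), 3L)
  }
})

test_that("empty input gives an empty alphabet", {
  a <- build_alphabet(list())
  expect_equal(length(a$entries), 0L)
})

test_that("alphabet construction and serialization are deterministic", {
  mols <- fixture_small()$molecules[1:10]
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_alphabet(build_alphabet(mols), p1)
  write_alphabet(build_alphabet(mols), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("alphabet files round-trip including boundary data", {
  a <- worked_alphabet()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_alphabet(a, path)
  b <- read_alphabet(path)
  expect_equal(length(b$entries), length(a$entries))
  for (i in seq_along(a$entries)) {
    expect_identical(b$entries[[i]]$bits, a$entries[[i]]$bits)
    expect_identical(b$entries[[i]]$sig$fragment, a$entries[[i]]$sig$fragment)
    expect_identical(b$entries[[i]]$sig$boundary, a$entries[[i]]$sig$boundary)
    expect_identical(b$entries[[i]]$n, a$entries[[i]]$n)
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alphabet_tsv(a, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), length(a$entries))
})

test_that("merging alphabets unions entries and sums occurrences", {
  m1 <- parse_smiles("CCO")[[1]]
  m2 <- parse_smiles("c1ccccc1")[[1]]
  a1 <- build_alphabet(list(m1))
  a2 <- build_alphabet(list(m2))
  empty <- build_alphabet(list())
  expect_equal(length(merge_alphabets(a1, empty)$entries),
               length(a1$entries))
  ab <- merge_alphabets(a1, a2)
  ba <- merge_alphabets(a2, a1)
  expect_equal(length(ab$entries), length(a1$entries) + length(a2$entries))
  key <- function(a) {
    sort(vapply(a$entries, function(e) {
      paste(e$sig$fragment, paste(e$bits, collapse = " "), e$n)
    }, ""))
  }
  expect_identical(key(ab), key(ba))
  self2 <- merge_alphabets(a1, a1)
  expect_equal(sum(vapply(self2$entries, `[[`, 0L, "n")), 2L * 3L)
  expect_error(
    merge_alphabets(a1, build_alphabet(list(m2), radius = 1L)),
    "mismatch"
  )
})

test_that("candidate selection drops oversized entries and closes reverses", {
  a <- worked_alphabet()
  fp <- worked_fp()
  # the full self query keeps every tuple (real molecules satisfy CE)
  cands <- candidates(a, fp)
  expect_equal(length(cands), length(a$entries))
  # halving one bit count must drop the entries needing it twice
  counts <- fp$counts
  big <- names(counts)[counts >= 2][1]
  counts[[big]] <- 1L
  fp_small <- counted_fp(counts)
  cands2 <- candidates(a, fp_small)
  expect_lte(length(cands2), length(cands))
  # post-condition sweep: every boundary descriptor has its reverse present
  present <- unlist(lapply(cands2, function(e) {
    b <- e$sig$boundary
    paste(b$source, b$order, b$target)
  }))
  for (e in cands2) {
    b <- e$sig$boundary
    if (nrow(b) > 0) {
      expect_true(all(paste(b$target, b$order, b$source) %in% present))
    }
  }
})

test_that("candidate selection is monotone under alphabet restriction", {
  mols <- fixture_small()$molecules[1:6]
  a <- build_alphabet(mols)
  fp <- counted_ecfp(mols[[1]])
  full <- vapply(candidates(a, fp), function(e) {
    paste(e$sig$fragment, paste(e$bits, collapse = " "))
  }, "")
  half <- a
  half$entries <- a$entries[seq(1, length(a$entries), by = 2)]
  restricted <- vapply(candidates(half, fp), function(e) {
    paste(e$sig$fragment, paste(e$bits, collapse = " "))
  }, "")
  expect_true(all(restricted %in% full))
})

test_that("all tuples of a source molecule survive their own query", {
  mols <- fixture_small()$molecules[1:10]
  a <- build_alphabet(mols)
  for (m in mols[1:5]) {
    own <- build_alphabet(list(m))
    fp <- counted_ecfp(m)
    kept <- vapply(candidates(a, fp), function(e) {
      paste(e$sig$fragment, paste(e$bits, collapse = " "))
    }, "")
    for (e in own$entries) {
      expect_true(paste(e$sig$fragment, paste(e$bits, collapse = " "))
                  %in% kept)
    }
  }
})

test_that("pielou evenness follows the entropy formula", {
  a <- worked_alphabet()
  fake <- function(ns) {
    e <- a
    e$entries <- lapply(seq_along(ns), function(i) {
      x <- a$entries[[(i - 1) %% length(a$entries) + 1]]
      x$n <- ns[i]
      x
    })
    e
  }
  expect_equal(pielou_evenness(fake(c(2L, 2L, 2L))), 1)
  expect_equal(pielou_evenness(fake(5L)), 1)
  expect_equal(
    pielou_evenness(fake(c(3L, 1L))),
    (-0.75 * log(0.75) - 0.25 * log(0.25)) / log(2)
  )
  expect_error(pielou_evenness(fake(integer())), "empty")
})

test_that("growth curves are monotone, seeded, and end at the full size", {
  mols <- fixture_small()$molecules[1:12]
  full_size <- length(build_alphabet(mols)$entries)
  g1 <- growth_curve(mols, c(3, 6, 12), repeats = 2, seed = 4)
  g2 <- growth_curve(mols, c(3, 6, 12), repeats = 2, seed = 4)
  expect_identical(g1, g2)
  expect_true(all(diff(g1$mean_alphabet_size) >= 0))
  expect_equal(g1$mean_alphabet_size[3], full_size)
})

test_that("duplication histograms group molecules by shared descriptors", {
  mols <- fixture_small()$molecules[1:10]
  h <- duplication_histogram(mols, "signature")
  expect_equal(h$duplication, 1L)
  expect_equal(h$frequency, 10L)
  expect_equal(sum(h$duplication * h$frequency), 10L)
  # ortho- and para-xylene share atom multisets: a radius-0 collision
  twins <- parse_smiles(c("Cc1ccccc1C", "Cc1ccc(C)cc1", "CCO"))
  h0 <- duplication_histogram(twins, "signature", radius = 0L)
  expect_true(2L %in% h0$duplication)
  expect_equal(sum(h0$duplication * h0$frequency), 3L)
})
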