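test_that("integer partitions match known counts and explicit sets", {
  expect_equal(length(integer_partitions(20, 1:20)$partitions), 627L)
  p42 <- integer_partitions(4, c(1, 2))
  expect_false(p42$truncated)
  expect_setequal(
    vapply(p42$partitions, paste, "", collapse = "+"),
    c("2+2", "2+1+1", "1+1+1+1")
  )
  p0 <- integer_partitions(0, 1)
  expect_equal(length(p0$partitions), 1L)
  expect_equal(p0$partitions[[1]], integer())
  # parts not dividing n
  expect_equal(length(integer_partitions(3, 2)$partitions), 0L)
})

test_that("partition truncation keeps the smallest norms first", {
  res <- integer_partitions(10, 1:10, cap = 5)
  expect_true(res$truncated)
  expect_equal(length(res$partitions), 5L)
  expect_lte(max(lengths(res$partitions)), 3L)  # shortest of 42 partitions
})

synthetic_entry <- function(bits, own = "P", deg = 0L, frag = "syn") {
  boundary <- if (deg > 0) {
    data.frame(source = rep(own, deg), order = rep("1", deg),
               target = rep(own, deg), stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), order = character(),
               target = character(), stringsAsFactors = FALSE)
  }
  list(
    bits = as.integer(bits),
    sig = structure(
      list(fragment = frag, radius = 2L, root = NULL, degree = deg,
           boundary = boundary),
      class = "atomic_sig"
    ),
    n = 1L
  )
}

test_that("single partition equations enumerate coefficient assignments", {
  fp2 <- counted_fp(c(`0` = 2L))
  sys <- dio_system(
    list(synthetic_entry(0, frag = "a"), synthetic_entry(0, frag = "b")),
    fp2
  )
  sols <- solve_pe(sys, 0)$solutions
  expect_setequal(
    vapply(sols, paste, "", collapse = ","),
    c("2,0", "1,1", "0,2")
  )
  # coefficient 2 (an atom emitting the same bit twice)
  sys2 <- dio_system(list(synthetic_entry(c(0, 0))), fp2)
  expect_equal(solve_pe(sys2, 0)$solutions, list(1L))
  sys3 <- dio_system(list(synthetic_entry(c(0, 0))), counted_fp(c(`0` = 3L)))
  expect_equal(length(solve_pe(sys3, 0)$solutions), 0L)
})

test_that("orbits link candidates through shared bits", {
  fp <- counted_fp(c(`0` = 1L, `1` = 1L, `2` = 2L, `3` = 1L))
  disjoint <- dio_system(
    list(synthetic_entry(0), synthetic_entry(1), synthetic_entry(2)),
    fp
  )
  expect_equal(lengths(lapply(orbits(disjoint), `[[`, "indices")),
               c(1L, 1L, 1L))
  chain <- dio_system(
    list(
      synthetic_entry(c(0, 1)), synthetic_entry(c(1, 2)),
      synthetic_entry(c(2, 3))
    ),
    fp
  )
  orb <- orbits(chain)
  expect_equal(length(orb), 1L)
  expect_setequal(orb[[1]]$indices, 1:3)
})

test_that("within-orbit combination applies the compatibility rule", {
  # one candidate active at two bits with matching targets: max merges
  fp <- counted_fp(c(`0` = 2L, `1` = 2L))
  sys <- dio_system(list(synthetic_entry(c(0, 1))), fp)
  orb <- orbits(sys)[[1]]
  per_bit <- list(`0` = solve_pe(sys, 0)$solutions,
                  `1` = solve_pe(sys, 1)$solutions)
  merged <- combine_within_orbit(per_bit, orb, sys$coef)
  expect_equal(merged, list(2L))
  # incompatible targets yield nothing
  fp2 <- counted_fp(c(`0` = 2L, `1` = 3L))
  sys2 <- dio_system(list(synthetic_entry(c(0, 1))), fp2)
  per_bit2 <- list(`0` = solve_pe(sys2, 0)$solutions,
                   `1` = solve_pe(sys2, 1)$solutions)
  expect_equal(length(combine_within_orbit(per_bit2, orbits(sys2)[[1]],
                                           sys2$coef)), 0L)
})

test_that("across-orbit combination obeys the product law", {
  sets <- list(
    list(c(1L, 0L, 0L), c(2L, 0L, 0L), c(3L, 0L, 0L)),
    list(c(0L, 1L, 1L), c(0L, 2L, 2L))
  )
  combined <- combine_across_orbits(sets)
  expect_equal(length(combined), 6L)
  expect_equal(length(combine_across_orbits(list(sets[[1]], list()))), 0L)
})

test_that("CE/GE filtering removes unbalanced solution vectors", {
  # entry with an unmatched directed boundary bond can never survive alone
  bad <- synthetic_entry(0, frag = "bad", deg = 1L)
  bad$sig$boundary$target <- "Z"
  good <- synthetic_entry(1, frag = "good", deg = 0L)
  sys <- dio_system(list(bad, good), counted_fp(c(`0` = 1L, `1` = 1L)))
  kept <- filter_solutions(list(c(1L, 1L), c(0L, 1L)), sys)
  expect_equal(kept, list(c(0L, 1L)))
})

test_that("the staged solver matches the brute-force oracle exactly", {
  n_product_checked <- 0L
  for (seed in 1:60) {
    rs <- random_system(seed)
    sys <- dio_system(rs$cands, rs$fp)
    res <- solve_system(sys)
    expect_false(res$truncated)
    expect_identical(
      solutions_as_keys(res$solutions),
      oracle_solve(rs$cands, rs$fp),
      info = paste("seed", seed)
    )
    expect_equal(res$n_pe_solutions, prod(res$orbit_sizes))
    n_product_checked <- n_product_checked + 1L
  }
  expect_equal(n_product_checked, 60L)
})

test_that("solver results are independent of candidate ordering", {
  for (seed in c(3, 17, 29)) {
    rs <- random_system(seed)
    res1 <- solve_system(dio_system(rs$cands, rs$fp))
    perm <- rev(seq_along(rs$cands))
    res2 <- solve_system(dio_system(rs$cands[perm], rs$fp))
    back <- lapply(res2$solutions, function(v) v[order(perm)])
    expect_setequal(
      solutions_as_keys(res1$solutions),
      solutions_as_keys(back)
    )
  }
})

test_that("re-substitution holds for every emitted solution", {
  m <- worked_mol()
  fp <- worked_fp()
  cands <- candidates(worked_alphabet(), fp)
  sys <- dio_system(cands, fp)
  res <- solve_system(sys)
  for (v in res$solutions) {
    expect_identical(as.integer(v %*% sys$coef), unname(fp$counts))
  }
})
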