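# Independent brute-force oracle for the Diophantine solver -----------------
#
# Enumerates the full grid n_j in {0..max(target)}^l, keeps the vectors
# satisfying every partition equation by direct substitution, then filters
# by direct CE tallies (data-frame aggregation, a different code path from
# ce_holds) and the GE formula.

oracle_solve <- function(cands, fp) {
  l <- length(cands)
  bits <- as.integer(names(fp$counts))
  target <- unname(as.integer(fp$counts))
  coef <- matrix(0L, nrow = l, ncol = length(bits))
  for (j in seq_len(l)) {
    tb <- table(cands[[j]]$bits)
    coef[j, match(as.integer(names(tb)), bits)] <- as.integer(tb)
  }
  maxn <- max(target)
  grid <- as.matrix(expand.grid(rep(list(0:maxn), l)))
  pe_ok <- rowSums(abs(
    grid %*% coef - matrix(target, nrow(grid), length(target), byrow = TRUE)
  )) == 0
  sols <- grid[pe_ok, , drop = FALSE]
  keep <- logical(nrow(sols))
  for (r in seq_len(nrow(sols))) {
    keep[r] <- oracle_ce(cands, sols[r, ]) && oracle_ge(cands, sols[r, ])
  }
  sols <- sols[keep, , drop = FALSE]
  if (nrow(sols) == 0) return(character(0))
  sort(vapply(seq_len(nrow(sols)), function(r) {
    paste(sols[r, ], collapse = ",")
  }, ""))
}

oracle_ce <- function(cands, weights) {
  rows <- do.call(rbind, lapply(seq_along(cands), function(j) {
    b <- cands[[j]]$sig$boundary
    if (weights[j] == 0 || nrow(b) == 0) return(NULL)
    data.frame(
      source = b$source, order = b$order, target = b$target,
      w = unname(weights[j]), stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) return(TRUE)
  agg <- stats::aggregate(
    w ~ source + order + target, data = rows, FUN = sum
  )
  for (r in seq_len(nrow(agg))) {
    s <- agg$source[r]; o <- agg$order[r]; t <- agg$target[r]
    if (s == t) {
      if (agg$w[r] %% 2 != 0) return(FALSE)
    } else {
      rev_w <- agg$w[agg$source == t & agg$order == o & agg$target == s]
      if (length(rev_w) == 0) rev_w <- 0
      if (agg$w[r] != rev_w) return(FALSE)
    }
  }
  TRUE
}

oracle_ge <- function(cands, weights) {
  deg <- vapply(cands, function(e) e$sig$degree, 0L)
  n1 <- sum(weights[deg == 1])
  v <- sum(pmax(deg - 2, 0) * weights) - n1 + 2
  v >= 0 && v %% 2 == 0
}

# Random synthetic Diophantine systems: candidates with made-up radius-1
# fragment labels, random boundary descriptors and random bit multisets.
random_system <- function(seed) {
  set.seed(seed)
  l <- sample(1:5, 1)
  labels <- c("P", "Q", "R")
  orders <- c("1", "2")
  cands <- lapply(seq_len(l), function(j) {
    own <- sample(labels, 1)
    deg <- sample(0:3, 1)
    boundary <- if (deg > 0) {
      data.frame(
        source = rep(own, deg),
        order = sample(orders, deg, replace = TRUE),
        target = sample(labels, deg, replace = TRUE),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        source = character(), order = character(), target = character(),
        stringsAsFactors = FALSE
      )
    }
    nbit <- sample(1:3, 1)
    bits <- sort(sample(0:5, nbit, replace = TRUE))
    sig <- structure(
      list(
        fragment = paste0("synthetic-", j), radius = 2L, root = NULL,
        degree = deg, boundary = boundary
      ),
      class = "atomic_sig"
    )
    list(bits = bits, sig = sig, n = 1L)
  })
  support <- sort(unique(unlist(lapply(cands, `[[`, "bits"))))
  counts <- stats::setNames(
    sample(3:8, length(support), replace = TRUE),
    as.character(support)
  )
  fp <- counted_fp(counts, radius = 2L, nbits = 2048L, chirality = TRUE)
  list(cands = cands, fp = fp)
}

solutions_as_keys <- function(sols) {
  sort(vapply(sols, paste, "", collapse = ","))
}
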