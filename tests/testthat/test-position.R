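test_that("individual strength sums dependencies and is conserved", {
  expect_equal(unname(individual_strength(rbind(c(2, 0), c(1, 1)))),
               c(2 / 3, 4 / 3))
  expect_equal(unname(individual_strength(diag(2) + 0)), c(1, 1))
  expect_error(individual_strength(matrix(c(3, 1), 1)), "2 host rows")
  set.seed(11)
  for (k in 1:1000) {
    m <- random_count_matrix(sample(2:8, 1), sample(2:6, 1))
    expect_equal(sum(individual_strength(m)), ncol(m), tolerance = 1e-9)
  }
})

test_that("nested rank sorts by degree with abundance tie-break", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 1, 0), c = c(1, 0, 0))
  expect_equal(unname(nested_rank(m)), c(0, 0.5, 1))
  expect_equal(unname(nested_rank(rbind(c(1, 1), c(1, 0)))), c(0, 1))
  # equal degrees, A_i = (5, 3): abundance breaks the tie
  m <- rbind(a = c(3, 2, 0), b = c(2, 1, 0), c = c(0, 0, 1))
  expect_equal(unname(nested_rank(m))[1:2], c(0, 0.5))
  expect_error(nested_rank(matrix(1:2, 1)), "2 host rows")
})

test_that("nested rank endpoints and permutation behaviour", {
  set.seed(21)
  for (k in 1:50) {
    m <- random_count_matrix(sample(3:8, 1), sample(2:5, 1))
    r <- nested_rank(m)
    expect_equal(min(r), 0)
    expect_equal(max(r), 1)
    expect_true(all(r >= 0 & r <= 1))
    # shuffling rows only moves ranks among exact (degree, total) ties
    perm <- sample(nrow(m))
    r2 <- nested_rank(m[perm, , drop = FALSE])[rownames(m)]
    key <- paste(rowSums(m > 0), rowSums(m))
    unique_key <- !(key %in% key[duplicated(key)])
    expect_equal(r2[unique_key], r[unique_key])
  }
})

test_that("d' endpoints match closed forms", {
  # profile proportional to the marginals -> d' = 0
  m <- rbind(c(2, 4), c(1, 2), c(1, 2))
  expect_equal(unname(specialization_dprime(m)), c(0, 0, 0))
  # fully specialized 2x2 diagonal -> d' = 1
  expect_equal(unname(specialization_dprime(rbind(c(5, 0), c(0, 5)))), c(1, 1))
  set.seed(31)
  for (k in 1:200) {
    d <- specialization_dprime(random_count_matrix(sample(2:7, 1),
                                                   sample(2:5, 1)))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("relaxed d' normalization is bounded by the exhaustive allocation oracle", {
  # all allocations of A_i among the columns, at fixed totals
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L))
    out <- NULL
    for (first in 0:n) {
      rest <- compositions(n - first, k - 1L)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  d_of <- function(a, Ai, q) {
    j <- a > 0
    p <- a[j] / Ai
    sum(p * log(p / q[j]))
  }
  set.seed(41)
  gaps <- c()
  for (k in 1:20) {
    repeat {
      m <- random_count_matrix(3L, sample(2:3, 1), lambda = 0.8)
      if (sum(m) <= 12) break
    }
    q <- colSums(m) / sum(m)
    drel <- specialization_dprime(m)
    for (i in seq_len(nrow(m))) {
      Ai <- sum(m[i, ])
      alloc <- compositions(Ai, ncol(m))
      dvals <- apply(alloc, 1L, d_of, Ai = Ai, q = q)
      dobs <- d_of(m[i, ], Ai, q)
      dmin <- min(dvals); dmax <- max(dvals)
      # the observed profile is one of the enumerated allocations
      expect_gte(dobs, dmin - 1e-9)
      expect_lte(dobs, dmax + 1e-9)
      oracle <- if (dmax - dmin < 1e-12) 0 else (dobs - dmin) / (dmax - dmin)
      gaps <- c(gaps, abs(drel[i] - oracle))
    }
  }
  # the real-valued normalization and the integer-constrained one disagree
  # only by the discreteness gap, which is coarse at these tiny totals
  # (m <= 12, often only a handful of feasible allocations): frozen
  # oracle-computed bounds for this fixture set
  expect_lt(max(gaps), 0.55)
  expect_lt(mean(gaps), 0.25)
})

test_that("unipartite projections follow the stated weighting rules", {
  m <- rbind(c(1, 0), c(1, 0))
  expect_equal(project_unipartite(m, "sum")[1, 2], 2)
  m <- rbind(c(2, 1), c(3, 4))
  expect_equal(project_unipartite(m, "binary")[1, 2], 2)
  expect_equal(project_unipartite(m, "sum")[1, 2], (2 + 3) + (1 + 4))
  # no shared species -> zero weights
  expect_true(all(project_unipartite(diag(2) + 0) == 0))
  # newman: shared species j contributes 1/(n_j - 1); singletons nothing
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0))
  W <- project_unipartite(m, "newman")
  expect_equal(W[1, 2], 1 / 2)
  expect_equal(W[1, 3], 1 / 2)
  for (meth in c("sum", "binary", "newman")) {
    W <- project_unipartite(random_count_matrix(), meth)
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
  }
})

test_that("eigenvector centrality matches the dense eigen oracle", {
  W <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(unname(eigenvector_centrality(W)),
               c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-10)
  # complete graph: all equal
  K <- matrix(1, 4, 4); diag(K) <- 0
  expect_equal(unname(eigenvector_centrality(K)), rep(1, 4))
  set.seed(51)
  for (k in 1:20) {
    m <- random_count_matrix(20L, 8L)
    W <- project_unipartite(m)
    got <- eigenvector_centrality(W)
    e <- eigen(W, symmetric = TRUE)
    v <- abs(e$vectors[, which.max(e$values)])
    expect_equal(unname(got), v / max(v), tolerance = 1e-8)
    # scale invariance
    expect_equal(eigenvector_centrality(2 * W), got, tolerance = 1e-9)
  }
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "zero")
})

test_that("position table assembles all four indices per host", {
  b <- toy_bundle(nF = 4L, nM = 4L, seed = 8L)
  pt <- position_table(b)
  expect_equal(nrow(pt), nrow(b$matrix))
  expect_equal(sum(pt$strength), ncol(b$matrix), tolerance = 1e-9)
  expect_true(all(pt$nested_rank >= 0 & pt$nested_rank <= 1))
  expect_true(all(pt$dprime >= 0 & pt$dprime <= 1))
  expect_equal(max(pt$evcent), 1)
  expect_identical(pt$host_id, b$hosts$host_id)
})
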