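test_that("correlation matrix matches the textbook formula", {
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  r <- correlation_matrix(x)
  # direct covariance / sigma-sigma oracle
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  expect_equal(r["g1", "g1"], 1)
  # identical and negated profiles
  y <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ])
  ry <- correlation_matrix(y)
  expect_equal(ry["a", "b"], 1)
  expect_equal(ry["a", "c"], -1)
  expect_error(correlation_matrix(x[, 1:2]), ">= 3 samples")
  xz <- rbind(x, flat = rep(1, 6))
  expect_warning(rz <- correlation_matrix(xz), "zero-variance")
  expect_false("flat" %in% rownames(rz))
})

test_that("soft-threshold adjacency is |r|^power with unit diagonal", {
  r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3)
  a <- adjacency(r, 12)
  expect_equal(a[1, 2], 0.000244140625)   # 0.5^12
  expect_equal(a[1, 3], 1)                # unsigned network
  expect_equal(a[2, 3], 0)
  expect_equal(diag(a), rep(1, 3))
  expect_error(adjacency(r, 0), ">= 1")
})

test_that("TOM has the closed form c on uniform 3-gene networks", {
  for (c0 in c(0.1, 0.5, 0.9)) {
    a <- matrix(c0, 3, 3); diag(a) <- 1
    tom <- topological_overlap(a)
    expect_equal(tom[lower.tri(tom)], rep(c0, 3), tolerance = 1e-12)
    expect_equal(diag(tom), rep(1, 3))
  }
  a0 <- diag(3)
  expect_equal(topological_overlap(a0)[lower.tri(a0)], rep(0, 3))
})

test_that("matrix-product TOM equals the triple-loop oracle", {
  for (seed in 1:3) {
    a <- random_adjacency(20, seed)
    tom <- topological_overlap(a)
    expect_lt(max(abs(tom - tom_brute_force(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.8, 1), 2)),
               "symmetric")
})

test_that("TOM of a single-edge network reduces to the edge weight", {
  # with one nonzero off-diagonal a, k_i = k_j = a, l = 0 => TOM = a
  for (aij in c(0.2, 0.7)) {
    a <- diag(4)
    a[1, 2] <- a[2, 1] <- aij
    expect_equal(topological_overlap(a)[1, 2], aij, tolerance = 1e-14)
  }
})

test_that("average-linkage dendrogram separates planted blocks", {
  tom <- matrix(0.02, 20, 20)
  tom[1:10, 1:10] <- 0.8
  tom[11:20, 11:20] <- 0.8
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:20), paste0("g", 1:20))
  hc <- cluster_dendrogram(tom)
  top <- cutree(hc, k = 2)
  expect_equal(length(unique(top[1:10])), 1L)
  expect_equal(length(unique(top[11:20])), 1L)
  expect_false(top[1] == top[11])
  expect_true(all(diff(hc$height) >= -1e-12))  # nondecreasing merges
  expect_error(cluster_dendrogram(tom[1:2, 1:2]), ">= 3")
})

test_that("eigengene is the dominant right-singular vector, sign-aligned", {
  x <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  e <- module_eigengene(x, rownames(x))
  expect_equal(sum(e^2), 1)
  z <- t(scale(t(x)))
  expect_gte(cor(e, colMeans(z)), 0)
  # SVD optimality: no other unit vector explains more variance
  ve <- sum((z %*% e)^2)
  sv <- svd(z)
  expect_equal(ve, sv$d[1]^2, tolerance = 1e-10)
  set.seed(1)
  for (k in 1:20) {
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    expect_lte(sum((z %*% u)^2), ve + 1e-8)
  }
  # identical profiles: eigengene correlates 1 with every member
  xi <- matrix(rep(rnorm(6), 5), 5, byrow = TRUE,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  ei <- module_eigengene(xi, rownames(xi))
  expect_equal(abs(cor(ei, xi[1, ])), 1, tolerance = 1e-10)
  expect_gte(cor(ei, xi[1, ]), 0)
  # negating every member leaves |correlation| unchanged
  en <- module_eigengene(-x, rownames(x))
  expect_equal(abs(cor(en, e)), 1, tolerance = 1e-10)
})

test_that("module merging is a fixpoint that respects the threshold", {
  # three planted profiles: A ~ B correlated above 0.9, C apart
  set.seed(4)
  base1 <- rnorm(10); base2 <- rnorm(10)
  mk <- function(base, n, sd) t(replicate(n, base + rnorm(10, 0, sd)))
  x <- rbind(mk(base1, 6, 0.1), mk(base1, 6, 0.1), mk(base2, 6, 0.1))
  dimnames(x) <- list(sprintf("g%02d", 1:18), paste0("s", 1:10))
  a <- setNames(rep(1:3, each = 6), rownames(x))
  merged <- merge_close_modules(x, a, 0.9)
  expect_equal(length(unique(merged$assignment[merged$assignment != 0])), 2L)
  cc <- cor(t(merged$eigengenes))
  expect_true(all(cc[lower.tri(cc)] <= 0.9))
  # re-running changes nothing
  again <- merge_close_modules(x, merged$assignment, 0.9)
  expect_identical(again$assignment, merged$assignment)
  # far-apart modules stay put
  keep <- merge_close_modules(x, setNames(rep(c(1, 2), c(12, 6)),
                                          rownames(x)), 0.9)
  expect_equal(length(unique(keep$assignment)), 2L)
})

test_that("chained merges terminate with all pairs at or below the threshold", {
  # A ~ B and B ~ C strongly correlated, A ~ C less so; fixpoint must hold
  set.seed(9)
  s <- 12
  b1 <- rnorm(s)
  b2 <- b1 + rnorm(s, 0, 0.25)
  b3 <- b2 + rnorm(s, 0, 0.25)
  mk <- function(base, n) t(replicate(n, base + rnorm(s, 0, 0.05)))
  x <- rbind(mk(b1, 5), mk(b2, 5), mk(b3, 5))
  dimnames(x) <- list(sprintf("g%02d", 1:15), paste0("s", 1:s))
  a <- setNames(rep(1:3, each = 5), rownames(x))
  merged <- merge_close_modules(x, a, 0.9)
  if (nrow(merged$eigengenes) > 1) {
    cc <- cor(t(merged$eigengenes))
    expect_true(all(cc[lower.tri(cc)] <= 0.9))
  } else succeed()
})
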