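mm4 <- module_map(face = 1:2, braincase = 3:4)

test_that("CR is zero for block-diagonal data and scale-invariant", {
  # modules supported on disjoint row blocks: cross-covariance exactly zero
  A <- matrix(rnorm(20), 5, 4)
  U <- rbind(cbind(A, matrix(0, 5, 4)), cbind(matrix(0, 5, 4), A))
  expect_equal(cr_coefficient(U, mm4), 0)

  set.seed(10)
  U <- matrix(rnorm(12 * 8), 12, 8)
  expect_equal(cr_coefficient(3.7 * U, mm4), cr_coefficient(U, mm4), tolerance = 1e-12)
})

test_that("CR matches an element-wise evaluation of the formula", {
  set.seed(11)
  U <- matrix(rnorm(10 * 8), 10, 8)
  U[, 5:8] <- U[, 1:4]  # module 2 duplicates module 1
  # independent brute-force oracle: explicit loops over matrix elements
  n <- nrow(U); d <- ncol(U)
  S <- matrix(0, d, d)
  for (i in 1:d) for (j in 1:d) {
    S[i, j] <- sum((U[, i] - 0) * (U[, j] - 0)) / (n - 1)
  }
  lmk <- rep(1:4, each = 2)
  num <- 0
  for (i in 1:4) for (j in 5:8) num <- num + S[i, j]^2
  den1 <- 0; den2 <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i != j && lmk[i] != lmk[j]) den1 <- den1 + S[i, j]^2
  }
  for (i in 5:8) for (j in 5:8) {
    if (i != j && lmk[i] != lmk[j]) den2 <- den2 + S[i, j]^2
  }
  oracle <- sqrt(num) / sqrt(sqrt(den1) * sqrt(den2))
  expect_equal(cr_coefficient(U, mm4), oracle, tolerance = 1e-12)
})

test_that("CR respects the within-landmark exclusion toggle and errors on empty blocks", {
  set.seed(12)
  U <- matrix(rnorm(10 * 8), 10, 8)
  expect_false(isTRUE(all.equal(cr_coefficient(U, mm4),
                                cr_coefficient(U, mm4, exclude_within_landmark = FALSE))))
  mm_tiny <- module_map(face = 1, braincase = 2:3)
  U6 <- matrix(rnorm(10 * 6), 10, 6)
  expect_error(cr_coefficient(U6, mm_tiny), "single landmark")
})

test_that("cr_test permutes whole landmarks and applies the add-one rule", {
  spec <- simulation_spec(n_species = 12, p = 8,
                          modules = module_map(face = 1:4, braincase = 5:8), seed = 13)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  res <- cr_test(fit, st$tree, st$modules, n_perm = 49, seed = 1)  # < choose(8,4)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_equal(res$n_perm, 49)
  expect_false(res$exact)
  # identical seed reproduces the null exactly
  res2 <- cr_test(fit, st$tree, st$modules, n_perm = 49, seed = 1)
  expect_equal(res$null, res2$null)
})

test_that("cr_test enumerates exactly when permutations exceed distinct assignments", {
  spec <- simulation_spec(n_species = 10, p = 4, modules = mm4, seed = 14)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  res <- cr_test(fit, st$tree, mm4, n_perm = 999, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_perm, choose(4, 2))
  expect_gt(res$p_value, 0)
})

test_that("phylo_pls is exact under similarity maps of a block", {
  tr <- unit_tree(15, seed = 15)
  set.seed(16)
  Y1 <- matrix(rnorm(15 * 4), 15, 4)
  th <- 0.6
  Q <- kronecker(diag(2), matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
  Y <- cbind(Y1, 2.5 * Y1 %*% Q)  # block 2 = scaled rotation of block 1
  rownames(Y) <- sort(tr$tip.label)
  res <- phylo_pls(Y, tr, mm4, n_perm = 49, seed = 2)
  expect_equal(res$r_pls, 1, tolerance = 1e-10)
  expect_lt(res$p_value, 0.05)
  # singular vectors unit length
  expect_equal(sum(res$left_vectors^2), 1, tolerance = 1e-12)
  expect_equal(sum(res$right_vectors^2), 1, tolerance = 1e-12)
})

test_that("r_PLS equals the first-pair score correlation and is rescale-invariant", {
  spec <- simulation_spec(n_species = 14, p = 8,
                          modules = module_map(face = 1:4, braincase = 5:8),
                          rho = 0.6, seed = 17)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  res <- phylo_pls(fit, st$tree, st$modules, n_perm = 49, seed = 3)
  expect_equal(res$r_pls, cor(res$scores$block1, res$scores$block2), tolerance = 1e-12)
  expect_gte(res$r_pls, 0)
  expect_lte(res$r_pls, 1)
  # global positive rescaling leaves both CR and r_PLS unchanged
  Y <- fit$species_tangent * 12.3
  res2 <- phylo_pls(Y, st$tree, st$modules, n_perm = 49, seed = 3)
  expect_equal(res2$r_pls, res$r_pls, tolerance = 1e-10)
})

test_that("on a star tree phylo_pls equals ordinary two-block PLS", {
  tr <- star_tree(12)
  set.seed(18)
  Y <- sim_tips(tr, block_cov(2, 2, rho = 0.5), seed = 18)
  res <- phylo_pls(Y, tr, mm4, n_perm = 9, seed = 4)
  # plain (non-phylogenetic) oracle on centered data
  Yc <- scale(Y, scale = FALSE)
  S12 <- crossprod(Yc[, 1:4], Yc[, 5:8]) / (nrow(Y) - 1)
  sv <- svd(S12)
  plain_r <- cor(Yc[, 1:4] %*% sv$u[, 1], Yc[, 5:8] %*% sv$v[, 1])
  expect_equal(res$r_pls, as.vector(plain_r), tolerance = 1e-8)
})

test_that("permuting landmark order within a module leaves CR unchanged", {
  set.seed(19)
  U <- matrix(rnorm(10 * 8), 10, 8)
  # swap landmarks 1 and 2 (both in module 1): swap column pairs (1,2) and (3,4)
  U_sw <- U[, c(3, 4, 1, 2, 5, 6, 7, 8)]
  expect_equal(cr_coefficient(U_sw, mm4), cr_coefficient(U, mm4), tolerance = 1e-12)
})
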