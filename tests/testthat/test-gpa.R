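test_that("identical configurations align onto each other exactly", {
  tri <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  lm <- landmark_tbl(list(a = tri, b = tri))
  fit <- gpa(lm)
  expect_true(fit$converged)
  expect_equal(fit$aligned[, , 1], fit$aligned[, , 2], tolerance = 1e-12)
  # zero Procrustes variance
  expect_lt(glance(fit)$procrustes_variance, 1e-20)
})

test_that("superimposition removes similarity transforms", {
  set.seed(42)
  base <- matrix(rnorm(12), 6, 2)
  moved <- similarity(base, theta = 37 * pi / 180, s = 2.5, t = c(3, -1))
  fit <- gpa(landmark_tbl(list(a = base, b = moved)))
  expect_lt(max(abs(fit$aligned[, , 1] - fit$aligned[, , 2])), 1e-8)
  # aligned configurations are centered with unit centroid size
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-8)
    expect_equal(sum(fit$aligned[, , i]^2), 1, tolerance = 1e-8)
  }
  # consensus is the (renormalized) mean of aligned configurations
  expect_equal(fit$consensus, apply(fit$aligned, c(1, 2), mean) /
                 sqrt(sum(apply(fit$aligned, c(1, 2), mean)^2)), tolerance = 1e-8)
})

test_that("Procrustes distance matches a brute-force rotation grid search", {
  pre <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  # independent oracle: exhaustive search over rotation angle on
  # pre-centered, pre-scaled configurations
  grid_min <- function(A, B) {
    a <- pre(A); b <- pre(B)
    thetas <- seq(0, 2 * pi, by = 1e-5)
    min(vapply(thetas, function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sqrt(sum((a %*% R - b)^2))
    }, numeric(1)))
  }
  A <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  B <- matrix(c(0, 0, 1, 0.1, -0.1, 1), 3, 2, byrow = TRUE)
  # B is an exact scaled rotation of A, so the distance is 0; the oracle can
  # only get within its angular resolution of that
  expect_lt(abs(procrustes_distance(A, B) - grid_min(A, B)), 1e-5)
  B2 <- matrix(c(0, 0, 1, 0.1, -0.3, 0.9), 3, 2, byrow = TRUE)
  d2 <- procrustes_distance(A, B2)
  expect_gt(d2, 0.05)
  expect_lt(abs(d2 - grid_min(A, B2)), 1e-5)
})

test_that("GPA summaries are invariant to specimen order and input transforms", {
  set.seed(7)
  cfgs <- lapply(1:5, function(i) matrix(rnorm(10, sd = 0.1), 5, 2) +
                   matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0.5, 0.5), 5, 2, byrow = TRUE))
  names(cfgs) <- paste0("s", 1:5)
  fit1 <- gpa(landmark_tbl(cfgs))
  cfgs2 <- rev(lapply(cfgs, similarity, theta = 1.1, s = 3, t = c(5, 5)))
  fit2 <- gpa(landmark_tbl(cfgs2))
  # rotation-invariant summaries agree
  expect_equal(procrustes_distance(fit1$consensus, fit2$consensus), 0, tolerance = 1e-6)
  d1 <- as.matrix(dist(fit1$species_means))
  d2 <- as.matrix(dist(fit2$species_means))[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("summed squared distance to consensus decreases across sweeps", {
  set.seed(9)
  cfgs <- lapply(1:8, function(i) matrix(rnorm(16, sd = 0.3), 8, 2) + cbind(1:8, (1:8)^1.5))
  names(cfgs) <- paste0("s", 1:8)
  fit <- gpa(landmark_tbl(cfgs))
  expect_true(all(diff(fit$q_history) <= 1e-10))
})

test_that("degenerate configurations raise errors", {
  flat <- matrix(0, 4, 2)  # all-coincident: zero centroid size
  good <- matrix(rnorm(8), 4, 2)
  expect_error(gpa(landmark_tbl(list(a = flat, b = good))), "zero centroid size")
})

test_that("shape PCA satisfies Parseval and the Procrustes rank bound", {
  spec <- simulation_spec(n_species = 15, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 3)
  fit <- gpa(simulate_study(spec)$landmarks)
  pca <- shape_pca(fit)
  # total score variance equals the summed retained eigenvalues
  score_var <- sum(apply(pca$scores, 2, var))
  expect_equal(score_var, sum(pca$eigenvalues[seq_len(ncol(pca$scores))]), tolerance = 1e-10)
  # similarity transforms remove 4 degrees of freedom from 2-D data
  lam <- pca$eigenvalues
  expect_true(all(lam[(2 * fit$p - 4 + 1):length(lam)] < 1e-10 * lam[1]))
  # loadings orthonormal
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # all components reproduce pairwise distances among tangent shapes
  expect_equal(as.matrix(dist(pca$scores)),
               as.matrix(dist(fit$species_tangent)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # over-asking truncates with a warning
  expect_warning(shape_pca(fit, n_components = 2 * fit$p), "truncating")
})

test_that("identical species means give an all-zero eigenvalue spectrum", {
  tri <- matrix(c(0, 0, 2, 0, 1, 2, 0, 1), 4, 2, byrow = TRUE)
  lm <- landmark_tbl(list(a = tri, b = tri, c = tri))
  fit <- gpa(lm)
  pca <- suppressWarnings(shape_pca(fit))
  expect_true(all(abs(pca$eigenvalues) < 1e-16))
})

test_that("tidiers return the documented shapes", {
  spec <- simulation_spec(n_species = 8, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 5)
  fit <- gpa(simulate_study(spec)$landmarks)
  td <- tidy(fit)
  expect_tibble(td)
  expect_named(td, c("specimen", "species", "landmark", "x", "y"))
  expect_equal(nrow(td), 8 * 6)
  g <- glance(fit)
  expect_equal(g$n_species, 8)
  expect_true(g$converged)
})
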