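mm4 <- module_map(face = 1:2, braincase = 3:4)

test_that("sigma_mult normalizes per landmark and vanishes for constant data", {
  expect_equal(sigma_mult(matrix(0, 6, 4), 2), 0)
  set.seed(20)
  U <- matrix(rnorm(10 * 4), 10, 4)
  # duplicating every landmark (same data, k doubled) leaves the rate unchanged
  expect_equal(sigma_mult(cbind(U, U), 4), sigma_mult(U, 2), tolerance = 1e-12)
  expect_error(sigma_mult(U, 0), "at least 1")
})

test_that("star-tree rates equal the analytic mean squared deviation form", {
  b <- 2.5
  tr <- star_tree(9, len = b)
  set.seed(21)
  Y <- matrix(rnorm(9 * 4), 9, 4, dimnames = list(tr$tip.label, NULL))
  bm <- bm_structure(tr)
  U <- phylo_transform(Y, bm)
  # closed form on a star: squared deviations from the mean / (branch * n * k)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(sigma_mult(U, 2), sum(Yc^2) / (b * 9 * 2), tolerance = 1e-10)
})

test_that("equal modules give ratio 1 with p near 1", {
  tr <- unit_tree(20, seed = 22)
  set.seed(23)
  Y1 <- sim_tips(tr, diag(4), seed = 23)
  Y <- cbind(Y1, Y1)  # braincase block identical to face block
  rownames(Y) <- rownames(Y1)
  res <- compare_module_rates(Y, tr, mm4, n_sim = 99, seed = 5)
  expect_equal(res$ratio, 1, tolerance = 1e-12)
  expect_gt(res$p_value, 0.9)
})

test_that("rate ratios are invariant to coordinate and time rescaling", {
  spec <- simulation_spec(n_species = 16, p = 8,
                          modules = module_map(face = 1:4, braincase = 5:8), seed = 24)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  r1 <- compare_module_rates(fit, st$tree, st$modules, n_sim = 19, seed = 6)

  Y <- fit$species_tangent * 7
  r2 <- compare_module_rates(Y, st$tree, st$modules, n_sim = 19, seed = 6)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-10)
  expect_equal(r2$sigma, r1$sigma * 49, tolerance = 1e-8)

  tr2 <- st$tree
  tr2$edge.length <- tr2$edge.length * 10  # change time units
  r3 <- compare_module_rates(fit, tr2, st$modules, n_sim = 19, seed = 6)
  expect_equal(r3$ratio, r1$ratio, tolerance = 1e-10)
  expect_equal(unname(r3$sigma), unname(r1$sigma) / 10, tolerance = 1e-8)
})

test_that("one-sided and two-sided statistics follow their counting rules", {
  spec <- simulation_spec(n_species = 12, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 25)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  two <- compare_module_rates(fit, st$tree, st$modules, n_sim = 49, seed = 7)
  one <- compare_module_rates(fit, st$tree, st$modules, n_sim = 49, seed = 7, one_sided = TRUE)
  expect_equal(two$null_ratio, one$null_ratio)  # same simulated world
  expect_equal(one$p_value,
               (sum(one$null_ratio >= one$ratio) + 1) / (49 + 1))
  stat <- pmax(two$null_ratio, 1 / two$null_ratio)
  expect_equal(two$p_value,
               (sum(stat >= max(two$ratio, 1 / two$ratio)) + 1) / (49 + 1))
})

test_that("clade_rates reduces to compare_module_rates for a single clade", {
  spec <- simulation_spec(n_species = 12, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 26)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  cl <- stats::setNames(rep("all", 12), rownames(fit$species_tangent))
  res <- clade_rates(fit, st$tree, st$modules, cl, n_sim = 9, seed = 8)
  whole <- compare_module_rates(fit, st$tree, st$modules, n_sim = 9, seed = 8)
  expect_equal(stats::setNames(res$rates$sigma2, res$rates$module), whole$sigma,
               tolerance = 1e-10)
  expect_equal(res$ratios$ratio, whole$ratio, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 0)
})

test_that("clade_rates drops small clades, reports pairs symmetrically", {
  tr <- ape::stree(8, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))  # ultrametric, two 4-tip root clades
  spec <- simulation_spec(n_species = 8, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 27)
  st <- simulate_study(spec, tree = tr)
  fit <- gpa(st$landmarks)
  sp <- rownames(fit$species_tangent)
  cl <- ifelse(sp %in% root_clade_tips(tr), "left", "right")
  names(cl) <- sp
  small <- cl
  small[1] <- "tiny"
  w <- testthat::capture_warnings(
    clade_rates(fit, st$tree, st$modules, small, n_sim = 9, seed = 9))
  expect_true(any(grepl("fewer than 3", w)))
  res <- suppressWarnings(clade_rates(fit, st$tree, st$modules, cl, n_sim = 9, seed = 9))
  expect_setequal(unique(res$rates$clade), c("left", "right"))
  pm <- pairwise_matrix(res, "face")
  expect_equal(pm, t(pm))
  expect_true(all(res$pairwise$p_value > 0 & res$pairwise$p_value <= 1))
})

test_that("non-monophyletic clade assignments raise a warning", {
  spec <- simulation_spec(n_species = 10, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 28)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  sp <- rownames(fit$species_tangent)
  cl <- stats::setNames(rep(c("odd", "even"), length.out = 10), sp)  # interleaved: not clades
  w <- testthat::capture_warnings(
    clade_rates(fit, st$tree, st$modules, cl, n_sim = 5, seed = 10))
  expect_true(any(grepl("monophyletic", w)))
})
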