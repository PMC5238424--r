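test_that("BM covariance encodes shared path lengths", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  bm <- bm_structure(tr, c("A", "B"))
  expect_equal(unname(bm$C), diag(2), tolerance = 1e-12)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  bm <- bm_structure(tr, c("A", "B", "C"))
  expect_equal(bm$C["A", "B"], 1)
  expect_equal(bm$C["A", "C"], 0)
  expect_equal(unname(diag(bm$C)), rep(2, 3))

  # any ultrametric tree: diagonal equals tree height
  tr <- unit_tree(12, seed = 4)
  bm <- bm_structure(tr)
  expect_equal(unname(bm$depths), rep(1, 12), tolerance = 1e-8)
  # T reproduces the inverse covariance
  expect_equal(crossprod(bm$Tmat), solve(bm$C), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-length terminal branches are rejected by name", {
  tr <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  expect_error(bm_structure(tr), "A")
})

test_that("phylo_transform zeroes constant columns and is exactly linear", {
  tr <- unit_tree(8, seed = 5)
  bm <- bm_structure(tr)
  set.seed(1)
  Y1 <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(bm$species, NULL))
  Y2 <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(bm$species, NULL))
  Yc <- Y1; Yc[, 2] <- 5
  expect_equal(unname(phylo_transform(Yc, bm)[, 2]), rep(0, 8), tolerance = 1e-12)
  lhs <- phylo_transform(2 * Y1 - 3 * Y2, bm)
  rhs <- 2 * phylo_transform(Y1, bm) - 3 * phylo_transform(Y2, bm)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("on a star tree the transform reduces to ordinary centering", {
  tr <- star_tree(10)
  bm <- bm_structure(tr)
  set.seed(2)
  Y <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(bm$species, NULL))
  U <- phylo_transform(Y, bm)
  expect_equal(crossprod(U), crossprod(scale(Y, scale = FALSE)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("evolutionary SSCP matches the independent-contrasts oracle", {
  tr <- ape::read.tree(text = "(((A:0.3,B:0.3):0.4,C:0.7):0.3,(D:0.5,E:0.5):0.5);")
  bm <- bm_structure(tr)
  set.seed(3)
  Y <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(bm$species, NULL))
  U <- phylo_transform(Y, bm)
  # oracle: Felsenstein's pruning contrasts, trait by trait (ape::pic)
  pics <- apply(Y[tr$tip.label, ], 2, function(col) ape::pic(col, tr))
  expect_equal(crossprod(U), crossprod(pics), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ancestral states solve weighted squared-change minimization", {
  # symmetric two-tip case
  tr <- ape::read.tree(text = "(A:1,B:1);")
  st <- ancestral_states(c(A = 0, B = 2), tr)
  expect_equal(unname(st[1, 1]), 1)

  # star tree with equal branches: root is the arithmetic mean
  tr <- star_tree(6)
  y <- stats::setNames(rnorm(6), tr$tip.label)
  st <- ancestral_states(y, tr)
  expect_equal(unname(st[1, 1]), mean(y), tolerance = 1e-10)

  # random 6-tip tree vs direct numerical minimization of sum(change^2/len)
  tr <- unit_tree(6, seed = 8)
  set.seed(4)
  Y <- matrix(rnorm(6 * 2), 6, 2, dimnames = list(tr$tip.label, NULL))
  st <- ancestral_states(Y, tr)
  score <- function(v, col) {
    states <- c(Y[tr$tip.label, col], v)
    sum((states[tr$edge[, 1]] - states[tr$edge[, 2]])^2 / tr$edge.length)
  }
  for (col in 1:2) {
    opt <- optim(rep(mean(Y[, col]), tr$Nnode), score, col = col, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(unname(st[, col]), opt$par, tolerance = 1e-5)
  }
})

test_that("root estimates are invariant to tip ordering and match the GLS mean", {
  tr <- unit_tree(7, seed = 9)
  set.seed(5)
  Y <- matrix(rnorm(7 * 2), 7, 2, dimnames = list(tr$tip.label, NULL))
  st1 <- ancestral_states(Y, tr)
  perm <- sample(rownames(Y))
  st2 <- ancestral_states(Y[perm, ], tr)
  expect_equal(st1, st2, tolerance = 1e-12)
  bm <- bm_structure(tr)
  gls_root <- as.vector(bm$root_weights %*% Y[bm$species, ])
  expect_equal(unname(attr(st1, "root")), gls_root, tolerance = 1e-10)
})

test_that("phylomorphospace places nodes and edges consistently", {
  # two tips with equal branches: root at the segment midpoint
  tr <- ape::read.tree(text = "(A:1,B:1);")
  scores <- matrix(c(0, 2, 1, 3), 2, 2, dimnames = list(c("A", "B"), c("PC1", "PC2")))
  pm <- phylomorphospace(scores, tr)
  root <- pm$nodes[pm$nodes$type == "internal", ]
  expect_equal(c(root$PC1, root$PC2), c(1, 2))

  # bifurcating n-tip tree: 2n - 2 edges; internal nodes match the optimizer-
  # free closed form used in ancestral_states
  spec <- simulation_spec(n_species = 10, p = 6,
                          modules = module_map(face = 1:3, braincase = 4:6), seed = 6)
  st <- simulate_study(spec)
  fit <- gpa(st$landmarks)
  pca <- shape_pca(fit)
  pm <- phylomorphospace(pca, st$tree)
  expect_equal(nrow(pm$edges), 2 * 10 - 2)
  anc <- ancestral_states(pca$scores[, 1:2], st$tree)
  ints <- pm$nodes[pm$nodes$type == "internal", ]
  expect_equal(ints$PC1, unname(anc[, 1]), tolerance = 1e-12)
  # ancestral states on scores equal projected ancestral states on shapes
  anc_shapes <- ancestral_states(fit$species_tangent, st$tree)
  proj <- sweep(anc_shapes, 2, pca$center) %*% pca$loadings[, 1:2]
  expect_equal(unname(anc[, 1:2]), unname(proj), tolerance = 1e-8)
})

test_that("zero-length branches are refused for ancestral states", {
  tr <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  Y <- matrix(1:3, 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  expect_error(ancestral_states(Y, tr), "positive branch lengths")
})
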