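# Shared fixtures, all built in code.

# star phylogeny with n tips of equal branch length
star_tree <- function(n, len = 1, labels = sprintf("t%d", seq_len(n))) {
  tree <- ape::stree(n, type = "star")
  tree$tip.label <- labels
  tree$edge.length <- rep(len, nrow(tree$edge))
  tree
}

# balanced/random ultrametric tree of unit height
unit_tree <- function(n, seed = 1) {
  modulrate::simulate_tree(n, seed = seed)
}

# small landmark tibble from a list of p x 2 configuration matrices; one
# specimen per species unless a named `species` vector overrides it
landmark_tbl <- function(configs, species = NULL) {
  stopifnot(!is.null(names(configs)))
  purrr::imap_dfr(configs, function(m, id) {
    sp <- if (is.null(species)) id else unname(species[id])
    tibble::tibble(
      specimen = id, species = sp,
      landmark = seq_len(nrow(m)), x = m[, 1], y = m[, 2]
    )
  })
}

# apply a similarity transform (rotation theta, scale s, translation t) to a
# p x 2 configuration
similarity <- function(m, theta = 0, s = 1, t = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * m %*% R, 2, t, "+")
}

# species x d BM tip data on a tree with trait covariance Rmat (exact joint law)
sim_tips <- function(tree, Rmat, seed = NULL) {
  C <- ape::vcv(tree)
  L <- t(chol(C))
  d <- ncol(Rmat)
  e <- eigen(Rmat, symmetric = TRUE)
  E <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  if (!is.null(seed)) set.seed(seed)
  X <- L %*% matrix(rnorm(nrow(C) * d), nrow(C), d) %*% t(E)
  rownames(X) <- rownames(C)
  X
}

# block-structured trait covariance: two modules of k landmarks each (2k
# coordinates), per-coordinate variances v1/v2, within-module equicorrelation
# w, between-module correlation rho on corresponding coordinates
block_cov <- function(k1, k2, v1 = 1, v2 = 1, w = 0, rho = 0) {
  d1 <- 2 * k1; d2 <- 2 * k2
  R11 <- v1 * ((1 - w) * diag(d1) + w)
  R22 <- v2 * ((1 - w) * diag(d2) + w)
  R12 <- matrix(0, d1, d2)
  for (i in seq_len(2 * min(k1, k2))) R12[i, i] <- rho * sqrt(v1 * v2)
  rbind(cbind(R11, R12), cbind(t(R12), R22))
}

new_pm <- function(m) modulrate:::new_pmatrix(m)

# tips descending from the first child of the root (a monophyletic group)
root_clade_tips <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kid <- tree$edge[tree$edge[, 1] == root, 2][1]
  if (kid <= ape::Ntip(tree)) tree$tip.label[kid] else ape::extract.clade(tree, kid)$tip.label
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
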