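#' Brownian-motion covariance structure of a tree
#'
#' Builds the n x n matrix `C` of shared root-to-tip path lengths implied by a
#' Brownian-motion model, together with the whitening transform `T`
#' (`t(T) %*% T == solve(C)`, computed by inverting the lower Cholesky factor)
#' and the generalized-least-squares root weights
#' `w = solve(1'C^-1 1) 1'C^-1`. These three objects are the shared mechanism
#' behind every phylogenetic statistic in the package.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param ordering Character vector of species defining row/column order;
#'   must equal the tree's tip set.
#' @return An object of class `bm_structure`: `species`, `C`, `L` (lower
#'   Cholesky factor of C), `Tmat`, `root_weights`, `depths` (diagonal of C),
#'   `ultrametric`.
#' @export
bm_structure <- function(tree, ordering = NULL) {
  tree <- validate_tree(tree)
  ordering <- ordering %||% sort(tree$tip.label)
  if (!setequal(ordering, tree$tip.label) || length(ordering) != length(tree$tip.label)) {
    abort_mr("ordering must contain exactly the tree's tips")
  }
  C <- ape::vcv(tree)[ordering, ordering]
  term_edges <- which(tree$edge[, 2] <= length(tree$tip.label))
  term_len <- tree$edge.length[term_edges]
  zero_tips <- tree$tip.label[tree$edge[term_edges, 2][term_len <= 0]]
  if (length(zero_tips)) {
    abort_mr("zero-length terminal branch(es) make the BM covariance singular: %s",
             paste(zero_tips, collapse = ", "))
  }
  if (kappa(C, exact = FALSE) > 1e12) {
    abort_mr("BM covariance is numerically singular (condition number > 1e12); check the tree")
  }
  L <- t(chol(C))                      # C = L L'
  Tmat <- forwardsolve(L, diag(nrow(C)))  # T = L^-1, so T'T = C^-1
  Ci <- chol2inv(chol(C))
  w <- colSums(Ci) / sum(Ci)
  structure(list(
    species = ordering,
    C = C,
    L = L,
    Tmat = Tmat,
    root_weights = w,
    depths = diag(C),
    ultrametric = isTRUE(attr(tree, "ultrametric"))
  ), class = "bm_structure")
}

#' Phylogenetic (GLS) whitening transform of species data
#'
#' Removes the GLS root estimate and whitens by the inverse Cholesky factor of
#' the BM covariance: `U = T (Y - 1 a')` with `a = w'Y`. `t(U) %*% U` is the
#' evolutionary sums-of-squares-and-cross-products matrix, equivalent (up to
#' the `n-1` divisor) to the covariance of phylogenetically independent
#' contrasts.
#'
#' @param Y Numeric matrix, one row per species; rownames must match
#'   `bm$species` (rows are re-ordered by name if needed).
#' @param bm A [bm_structure()].
#' @return Matrix `U`, same dimensions as `Y`, rows in `bm$species` order.
#' @export
phylo_transform <- function(Y, bm) {
  stopifnot(inherits(bm, "bm_structure"))
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) {
    if (nrow(Y) != length(bm$species)) abort_mr("Y has %d rows but the tree has %d tips", nrow(Y), length(bm$species))
    rownames(Y) <- bm$species
  }
  if (!setequal(rownames(Y), bm$species)) abort_mr("row names of Y do not match the tree's species")
  Y <- Y[bm$species, , drop = FALSE]
  a <- as.vector(bm$root_weights %*% Y)
  U <- bm$Tmat %*% sweep(Y, 2, a)
  rownames(U) <- bm$species
  U
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML estimates of the states at every internal node, equivalent to
#' branch-length-weighted squared-change parsimony: the estimates minimize
#' the sum over edges of (state change)^2 / branch length. Solved as one
#' linear system on the tree's weighted graph Laplacian, so polytomies —
#' including basal ones, i.e. star phylogenies — need no special handling;
#' the edge matrix's origin (node `n + 1`) is taken as the root.
#'
#' @param Y Numeric matrix (species x d) or vector; rownames/names must match
#'   the tree's tips.
#' @param tree Rooted `phylo` tree with positive branch lengths.
#' @return Matrix (internal nodes x d) with rownames the ape node numbers
#'   (`n+1` is the root); attribute `root` holds the root row.
#' @export
ancestral_states <- function(Y, tree) {
  tree <- validate_tree(tree)
  if (any(tree$edge.length <= 0)) abort_mr("ancestral states require strictly positive branch lengths")
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), NULL))
  Y <- as.matrix(Y)
  if (!setequal(rownames(Y), tree$tip.label)) abort_mr("row names of Y must match the tree's tips")
  Y <- Y[tree$tip.label, , drop = FALSE]

  n <- length(tree$tip.label)
  m <- tree$Nnode
  wts <- 1 / tree$edge.length
  # Weighted Laplacian over all n + m nodes, assembled edge by edge.
  N <- n + m
  L <- matrix(0, N, N)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]; w <- wts[e]
    L[i, i] <- L[i, i] + w
    L[j, j] <- L[j, j] + w
    L[i, j] <- L[i, j] - w
    L[j, i] <- L[j, i] - w
  }
  int <- (n + 1):N
  tip <- 1:n
  A <- L[int, int, drop = FALSE]
  B <- L[int, tip, drop = FALSE]
  states <- solve(A, -B %*% Y)
  rownames(states) <- as.character(int)
  colnames(states) <- colnames(Y)
  attr(states, "root") <- states[1, ]
  states
}

#' Project a phylogeny into shape space
#'
#' Places tips at their PC1/PC2 scores and internal nodes at their
#' Brownian-motion ancestral states estimated on the scores (equivalent, by
#' linearity of the GLS estimator, to estimating on full shapes and
#' projecting), and returns plot-ready node and edge tables.
#'
#' @param space A [shape_pca()] with at least 2 components, or a plain
#'   species x (>= 2) score matrix with species rownames.
#' @param tree `phylo` tree whose tips match the scored species.
#' @param groups Optional named vector mapping species to group/clade labels,
#'   passed through to the node table for coloring.
#' @return An object of class `phylomorphospace`: list with tibbles `nodes`
#'   (`node`, `label`, `type`, `PC1`, `PC2`, `group`) and `edges` (`from`,
#'   `to`, and segment coordinates `x`, `y`, `xend`, `yend`).
#' @export
phylomorphospace <- function(space, tree, groups = NULL) {
  scores <- if (inherits(space, "shape_pca")) space$scores else as.matrix(space)
  if (ncol(scores) < 2) abort_mr("phylomorphospace needs at least 2 principal components")
  if (is.null(rownames(scores))) abort_mr("scores must carry species rownames")
  tree <- validate_tree(tree)
  scores <- scores[, 1:2, drop = FALSE]
  if (!setequal(rownames(scores), tree$tip.label)) {
    abort_mr("PCA species and tree tips do not match")
  }
  anc <- ancestral_states(scores, tree)
  n <- length(tree$tip.label)
  tips <- tibble::tibble(
    node = seq_len(n), label = tree$tip.label, type = "tip",
    PC1 = unname(scores[tree$tip.label, 1]), PC2 = unname(scores[tree$tip.label, 2])
  )
  internals <- tibble::tibble(
    node = as.integer(rownames(anc)), label = NA_character_, type = "internal",
    PC1 = unname(anc[, 1]), PC2 = unname(anc[, 2])
  )
  nodes <- dplyr::bind_rows(tips, internals)
  nodes$group <- if (!is.null(groups)) unname(groups[nodes$label]) else NA_character_
  coord <- function(node, col) nodes[[col]][match(node, nodes$node)]
  edges <- tibble::tibble(
    from = tree$edge[, 1], to = tree$edge[, 2],
    x = coord(tree$edge[, 1], "PC1"), y = coord(tree$edge[, 1], "PC2"),
    xend = coord(tree$edge[, 2], "PC1"), yend = coord(tree$edge[, 2], "PC2")
  )
  structure(list(nodes = nodes, edges = edges), class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat(sprintf("Phylomorphospace: %d tips, %d internal nodes, %d edges\n",
              sum(x$nodes$type == "tip"), sum(x$nodes$type == "internal"), nrow(x$edges)))
  invisible(x)
}
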