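#' Covariance-ratio coefficient between two landmark modules
#'
#' With `S = t(U) %*% U / (n - 1)` partitioned by module into within-module
#' blocks `S11`, `S22` and the between-module block `S12`, the covariance
#' ratio is
#' \deqn{CR = \|S_{12}\|_F / \sqrt{\|S_{11}^\circ\|_F \, \|S_{22}^\circ\|_F}}
#' where the circle zeroes the diagonal of each within-module block and — by
#' default — also the covariance between the x and y coordinates of the same
#' landmark, which is a property of digitizing geometry rather than of
#' biological covariation. Values near 0 indicate modularity; values near or
#' above 1 indicate integration.
#'
#' @param U Species x 2p matrix, typically [phylo_transform()]ed tangent
#'   shapes; flattened as x1,y1,...,xp,yp.
#' @param modules A [module_map()].
#' @param exclude_within_landmark Zero same-landmark x/y covariances in the
#'   denominator blocks (default `TRUE`; set `FALSE` for sensitivity
#'   analysis).
#' @return The CR coefficient (non-negative scalar).
#' @export
cr_coefficient <- function(U, modules, exclude_within_landmark = TRUE) {
  U <- as.matrix(U)
  d <- ncol(U)
  if (d != 2 * nrow(modules)) abort_mr("U has %d columns but the module map covers %d landmarks", d, nrow(modules))
  S <- crossprod(U) / (nrow(U) - 1)
  labs <- module_labels(modules)
  cr_from_S(S,
            module_landmarks(modules, labs[1]),
            module_landmarks(modules, labs[2]),
            exclude_within_landmark)
}

# CR from a precomputed trait covariance, partitioned by landmark sets;
# shared by cr_coefficient() and the permutation loop of cr_test().
cr_from_S <- function(S, lms1, lms2, exclude_within_landmark = TRUE) {
  cols <- function(lms) sort(c(2L * lms - 1L, 2L * lms))
  i1 <- cols(lms1)
  i2 <- cols(lms2)
  owner <- column_landmark(ncol(S))
  off <- function(idx) {
    B <- S[idx, idx, drop = FALSE]
    diag(B) <- 0
    if (exclude_within_landmark) {
      same <- outer(owner[idx], owner[idx], "==")
      B[same] <- 0
    }
    if (all(B == 0)) {
      abort_mr("a module's within-block has no usable off-diagonal covariances (single landmark?)")
    }
    B
  }
  frobenius(S[i1, i2, drop = FALSE]) / sqrt(frobenius(off(i1)) * frobenius(off(i2)))
}

#' Phylogenetic modularity test (covariance ratio)
#'
#' Computes the CR coefficient on phylogenetically transformed species-mean
#' shapes and assesses it against a null distribution built by randomly
#' re-assigning whole landmarks (x and y together) to pseudo-modules of the
#' observed sizes. Modularity is signalled by a CR that is *small* relative
#' to the permuted values, so the p-value is the lower-tail proportion with
#' the add-one rule. When the number of distinct landmark assignments does
#' not exceed `n_perm`, all assignments are enumerated exactly instead.
#'
#' @param fit A [gpa()] fit, or a species x 2p numeric matrix (flattened
#'   x1,y1,...,xp,yp, species rownames) to run the statistic on data that
#'   did not pass through superimposition.
#' @param tree `phylo` tree covering the fit's species.
#' @param modules A [module_map()].
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Optional integer seed for reproducibility.
#' @param exclude_within_landmark Passed to [cr_coefficient()].
#' @return An object of class `cr_test`: `observed`, `p_value`, `null`
#'   (numeric vector of permuted/enumerated CRs), `n_perm`, `exact`,
#'   `module_sizes`.
#' @export
cr_test <- function(fit, tree, modules, n_perm = 9999, seed = NULL,
                    exclude_within_landmark = TRUE) {
  stopifnot(n_perm >= 1)
  Y <- species_matrix(fit)
  bm <- bm_structure(tree, rownames(Y))
  U <- phylo_transform(Y, bm)
  observed <- cr_coefficient(U, modules, exclude_within_landmark)

  labs <- module_labels(modules)
  p <- nrow(modules)
  k1 <- length(module_landmarks(modules, labs[1]))
  n_distinct <- choose(p, k1)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  S <- crossprod(U) / (nrow(U) - 1)
  if (exact) {
    combos <- utils::combn(p, k1, simplify = FALSE)
    null <- vapply(combos, function(s) {
      cr_from_S(S, s, setdiff(seq_len(p), s), exclude_within_landmark)
    }, numeric(1))
    # observed assignment is one of the enumerated ones: exact p, no add-one
    p_value <- mean(null <= observed + 1e-12)
  } else {
    null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      s <- sample.int(p, k1)
      cr_from_S(S, s, setdiff(seq_len(p), s), exclude_within_landmark)
    }, numeric(1)))
    p_value <- perm_pvalue(null, observed, "le")
  }
  structure(list(
    observed = observed, p_value = p_value, null = null,
    n_perm = length(null), exact = exact,
    module_sizes = stats::setNames(c(k1, p - k1), labs),
    modules = modules
  ), class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat(sprintf("Phylogenetic modularity (covariance ratio)\n  CR = %.4f, p = %.4g (%s, %d %s)\n",
              x$observed, x$p_value,
              if (x$exact) "exact enumeration" else "permutation",
              x$n_perm, if (x$exact) "assignments" else "permutations"))
  invisible(x)
}

#' Phylogenetic two-block partial least squares (integration test)
#'
#' Quantifies evolutionary integration between two landmark modules as the
#' correlation of the first pair of partial-least-squares scores computed on
#' phylogenetically transformed data: the cross-block evolutionary covariance
#' `S12` is decomposed by SVD and `r_PLS = cor(U1 v1, U2 w1)`. Significance
#' comes from permuting the species rows of the second block across the tips
#' of the tree on the *original* species means and re-applying the
#' phylogenetic transform each iteration; the p-value is the upper-tail
#' proportion with the add-one rule. `r_PLS` near 1 means integrated, near 0
#' modular.
#'
#' @inheritParams cr_test
#' @return An object of class `phylo_pls`: `r_pls`, `p_value`, `null`,
#'   `n_perm`, `left_vectors`, `right_vectors` (unit singular vectors),
#'   `scores` (tibble: species, block1, block2), `pct_covariance` (percent of
#'   total squared cross-block covariance carried by the first pair).
#' @export
phylo_pls <- function(fit, tree, modules, n_perm = 9999, seed = NULL) {
  stopifnot(n_perm >= 1)
  Y <- species_matrix(fit)
  if (nrow(Y) < 4) abort_mr("phylogenetic PLS needs at least 4 species")
  bm <- bm_structure(tree, rownames(Y))
  labs <- module_labels(modules)
  i1 <- module_columns(modules, labs[1])
  i2 <- module_columns(modules, labs[2])
  if (length(i1) < 2 || length(i2) < 2) abort_mr("each block needs at least 2 columns")

  pls_r <- function(Y1, Y2, return_full = FALSE) {
    U1 <- phylo_transform(Y1, bm)
    U2 <- phylo_transform(Y2, bm)
    S12 <- crossprod(U1, U2) / (nrow(U1) - 1)
    sv <- svd(S12)
    s1 <- as.vector(U1 %*% sv$u[, 1])
    s2 <- as.vector(U2 %*% sv$v[, 1])
    if (stats::sd(s1) < 1e-14 || stats::sd(s2) < 1e-14) {
      abort_mr("a block is constant after transformation; PLS correlation undefined")
    }
    r <- stats::cor(s1, s2)
    if (!return_full) return(r)
    list(r = r, u = sv$u[, 1], v = sv$v[, 1], d = sv$d,
         scores = tibble::tibble(species = rownames(U1), block1 = s1, block2 = s2))
  }

  Y1 <- Y[, i1, drop = FALSE]
  Y2 <- Y[, i2, drop = FALSE]
  obs <- pls_r(Y1, Y2, return_full = TRUE)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(nrow(Y2))
    Y2p <- Y2[perm, , drop = FALSE]
    rownames(Y2p) <- rownames(Y2)
    pls_r(Y1, Y2p)
  }, numeric(1)))
  structure(list(
    r_pls = obs$r,
    p_value = perm_pvalue(null, obs$r, "ge"),
    null = null, n_perm = n_perm,
    left_vectors = obs$u, right_vectors = obs$v,
    scores = obs$scores,
    pct_covariance = 100 * obs$d[1]^2 / sum(obs$d^2),
    blocks = stats::setNames(list(i1, i2), labs)
  ), class = "phylo_pls")
}

#' @export
print.phylo_pls <- function(x, ...) {
  cat(sprintf("Phylogenetic two-block PLS\n  r_PLS = %.4f, p = %.4g (%d permutations)\n  first pair carries %.1f%% of squared cross-block covariance\n",
              x$r_pls, x$p_value, x$n_perm, x$pct_covariance))
  invisible(x)
}
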