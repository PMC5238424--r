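#' Generalized Procrustes superimposition
#'
#' Partial Procrustes alignment of 2-D landmark configurations: each specimen
#' is translated to the origin, scaled to unit centroid size, and rotated to
#' the running consensus by the optimal orthogonal rotation (reflections
#' forbidden via a determinant correction of the SVD); the consensus is
#' updated and the loop repeats until its root-mean-square displacement falls
#' below `tol`. Scale stays fixed at unit centroid size (no cos-rho
#' re-scaling).
#'
#' Species means are computed by averaging the aligned conspecific specimens
#' and re-scaling the average to unit centroid size; an orthogonal projection
#' onto the tangent plane at the consensus is then applied, and the projected
#' means (`species_tangent`) are what all downstream statistics consume.
#'
#' @param landmarks Landmark tibble ([read_tps()] output): columns `specimen`,
#'   `species`, `landmark`, `x`, `y`.
#' @param tol Convergence threshold on consensus RMS displacement.
#' @param max_iter Maximum number of alignment sweeps.
#' @return An object of class `gpa`: a list with `aligned` (p x 2 x n array),
#'   `centroid_sizes` (named numeric), `consensus` (p x 2), `species_means`
#'   and `species_tangent` (species x 2p matrices, flattened as
#'   x1,y1,...,xp,yp), `species`, `p`, `iterations`, `converged`, and
#'   `q_history` (summed squared distance to the consensus per sweep).
#' @examples
#' lm <- simulate_study(simulation_spec(n_species = 8, seed = 1))$landmarks
#' fit <- gpa(lm)
#' fit$converged
#' @export
gpa <- function(landmarks, tol = 1e-10, max_iter = 100) {
  arr <- landmarks_to_array(landmarks)
  p <- dim(arr)[1]
  n <- dim(arr)[3]
  if (p < 3) abort_mr("at least 3 landmarks are required for superimposition")

  sizes <- numeric(n)
  for (i in seq_len(n)) {
    m <- arr[, , i]
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12) abort_mr("specimen '%s' has zero centroid size", dimnames(arr)[[3]][i])
    sizes[i] <- cs
    arr[, , i] <- m / cs
  }
  names(sizes) <- dimnames(arr)[[3]]

  consensus <- arr[, , 1]
  iterations <- 0L
  converged <- FALSE
  q_history <- numeric(0)
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      arr[, , i] <- arr[, , i] %*% rotation_to(arr[, , i], consensus)
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    q_history[iterations] <- sum(apply(arr, 3, function(m) sum((m - consensus)^2)))
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) {
      warn_mr("GPA did not converge after %d iterations (last RMS step %.3g)", max_iter, delta)
      break
    }
  }

  species <- attr(arr, "species")
  flat <- t(apply(arr, 3, flatten_config))  # n x 2p
  sp_levels <- sort(unique(species))
  means <- t(vapply(sp_levels, function(s) {
    m <- colMeans(flat[species == s, , drop = FALSE])
    m / sqrt(sum(m^2))  # re-project averaged shape to unit centroid size
  }, numeric(2 * p)))
  rownames(means) <- sp_levels

  structure(list(
    aligned = arr,
    centroid_sizes = sizes,
    consensus = consensus,
    species_means = means,
    species_tangent = tangent_project(means, flatten_config(consensus)),
    species = sp_levels,
    p = p,
    iterations = iterations,
    converged = converged,
    q_history = q_history
  ), class = "gpa")
}

# Optimal rotation taking configuration `x` onto `target` (both centered,
# p x 2), restricted to proper rotations: SVD of the cross-product with the
# sign of the determinant folded into the smallest singular direction.
rotation_to <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# Statistical stages accept either a gpa fit (tangent-projected species
# means) or a bare species x d matrix with species rownames.
species_matrix <- function(fit) {
  if (inherits(fit, "gpa")) return(fit$species_tangent)
  m <- as.matrix(fit)
  if (!is.numeric(m)) abort_mr("expected a gpa fit or a numeric species matrix")
  if (is.null(rownames(m))) abort_mr("a species matrix must carry species rownames")
  m
}

# Orthogonal projection of flattened shapes (rows of `m`) onto the tangent
# plane at the unit-norm consensus vector `c0`.
tangent_project <- function(m, c0) {
  c0 <- c0 / sqrt(sum(c0^2))
  proj <- m - outer(as.vector(m %*% c0) - 1, c0)
  dimnames(proj) <- dimnames(m)
  proj
}

#' Full Procrustes distance between two configurations
#'
#' Centers and scales both configurations to unit centroid size, then rotates
#' the first onto the second optimally; returns the Euclidean norm of the
#' residual. Used mainly for diagnostics and testing.
#'
#' @param a,b p x 2 coordinate matrices.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  pre <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- pre(a); b <- pre(b)
  sqrt(sum((a %*% rotation_to(a, b) - b)^2))
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes fit: %d specimens, %d species, %d landmarks\n  %s after %d iteration(s)\n",
    dim(x$aligned)[3], length(x$species), x$p,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Principal components of shape
#'
#' Eigendecomposition of the covariance matrix of the tangent-projected
#' species-mean shapes. For 2-D Procrustes data the covariance has rank at
#' most `2p - 4` (translation, rotation and scale are removed by the
#' superimposition), so requesting more components truncates with a warning.
#'
#' @param fit A [gpa()] fit.
#' @param n_components Number of components to retain, or `NULL` for all
#'   non-degenerate ones.
#' @return An object of class `shape_pca`: `eigenvalues`, `loadings`
#'   (orthonormal columns), `scores` (species x components), `prop_var`,
#'   `center`, `consensus`, `p`.
#' @export
shape_pca <- function(fit, n_components = NULL) {
  stopifnot(inherits(fit, "gpa"))
  Y <- fit$species_tangent
  if (nrow(Y) < 3) abort_mr("at least 3 species are required for a shape PCA")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  e <- eigen(stats::cov(Y), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rank <- sum(vals > max(vals[1], .Machine$double.eps) * 1e-10)
  k <- n_components %||% rank
  if (k > rank) {
    warn_mr("requested %d components but rank is %d; truncating", k, rank)
    k <- rank
  }
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  scores <- Yc %*% loadings
  if (k > 0) colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(Y)
  structure(list(
    eigenvalues = vals,
    loadings = loadings,
    scores = scores,
    prop_var = vals / sum(vals),
    center = ctr,
    consensus = fit$consensus,
    p = fit$p
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("Shape PCA: %d species, %d components retained\n", nrow(x$scores), k))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$prop_var[1], 100 * x$prop_var[min(2, length(x$prop_var))]))
  invisible(x)
}
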