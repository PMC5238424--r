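#' Phylogenetically corrected P-matrix of a module
#'
#' The evolutionary (phylogenetically corrected) phenotypic
#' variance-covariance matrix of a module's shape coordinates:
#' `P = t(U) %*% U / (n - 1)` on the module's columns of the
#' phylogenetically transformed species means, equivalent to the covariance
#' of phylogenetically independent contrasts. Procrustes alignment removes
#' four degrees of freedom from 2-D data, so these matrices are expected to
#' be rank-deficient; [skewer_indices()] handles that by working in the
#' positive eigenspace.
#'
#' @inheritParams cr_test
#' @param module Module label to extract.
#' @return An object of class `pmatrix`: `matrix` (2k x 2k), `module`,
#'   `eigenvalues`, `effective_rank` (eigenvalues above `1e-10` of the
#'   largest), `n_species`.
#' @export
evolutionary_pmatrix <- function(fit, tree, modules, module) {
  if (!module %in% module_labels(modules)) abort_mr("unknown module '%s'", module)
  Y <- species_matrix(fit)
  if (nrow(Y) < 4) abort_mr("P-matrix estimation needs at least 4 species")
  bm <- bm_structure(tree, rownames(Y))
  U <- phylo_transform(Y, bm)[, module_columns(modules, module), drop = FALSE]
  P <- crossprod(U) / (nrow(U) - 1)
  P <- (P + t(P)) / 2
  new_pmatrix(P, module, nrow(U))
}

new_pmatrix <- function(P, module = "module", n_species = NA_integer_) {
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  structure(list(
    matrix = P, module = module, eigenvalues = ev,
    effective_rank = sum(ev > 1e-10 * max(ev, .Machine$double.eps)),
    n_species = n_species
  ), class = "pmatrix")
}

#' @export
print.pmatrix <- function(x, ...) {
  cat(sprintf("P-matrix for module '%s': %d x %d, effective rank %d (n = %s species)\n",
              x$module, nrow(x$matrix), ncol(x$matrix), x$effective_rank, x$n_species))
  invisible(x)
}

#' Draw random selection gradients (skewers)
#'
#' Selection gradients for the random-skewers method: each vector has
#' independent standard-normal coordinates and is normalized to unit length,
#' giving the uniform distribution on the unit sphere.
#'
#' @param d Dimension of the trait space.
#' @param n Number of skewers (default 1000).
#' @param seed Optional integer seed.
#' @return An n x d matrix; every row has unit Euclidean norm.
#' @export
draw_skewers <- function(d, n = 1000, seed = NULL) {
  stopifnot(d >= 1, n >= 1)
  with_seed(seed, {
    B <- matrix(stats::rnorm(n * d), n, d)
    B / sqrt(rowSums(B^2))
  })
}

#' Random-skewers evolvability indices
#'
#' Applies the multivariate selection-response equation `dz = P b` to each
#' selection gradient and summarizes the response with the Hansen-Houle
#' indices: evolvability `e = b'Pb` (response in the direction of selection),
#' respondability `|Pb|` (total response magnitude), conditional
#' evolvability `c = 1 / (b' P^- b)` (response available under stabilizing
#' selection on other trait combinations), autonomy `a = c / e`, and
#' constraints, the absolute cosine between the response and the leading
#' eigenvector of `P` (the line of least resistance).
#'
#' All quantities are evaluated in the positive eigenspace of `P`
#' (eigenvalues above `rel_tol` of the largest): each skewer is projected
#' into that space and re-normalized to unit length there. Within that
#' contract the inequalities `c <= e <= r` and `a` in (0, 1] always hold,
#' even for the rank-deficient P-matrices that Procrustes data produce.
#'
#' @param P A `pmatrix` (from [evolutionary_pmatrix()]) or a plain symmetric
#'   matrix.
#' @param skewers Matrix of selection gradients ([draw_skewers()] output), or
#'   `NULL` to draw `n_skewers` fresh ones.
#' @param n_skewers,seed Used only when `skewers` is `NULL`.
#' @param rel_tol Relative eigenvalue cutoff defining the positive eigenspace.
#' @return An object of class `skewer_result`: `raw` (tibble with one row per
#'   skewer: evolvability, respondability, conditional_evolvability,
#'   autonomy, constraints), `summary` (tibble with rows mean/min/max),
#'   `responses` (n x d matrix of response vectors dz), `n_skewers`,
#'   `module`, `rank_used`.
#' @export
skewer_indices <- function(P, skewers = NULL, n_skewers = 1000, seed = NULL,
                           rel_tol = 1e-10) {
  if (inherits(P, "pmatrix")) {
    module <- P$module
    P <- P$matrix
  } else {
    module <- "module"
    P <- as.matrix(P)
  }
  if (max(abs(P - t(P))) > 1e-8) abort_mr("P must be symmetric")
  d <- ncol(P)
  e <- eigen(P, symmetric = TRUE)
  keep <- e$values > rel_tol * max(e$values, 0)
  if (!any(keep)) abort_mr("P has no positive eigenvalues; indices undefined")
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  if (is.null(skewers)) skewers <- draw_skewers(d, n_skewers, seed)
  skewers <- as.matrix(skewers)
  if (ncol(skewers) != d) abort_mr("skewers have %d columns but P is %d x %d", ncol(skewers), d, d)

  B <- skewers %*% V                         # coordinates in the eigenspace
  nb <- sqrt(rowSums(B^2))
  if (any(nb < 1e-12)) abort_mr("a skewer is orthogonal to P's positive eigenspace")
  B <- B / nb
  evol <- as.vector(B^2 %*% lam)
  resp <- sqrt(as.vector(B^2 %*% lam^2))
  cond <- 1 / as.vector(B^2 %*% (1 / lam))
  auto <- cond / evol
  constr <- abs(B[, 1] * lam[1]) / resp      # |cos(dz, leading eigenvector)|
  responses <- (B %*% (lam * t(V)))          # dz = V diag(lam) B'
  raw <- tibble::tibble(
    skewer = seq_len(nrow(B)),
    evolvability = evol, respondability = resp,
    conditional_evolvability = cond, autonomy = auto, constraints = constr
  )
  summ <- dplyr::bind_rows(
    dplyr::summarise(raw, dplyr::across(-"skewer", mean)),
    dplyr::summarise(raw, dplyr::across(-"skewer", min)),
    dplyr::summarise(raw, dplyr::across(-"skewer", max))
  )
  summ <- dplyr::bind_cols(tibble::tibble(stat = c("mean", "min", "max")), summ)
  structure(list(
    raw = raw, summary = summ, responses = responses,
    n_skewers = nrow(B), module = module, rank_used = sum(keep)
  ), class = "skewer_result")
}

#' @export
print.skewer_result <- function(x, ...) {
  cat(sprintf("Random-skewers indices for module '%s' (%d skewers, eigenspace rank %d)\n",
              x$module, x$n_skewers, x$rank_used))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
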