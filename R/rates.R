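#' Multivariate Brownian-motion rate of a landmark block
#'
#' The net evolutionary rate of a module's shape coordinates, per landmark
#' per unit branch-length time:
#' \deqn{\hat\sigma^2 = \mathrm{tr}(U'U) / (n k)}
#' where `U` is the phylogenetically transformed block and `k` its landmark
#' count. Normalizing per landmark (rather than per coordinate) makes modules
#' of unequal landmark counts comparable; for 2-D data the face:braincase
#' ratio is invariant to this choice.
#'
#' @param U Species x 2k matrix from [phylo_transform()].
#' @param k Number of landmarks in the block.
#' @return Non-negative scalar rate.
#' @export
sigma_mult <- function(U, k) {
  if (k < 1) abort_mr("landmark count k must be at least 1")
  sum(U^2) / (nrow(U) * k)
}

# Null-world machinery shared by compare_module_rates() and clade_rates():
# the observed evolutionary correlation structure, re-scaled to a common
# per-coordinate variance, eigendecomposed for simulation.
equal_rate_structure <- function(U) {
  n <- nrow(U); d <- ncol(U)
  S <- crossprod(U) / (n - 1)
  dv <- diag(S)
  v <- mean(dv)
  Corr <- diag(d)
  ok <- dv > 1e-15 * max(dv, .Machine$double.eps)
  if (any(ok)) Corr[ok, ok] <- stats::cov2cor(S[ok, ok, drop = FALSE])
  Rnull <- v * Corr
  e <- eigen(Rnull, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values)) {
    warn_mr("evolutionary correlation matrix not positive semidefinite; shrunk to nearest PSD")
  }
  lam <- pmax(e$values, 0)
  # E such that E %*% t(E) = nearest-PSD Rnull; rows of Z %*% t(E) ~ N(0, Rnull)
  E <- e$vectors %*% diag(sqrt(lam), d)
  list(E = E, v = v)
}

# One simulated tip dataset of d traits under BM with trait covariance
# E %*% t(E), on the tree encoded by bm (tip covariance C = L L').
sim_bm_tips <- function(bm, E) {
  n <- length(bm$species)
  Z <- matrix(stats::rnorm(n * ncol(E)), n, ncol(E))
  X <- bm$L %*% Z %*% t(E)
  rownames(X) <- bm$species
  X
}

#' Compare evolutionary rates between two modules
#'
#' Estimates per-module multivariate BM rates on phylogenetically transformed
#' species-mean shapes and tests the observed rate ratio against a simulated
#' null of equal rates in both modules. Null datasets are multivariate BM on
#' the same tree under a common per-landmark rate (the pooled observed rate)
#' with the observed between-trait evolutionary correlations preserved
#' (re-scaled to a common diagonal) — integration inflates the sampling
#' variance of the ratio, so it must be in the null. The default test
#' statistic is the direction-free `max(ratio, 1/ratio)`; `one_sided = TRUE`
#' uses the raw ratio and counts null ratios at least as large.
#'
#' @inheritParams cr_test
#' @param n_sim Number of simulated null datasets (default 999).
#' @param one_sided Use the one-sided upper-tail rule on the raw ratio.
#' @return An object of class `rate_test`: `sigma` (named per-module rates),
#'   `ratio` (first module / second module), `p_value`, `null_ratio`
#'   (simulated ratios), `statistic`, `n_sim`, `ultrametric`.
#' @export
compare_module_rates <- function(fit, tree, modules, n_sim = 999, seed = NULL,
                                 one_sided = FALSE) {
  stopifnot(n_sim >= 1)
  Y <- species_matrix(fit)
  bm <- bm_structure(tree, rownames(Y))
  if (!bm$ultrametric) warn_mr("tree is not ultrametric; rates are per unit branch length")
  U <- phylo_transform(Y, bm)
  labs <- module_labels(modules)
  idx <- lapply(labs, function(l) module_columns(modules, l))
  k <- vapply(labs, function(l) length(module_landmarks(modules, l)), numeric(1))
  sig <- vapply(seq_along(labs), function(m) sigma_mult(U[, idx[[m]], drop = FALSE], k[m]), numeric(1))
  names(sig) <- labs
  if (any(sig <= 0)) abort_mr("degenerate data: a module has zero evolutionary rate")
  ratio <- sig[[1]] / sig[[2]]

  ns <- equal_rate_structure(U)
  stat <- function(r) if (one_sided) r else max(r, 1 / r)
  null_ratio <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    Us <- phylo_transform(sim_bm_tips(bm, ns$E), bm)
    s1 <- sigma_mult(Us[, idx[[1]], drop = FALSE], k[1])
    s2 <- sigma_mult(Us[, idx[[2]], drop = FALSE], k[2])
    s1 / s2
  }, numeric(1)))
  p_value <- perm_pvalue(vapply(null_ratio, stat, numeric(1)), stat(ratio), "ge")
  structure(list(
    sigma = sig, ratio = unname(ratio), p_value = p_value,
    null_ratio = null_ratio, statistic = if (one_sided) "ratio" else "max(ratio, 1/ratio)",
    n_sim = n_sim, ultrametric = bm$ultrametric, modules = labs
  ), class = "rate_test")
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf(
    "Module rate comparison (multivariate BM)\n  sigma^2[%s] = %.4g, sigma^2[%s] = %.4g\n  ratio = %.3f, p = %.4g (%d simulated equal-rate datasets, statistic %s)\n",
    x$modules[1], x$sigma[[1]], x$modules[2], x$sigma[[2]],
    x$ratio, x$p_value, x$n_sim, x$statistic))
  invisible(x)
}

#' Per-clade module rates with pairwise comparisons
#'
#' Estimates face/braincase rates separately within each clade (on the clade's
#' induced subtree) and tests every pair of clades, per module, against a
#' simulated single-rate null: BM data are simulated on the pair's combined
#' subtree under a common rate with the pooled evolutionary correlation
#' structure, and the direction-free rate-ratio statistic is recomputed on
#' each simulated dataset.
#'
#' @inheritParams compare_module_rates
#' @param clades Named character vector mapping species to clade labels (or a
#'   data frame with columns `species` and `clade`).
#' @return An object of class `clade_rate_table`: `rates` (tibble: clade,
#'   module, sigma2, n_species), `ratios` (tibble: clade, ratio), `pairwise`
#'   (tibble: module, clade_a, clade_b, ratio, p_value; one row per unordered
#'   pair), `n_sim`.
#' @export
clade_rates <- function(fit, tree, modules, clades, n_sim = 999, seed = NULL) {
  if (is.data.frame(clades)) clades <- stats::setNames(clades$clade, clades$species)
  names(clades) <- normalize_taxon(names(clades))
  Y <- species_matrix(fit)
  tree <- validate_tree(tree)
  clades <- clades[intersect(names(clades), rownames(Y))]
  split_sp <- split(names(clades), unname(clades))
  sizes <- lengths(split_sp)
  if (any(sizes < 3)) {
    warn_mr("clade(s) with fewer than 3 species excluded: %s",
            paste(names(sizes)[sizes < 3], collapse = ", "))
    split_sp <- split_sp[sizes >= 3]
  }
  if (!length(split_sp)) abort_mr("no clade has at least 3 species")
  labs <- module_labels(modules)
  idx <- lapply(labs, function(l) module_columns(modules, l))
  k <- vapply(labs, function(l) length(module_landmarks(modules, l)), numeric(1))

  clade_fit <- purrr::imap(split_sp, function(sp, cl) {
    if (!ape::is.monophyletic(tree, sp)) {
      warn_mr("clade '%s' is not monophyletic in the tree", cl)
    }
    sub <- validate_tree(ape::keep.tip(tree, sp))
    bm <- bm_structure(sub, sort(sp))
    U <- phylo_transform(Y[sort(sp), , drop = FALSE], bm)
    sig <- vapply(seq_along(labs), function(m) sigma_mult(U[, idx[[m]], drop = FALSE], k[m]), numeric(1))
    list(bm = bm, sigma = stats::setNames(sig, labs), n = length(sp))
  })

  rates <- purrr::imap_dfr(clade_fit, function(cf, cl) {
    tibble::tibble(clade = cl, module = labs, sigma2 = unname(cf$sigma), n_species = cf$n)
  })
  ratios <- purrr::imap_dfr(clade_fit, function(cf, cl) {
    tibble::tibble(clade = cl, ratio = cf$sigma[[1]] / cf$sigma[[2]])
  })

  cls <- sort(names(clade_fit))
  pairs <- if (length(cls) >= 2) utils::combn(cls, 2, simplify = FALSE) else list()
  pairwise <- purrr::imap_dfr(pairs, function(pr, i) {
    a <- pr[1]; b <- pr[2]
    sp_ab <- c(split_sp[[a]], split_sp[[b]])
    sub <- validate_tree(ape::keep.tip(tree, sp_ab))
    bm_ab <- bm_structure(sub, sort(sp_ab))
    U_ab <- phylo_transform(Y[sort(sp_ab), , drop = FALSE], bm_ab)
    ns <- equal_rate_structure(U_ab)
    bma <- clade_fit[[a]]$bm; bmb <- clade_fit[[b]]$bm
    obs_r <- vapply(seq_along(labs), function(m) {
      clade_fit[[a]]$sigma[[m]] / clade_fit[[b]]$sigma[[m]]
    }, numeric(1))
    null_stat <- with_seed(substream_seed(seed, paste0("pair_", a, "_", b)), {
      vapply(seq_len(n_sim), function(s) {
        X <- sim_bm_tips(bm_ab, ns$E)
        Ua <- phylo_transform(X[bma$species, , drop = FALSE], bma)
        Ub <- phylo_transform(X[bmb$species, , drop = FALSE], bmb)
        vapply(seq_along(labs), function(m) {
          r <- sigma_mult(Ua[, idx[[m]], drop = FALSE], k[m]) /
            sigma_mult(Ub[, idx[[m]], drop = FALSE], k[m])
          max(r, 1 / r)
        }, numeric(1))
      }, numeric(length(labs)))
    })
    null_stat <- matrix(null_stat, nrow = length(labs))
    tibble::tibble(
      module = labs, clade_a = a, clade_b = b, ratio = obs_r,
      p_value = vapply(seq_along(labs), function(m) {
        perm_pvalue(null_stat[m, ], max(obs_r[m], 1 / obs_r[m]), "ge")
      }, numeric(1))
    )
  })
  structure(list(rates = rates, ratios = ratios, pairwise = pairwise, n_sim = n_sim),
            class = "clade_rate_table")
}

#' Symmetric pairwise p-value matrix for one module
#'
#' @param x A [clade_rates()] result.
#' @param module Module label.
#' @return Square symmetric matrix of p-values (diagonal `NA`).
#' @export
pairwise_matrix <- function(x, module) {
  stopifnot(inherits(x, "clade_rate_table"))
  pw <- x$pairwise[x$pairwise$module == module, ]
  cls <- sort(unique(c(pw$clade_a, pw$clade_b, x$ratios$clade)))
  m <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  for (r in seq_len(nrow(pw))) {
    m[pw$clade_a[r], pw$clade_b[r]] <- m[pw$clade_b[r], pw$clade_a[r]] <- pw$p_value[r]
  }
  m
}

#' @export
print.clade_rate_table <- function(x, ...) {
  cat(sprintf("Per-clade module rates (%d clades, %d null simulations per pair)\n",
              nrow(x$ratios), x$n_sim))
  print(tidyr::pivot_wider(x$rates, names_from = "module", values_from = "sigma2"))
  invisible(x)
}
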