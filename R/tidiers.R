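#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Procrustes fit into long aligned coordinates
#'
#' @param x A [gpa()] fit.
#' @param ... Unused.
#' @return Tibble: `specimen`, `species`, `landmark`, `x`, `y` (aligned,
#'   unit-centroid-size coordinates).
#' @export
tidy.gpa <- function(x, ...) {
  specs <- dimnames(x$aligned)[[3]]
  species <- attr(x$aligned, "species")
  purrr::map_dfr(seq_along(specs), function(i) {
    xs <- x$aligned[, 1, i]
    ys <- x$aligned[, 2, i]
    tibble::tibble(
      specimen = specs[i], species = unname(species[i]),
      landmark = seq_len(x$p), x = xs, y = ys
    )
  })
}

#' @export
glance.gpa <- function(x, ...) {
  tibble::tibble(
    n_specimens = dim(x$aligned)[3], n_species = length(x$species),
    p = x$p, iterations = x$iterations, converged = x$converged,
    procrustes_variance = sum(sweep(t(apply(x$aligned, 3, flatten_config)), 2,
                                    flatten_config(x$consensus))^2) / dim(x$aligned)[3]
  )
}

#' @export
tidy.shape_pca <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores)
  dplyr::bind_cols(tibble::tibble(species = rownames(x$scores)), scores)
}

#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$scores), n_components = ncol(x$scores),
    total_variance = sum(x$eigenvalues),
    pc1_prop = x$prop_var[1],
    pc2_prop = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_
  )
}

#' @export
tidy.cr_test <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), cr = x$null)
}

#' @export
glance.cr_test <- function(x, ...) {
  tibble::tibble(cr = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm, exact = x$exact)
}

#' @export
tidy.phylo_pls <- function(x, ...) x$scores

#' @export
glance.phylo_pls <- function(x, ...) {
  tibble::tibble(r_pls = x$r_pls, p_value = x$p_value,
                 pct_covariance = x$pct_covariance, n_perm = x$n_perm)
}

#' @export
tidy.rate_test <- function(x, ...) {
  tibble::tibble(module = names(x$sigma), sigma2 = unname(x$sigma))
}

#' @export
glance.rate_test <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, p_value = x$p_value,
                 statistic = x$statistic, n_sim = x$n_sim,
                 ultrametric = x$ultrametric)
}

#' @export
tidy.clade_rate_table <- function(x, ...) {
  dplyr::left_join(x$rates, x$ratios, by = "clade")
}

#' @export
glance.clade_rate_table <- function(x, ...) {
  tibble::tibble(n_clades = nrow(x$ratios), n_pairs = nrow(x$pairwise) /
                   max(1, length(unique(x$pairwise$module))), n_sim = x$n_sim)
}

#' @export
tidy.skewer_result <- function(x, ...) x$raw

#' @export
glance.skewer_result <- function(x, ...) {
  mx <- x$summary[x$summary$stat == "max", -1]
  names(mx) <- paste0("max_", names(mx))
  dplyr::bind_cols(
    tibble::tibble(module = x$module, n_skewers = x$n_skewers, rank_used = x$rank_used),
    mx
  )
}

#' @export
tidy.phylomorphospace <- function(x, ...) x$nodes

#' Stage summaries of a full report
#'
#' @param x A `modulrate_report`.
#' @param ... Unused.
#' @return One-row-per-stage tibble of headline statistics.
#' @export
tidy.modulrate_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$modularity)) {
    rows$modularity <- tibble::tibble(stage = "modularity", statistic = "CR",
                                      value = x$modularity$observed, p_value = x$modularity$p_value)
  }
  if (!is.null(x$integration)) {
    rows$integration <- tibble::tibble(stage = "integration", statistic = "r_PLS",
                                       value = x$integration$r_pls, p_value = x$integration$p_value)
  }
  if (!is.null(x$rates)) {
    rows$rates <- tibble::tibble(stage = "rates", statistic = "rate_ratio",
                                 value = x$rates$ratio, p_value = x$rates$p_value)
  }
  if (!is.null(x$skewers)) {
    rows$skewers <- purrr::imap_dfr(x$skewers, function(s, m) {
      mx <- s$summary[s$summary$stat == "max", ]
      tibble::tibble(stage = paste0("skewers_", m), statistic = "max_evolvability",
                     value = mx$evolvability, p_value = NA_real_)
    })
  }
  dplyr::bind_rows(rows)
}
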