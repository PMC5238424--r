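#' Configure a full comparative analysis
#'
#' Bundles the file paths, resampling effort, seed and per-stage toggles used
#' by [run_full_analysis()]. Files are checked for existence at validation
#' time, before any computation starts.
#'
#' @param tps Path to the TPS landmark file.
#' @param tree Path to the Newick/NEXUS tree.
#' @param modules Path to the module-map CSV (`landmark_index`, `module`).
#' @param clades Optional path to a clade-assignment CSV (`species`, `clade`).
#' @param n_perm Permutations for the modularity and integration tests.
#' @param n_sim Simulated null datasets for the rate tests.
#' @param n_skewers Random selection gradients per module.
#' @param seed Master seed; each stage draws from a named substream, so
#'   disabling one stage does not shift another stage's randomness.
#' @param out_dir Optional directory for `report.json` and CSV tables.
#' @param modularity,integration,rates,skewers Logical stage toggles.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(tps, tree, modules, clades = NULL,
                            n_perm = 9999, n_sim = 999, n_skewers = 1000,
                            seed = 1, out_dir = NULL,
                            modularity = TRUE, integration = TRUE,
                            rates = TRUE, skewers = TRUE) {
  cfg <- list(
    tps = tps, tree = tree, modules = modules, clades = clades,
    n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
    n_skewers = as.integer(n_skewers), seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(modularity = modularity, integration = integration,
                  rates = rates, clades = !is.null(clades), skewers = skewers)
  )
  if (any(c(cfg$n_perm, cfg$n_sim, cfg$n_skewers) < 1)) {
    abort_mr("n_perm, n_sim and n_skewers must all be at least 1")
  }
  for (f in c("tps", "tree", "modules", "clades")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort_mr("config error: %s file does not exist: %s", f, cfg[[f]])
    }
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()]; relative paths are resolved against the YAML file's
#'   directory.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_mr("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("tps", "tree", "modules", "clades")) {
    if (!is.null(y[[f]]) && !file.exists(y[[f]])) y[[f]] <- file.path(base, y[[f]])
  }
  do.call(analysis_config, y[intersect(names(y), names(formals(analysis_config)))])
}

#' Run the full comparative pipeline
#'
#' Executes the stages in order — I/O and taxon reconciliation, Procrustes
#' superimposition, shape PCA, then (as toggled) the covariance-ratio
#' modularity test, phylogenetic PLS integration, module rate comparison,
#' per-clade rates, and random-skewers evolvability per module — and collects
#' the results in a report with a provenance block. All randomness derives
#' from `config$seed` via named substreams.
#'
#' @param config An [analysis_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `modulrate_report`: `gpa`, `pca`,
#'   `modularity` (`cr_test`), `integration` (`phylo_pls`), `rates`
#'   (`rate_test`), `clades` (`clade_rate_table` or NULL), `skewers` (named
#'   list of `skewer_result`), `provenance`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  landmarks <- read_tps(config$tps)
  tree <- read_tree(config$tree)
  modules <- read_module_map(config$modules)
  matched <- match_taxa(landmarks, tree, policy = "intersect")
  say("io: %d specimens, %d species, %d landmarks; tree with %d tips",
      length(unique(matched$landmarks$specimen)),
      length(unique(matched$landmarks$species)),
      max(matched$landmarks$landmark), length(matched$tree$tip.label))

  fit <- gpa(matched$landmarks)
  say("gpa: %s after %d iterations", if (fit$converged) "converged" else "NOT converged",
      fit$iterations)
  pca <- shape_pca(fit)

  report <- list(gpa = fit, pca = pca, modularity = NULL, integration = NULL,
                 rates = NULL, clades = NULL, skewers = NULL)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_mr("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (config$stages$modularity) {
    report$modularity <- run_stage("modularity", cr_test(
      fit, matched$tree, modules, n_perm = config$n_perm,
      seed = substream_seed(config$seed, "modularity")))
    say("modularity: CR = %.4f, p = %.4g", report$modularity$observed, report$modularity$p_value)
  }
  if (config$stages$integration) {
    report$integration <- run_stage("integration", phylo_pls(
      fit, matched$tree, modules, n_perm = config$n_perm,
      seed = substream_seed(config$seed, "integration")))
    say("integration: r_PLS = %.4f, p = %.4g", report$integration$r_pls, report$integration$p_value)
  }
  if (config$stages$rates) {
    report$rates <- run_stage("rates", compare_module_rates(
      fit, matched$tree, modules, n_sim = config$n_sim,
      seed = substream_seed(config$seed, "rates")))
    say("rates: ratio = %.3f, p = %.4g", report$rates$ratio, report$rates$p_value)
  }
  if (config$stages$clades) {
    cl <- utils::read.csv(config$clades, stringsAsFactors = FALSE)
    report$clades <- run_stage("clades", clade_rates(
      fit, matched$tree, modules, cl, n_sim = config$n_sim,
      seed = substream_seed(config$seed, "clades")))
    say("clades: %d clades analysed", nrow(report$clades$ratios))
  }
  if (config$stages$skewers) {
    report$skewers <- purrr::map(
      stats::setNames(module_labels(modules), module_labels(modules)),
      function(m) run_stage("skewers", {
        P <- evolutionary_pmatrix(fit, matched$tree, modules, m)
        skewer_indices(P, n_skewers = config$n_skewers,
                       seed = substream_seed(config$seed, paste0("skewers_", m)))
      }))
    say("skewers: %d modules x %d skewers", length(report$skewers), config$n_skewers)
  }

  report$provenance <- list(
    package = "modulrate",
    version = as.character(utils::packageVersion("modulrate")),
    seed = config$seed,
    n_perm = config$n_perm, n_sim = config$n_sim, n_skewers = config$n_skewers,
    stages = config$stages,
    inputs = list(tps = config$tps, tree = config$tree,
                  modules = config$modules, clades = config$clades),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  report <- structure(report, class = "modulrate_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (all stage statistics including null distributions),
#' `table_rates.csv` (per-module and per-clade rates with ratios) and
#' `table_evolvability.csv` (mean/min/max skewer indices per module).
#'
#' @param report A `modulrate_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "modulrate_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$rates)) {
    tab <- tibble::tibble(
      clade = "all", module = names(report$rates$sigma),
      sigma2 = unname(report$rates$sigma)
    )
    if (!is.null(report$clades)) {
      tab <- dplyr::bind_rows(tab, report$clades$rates[, c("clade", "module", "sigma2")])
    }
    utils::write.csv(tab, file.path(dir, "table_rates.csv"), row.names = FALSE)
  }
  if (!is.null(report$skewers)) {
    ev <- purrr::imap_dfr(report$skewers, function(s, m) {
      dplyr::bind_cols(tibble::tibble(module = m), s$summary)
    })
    utils::write.csv(ev, file.path(dir, "table_evolvability.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# Plain-list view of a report for JSON serialization (drops the large
# aligned-coordinate array, keeps every statistic and null distribution).
report_as_list <- function(report) {
  list(
    provenance = report$provenance,
    gpa = list(converged = report$gpa$converged, iterations = report$gpa$iterations,
               n_species = length(report$gpa$species), p = report$gpa$p),
    pca = list(eigenvalues = report$pca$eigenvalues,
               prop_var = report$pca$prop_var),
    modularity = if (!is.null(report$modularity)) {
      list(cr = report$modularity$observed, p_value = report$modularity$p_value,
           exact = report$modularity$exact, n_perm = report$modularity$n_perm,
           null = report$modularity$null)
    },
    integration = if (!is.null(report$integration)) {
      list(r_pls = report$integration$r_pls, p_value = report$integration$p_value,
           pct_covariance = report$integration$pct_covariance,
           n_perm = report$integration$n_perm, null = report$integration$null)
    },
    rates = if (!is.null(report$rates)) {
      list(sigma = as.list(report$rates$sigma), ratio = report$rates$ratio,
           p_value = report$rates$p_value, statistic = report$rates$statistic,
           n_sim = report$rates$n_sim, null_ratio = report$rates$null_ratio)
    },
    clades = if (!is.null(report$clades)) {
      list(rates = as.data.frame(report$clades$rates),
           ratios = as.data.frame(report$clades$ratios),
           pairwise = as.data.frame(report$clades$pairwise))
    },
    skewers = if (!is.null(report$skewers)) {
      purrr::map(report$skewers, function(s) {
        list(n_skewers = s$n_skewers, rank_used = s$rank_used,
             summary = as.data.frame(s$summary))
      })
    }
  )
}

#' @export
print.modulrate_report <- function(x, ...) {
  cat("modulrate analysis report\n")
  cat(sprintf("  seed %d, %s\n", x$provenance$seed, x$provenance$timestamp))
  if (!is.null(x$modularity)) {
    cat(sprintf("  modularity:  CR = %.4f, p = %.4g\n", x$modularity$observed, x$modularity$p_value))
  }
  if (!is.null(x$integration)) {
    cat(sprintf("  integration: r_PLS = %.4f, p = %.4g\n", x$integration$r_pls, x$integration$p_value))
  }
  if (!is.null(x$rates)) {
    cat(sprintf("  rates:       ratio = %.3f, p = %.4g\n", x$rates$ratio, x$rates$p_value))
  }
  if (!is.null(x$skewers)) {
    for (m in names(x$skewers)) {
      mx <- x$skewers[[m]]$summary[x$skewers[[m]]$summary$stat == "max", ]
      cat(sprintf("  skewers[%s]: max e = %.4g, max r = %.4g, max a = %.3f\n",
                  m, mx$evolvability, mx$respondability, mx$autonomy))
    }
  }
  invisible(x)
}
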