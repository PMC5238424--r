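#' Read a time-calibrated phylogeny
#'
#' Thin wrapper over \pkg{ape}'s Newick/NEXUS readers that enforces the
#' contract the comparative machinery needs: branch lengths present and
#' non-negative, tip labels unique. Polytomies are permitted. Tip labels are
#' normalized (whitespace trimmed, internal whitespace replaced by
#' underscores) so they match landmark species labels exactly.
#'
#' @param path Tree file path.
#' @param format `"auto"` (sniff from content), `"newick"`, or `"nexus"`.
#' @return An \pkg{ape} `phylo` object with attribute `ultrametric` (logical,
#'   within `ape::is.ultrametric()` tolerance).
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_mr("tree file not found: %s", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tree <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) abort_mr("could not parse %s tree '%s': %s", format, path, conditionMessage(e))
  )
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) abort_mr("could not parse tree file: %s", path)
  validate_tree(tree)
}

# Contract checks shared by read_tree() and the simulator.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort_mr("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length)) abort_mr("branch lengths required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort_mr("branch lengths must be finite and non-negative")
  }
  tree$tip.label <- normalize_taxon(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) abort_mr("duplicate tip labels in tree")
  attr(tree, "ultrametric") <- ape::is.ultrametric(tree, option = 2)
  tree
}

#' Reconcile landmark data with a phylogeny
#'
#' Matches species labels between a landmark tibble and a tree by exact string
#' comparison after normalization. Under `policy = "intersect"` both objects
#' are pruned to the shared species (branch lengths of the induced subtree are
#' preserved by `ape::keep.tip()`); under `policy = "strict"` any mismatch is
#' an error.
#'
#' @param landmarks Landmark tibble ([read_tps()] output).
#' @param tree `phylo` tree.
#' @param policy `"intersect"` or `"strict"`.
#' @return A list with elements `landmarks` (tibble, rows ordered by species)
#'   and `tree` (`phylo`), covering an identical species set.
#' @export
match_taxa <- function(landmarks, tree, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  validate_landmarks(landmarks)
  tree <- validate_tree(tree)
  data_sp <- sort(unique(landmarks$species))
  tree_sp <- sort(tree$tip.label)
  shared <- intersect(data_sp, tree_sp)
  only_data <- setdiff(data_sp, tree_sp)
  only_tree <- setdiff(tree_sp, data_sp)
  fmt <- function(x) if (length(x)) paste(x, collapse = ", ") else "none"
  if (length(shared) < 3) {
    abort_mr(paste0(
      "fewer than 3 species shared between data and tree.\n",
      "  in data only: %s\n  in tree only: %s"),
      fmt(only_data), fmt(only_tree))
  }
  if (policy == "strict" && (length(only_data) || length(only_tree))) {
    abort_mr("taxon mismatch under strict policy (data-only: %s; tree-only: %s)",
             paste(only_data, collapse = ", "), paste(only_tree, collapse = ", "))
  }
  if (length(only_tree)) tree <- validate_tree(ape::keep.tip(tree, shared))
  landmarks <- landmarks |>
    dplyr::filter(.data$species %in% shared) |>
    dplyr::arrange(.data$species, .data$specimen, .data$landmark)
  list(landmarks = landmarks, tree = tree)
}
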