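#' Define a two-module landmark partition
#'
#' A module map assigns every landmark to exactly one of two modules,
#' typically the face and the braincase of a skull. Landmark indices are
#' 1-based and must cover `1..p` with no overlap.
#'
#' @param ... Exactly two named integer vectors of landmark indices, e.g.
#'   `module_map(face = 1:10, braincase = 11:20)`.
#' @return A tibble with columns `landmark` and `module` (factor, levels in
#'   the order given), of class `module_map`.
#' @examples
#' module_map(face = 1:5, braincase = 6:10)
#' @export
module_map <- function(...) {
  parts <- list(...)
  if (length(parts) != 2 || is.null(names(parts)) || any(!nzchar(names(parts)))) {
    abort_mr("module_map() takes exactly two named sets of landmark indices")
  }
  idx <- unlist(parts, use.names = FALSE)
  if (any(idx != as.integer(idx)) || any(idx < 1)) abort_mr("landmark indices must be positive integers")
  if (anyDuplicated(idx)) abort_mr("a landmark is assigned to more than one module")
  p <- max(idx)
  if (!setequal(idx, seq_len(p))) {
    abort_mr("module assignments must cover landmarks 1..%d with no gaps", p)
  }
  if (any(lengths(parts) == 0)) abort_mr("both modules must be non-empty")
  out <- tibble::tibble(
    landmark = as.integer(idx),
    module = factor(rep(names(parts), lengths(parts)), levels = names(parts))
  )
  out <- dplyr::arrange(out, .data$landmark)
  class(out) <- c("module_map", class(out))
  out
}

#' Read a module map from CSV
#'
#' Expects columns `landmark_index` (or `landmark`) and `module`, one row per
#' landmark, exactly two distinct module labels.
#'
#' @param path CSV file path.
#' @return A `module_map` tibble.
#' @export
read_module_map <- function(path) {
  if (!file.exists(path)) abort_mr("module map file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lm_col <- intersect(c("landmark_index", "landmark"), names(df))[1]
  if (is.na(lm_col) || !"module" %in% names(df)) {
    abort_mr("module map needs columns 'landmark_index' (or 'landmark') and 'module'")
  }
  labs <- unique(df$module)
  if (length(labs) != 2) abort_mr("expected exactly 2 module labels, found %d", length(labs))
  args <- stats::setNames(
    lapply(labs, function(l) as.integer(df[[lm_col]][df$module == l])),
    labs
  )
  do.call(module_map, args)
}

#' @export
write_module_map <- function(modules, path) {
  utils::write.csv(
    data.frame(landmark_index = modules$landmark, module = as.character(modules$module)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

module_labels <- function(modules) levels(modules$module)

module_landmarks <- function(modules, label) {
  modules$landmark[modules$module == label]
}

# Column indices of a module's coordinates in the flattened
# (x1, y1, ..., xp, yp) layout.
module_columns <- function(modules, label) {
  lms <- module_landmarks(modules, label)
  sort(c(2L * lms - 1L, 2L * lms))
}

# Map flattened column index -> owning landmark (for the same-landmark
# x/y exclusion in the covariance-ratio denominator).
column_landmark <- function(d) rep(seq_len(d / 2), each = 2)
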