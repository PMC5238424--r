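#' Read a TPS landmark file
#'
#' Parses the tpsDig2 dialect of the TPS format: an `LM=p` (or `LM3=p`) header
#' per specimen, `p` whitespace-separated coordinate rows, and trailing
#' `ID=`, `IMAGE=` and `SCALE=` records. Only two-dimensional data are
#' supported; `LM3=` blocks raise an error. When a `SCALE=` record is present
#' the coordinates of that specimen are multiplied by it, so all specimens end
#' up in common physical units.
#'
#' Species labels are derived from specimen IDs via `species_from_id`; the
#' default strips a `__<n>` replicate suffix (the convention used by
#' [generate_study()]), so IDs without such a suffix map to themselves, i.e.
#' one specimen per species.
#'
#' @param path Path to a TPS file.
#' @param species_from_id Function mapping a character vector of specimen IDs
#'   to species labels.
#' @return A tibble with columns `specimen`, `species`, `landmark`, `x`, `y`,
#'   one row per landmark per specimen. Landmark indices are 1-based.
#' @seealso [write_tps()], [gpa()]
#' @export
read_tps <- function(path, species_from_id = function(id) sub("__\\d+$", "", id)) {
  if (!file.exists(path)) abort_mr("TPS file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_mr("TPS file is empty: %s", path)

  is_header <- grepl("^LM3?=", lines, ignore.case = TRUE)
  if (!is_header[1]) abort_mr("TPS file must start with an LM= record: %s", path)
  starts <- which(is_header)
  ends <- c(starts[-1] - 1, length(lines))

  specimens <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    header <- block[1]
    if (grepl("^LM3=", header, ignore.case = TRUE)) {
      abort_mr("3-D landmark data (LM3=) are not supported; this pipeline is strictly 2-D")
    }
    p <- suppressWarnings(as.integer(sub("^LM=", "", header, ignore.case = TRUE)))
    if (is.na(p) || p < 1) abort_mr("unparseable LM= record: '%s'", header)
    body <- block[-1]
    is_kv <- grepl("^[A-Za-z]+=", body)
    coord_rows <- body[!is_kv]
    kv <- body[is_kv]
    id <- sub("^ID=", "", kv[grepl("^ID=", kv, ignore.case = TRUE)][1], ignore.case = TRUE)
    scale_rec <- kv[grepl("^SCALE=", kv, ignore.case = TRUE)]
    scale <- if (length(scale_rec)) as.numeric(sub("^SCALE=", "", scale_rec[1], ignore.case = TRUE)) else 1
    label <- if (is.na(id) || !nzchar(id)) sprintf("specimen_%d", s) else id
    if (length(coord_rows) != p) {
      abort_mr("specimen '%s': LM=%d but %d coordinate rows found", label, p, length(coord_rows))
    }
    xy <- do.call(rbind, lapply(coord_rows, function(r) {
      vals <- suppressWarnings(as.numeric(strsplit(r, "[[:space:],]+")[[1]]))
      vals <- vals[!is.na(vals)]
      if (length(vals) != 2) abort_mr("specimen '%s': expected 2 coordinates per row, got '%s'", label, r)
      vals
    }))
    if (!all(is.finite(xy))) abort_mr("specimen '%s': non-finite coordinates", label)
    tibble::tibble(
      specimen = label, landmark = seq_len(p),
      x = xy[, 1] * scale, y = xy[, 2] * scale
    )
  })

  labels <- purrr::map_chr(specimens, ~ .x$specimen[1])
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) abort_mr("duplicate specimen ID(s): %s", paste(dup, collapse = ", "))
  out <- dplyr::bind_rows(specimens)
  p_per <- dplyr::count(out, .data$specimen)$n
  if (length(unique(p_per)) != 1) {
    abort_mr("all specimens must share the same landmark count; found %s",
             paste(unique(p_per), collapse = ", "))
  }
  out$species <- normalize_taxon(species_from_id(out$specimen))
  dplyr::select(out, "specimen", "species", "landmark", "x", "y")
}

#' Write landmarks to a TPS file
#'
#' Inverse of [read_tps()] up to numeric formatting: one `LM=` block per
#' specimen with an `ID=` record. No `SCALE=` records are written (coordinates
#' are assumed to be in final units).
#'
#' @param landmarks Landmark tibble as returned by [read_tps()].
#' @param path Output path.
#' @param digits Significant digits used for coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path, digits = 10) {
  validate_landmarks(landmarks)
  blocks <- landmarks |>
    dplyr::group_by(.data$specimen) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$landmark)
      c(sprintf("LM=%d", nrow(df)),
        sprintf(paste0("%.", digits, "g %.", digits, "g"), df$x, df$y),
        sprintf("ID=%s", key$specimen))
    })
  writeLines(unlist(blocks), path)
  invisible(path)
}

# Shared validation for the long landmark-tibble contract.
validate_landmarks <- function(landmarks) {
  req <- c("specimen", "species", "landmark", "x", "y")
  missing_cols <- setdiff(req, names(landmarks))
  if (length(missing_cols)) {
    abort_mr("landmark data lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    abort_mr("landmark coordinates contain non-finite values")
  }
  counts <- dplyr::count(landmarks, .data$specimen)
  if (length(unique(counts$n)) != 1) abort_mr("unequal landmark counts across specimens")
  sp_map <- dplyr::distinct(landmarks, .data$specimen, .data$species)
  if (anyDuplicated(sp_map$specimen)) abort_mr("a specimen maps to more than one species")
  invisible(landmarks)
}

# Long tibble -> p x 2 x n array (geomorph-style), with specimen dimnames and
# a species attribute. The flattening convention everywhere downstream is
# (x1, y1, x2, y2, ..., xp, yp), so module column blocks stay contiguous.
landmarks_to_array <- function(landmarks) {
  validate_landmarks(landmarks)
  specs <- unique(landmarks$specimen)
  p <- max(landmarks$landmark)
  arr <- array(NA_real_, dim = c(p, 2, length(specs)),
               dimnames = list(NULL, c("x", "y"), specs))
  for (i in seq_along(specs)) {
    df <- dplyr::arrange(landmarks[landmarks$specimen == specs[i], ], landmark)
    arr[, 1, i] <- df$x
    arr[, 2, i] <- df$y
  }
  sp_map <- dplyr::distinct(landmarks, .data$specimen, .data$species)
  attr(arr, "species") <- stats::setNames(sp_map$species, sp_map$specimen)[specs]
  arr
}

# p x 2 configuration -> flat vector (x1, y1, ..., xp, yp)
flatten_config <- function(m) as.vector(t(m))

unflatten_config <- function(v) matrix(v, ncol = 2, byrow = TRUE)

centroid_size <- function(m) {
  cent <- colMeans(m)
  sqrt(sum((m[, 1] - cent[1])^2 + (m[, 2] - cent[2])^2))
}
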