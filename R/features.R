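# Morphometric features of a segmented cell.
#
# Thirteen scalars describe nucleus geometry and intensity, cytoplasm
# intensity, cell area and the nucleus/cell area ratio (N/C ratio, the key
# cytological cancer indicator). Conventions chosen so every example value is
# exact on hand-countable inputs:
#   * perimeter = number of nucleus pixels with at least one 4-neighbor
#     outside the mask (boundary-pixel count);
#   * roundness = circularity 4*pi*A/P^2 under that perimeter;
#   * homogeneity = histogram energy sum(p_i^2) over the 256-bin normalized
#     gray histogram of the nucleus (1 iff uniform intensity);
#   * length/width = larger/smaller side of the axis-aligned bounding box,
#     so aspect ratio = W/L lies in (0, 1].

#' Canonical morphometric feature names, in fixed order
#' @return character vector of length 13.
#' @export
morpho_names <- function() {
  c("nucleus_area", "nucleus_length", "nucleus_width", "aspect_ratio",
    "nucleus_perimeter", "nucleus_roundness", "nucleus_homogeneity",
    "nucleus_brightness", "cytoplasm_max", "cytoplasm_min",
    "cytoplasm_brightness", "cell_area", "nucleus_cell_ratio")
}

#' Convert an RGB pixel array to gray levels
#'
#' Luma transform `0.299 R + 0.587 G + 0.114 B`, rounded half-up to an
#' integer gray level. A matrix input is returned unchanged (already gray).
#'
#' @param pixels H x W x 3 array or H x W matrix with values in `[0, 255]`.
#' @return H x W numeric matrix of integer gray levels.
#' @export
to_gray <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 3)
  out <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  matrix(round_half_up(out), dim(pixels)[1], dim(pixels)[2])
}

# boundary pixels: in the mask, with >= 1 four-neighbor outside (image
# border counts as outside)
boundary_pixels <- function(mask) {
  interior <- shift_mask(mask, 1, 0) & shift_mask(mask, -1, 0) &
    shift_mask(mask, 0, 1) & shift_mask(mask, 0, -1)
  mask & !interior
}

#' Extract the 13 morphometric scalars
#'
#' @param gray H x W gray-level matrix (see [to_gray()]).
#' @param nucleus_mask,cytoplasm_mask logical H x W masks; must be nonempty
#'   and disjoint.
#' @return named numeric vector of length 13 in [morpho_names()] order.
#' @export
extract_morphometrics <- function(gray, nucleus_mask, cytoplasm_mask) {
  if (!any(nucleus_mask)) stop("nucleus_mask is empty")
  if (!any(cytoplasm_mask)) stop("cytoplasm_mask is empty")
  if (any(nucleus_mask & cytoplasm_mask))
    stop("nucleus_mask and cytoplasm_mask must be disjoint")
  stopifnot(all(dim(gray) == dim(nucleus_mask)),
            all(dim(gray) == dim(cytoplasm_mask)))

  a_n <- sum(nucleus_mask)
  rows <- range(which(rowSums(nucleus_mask) > 0))
  cols <- range(which(colSums(nucleus_mask) > 0))
  side1 <- diff(rows) + 1
  side2 <- diff(cols) + 1
  l_n <- max(side1, side2)
  w_n <- min(side1, side2)
  p_n <- sum(boundary_pixels(nucleus_mask))

  nuc <- gray[nucleus_mask]
  hist_counts <- tabulate(pmin(255, pmax(0, round_half_up(nuc))) + 1L, 256L)
  p_i <- hist_counts / a_n
  cyt <- gray[cytoplasm_mask]

  out <- c(
    nucleus_area = a_n,
    nucleus_length = l_n,
    nucleus_width = w_n,
    aspect_ratio = w_n / l_n,
    nucleus_perimeter = p_n,
    nucleus_roundness = 4 * pi * a_n / p_n^2,
    nucleus_homogeneity = sum(p_i^2),
    nucleus_brightness = mean(nuc),
    cytoplasm_max = max(cyt),
    cytoplasm_min = min(cyt),
    cytoplasm_brightness = mean(cyt),
    cell_area = a_n + sum(cytoplasm_mask),
    nucleus_cell_ratio = a_n / (a_n + sum(cytoplasm_mask))
  )
  out
}

#' Extract the full feature vector of one cell
#'
#' Composes [to_gray()], [extract_morphometrics()] and [compute_bhf()] (BHF
#' computed on the whole cell region, nucleus plus cytoplasm). Deterministic.
#'
#' @param cell a `cell_image` (see [generate_cell()]).
#' @param P,R BHF neighborhood parameters.
#' @return object of class `cell_features`: list with `morpho` (named
#'   13-vector), `bhf` (named vector, see [compute_bhf()]), `label`,
#'   `image_id`.
#' @export
extract_features <- function(cell, P = 8, R = 1) {
  stopifnot(inherits(cell, "cell_image"))
  gray <- to_gray(cell$pixels)
  morpho <- extract_morphometrics(gray, cell$nucleus_mask, cell$cytoplasm_mask)
  bhf <- compute_bhf(gray, cell$nucleus_mask | cell$cytoplasm_mask, P = P, R = R)
  structure(list(morpho = morpho, bhf = bhf$vector,
                 label = cell$label, image_id = cell$image_id),
            class = "cell_features")
}

#' @export
print.cell_features <- function(x, ...) {
  cat(sprintf("<cell_features %s> label %s, %d morphometrics + %d BHF entries\n",
              x$image_id %||% "?", x$label %||% "?",
              length(x$morpho), length(x$bhf)))
  invisible(x)
}

#' Feature table for a list of cells
#'
#' @param cells list of `cell_image` objects.
#' @param P,R BHF parameters.
#' @return data.frame: `image_id`, `label`, 13 morphometric columns, BHF
#'   columns.
#' @export
feature_table <- function(cells, P = 8, R = 1) {
  fv <- lapply(cells, extract_features, P = P, R = R)
  num <- do.call(rbind, lapply(fv, function(f) c(f$morpho, f$bhf)))
  data.frame(image_id = vapply(fv, function(f) f$image_id %||% NA_character_, ""),
             label = vapply(fv, function(f) f$label %||% NA_character_, ""),
             num, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Feature groups for subset selection
#'
#' Selection operates on 14 groups: the 13 morphometric scalars plus the BHF
#' block as a single selectable unit, so a "seven feature" subset counts BHF
#' as one feature.
#'
#' @param feature_names column names of a feature matrix/table.
#' @return named list mapping each group to its member column names.
#' @export
feature_groups <- function(feature_names) {
  g <- lapply(morpho_names(), function(nm) nm[nm %in% feature_names])
  names(g) <- morpho_names()
  bhf <- grep("^bhf_", feature_names, value = TRUE)
  if (length(bhf)) g$bhf <- bhf
  g <- g[vapply(g, length, 0L) > 0]
  if (!length(g)) { # not the canonical schema: one group per column
    g <- as.list(feature_names)
    names(g) <- feature_names
  }
  g
}

#' Reduce a feature vector or table to a subset of groups
#'
#' @param x a `cell_features` object, or a numeric feature matrix/data.frame
#'   with canonical column names.
#' @param subset binary/logical vector over the feature groups, or a preset
#'   name: `"all"`, or `"pruned7"` — the reduced seven-feature set (nucleus
#'   area, roundness and brightness; cytoplasm brightness; cell area; N/C
#'   ratio; the BHF block as the seventh feature).
#' @return reduced named numeric vector (for `cell_features`) or the reduced
#'   matrix/data.frame columns, in canonical order.
#' @export
reduce_features <- function(x, subset = "all") {
  if (inherits(x, "cell_features")) {
    v <- c(x$morpho, x$bhf)
    groups <- feature_groups(names(v))
    keep <- subset_to_keep(subset, groups)
    return(v[unlist(groups[keep], use.names = FALSE)])
  }
  nms <- colnames(x)
  groups <- feature_groups(nms)
  keep <- subset_to_keep(subset, groups)
  x[, unlist(groups[keep], use.names = FALSE), drop = FALSE]
}

#' The pruned seven-feature group subset
#' @return character vector of the 7 group names.
#' @export
pruned7_groups <- function() {
  c("nucleus_area", "nucleus_roundness", "nucleus_brightness",
    "cytoplasm_brightness", "cell_area", "nucleus_cell_ratio", "bhf")
}

subset_to_keep <- function(subset, groups) {
  if (is.character(subset) && length(subset) == 1) {
    keep <- switch(subset,
      all = names(groups),
      pruned7 = intersect(names(groups), pruned7_groups()),
      stop("unknown feature preset: ", subset))
  } else {
    if (length(subset) != length(groups))
      stop("subset mask length ", length(subset), " != number of groups ",
           length(groups))
    keep <- names(groups)[as.logical(subset)]
  }
  if (!length(keep)) stop("subset must keep at least one feature group")
  keep
}

#' Write / read a feature table as CSV
#'
#' The file starts with a schema comment line; columns are `image_id`,
#' `label`, the 13 morphometric scalars, then the BHF block.
#'
#' @param features data.frame from [feature_table()].
#' @param path CSV path.
#' @return `path`, invisibly (write) / the data.frame (read).
#' @export
write_features <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cytoswarm feature table v1", con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Numeric feature matrix and labels from a feature table
#'
#' @param features data.frame from [feature_table()] / [read_features()].
#' @return list with `x` (numeric matrix) and `y` (character labels).
#' @export
feature_matrix <- function(features) {
  num_cols <- setdiff(colnames(features), c("image_id", "label"))
  x <- as.matrix(features[, num_cols, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = features$label)
}
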