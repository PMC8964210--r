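# Synthetic single-cell image generator.
#
# Emulates the seven Herlev-style Pap smear classes: across the dysplasia
# grades the nucleus enlarges and darkens while the cytoplasm shrinks, ending
# in carcinoma in situ with a very large malignant nucleus. Cells are drawn
# as two nested rasterized ellipses (cytoplasm, nucleus) with class-dependent
# mean intensities, Gaussian pixel noise and a band-limited sinusoidal
# texture. Masks are the exact rasterized ellipse interiors, so every
# geometric feature downstream has a pixel-level ground truth.

#' Canonical seven cell classes
#'
#' Class names in the canonical order used throughout the package: the three
#' normal categories (superficial/preliminary squamous, moderate/intermediate
#' squamous, columnar) followed by the four cancerous ones (carcinoma in
#' situ and the three dysplastic grades).
#'
#' @return character vector of length 7.
#' @export
cell_classes <- function() {
  c("preliminary_squamous", "moderate_squamous", "columnar",
    "in_situ", "preliminary_dysplastic", "intermediate_dysplastic",
    "last_stage_dysplastic")
}

#' Normal / cancerous grouping of the seven classes
#'
#' @return list with elements `normal` (3 classes) and `cancerous` (4 classes).
#' @export
class_groups <- function() {
  cls <- cell_classes()
  list(normal = cls[1:3], cancerous = cls[4:7])
}

#' Construct a class morphology profile
#'
#' A profile parameterizes the synthetic generator for one cell class:
#' nucleus and cytoplasm equivalent radii (pixels, mean and sd of a truncated
#' normal), mean gray intensities (0-255) with pixel noise sds, the amplitude
#' of the sinusoidal texture and the admissible ellipse eccentricity range.
#'
#' @param class_name one of [cell_classes()].
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius (px).
#' @param nucleus_intensity_mean,nucleus_intensity_sd nucleus gray level.
#' @param cytoplasm_radius_mean,cytoplasm_radius_sd cytoplasm radius (px).
#' @param cytoplasm_intensity_mean,cytoplasm_intensity_sd cytoplasm gray level.
#' @param texture_amplitude amplitude (gray levels) of the sinusoidal texture.
#' @param eccentricity_range length-2 numeric in `[0, 1)`.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(class_name,
                          nucleus_radius_mean, nucleus_radius_sd,
                          nucleus_intensity_mean, nucleus_intensity_sd,
                          cytoplasm_radius_mean, cytoplasm_radius_sd,
                          cytoplasm_intensity_mean, cytoplasm_intensity_sd,
                          texture_amplitude = 8,
                          eccentricity_range = c(0, 0.5)) {
  p <- list(class_name = match.arg(class_name, cell_classes()),
            nucleus_radius_mean = nucleus_radius_mean,
            nucleus_radius_sd = nucleus_radius_sd,
            nucleus_intensity_mean = nucleus_intensity_mean,
            nucleus_intensity_sd = nucleus_intensity_sd,
            cytoplasm_radius_mean = cytoplasm_radius_mean,
            cytoplasm_radius_sd = cytoplasm_radius_sd,
            cytoplasm_intensity_mean = cytoplasm_intensity_mean,
            cytoplasm_intensity_sd = cytoplasm_intensity_sd,
            texture_amplitude = texture_amplitude,
            eccentricity_range = eccentricity_range)
  class(p) <- "class_profile"
  validate_class_profile(p)
  p
}

validate_class_profile <- function(p) {
  stopifnot(inherits(p, "class_profile"))
  if (p$nucleus_radius_mean >= p$cytoplasm_radius_mean)
    stop("nucleus_radius_mean must be smaller than cytoplasm_radius_mean")
  sds <- c(p$nucleus_radius_sd, p$nucleus_intensity_sd,
           p$cytoplasm_radius_sd, p$cytoplasm_intensity_sd)
  if (any(sds < 0)) stop("all sds must be >= 0")
  ints <- c(p$nucleus_intensity_mean, p$cytoplasm_intensity_mean)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  if (length(p$eccentricity_range) != 2 ||
      any(p$eccentricity_range < 0) || any(p$eccentricity_range >= 1) ||
      diff(p$eccentricity_range) < 0)
    stop("eccentricity_range must be an increasing pair in [0, 1)")
  invisible(p)
}

#' Default morphology profiles for the seven classes
#'
#' Encodes the dysplasia progression: nucleus radius strictly increases and
#' nucleus intensity strictly decreases from mild (preliminary) dysplasia
#' through severe (last stage) dysplasia to carcinoma in situ, while the
#' cytoplasm shrinks for the severe grades. The numeric values are free
#' generator parameters chosen to keep the classes separable at a 128 px
#' frame; they are not measurements of any real dataset.
#'
#' @return named list of 7 [class_profile()] objects in [cell_classes()] order.
#' @export
default_profiles <- function() {
  p <- list(
    class_profile("preliminary_squamous",      5.0, 0.8, 120, 10, 30, 3.0, 190, 8,
                  texture_amplitude = 6,  eccentricity_range = c(0, 0.4)),
    class_profile("moderate_squamous",         6.0, 1.0, 115, 10, 27, 3.0, 185, 8,
                  texture_amplitude = 6,  eccentricity_range = c(0, 0.4)),
    class_profile("columnar",                  8.0, 1.0, 100, 10, 14, 1.5, 170, 8,
                  texture_amplitude = 8,  eccentricity_range = c(0, 0.5)),
    class_profile("in_situ",                  18.0, 1.6,  50, 10, 24, 2.0, 160, 8,
                  texture_amplitude = 16, eccentricity_range = c(0, 0.5)),
    class_profile("preliminary_dysplastic",   10.0, 1.2,  95, 10, 26, 2.5, 175, 8,
                  texture_amplitude = 10, eccentricity_range = c(0, 0.5)),
    class_profile("intermediate_dysplastic",  13.0, 1.4,  80, 10, 23, 2.2, 170, 8,
                  texture_amplitude = 12, eccentricity_range = c(0, 0.5)),
    class_profile("last_stage_dysplastic",    16.0, 1.5,  65, 10, 21, 2.0, 165, 8,
                  texture_amplitude = 14, eccentricity_range = c(0, 0.6))
  )
  names(p) <- vapply(p, `[[`, "", "class_name")
  p
}

# Truncated-normal draw clipped to mean +/- 3 sd and a hard floor.
rtrunc <- function(mean, sd, lo = 2) {
  max(lo, min(mean + 3 * sd, max(mean - 3 * sd, stats::rnorm(1, mean, sd))))
}

# TRUE where pixel centers (row r, col c) fall inside the ellipse.
ellipse_mask <- function(n, cx, cy, a, b, theta) {
  r <- matrix(seq_len(n), n, n)          # row index
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- c - cx
  dy <- r - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# Points on the ellipse boundary, for containment checks.
ellipse_boundary <- function(cx, cy, a, b, theta, k = 72) {
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(x = cx + x0 * cos(theta) - y0 * sin(theta),
        y = cy + x0 * sin(theta) + y0 * cos(theta))
}

inside_ellipse <- function(pts, cx, cy, a, b, theta, margin = 1) {
  dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / (a - margin)
  v <- (-dx * sin(theta) + dy * cos(theta)) / (b - margin)
  all(u * u + v * v <= 1)
}

# Zero-luma chroma offsets (0.299 R + 0.587 G + 0.114 B == 0), so the RGB
# tinting leaves the luma equal to the profile's gray target.
.chroma_nucleus   <- c(-20, (0.299 * 20 - 0.114 * 30) / 0.587, 30)
.chroma_cytoplasm <- c(15, -(0.299 * 15 + 0.114 * 10) / 0.587, 10)

#' Generate one synthetic cell image
#'
#' Draws the cytoplasm as a rasterized ellipse (random orientation and
#' eccentricity within the profile range) and the nucleus as a smaller
#' ellipse fully contained in it, then fills intensities with the class
#' means, Gaussian pixel noise, and a sinusoidal texture of random
#' orientation and frequency scaled by `texture_amplitude`. The nucleus and
#' cytoplasm masks are the exact rasterized interiors, with the nucleus
#' removed from the cytoplasm mask (disjoint by construction).
#'
#' @param profile a [class_profile()].
#' @param seed integer seed; the same profile and seed give a bit-identical
#'   cell.
#' @param image_size side of the square frame in pixels.
#' @param background background gray level.
#' @param image_id identifier stored in the result.
#' @param max_attempts redraw budget for fitting the nucleus inside the
#'   cytoplasm before erroring.
#' @return an object of class `cell_image`: list with `pixels`
#'   (H x W x 3 array, 0-255), `nucleus_mask`, `cytoplasm_mask` (logical
#'   H x W, disjoint), `label`, `image_id`.
#' @export
generate_cell <- function(profile, seed, image_size = 128, background = 30,
                          image_id = profile$class_name, max_attempts = 100) {
  validate_class_profile(profile)
  n <- image_size
  with_seed(seed, {
    cx <- n / 2 + stats::runif(1, -2, 2)
    cy <- n / 2 + stats::runif(1, -2, 2)

    cyt <- NULL
    for (i in seq_len(max_attempts)) {
      rc <- rtrunc(profile$cytoplasm_radius_mean, profile$cytoplasm_radius_sd)
      ec <- stats::runif(1, profile$eccentricity_range[1], profile$eccentricity_range[2])
      th <- stats::runif(1, 0, pi)
      s <- (1 - ec^2)^0.25
      a <- rc / s; b <- rc * s
      if (cx - a > 2 && cx + a < n - 1 && cy - a > 2 && cy + a < n - 1) {
        cyt <- list(a = a, b = b, theta = th)
        break
      }
    }
    if (is.null(cyt)) stop("cytoplasm does not fit in the image frame")

    nuc <- NULL
    for (i in seq_len(max_attempts)) {
      rn <- rtrunc(profile$nucleus_radius_mean, profile$nucleus_radius_sd)
      en <- stats::runif(1, profile$eccentricity_range[1], profile$eccentricity_range[2])
      tn <- stats::runif(1, 0, pi)
      s <- (1 - en^2)^0.25
      an <- rn / s; bn <- rn * s
      jit <- 0.2 * (profile$cytoplasm_radius_mean - profile$nucleus_radius_mean)
      nx <- cx + stats::runif(1, -jit, jit)
      ny <- cy + stats::runif(1, -jit, jit)
      pts <- ellipse_boundary(nx, ny, an, bn, tn)
      if (inside_ellipse(pts, cx, cy, cyt$a, cyt$b, cyt$theta)) {
        nuc <- list(cx = nx, cy = ny, a = an, b = bn, theta = tn)
        break
      }
    }
    if (is.null(nuc))
      stop("nucleus does not fit inside the cytoplasm after ", max_attempts,
           " redraws for class ", profile$class_name)

    cyt_full <- ellipse_mask(n, cx, cy, cyt$a, cyt$b, cyt$theta)
    nuc_mask <- ellipse_mask(n, nuc$cx, nuc$cy, nuc$a, nuc$b, nuc$theta) & cyt_full
    cyt_mask <- cyt_full & !nuc_mask
    if (!any(nuc_mask) || !any(cyt_mask))
      stop("degenerate rasterization: empty mask for class ", profile$class_name)

    gray <- matrix(background, n, n)
    gray[cyt_mask] <- profile$cytoplasm_intensity_mean
    gray[nuc_mask] <- profile$nucleus_intensity_mean

    # band-limited texture: one sinusoid of random direction and frequency
    freq <- stats::runif(1, 0.06, 0.15)
    ang <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    tex <- profile$texture_amplitude *
      sin(2 * pi * freq * (cc * cos(ang) + rr * sin(ang)) + phase)
    cell <- cyt_mask | nuc_mask
    gray[cell] <- gray[cell] + tex[cell]
    gray[nuc_mask] <- gray[nuc_mask] +
      stats::rnorm(sum(nuc_mask), 0, profile$nucleus_intensity_sd)
    gray[cyt_mask] <- gray[cyt_mask] +
      stats::rnorm(sum(cyt_mask), 0, profile$cytoplasm_intensity_sd)

    px <- array(0, c(n, n, 3))
    for (ch in 1:3) {
      plane <- gray
      plane[nuc_mask] <- plane[nuc_mask] + .chroma_nucleus[ch]
      plane[cyt_mask] <- plane[cyt_mask] + .chroma_cytoplasm[ch]
      px[, , ch] <- plane
    }
    px <- round_half_up(pmin(pmax(px, 0), 255))

    structure(list(pixels = px, nucleus_mask = nuc_mask,
                   cytoplasm_mask = cyt_mask,
                   label = profile$class_name, image_id = image_id),
              class = "cell_image")
  })
}

#' Generator configuration
#'
#' @param counts_per_class integer vector of length 7, named by
#'   [cell_classes()] (or unnamed, taken in canonical order).
#' @param image_size square frame side in pixels.
#' @param seed master seed; each image uses a sub-seed hashed from
#'   `(seed, class, index)` so generation order cannot change outputs.
#' @param background_intensity background gray level.
#' @param profiles list of 7 [class_profile()] objects.
#' @param pixel_scale_um physical scale tag recorded in metadata
#'   (micrometres per pixel); metadata only, never used in computation.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(counts_per_class, image_size = 128, seed = 1,
                             background_intensity = 30,
                             profiles = default_profiles(),
                             pixel_scale_um = 0.197) {
  cls <- cell_classes()
  if (is.null(names(counts_per_class))) {
    stopifnot(length(counts_per_class) == 7)
    names(counts_per_class) <- cls
  }
  stopifnot(setequal(names(counts_per_class), cls))
  counts_per_class <- counts_per_class[cls]
  if (any(counts_per_class < 0)) stop("counts must be >= 0")
  max_r <- max(vapply(profiles, `[[`, 0, "cytoplasm_radius_mean") +
                 3 * vapply(profiles, `[[`, 0, "cytoplasm_radius_sd"))
  if (image_size < 2 * (max_r / (1 - 0.6^2)^0.25 + 4))
    stop("image_size too small to contain the largest cytoplasm plus margin")
  structure(list(counts_per_class = counts_per_class, image_size = image_size,
                 seed = as.integer(seed),
                 background_intensity = background_intensity,
                 profiles = profiles, pixel_scale_um = pixel_scale_um),
            class = "generator_config")
}

#' Preset per-class image counts of the two reference datasets
#'
#' The two public Herlev-style single-cell collections the method targets
#' hold 1614 and 1500 labelled images; these presets reproduce their
#' per-class distribution so manifest arithmetic is testable.
#'
#' @param name `"herlev1614"` or `"herlev1500"`.
#' @param ... passed on to [generator_config()].
#' @return a [generator_config()].
#' @export
generator_preset <- function(name = c("herlev1614", "herlev1500"), ...) {
  name <- match.arg(name)
  counts <- switch(name,
    herlev1614 = c(174, 170, 190, 258, 280, 248, 294),
    herlev1500 = c(190, 250, 280, 240, 290, 100, 150))
  generator_config(stats::setNames(counts, cell_classes()), ...)
}

#' Build the dataset manifest for a configuration
#'
#' One row per image: `image_id`, `label` and the relative file paths used
#' by [write_dataset()]. Deterministic in the configuration alone; no images
#' are rendered.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `image_id`, `label`, `image_path`,
#'   `nucleus_mask_path`, `cytoplasm_mask_path`.
#' @export
dataset_manifest <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rows <- lapply(cell_classes(), function(cl) {
    k <- config$counts_per_class[[cl]]
    if (k == 0) return(NULL)
    id <- sprintf("%s_%04d", cl, seq_len(k))
    data.frame(image_id = id, label = cl,
               image_path = file.path("images", paste0(id, ".png")),
               nucleus_mask_path = file.path("masks", paste0(id, "_nucleus.png")),
               cytoplasm_mask_path = file.path("masks", paste0(id, "_cytoplasm.png")),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(image_id = character(), label = character(),
               image_path = character(), nucleus_mask_path = character(),
               cytoplasm_mask_path = character(), stringsAsFactors = FALSE)
  }
  attr(out, "pixel_scale_um") <- config$pixel_scale_um
  out
}

#' Generate a labelled synthetic dataset in memory
#'
#' @param config a [generator_config()].
#' @return list with `cells` (list of `cell_image`) and `manifest`
#'   (see [dataset_manifest()]).
#' @export
generate_dataset <- function(config) {
  manifest <- dataset_manifest(config)
  profiles <- config$profiles
  cells <- vector("list", nrow(manifest))
  idx_in_class <- stats::ave(seq_len(nrow(manifest)), manifest$label,
                             FUN = seq_along)
  for (i in seq_len(nrow(manifest))) {
    cl <- manifest$label[i]
    cells[[i]] <- generate_cell(
      profiles[[cl]],
      seed = derive_seed(config$seed, cl, idx_in_class[i]),
      image_size = config$image_size,
      background = config$background_intensity,
      image_id = manifest$image_id[i])
  }
  names(cells) <- manifest$image_id
  list(cells = cells, manifest = manifest)
}

#' Write a dataset (images, masks, manifest) to disk
#'
#' Images are written as RGB PNG, masks as single-channel 0/255 PNG, the
#' manifest as `manifest.csv` and the configuration echo as `dataset.json`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param config optional [generator_config()] echoed to `dataset.json`.
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  for (i in seq_len(nrow(m))) {
    cell <- dataset$cells[[m$image_id[i]]]
    png::writePNG(cell$pixels / 255, file.path(dir, m$image_path[i]))
    png::writePNG(cell$nucleus_mask * 1, file.path(dir, m$nucleus_mask_path[i]))
    png::writePNG(cell$cytoplasm_mask * 1, file.path(dir, m$cytoplasm_mask_path[i]))
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- list(n_images = nrow(m), pixel_scale_um = attr(m, "pixel_scale_um"))
  if (!is.null(config))
    meta$config <- list(counts_per_class = as.list(config$counts_per_class),
                        image_size = config$image_size, seed = config$seed,
                        background_intensity = config$background_intensity)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list with `cells` and `manifest` as in [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  m <- utils::read.csv(mf, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(m)), function(i) {
    ip <- file.path(dir, m$image_path[i])
    np <- file.path(dir, m$nucleus_mask_path[i])
    cp <- file.path(dir, m$cytoplasm_mask_path[i])
    for (p in c(ip, np, cp))
      if (!file.exists(p)) stop("missing file for image_id ", m$image_id[i], ": ", p)
    px <- png::readPNG(ip)
    if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
    structure(list(pixels = round_half_up(px[, , 1:3] * 255),
                   nucleus_mask = png::readPNG(np)[, , drop = TRUE] > 0.5,
                   cytoplasm_mask = png::readPNG(cp)[, , drop = TRUE] > 0.5,
                   label = m$label[i], image_id = m$image_id[i]),
              class = "cell_image")
  })
  names(cells) <- m$image_id
  list(cells = cells, manifest = m)
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cell_image %s> %dx%d px, class %s, nucleus %d px, cytoplasm %d px\n",
              x$image_id, d[1], d[2], x$label,
              sum(x$nucleus_mask), sum(x$cytoplasm_mask)))
  invisible(x)
}
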