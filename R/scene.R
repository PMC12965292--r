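#' Synthetic nuclear scene with a planted locus spot
#'
#' Describes an image of disk-shaped nuclei at a uniform background level,
#' each with a diffraction-like (Gaussian) locus spot of known
#' fold-enrichment planted inside. The spot amplitude is scaled so that the
#' mean intensity of a `roi_px`-sided ROI centered on the locus equals
#' `fold_enrichment * background` exactly, making the planted fold the
#' ground truth for ROI-based enrichment quantification.
#'
#' @param dim_px Image size, c(rows, cols).
#' @param px_um Pixel size in micrometers.
#' @param n_nuclei Number of non-overlapping nuclei to place.
#' @param nucleus_radius_px Nucleus radius (pixels).
#' @param background Nuclear background intensity (a.u.), > 0.
#' @param fold_enrichment Planted locus fold-enrichment, >= 1 (length 1 or
#'   `n_nuclei`); 1 plants no spot (control nuclei).
#' @param spot_sigma_px Gaussian spot width (pixels).
#' @param roi_px ROI side the fold is defined against (default 30).
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(dim_px = c(320, 320), px_um = 0.1, n_nuclei = 4,
                            nucleus_radius_px = 60, background = 100,
                            fold_enrichment = 2, spot_sigma_px = 2,
                            roi_px = 30, noise_sd = 0, seed = NULL) {
  if (background <= 0) stop("background must be > 0")
  if (any(fold_enrichment < 1)) stop("fold_enrichment must be >= 1")
  fold <- rep_len(fold_enrichment, n_nuclei)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  r <- nucleus_radius_px
  # jittered grid placement: always succeeds when the grid cells are large
  # enough to hold one nucleus each
  g <- ceiling(sqrt(n_nuclei))
  cell <- dim_px / g
  if (any(cell < 2 * r + 2))
    stop("could not place ", n_nuclei, " non-overlapping nuclei; reduce n or radius")
  slots <- expand.grid(gr = seq_len(g), gc = seq_len(g))
  slots <- slots[sample.int(nrow(slots), n_nuclei), , drop = FALSE]
  jit <- (cell / 2 - r - 1)
  centers <- cbind(
    (slots$gr - 0.5) * cell[1] + stats::runif(n_nuclei, -jit[1], jit[1]),
    (slots$gc - 0.5) * cell[2] + stats::runif(n_nuclei, -jit[2], jit[2]))
  # locus near the nucleus center so the quantification ROI, and random
  # ROIs avoiding it, fit fully inside the nucleus
  theta <- stats::runif(n_nuclei, 0, 2 * pi)
  rad <- sqrt(stats::runif(n_nuclei)) * pmax(0.15 * r, 2)
  loci <- data.frame(nucleus_id = seq_len(n_nuclei),
                     row = centers[, 1] + rad * sin(theta),
                     col = centers[, 2] + rad * cos(theta),
                     fold = fold)
  structure(list(dim_px = dim_px, px_um = px_um, n_nuclei = n_nuclei,
                 nucleus_radius_px = r, background = background,
                 centers = centers, loci = loci,
                 spot_sigma_px = spot_sigma_px, roi_px = roi_px,
                 noise_sd = noise_sd),
            class = "synthetic_scene")
}

#' Render a synthetic scene to an image and label mask
#'
#' @param scene A `synthetic_scene`.
#' @param seed Optional integer seed for the pixel noise.
#' @return List with `image` (matrix), `mask` (integer label matrix, 0 =
#'   outside nuclei) and `loci` (data.frame `nucleus_id`, `row`, `col`,
#'   `fold`).
#' @export
render_scene <- function(scene, seed = NULL) {
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  nr <- scene$dim_px[1]; nc <- scene$dim_px[2]
  img <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  rows <- row(img); cols <- col(img)
  for (i in seq_len(scene$n_nuclei)) {
    inside <- (rows - scene$centers[i, 1])^2 + (cols - scene$centers[i, 2])^2 <=
      scene$nucleus_radius_px^2
    img[inside] <- scene$background
    mask[inside] <- i
    f <- scene$loci$fold[i]
    if (f > 1) {
      s <- scene$spot_sigma_px
      amp <- (f - 1) * scene$background * scene$roi_px^2 / (2 * pi * s^2)
      g <- amp * exp(-((rows - scene$loci$row[i])^2 +
                       (cols - scene$loci$col[i])^2) / (2 * s^2))
      img <- img + g
    }
  }
  if (scene$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, scene$noise_sd)
  list(image = img, mask = mask, loci = scene$loci)
}

#' Write a rendered scene to disk as TIFF images plus ground truth
#'
#' Writes the intensity image (32-bit float TIFF), the label mask
#' (16-bit TIFF), the locus table (CSV) and the full ground truth (JSON).
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param seed Optional integer seed for the pixel noise.
#' @return Invisibly, the rendered list from [render_scene()] with a
#'   `paths` element.
#' @export
generate_locus_image_stack <- function(scene, dir, prefix = "scene",
                                       seed = NULL) {
  sc <- render_scene(scene, seed = seed)
  if (any(sc$loci$row < 1 | sc$loci$row > scene$dim_px[1] |
          sc$loci$col < 1 | sc$loci$col > scene$dim_px[2]))
    stop("locus coordinates outside the image")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(image = file.path(dir, paste0(prefix, "_image.tif")),
                mask = file.path(dir, paste0(prefix, "_mask.tif")),
                loci = file.path(dir, paste0(prefix, "_loci.csv")),
                truth = file.path(dir, paste0(prefix, "_truth.json")))
  # intensities are stored normalized to [0, 1]; the scale (image maximum)
  # is recorded in the ground-truth JSON. Noise can push pixels slightly
  # below zero, which TIFF storage does not represent; clip.
  tiff::writeTIFF(pmin(pmax(sc$image / max(sc$image), 0), 1), paths$image,
                  bits.per.sample = 32L)
  tiff::writeTIFF(sc$mask / 65535, paths$mask, bits.per.sample = 16L)
  utils::write.csv(sc$loci, paths$loci, row.names = FALSE)
  jsonlite::write_json(list(px_um = scene$px_um,
                            background = scene$background,
                            fold_enrichment = scene$loci$fold,
                            roi_px = scene$roi_px,
                            intensity_scale = max(sc$image)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  sc$paths <- paths
  invisible(sc)
}

#' Read back a label mask written by [generate_locus_image_stack()]
#' @param path Mask TIFF path.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}
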