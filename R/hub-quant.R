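#' ROI enrichment at gene loci versus random nuclear ROIs
#'
#' Averages a square ROI centered on each nucleus's locus, and normalizes by
#' the mean of ROIs placed uniformly at random inside the same nuclei (the
#' full ROI inside the nucleus mask; centers whose ROI would reach within
#' `locus_margin_px` of the locus are excluded so the reference ROIs are
#' free of locus signal). The scalar enrichment is the locus-ROI pixel mean divided by
#' the random-ROI pixel mean; a uniform image therefore scores exactly 1 and
#' the measure is invariant to global intensity scaling.
#'
#' @param image Intensity matrix.
#' @param mask Integer label matrix (0 = outside nuclei).
#' @param loci data.frame with `nucleus_id`, `row`, `col` (pixel centers).
#' @param roi_px ROI side in pixels (default 30).
#' @param n_random Random ROIs per nucleus (default 1, matching the number
#'   of locus ROIs).
#' @param locus_margin_px Extra exclusion margin around the locus beyond
#'   the ROI half-width (default 6, covering the diffraction spot's tails).
#' @param seed Optional integer seed for ROI placement.
#' @return An `enrichment_map`: list with `map` (mean locus ROI, normalized
#'   by the random mean), `enrichment` (scalar), `random_mean`, `n_nuclei`,
#'   `roi_px`, `skipped` (nuclei whose ROI left the image).
#' @export
roi_enrichment <- function(image, mask, loci, roi_px = 30, n_random = 1,
                           locus_margin_px = 6, seed = NULL) {
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  half <- floor(roi_px / 2)
  extract <- function(r, c) {
    r0 <- round(r) - half; c0 <- round(c) - half
    if (r0 < 1 || c0 < 1 || r0 + roi_px - 1 > nrow(image) ||
        c0 + roi_px - 1 > ncol(image)) return(NULL)
    image[r0:(r0 + roi_px - 1), c0:(c0 + roi_px - 1)]
  }
  maps <- list(); rand_means <- numeric(0); skipped <- integer(0)
  for (i in seq_len(nrow(loci))) {
    roi <- extract(loci$row[i], loci$col[i])
    if (is.null(roi)) { skipped <- c(skipped, loci$nucleus_id[i]); next }
    maps[[length(maps) + 1L]] <- roi
    lab <- mask[round(loci$row[i]), round(loci$col[i])]
    # centers whose full ROI lies inside this nucleus: erode the nucleus
    # by an ROI-sized box
    inside <- EBImage::erode(mask == lab,
                             EBImage::makeBrush(2 * half + 1, "box"))
    cand <- which(inside > 0, arr.ind = TRUE)
    # exclude centers whose ROI overlaps the locus spot
    excl <- half + locus_margin_px
    ok <- abs(cand[, 1] - loci$row[i]) > excl |
      abs(cand[, 2] - loci$col[i]) > excl
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    picks <- cand[sample.int(nrow(cand), n_random, replace = TRUE), ,
                  drop = FALSE]
    for (j in seq_len(nrow(picks))) {
      rr <- extract(picks[j, 1], picks[j, 2])
      if (!is.null(rr)) rand_means <- c(rand_means, mean(rr))
    }
  }
  if (!length(maps)) stop("no locus ROI fits inside the image")
  if (!length(rand_means)) stop("no random ROI could be placed")
  mean_map <- Reduce(`+`, maps) / length(maps)
  random_mean <- mean(rand_means)
  structure(list(map = mean_map / random_mean,
                 enrichment = mean(mean_map) / random_mean,
                 random_mean = random_mean, n_nuclei = length(maps),
                 roi_px = roi_px, skipped = skipped),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("<enrichment_map> %dx%d ROI over %d nuclei: %.3g-fold\n",
              x$roi_px, x$roi_px, x$n_nuclei, x$enrichment))
  invisible(x)
}

#' Average pixel profile of an enrichment map
#'
#' Averages the map in the y dimension (over rows), giving a per-column
#' mean profile with SEM.
#'
#' @param map An `enrichment_map` or plain matrix.
#' @return data.frame (`column`, `mean`, `sem`).
#' @export
average_pixel_profile <- function(map) {
  m <- if (inherits(map, "enrichment_map")) map$map else map
  if (!length(m)) stop("empty map")
  data.frame(column = seq_len(ncol(m)),
             mean = colMeans(m),
             sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
}

#' Count active transcription sites inside nuclear masks
#'
#' Thresholds the image within each labeled nucleus and counts connected
#' supra-threshold components; at most one ATS per nucleus is retained (the
#' brightest), and the proportion active is the ATS count divided by the
#' number of nuclear masks.
#'
#' @param image Intensity matrix.
#' @param mask Integer label matrix with >= 1 nucleus.
#' @param threshold ATS intensity threshold.
#' @return List: `n_ats`, `n_nuclei`, `proportion`, `per_nucleus`
#'   (data.frame `nucleus_id`, `has_ats`, `peak_row`, `peak_col`,
#'   `peak_intensity`).
#' @export
count_ats <- function(image, mask, threshold) {
  labels <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (!length(labels)) stop("mask contains no nuclei")
  rows <- lapply(labels, function(lab) {
    sel <- mask == lab & image > threshold
    if (!any(sel))
      return(data.frame(nucleus_id = lab, has_ats = FALSE,
                        peak_row = NA_integer_, peak_col = NA_integer_,
                        peak_intensity = NA_real_))
    comp <- EBImage::bwlabel(sel)
    # brightest component only
    peaks <- tapply(image[sel], comp[sel], max)
    best <- as.integer(names(peaks)[which.max(peaks)])
    idx <- which(comp == best & image == max(peaks), arr.ind = TRUE)[1, ]
    data.frame(nucleus_id = lab, has_ats = TRUE,
               peak_row = idx[1], peak_col = idx[2],
               peak_intensity = max(peaks))
  })
  per <- do.call(rbind, rows)
  n_ats <- sum(per$has_ats)
  list(n_ats = n_ats, n_nuclei = length(labels),
       proportion = n_ats / length(labels), per_nucleus = per)
}

#' Pair hub and transcription foci by proximity
#'
#' Mutual-nearest-neighbor pairing with a distance ceiling (default 1 um):
#' a hub focus and an MS2 focus are paired when each is the other's nearest
#' neighbor and they lie within `max_dist_um`. The operation is symmetric
#' in its two inputs and deterministic.
#'
#' @param hub_foci,ms2_foci data.frames with columns `track_id`, `x_um`,
#'   `y_um`.
#' @param max_dist_um Pairing ceiling (default 1).
#' @return List: `pairs` (data.frame `hub_id`, `ms2_id`, `dist_um`),
#'   `unpaired_hub`, `unpaired_ms2`.
#' @export
pair_foci <- function(hub_foci, ms2_foci, max_dist_um = 1) {
  if (!nrow(hub_foci) || !nrow(ms2_foci))
    return(list(pairs = data.frame(hub_id = character(0),
                                   ms2_id = character(0),
                                   dist_um = numeric(0)),
                unpaired_hub = hub_foci$track_id,
                unpaired_ms2 = ms2_foci$track_id))
  D <- outer(seq_len(nrow(hub_foci)), seq_len(nrow(ms2_foci)),
             Vectorize(function(i, j)
               sqrt((hub_foci$x_um[i] - ms2_foci$x_um[j])^2 +
                    (hub_foci$y_um[i] - ms2_foci$y_um[j])^2)))
  nn_h <- apply(D, 1, which.min)
  nn_m <- apply(D, 2, which.min)
  pairs <- do.call(rbind, lapply(seq_len(nrow(hub_foci)), function(i) {
    j <- nn_h[i]
    if (nn_m[j] == i && D[i, j] <= max_dist_um)
      data.frame(hub_id = hub_foci$track_id[i],
                 ms2_id = ms2_foci$track_id[j], dist_um = D[i, j])
  }))
  if (is.null(pairs))
    pairs <- data.frame(hub_id = character(0), ms2_id = character(0),
                        dist_um = numeric(0))
  list(pairs = pairs,
       unpaired_hub = setdiff(hub_foci$track_id, pairs$hub_id),
       unpaired_ms2 = setdiff(ms2_foci$track_id, pairs$ms2_id))
}

#' Paired hub/transcription trace on a shared clock
#'
#' @param hub_trace,ms2_trace `fluor_trace` objects with equal frame grids.
#' @param dist_um Pairing distance (must be <= `max_dist_um`).
#' @param max_dist_um Pairing ceiling (default 1).
#' @return An object of class `paired_trace`.
#' @export
paired_trace <- function(hub_trace, ms2_trace, dist_um = 0, max_dist_um = 1) {
  if (dist_um > max_dist_um) stop("pairing distance exceeds the ceiling")
  if (abs(hub_trace$frame_interval_s - ms2_trace$frame_interval_s) > 1e-9)
    stop("paired traces must share a frame interval")
  structure(list(hub = hub_trace, ms2 = ms2_trace, dist_um = dist_um),
            class = "paired_trace")
}

#' Rescale a trace to the unit interval
#'
#' Maps the lowest intensity to 0 and the highest to 1 (used before
#' combining tracks with very different absolute brightness).
#'
#' @param trace A `fluor_trace` or numeric vector; must not be constant.
#' @return Same type as the input, rescaled.
#' @export
minmax_normalize <- function(trace) {
  x <- if (inherits(trace, "fluor_trace")) trace$intensity else trace
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) stop("constant trace cannot be min-max normalized")
  y <- (x - rng[1]) / diff(rng)
  if (inherits(trace, "fluor_trace")) { trace$intensity <- y; trace }
  else y
}

#' Persistent high-intensity regions on a coarse grid
#'
#' Bins each movie frame into a `grid x grid` array of cell means, compares
#' each cell to the frame's nuclear reference level (median intensity within
#' the nuclear mask), and retains cells exceeding `fold` times that level
#' for at least `persist_frames` consecutive frames. Per retained cell the
#' maximum and standard deviation of its binned intensity over the analysis
#' span are reported.
#'
#' @param movie 3D array (rows x cols x frames).
#' @param mask Integer/logical nuclear mask (nonzero = nuclear).
#' @param grid Grid size per side (default 10).
#' @param fold Intensity ratio threshold (default 1.5).
#' @param persist_frames Minimum consecutive frames above threshold
#'   (default 5, i.e. 2.5 min at 30-s frames).
#' @param span_frames Number of leading frames to analyze (default all;
#'   set to cover e.g. a 15-min span).
#' @return data.frame (`cell_row`, `cell_col`, `retained`, `max`, `sd`,
#'   `longest_run`).
#' @export
grid_fluctuations <- function(movie, mask, grid = 10, fold = 1.5,
                              persist_frames = 5, span_frames = NULL) {
  nf <- dim(movie)[3]
  if (is.null(span_frames)) span_frames <- nf
  span_frames <- min(span_frames, nf)
  if (span_frames < persist_frames)
    stop("movie shorter than the persistence window")
  row_bins <- ceiling(seq_len(dim(movie)[1]) / (dim(movie)[1] / grid))
  col_bins <- ceiling(seq_len(dim(movie)[2]) / (dim(movie)[2] / grid))
  nuclear <- mask != 0
  cell_series <- array(NA_real_, c(grid, grid, span_frames))
  above <- array(FALSE, c(grid, grid, span_frames))
  for (f in seq_len(span_frames)) {
    fr <- movie[, , f]
    ref <- stats::median(fr[nuclear])
    means <- tapply(as.vector(fr),
                    list(row_bins[row(fr)], col_bins[col(fr)]), mean)
    cell_series[, , f] <- means
    above[, , f] <- means > fold * ref
  }
  out <- expand.grid(cell_row = seq_len(grid), cell_col = seq_len(grid))
  out$longest_run <- mapply(function(i, j) {
    r <- rle(above[i, j, ])
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }, out$cell_row, out$cell_col)
  out$retained <- out$longest_run >= persist_frames
  out$max <- mapply(function(i, j) max(cell_series[i, j, ]),
                    out$cell_row, out$cell_col)
  out$sd <- mapply(function(i, j) stats::sd(cell_series[i, j, ]),
                   out$cell_row, out$cell_col)
  out[order(out$cell_row, out$cell_col), ]
}
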