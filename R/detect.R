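#' Lazy field collection
#'
#' Several stages iterate over all fields of a sample. To keep memory flat
#' on large mosaics, any function accepting fields takes either a plain
#' list of `field_of_view` objects or a `field_source`: a length + getter
#' pair that renders/reads field `i` on demand.
#'
#' @param n number of fields.
#' @param get `function(i)` returning the i-th `field_of_view`.
#' @export
field_source <- function(n, get) {
  structure(list(n = as.integer(n), get = get), class = "field_source")
}

n_fields <- function(fields) {
  if (inherits(fields, "field_source")) fields$n else length(fields)
}

get_field <- function(fields, i) {
  if (inherits(fields, "field_source")) fields$get(i) else fields[[i]]
}

#' Estimate per-channel background and detection thresholds
#'
#' For each fluorescence (maskable) channel, the mean and population
#' standard deviation of all voxel intensities over all supplied fields
#' are computed, and the detection threshold set to
#' `max(mean + 1.5 * sd, 1)`: intensity 1 is the floor when the
#' statistic falls below it. The bright-field channel gets no threshold.
#' Statistics are pooled over the whole sample once, before any per-field
#' processing.
#'
#' @param fields list of `field_of_view` or a [field_source()].
#' @param config an `acquisition_config`.
#' @param k threshold multiplier (default 1.5).
#' @param floor minimum threshold (default 1).
#' @return a `background_model`: data.frame with columns `channel`,
#'   `mean`, `sd`, `threshold`.
#' @export
estimate_background <- function(fields, config, k = 1.5, floor = 1) {
  nf <- n_fields(fields)
  if (nf < 1L) stop("at least one field is required")
  ch <- maskable_channels(config)
  s <- s2 <- stats::setNames(numeric(length(ch)), ch)
  n <- 0
  for (i in seq_len(nf)) {
    f <- get_field(fields, i)
    for (nm in ch) {
      v <- as.numeric(f$channels[[nm]])
      s[nm] <- s[nm] + sum(v)
      s2[nm] <- s2[nm] + sum(v * v)
    }
    n <- n + length(f$channels[[ch[1]]])
  }
  mu <- s / n
  sigma <- sqrt(pmax(s2 / n - mu^2, 0))
  structure(data.frame(channel = ch, mean = mu, sd = sigma,
                       threshold = pmax(mu + k * sigma, floor),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("background_model", "data.frame"), k = k, floor = floor)
}

#' Almost-max projection of a Z stack
#'
#' Robust variant of the max projection: each (x, y) position of the
#' output is the second-highest value of its Z column, which suppresses
#' single-voxel spikes (hot pixels, cosmic events). Ties are retained:
#' two equal maxima project to that value.
#'
#' @param grid 3D array (x, y, z) with at least 2 Z planes.
#' @return 2D matrix P(x, y).
#' @export
almost_max_project <- function(grid) {
  d <- dim(grid)
  if (length(d) != 3L || d[3] < 2L)
    stop("almost-max projection requires at least 2 Z planes")
  slice <- function(k) matrix(grid[, , k], d[1], d[2])
  top <- pmax(slice(1), slice(2))
  second <- pmin(slice(1), slice(2))
  for (k in seq_len(d[3] - 2L) + 2L) {
    v <- slice(k)
    second <- pmax(second, pmin(top, v))
    top <- pmax(top, v)
  }
  second
}

#' Median filters with reflected edges
#'
#' 3x3 (2D) and 3x3x3 (3D) median filters used to denoise projections and
#' crops before thresholding. Edges are handled by reflection, so integer
#' inputs yield integer outputs and thresholds stay bit-exact.
#'
#' @param x numeric matrix / 3D array.
#' @return filtered matrix / array of the same shape.
#' @export
median_filter_2d <- function(x) .median2d(x)

#' @rdname median_filter_2d
#' @export
median_filter_3d <- function(x) .median3d(x, dim(x))

#' Binary mask of one channel projection
#'
#' The projection is 3x3 median filtered, then thresholded (strictly
#' greater than) at the channel's background threshold.
#'
#' @param projection 2D matrix from [almost_max_project()].
#' @param threshold channel threshold from the [background_model][estimate_background()].
#' @return logical matrix.
#' @export
make_channel_mask <- function(projection, threshold) {
  median_filter_2d(projection) > threshold
}

#' Per-channel Otsu thresholds on the projections
#'
#' Comparison variant of the background threshold: for each maskable
#' channel, the almost-max projections of all fields are pooled and an
#' Otsu threshold computed on their integer histogram. Used to reproduce
#' the detector comparison on low-contrast scenes; the 1.5-sigma detector
#' is the default.
#'
#' @inheritParams estimate_background
#' @return a `background_model`-shaped data.frame whose `threshold`
#'   column holds the Otsu values (mean/sd are those of the projections).
#' @export
otsu_thresholds <- function(fields, config) {
  nf <- n_fields(fields)
  if (nf < 1L) stop("at least one field is required")
  ch <- maskable_channels(config)
  pooled <- stats::setNames(vector("list", length(ch)), ch)
  for (i in seq_len(nf)) {
    f <- get_field(fields, i)
    for (nm in ch)
      pooled[[nm]] <- c(pooled[[nm]], as.numeric(almost_max_project(f$channels[[nm]])))
  }
  thr <- mu <- sigma <- stats::setNames(numeric(length(ch)), ch)
  for (nm in ch) {
    v <- pooled[[nm]]
    top <- max(v, 1)
    thr[nm] <- EBImage::otsu(matrix(v / top, nrow = 1), range = c(0, 1),
                             levels = min(65536, round(top) + 1)) * top
    mu[nm] <- mean(v)
    sigma[nm] <- stats::sd(v)
  }
  structure(data.frame(channel = ch, mean = mu, sd = sigma, threshold = thr,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("background_model", "data.frame"))
}

cross_kernel <- function() EBImage::makeBrush(3L, shape = "diamond")

#' Identify objects in one field of view
#'
#' Pipeline per field: per maskable channel an almost-max projection is
#' median filtered and thresholded; the channel masks are OR-combined;
#' one binary opening then one closing with the 4-connected cross
#' structuring element remove noise; holes are closed; 4-connected
#' labeling; objects with projected area below `min_area_um2`
#' (default 12.6 um^2) are removed, as is any object touching one of the
#' four image borders.
#'
#' @param field a `field_of_view`.
#' @param background a [background_model][estimate_background()] (or the
#'   [otsu_thresholds()] variant).
#' @param config an `acquisition_config`.
#' @param min_area_um2 strict lower area cutoff, um^2.
#' @return a `detection_set`: list with `labels` (integer matrix, 0 =
#'   background) and `objects` (data.frame: `label`, `n_pixels`,
#'   `area_um2`, 0-based half-open bbox `x0,x1,y0,y1`, 0-based pixel
#'   centroid `cx,cy`), plus field provenance.
#' @export
identify_objects <- function(field, background, config, min_area_um2 = 12.6) {
  np <- config$frame_pixels
  combined <- matrix(FALSE, np, np)
  for (nm in maskable_channels(config)) {
    thr <- background$threshold[background$channel == nm]
    proj <- almost_max_project(field$channels[[nm]])
    combined <- combined | make_channel_mask(proj, thr)
  }
  mask <- morph_clean(combined)
  labels <- label_2d(mask)
  objects <- label_stats(labels, config)
  keep <- objects$area_um2 >= min_area_um2
  if (any(keep)) {
    border <- unique(c(labels[1, ], labels[np, ], labels[, 1], labels[, np]))
    keep <- keep & !(objects$label %in% border)
  }
  objects <- objects[keep, , drop = FALSE]
  labels[!(labels %in% objects$label)] <- 0L
  # relabel 1..K in raster order
  if (nrow(objects)) {
    remap <- stats::setNames(seq_len(nrow(objects)), objects$label)
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
    objects$label <- as.integer(remap[as.character(objects$label)])
  }
  rownames(objects) <- NULL
  structure(list(labels = labels, objects = objects,
                 sample_id = field$sample_id, mosaic_row = field$mosaic_row,
                 mosaic_col = field$mosaic_col, config = config),
            class = "detection_set")
}

# open, close (4-connected cross, one iteration each), then hole closing
morph_clean <- function(mask) {
  k <- cross_kernel()
  m <- EBImage::closing(EBImage::opening(mask * 1, k), k)
  m <- EBImage::fillHull(m)
  m > 0.5
}

label_2d <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

label_stats <- function(labels, config) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0), cx = numeric(0),
                      cy = numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  x <- (idx - 1L) %% nrow(labels)          # 0-based
  y <- (idx - 1L) %/% nrow(labels)
  n <- as.integer(tapply(lab, lab, length))
  data.frame(label = ids, n_pixels = n,
             area_um2 = n * pixel_area_um2(config),
             x0 = as.integer(tapply(x, lab, min)),
             x1 = as.integer(tapply(x, lab, max)) + 1L,
             y0 = as.integer(tapply(y, lab, min)),
             y1 = as.integer(tapply(y, lab, max)) + 1L,
             cx = as.numeric(tapply(x, lab, mean)),
             cy = as.numeric(tapply(y, lab, mean)),
             row.names = NULL)
}

#' Extract per-object crops from a field
#'
#' For each detected object, cut the bounding-box crop of every channel
#' stack and the object's 2D mask. The crop keeps all Z planes.
#'
#' @param field a `field_of_view`.
#' @param detections the field's `detection_set`.
#' @return list of `detected_object`: `label`, `mask` (logical crop),
#'   `crops` (named list of 3D arrays), `bbox`, `centroid_px`,
#'   `area_um2`, provenance and config.
#' @export
extract_objects <- function(field, detections) {
  obj <- detections$objects
  out <- vector("list", nrow(obj))
  for (i in seq_len(nrow(obj))) {
    o <- obj[i, ]
    xs <- (o$x0 + 1):o$x1
    ys <- (o$y0 + 1):o$y1
    mask <- detections$labels[xs, ys, drop = FALSE] == o$label
    crops <- lapply(field$channels, function(a) a[xs, ys, , drop = FALSE])
    out[[i]] <- structure(list(label = o$label, mask = mask, crops = crops,
                               bbox = c(x0 = o$x0, x1 = o$x1, y0 = o$y0,
                                        y1 = o$y1),
                               centroid_px = c(o$cx, o$cy),
                               area_um2 = o$area_um2,
                               n_pixels = o$n_pixels,
                               sample_id = field$sample_id,
                               mosaic_row = field$mosaic_row,
                               mosaic_col = field$mosaic_col,
                               config = field$config),
                          class = "detected_object")
  }
  out
}

#' Display vignette of a detected object
#'
#' Per-channel almost-max projections of the object's bounding-box crop,
#' contrast-stretched per channel to the 1st-99th intensity percentiles
#' and clipped to [0, 1]. XY dimensions equal the bounding box.
#'
#' @param object a `detected_object`.
#' @return 3D array (x, y, channel) of values in [0, 1].
#' @export
make_vignette <- function(object) {
  ch <- names(object$crops)
  d <- dim(object$crops[[1]])
  out <- array(0, dim = c(d[1], d[2], length(ch)), dimnames = list(NULL, NULL, ch))
  for (i in seq_along(ch)) {
    p <- almost_max_project(object$crops[[ch[i]]])
    q <- stats::quantile(p, c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) {
      out[, , i] <- pmin(pmax((p - q[1]) / (q[2] - q[1]), 0), 1)
    } else {
      out[, , i] <- 0
    }
  }
  out
}

#' Write a per-field label image and object index
#'
#' The label image is written as a 16-bit TIFF, the object index as TSV
#' (label, centroid, area, bbox).
#'
#' @param detections a `detection_set`.
#' @param dir output directory.
#' @export
write_detections <- function(detections, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_%d_%d", detections$sample_id, detections$mosaic_row,
                  detections$mosaic_col)
  tiff::writeTIFF(detections$labels / 65535,
                  file.path(dir, paste0(stem, "_labels.tif")),
                  bits.per.sample = 16L, compression = "none")
  utils::write.table(detections$objects,
                     file.path(dir, paste0(stem, "_objects.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
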