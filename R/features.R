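#' The versioned 480-descriptor catalog
#'
#' Fixed catalog of all object descriptors, grouped as: per channel (5
#' channels: bright field + 4 fluorescence) 26 Haralick direction
#' means/ranges, 24 uniform LBP bins (radius 1 / 8 points and radius 2 /
#' 12 points), 25 Zernike magnitudes to degree 8 and 10 intensity
#' statistics (85 x 5 = 425); 20 combined-mask 2D morphology
#' descriptors; 5 3D biovolume descriptors per fluorescence channel
#' (20); 2 overlap measures per fluorescence channel pair (12); 3 3D
#' bounding-box extents. 480 in total. `scale_behavior` documents the
#' response of each entry to multiplying intensities by a positive
#' constant after masking: `invariant`, `linear`, or `threshold`
#' (depends on the fixed background threshold).
#'
#' @param config an `acquisition_config` (channel names/order).
#' @param version catalog version identifier.
#' @return a `feature_catalog`: data.frame with columns `name`, `group`,
#'   `channel`, `scale_behavior` and attribute `version`.
#' @export
feature_catalog <- function(config = acquisition_config(),
                            version = "hcfm-480-1.0") {
  chs <- config$channels$name
  fluo <- maskable_channels(config)
  rows <- list()
  add <- function(name, group, channel, scale)
    rows[[length(rows) + 1]] <<- data.frame(name = name, group = group,
                                            channel = channel,
                                            scale_behavior = scale,
                                            stringsAsFactors = FALSE)
  har <- c("asm", "contrast", "correlation", "variance", "homogeneity",
           "sum_average", "sum_variance", "sum_entropy", "entropy",
           "diff_variance", "diff_entropy", "imc1", "imc2")
  zo <- zernike_orders(8L)
  for (ch in chs) {
    add(paste0(ch, "_h_", rep(har, 2), "_", rep(c("mean", "range"), each = 13)),
        "haralick", ch, "invariant")
    add(paste0(ch, "_lbp1_", c(paste0("u", 0:8), "nonuniform")),
        "lbp", ch, "invariant")
    add(paste0(ch, "_lbp2_", c(paste0("u", 0:12), "nonuniform")),
        "lbp", ch, "invariant")
    add(sprintf("%s_z_%d_%d", ch, zo[, "n"], zo[, "m"]),
        "zernike", ch, "invariant")
    int <- c("min", "max", "mean", "sd", "median", "mad", "integrated")
    add(paste0(ch, "_int_", int), "intensity", ch, "linear")
    add(paste0(ch, "_int_", c("skewness", "kurtosis")), "intensity", ch,
        "invariant")
    add(paste0(ch, "_int_frac_above_threshold"), "intensity", ch, "threshold")
  }
  add(c("area_um2", "perimeter_um", "convex_area_um2", "solidity",
        "eccentricity", "major_axis_um", "minor_axis_um", "aspect_ratio",
        "equivalent_diameter_um", "circularity", "extent", "euler_number",
        "hole_count", "feret_max_um", "feret_min_um",
        paste0("hu", 1:4), "roundness"),
      "morphology2d", "combined", "invariant")
  for (ch in fluo)
    add(paste0(ch, "_", c("biovolume_um3", "subobj_count",
                          "subobj_volume_um3", "subobj_max_um3",
                          "subobj_mean_um3")),
        "biovolume3d", ch, "threshold")
  pairs <- utils::combn(fluo, 2)
  for (k in seq_len(ncol(pairs)))
    add(paste0(pairs[1, k], "_", pairs[2, k], c("_jaccard", "_overlap_frac")),
        "overlap3d", paste0(pairs[1, k], "+", pairs[2, k]), "threshold")
  add(paste0("bbox3d_extent_", c("x", "y", "z"), "_um"),
      "geometry3d", "combined", "threshold")
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(nrow(cat) == 480L, !anyDuplicated(cat$name))
  structure(cat, version = version, class = c("feature_catalog", "data.frame"))
}

#' Ordered feature names of a catalog
#' @param catalog a `feature_catalog`.
#' @export
feature_names <- function(catalog) catalog$name

#' Catalog version string
#' @param catalog a `feature_catalog`.
#' @export
catalog_version <- function(catalog) attr(catalog, "version")

#' Indices of the bright-field-only feature subset
#'
#' All catalog entries whose channel scope is the bright-field channel
#' (85 entries): the descriptors available without any fluorescent
#' staining.
#'
#' @param catalog a `feature_catalog`.
#' @param config an `acquisition_config`.
#' @return integer vector of catalog positions.
#' @export
brightfield_only_subset <- function(catalog, config = acquisition_config()) {
  which(catalog$channel == brightfield_channel(config))
}

#' 3D sub-segmentation of one object
#'
#' Per fluorescence channel: the object's bounding-box crop is masked to
#' the 2D object footprint, 3x3x3 median filtered, thresholded at the
#' channel's global background threshold (the same thresholding
#' procedure as detection, applied to the 3D volume), labeled with
#' 6-connectivity, and components with volume below `min_volume_um3`
#' (default 0.5 um^3) are removed.
#'
#' @param object a `detected_object`.
#' @param background a [background_model][estimate_background()].
#' @param min_volume_um3 strict lower volume cutoff, um^3.
#' @return named list per fluorescence channel: `mask` (logical 3D array
#'   of all above-threshold voxels), `labels` (retained sub-objects),
#'   `subobjects` (data.frame `id`, `n_voxels`, `volume_um3`).
#' @export
subsegment_3d <- function(object, background, min_volume_um3 = 0.5) {
  cfg <- object$config
  vv <- voxel_volume_um3(cfg)
  out <- list()
  for (nm in maskable_channels(cfg)) {
    thr <- background$threshold[background$channel == nm]
    crop <- object$crops[[nm]]
    foot <- array(object$mask, dim = dim(crop))   # recycled along z
    crop <- crop * foot
    mask <- (median_filter_3d(crop) > thr) & foot
    lab <- .label3d(as.logical(mask), dim(crop))
    sub <- filter_subobjects(lab, vv, min_volume_um3)
    out[[nm]] <- list(mask = mask, labels = sub$labels,
                      subobjects = sub$table)
  }
  out
}

# volume filter on a 3D label array: drop components < min_volume_um3
filter_subobjects <- function(labels, voxel_volume, min_volume_um3) {
  k <- attr(labels, "max") %||% max(labels)
  if (k == 0)
    return(list(labels = labels,
                table = data.frame(id = integer(0), n_voxels = integer(0),
                                   volume_um3 = numeric(0))))
  n <- tabulate(labels[labels > 0L], nbins = k)
  vol <- n * voxel_volume
  keep <- which(vol >= min_volume_um3)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  list(labels = labels,
       table = data.frame(id = seq_along(keep), n_voxels = n[keep],
                          volume_um3 = vol[keep]))
}

intensity_stats <- function(v, threshold) {
  if (length(v) == 0)
    return(stats::setNames(numeric(10),
                           c("min", "max", "mean", "sd", "median", "mad",
                             "integrated", "skewness", "kurtosis",
                             "frac_above_threshold")))
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))             # population sd
  skew <- if (s > 0) mean((v - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((v - mu)^4) / s^4 - 3 else 0
  c(min = min(v), max = max(v), mean = mu, sd = s,
    median = stats::median(v), mad = stats::median(abs(v - stats::median(v))),
    integrated = sum(v), skewness = skew, kurtosis = kurt,
    frac_above_threshold = mean(v > threshold))
}

#' Compute the full 480-feature vector of one object
#'
#' Per-channel 2D descriptors (Haralick, LBP, Zernike, intensity) are
#' computed on the almost-max projection of the object's crop within the
#' object mask; 2D morphology on the combined mask; 3D biovolume,
#' overlap and extent descriptors from the 3D sub-segmentation.
#' Degenerate descriptors are 0 by convention, never NA/NaN.
#'
#' @param object a `detected_object`.
#' @param background a [background_model][estimate_background()].
#' @param catalog a `feature_catalog`.
#' @param subseg optional precomputed [subsegment_3d()] result.
#' @return named numeric vector of length 480 in catalog order, with a
#'   `catalog_version` attribute.
#' @export
compute_features <- function(object, background, catalog,
                             subseg = NULL) {
  cfg <- object$config
  if (is.null(subseg)) subseg <- subsegment_3d(object, background)
  vals <- numeric(0)
  mask <- object$mask
  for (nm in cfg$channels$name) {
    proj <- almost_max_project(object$crops[[nm]])
    thr <- if (nm %in% background$channel)
      background$threshold[background$channel == nm]
    else mean(proj[mask])                 # bright field: crop-mean reference
    vals <- c(vals,
              haralick_features(proj, mask),
              lbp_histogram(proj, mask, radius = 1, points = 8L),
              lbp_histogram(proj, mask, radius = 2, points = 12L),
              zernike_magnitudes(proj, mask),
              intensity_stats(proj[mask], thr))
  }
  vals <- c(vals, morphology_2d(mask, cfg))
  vv <- voxel_volume_um3(cfg)
  fluo <- maskable_channels(cfg)
  for (nm in fluo) {
    s <- subseg[[nm]]
    nsub <- nrow(s$subobjects)
    vals <- c(vals,
              biovolume = sum(s$mask) * vv,
              subobj_count = nsub,
              subobj_volume = sum(s$subobjects$volume_um3),
              subobj_max = if (nsub) max(s$subobjects$volume_um3) else 0,
              subobj_mean = if (nsub) mean(s$subobjects$volume_um3) else 0)
  }
  pairs <- utils::combn(fluo, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- subseg[[pairs[1, k]]]$mask
    b <- subseg[[pairs[2, k]]]$mask
    inter <- sum(a & b)
    uni <- sum(a | b)
    vals <- c(vals,
              jaccard = if (uni > 0) inter / uni else 0,
              overlap_frac = if (min(sum(a), sum(b)) > 0)
                inter / min(sum(a), sum(b)) else 0)
  }
  union3d <- Reduce(`|`, lapply(fluo, function(nm) subseg[[nm]]$mask))
  if (any(union3d)) {
    idx <- which(union3d, arr.ind = TRUE)
    ext <- c((diff(range(idx[, 1])) + 1) * cfg$voxel_size_xy,
             (diff(range(idx[, 2])) + 1) * cfg$voxel_size_xy,
             (diff(range(idx[, 3])) + 1) * cfg$voxel_size_z)
  } else ext <- c(0, 0, 0)
  vals <- c(vals, ext)
  vals[!is.finite(vals)] <- 0
  stopifnot(length(vals) == nrow(catalog))
  vals <- stats::setNames(as.numeric(vals), catalog$name)
  attr(vals, "catalog_version") <- catalog_version(catalog)
  vals
}

# 20 descriptors of the combined binary mask; lengths in um
morphology_2d <- function(mask, cfg) {
  px <- cfg$voxel_size_xy
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  out <- stats::setNames(numeric(20),
                         c("area_um2", "perimeter_um", "convex_area_um2",
                           "solidity", "eccentricity", "major_axis_um",
                           "minor_axis_um", "aspect_ratio",
                           "equivalent_diameter_um", "circularity", "extent",
                           "euler_number", "hole_count", "feret_max_um",
                           "feret_min_um", paste0("hu", 1:4), "roundness"))
  if (n == 0) return(out)
  perim_px <- perimeter_px(mask)
  # convex hull pixel count via Pick's theorem on the hull of pixel centers
  conv_px <- n
  hull <- NULL
  if (n >= 3) {
    h <- grDevices::chull(idx[, 1], idx[, 2])
    hull <- idx[h, , drop = FALSE]
    if (nrow(hull) >= 3) {
      xs <- hull[, 1]; ys <- hull[, 2]
      A <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
      e <- cbind(c(xs[-1], xs[1]) - xs, c(ys[-1], ys[1]) - ys)
      B <- sum(mapply(function(a, b) gcd_int(abs(a), abs(b)), e[, 1], e[, 2]))
      conv_px <- max(A + B / 2 + 1, n)
    }
  }
  # second central moments (per-pixel, normalized by n) + 1/12 pixel term
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  mu20 <- mean((idx[, 1] - cx)^2) + 1 / 12
  mu02 <- mean((idx[, 2] - cy)^2) + 1 / 12
  mu11 <- mean((idx[, 1] - cx) * (idx[, 2] - cy))
  tr <- mu20 + mu02
  det <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + det) / 2
  l2 <- (tr - det) / 2
  major_px <- 4 * sqrt(max(l1, 0))
  minor_px <- 4 * sqrt(max(l2, 0))
  bw <- diff(range(idx[, 1])) + 1
  bh <- diff(range(idx[, 2])) + 1
  holes <- count_holes(mask)
  # Feret diameters from the hull of pixel centers (+1 px pixel extent)
  if (!is.null(hull) && nrow(hull) >= 2) {
    d <- as.matrix(stats::dist(hull))
    feret_max <- max(d) + 1
    feret_min <- min_feret(hull) + 1
  } else {
    feret_max <- feret_min <- sqrt(bw^2 + bh^2)
  }
  hu <- hu_moments_1_4(idx, n)
  area <- n * px^2
  perim <- perim_px * px
  out["area_um2"] <- area
  out["perimeter_um"] <- perim
  out["convex_area_um2"] <- conv_px * px^2
  out["solidity"] <- n / conv_px
  out["eccentricity"] <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  out["major_axis_um"] <- major_px * px
  out["minor_axis_um"] <- minor_px * px
  out["aspect_ratio"] <- if (minor_px > 0) major_px / minor_px else 0
  out["equivalent_diameter_um"] <- 2 * sqrt(n / pi) * px
  out["circularity"] <- if (perim > 0) 4 * pi * area / perim^2 else 0
  out["extent"] <- n / (bw * bh)
  out["euler_number"] <- 1 - holes
  out["hole_count"] <- holes
  out["feret_max_um"] <- feret_max * px
  out["feret_min_um"] <- feret_min * px
  out[paste0("hu", 1:4)] <- hu
  out["roundness"] <- if (major_px > 0) 4 * n / (pi * major_px^2) else 0
  out
}

# outer-boundary chain length through boundary pixel centers (1 per
# axis step, sqrt(2) per diagonal step); tiny masks (< 3 contour points)
# fall back to the exposed-edge count
perimeter_px <- function(mask) {
  oc <- tryCatch(EBImage::ocontour(mask * 1), error = function(e) NULL)
  if (!is.null(oc) && length(oc) >= 1 && nrow(oc[[1]]) >= 3) {
    p <- oc[[1]]
    q <- p[c(2:nrow(p), 1), , drop = FALSE]
    return(sum(sqrt(rowSums((p - q)^2))))
  }
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  sum(core & !pad[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]) +
    sum(core & !pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]) +
    sum(core & !pad[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]) +
    sum(core & !pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE])
}

gcd_int <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

# background components of the padded inverted mask not touching the border
count_holes <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  bg <- label_2d(!pad)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(bg[bg > 0L]), border))
}

min_feret <- function(hull) {
  m <- nrow(hull)
  widths <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    p <- hull %*% nrm
    max(p) - min(p)
  }, numeric(1))
  v <- widths[is.finite(widths)]
  if (length(v)) min(v) else 0
}

hu_moments_1_4 <- function(idx, n) {
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  x <- idx[, 1] - cx; y <- idx[, 2] - cy
  eta <- function(p, q) sum(x^p * y^q) / n^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  c(e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    (e30 - 3 * e12)^2 + (3 * e21 - e03)^2,
    (e30 + e12)^2 + (e21 + e03)^2)
}

#' Detect, extract and featurize all objects of one field
#'
#' Convenience wrapper chaining [identify_objects()], [extract_objects()]
#' and [compute_features()].
#'
#' @param field a `field_of_view`.
#' @param background a [background_model][estimate_background()].
#' @param catalog a `feature_catalog`.
#' @param ... passed to [identify_objects()].
#' @return list with `detections`, `objects`, `features` (matrix, one
#'   row per object) and `provenance` (data.frame).
#' @export
featurize_field <- function(field, background, catalog, ...) {
  det <- identify_objects(field, background, field$config, ...)
  objs <- extract_objects(field, det)
  feats <- matrix(numeric(0), 0, nrow(catalog),
                  dimnames = list(NULL, catalog$name))
  if (length(objs))
    feats <- do.call(rbind, lapply(objs, compute_features,
                                   background = background,
                                   catalog = catalog))
  attr(feats, "catalog_version") <- catalog_version(catalog)
  k <- nrow(det$objects)
  prov <- data.frame(sample = rep(field$sample_id, k),
                     field_row = rep(field$mosaic_row, k),
                     field_col = rep(field$mosaic_col, k),
                     object_id = det$objects$label)
  list(detections = det, objects = objs, features = feats, provenance = prov)
}
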