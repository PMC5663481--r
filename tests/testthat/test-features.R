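test_that("the catalog has exactly 480 uniquely named entries per manifest", {
  catg <- feature_catalog()
  expect_equal(nrow(catg), 480L)
  expect_false(anyDuplicated(catg$name) > 0)
  expect_equal(feature_names(catg), catg$name)
  counts <- table(catg$group)
  expect_equal(counts[["haralick"]], 26L * 5L)
  expect_equal(counts[["lbp"]], 24L * 5L)
  expect_equal(counts[["zernike"]], 25L * 5L)
  expect_equal(counts[["intensity"]], 10L * 5L)
  expect_equal(counts[["morphology2d"]], 20L)
  expect_equal(counts[["biovolume3d"]], 20L)
  expect_equal(counts[["overlap3d"]], 12L)
  expect_equal(counts[["geometry3d"]], 3L)
})

test_that("the bright-field subset has 85 entries, none fluorescent", {
  catg <- feature_catalog()
  idx <- brightfield_only_subset(catg)
  expect_length(idx, 85L)
  fluo <- maskable_channels(acquisition_config())
  expect_false(any(catg$channel[idx] %in% fluo))
})

test_that("haralick contrast matches a direction-wise counting oracle", {
  # vertical stripes: along axis 1 neighbours are equal, along axis 2 and
  # both diagonals they always differ by the full quantization span
  img <- matrix(rep(c(0, 1), 3), 6, 6)[, rep(1:2, 3)]
  img <- matrix(0, 6, 6)
  img[, c(2, 4, 6)] <- 1
  h <- haralick_features(img, matrix(TRUE, 6, 6))
  span2 <- 63^2                         # levels 1 and 64 after quantization
  expect_equal(h[["h_contrast_mean"]], 3 / 4 * span2)
  expect_equal(h[["h_contrast_range"]], span2)
  # constant image: every contrast-type statistic is 0
  hc <- haralick_features(matrix(7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(hc[["h_contrast_mean"]], 0)
  expect_equal(hc[["h_entropy_mean"]], 0)
  expect_equal(hc[["h_asm_mean"]], 1)
  # degenerate 1-pixel mask: all zeros by convention
  h1 <- haralick_features(matrix(5, 3, 3), matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_true(all(h1 == 0))
})

test_that("haralick features are invariant to affine intensity changes", {
  set.seed(21)
  img <- matrix(sample(0:200, 100, TRUE), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(haralick_features(img, mask),
               haralick_features(img * 3.7 + 11, mask))
})

test_that("LBP histograms are normalized, scale-invariant frequencies", {
  set.seed(31)
  img <- matrix(runif(400, 0, 50), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  for (p in list(c(1, 8), c(2, 12))) {
    h <- lbp_histogram(img, mask, radius = p[1], points = p[2])
    expect_length(h, p[2] + 2)
    expect_equal(sum(h), 1)
    expect_equal(h, lbp_histogram(img * 4.2, mask, radius = p[1],
                                  points = p[2]))
  }
  # constant image: every sample >= center -> all-ones uniform pattern
  h <- lbp_histogram(matrix(3, 12, 12), matrix(TRUE, 12, 12), 1, 8L)
  expect_equal(unname(h[["u8"]]), 1)
})

test_that("LBP code of a hand-built neighbourhood matches the definition", {
  # 3x3 image, center pixel only; samples at radius 1 land on the 8
  # neighbours (bilinear interpolation is exact on the 4 axis samples and
  # averages 4 pixels on the diagonals)
  img <- matrix(0, 3, 3)
  img[2, 2] <- 30
  img[3, 2] <- 50   # only the +x axis sample reaches the center value
                    # (diagonal bilinear samples mix in at most ~11)
  mask <- matrix(FALSE, 3, 3)
  mask[2, 2] <- TRUE
  h <- lbp_histogram(img, mask, radius = 1, points = 8L)
  # exactly one bit set -> uniform pattern with 1 bit
  expect_equal(unname(h[["u1"]]), 1)
})

test_that("zernike magnitudes are rotation-invariant and ordered", {
  catg <- feature_catalog()
  set.seed(41)
  m <- matrix(FALSE, 21, 21)
  m[(row(m) - 11)^2 + (col(m) - 11)^2 <= 64] <- TRUE
  img <- matrix(0, 21, 21)
  img[m] <- runif(sum(m), 10, 100)
  z <- zernike_magnitudes(img, m)
  expect_length(z, 25L)
  # 90 degree rotation of the grid is exact: magnitudes must agree
  rot <- function(x) t(x)[, rev(seq_len(ncol(x)))]
  z90 <- zernike_magnitudes(rot(img), rot(m))
  expect_equal(z, z90, tolerance = 1e-6, ignore_attr = TRUE)
  # intensity scaling after masking leaves magnitudes unchanged
  expect_equal(z, zernike_magnitudes(img * 5, m))
  # empty / zero-intensity masks give zeros
  expect_true(all(zernike_magnitudes(img * 0, m) == 0))
})

test_that("sub-object volume filter removes components below 0.5 um^3", {
  cfg <- acquisition_config()
  vv <- voxel_volume_um3(cfg)                       # 0.188^2 * 1.090
  expect_equal(vv, 0.03852496, tolerance = 1e-7)
  lab <- array(0L, c(10, 10, 4))
  lab[1:12 + 0] <- NA                               # placeholder
  lab <- array(0L, c(10, 10, 4))
  lab[1:12] <- 1L                                   # 12 voxels: 0.462 um^3
  lab[301:313] <- 2L                                # 13 voxels: 0.501 um^3
  attr(lab, "max") <- 2L
  out <- hcfm:::filter_subobjects(lab, vv, 0.5)
  expect_equal(nrow(out$table), 1L)
  expect_equal(out$table$n_voxels, 13L)
  expect_equal(out$table$volume_um3, 13 * vv)
  expect_true(all(out$labels[301:313] == 1L))       # renumbered sequentially
  expect_true(all(out$labels[1:12] == 0L))
})

test_that("3D sub-segmentation labels 6-connected components above threshold", {
  cfg <- tiny_config(frame = 40L, z = 6L)
  # two solid boxes in the dna channel, far apart
  arr <- array(0, c(40, 40, 6))
  arr[5:12, 5:12, 2:5] <- 100
  arr[25:32, 25:32, 2:5] <- 100
  mask2d <- matrix(FALSE, 40, 40)
  mask2d[3:36, 3:36] <- TRUE
  obj <- structure(list(
    label = 1L, mask = mask2d,
    crops = stats::setNames(lapply(tiny_config(frame = 40L, z = 6L)$channels$name,
                                   function(nm) arr), cfg$channels$name),
    bbox = c(x0 = 0, x1 = 40, y0 = 0, y1 = 40), centroid_px = c(20, 20),
    area_um2 = sum(mask2d) * pixel_area_um2(cfg), n_pixels = sum(mask2d),
    sample_id = "s", mosaic_row = 0L, mosaic_col = 0L, config = cfg),
    class = "detected_object")
  ss <- subsegment_3d(obj, manual_background(cfg, threshold = 50))
  expect_equal(nrow(ss$dna$subobjects), 2L)
  # median erosion only affects component surfaces; both boxes survive
  expect_true(all(ss$dna$subobjects$volume_um3 > 0.5))
  # crop entirely below threshold -> zero sub-objects
  ss0 <- subsegment_3d(obj, manual_background(cfg, threshold = 1e5))
  expect_equal(nrow(ss0$dna$subobjects), 0L)
})

test_that("2D morphology descriptors behave on canonical shapes", {
  cfg <- acquisition_config()
  px <- cfg$voxel_size_xy
  sq <- matrix(FALSE, 20, 20)
  sq[5:14, 5:14] <- TRUE
  m <- hcfm:::morphology_2d(sq, cfg)
  expect_equal(m[["area_um2"]], 100 * px^2)
  expect_equal(m[["perimeter_um"]], 36 * px)   # boundary chain length
  expect_equal(m[["extent"]], 1)
  expect_equal(m[["solidity"]], 1)
  expect_equal(m[["euler_number"]], 1)
  expect_equal(m[["hole_count"]], 0)
  expect_equal(m[["aspect_ratio"]], 1)
  expect_equal(m[["eccentricity"]], 0)
  ring <- sq
  ring[8:11, 8:11] <- FALSE
  mr <- hcfm:::morphology_2d(ring, cfg)
  expect_equal(mr[["hole_count"]], 1)
  expect_equal(mr[["euler_number"]], 0)
  expect_lt(mr[["solidity"]], 1)
  # disk: circularity near 1, feret diameters near the diameter
  d <- matrix(FALSE, 41, 41)
  d[(row(d) - 21)^2 + (col(d) - 21)^2 <= 15^2] <- TRUE
  md <- hcfm:::morphology_2d(d, cfg)
  expect_gt(md[["circularity"]], 0.9)
  expect_equal(md[["feret_max_um"]], 31 * px, tolerance = 0.05)
  expect_equal(md[["feret_min_um"]], 31 * px, tolerance = 0.05)
  expect_equal(md[["equivalent_diameter_um"]], 2 * sqrt(sum(d) / pi) * px)
  expect_equal(md[["roundness"]], 1, tolerance = 0.05)
})

test_that("feature vectors are complete, finite and catalog-versioned", {
  cfg <- tiny_config(frame = 64L, z = 5L)
  catg <- feature_catalog(cfg)
  set.seed(6)
  obj <- synth_object("c", "sphere", center = c(6, 6, 2.7), r = 2.2)
  spec <- scene_spec(c(1, 1), cfg, list(obj),
                     hcfm:::default_synth_background(config = cfg), seed = 4)
  f <- render_field(spec, 0, 0)
  bg <- estimate_background(list(f), cfg)
  det <- identify_objects(f, bg, cfg, min_area_um2 = 5)
  o <- extract_objects(f, det)[[1]]
  fv <- compute_features(o, bg, catg)
  expect_length(fv, 480L)
  expect_true(all(is.finite(fv)))
  expect_equal(names(fv), catg$name)
  expect_equal(attr(fv, "catalog_version"), catalog_version(catg))
  # biovolume additivity: total sub-object volume = sum of sub-objects
  ss <- subsegment_3d(o, bg)
  for (ch in maskable_channels(cfg))
    expect_equal(unname(fv[[paste0(ch, "_subobj_volume_um3")]]),
                 sum(ss[[ch]]$subobjects$volume_um3))
})

test_that("identical channel volumes give overlap features of 1", {
  cfg <- tiny_config(frame = 40L, z = 5L)
  catg <- feature_catalog(cfg)
  arr <- array(0, c(40, 40, 5))
  arr[10:29, 10:29, 2:4] <- 100
  f <- make_test_field(cfg, list(dna = arr, membranes = arr))
  bg <- manual_background(cfg, threshold = 50)
  det <- identify_objects(f, bg, cfg)
  o <- extract_objects(f, det)[[1]]
  fv <- compute_features(o, bg, catg)
  expect_equal(unname(fv[["dna_membranes_jaccard"]]), 1)
  expect_equal(unname(fv[["dna_membranes_overlap_frac"]]), 1)
  expect_equal(unname(fv[["dna_surface_jaccard"]]), 0)
})

test_that("a digital sphere's biovolume matches the analytic volume", {
  # radius-10 sphere on an isotropic unit-voxel grid
  cfg <- acquisition_config(voxel_size_xy = 1, voxel_size_z = 1,
                            frame_pixels = 28L, z_planes = 28L)
  catg <- feature_catalog(cfg)
  arr <- array(0, c(28, 28, 28))
  ii <- as.matrix(expand.grid(x = 1:28, y = 1:28, z = 1:28))
  inside <- (ii[, 1] - 14.5)^2 + (ii[, 2] - 14.5)^2 + (ii[, 3] - 14.5)^2 <= 100
  arr[ii[inside, ]] <- 100
  mask <- matrix(FALSE, 28, 28)
  mask[(row(mask) - 14.5)^2 + (col(mask) - 14.5)^2 <= 100] <- TRUE
  obj <- structure(list(
    label = 1L, mask = mask,
    crops = stats::setNames(lapply(cfg$channels$name, function(nm) arr),
                            cfg$channels$name),
    bbox = c(x0 = 0, x1 = 28, y0 = 0, y1 = 28), centroid_px = c(14, 14),
    area_um2 = sum(mask), n_pixels = sum(mask), sample_id = "s",
    mosaic_row = 0L, mosaic_col = 0L, config = cfg),
    class = "detected_object")
  # count above-threshold voxels without median smoothing interference:
  # use the raw voxel count oracle
  expect_equal(sum(inside), 4188.79, tolerance = 0.02)
  ss <- subsegment_3d(obj, manual_background(cfg, threshold = 50))
  fv <- compute_features(obj, manual_background(cfg, threshold = 50), catg,
                         subseg = ss)
  expect_equal(unname(fv[["dna_biovolume_um3"]]), 4 / 3 * pi * 1000,
               tolerance = 0.02)
})

test_that("features are invariant to whole-voxel translation", {
  cfg <- tiny_config(frame = 72L, z = 5L)
  catg <- feature_catalog(cfg)
  bgspec <- list(mean = as.list(stats::setNames(rep(0, 5), cfg$channels$name)),
                 sd = as.list(stats::setNames(rep(0, 5), cfg$channels$name)))
  mkfv <- function(shift_px) {
    set.seed(9)   # same organelle placements for both renders
    ctr <- c(5.5, 5.5, 2.7) + c(shift_px * cfg$voxel_size_xy, 0)
    obj <- synth_object("c", "sphere", center = ctr, r = 2.0)
    spec <- scene_spec(c(1, 1), cfg, list(obj), bgspec, seed = 4)
    f <- render_field(spec, 0, 0)
    bg <- manual_background(cfg, threshold = 10)
    det <- identify_objects(f, bg, cfg, min_area_um2 = 5)
    compute_features(extract_objects(f, det)[[1]], bg, catg)
  }
  a <- mkfv(c(0, 0))
  b <- mkfv(c(7, 11))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("intensity scaling behaves as the catalog documents", {
  cfg <- tiny_config(frame = 64L, z = 5L)
  catg <- feature_catalog(cfg)
  set.seed(14)
  obj <- synth_object("c", "sphere", center = c(6, 6, 2.7), r = 2.2)
  spec <- scene_spec(c(1, 1), cfg, list(obj),
                     hcfm:::default_synth_background(config = cfg), seed = 4)
  f <- render_field(spec, 0, 0)
  bg <- estimate_background(list(f), cfg)
  det <- identify_objects(f, bg, cfg, min_area_um2 = 5)
  o <- extract_objects(f, det)[[1]]
  fv <- compute_features(o, bg, catg)
  o2 <- o
  o2$crops <- lapply(o$crops, function(a) a * 3)    # scale after masking
  fv2 <- compute_features(o2, bg, catg)
  inv <- catg$scale_behavior == "invariant"
  lin <- catg$scale_behavior == "linear"
  expect_equal(fv2[inv], fv[inv], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fv2[lin], 3 * fv[lin], tolerance = 1e-9, ignore_attr = TRUE)
})
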