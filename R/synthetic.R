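#' Synthetic acquisition scenes with ground truth
#'
#' The generator emulates the confocal acquisition on a global sample
#' coordinate system: cell-like objects are parameterized solids
#' (sphere, ellipsoid chain, spiky star, hollow ring, textured blob,
#' touching pair) with channel-specific structure (one DNA nucleus per
#' cell, a membrane shell, a surface rim, 0-4 chloroplast blobs, a faint
#' bright-field silhouette), sampled at the anisotropic voxel centers of
#' each mosaic field, so an object inside an overlap region appears
#' consistently in every field imaging it. Per-channel Gaussian
#' background noise (optionally with a heavy-tailed speckle-column
#' component) is added per field. Everything is deterministic given the
#' scene seed.
#'
#' @name synthetic-scenes
NULL

#' Scene specification
#'
#' @param layout integer `c(rows, cols)` of the mosaic.
#' @param config an `acquisition_config`.
#' @param objects object roster: list of object descriptions built by
#'   [synth_object()].
#' @param background list: per-channel `mean` and `sd` (named by channel
#'   name), optional heavy-tail speckle `speckle_prob` (per XY column),
#'   `speckle_value`, `speckle_depth`.
#' @param seed integer master seed.
#' @param sample_id sample identifier.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(layout, config, objects, background, seed = 1L,
                       sample_id = "synthetic") {
  lay <- mosaic_layout(layout[1], layout[2], config)
  ext1 <- (lay$rows - 1) * lay$spacing + lay$field_extent
  ext2 <- (lay$cols - 1) * lay$spacing + lay$field_extent
  for (o in objects) {
    if (o$center[1] < 0 || o$center[1] > ext1 ||
        o$center[2] < 0 || o$center[2] > ext2)
      stop("object center outside the mosaic extent")
    if (2 * o$ext > lay$field_extent)
      stop("object larger than the field extent")
  }
  structure(list(layout = layout, config = config, objects = objects,
                 background = background, seed = as.integer(seed),
                 sample_id = sample_id, mosaic = lay),
            class = "scene_spec")
}

#' Construct one synthetic object
#'
#' @param class leaf class name.
#' @param shape one of `"sphere"`, `"chain"`, `"star"`, `"ring"`,
#'   `"pair"`.
#' @param center global center, um, `c(u1, u2, uz)`.
#' @param r size parameter, um.
#' @param phi in-plane orientation, radians.
#' @param amps named intensity amplitudes per channel kind
#'   (`bright_field`, `dna`, `membranes`, `surface`, `chlorophyll`).
#' @param style `"cell"` (structured organelles) or `"solid"` (uniform
#'   body in every non-zero channel).
#' @param n_chloro chloroplast blobs per cell (0-4).
#' @param spikes spike count for the star shape.
#' @param textured modulate the membrane signal with a deterministic
#'   spatial texture.
#' @param rng draw organelle placements (requires a seeded RNG state).
#' @return an object description for [scene_spec()].
#' @export
synth_object <- function(class, shape, center, r, phi = 0,
                         amps = c(bright_field = 20, dna = 120,
                                  membranes = 100, surface = 110,
                                  chlorophyll = 120),
                         style = "cell", n_chloro = 2L, spikes = 7L,
                         textured = FALSE, rng = TRUE) {
  cells <- switch(shape,
    chain = {
      a <- 0.9 * r
      t(vapply(c(-1, 0, 1), function(t)
        c(t * 1.8 * a * cos(phi), t * 1.8 * a * sin(phi), 0), numeric(3)))
    },
    pair = {
      off <- 0.6 * r
      rbind(c(off * cos(phi), off * sin(phi), 0),
            c(-off * cos(phi), -off * sin(phi), 0))
    },
    matrix(0, 1, 3))
  cell_r <- switch(shape, chain = 0.62 * r, pair = 0.72 * r, r)
  nucleus_r <- 0.45 * cell_r
  chloro_r <- 0.35 * cell_r
  jitter3 <- function(scale) if (rng)
    stats::runif(3, -scale, scale) * c(1, 1, 0.3) else c(0, 0, 0)
  nuclei <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    cells[i, ] + jitter3(0.25 * cell_r)))
  chloro <- NULL
  if (n_chloro > 0) {
    chloro <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      do.call(rbind, lapply(seq_len(n_chloro), function(k) {
        ang <- if (rng) stats::runif(1, 0, 2 * pi) else 2 * pi * k / n_chloro
        cells[i, ] + c(0.5 * cell_r * cos(ang), 0.5 * cell_r * sin(ang), 0)
      }))
    }))
  }
  ext <- switch(shape, chain = 2.85 * r, pair = 1.35 * r, 1.15 * r) + 0.3
  list(class = class, shape = shape, center = center, r = r, phi = phi,
       amps = amps, style = style, spikes = spikes, textured = textured,
       cells = cells, nuclei = nuclei, chloro = chloro,
       nucleus_r = nucleus_r, chloro_r = chloro_r, ext = ext)
}

# body membership at offsets (d1, d2, dz) from the center, optionally
# shrunk by scale s about the center
synth_body <- function(obj, d1, d2, dz, s = 1) {
  if (s != 1) { d1 <- d1 / s; d2 <- d2 / s; dz <- dz / s }
  r <- obj$r
  switch(obj$shape,
    sphere = d1^2 + d2^2 + dz^2 <= r^2,
    chain = {
      a <- 0.9 * r; b <- 0.62 * r
      u <- cos(obj$phi); v <- sin(obj$phi)
      par <- d1 * u + d2 * v
      perp <- -d1 * v + d2 * u
      m <- rep(FALSE, length(d1))
      for (t in c(-1, 0, 1)) {
        pp <- par - t * 1.8 * a
        m <- m | ((pp / a)^2 + (perp / b)^2 + (dz / b)^2 <= 1)
      }
      m
    },
    star = {
      rho <- sqrt(d1^2 + d2^2)
      th <- atan2(d2, d1)
      rad <- r * (0.6 + 0.4 * cos(obj$spikes * (th - obj$phi)))
      (rho / pmax(rad, 1e-9))^2 + (dz / (0.6 * r))^2 <= 1
    },
    ring = {
      rho <- sqrt(d1^2 + d2^2)
      rho <= r & rho >= 0.55 * r & abs(dz) <= 0.45 * r
    },
    pair = {
      rr <- 0.72 * r
      m <- rep(FALSE, length(d1))
      for (i in seq_len(nrow(obj$cells)))
        m <- m | ((d1 - obj$cells[i, 1])^2 + (d2 - obj$cells[i, 2])^2 +
                    (dz - obj$cells[i, 3])^2 <= rr^2)
      m
    },
    stop("unknown shape: ", obj$shape))
}

# union of organelle blobs: ellipsoids with a minimum z semi-axis so a
# blob always spans at least two Z planes of the 1.09-um grid
blob_union <- function(centers, radius, d1, d2, dz) {
  m <- rep(FALSE, length(d1))
  if (is.null(centers)) return(m)
  za <- max(radius, 1.15)
  for (i in seq_len(nrow(centers)))
    m <- m | ((d1 - centers[i, 1])^2 + (d2 - centers[i, 2])^2) / radius^2 +
      ((dz - centers[i, 3]) / za)^2 <= 1
  m
}

# per-channel-kind intensity contribution of one object at offsets
# (d1, d2, dz); a1/a2 are absolute um coordinates for the texture term
synth_channel_values <- function(obj, kind, d1, d2, dz, a1, a2) {
  amp <- obj$amps[[kind]]
  if (is.null(amp) || is.na(amp) || amp <= 0) return(NULL)
  if (obj$style == "solid" || kind == "bright_field")
    return(amp * synth_body(obj, d1, d2, dz))
  v <- switch(kind,
    dna = amp * blob_union(obj$nuclei, obj$nucleus_r, d1, d2, dz),
    membranes = {
      # intracellular membranes fill the cytoplasm: solid body signal
      m <- amp * synth_body(obj, d1, d2, dz)
      if (obj$textured)
        m <- m * (0.725 + 0.275 * sin(3.1 * a1) * cos(2.7 * a2))
      m
    },
    surface = amp * (synth_body(obj, d1, d2, dz) &
                       !synth_body(obj, d1, d2, dz, s = 0.85)),
    chlorophyll = amp * blob_union(obj$chloro, obj$chloro_r, d1, d2, dz))
  v
}

#' Render one mosaic field of a scene
#'
#' @param spec a `scene_spec`.
#' @param row,col 0-based mosaic position.
#' @return a `field_of_view` with integer intensities in [0, 65535].
#' @export
render_field <- function(spec, row, col) {
  cfg <- spec$config
  np <- cfg$frame_pixels; nz <- cfg$z_planes
  lay <- spec$mosaic
  origin <- c(row, col) * lay$spacing
  idx <- row * spec$layout[2] + col
  set.seed((spec$seed + 7919L * (idx + 1L)) %% .Machine$integer.max)
  bg <- spec$background
  arrs <- list()
  for (i in seq_len(nrow(cfg$channels))) {
    nm <- cfg$channels$name[i]
    mu <- bg$mean[[nm]] %||% 0
    sg <- bg$sd[[nm]] %||% 0
    a <- array(pmax(stats::rnorm(np * np * nz, mu, sg), 0), c(np, np, nz))
    sp <- bg$speckle_prob %||% 0
    if (sp > 0 && cfg$channels$use_for_masking[i]) {
      cols <- which(stats::runif(np * np) < sp)
      if (length(cols)) {
        depth <- bg$speckle_depth %||% 3L
        z0 <- sample.int(nz - depth + 1L, length(cols), replace = TRUE)
        for (d in seq_len(depth) - 1L) {
          a[cols + (z0 + d - 1L) * np * np] <- bg$speckle_value %||% 180
        }
      }
    }
    arrs[[nm]] <- a
  }
  vox <- cfg$voxel_size_xy; vz <- cfg$voxel_size_z
  for (obj in spec$objects) {
    x0 <- max(0L, floor((obj$center[1] - obj$ext - origin[1]) / vox))
    x1 <- min(np - 1L, ceiling((obj$center[1] + obj$ext - origin[1]) / vox))
    y0 <- max(0L, floor((obj$center[2] - obj$ext - origin[2]) / vox))
    y1 <- min(np - 1L, ceiling((obj$center[2] + obj$ext - origin[2]) / vox))
    z0 <- max(0L, floor((obj$center[3] - obj$ext) / vz))
    z1 <- min(nz - 1L, ceiling((obj$center[3] + obj$ext) / vz))
    if (x0 > x1 || y0 > y1 || z0 > z1) next
    xs <- x0:x1; ys <- y0:y1; zs <- z0:z1
    n1 <- length(xs); n2 <- length(ys); n3 <- length(zs)
    a1 <- origin[1] + (xs + 0.5) * vox
    a2 <- origin[2] + (ys + 0.5) * vox
    az <- (zs + 0.5) * vz
    g1 <- rep(a1, times = n2 * n3)
    g2 <- rep(rep(a2, each = n1), times = n3)
    gz <- rep(az, each = n1 * n2)
    d1 <- g1 - obj$center[1]; d2 <- g2 - obj$center[2]
    dz <- gz - obj$center[3]
    for (i in seq_len(nrow(cfg$channels))) {
      nm <- cfg$channels$name[i]
      v <- synth_channel_values(obj, cfg$channels$kind[i], d1, d2, dz, g1, g2)
      if (is.null(v) || !any(v > 0)) next
      blk <- arrs[[nm]][xs + 1L, ys + 1L, zs + 1L, drop = FALSE]
      arrs[[nm]][xs + 1L, ys + 1L, zs + 1L] <- blk + array(v, c(n1, n2, n3))
    }
  }
  for (nm in names(arrs)) arrs[[nm]] <- round(pmin(pmax(arrs[[nm]], 0), 65535))
  field_of_view(arrs, row, col, spec$sample_id, cfg)
}

#' Render a whole scene
#'
#' @param spec a `scene_spec`.
#' @param as_source return a lazy [field_source()] instead of a list
#'   (recommended for large mosaics).
#' @return list with `fields` (list of `field_of_view` or a
#'   `field_source`), `truth` (ground-truth data.frame, see
#'   [scene_truth()]) and `spec`.
#' @export
render_scene <- function(spec, as_source = FALSE) {
  rc <- expand.grid(col = seq_len(spec$layout[2]) - 1L,
                    row = seq_len(spec$layout[1]) - 1L)[, c("row", "col")]
  fields <- if (as_source) {
    field_source(nrow(rc), function(i)
      render_field(spec, rc$row[i], rc$col[i]))
  } else {
    lapply(seq_len(nrow(rc)), function(i)
      render_field(spec, rc$row[i], rc$col[i]))
  }
  list(fields = fields, truth = scene_truth(spec), spec = spec)
}

#' Ground truth table of a scene
#'
#' One row per roster object: class, global centroid (um), size, the
#' canonical field owning the centroid, and true rendered voxel volumes
#' of the whole body and of the DNA compartment (counted on the
#' canonical field's voxel grid).
#'
#' @param spec a `scene_spec`.
#' @return data.frame.
#' @export
scene_truth <- function(spec) {
  lay <- spec$mosaic
  cfg <- spec$config
  rows <- lapply(seq_along(spec$objects), function(i) {
    o <- spec$objects[[i]]
    crow <- canonical_index(o$center[1], lay$rows, lay)
    ccol <- canonical_index(o$center[2], lay$cols, lay)
    vol <- true_object_volumes(o, c(crow, ccol) * lay$spacing, cfg)
    data.frame(object_id = i, class = o$class, u1 = o$center[1],
               u2 = o$center[2], uz = o$center[3], r = o$r,
               canonical_row = crow, canonical_col = ccol,
               body_volume_um3 = vol["body"], dna_volume_um3 = vol["dna"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# rendered voxel counts of body and DNA compartment on the grid of the
# field with the given origin
true_object_volumes <- function(obj, origin, cfg) {
  vox <- cfg$voxel_size_xy; vz <- cfg$voxel_size_z
  xs <- floor((obj$center[1] - obj$ext - origin[1]) / vox):
    ceiling((obj$center[1] + obj$ext - origin[1]) / vox)
  ys <- floor((obj$center[2] - obj$ext - origin[2]) / vox):
    ceiling((obj$center[2] + obj$ext - origin[2]) / vox)
  zs <- max(0, floor((obj$center[3] - obj$ext) / vz)):
    min(cfg$z_planes - 1, ceiling((obj$center[3] + obj$ext) / vz))
  n1 <- length(xs); n2 <- length(ys); n3 <- length(zs)
  d1 <- rep(origin[1] + (xs + 0.5) * vox, times = n2 * n3) - obj$center[1]
  d2 <- rep(rep(origin[2] + (ys + 0.5) * vox, each = n1), times = n3) -
    obj$center[2]
  dz <- rep((zs + 0.5) * vz, each = n1 * n2) - obj$center[3]
  body <- synth_body(obj, d1, d2, dz)
  dna <- if (obj$style == "solid") {
    if ((obj$amps[["dna"]] %||% 0) > 0) body else rep(FALSE, length(d1))
  } else blob_union(obj$nuclei, obj$nucleus_r, d1, d2, dz)
  c(body = sum(body), dna = sum(dna)) * voxel_volume_um3(cfg)
}

#' Taxonomy of the six synthetic classes
#'
#' Four-level hierarchy used by the `six_classes` fixture: the textured
#' blob shares the bright-field silhouette (and the level-3 parent) of
#' the coccosphere and differs mainly in its fluorescence structure.
#'
#' @return a `taxonomy_tree` with 6 leaves.
#' @export
six_class_taxonomy <- function() {
  taxonomy_tree(data.frame(
    level1 = c("living", "living", "living", "living", "living", "detritus"),
    level2 = c("round_cells", "round_cells", "round_cells", "elongated",
               "spiny", "ringed"),
    level3 = c("coccoid", "coccoid", "paired", "chained", "radial",
               "annular"),
    level4 = c("coccosphere", "textured_blob", "cell_pair", "diatom_chain",
               "spiky_star", "hollow_ring"),
    stringsAsFactors = FALSE))
}

six_class_defs <- function() {
  list(
    coccosphere = list(shape = "sphere", r = c(2.1, 2.5), n_chloro = 2L,
                       textured = FALSE,
                       amps = c(bright_field = 20, dna = 120, membranes = 100,
                                surface = 130, chlorophyll = 120)),
    textured_blob = list(shape = "sphere", r = c(2.1, 2.5), n_chloro = 0L,
                         textured = TRUE,
                         amps = c(bright_field = 20, dna = 120,
                                  membranes = 90, surface = 25,
                                  chlorophyll = 0)),
    cell_pair = list(shape = "pair", r = c(2.4, 2.6), n_chloro = 1L,
                     textured = FALSE,
                     amps = c(bright_field = 20, dna = 110, membranes = 100,
                              surface = 80, chlorophyll = 110)),
    diatom_chain = list(shape = "chain", r = c(1.9, 2.2), n_chloro = 1L,
                        textured = FALSE,
                        amps = c(bright_field = 20, dna = 110,
                                 membranes = 95, surface = 60,
                                 chlorophyll = 130)),
    spiky_star = list(shape = "star", r = c(3.2, 3.6), n_chloro = 0L,
                      textured = FALSE,
                      amps = c(bright_field = 20, dna = 100, membranes = 90,
                               surface = 140, chlorophyll = 0)),
    hollow_ring = list(shape = "ring", r = c(2.3, 2.6), n_chloro = 0L,
                       textured = FALSE,
                       amps = c(bright_field = 20, dna = 0, membranes = 110,
                                surface = 120, chlorophyll = 0)))
}

default_synth_background <- function(heavy_tail = FALSE,
                                     config = acquisition_config()) {
  nms <- config$channels$name
  kinds <- config$channels$kind
  mu <- stats::setNames(ifelse(kinds == "bright_field", 30, 12), nms)
  sg <- stats::setNames(ifelse(kinds == "bright_field", 4, 3), nms)
  out <- list(mean = as.list(mu), sd = as.list(sg))
  if (heavy_tail) {
    out$speckle_prob <- 0.01
    out$speckle_value <- 180
    out$speckle_depth <- 3L
  }
  out
}

#' Packaged ground-truthed fixtures
#'
#' Three standard scenes exercising specific pipeline stages:
#' \describe{
#'   \item{dim_field}{one 640-px field with 30 low-contrast solid
#'     particles over a heavy-tailed speckle background, built so a
#'     global Otsu threshold lands in the gap between the particle mode
#'     and the speckle mode (missing the particles) while the
#'     mean + 1.5 sd threshold separates particles from the Gaussian
#'     noise floor.}
#'   \item{six_classes}{900 single-object fields (150 per leaf class of
#'     [six_class_taxonomy()]), 96 px, returned as a lazy field source.}
#'   \item{mosaic_straddle}{a 3x3 mosaic of 384-px fields with 10
#'     objects placed inside mosaic overlap regions (fully visible in at
#'     least two fields) plus 8 interior objects.}
#' }
#'
#' @param name fixture name.
#' @param seed master seed.
#' @return list with `spec`, `fields` (list or [field_source()]),
#'   `truth`, `config`, and for `six_classes` also `labels` (a label
#'   table) and `tree`.
#' @export
make_fixture <- function(name, seed = 1L) {
  switch(name,
    dim_field = fixture_dim_field(seed),
    six_classes = fixture_six_classes(seed),
    mosaic_straddle = fixture_mosaic_straddle(seed),
    stop("unknown fixture: ", name))
}

fixture_dim_field <- function(seed) {
  cfg <- acquisition_config(frame_pixels = 640L, z_planes = 6L)
  set.seed(seed)
  grid <- expand.grid(i = 0:5, j = 0:4)
  objs <- lapply(seq_len(30), function(k) {
    c1 <- 15 + grid$i[k] * 18 + stats::runif(1, -2, 2)
    c2 <- 18 + grid$j[k] * 21 + stats::runif(1, -2, 2)
    synth_object(class = "dim_particle", shape = "sphere",
                 center = c(c1, c2, 3.3), r = stats::runif(1, 2.2, 2.6),
                 amps = c(bright_field = 8, dna = 45, membranes = 45,
                          surface = 0, chlorophyll = 0),
                 style = "solid")
  })
  spec <- scene_spec(c(1L, 1L), cfg, objs,
                     default_synth_background(heavy_tail = TRUE, cfg),
                     seed = seed, sample_id = "dim_field")
  c(render_scene(spec), list(config = cfg))
}

fixture_six_classes <- function(seed, n_per_class = 150L) {
  cfg <- acquisition_config(frame_pixels = 96L, z_planes = 8L)
  defs <- six_class_defs()
  tree <- six_class_taxonomy()
  n <- 6L * n_per_class
  rows <- ceiling(sqrt(n))
  lay <- mosaic_layout(rows, rows, cfg)
  set.seed(seed)
  classes <- rep(names(defs), n_per_class)
  objs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- defs[[classes[i]]]
    row <- (i - 1L) %/% rows; col <- (i - 1L) %% rows
    center <- c(row, col) * lay$spacing + cfg$field_width / 2 +
      stats::runif(2, -0.8, 0.8)
    objs[[i]] <- synth_object(class = classes[i], shape = d$shape,
                              center = c(center, cfg$z_planes *
                                           cfg$voxel_size_z / 2),
                              r = stats::runif(1, d$r[1], d$r[2]),
                              phi = stats::runif(1, 0, pi),
                              amps = d$amps, n_chloro = d$n_chloro,
                              textured = d$textured)
  }
  spec <- scene_spec(c(rows, rows), cfg, objs,
                     default_synth_background(config = cfg), seed = seed,
                     sample_id = "six_classes")
  sc <- render_scene(spec, as_source = TRUE)
  paths <- sc$truth
  m <- match(paths$class, tree$paths$level4)
  labels <- data.frame(object_id = paths$object_id,
                       level1 = tree$paths$level1[m],
                       level2 = tree$paths$level2[m],
                       level3 = tree$paths$level3[m],
                       level4 = paths$class, stringsAsFactors = FALSE)
  c(sc, list(config = cfg, labels = labels, tree = tree))
}

fixture_mosaic_straddle <- function(seed) {
  cfg <- acquisition_config(frame_pixels = 384L, z_planes = 8L)
  lay <- mosaic_layout(3L, 3L, cfg)
  set.seed(seed)
  mid <- function(k) k * lay$spacing + lay$overlap_width / 2
  extent <- 2 * lay$spacing + lay$field_extent
  zc <- cfg$z_planes * cfg$voxel_size_z / 2
  objs <- list()
  # 10 straddlers: centers just off a core midline, fully inside the
  # overlap band of two adjacent fields
  along <- seq(20, extent - 20, length.out = 5)
  for (i in 1:5) {
    k <- 1L + (i %% 2L)
    objs[[length(objs) + 1]] <- synth_object(
      class = "straddler", shape = "sphere",
      center = c(along[i], mid(k) + sample(c(-0.6, 0.6), 1), zc),
      r = stats::runif(1, 2.15, 2.25))
  }
  for (i in 1:5) {
    k <- 1L + (i %% 2L)
    objs[[length(objs) + 1]] <- synth_object(
      class = "straddler", shape = "sphere",
      center = c(mid(k) + sample(c(-0.6, 0.6), 1), along[6 - i], zc),
      r = stats::runif(1, 2.15, 2.25))
  }
  # 8 interior objects, away from every overlap band
  core_pos <- c(25, 100, 160, 190)
  pts <- cbind(c(25, 100, 160, 190, 35, 110, 170, 60),
               c(35, 25, 110, 170, 185, 160, 30, 95))
  for (i in 1:8) {
    objs[[length(objs) + 1]] <- synth_object(
      class = "interior", shape = "sphere",
      center = c(pts[i, 1], pts[i, 2], zc),
      r = stats::runif(1, 2.5, 3.0))
  }
  spec <- scene_spec(c(3L, 3L), cfg, objs,
                     default_synth_background(config = cfg), seed = seed,
                     sample_id = "mosaic_straddle")
  c(render_scene(spec), list(config = cfg, layout = lay))
}
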