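# shared helpers: tiny configs, hand-built fields, memoized heavy fixtures

tiny_config <- function(frame = 32L, z = 4L, ...) {
  acquisition_config(frame_pixels = frame, z_planes = z, ...)
}

# a field with all channels zero except those supplied
make_test_field <- function(cfg, channels = list(), row = 0L, col = 0L,
                            sample = "test") {
  grids <- stats::setNames(lapply(cfg$channels$name, function(x)
    array(0, c(cfg$frame_pixels, cfg$frame_pixels, cfg$z_planes))),
    cfg$channels$name)
  for (nm in names(channels)) grids[[nm]] <- channels[[nm]]
  field_of_view(grids, row, col, sample, cfg)
}

# background model with hand-set thresholds (bypasses estimation)
manual_background <- function(cfg, threshold = 1, mean = 0, sd = 0) {
  data.frame(channel = maskable_channels(cfg), mean = mean, sd = sd,
             threshold = threshold, stringsAsFactors = FALSE)
}

# W x H rectangle minus its 4 corners: stable under the 3x3 median and
# the cross opening/closing, so its pixel count passes through object
# identification unchanged (W, H >= 3)
rect_minus_corners <- function(frame, W, H, x0 = 6L, y0 = 6L) {
  m <- matrix(FALSE, frame, frame)
  m[x0:(x0 + W - 1), y0:(y0 + H - 1)] <- TRUE
  m[cbind(c(x0, x0, x0 + W - 1, x0 + W - 1),
          c(y0, y0 + H - 1, y0, y0 + H - 1))] <- FALSE
  m
}

# field whose dna channel holds the given 2D mask at constant intensity
# on every z-plane
mask_field <- function(cfg, mask, value = 100, channel = "dna") {
  arr <- array(rep(mask * value, cfg$z_planes),
               c(cfg$frame_pixels, cfg$frame_pixels, cfg$z_planes))
  make_test_field(cfg, stats::setNames(list(arr), channel))
}

# memoized heavy fixtures, shared between module and acceptance tests
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  .fixture_cache[[key]]
}

# full pipeline run on the mosaic_straddle fixture, memoized
cached_straddle_run <- function(seed = 1L) {
  key <- paste0("straddle_run_", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture("mosaic_straddle", seed)
    .fixture_cache[[key]] <- run_pipeline(fx$fields, fx$config,
                                          layout = fx$layout)
  }
  .fixture_cache[[key]]
}

# detection + feature extraction over the six_classes fixture, memoized
# (the single most expensive computation in the suite)
six_classes_training <- function(seed = 1L) {
  key <- paste0("six_training_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- cached_fixture("six_classes", seed)
  cfg <- fx$config
  catg <- feature_catalog(cfg)
  bg <- estimate_background(fx$fields, cfg)
  n <- fx$fields$n
  feats <- vector("list", n)
  labs <- character(n)
  for (i in seq_len(n)) {
    fr <- featurize_field(fx$fields$get(i), bg, catg)
    if (nrow(fr$features) >= 1) {
      feats[[i]] <- fr$features[1, , drop = FALSE]
      labs[i] <- fx$truth$class[i]
    }
  }
  ok <- !vapply(feats, is.null, logical(1))
  features <- do.call(rbind, feats[ok])
  attr(features, "catalog_version") <- catalog_version(catg)
  labs <- labs[ok]
  m <- match(labs, fx$labels$level4)
  labels <- data.frame(object_id = seq_along(labs),
                       level1 = fx$labels$level1[m],
                       level2 = fx$labels$level2[m],
                       level3 = fx$labels$level3[m],
                       level4 = labs, stringsAsFactors = FALSE)
  out <- list(features = features, labels = labels, config = cfg,
              catalog = catg, background = bg, n_rendered = n,
              n_detected = sum(ok))
  .fixture_cache[[key]] <- out
  out
}
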