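#' Field of view container
#'
#' A field of view holds one 3D intensity array per channel (dimension
#' `c(frame_pixels, frame_pixels, z_planes)`, axis order (x, y, z) with x
#' fastest-varying) plus its mosaic position. Intensities are stored as
#' the integers read from file; feature computation promotes to double.
#'
#' @param channel_grids named list of 3D arrays, one per channel, in
#'   config channel order.
#' @param mosaic_row,mosaic_col 0-based mosaic indices.
#' @param sample_id sample identifier.
#' @param config an `acquisition_config`.
#' @export
field_of_view <- function(channel_grids, mosaic_row = 0L, mosaic_col = 0L,
                          sample_id = "sample", config) {
  stopifnot(is.list(channel_grids), length(channel_grids) >= 1L)
  dims <- lapply(channel_grids, dim)
  ref <- dims[[1]]
  for (nm in names(channel_grids)) {
    d <- dim(channel_grids[[nm]])
    if (length(d) != 3L || !all(d == ref))
      stop("channel '", nm, "' has dimensions inconsistent with the field")
  }
  if (!all(ref[1:2] == config$frame_pixels) || ref[3] != config$z_planes)
    stop("field dimensions do not match the acquisition config")
  if (mosaic_row < 0L || mosaic_col < 0L) stop("mosaic indices must be >= 0")
  structure(list(channels = channel_grids,
                 mosaic_row = as.integer(mosaic_row),
                 mosaic_col = as.integer(mosaic_col),
                 sample_id = sample_id, config = config),
            class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("field_of_view %s (row %d, col %d): %d channel(s), %d x %d x %d\n",
              x$sample_id, x$mosaic_row, x$mosaic_col, length(x$channels),
              d[1], d[2], d[3]))
  invisible(x)
}

#' Default stack file name for one channel of one field
#'
#' `{sample}_{row}_{col}_{channel}.tif`, one multi-page TIFF per channel
#' per field, one page per Z plane.
#'
#' @param sample_id,row,col,channel naming components.
#' @export
field_file_name <- function(sample_id, row, col, channel) {
  sprintf("%s_%d_%d_%s.tif", sample_id, row, col, channel)
}

#' Read one field of view from per-channel TIFF stacks
#'
#' Each file is a multi-page TIFF, one page per Z plane, bit depth 8 or
#' 16; page rows index image axis 1 (x) and page columns axis 2 (y).
#' Intensities are read as stored integers (lossless).
#'
#' @param paths named character vector of file paths, names = channel
#'   names in `config$channels` order.
#' @param config an `acquisition_config`.
#' @param mosaic_row,mosaic_col,sample_id provenance, see
#'   [field_of_view()].
#' @return a `field_of_view`.
#' @export
read_field <- function(paths, config, mosaic_row = 0L, mosaic_col = 0L,
                       sample_id = "sample") {
  want <- config$channels$name
  if (is.null(names(paths)) || !setequal(names(paths), want))
    stop("paths must be named by the config channel names")
  grids <- list()
  ref <- NULL
  for (nm in want) {
    pages <- tiff::readTIFF(paths[[nm]], all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]]), length(pages))
    if (is.null(ref)) ref <- d
    if (!all(d == ref))
      stop("channel '", nm, "' has dimensions inconsistent with the field")
    arr <- array(0, dim = d)
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    grids[[nm]] <- arr
  }
  field_of_view(grids, mosaic_row, mosaic_col, sample_id, config)
}

#' Write one field of view as per-channel 16-bit TIFF stacks
#'
#' @param field a `field_of_view`.
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (nm in names(field$channels)) {
    arr <- field$channels[[nm]]
    if (any(arr < 0) || any(arr > 65535))
      stop("intensities outside the 16-bit range in channel '", nm, "'")
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) round(arr[, , k]) / 65535)
    path <- file.path(dir, field_file_name(field$sample_id, field$mosaic_row,
                                           field$mosaic_col, nm))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    out[nm] <- path
  }
  out
}

#' Write / read an object feature table
#'
#' Tab-separated, one row per object: provenance columns (`sample`,
#' `field_row`, `field_col`, `object_id`) followed by the 480 catalog
#' features in catalog order. The first line is a comment carrying the
#' catalog version; values round-trip at 12 significant digits.
#'
#' @param features numeric matrix (objects x features) with catalog
#'   column names and a `catalog_version` attribute, as returned by the
#'   feature stage, or a list of feature vectors sharing one version.
#' @param provenance data.frame with columns `sample`, `field_row`,
#'   `field_col`, `object_id` (one row per object).
#' @param path destination file.
#' @export
write_feature_table <- function(features, provenance, path) {
  if (is.list(features) && !is.matrix(features) && !is.data.frame(features)) {
    vers <- unique(vapply(features, function(f)
      attr(f, "catalog_version") %||% NA_character_, character(1)))
    if (length(vers) != 1L || is.na(vers))
      stop("mixed or missing catalog versions in feature records")
    features <- do.call(rbind, features)
    attr(features, "catalog_version") <- vers
  }
  version <- attr(features, "catalog_version")
  if (is.null(version)) stop("features must carry a catalog_version attribute")
  stopifnot(nrow(provenance) == nrow(features))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# catalog_version: %s", version), con)
  header <- c("sample", "field_row", "field_col", "object_id",
              colnames(features))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(features) > 0) {
    vals <- apply(features, 1, function(r)
      paste(sprintf("%.12g", r), collapse = "\t"))
    lines <- paste(provenance$sample, provenance$field_row,
                   provenance$field_col, provenance$object_id, vals,
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_feature_table
#' @return `read_feature_table()` returns a list with `features` (matrix
#'   with `catalog_version` attribute) and `provenance` (data.frame).
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  version <- sub("^# catalog_version: *", "", first)
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  prov <- tab[, 1:4, drop = FALSE]
  feats <- as.matrix(tab[, -(1:4), drop = FALSE])
  rownames(feats) <- NULL
  attr(feats, "catalog_version") <- version
  list(features = feats, provenance = prov)
}

#' Read / write a curated label table
#'
#' Five tab-separated columns: `object_id`, `level1` .. `level4`; each
#' row gives the full 4-level taxonomic path of one training object.
#'
#' @param path file path.
#' @param labels data.frame with those five columns (for writing).
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("object_id", "level1", "level2", "level3", "level4")
  if (!all(need %in% names(tab))) stop("label table must have columns: ",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(tab$object_id)) stop("object_ids must be unique")
  tab[, need]
}

#' @rdname read_label_table
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 4-level taxonomy from a 4-column TSV
#'
#' Each row is one leaf path `level1 .. level4`. The tree has exactly 4
#' levels; a leaf name reachable through two distinct parent paths is
#' rejected.
#'
#' @param path file path (TSV with a header of 4 columns).
#' @return a `taxonomy_tree`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) != 4L) stop("taxonomy file must have exactly 4 columns")
  names(tab) <- paste0("level", 1:4)
  taxonomy_tree(tab)
}

#' Build a 4-level taxonomy tree from a path table
#'
#' @param paths data.frame with columns `level1` .. `level4`, one row per
#'   leaf path (duplicate identical rows are collapsed).
#' @return an object of class `taxonomy_tree` with the distinct paths and
#'   a leaf -> path lookup.
#' @export
taxonomy_tree <- function(paths) {
  need <- paste0("level", 1:4)
  stopifnot(all(need %in% names(paths)))
  paths <- unique(paths[, need])
  rownames(paths) <- NULL
  dup <- duplicated(paths$level4)
  if (any(dup))
    stop("leaf '", paths$level4[dup][1],
         "' is reachable by two distinct parent paths")
  structure(list(paths = paths), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  p <- x$paths
  cat(sprintf("taxonomy_tree: %d / %d / %d / %d categories at levels 1-4\n",
              length(unique(p$level1)), length(unique(p$level2)),
              length(unique(p$level3)), length(unique(p$level4))))
  invisible(x)
}

#' Number of leaves (level-4 categories) of a taxonomy
#' @param tree a `taxonomy_tree`.
#' @export
n_leaves <- function(tree) nrow(tree$paths)

#' Map leaf labels to their ancestor category at a given level
#'
#' @param tree a `taxonomy_tree`.
#' @param leaves character vector of level-4 names.
#' @param level integer 1..4.
#' @return character vector of ancestor names at `level`.
#' @export
ancestor_at_level <- function(tree, leaves, level) {
  stopifnot(level %in% 1:4)
  idx <- match(leaves, tree$paths$level4)
  if (anyNA(idx)) stop("unknown leaf label(s): ",
                       paste(unique(leaves[is.na(idx)]), collapse = ", "))
  tree$paths[[paste0("level", level)]][idx]
}

#' Write the deduplicated object registry as TSV
#'
#' Columns: sequential `object_id`, `sample`, canonical `field_row` /
#' `field_col`, global centroid (um), and the source label in the
#' detection field.
#'
#' @param registry data.frame as returned by [dedup_counts()].
#' @param path destination file.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
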