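#' Mosaic layout geometry
#'
#' Fields tile the sample in a rectangular mosaic; adjacent fields
#' overlap by `overlap_fraction * field_width` so cells crossing a field
#' edge are fully visible in a neighbor. The field at (row, col) has its
#' origin at `(row * spacing, col * spacing)` um, where
#' `spacing = field_width * (1 - overlap_fraction)`. 2D um coordinates
#' are ordered (axis 1, axis 2): mosaic rows shift axis 1, columns axis 2.
#'
#' @param rows,cols mosaic dimensions.
#' @param config an `acquisition_config`.
#' @return a `mosaic_layout`.
#' @export
mosaic_layout <- function(rows, cols, config) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L)
  w <- config$field_width
  s <- w * (1 - config$overlap_fraction)
  structure(list(rows = rows, cols = cols, field_extent = w, spacing = s,
                 overlap_width = w - s, config = config),
            class = "mosaic_layout")
}

#' Local to global coordinates and back
#'
#' `to_global()` adds the field origin to a local (within-field) um
#' coordinate; `to_local()` is its exact inverse.
#'
#' @param field_pos integer vector `c(row, col)`, 0-based.
#' @param local_um,global_um numeric `c(u1, u2)` um coordinates.
#' @param layout a `mosaic_layout`.
#' @export
to_global <- function(field_pos, local_um, layout) {
  check_field_pos(field_pos, layout)
  local_um + field_pos * layout$spacing
}

#' @rdname to_global
#' @export
to_local <- function(field_pos, global_um, layout) {
  check_field_pos(field_pos, layout)
  global_um - field_pos * layout$spacing
}

check_field_pos <- function(field_pos, layout) {
  if (field_pos[1] < 0 || field_pos[1] >= layout$rows ||
      field_pos[2] < 0 || field_pos[2] >= layout$cols)
    stop("field position out of mosaic range")
  invisible(TRUE)
}

# canonical index along one axis: number of core midlines strictly below p.
# Midline between fields i and i+1 sits at (i+1)*spacing + overlap/2; a point
# exactly on a midline belongs to the smaller index (row-major tie-break).
canonical_index <- function(p, n, layout) {
  if (n == 1L) return(rep(0L, length(p)))
  mid <- (seq_len(n - 1L)) * layout$spacing + layout$overlap_width / 2
  as.integer(rowSums(outer(p, mid, ">")))
}

#' Assign detections to their canonical fields
#'
#' Every field rectangle, shrunk by half the overlap width on each edge
#' shared with a neighbor (edge fields extend to the mosaic border), is
#' that field's core; the cores tile the mosaic exactly. An object's
#' canonical field is the core containing its global centroid; a centroid
#' exactly on a core boundary goes to the field with the smaller
#' (row, col). Detections made in a non-canonical field are duplicates of
#' a neighbor's detection and are dropped.
#'
#' @param detections data.frame with columns `sample`, `field_row`,
#'   `field_col`, `label`, `u1`, `u2` (global centroid, um) — see
#'   [collect_detections()].
#' @param layout a `mosaic_layout`.
#' @return the input with added `canonical_row`, `canonical_col`,
#'   `canonical` (logical).
#' @export
assign_canonical <- function(detections, layout) {
  extent_1 <- (layout$rows - 1L) * layout$spacing + layout$field_extent
  extent_2 <- (layout$cols - 1L) * layout$spacing + layout$field_extent
  if (any(detections$u1 < 0 | detections$u1 > extent_1 |
          detections$u2 < 0 | detections$u2 > extent_2))
    stop("centroid outside the mosaic extent: geometry inconsistency")
  detections$canonical_row <-
    canonical_index(detections$u1, layout$rows,
                    layout)
  detections$canonical_col <-
    canonical_index(detections$u2, layout$cols, layout)
  detections$canonical <- detections$canonical_row == detections$field_row &
    detections$canonical_col == detections$field_col
  detections
}

#' Gather per-field detections into one table with global centroids
#'
#' @param detection_sets list of `detection_set` (one per field).
#' @param layout a `mosaic_layout`.
#' @return data.frame: `sample`, `field_row`, `field_col`, `label`,
#'   local centroid um (`l1`, `l2`), global centroid um (`u1`, `u2`),
#'   `area_um2`.
#' @export
collect_detections <- function(detection_sets, layout) {
  cfg <- layout$config
  rows <- lapply(detection_sets, function(d) {
    if (nrow(d$objects) == 0) return(NULL)
    l1 <- px_to_um(d$objects$cx, cfg)
    l2 <- px_to_um(d$objects$cy, cfg)
    g <- cbind(l1 + d$mosaic_row * layout$spacing,
               l2 + d$mosaic_col * layout$spacing)
    data.frame(sample = d$sample_id, field_row = d$mosaic_row,
               field_col = d$mosaic_col, label = d$objects$label,
               l1 = l1, l2 = l2, u1 = g[, 1], u2 = g[, 2],
               area_um2 = d$objects$area_um2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(0), field_row = integer(0),
                      field_col = integer(0), label = integer(0),
                      l1 = numeric(0), l2 = numeric(0), u1 = numeric(0),
                      u2 = numeric(0), area_um2 = numeric(0))
  out
}

#' Deduplicated object registry
#'
#' Keeps only canonical detections and renumbers them sequentially
#' (1..K) within the sample, ordered by (canonical row, canonical col,
#' source label), so the registry contains each physical object exactly
#' once regardless of how many fields imaged it.
#'
#' @param assignments output of [assign_canonical()].
#' @return data.frame: `object_id`, `sample`, `field_row`, `field_col`
#'   (canonical), `u1`, `u2`, `source_label`, `area_um2`.
#' @export
dedup_counts <- function(assignments) {
  kept <- assignments[assignments$canonical, , drop = FALSE]
  ord <- order(kept$field_row, kept$field_col, kept$label)
  kept <- kept[ord, , drop = FALSE]
  data.frame(object_id = seq_len(nrow(kept)), sample = kept$sample,
             field_row = kept$field_row, field_col = kept$field_col,
             u1 = kept$u1, u2 = kept$u2, source_label = kept$label,
             area_um2 = kept$area_um2 %||% NA_real_, row.names = NULL,
             stringsAsFactors = FALSE)
}
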