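#' Run the full analysis pipeline on one sample
#'
#' Stage order: global background estimation (pooled over all fields of
#' the sample) -> per-field detection and feature extraction -> mosaic
#' deduplication and sequential relabeling -> optional classification.
#' After the background pass, per-field work is independent, and outputs
#' are merged on the deterministic (row, col, label) sort key, so the
#' order in which fields are supplied or processed never changes any
#' output.
#'
#' @param fields list of `field_of_view` or a [field_source()] covering
#'   the sample's mosaic.
#' @param config an `acquisition_config`.
#' @param layout a `mosaic_layout`; default inferred from the maximal
#'   mosaic indices present.
#' @param catalog a `feature_catalog` (default built from `config`).
#' @param model optional `hcfm_model`; when present, registry objects
#'   are classified and scored.
#' @param min_area_um2 2D size filter, um^2.
#' @param min_volume_um3 3D sub-object size filter, um^3.
#' @param verbose emit per-stage log lines via `message()`.
#' @return an `hcfm_run`: list with `background`, `registry` (one row
#'   per physical object, sequential ids), `detections` (every per-field
#'   detection with its canonical assignment), `features` (matrix aligned
#'   with the registry), `provenance`, `predictions` (or NULL),
#'   `tallies` (per-field detection/duplicate counts) and
#'   `catalog_version`.
#' @export
run_pipeline <- function(fields, config, layout = NULL,
                         catalog = feature_catalog(config), model = NULL,
                         min_area_um2 = 12.6, min_volume_um3 = 0.5,
                         verbose = FALSE) {
  nf <- n_fields(fields)
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage background: pooling %d field(s)", nf)
  background <- estimate_background(fields, config)
  dets <- vector("list", nf)
  feats <- vector("list", nf)
  provs <- vector("list", nf)
  max_row <- 0L; max_col <- 0L
  for (i in seq_len(nf)) {
    f <- get_field(fields, i)
    max_row <- max(max_row, f$mosaic_row)
    max_col <- max(max_col, f$mosaic_col)
    fr <- featurize_field(f, background, catalog,
                          min_area_um2 = min_area_um2)
    dets[[i]] <- fr$detections
    feats[[i]] <- fr$features
    provs[[i]] <- fr$provenance
    say("stage detect/features: field (%d,%d): %d object(s)",
        f$mosaic_row, f$mosaic_col, nrow(fr$provenance))
  }
  if (is.null(layout)) layout <- mosaic_layout(max_row + 1L, max_col + 1L,
                                               config)
  all_det <- collect_detections(dets, layout)
  assigned <- assign_canonical(all_det, layout)
  registry <- dedup_counts(assigned)
  say("stage dedup: %d detection(s) -> %d object(s)", nrow(all_det),
      nrow(registry))
  features <- do.call(rbind, feats)
  prov <- do.call(rbind, provs)
  key <- function(r, c, l) paste(r, c, l, sep = "/")
  idx <- match(key(registry$field_row, registry$field_col,
                   registry$source_label),
               key(prov$field_row, prov$field_col, prov$object_id))
  features <- features[idx, , drop = FALSE]
  attr(features, "catalog_version") <- catalog_version(catalog)
  prov <- prov[idx, , drop = FALSE]
  prov$object_id <- registry$object_id
  rownames(prov) <- NULL
  predictions <- NULL
  if (!is.null(model) && nrow(features) > 0) {
    say("stage classify: %d object(s)", nrow(features))
    predictions <- predict_with_confidence(model, features)
    predictions <- cbind(object_id = registry$object_id, predictions)
  }
  tallies <- data.frame(
    total_detections = nrow(all_det),
    duplicates_removed = nrow(all_det) - nrow(registry),
    objects = nrow(registry))
  structure(list(background = background, registry = registry,
                 detections = assigned, features = features,
                 provenance = prov,
                 predictions = predictions, tallies = tallies,
                 layout = layout, catalog_version = catalog_version(catalog)),
            class = "hcfm_run")
}

#' @export
print.hcfm_run <- function(x, ...) {
  cat(sprintf("hcfm_run: %d object(s) from %d detection(s) (%d duplicate(s) removed), catalog %s\n",
              x$tallies$objects, x$tallies$total_detections,
              x$tallies$duplicates_removed, x$catalog_version))
  invisible(x)
}

#' Summary report of a pipeline run
#'
#' @param run an `hcfm_run`.
#' @return a `run_report` list: object counts, per-category counts when
#'   predictions exist, and the catalog version; regenerating the report
#'   from the same run is identical.
#' @export
make_report <- function(run) {
  rep <- list(sample = unique(run$registry$sample),
              n_objects = nrow(run$registry),
              n_detections = run$tallies$total_detections,
              duplicates_removed = run$tallies$duplicates_removed,
              catalog_version = run$catalog_version)
  if (!is.null(run$predictions)) {
    rep$category_counts <- as.data.frame(table(
      category = run$predictions$predicted), stringsAsFactors = FALSE)
    rep$mean_confidence <- mean(run$predictions$confidence)
  }
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s): %d objects / %d detections (catalog %s)\n",
              paste(x$sample, collapse = ","), x$n_objects, x$n_detections,
              x$catalog_version))
  if (!is.null(x$category_counts)) {
    cat("  categories:\n")
    for (i in seq_len(nrow(x$category_counts)))
      cat(sprintf("    %-20s %d\n", x$category_counts$category[i],
                  x$category_counts$Freq[i]))
  }
  invisible(x)
}
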