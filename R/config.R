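#' Channel role table
#'
#' Describes the acquisition channels: one transmitted-light bright-field
#' channel plus fluorescence channels used for masking. `use_for_masking`
#' is `FALSE` exactly for the bright-field channel, which contributes
#' intensity/texture features but is never thresholded.
#'
#' @param kinds character vector of channel kinds, each one of
#'   `"bright_field"`, `"dna"`, `"membranes"`, `"surface"`,
#'   `"chlorophyll"`.
#' @param names channel identifiers; default the kinds themselves.
#' @return a data.frame with columns `name`, `kind`, `use_for_masking`.
#' @export
channel_roles <- function(kinds = c("bright_field", "dna", "membranes",
                                    "surface", "chlorophyll"),
                          names = kinds) {
  allowed <- c("bright_field", "dna", "membranes", "surface", "chlorophyll")
  if (!all(kinds %in% allowed))
    stop("unknown channel kind(s): ", paste(setdiff(kinds, allowed), collapse = ", "))
  if (sum(kinds == "bright_field") != 1L)
    stop("exactly one channel must have kind 'bright_field'")
  if (anyDuplicated(names)) stop("channel names must be unique")
  data.frame(name = names, kind = kinds,
             use_for_masking = kinds != "bright_field",
             stringsAsFactors = FALSE)
}

#' Acquisition configuration
#'
#' Physical geometry of the confocal acquisition: voxel size, frame size,
#' mosaic overlap and channel roles. Defaults reproduce the reference
#' acquisition: 0.188 x 0.188 x 1.090 um voxels, 2048 px square frames
#' (385.62 um field width), 10% mosaic overlap in both axes, five channels.
#'
#' @param voxel_size_xy lateral voxel size, um.
#' @param voxel_size_z axial step, um.
#' @param frame_pixels pixels per frame side.
#' @param field_width physical frame width, um. Default 385.62 for the
#'   2048-px reference frame, otherwise `frame_pixels * voxel_size_xy`.
#'   Must agree with `frame_pixels * voxel_size_xy` within 1%.
#' @param overlap_fraction mosaic overlap fraction in `[0, 0.5)`.
#' @param channels channel role table, see [channel_roles()].
#' @param z_planes number of Z planes per stack (>= 1).
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(voxel_size_xy = 0.188, voxel_size_z = 1.090,
                               frame_pixels = 2048L, field_width = NULL,
                               overlap_fraction = 0.10,
                               channels = channel_roles(),
                               z_planes = 21L) {
  if (voxel_size_xy <= 0 || voxel_size_z <= 0) stop("voxel sizes must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must lie in [0, 0.5)")
  frame_pixels <- as.integer(frame_pixels)
  z_planes <- as.integer(z_planes)
  if (frame_pixels < 1L || z_planes < 1L)
    stop("frame_pixels and z_planes must be >= 1")
  if (is.null(field_width)) {
    field_width <- if (frame_pixels == 2048L && voxel_size_xy == 0.188)
      385.62 else frame_pixels * voxel_size_xy
  }
  if (abs(field_width - frame_pixels * voxel_size_xy) / field_width > 0.01)
    stop("field_width inconsistent with frame_pixels * voxel_size_xy (> 1%)")
  if (!is.data.frame(channels) ||
      !all(c("name", "kind", "use_for_masking") %in% names(channels)))
    stop("channels must be a channel role table")
  if (sum(channels$kind == "bright_field") != 1L)
    stop("exactly one bright_field channel required")
  if (any(channels$use_for_masking == (channels$kind == "bright_field")))
    stop("use_for_masking must be FALSE exactly for the bright_field channel")
  structure(list(voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
                 frame_pixels = frame_pixels, field_width = field_width,
                 overlap_fraction = overlap_fraction, channels = channels,
                 z_planes = z_planes),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("acquisition_config: %d px frames (%.2f um), voxel %.3f x %.3f x %.3f um,\n",
              x$frame_pixels, x$field_width, x$voxel_size_xy, x$voxel_size_xy,
              x$voxel_size_z))
  cat(sprintf("  %d Z planes, %.0f%% mosaic overlap, channels: %s\n",
              x$z_planes, 100 * x$overlap_fraction,
              paste(x$channels$name, collapse = ", ")))
  invisible(x)
}

#' Volume of one voxel in cubic micrometers
#' @param config an `acquisition_config`.
#' @export
voxel_volume_um3 <- function(config) {
  config$voxel_size_xy^2 * config$voxel_size_z
}

#' Area of one pixel in square micrometers
#' @param config an `acquisition_config`.
#' @export
pixel_area_um2 <- function(config) config$voxel_size_xy^2

#' Convert physical to pixel coordinates and back
#'
#' Pixels are 0-based; pixel `i` covers the half-open physical interval
#' `[i, i+1) * voxel_size_xy` and its center sits at `(i + 0.5) *
#' voxel_size_xy`, so `px_to_um(um_to_px(x))` reproduces `x` within half a
#' voxel.
#'
#' @param um,px coordinates in micrometers / 0-based pixels.
#' @param config an `acquisition_config`.
#' @return numeric vector of converted coordinates.
#' @export
um_to_px <- function(um, config) floor(um / config$voxel_size_xy)

#' @rdname um_to_px
#' @export
px_to_um <- function(px, config) (px + 0.5) * config$voxel_size_xy

#' Maskable (fluorescence) channel names
#' @param config an `acquisition_config`.
#' @export
maskable_channels <- function(config) {
  config$channels$name[config$channels$use_for_masking]
}

#' Name of the bright-field channel
#' @param config an `acquisition_config`.
#' @export
brightfield_channel <- function(config) {
  config$channels$name[config$channels$kind == "bright_field"]
}

#' Read / write an acquisition configuration descriptor
#'
#' The descriptor is a plain YAML or JSON mapping with the same field
#' names as [acquisition_config()]; channels are a list of
#' `{name, kind, use_for_masking}` records. The format is chosen from the
#' file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path file path.
#' @param config an `acquisition_config` (for writing).
#' @return `read_acquisition_config()` returns an `acquisition_config`.
#' @export
read_acquisition_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  ch <- if (is.data.frame(raw$channels)) raw$channels
        else do.call(rbind, lapply(raw$channels, function(r)
          as.data.frame(r, stringsAsFactors = FALSE)))
  acquisition_config(voxel_size_xy = raw$voxel_size_xy,
                     voxel_size_z = raw$voxel_size_z,
                     frame_pixels = raw$frame_pixels,
                     field_width = raw$field_width,
                     overlap_fraction = raw$overlap_fraction,
                     channels = ch, z_planes = raw$z_planes)
}

#' @rdname read_acquisition_config
#' @export
write_acquisition_config <- function(config, path) {
  raw <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    raw$channels <- lapply(seq_len(nrow(config$channels)), function(i)
      as.list(config$channels[i, ]))
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}
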