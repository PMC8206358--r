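#' Image volume container
#'
#' A 3-D single-channel intensity stack with physical pixel metadata.  The
#' voxel array is indexed `(z, y, x)`; all lengths are nanometers.  For
#' expanded samples, in-plane physical lengths follow the post-expansion
#' convention: a segment of `n` pixels measures `n * pixel_size_xy` nm in
#' the expanded gel.
#'
#' @param voxels numeric 3-D array `(z, y, x)`, or a matrix (taken as a
#'   single z-slice).  All values must be finite.
#' @param pixel_size_xy in-plane pixel size, nm/pixel (> 0).
#' @param z_step spacing between z-slices, nm (> 0).
#' @param channel_label free-text channel name, e.g. `"CH3-2940"`,
#'   `"lectin"`, `"DAPI"`.
#' @param expansion_state `"unprocessed"` or `"expanded"`.
#' @param expansion_factor linear expansion ratio (>= 1); required when
#'   `expansion_state == "expanded"`, must be `NULL` otherwise.
#' @return an object of class `vista_volume`.
#' @export
image_volume <- function(voxels, pixel_size_xy, z_step = 1000,
                         channel_label = "",
                         expansion_state = c("unprocessed", "expanded"),
                         expansion_factor = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a (z, y, x) array or a matrix")
  if (!all(is.finite(voxels))) stop("all voxel values must be finite")
  expansion_state <- match.arg(expansion_state)
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1L, pixel_size_xy > 0)
  stopifnot(is.numeric(z_step), length(z_step) == 1L, z_step > 0)
  if (expansion_state == "expanded") {
    if (is.null(expansion_factor) || !is.numeric(expansion_factor) ||
        expansion_factor < 1)
      stop("`expansion_factor` must be >= 1 for an expanded volume")
  } else if (!is.null(expansion_factor)) {
    stop("`expansion_factor` is only meaningful for expanded volumes")
  }
  structure(list(
    voxels = voxels * 1.0,
    pixel_size_xy = as.numeric(pixel_size_xy),
    z_step = as.numeric(z_step),
    channel_label = as.character(channel_label),
    expansion_state = expansion_state,
    expansion_factor = if (is.null(expansion_factor)) NULL else as.numeric(expansion_factor)
  ), class = "vista_volume")
}

#' @export
print.vista_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vista_volume> %s  %d z x %d y x %d x px  (%g nm/px, z-step %g nm, %s%s)\n",
              if (nzchar(x$channel_label)) x$channel_label else "(unlabeled)",
              d[1], d[2], d[3], x$pixel_size_xy, x$z_step, x$expansion_state,
              if (!is.null(x$expansion_factor))
                sprintf(", %gx", x$expansion_factor) else ""))
  invisible(x)
}

n_slices <- function(v) dim(v$voxels)[1]

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read an image volume from a multi-page grayscale TIFF
#'
#' Pages become z-slices.  Integer pixel data (8/16-bit) are promoted to
#' float without rescaling, so quantitative intensities survive; 32-bit
#' float pages are read as stored.  Metadata are taken from the JSON
#' sidecar (written by [write_volume()]) when present, else from the
#' arguments, else defaults with a warning.
#'
#' @param path TIFF file path.
#' @param metadata optional explicit sidecar path; default
#'   `<path minus extension>.json`.
#' @param pixel_size_xy,z_step,channel_label fallbacks used when no sidecar
#'   exists.
#' @return a [image_volume()] object.
#' @export
read_volume <- function(path, metadata = NULL, pixel_size_xy = NULL,
                        z_step = NULL, channel_label = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  # as.is=TRUE keeps integer samples as raw counts, but is rejected for
  # float pages, which are already returned as stored
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      if (grepl("floating point", conditionMessage(e)))
        tryCatch(tiff::readTIFF(path, all = TRUE),
                 error = function(e2) stop("not a readable TIFF (", path,
                                           "): ", conditionMessage(e2)))
      else stop("not a readable TIFF (", path, "): ", conditionMessage(e))
    })
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3L)
      stop(sprintf("unsupported multi-sample (RGB) TIFF page %d in %s", i, path))
  }
  nz <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  vox <- array(0, c(nz, h, w))
  for (i in seq_len(nz)) vox[i, , ] <- pages[[i]]

  sc <- if (is.null(metadata)) sidecar_path(path) else metadata
  meta <- list()
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    if (is.null(pixel_size_xy) && is.null(z_step))
      warning("no sidecar metadata for ", path,
              "; using defaults pixel_size_xy = 1000 nm, z_step = 1000 nm")
  }
  get <- function(name, arg, default) {
    if (!is.null(meta[[name]])) meta[[name]] else if (!is.null(arg)) arg else default
  }
  ef <- meta[["expansion_factor"]]
  image_volume(vox,
               pixel_size_xy = get("pixel_size_xy", pixel_size_xy, 1000),
               z_step = get("z_step", z_step, 1000),
               channel_label = get("channel_label", channel_label, ""),
               expansion_state = get("expansion_state", NULL, "unprocessed"),
               expansion_factor = if (is.null(ef)) NULL else ef)
}

# Minimal uncompressed little-endian float32 multi-page TIFF writer.
# tiff::writeTIFF stores 32-bit pages as *integer* samples scaled to [0,1],
# which destroys quantitative intensities, so volumes are written here with
# SampleFormat = IEEE float and read back bit-exactly by tiff::readTIFF.
write_float_tiff <- function(slices, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); u16(42L)
  n <- length(slices)
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  data_bytes <- 4 * h * w
  ifd_bytes <- 2 + 12 * 10 + 4
  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  page_bytes <- data_bytes + ifd_bytes
  u32(8L + data_bytes)                     # offset of first IFD
  for (i in seq_len(n)) {
    data_off <- 8L + (i - 1L) * page_bytes
    ifd_off <- data_off + data_bytes
    next_ifd <- if (i < n) ifd_off + ifd_bytes + data_bytes else 0L
    writeBin(as.numeric(t(slices[[i]])), con, size = 4, endian = "little")
    u16(10L)  # tag count
    tag <- function(id, type, count, value) {
      u16(id); u16(type); u32(count)
      if (type == 3L) { u16(value); u16(0L) } else u32(value)
    }
    tag(256L, 3L, 1L, w)          # ImageWidth
    tag(257L, 3L, 1L, h)          # ImageLength
    tag(258L, 3L, 1L, 32L)        # BitsPerSample
    tag(259L, 3L, 1L, 1L)         # Compression: none
    tag(262L, 3L, 1L, 1L)         # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off)   # StripOffsets
    tag(277L, 3L, 1L, 1L)         # SamplesPerPixel
    tag(278L, 3L, 1L, h)          # RowsPerStrip
    tag(279L, 4L, 1L, data_bytes) # StripByteCounts
    tag(339L, 3L, 1L, 3L)         # SampleFormat: IEEE float
    u32(next_ifd)
  }
  invisible(path)
}

#' Write an image volume as a float32 multi-page TIFF plus JSON sidecar
#'
#' One page per z-slice; all [image_volume()] metadata go to
#' `<path minus extension>.json`.  Voxels are stored as IEEE 32-bit floats,
#' so data already on the float32 grid round-trip bitwise.
#'
#' @param v a [image_volume()] object.
#' @param path output TIFF path.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vista_volume"))
  slices <- lapply(seq_len(n_slices(v)), function(z) v$voxels[z, , ])
  tryCatch(write_float_tiff(slices, path),
           error = function(e) stop("cannot write TIFF at ", path, ": ",
                                    conditionMessage(e)))
  meta <- list(pixel_size_xy = v$pixel_size_xy, z_step = v$z_step,
               channel_label = v$channel_label,
               expansion_state = v$expansion_state)
  if (!is.null(v$expansion_factor)) meta$expansion_factor <- v$expansion_factor
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Maximum intensity projection of a z-stack
#'
#' @param v a [image_volume()] or a 3-D `(z, y, x)` array.
#' @return a 2-D `(y, x)` matrix, `out[y, x] = max_z voxels[z, y, x]`.
#' @export
max_intensity_projection <- function(v) {
  vox <- if (inherits(v, "vista_volume")) v$voxels else v
  stopifnot(length(dim(vox)) == 3L, dim(vox)[1] >= 1L)
  out <- vox[1, , ]
  for (z in seq_len(dim(vox)[1])[-1]) out <- pmax(out, vox[z, , ])
  out
}

#' Merge grayscale channels into a tinted RGB composite
#'
#' Each channel is rescaled to `[0, 1]` by its percentile window, tinted by
#' its color, and composited additively with clipping at 1 — the usual
#' multi-channel overlay used for merged virtual-staining panels.
#'
#' @param channels list of 1–8 2-D matrices of identical shape.
#' @param colors character vector of R colors (or hex), one per channel.
#' @param normalization either a length-2 percentile pair in `[0, 100]`
#'   applied to every channel, or a list of such pairs per channel.
#' @return an `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
merge_channels <- function(channels, colors,
                           normalization = c(0, 100)) {
  if (!is.list(channels) || length(channels) < 1L || length(channels) > 8L)
    stop("`channels` must be a list of 1-8 images")
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same shape")
  if (length(colors) != length(channels))
    stop("need one color per channel")
  if (!is.list(normalization))
    normalization <- rep(list(normalization), length(channels))
  h <- nrow(channels[[1]]); w <- ncol(channels[[1]])
  out <- array(0, c(h, w, 3))
  for (i in seq_along(channels)) {
    win <- quantile(channels[[i]], normalization[[i]] / 100, names = FALSE)
    rng <- win[2] - win[1]
    sc <- if (rng > 0) pmin(pmax((channels[[i]] - win[1]) / rng, 0), 1)
          else channels[[i]] * 0
    tint <- as.numeric(grDevices::col2rgb(colors[i])) / 255
    for (k in 1:3) out[, , k] <- out[, , k] + sc * tint[k]
  }
  pmin(out, 1)
}

#' Write an RGB composite as PNG
#' @param rgb an `(H, W, 3)` array in `[0, 1]` (e.g. from [merge_channels()]).
#' @param path output path.
#' @export
write_composite_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Analysis report container
#'
#' A typed key-value payload with provenance, serialized losslessly to JSON.
#' Numeric payload entries carry their units in the key name
#' (e.g. `psf_fwhm_nm`).
#'
#' @param kind one of `"resolution"`, `"expansion"`, `"retention"`,
#'   `"evaluation"`.
#' @param payload named list of values.
#' @param provenance named list: input identifiers, parameters, seed.
#' @export
analysis_report <- function(kind = c("resolution", "expansion", "retention",
                                     "evaluation"),
                            payload = list(), provenance = list()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, payload = payload, provenance = provenance),
            class = "vista_report")
}

#' @rdname analysis_report
#' @param report a `vista_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "vista_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname analysis_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = x$kind, payload = as.list(x$payload),
                 provenance = as.list(x$provenance)), class = "vista_report")
}
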