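#' Calibrated multi-channel confocal z-stack
#'
#' A `calibrated_stack` holds nonnegative intensities indexed
#' `(channel, z, y, x)` together with the spatial calibration needed to turn
#' pixel counts into physical areas. Lateral calibration (`pixel_size_nm`) is
#' a required user input: object-size thresholds downstream are expressed in
#' nm^2, so no analysis can proceed without it. The axial step defaults to
#' 500 nm, a common confocal z-sampling for fixed cells.
#'
#' @param pixels numeric array with `dim = c(n_channel, n_z, ny, nx)`, all
#'   values `>= 0`
#' @param channel_names character vector of length `n_channel`, e.g.
#'   `c("green", "red")`
#' @param pixel_size_nm lateral pixel edge length in nm (> 0)
#' @param z_step_nm axial step in nm (> 0); default 500
#' @param bit_depth source bit depth (informational; default 8)
#' @return an object of class `calibrated_stack`
#' @export
calibrated_stack <- function(pixels, channel_names, pixel_size_nm,
                             z_step_nm = 500, bit_depth = 8L) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  if (length(channel_names) != dim(pixels)[1])
    stop("channel_names length (", length(channel_names),
         ") does not match channel dimension (", dim(pixels)[1], ")")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  if (!is.numeric(z_step_nm) || z_step_nm <= 0)
    stop("z_step_nm must be > 0")
  if (any(pixels < 0)) stop("stack intensities must be >= 0")
  structure(
    list(pixels = pixels,
         channel_names = as.character(channel_names),
         pixel_size_nm = as.numeric(pixel_size_nm),
         z_step_nm = as.numeric(z_step_nm),
         bit_depth = as.integer(bit_depth)),
    class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "calibrated_stack: %d channel(s) [%s], z=%d, %dx%d px, %g nm/px, z-step %g nm\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
    x$pixel_size_nm, x$z_step_nm))
  invisible(x)
}

#' Single 2-D calibrated image
#'
#' Carries provenance describing how the plane was obtained from a stack:
#' either a single optical slice (`single_slice`, with its z index) or a
#' maximum-intensity projection (`max_projection`, with its z range).
#'
#' @param pixels numeric matrix (rows = y, cols = x), values `>= 0`
#' @param pixel_size_nm lateral calibration in nm (> 0)
#' @param provenance list with elements `type` (`"single_slice"` or
#'   `"max_projection"`) and `z` (index or range); free-form extras allowed
#' @return an object of class `image2d`
#' @export
image2d <- function(pixels, pixel_size_nm,
                    provenance = list(type = "single_slice", z = 1L)) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0)) stop("image intensities must be >= 0")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  structure(list(pixels = pixels,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 provenance = provenance),
            class = "image2d")
}

channel_index <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop("unknown channel '", channel, "'; stack has: ",
         paste(stack$channel_names, collapse = ", "))
  i
}

#' Read a multi-page TIFF as a calibrated stack
#'
#' Pages are assumed grayscale and ordered z-within-channel (all z of the
#' first channel, then the second, ...); set `page_order = "channel_within_z"`
#' for interleaved exports. The declared channel count must divide the page
#' count. Intensities are read as stored (no rescaling).
#'
#' @param path path to a multi-page TIFF
#' @param pixel_size_nm lateral calibration in nm
#' @param z_step_nm axial step in nm; default 500
#' @param channel_names channel labels, in page order
#' @param page_order `"z_within_channel"` (default) or `"channel_within_z"`
#' @return a [calibrated_stack()]
#' @export
read_stack <- function(path, pixel_size_nm, z_step_nm = 500,
                       channel_names = c("green", "red"),
                       page_order = c("z_within_channel", "channel_within_z")) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop("cannot read TIFF: no such file '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_names)
  np <- length(pages)
  if (np %% nc != 0)
    stop("page count (", np, ") is not divisible by declared channel count (",
         nc, ")")
  nz <- np %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  px <- array(0, dim = c(nc, nz, ny, nx))
  for (p in seq_len(np)) {
    pg <- pages[[p]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # tolerate single-plane RGB pages
    if (nrow(pg) != ny || ncol(pg) != nx)
      stop("TIFF pages differ in shape")
    if (page_order == "z_within_channel") {
      ch <- (p - 1) %/% nz + 1; z <- (p - 1) %% nz + 1
    } else {
      ch <- (p - 1) %% nc + 1; z <- (p - 1) %/% nc + 1
    }
    px[ch, z, , ] <- pg
  }
  bd <- if (max(px) > 255) 16L else 8L
  calibrated_stack(px, channel_names, pixel_size_nm, z_step_nm, bd)
}

#' Write a calibrated stack as a multi-page 8-bit TIFF
#'
#' Pages are written z-within-channel. Values are clipped to \[0, 255\] and
#' rounded; use [to_8bit()] on projections when a different conversion is
#' wanted.
#'
#' @param stack a [calibrated_stack()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2])
  i <- 0
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1
    pages[[i]] <- pmin(pmax(round(stack$pixels[ch, z, , ]), 0), 255) / 255
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Maximum-intensity projection of one channel
#'
#' Each output pixel is the maximum over the selected z-slices, the standard
#' reduction applied to confocal stacks before 2-D quantification.
#'
#' @param stack a [calibrated_stack()]
#' @param channel channel label
#' @param z_range `"all"` (default) or an inclusive integer range `c(lo, hi)`
#' @return an [image2d()] with `max_projection` provenance
#' @export
max_projection <- function(stack, channel, z_range = "all") {
  stopifnot(inherits(stack, "calibrated_stack"))
  ci <- channel_index(stack, channel)
  nz <- dim(stack$pixels)[2]
  if (identical(z_range, "all")) z_range <- c(1L, nz)
  z_range <- as.integer(z_range)
  if (length(z_range) != 2 || z_range[1] > z_range[2])
    stop("z_range must be 'all' or c(lo, hi) with lo <= hi")
  if (z_range[1] < 1 || z_range[2] > nz)
    stop("z_range [", z_range[1], ", ", z_range[2],
         "] outside stack depth 1..", nz)
  zs <- z_range[1]:z_range[2]
  sub <- stack$pixels[ci, zs, , , drop = FALSE]
  proj <- apply(sub, c(3, 4), max)
  image2d(proj, stack$pixel_size_nm,
          provenance = list(type = "max_projection", z = z_range,
                            channel = channel))
}

#' Extract a single optical slice of one channel
#'
#' @param stack a [calibrated_stack()]
#' @param channel channel label
#' @param z slice index
#' @return an [image2d()] with `single_slice` provenance
#' @export
single_slice <- function(stack, channel, z) {
  stopifnot(inherits(stack, "calibrated_stack"))
  ci <- channel_index(stack, channel)
  nz <- dim(stack$pixels)[2]
  z <- as.integer(z)
  if (z < 1 || z > nz) stop("slice ", z, " outside stack depth 1..", nz)
  image2d(matrix(stack$pixels[ci, z, , ], dim(stack$pixels)[3],
                 dim(stack$pixels)[4]),
          stack$pixel_size_nm,
          provenance = list(type = "single_slice", z = z, channel = channel))
}

#' Convert an image to 8-bit
#'
#' `rescale_minmax` (the default for raw confocal exports) maps
#' `[min, max]` affinely onto `[0, 255]`; a constant image maps to 0.
#' `clip` keeps values, saturating at 255 and rounding fractions — the
#' semantics of an 8-bit pixel buffer. The mode used is recorded in the
#' output provenance so every downstream table can state it.
#'
#' @param image an [image2d()]
#' @param mode `"rescale_minmax"` or `"clip"`
#' @return an [image2d()] with integer values in \[0, 255\]
#' @export
to_8bit <- function(image, mode = c("rescale_minmax", "clip")) {
  stopifnot(inherits(image, "image2d"))
  mode <- match.arg(mode)
  px <- image$pixels
  if (mode == "clip") {
    out <- pmin(round(px), 255)
  } else {
    rng <- range(px)
    out <- if (rng[2] > rng[1])
      round((px - rng[1]) / (rng[2] - rng[1]) * 255)
    else matrix(0, nrow(px), ncol(px))
  }
  prov <- image$provenance
  prov$bit_conversion <- mode
  image2d(out, image$pixel_size_nm, prov)
}
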