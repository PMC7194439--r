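#' Per-vesicle measurements on the original image
#'
#' For every labelled object, the integral density (sum of ORIGINAL image
#' intensities over the object's footprint — the selections are restored on
#' the unenhanced image), the calibrated area, and the intensity-independent
#' centroid are computed.
#'
#' @param labels a `labeled_objects` from [segment_channel()] /
#'   [extract_objects()]
#' @param original the original [image2d()] the labels were derived from
#' @return data.frame with one row per object: `id`, `channel`, `area_nm2`,
#'   `integral_density`, `centroid_y_nm`, `centroid_x_nm`, `provenance`
#' @export
measure_objects <- function(labels, original) {
  stopifnot(inherits(labels, "labeled_objects"), inherits(original, "image2d"))
  if (!all(dim(labels$labels) == dim(original$pixels)))
    stop("label map and original image differ in shape")
  if (labels$pixel_size_nm != original$pixel_size_nm)
    stop("label map and original image differ in calibration")
  n <- labels$n_objects
  prov <- labels$provenance
  prov_str <- if (is.null(prov)) NA_character_ else
    paste0(prov$type, ":", paste(prov$z, collapse = "-"))
  if (n == 0)
    return(data.frame(id = integer(), channel = character(),
                      area_nm2 = numeric(), integral_density = numeric(),
                      centroid_y_nm = numeric(), centroid_x_nm = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  lab <- labels$labels
  idx <- which(lab > 0)
  l <- lab[idx]
  vals <- original$pixels[idx]
  ny <- nrow(lab)
  ps <- labels$pixel_size_nm
  ys <- ((idx - 1) %% ny) + 1
  xs <- ((idx - 1) %/% ny) + 1
  dens <- vapply(split(vals, l), sum, numeric(1))
  cy <- vapply(split(ys, l), mean, numeric(1))
  cx <- vapply(split(xs, l), mean, numeric(1))
  counts <- tabulate(l, nbins = n)
  data.frame(id = seq_len(n),
             channel = rep(labels$channel, n),
             area_nm2 = counts * ps^2,
             integral_density = as.numeric(dens),
             centroid_y_nm = (as.numeric(cy) - 0.5) * ps,
             centroid_x_nm = (as.numeric(cx) - 0.5) * ps,
             provenance = rep(prov_str, n),
             stringsAsFactors = FALSE)
}

#' Per-cell summary of vesicle records
#'
#' Counts, mean integral density and total vesicle area per channel — the
#' three per-cell quantities tracked across the endocytosis timecourse.
#' Channels with zero vesicles report `NA` mean density (flagged, not zero).
#'
#' @param records data.frame of vesicle records from [measure_objects()]
#'   (possibly several channels row-bound), all from one cell
#' @param cell_id identifier recorded in the output
#' @param channels channels to report; defaults to those present
#' @return data.frame with one row per channel: `cell`, `channel`,
#'   `n_vesicles`, `mean_integral_density`, `total_area_nm2`
#' @export
summarize_cell <- function(records, cell_id = 1L,
                           channels = unique(records$channel)) {
  rows <- lapply(channels, function(ch) {
    r <- records[records$channel == ch, , drop = FALSE]
    data.frame(cell = cell_id, channel = ch, n_vesicles = nrow(r),
               mean_integral_density = if (nrow(r) == 0) NA_real_
                                       else mean(r$integral_density),
               total_area_nm2 = sum(r$area_nm2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Object-based colocalization between two channels
#'
#' A source object counts as overlapping when at least one of its pixels is
#' foreground in the target channel's binarized mask — partial overlap
#' suffices. The percentage is reported under an explicit normalization:
#' `by_source` divides by the number of source objects; `by_target` divides
#' by the supplied target object count (the two conventions that a
#' "percentage of overlapping objects from the total number of objects" can
#' denote, depending on which channel's total is meant). Both directions are
#' obtained by swapping the channels.
#'
#' @param source a `labeled_objects` for the source channel
#' @param target_mask a `binary_mask` for the target channel
#' @param normalization `"by_source"` or `"by_target"`
#' @param n_target_objects required for `"by_target"`
#' @return data.frame row: `source_channel`, `target_channel`,
#'   `n_source_objects`, `n_overlapping`, `normalization`, `percent`,
#'   `provenance`
#' @export
object_colocalization <- function(source, target_mask,
                                  normalization = c("by_source", "by_target"),
                                  n_target_objects = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(source, "labeled_objects"),
            inherits(target_mask, "binary_mask"))
  if (!all(dim(source$labels) == dim(target_mask$mask)))
    stop("source labels and target mask differ in shape")
  if (source$pixel_size_nm != target_mask$pixel_size_nm)
    stop("source labels and target mask differ in calibration")
  n_src <- source$n_objects
  hit <- rep(FALSE, n_src)
  if (n_src > 0) {
    l <- source$labels[source$labels > 0]
    m <- target_mask$mask[source$labels > 0]
    hit_ids <- unique(l[m])
    hit[hit_ids] <- TRUE
  }
  n_over <- sum(hit)
  denom <- if (normalization == "by_source") n_src else {
    if (is.null(n_target_objects))
      stop("by_target normalization requires n_target_objects")
    n_target_objects
  }
  prov <- source$provenance
  data.frame(source_channel = source$channel,
             target_channel = if (!is.null(target_mask$provenance$channel))
               target_mask$provenance$channel else NA_character_,
             n_source_objects = n_src,
             n_overlapping = n_over,
             normalization = normalization,
             percent = if (denom > 0) 100 * n_over / denom else NA_real_,
             provenance = if (is.null(prov)) NA_character_ else
               paste0(prov$type, ":", paste(prov$z, collapse = "-")),
             stringsAsFactors = FALSE)
}

#' Pick the base-plane slice of a stack
#'
#' Colocalization is evaluated on a single optical slice representing the
#' base plane of the cell, where the majority of endosomes sit. As a
#' reproducible proxy, the slice with the greatest total intensity summed
#' over the given channels is chosen (ties toward the lower index).
#'
#' @param stack a [calibrated_stack()]
#' @param channels channels to sum over; default all
#' @return integer z index
#' @export
base_plane_slice <- function(stack, channels = stack$channel_names) {
  stopifnot(inherits(stack, "calibrated_stack"))
  ci <- vapply(channels, function(ch) channel_index(stack, ch), integer(1))
  nz <- dim(stack$pixels)[2]
  totals <- vapply(seq_len(nz),
                   function(z) sum(stack$pixels[ci, z, , ]), numeric(1))
  which.max(totals)
}

#' Five-number summary (boxplot statistics)
#'
#' Median, 25% and 75% quartiles, minimum and maximum — the statistics shown
#' in the timecourse boxplots. Quartiles use linear interpolation between
#' order statistics ([stats::quantile()] type 7), so figures regenerate
#' identically.
#'
#' @param values numeric sample, `n >= 1`
#' @return named numeric vector: `min`, `q25`, `median`, `q75`, `max`
#' @export
five_number <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("five_number needs at least one value")
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
}
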