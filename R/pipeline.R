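#' Analysis configuration for a timecourse run
#'
#' Binds together the channel roles (which stack channel is the EEA1-like
#' marker and which the EGFR-like cargo), the segmentation configuration,
#' the 8-bit conversion mode, the colocalization slice policy and the
#' significance level.
#'
#' @param marker_channel green/marker channel label; default `"green"`
#' @param cargo_channel red/cargo channel label; default `"red"`
#' @param seg a [seg_config()]
#' @param bit_mode 8-bit conversion mode for projections and slices
#' @param coloc_slice `"base_plane"` (auto-pick, see [base_plane_slice()])
#'   or an explicit z index
#' @param alpha significance mark level
#' @return a `run_config` list
#' @export
run_config <- function(marker_channel = "green", cargo_channel = "red",
                       seg = seg_config(),
                       bit_mode = c("rescale_minmax", "clip"),
                       coloc_slice = "base_plane", alpha = 0.05) {
  bit_mode <- match.arg(bit_mode)
  if (is.null(marker_channel) || is.null(cargo_channel) ||
      is.na(marker_channel) || is.na(cargo_channel))
    stop("both channel roles (marker, cargo) must be set")
  structure(list(marker_channel = marker_channel,
                 cargo_channel = cargo_channel, seg = seg,
                 bit_mode = bit_mode, coloc_slice = coloc_slice,
                 alpha = alpha),
            class = "run_config")
}

# Segment one image, returning both the thresholded mask (pre area filter)
# and the area-filtered labels: colocalization superimposes source ROIs on
# the target channel's binarized image, not on its filtered label map.
segment_with_mask <- function(image, seg, channel) {
  enhanced <- median_subtract(image, seg$median_radius_px[[channel]],
                              seg$clamp_negative)
  thr <- tryCatch(
    select_threshold(enhanced, image, seg$threshold_mode,
                     seg$fixed_threshold),
    endoquant_degenerate_image = function(e) Inf)
  mask <- binarize(enhanced, thr)
  mask$provenance$channel <- channel
  list(mask = mask,
       labels = extract_objects(mask, seg$min_area_nm2, channel))
}

#' Analyze one cell (one stack)
#'
#' Per channel: 8-bit maximum-intensity projection, segmentation, and
#' per-vesicle measurement on the projection. Colocalization is computed on
#' a single optical slice in both directions and under both normalization
#' conventions.
#'
#' @param stack a [calibrated_stack()] (one cell)
#' @param config a [run_config()]
#' @param cell_id identifier carried into the tables
#' @return list of data.frames: `vesicles`, `summary`, `coloc`
#' @export
analyze_cell <- function(stack, config = run_config(), cell_id = 1L) {
  stopifnot(inherits(stack, "calibrated_stack"), inherits(config, "run_config"))
  roles <- c(config$marker_channel, config$cargo_channel)
  missing <- setdiff(roles, stack$channel_names)
  if (length(missing) > 0)
    stop("stack lacks configured channel role(s): ",
         paste(missing, collapse = ", "))
  vesicles <- list(); per_channel <- list()
  for (ch in roles) {
    img <- to_8bit(max_projection(stack, ch), config$bit_mode)
    seg <- segment_channel(img, config$seg, ch)
    rec <- measure_objects(seg, img)
    if (nrow(rec) > 0) rec$cell <- cell_id
    vesicles[[ch]] <- rec
  }
  vrec <- do.call(rbind, vesicles)
  summary <- summarize_cell(vrec, cell_id, channels = roles)
  # colocalization on the base-plane slice
  z <- if (identical(config$coloc_slice, "base_plane"))
    base_plane_slice(stack, roles) else as.integer(config$coloc_slice)
  sl <- lapply(roles, function(ch)
    segment_with_mask(to_8bit(single_slice(stack, ch, z), config$bit_mode),
                      config$seg, ch))
  names(sl) <- roles
  coloc <- list()
  for (dir in list(c(roles[2], roles[1]), c(roles[1], roles[2]))) {
    src <- dir[1]; tgt <- dir[2]
    for (norm in c("by_source", "by_target")) {
      coloc[[length(coloc) + 1]] <- object_colocalization(
        sl[[src]]$labels, sl[[tgt]]$mask, norm,
        n_target_objects = sl[[tgt]]$labels$n_objects)
    }
  }
  coloc <- do.call(rbind, coloc)
  coloc$cell <- cell_id
  coloc$slice <- z
  rownames(vrec) <- rownames(coloc) <- NULL
  list(vesicles = vrec, summary = summary, coloc = coloc)
}

#' Simulate a timecourse to disk
#'
#' Writes one multi-page TIFF plus a tabular ground-truth sidecar per cell,
#' and a manifest recording labels, paths, calibration, and the derived
#' per-scene seeds.
#'
#' @param scenario a [timecourse_scenario()]
#' @param out_dir output directory
#' @param cells_per_timepoint scenes per timepoint
#' @return the manifest data.frame (also written as `manifest.csv`)
#' @export
run_simulate <- function(scenario, out_dir, cells_per_timepoint = 1L) {
  scenes <- generate_timecourse(scenario, cells_per_timepoint)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scenes, function(s) {
    stem <- sprintf("%s_cell%02d", gsub("[^A-Za-z0-9_-]", "_", s$label),
                    s$cell)
    paths <- write_scene(s, out_dir, stem)
    data.frame(label = s$label, cell = s$cell,
               tiff = basename(paths[["tiff"]]),
               truth = basename(paths[["truth"]]),
               pixel_size_nm = s$stack$pixel_size_nm,
               z_step_nm = s$stack$z_step_nm,
               seed = s$truth$config$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Analyze a set of cells across timecourse conditions
#'
#' Accepts either in-memory scene records (as from [generate_timecourse()])
#' or a directory written by [run_simulate()]. Produces the per-vesicle,
#' per-cell and colocalization tables, five-number summaries per condition,
#' and Mann-Whitney comparisons of per-cell marker counts and mean integral
#' densities against the control condition with Holm adjustment. When an
#' output directory is given, all tables and a parameter log are written as
#' CSV/text.
#'
#' @param input list of records with `label`, `cell`, `stack` — or a
#'   directory containing `manifest.csv`
#' @param config a [run_config()]
#' @param control_label control condition; default the first label
#' @param out_dir optional output directory for CSV tables and the log
#' @return list: `vesicles`, `summaries`, `coloc`, `five_numbers`,
#'   `stats_counts`, `stats_density`
#' @export
run_analyze <- function(input, config = run_config(), control_label = NULL,
                        out_dir = NULL) {
  scenes <- if (is.character(input)) load_scene_dir(input) else input
  if (length(scenes) == 0) stop("no cells to analyze")
  labels <- vapply(scenes, `[[`, character(1), "label")
  if (is.null(control_label)) control_label <- labels[1]
  ves <- list(); summ <- list(); col <- list()
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]
    res <- analyze_cell(s$stack, config, cell_id = i)
    res$vesicles$label <- s$label
    res$summary$label <- s$label
    res$coloc$label <- s$label
    ves[[i]] <- res$vesicles; summ[[i]] <- res$summary; col[[i]] <- res$coloc
  }
  vesicles <- do.call(rbind, ves)
  summaries <- do.call(rbind, summ)
  coloc <- do.call(rbind, col)
  marker <- config$marker_channel
  # five-number summaries per condition for the boxplotted quantities
  fn_rows <- list()
  for (lab in unique(labels)) {
    msum <- summaries[summaries$label == lab & summaries$channel == marker, ]
    csl <- coloc[coloc$label == lab &
                   coloc$source_channel == config$cargo_channel &
                   coloc$normalization == "by_source", ]
    for (q in list(list("marker_count", msum$n_vesicles),
                   list("marker_mean_integral_density",
                        msum$mean_integral_density),
                   list("cargo_to_marker_coloc_pct", csl$percent))) {
      vals <- q[[2]][!is.na(q[[2]])]
      if (length(vals) == 0) next
      fn <- five_number(vals)
      fn_rows[[length(fn_rows) + 1]] <- data.frame(
        label = lab, quantity = q[[1]], n = length(vals), t(fn),
        stringsAsFactors = FALSE)
    }
  }
  five_numbers <- do.call(rbind, fn_rows)
  per_cond <- function(column) {
    sub <- summaries[summaries$channel == marker, ]
    split(sub[[column]], factor(sub$label, levels = unique(labels)))
  }
  stats_counts <- stats_density <- NULL
  if (length(unique(labels)) > 1) {
    stats_counts <- timecourse_tests(per_cond("n_vesicles"), control_label,
                                     alpha = config$alpha)
    stats_density <- timecourse_tests(per_cond("mean_integral_density"),
                                      control_label, alpha = config$alpha)
  }
  out <- list(vesicles = vesicles, summaries = summaries, coloc = coloc,
              five_numbers = five_numbers, stats_counts = stats_counts,
              stats_density = stats_density)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]]))
        write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                  row.names = FALSE)
    }
    writeLines(c(
      sprintf("endoquant run: %d cells, control = %s", length(scenes),
              control_label),
      sprintf("channel roles: marker=%s cargo=%s", marker,
              config$cargo_channel),
      sprintf("median radii (px): %s",
              paste(names(config$seg$median_radius_px),
                    config$seg$median_radius_px, sep = "=",
                    collapse = " ")),
      sprintf("threshold mode: %s", config$seg$threshold_mode),
      sprintf("min area (nm^2, strict): %g", config$seg$min_area_nm2),
      sprintf("8-bit mode: %s; coloc slice: %s; alpha: %g",
              config$bit_mode, as.character(config$coloc_slice),
              config$alpha)),
      file.path(out_dir, "run_log.txt"))
  }
  out
}

load_scene_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in '", dir, "'")
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    list(label = m$label, cell = m$cell,
         stack = read_stack(file.path(dir, m$tiff), m$pixel_size_nm,
                            m$z_step_nm),
         truth = read_scene_truth(file.path(dir, m$truth)))
  })
}

#' Compare pipeline output against generator ground truth
#'
#' For every cell with a ground-truth record: the marker-channel count error
#' (segmented minus true) and, when red objects are present, the error of
#' the by-source cargo-to-marker colocalization percentage against the
#' geometric truth. Reports bias, absolute error, and pass/fail against the
#' declared tolerances.
#'
#' @param scenes list of records with `label`, `stack`, `truth` (in-memory or
#'   via [load_scene_dir()])
#' @param config a [run_config()]
#' @param count_exact_frac required fraction of cells with exact count
#'   recovery; default 0.95
#' @param coloc_tol_pp colocalization tolerance in percentage points;
#'   default 5
#' @return list: `per_cell` data.frame, `count_exact_fraction`,
#'   `coloc_max_abs_err_pp`, `pass_counts`, `pass_coloc`
#' @export
run_recovery <- function(scenes, config = run_config(),
                         count_exact_frac = 0.95, coloc_tol_pp = 5) {
  if (length(scenes) == 0) stop("no scenes to evaluate")
  rows <- list()
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]
    if (is.null(s$truth)) stop("scene ", i, " has no ground truth")
    res <- analyze_cell(s$stack, config, cell_id = i)
    marker <- config$marker_channel
    got_n <- res$summary$n_vesicles[res$summary$channel == marker]
    true_n <- unname(s$truth$true_counts[[marker]])
    cl <- res$coloc[res$coloc$source_channel == config$cargo_channel &
                      res$coloc$normalization == "by_source", ]
    true_pct <- 100 * s$truth$true_overlap$red_to_green
    rows[[i]] <- data.frame(
      cell = i, label = s$label,
      true_count = true_n, est_count = got_n,
      count_err = got_n - true_n,
      true_coloc_pct = true_pct,
      est_coloc_pct = cl$percent,
      coloc_err_pp = cl$percent - true_pct,
      stringsAsFactors = FALSE)
  }
  per_cell <- do.call(rbind, rows)
  exact <- mean(per_cell$count_err == 0)
  cerr <- per_cell$coloc_err_pp[!is.na(per_cell$coloc_err_pp)]
  max_abs <- if (length(cerr) > 0) max(abs(cerr)) else NA_real_
  list(per_cell = per_cell,
       count_exact_fraction = exact,
       count_bias = mean(per_cell$count_err),
       coloc_max_abs_err_pp = max_abs,
       pass_counts = exact >= count_exact_frac,
       pass_coloc = is.na(max_abs) || max_abs <= coloc_tol_pp)
}
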