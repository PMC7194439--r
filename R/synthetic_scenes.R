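#' Configuration for a synthetic two-channel confocal scene
#'
#' The generator emulates a single fixed cell imaged in two fluorescence
#' channels: a green (EEA1-like) channel with a baseline population of about
#' 150 vesicles, a red (EGFR-like) cargo channel, and "hybrid" two-domain
#' endosomes rendered as a touching green/red disk pair on one structure.
#' Vesicles are disks with radii drawn uniformly from `radius_nm_range`,
#' placed either in a juxtanuclear cluster (isotropic Gaussian around a
#' nucleus-edge point) or scattered uniformly, blurred with a Gaussian PSF,
#' then degraded with background plus Poisson and Gaussian read noise.
#'
#' Defaults describe the emulated study conditions: a 256 x 256 px per-cell
#' crop at 100 nm/px (a 25.6 um field, typical for one HeLa cell), 5 optical
#' slices 500 nm apart, 150 green vesicles, radii 200-500 nm (within the
#' 100 nm to several-um range reported for endosomes, kept sub-micron so the
#' baseline population fits one cell crop without contact), PSF sigma 100 nm,
#' and signal-to-background around 15.
#'
#' @param image_shape `c(ny, nx)` in pixels
#' @param pixel_size_nm lateral calibration; default 100
#' @param n_z number of optical slices
#' @param n_green,n_red,n_hybrid object counts; a hybrid contributes one
#'   green and one red domain to the per-channel counts
#' @param radius_nm_range uniform range for vesicle radii (nm)
#' @param placement `"juxtanuclear"` or `"scattered"`
#' @param cluster_center_frac fractional (y, x) position of the juxtanuclear
#'   cluster centre
#' @param cluster_spread_nm Gaussian spread of juxtanuclear placement (nm)
#' @param min_gap_nm minimum edge-to-edge clearance enforced between distinct
#'   structures (nm); keeps ground-truth counts and overlaps exact
#' @param psf_sigma_nm Gaussian PSF sigma (nm); 0 disables blur
#' @param background_level additive background intensity
#' @param poisson_scale photon-count scaling for shot noise; 0 disables
#' @param gaussian_sd additive read-noise sigma; 0 disables
#' @param amplitude_range uniform range of per-object peak intensity
#' @param z_placement `"base_plane"` (all vesicles in the middle slice, the
#'   plane where most endosomes sit) or `"uniform"` (random slice per object)
#' @param seed integer; fixes the whole scene
#' @return a `scene_config` list
#' @export
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size_nm = 100,
                         n_z = 5L,
                         n_green = 150L,
                         n_red = 0L,
                         n_hybrid = 0L,
                         radius_nm_range = c(200, 500),
                         placement = c("juxtanuclear", "scattered"),
                         cluster_center_frac = c(0.40, 0.50),
                         cluster_spread_nm = 8000,
                         min_gap_nm = 600,
                         psf_sigma_nm = 100,
                         background_level = 10,
                         poisson_scale = 1,
                         gaussian_sd = 2,
                         amplitude_range = c(120, 200),
                         z_placement = c("base_plane", "uniform"),
                         seed = 1L) {
  placement <- match.arg(placement)
  z_placement <- match.arg(z_placement)
  stopifnot(n_green >= 0, n_red >= 0, n_hybrid >= 0, n_z >= 1,
            pixel_size_nm > 0, psf_sigma_nm >= 0, min_gap_nm >= 0,
            length(radius_nm_range) == 2,
            radius_nm_range[1] <= radius_nm_range[2])
  if (radius_nm_range[1] < pixel_size_nm)
    stop("minimum radius must be at least one pixel (", pixel_size_nm, " nm)")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size_nm = pixel_size_nm,
    n_z = as.integer(n_z), n_green = as.integer(n_green),
    n_red = as.integer(n_red), n_hybrid = as.integer(n_hybrid),
    radius_nm_range = radius_nm_range, placement = placement,
    cluster_center_frac = cluster_center_frac,
    cluster_spread_nm = cluster_spread_nm, min_gap_nm = min_gap_nm,
    psf_sigma_nm = psf_sigma_nm, background_level = background_level,
    poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
    amplitude_range = amplitude_range, z_placement = z_placement,
    seed = as.integer(seed)), class = "scene_config")
}

# Hybrid domain centres sit 0.8 * (r_green + r_red) apart: the two disks
# overlap by 20% of the radius sum, giving touching-but-distinct domains
# whose binarized footprints always share pixels but never coincide.
HYBRID_SEPARATION_FACTOR <- 0.8

sample_center <- function(cfg, reach_nm) {
  ny_nm <- cfg$image_shape[1] * cfg$pixel_size_nm
  nx_nm <- cfg$image_shape[2] * cfg$pixel_size_nm
  lo_y <- reach_nm; hi_y <- ny_nm - reach_nm
  lo_x <- reach_nm; hi_x <- nx_nm - reach_nm
  if (lo_y >= hi_y || lo_x >= hi_x) stop("object too large for image")
  if (cfg$placement == "scattered")
    return(c(runif(1, lo_y, hi_y), runif(1, lo_x, hi_x)))
  mu <- cfg$cluster_center_frac * c(ny_nm, nx_nm)
  for (i in 1:200) {
    p <- rnorm(2, mu, cfg$cluster_spread_nm)
    if (p[1] > lo_y && p[1] < hi_y && p[2] > lo_x && p[2] < hi_x) return(p)
  }
  c(runif(1, lo_y, hi_y), runif(1, lo_x, hi_x))  # fall back after truncation
}

#' Generate one synthetic scene with geometric ground truth
#'
#' Objects are placed by rejection sampling (up to 1000 retries per object)
#' so that distinct structures keep an edge-to-edge clearance of at least
#' `min_gap_nm`; the ground truth (object table, per-channel counts,
#' per-direction overlap fractions) is therefore an exact function of the
#' layout, computed before any blur or noise is applied. The same config and
#' seed always produce a bit-identical stack.
#'
#' @param config a [scene_config()]
#' @return list with elements `stack` (a [calibrated_stack()] with channels
#'   `"green"` and `"red"`) and `truth` (see [ground_truth_from_objects()])
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    objects <- place_objects(config)
    stack <- render_scene(config, objects)
    list(stack = stack, truth = ground_truth_from_objects(objects, config))
  })
}

place_objects <- function(cfg) {
  rows <- list()
  placed <- NULL  # matrix: y, x, radius (one row per domain already placed)
  add_row <- function(sid, ch, hybrid, c_yx, r, amp, z) {
    rows[[length(rows) + 1]] <<- data.frame(
      structure_id = sid, channel = ch, hybrid = hybrid,
      center_y_nm = c_yx[1], center_x_nm = c_yx[2], radius_nm = r,
      amplitude = amp, z = z, stringsAsFactors = FALSE)
    placed <<- rbind(placed, c(c_yx, r))
  }
  clear_of_all <- function(c_yx, r) {
    if (is.null(placed)) return(TRUE)
    d <- sqrt((placed[, 1] - c_yx[1])^2 + (placed[, 2] - c_yx[2])^2)
    all(d > placed[, 3] + r + cfg$min_gap_nm)
  }
  draw_z <- function() {
    if (cfg$z_placement == "base_plane") as.integer(ceiling(cfg$n_z / 2))
    else sample.int(cfg$n_z, 1)
  }
  sid <- 0
  # simple structures: one disk in one channel
  for (spec in list(c("green", cfg$n_green), c("red", cfg$n_red))) {
    ch <- spec[1]; n <- as.integer(spec[2])
    for (i in seq_len(n)) {
      sid <- sid + 1
      ok <- FALSE
      for (try in 1:1000) {
        r <- runif(1, cfg$radius_nm_range[1], cfg$radius_nm_range[2])
        c_yx <- sample_center(cfg, r + cfg$min_gap_nm)
        if (clear_of_all(c_yx, r)) { ok <- TRUE; break }
      }
      if (!ok) stop("placement failed after 1000 retries (", ch,
                    " object ", i, "): scene too crowded")
      add_row(sid, ch, FALSE, c_yx,  r,
              runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2]),
              draw_z())
    }
  }
  # hybrids: a green and a red domain sharing one structure
  for (i in seq_len(cfg$n_hybrid)) {
    sid <- sid + 1
    ok <- FALSE
    for (try in 1:1000) {
      rg <- runif(1, cfg$radius_nm_range[1], cfg$radius_nm_range[2])
      rr <- runif(1, cfg$radius_nm_range[1], cfg$radius_nm_range[2])
      sep <- HYBRID_SEPARATION_FACTOR * (rg + rr)
      theta <- runif(1, 0, 2 * pi)
      reach <- sep + max(rg, rr) + cfg$min_gap_nm
      cg <- sample_center(cfg, reach)
      cr <- cg + sep * c(sin(theta), cos(theta))
      if (clear_of_all(cg, rg) && clear_of_all(cr, rr)) { ok <- TRUE; break }
    }
    if (!ok) stop("placement failed after 1000 retries (hybrid ", i,
                  "): scene too crowded")
    z <- draw_z()
    add_row(sid, "green", TRUE, cg, rg,
            runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2]), z)
    add_row(sid, "red", TRUE, cr, rr,
            runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2]), z)
  }
  if (length(rows) == 0)
    return(data.frame(structure_id = integer(), channel = character(),
                      hybrid = logical(), center_y_nm = numeric(),
                      center_x_nm = numeric(), radius_nm = numeric(),
                      amplitude = numeric(), z = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$id <- seq_len(nrow(df))
  df[, c("id", "structure_id", "channel", "hybrid", "center_y_nm",
         "center_x_nm", "radius_nm", "amplitude", "z")]
}

#' Ground truth derived from an object table
#'
#' Per-channel true counts and per-direction overlap fractions are computed
#' purely from disk geometry: a domain in one channel "overlaps" the other
#' channel when its disk intersects any disk of that channel. This is the
#' quantity the object-based colocalization estimator should recover.
#'
#' @param objects object table as produced by [generate_scene()] (one row per
#'   disk domain: `id`, `structure_id`, `channel`, `hybrid`, `center_y_nm`,
#'   `center_x_nm`, `radius_nm`, `amplitude`, `z`)
#' @param config optional [scene_config()] echoed into the result
#' @return list with `objects`, `true_counts` (named per channel), and
#'   `true_overlap` with elements `red_to_green` and `green_to_red`
#'   (fractions in \[0, 1\]; `NA` when the source channel is empty)
#' @export
ground_truth_from_objects <- function(objects, config = NULL) {
  overlap_frac <- function(src, tgt) {
    s <- objects[objects$channel == src, , drop = FALSE]
    t <- objects[objects$channel == tgt, , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    if (nrow(t) == 0) return(0)
    hits <- vapply(seq_len(nrow(s)), function(i) {
      d <- sqrt((t$center_y_nm - s$center_y_nm[i])^2 +
                (t$center_x_nm - s$center_x_nm[i])^2)
      any(d < t$radius_nm + s$radius_nm[i])
    }, logical(1))
    mean(hits)
  }
  list(objects = objects,
       true_counts = c(green = sum(objects$channel == "green"),
                       red = sum(objects$channel == "red")),
       true_overlap = list(red_to_green = overlap_frac("red", "green"),
                           green_to_red = overlap_frac("green", "red")),
       config = config)
}

render_scene <- function(cfg, objects) {
  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  ps <- cfg$pixel_size_nm
  px <- array(0, dim = c(2, cfg$n_z, ny, nx))
  chans <- c(green = 1L, red = 2L)
  yc <- (seq_len(ny) - 0.5) * ps  # pixel-centre coordinates in nm
  xc <- (seq_len(nx) - 0.5) * ps
  for (i in seq_len(nrow(objects))) {
    o <- objects[i, ]
    dy2 <- (yc - o$center_y_nm)^2
    dx2 <- (xc - o$center_x_nm)^2
    disk <- outer(dy2, dx2, "+") <= o$radius_nm^2
    sl <- px[chans[[o$channel]], o$z, , ]
    sl[disk] <- sl[disk] + o$amplitude
    px[chans[[o$channel]], o$z, , ] <- sl
  }
  if (cfg$psf_sigma_nm > 0) {
    sig_px <- cfg$psf_sigma_nm / ps
    for (ch in 1:2) for (z in seq_len(cfg$n_z)) {
      sl <- matrix(px[ch, z, , ], ny, nx)
      if (max(sl) > 0)
        px[ch, z, , ] <- as.matrix(EBImage::gblur(sl, sigma = sig_px))
    }
  }
  px <- px + cfg$background_level
  if (cfg$poisson_scale > 0) {
    lam <- pmax(px * cfg$poisson_scale, 0)
    px[] <- rpois(length(lam), lam) / cfg$poisson_scale
  }
  if (cfg$gaussian_sd > 0)
    px[] <- px + rnorm(length(px), 0, cfg$gaussian_sd)
  px[px < 0] <- 0
  calibrated_stack(px, c("green", "red"), ps, z_step_nm = 500, bit_depth = 8L)
}

#' Scenario for a synthetic endocytosis timecourse
#'
#' Each timepoint carries a target fraction of red (cargo) objects attached
#' to green (EEA1) structures; the generator realizes the target by making
#' `round(target * n_red_total)` of the red objects hybrid-attached and
#' keeping the rest clear of all green disks, so the geometric truth matches
#' the target up to that integer rounding. A per-timepoint red amplitude
#' multiplier emulates progressive cargo concentration.
#'
#' @param labels unique timepoint labels, in order (first = control)
#' @param overlap_targets red-to-green overlap fraction per timepoint, in
#'   \[0, 1\]
#' @param red_amplitude_multiplier per-timepoint multiplier on red-channel
#'   amplitudes; default all 1
#' @param n_red_total red objects per scene (attached + free)
#' @param base_config [scene_config()] template for every timepoint
#' @param seed root seed; per-timepoint seeds are derived from it
#' @return a `timecourse_scenario` list
#' @export
timecourse_scenario <- function(labels, overlap_targets,
                                red_amplitude_multiplier = rep(1, length(labels)),
                                n_red_total = 60L,
                                base_config = scene_config(),
                                seed = 1L) {
  stopifnot(length(labels) == length(overlap_targets),
            length(labels) == length(red_amplitude_multiplier))
  if (anyDuplicated(labels)) stop("timepoint labels must be unique")
  if (any(overlap_targets < 0 | overlap_targets > 1))
    stop("overlap targets must lie in [0, 1]")
  structure(list(labels = as.character(labels),
                 overlap_targets = overlap_targets,
                 red_amplitude_multiplier = red_amplitude_multiplier,
                 n_red_total = as.integer(n_red_total),
                 base_config = base_config,
                 seed = as.integer(seed)),
            class = "timecourse_scenario")
}

#' Generate a timecourse of synthetic scenes
#'
#' @param scenario a [timecourse_scenario()]
#' @param cells_per_timepoint scenes (cells) per timepoint; default 1
#' @return list of per-scene records: `label`, `cell`, `stack`, `truth`
#' @export
generate_timecourse <- function(scenario, cells_per_timepoint = 1L) {
  stopifnot(inherits(scenario, "timecourse_scenario"))
  out <- list()
  for (t in seq_along(scenario$labels)) {
    n_attached <- as.integer(round(scenario$overlap_targets[t] *
                                     scenario$n_red_total))
    for (cell in seq_len(cells_per_timepoint)) {
      cfg <- scenario$base_config
      cfg$n_hybrid <- n_attached
      cfg$n_red <- scenario$n_red_total - n_attached
      mult <- scenario$red_amplitude_multiplier[t]
      # per-scene seed: deterministic, distinct per (timepoint, cell)
      cfg$seed <- (scenario$seed + 7919L * t + 104729L * cell) %%
        .Machine$integer.max
      scn <- generate_scene(cfg)
      if (mult != 1) {  # rescale red-channel amplitudes by re-rendering
        obj <- scn$truth$objects
        obj$amplitude[obj$channel == "red"] <-
          obj$amplitude[obj$channel == "red"] * mult
        scn <- with_seed(cfg$seed, {
          list(stack = render_scene(cfg, obj),
               truth = ground_truth_from_objects(obj, cfg))
        })
      }
      out[[length(out) + 1]] <- list(label = scenario$labels[t], cell = cell,
                                     stack = scn$stack, truth = scn$truth)
    }
  }
  out
}

#' Generate replicate densitometry tables
#'
#' Emulates western-blot densitometry: per (timepoint, replicate) lane a band
#' density around `band_level` scaled by the timepoint's multiplicative
#' effect, and an independent loading-control density around `loading_level`,
#' both with multiplicative lognormal noise of the given coefficient of
#' variation. `effect = 1` everywhere is the null (no-change) condition.
#'
#' @param timepoints labels; the first is conventionally the control
#' @param n_reps replicates per timepoint (>= 1)
#' @param effect per-timepoint multiplicative effect (> 0); recycled
#' @param noise_cv coefficient of variation of the lognormal noise
#' @param seed integer seed
#' @param band_level,loading_level baseline densities
#' @return data.frame with columns `timepoint`, `replicate`, `band_density`,
#'   `loading_density`
#' @export
generate_densitometry <- function(timepoints, n_reps = 3L,
                                  effect = 1, noise_cv = 0.2, seed = 1L,
                                  band_level = 1000, loading_level = 500) {
  stopifnot(n_reps >= 1, all(effect > 0), noise_cv >= 0)
  effect <- rep_len(effect, length(timepoints))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_reps),
                        timepoint = as.character(timepoints),
                        stringsAsFactors = FALSE)[, c("timepoint", "replicate")]
    eff <- effect[match(grid$timepoint, as.character(timepoints))]
    n <- nrow(grid)
    grid$band_density <- band_level * eff *
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    grid$loading_density <- loading_level *
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    grid[order(match(grid$timepoint, timepoints), grid$replicate), ]
  })
}

#' Write a scene to disk (TIFF + tabular ground-truth sidecar)
#'
#' @param scene list with `stack` and `truth` as from [generate_scene()]
#' @param dir output directory (created if needed)
#' @param basename file stem; writes `<stem>.tif` and `<stem>_truth.tsv`
#' @return named character vector of the two paths, invisibly
#' @export
write_scene <- function(scene, dir, basename) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(basename, ".tif"))
  tsv <- file.path(dir, paste0(basename, "_truth.tsv"))
  write_stack(scene$stack, tif)
  write.table(scene$truth$objects, tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(tiff = tif, truth = tsv))
}

#' Read a ground-truth sidecar written by [write_scene()]
#'
#' @param path path to the `_truth.tsv` file
#' @return ground-truth list as from [ground_truth_from_objects()]
#' @export
read_scene_truth <- function(path) {
  obj <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ground_truth_from_objects(obj)
}
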