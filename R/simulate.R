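#' Simulate one cell's single-molecule recording
#'
#' Forward model of a sparse SMT acquisition. Molecules carry the
#' three-state kinetics of `preset` (free / short-lived bound / long-lived
#' bound) with exact exponential switching; switches occurring within a
#' frame contribute a time-weighted effective diffusion coefficient to
#' that frame's Gaussian displacement (per-axis variance `2 D dt`). The
#' nucleus boundary reflects overshoot. Reported positions add Gaussian
#' localization noise (truncated at vector norm `3 sigma`). Molecules
#' bleach permanently with a per-frame Bernoulli probability; as they do,
#' new molecules from the pool are activated so the emitting density stays
#' near `acq$density_per_um2`. In slow-dwell mode only molecules whose
#' true within-exposure displacement is at most `acq$blur_threshold_um`
#' are detected, so mobile molecules blur away.
#'
#' @param preset a [kinetic_preset()]. `F_bound = 0` simulates a pure-free
#'   species.
#' @param geometry a [nucleus_geometry()].
#' @param acq an [acquisition_config()].
#' @param n_molecules size of the labelled molecule pool (> 0).
#' @param seed integer seed; identical arguments and seed give
#'   bit-identical recordings.
#' @param chromatin_map optional [simulate_chromatin_map()] output;
#'   activates any `region_modifiers` carried by the preset.
#' @param cell_id identifier stored with the recording.
#' @param n_active optional override of the target number of concurrently
#'   emitting molecules (otherwise derived from the density and the
#'   nucleus area).
#' @param subframe_switching if `FALSE`, each frame's displacement uses
#'   the diffusion coefficient of the state occupied at the frame start
#'   instead of the time-weighted effective value (assumption-consistency
#'   checks only).
#' @return An object of class `cell_recording`: a list with
#'   `localizations` (data.frame `frame`, `t_s`, `x_um`, `y_um`,
#'   `molecule_id`), `ground_truth` (per molecule-frame true positions,
#'   dominant state and detection flag), `events` (exact bound-event
#'   intervals with censoring flags), plus the acquisition, geometry,
#'   preset name, seed and optional chromatin map.
#' @export
simulate_cell <- function(preset, geometry = nucleus_geometry(), acq,
                          n_molecules, seed, chromatin_map = NULL,
                          cell_id = "cell_1", n_active = NULL,
                          subframe_switching = TRUE) {
  stopifnot(inherits(preset, "kinetic_preset"),
            inherits(geometry, "nucleus_geometry"),
            inherits(acq, "acquisition_config"))
  if (n_molecules <= 0) stop("n_molecules must be positive")
  if (preset$F_bound >= 1) stop("F_bound = 1 is not simulable")
  set.seed(as.integer(seed))

  area <- pi * geometry$radius_um^2
  if (is.null(n_active))
    n_active <- max(1L, as.integer(round(acq$density_per_um2 * area)))
  n_active <- min(n_active, n_molecules)

  # warn when the field is dense enough to make fast-mode linking ambiguous
  r_max_fast <- sqrt(4 * 5 * acq$frame_interval_s)
  nn_mean <- 0.5 / sqrt(n_active / area)
  if (acq$mode == "fast" && nn_mean < 2 * r_max_fast)
    warning("emitter density high enough for tracking ambiguity")

  # per-region rates (euchromatin slot 1, heterochromatin slot 2)
  region_par <- function(region) {
    p <- preset
    mult <- 1
    mods <- preset$region_modifiers[[region]]
    if (!is.null(chromatin_map) && !is.null(mods)) {
      if (!is.null(mods$D_free_mult)) mult <- mods$D_free_mult
      for (nm in intersect(names(mods), c("F_bound", "f_long_event")))
        p[[nm]] <- mods[[nm]]
    }
    e_tau <- p$f_long_event * p$tau_long_s + (1 - p$f_long_event) * p$tau_short_s
    k_on <- if (p$F_bound <= 0) 0 else p$F_bound / ((1 - p$F_bound) * e_tau)
    c(k_on = k_on, f_long = p$f_long_event, D_free = p$D_free * mult)
  }
  eu <- region_par("euchromatin")
  het <- region_par("heterochromatin")

  # bleaching lifetimes (frames) drawn up front; activation schedule keeps
  # n_active molecules emitting until the pool is exhausted
  p_b <- acq$bleach_prob_per_frame
  life <- if (p_b > 0) 1L + rgeom(n_molecules, p_b) else
    rep(acq$n_frames, n_molecules)
  start <- integer(n_molecules)
  if (n_molecules > n_active) {
    deaths <- start[seq_len(n_active)] + life[seq_len(n_active)] - 1L
    for (j in (n_active + 1L):n_molecules) {
      i <- which.min(deaths)
      start[j] <- deaths[i] + 1L
      deaths[i] <- start[j] + life[j] - 1L
    }
  }

  grid <- NULL; px <- 1; ox <- 0; oy <- 0
  if (!is.null(chromatin_map)) {
    stopifnot(inherits(chromatin_map, "chromatin_map"))
    grid <- chromatin_map$grid
    storage.mode(grid) <- "integer"
    px <- chromatin_map$pixel_size_um
    ox <- chromatin_map$origin_x_um
    oy <- chromatin_map$origin_y_um
  }

  raw <- .simulate_cell_cpp(
    start_frame = start, life_frames = as.integer(life),
    n_frames = acq$n_frames, dt = acq$frame_interval_s,
    D_free_region = c(eu["D_free"], het["D_free"]),
    D_bound = preset$D_bound,
    k_on_region = c(eu["k_on"], het["k_on"]),
    f_long_region = c(eu["f_long"], het["f_long"]),
    k_off_short = 1 / preset$tau_short_s,
    k_off_long = 1 / preset$tau_long_s,
    sigma = acq$localization_sigma_um,
    slow_mode = (acq$mode == "slow"),
    blur_threshold = acq$blur_threshold_um,
    radius = geometry$radius_um,
    chrom_grid = grid, px_size = px, origin_x = ox, origin_y = oy,
    subframe_switching = subframe_switching)

  gt <- data.frame(molecule_id = raw$molecule_id, frame = raw$frame,
                   state = c("FREE", "BOUND_SHORT", "BOUND_LONG")[raw$state + 1L],
                   true_x_um = raw$true_x_um, true_y_um = raw$true_y_um,
                   detected = raw$detected == 1L)
  det <- raw$detected == 1L
  loc <- data.frame(frame = raw$frame[det],
                    t_s = raw$frame[det] * acq$frame_interval_s,
                    x_um = raw$obs_x_um[det], y_um = raw$obs_y_um[det],
                    molecule_id = raw$molecule_id[det])
  ev <- data.frame(molecule_id = raw$ev_molecule_id,
                   state = c("BOUND_SHORT", "BOUND_LONG")[raw$ev_state],
                   t_on = raw$ev_t_on, t_off = raw$ev_t_off,
                   censored_start = raw$ev_censored_start == 1L,
                   censored_end = raw$ev_censored_end == 1L)

  structure(list(localizations = loc, ground_truth = gt, events = ev,
                 acquisition = acq, geometry = geometry,
                 preset_name = preset$name, cell_id = cell_id,
                 chromatin_map = chromatin_map, seed = as.integer(seed),
                 n_molecules = n_molecules, n_active = n_active),
            class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %s | preset %s | %s mode\n",
              x$cell_id, x$preset_name, x$acquisition$mode))
  cat(sprintf("  %d localizations over %d frames (dt = %g s), seed %d\n",
              nrow(x$localizations), x$acquisition$n_frames,
              x$acquisition$frame_interval_s, x$seed))
  invisible(x)
}

#' Simulate replicate cells of one condition
#'
#' Cell `i` is simulated with seed `base_seed + i`, so cells are
#' statistically independent and the whole condition is reproducible from
#' `base_seed`.
#'
#' @inheritParams simulate_cell
#' @param n_cells number of replicate cells (>= 1).
#' @param base_seed integer; cell `i` uses `base_seed + i`.
#' @return List of `cell_recording` objects named by cell id.
#' @export
simulate_condition <- function(preset, n_cells, geometry = nucleus_geometry(),
                               acq, n_molecules, base_seed,
                               chromatin_map = NULL, ...) {
  stopifnot(n_cells >= 1)
  out <- lapply(seq_len(n_cells), function(i)
    simulate_cell(preset, geometry, acq, n_molecules,
                  seed = base_seed + i, chromatin_map = chromatin_map,
                  cell_id = sprintf("%s_cell_%02d", preset$name, i), ...))
  setNames(out, vapply(out, `[[`, "", "cell_id"))
}

# Gaussian smoothing with a brush capped to the image size (EBImage's
# gblur refuses kernels larger than the image)
.gauss_smooth <- function(img, sigma_px) {
  size <- 2 * ceiling(3 * sigma_px) + 1
  maxs <- 2 * floor((min(dim(img)) - 1) / 2) + 1
  size <- min(size, maxs)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  EBImage::filter2(img, brush)
}

#' Simulate a binary heterochromatin map
#'
#' Generates blob-like heterochromatin subdomains by thresholding a
#' Gaussian-smoothed white-noise field at the quantile that yields the
#' requested in-nucleus heterochromatin fraction. Pixels outside the
#' nucleus are 0.
#'
#' @param geometry a [nucleus_geometry()].
#' @param het_fraction target fraction of in-nucleus pixels that are
#'   heterochromatin, strictly in (0, 1).
#' @param blob_scale_um spatial scale of the subdomains (µm); the Gaussian
#'   smoothing SD of the underlying field.
#' @param pixel_size_um pixel size of the grid (µm); must be smaller than
#'   the nucleus diameter.
#' @param seed integer seed; identical seed gives an identical grid.
#' @return An object of class `chromatin_map`: list with binary `grid`
#'   (1 = heterochromatin; row 1/col 1 pixel's upper-left corner at
#'   (`-radius`, `+radius`), rows increasing downwards), `pixel_size_um`,
#'   `origin_x_um`, `origin_y_um` and the generating parameters.
#' @export
simulate_chromatin_map <- function(geometry, het_fraction, blob_scale_um = 0.8,
                                   pixel_size_um = 0.05, seed = 1) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (het_fraction <= 0 || het_fraction >= 1)
    stop("het_fraction must lie strictly in (0, 1)")
  R <- geometry$radius_um
  if (pixel_size_um >= 2 * R) stop("pixel_size_um exceeds the nucleus diameter")
  set.seed(as.integer(seed))
  n <- ceiling(2 * R / pixel_size_um)
  field <- matrix(rnorm(n * n), n, n)
  field <- .gauss_smooth(field, blob_scale_um / pixel_size_um)
  # pixel centres
  cx <- -R + (seq_len(n) - 0.5) * pixel_size_um   # columns: x
  cy <- R - (seq_len(n) - 0.5) * pixel_size_um    # rows: y
  inside <- outer(cy^2, cx^2, `+`) <= R^2
  thr <- quantile(field[inside], probs = 1 - het_fraction, names = FALSE)
  grid <- matrix(0L, n, n)
  grid[inside & field >= thr] <- 1L
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 origin_x_um = -R, origin_y_um = R,
                 het_fraction = het_fraction, blob_scale_um = blob_scale_um,
                 radius_um = R, seed = as.integer(seed)),
            class = "chromatin_map")
}

#' Render a synthetic intensity image from a chromatin map
#'
#' Convenience renderer for testing the image-derived masking path:
#' heterochromatin pixels are brighter by `contrast`, with additive
#' Gaussian noise.
#'
#' @param map a [simulate_chromatin_map()] output.
#' @param contrast intensity added to heterochromatin pixels.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed integer seed.
#' @return Numeric matrix of pixel intensities with the map's geometry.
#' @export
render_chromatin_image <- function(map, contrast = 5, noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(map, "chromatin_map"))
  set.seed(as.integer(seed))
  img <- 1 + contrast * map$grid +
    matrix(rnorm(length(map$grid), sd = noise_sd), nrow(map$grid))
  img
}
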