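#' Camera acquisition settings
#'
#' Describes one SMT acquisition. Two modes are supported:
#' `"fast"` (fast tracking, default 10 ms frames / 100 Hz) captures both
#' mobile and bound molecules and feeds the diffusion and jump-length
#' analyses; `"slow"` (slow dwell imaging, default 500 ms frames / 2 Hz)
#' blurs mobile molecules into the background so that only stably bound
#' molecules are recorded, feeding the residence-time analysis.
#'
#' @param mode `"fast"` or `"slow"`.
#' @param frame_interval_s seconds per frame; defaults 0.01 (fast) / 0.5
#'   (slow).
#' @param exposure_s exposure per frame; defaults to the frame interval.
#' @param n_frames number of frames in the acquisition.
#' @param localization_sigma_um localization error SD per coordinate (µm).
#' @param bleach_prob_per_frame per-frame photobleaching probability;
#'   defaults 0.01 (fast) / 0.005 (slow).
#' @param blur_threshold_um in slow mode, the maximum within-exposure
#'   motion-blur scale (`sqrt(2 * D_eff * exposure_s)`, the RMS spread of
#'   the emission path) for a molecule to be detected (µm).
#' @param density_per_um2 mean concurrently emitting molecules per µm²;
#'   the simulator activates molecules from the pool to hold this density
#'   as earlier molecules bleach.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(mode = c("fast", "slow"),
                               frame_interval_s = NULL,
                               exposure_s = NULL,
                               n_frames = 2000,
                               localization_sigma_um = 0.035,
                               bleach_prob_per_frame = NULL,
                               blur_threshold_um = 0.2,
                               density_per_um2 = 0.3) {
  mode <- match.arg(mode)
  if (is.null(frame_interval_s))
    frame_interval_s <- if (mode == "fast") 0.01 else 0.5
  if (is.null(exposure_s)) exposure_s <- frame_interval_s
  # fast tracking uses high excitation power, so bleaching is fast and
  # tracks are short (mean ~25 frames); dwell imaging uses low power
  if (is.null(bleach_prob_per_frame))
    bleach_prob_per_frame <- if (mode == "fast") 0.04 else 0.005
  if (!(frame_interval_s >= exposure_s && exposure_s > 0))
    stop("need frame_interval_s >= exposure_s > 0")
  if (bleach_prob_per_frame < 0 || bleach_prob_per_frame > 1)
    stop("bleach_prob_per_frame must lie in [0, 1]")
  if (n_frames < 1) stop("n_frames must be positive")
  structure(list(mode = mode, frame_interval_s = frame_interval_s,
                 exposure_s = exposure_s, n_frames = as.integer(n_frames),
                 localization_sigma_um = localization_sigma_um,
                 bleach_prob_per_frame = bleach_prob_per_frame,
                 blur_threshold_um = blur_threshold_um,
                 density_per_um2 = density_per_um2),
            class = "acquisition_config")
}

#' Nucleus geometry for the forward model
#'
#' The nucleus is modelled as a 2D disc with a reflecting boundary.
#' Cerebellar granule-cell nuclei are small and compact (default radius
#' 3 µm); Purkinje-cell nuclei are much larger (use 6 µm).
#'
#' @param radius_um nucleus radius in µm.
#' @return An object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(radius_um = 3.0) {
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("radius_um must be positive")
  structure(list(radius_um = radius_um, boundary = "reflecting"),
            class = "nucleus_geometry")
}
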