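#' Heterochromatin mask from an intensity snapshot
#'
#' Gaussian-smooths a single-channel intensity image (e.g. an HP1a or
#' whole-signal snapshot) and thresholds it into a binary mask
#' (1 = heterochromatin). The default threshold is Otsu's method; the
#' quantile method thresholds at quantile `q` of the smoothed image.
#' Connected components smaller than 3 pixels are removed. Method
#' parameters are recorded in the result.
#'
#' @param intensity_image numeric matrix (rows = y going down, columns =
#'   x, same convention as [simulate_chromatin_map()] grids).
#' @param pixel_size_um pixel size (µm).
#' @param smoothing_um Gaussian smoothing SD (µm), default 0.3.
#' @param method `"otsu"` or `"quantile"`.
#' @param q quantile for the quantile method (default 0.5).
#' @param origin_x_um,origin_y_um coordinates of the upper-left corner of
#'   pixel (1,1); default places the image centre at the origin.
#' @return An object of class `region_mask` (same geometry as a
#'   `chromatin_map`): `grid`, `pixel_size_um`, `origin_x_um`,
#'   `origin_y_um`, `method`.
#' @export
mask_from_image <- function(intensity_image, pixel_size_um,
                            smoothing_um = 0.3,
                            method = c("otsu", "quantile"), q = 0.5,
                            origin_x_um = NULL, origin_y_um = NULL) {
  method <- match.arg(method)
  img <- intensity_image
  if (!is.matrix(img)) stop("intensity_image must be a matrix")
  if (diff(range(img)) == 0) stop("constant image cannot be thresholded")
  if (smoothing_um > 0)
    img <- .gauss_smooth(img, smoothing_um / pixel_size_um)
  if (method == "otsu") {
    rg <- range(img)
    norm <- (img - rg[1]) / (rg[2] - rg[1])
    thr <- EBImage::otsu(EBImage::Image(norm))
    bin <- norm > thr
  } else {
    thr <- quantile(img, probs = q, names = FALSE)
    bin <- img >= thr
  }
  # drop connected components below 3 pixels
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  sizes <- table(lab[lab > 0])
  small <- as.integer(names(sizes)[sizes < 3])
  bin[lab %in% small] <- FALSE
  grid <- matrix(as.integer(bin), nrow(img), ncol(img))
  if (is.null(origin_x_um)) origin_x_um <- -ncol(img) * pixel_size_um / 2
  if (is.null(origin_y_um)) origin_y_um <- nrow(img) * pixel_size_um / 2
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 origin_x_um = origin_x_um, origin_y_um = origin_y_um,
                 method = list(type = method, q = q,
                               smoothing_um = smoothing_um)),
            class = c("region_mask", "chromatin_map"))
}

#' Use a simulated chromatin map directly as a region mask
#'
#' Bypasses the imaging path: the simulator's ground-truth map becomes
#' the analysis mask.
#'
#' @param map a [simulate_chromatin_map()] output.
#' @return A `region_mask`.
#' @export
mask_from_map <- function(map) {
  stopifnot(inherits(map, "chromatin_map"))
  structure(list(grid = map$grid, pixel_size_um = map$pixel_size_um,
                 origin_x_um = map$origin_x_um, origin_y_um = map$origin_y_um,
                 method = list(type = "ground_truth_map")),
            class = c("region_mask", "chromatin_map"))
}

.lookup_region <- function(x, y, mask, slack_um = 0.15) {
  px <- mask$pixel_size_um
  col <- floor((x - mask$origin_x_um) / px) + 1L
  row <- floor((mask$origin_y_um - y) / px) + 1L
  # localization noise can push positions marginally past the grid edge;
  # clamp within a small tolerance, NA beyond it
  slack <- ceiling(slack_um / px)
  near <- function(i, n) i >= 1 - slack & i <= n + slack
  ok <- near(row, nrow(mask$grid)) & near(col, ncol(mask$grid))
  row <- pmin(pmax(row, 1L), nrow(mask$grid))
  col <- pmin(pmax(col, 1L), ncol(mask$grid))
  out <- rep(NA_integer_, length(x))
  out[ok] <- mask$grid[cbind(row[ok], col[ok])]
  out
}

#' Assign tracks to chromatin regions
#'
#' Maps each localization to a mask pixel (half-open pixels, floor
#' convention) and labels each track by its majority region when the
#' majority fraction reaches `majority_threshold`; otherwise the track is
#' `ambiguous`. Tracks falling outside the mask extent are ambiguous with
#' a warning.
#'
#' @param tracks a `track_set`.
#' @param mask a `region_mask` or `chromatin_map`.
#' @param majority_threshold minimum majority fraction (default 0.8).
#' @return data.frame with `track_id`, `label`
#'   (`heterochromatin`/`euchromatin`/`ambiguous`), `majority_fraction`.
#' @export
assign_tracks <- function(tracks, mask, majority_threshold = 0.8) {
  reg <- .lookup_region(tracks$x_um, tracks$y_um, mask)
  if (anyNA(reg)) warning("localizations outside the mask extent; ",
                          "affected tracks labelled ambiguous")
  idx_all <- split(seq_len(nrow(tracks)), tracks$track_id)
  out <- lapply(names(idx_all), function(id) {
    r <- reg[idx_all[[id]]]
    if (anyNA(r))
      return(data.frame(track_id = as.integer(id), label = "ambiguous",
                        majority_fraction = NA_real_))
    f_het <- mean(r == 1L)
    maj <- max(f_het, 1 - f_het)
    lab <- if (maj < majority_threshold) "ambiguous"
      else if (f_het >= 0.5) "heterochromatin" else "euchromatin"
    data.frame(track_id = as.integer(id), label = lab,
               majority_fraction = maj)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# jump pool restricted to jumps with both endpoints inside one region
.collect_jumps_region <- function(tracks, mask, region, max_lag = 4,
                                  cap_per_track = Inf, dt = NULL) {
  if (is.null(dt)) {
    cfg <- attr(tracks, "config")
    if (!is.null(cfg)) dt <- cfg$frame_interval_s
  }
  want <- if (region == "heterochromatin") 1L else 0L
  reg <- .lookup_region(tracks$x_um, tracks$y_um, mask)
  jumps <- vector("list", max_lag)
  for (l in seq_len(max_lag)) jumps[[l]] <- list()
  for (idx in split(seq_len(nrow(tracks)), tracks$track_id)) {
    n <- length(idx)
    if (n < 2) next
    x <- tracks$x_um[idx]; y <- tracks$y_um[idx]; r <- reg[idx]
    for (l in seq_len(min(max_lag, n - 1))) {
      i0 <- 1:(n - l); i1 <- (l + 1):n
      keep <- !is.na(r[i0]) & !is.na(r[i1]) & r[i0] == want & r[i1] == want
      if (!any(keep)) next
      d <- sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2)[keep]
      if (length(d) > cap_per_track) d <- d[seq_len(cap_per_track)]
      jumps[[l]][[length(jumps[[l]]) + 1L]] <- d
    }
  }
  jumps <- lapply(jumps, function(v) if (length(v)) unlist(v) else numeric(0))
  structure(list(jumps = jumps, dt = dt, max_lag = max_lag,
                 n_total = sum(lengths(jumps))),
            class = "jump_data")
}

#' Region-stratified diffusion, kinetic and dwell analysis
#'
#' Splits the tracks of one cell into heterochromatin and euchromatin
#' subsets ([assign_tracks()]) and runs the analyses appropriate to the
#' acquisition mode on each subset: per-molecule `D'` distributions and
#' the two-state jump fit (jump pools keep only jumps with both endpoints
#' in-region) for fast recordings, and the dwell-time survival fit for
#' slow recordings. Regions contributing fewer than 50 jumps (or dwell
#' events) are flagged and their fit set to `NULL`.
#'
#' @param tracks a `track_set` from one cell.
#' @param mask a `region_mask`.
#' @param mode `"fast"` or `"slow"`.
#' @param sigma localization error SD (µm) for the two-state fit.
#' @param dt frame interval (s); from the linking config when available.
#' @param majority_threshold track-assignment threshold.
#' @return List with one element per region (`heterochromatin`,
#'   `euchromatin`), each holding `n_tracks` and (fast) `diffusion`,
#'   `two_state` or (slow) `dwell_fit`, `survival`; plus the
#'   `assignment` table.
#' @export
region_stratified_analysis <- function(tracks, mask, mode = c("fast", "slow"),
                                       sigma = 0.035, dt = NULL,
                                       majority_threshold = 0.8) {
  mode <- match.arg(mode)
  if (is.null(dt)) {
    cfg <- attr(tracks, "config")
    if (!is.null(cfg)) dt <- cfg$frame_interval_s
  }
  asg <- assign_tracks(tracks, mask, majority_threshold)
  out <- list(assignment = asg)
  for (region in c("heterochromatin", "euchromatin")) {
    ids <- asg$track_id[asg$label == region]
    sub <- tracks[tracks$track_id %in% ids, , drop = FALSE]
    attr(sub, "config") <- attr(tracks, "config")
    class(sub) <- class(tracks)
    res <- list(n_tracks = length(ids), flags = character(0))
    if (mode == "fast") {
      if (nrow(sub)) {
        dres <- estimate_D_tracks(sub, dt = dt)
        res$diffusion <- filter_results(dres, condition = region)
        jd <- .collect_jumps_region(tracks, mask, region, dt = dt)
        if (jd$n_total >= 50) {
          res$two_state <- fit_two_state(jd, sigma = sigma)
        } else {
          res$two_state <- NULL
          res$flags <- c(res$flags, "too_few_jumps")
        }
      }
    } else {
      dur <- track_durations(sub, dt = dt)
      if (length(dur) >= 50) {
        res$survival <- survival_curve(dur, dt = dt)
        res$dwell_fit <- fit_double_exponential(res$survival)
      } else {
        res$dwell_fit <- NULL
        res$flags <- c(res$flags, "too_few_events")
      }
    }
    out[[region]] <- res
  }
  out
}
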