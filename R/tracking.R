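#' Maximum translocation distance implied by D_max
#'
#' The linking gate used by MTT-style trackers: the largest frame-to-frame
#' displacement expected for a molecule diffusing at the maximum expected
#' diffusion coefficient, `sqrt(4 * D_max * dt)`, plus an allowance of
#' `3 * sigma` for localization noise at both endpoints.
#'
#' @param D_max maximum expected diffusion coefficient (µm²/s).
#' @param frame_interval_s frame interval (s).
#' @param sigma_um localization error SD (µm); 0 reproduces the bare gate.
#' @return Gate radius in µm.
#' @examples
#' compute_r_max(5, 0.01)        # fast-tracking gate
#' compute_r_max(0.05, 0.5)      # dwell-imaging gate
#' @export
compute_r_max <- function(D_max, frame_interval_s, sigma_um = 0) {
  if (D_max <= 0 || frame_interval_s <= 0 || sigma_um < 0)
    stop("D_max and frame_interval_s must be positive, sigma_um >= 0")
  sqrt(4 * D_max * frame_interval_s) + 3 * sigma_um
}

#' Linking configuration
#'
#' @param D_max maximum expected diffusion coefficient (µm²/s); the
#'   fast-tracking convention is 5, the dwell-imaging convention 0.05.
#' @param frame_interval_s frame interval (s).
#' @param localization_sigma_um localization error SD used in the noise
#'   allowance of the gate; set to 0 for the bare `sqrt(4 D dt)` gate.
#' @param gap_frames allowed missed frames within a track (default 0, no
#'   gap closing).
#' @return An object of class `linking_config` with the derived
#'   `r_max_um`.
#' @export
linking_config <- function(D_max = 5, frame_interval_s = 0.01,
                           localization_sigma_um = 0, gap_frames = 0L) {
  r_max <- compute_r_max(D_max, frame_interval_s, localization_sigma_um)
  structure(list(D_max = D_max, frame_interval_s = frame_interval_s,
                 localization_sigma_um = localization_sigma_um,
                 r_max_um = r_max, gap_frames = as.integer(gap_frames)),
            class = "linking_config")
}

# min-cost max-cardinality matching between track ends and localizations;
# returns for each column (localization) the matched row (track) or NA
.assign_frame <- function(cost, allowed) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  BIG <- 1e6
  m <- matrix(0, n, n)
  m[seq_len(nr), seq_len(nc)] <- ifelse(allowed, cost, BIG)
  match_row <- .hungarian_cpp(m) # column assigned to each row, 1-based
  out <- rep(NA_integer_, nc)
  for (i in seq_len(nr)) {
    j <- match_row[i]
    if (j <= nc && allowed[i, j]) out[j] <- i
  }
  out
}

#' Link localizations into trajectories
#'
#' Reconstructs 2D trajectories from per-frame localizations. For each
#' consecutive frame pair the assignment between open track ends and new
#' localizations minimizes the total squared displacement over all
#' pairings within the gate `r_max` (optimal bipartite assignment, which
#' first maximizes the number of links and then minimizes their summed
#' squared displacement). Localizations with no admissible track start
#' new tracks; a track ends once no localization falls inside its gate
#' for `gap_frames + 1` consecutive frames. The input row order within a
#' frame does not affect the result.
#'
#' @param localizations data.frame with columns `frame`, `x_um`, `y_um`
#'   (and optionally `t_s`, `molecule_id`, `cell_id`).
#' @param config a [linking_config()].
#' @return An object of class `track_set`: a data.frame with `track_id`,
#'   `frame`, `t_s`, `x_um`, `y_um` (plus `molecule_id`/`cell_id` when
#'   present in the input), ordered by track and frame, with the config
#'   stored in the `"config"` attribute.
#' @export
link_tracks <- function(localizations, config) {
  stopifnot(inherits(config, "linking_config"))
  req <- c("frame", "x_um", "y_um")
  miss <- setdiff(req, names(localizations))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  loc <- localizations
  if (nrow(loc) == 0) {
    out <- cbind(data.frame(track_id = integer(0)), loc)
    attr(out, "config") <- config
    class(out) <- c("track_set", "data.frame")
    return(out)
  }
  if (anyDuplicated(loc[c("frame", "x_um", "y_um")]))
    stop("duplicate (frame, x, y) localizations")
  # canonical order makes linking invariant to input row permutations
  loc <- loc[order(loc$frame, loc$x_um, loc$y_um), , drop = FALSE]
  if (is.null(loc$t_s)) loc$t_s <- loc$frame * config$frame_interval_s

  frames <- sort(unique(loc$frame))
  idx_by_frame <- split(seq_len(nrow(loc)), factor(loc$frame, levels = frames))
  x <- loc$x_um; y <- loc$y_um
  track_of <- integer(nrow(loc))
  n_tracks <- 0L
  # open track state
  t_id <- integer(0); t_x <- numeric(0); t_y <- numeric(0); t_f <- integer(0)
  gap <- config$gap_frames

  for (f in frames) {
    cur <- idx_by_frame[[as.character(f)]]
    keep <- t_f >= f - 1L - gap & t_f < f
    t_id <- t_id[keep]; t_x <- t_x[keep]; t_y <- t_y[keep]; t_f <- t_f[keep]
    assigned <- rep(NA_integer_, length(cur))
    if (length(t_id) > 0) {
      dx <- outer(t_x, x[cur], `-`)
      dy <- outer(t_y, y[cur], `-`)
      d2 <- dx * dx + dy * dy
      # gate scales with the number of elapsed frames for gap-closed links
      g <- as.numeric(f - t_f)
      gate <- sqrt(4 * config$D_max * g * config$frame_interval_s) +
        3 * config$localization_sigma_um
      allowed <- d2 <= (gate^2)
      if (any(allowed)) assigned <- .assign_frame(d2, allowed)
    }
    new_t_id <- integer(length(cur))
    for (j in seq_along(cur)) {
      i <- assigned[j]
      if (!is.na(i)) {
        new_t_id[j] <- t_id[i]
      } else {
        n_tracks <- n_tracks + 1L
        new_t_id[j] <- n_tracks
      }
      track_of[cur[j]] <- new_t_id[j]
    }
    # extended/new ends replace old ends
    still <- !(t_id %in% new_t_id)
    t_id <- c(t_id[still], new_t_id)
    t_x <- c(t_x[still], x[cur])
    t_y <- c(t_y[still], y[cur])
    t_f <- c(t_f[still], rep(f, length(cur)))
  }

  out <- cbind(data.frame(track_id = track_of), loc)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("track_set", "data.frame")
  out
}

#' Fraction of reconstructed links matching ground truth
#'
#' A link is a pair of consecutive localizations within a reconstructed
#' track; it is correct when both endpoints originate from the same
#' simulated molecule.
#'
#' @param tracks a [link_tracks()] result whose localizations carry the
#'   simulator's `molecule_id` column.
#' @return Fraction of correct links (NaN when there are no links).
#' @export
link_accuracy <- function(tracks) {
  if (is.null(tracks$molecule_id))
    stop("ground truth absent: tracks lack a molecule_id column")
  ok <- 0L; tot <- 0L
  for (idx in split(seq_len(nrow(tracks)), tracks$track_id)) {
    if (length(idx) < 2) next
    mid <- tracks$molecule_id[idx]
    ok <- ok + sum(mid[-1] == mid[-length(mid)])
    tot <- tot + length(idx) - 1L
  }
  ok / tot
}

#' Detect spots in a synthetic image stack
#'
#' Minimal local-maxima detector with intensity-weighted sub-pixel
#' centroids, intended for synthetic renderings only. A pixel is a
#' detection seed when it is the maximum of its 3x3 neighbourhood and
#' exceeds the robust background (median) by `threshold_sd` robust SDs
#' (MAD).
#'
#' @param image_stack a matrix (single frame) or list of matrices.
#' @param threshold_sd detection threshold in robust background SDs.
#' @return data.frame with `frame`, `x_px`, `y_px` (0-based pixel
#'   coordinates: `x_px` along columns, `y_px` along rows).
#' @export
detect_spots <- function(image_stack, threshold_sd = 5) {
  if (is.matrix(image_stack)) image_stack <- list(image_stack)
  out <- list()
  for (f in seq_along(image_stack)) {
    img <- image_stack[[f]]
    bg <- median(img); s <- mad(img)
    if (s == 0) {
      warning("frame ", f, " has zero background variation; no detections")
      next
    }
    thr <- bg + threshold_sd * s
    nr <- nrow(img); nc <- ncol(img)
    cand <- which(img > thr, arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      r0 <- max(1, r - 1); r1 <- min(nr, r + 1)
      c0 <- max(1, c - 1); c1 <- min(nc, c + 1)
      if (img[r, c] < max(img[r0:r1, c0:c1])) next
      # centroid over a 5x5 window, background-subtracted
      r0 <- max(1, r - 2); r1 <- min(nr, r + 2)
      c0 <- max(1, c - 2); c1 <- min(nc, c + 2)
      w <- pmax(img[r0:r1, c0:c1, drop = FALSE] - bg, 0)
      rr <- matrix(r0:r1, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1)
      cc <- matrix(c0:c1, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1, byrow = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        frame = f - 1L,
        x_px = sum(w * cc) / sum(w) - 1,
        y_px = sum(w * rr) / sum(w) - 1,
        peak = img[r, c])
    }
  }
  if (!length(out)) return(data.frame(frame = integer(0), x_px = numeric(0),
                                      y_px = numeric(0), peak = numeric(0)))
  det <- do.call(rbind, out)
  # suppress duplicate maxima of one spot (plateaus): keep the brightest
  # of any pair closer than 3 px within a frame
  keep <- rep(TRUE, nrow(det))
  ord <- order(-det$peak)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    close <- keep & det$frame == det$frame[i] &
      (det$x_px - det$x_px[i])^2 + (det$y_px - det$y_px[i])^2 < 9
    close[i] <- FALSE
    keep[close & det$peak <= det$peak[i]] <- FALSE
  }
  det <- det[keep, c("frame", "x_px", "y_px")]
  rownames(det) <- NULL
  det
}
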