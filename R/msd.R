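#' Time-averaged mean squared displacement of a track
#'
#' `MSD(n dt)` is the mean over all start frames `i` of
#' `|pos(i+n) - pos(i)|^2`, computed for lags `n = 1 .. len-1` over the
#' overlapping pairs of a gap-free track.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` (strictly
#'   increasing consecutive frames) and either `t_s` or a known frame
#'   interval via `dt`.
#' @param dt frame interval (s); taken from `t_s` if absent.
#' @return data.frame with `lag`, `t_lag_s`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(track, dt = NULL) {
  n <- nrow(track)
  if (n < 2) stop("track must have at least 2 localizations")
  fr <- track$frame
  if (any(diff(fr) != 1)) stop("gapped track rejected")
  if (is.null(dt)) {
    if (is.null(track$t_s)) stop("supply dt or a t_s column")
    dt <- (track$t_s[n] - track$t_s[1]) / (n - 1)
  }
  x <- track$x_um; y <- track$y_um
  lags <- seq_len(n - 1)
  msd <- vapply(lags, function(l) {
    dx <- x[(l + 1):n] - x[1:(n - l)]
    dy <- y[(l + 1):n] - y[1:(n - l)]
    mean(dx * dx + dy * dy)
  }, 0)
  data.frame(lag = lags, t_lag_s = lags * dt, msd_um2 = msd,
             n_pairs = n - lags)
}

#' Apparent diffusion coefficient of one track
#'
#' Ordinary least squares of `MSD(tau) = 4 D' tau + b` over the first
#' `fit_lags` lags (free intercept absorbing the localization-error
#' offset `4 sigma^2`). Tracks shorter than `min_frames` or longer than
#' `max_frames` are excluded with a reason code rather than an error.
#' Non-positive slopes yield the floor `D' = 1e-4` µm²/s with a flag so
#' log-scale distributions stay defined.
#'
#' @param track gap-free track data.frame (see [compute_msd()]).
#' @param fit_lags number of MSD lags fitted (default 4).
#' @param dt frame interval (s).
#' @param min_frames,max_frames inclusive track-length bounds (defaults 5
#'   and 150 frames).
#' @return One-row data.frame: `n_frames`, `D_prime`, `r_squared`,
#'   `slope`, `intercept`, `flag` (`"ok"`, `"nonpositive_slope"`,
#'   `"too_short"`, `"too_long"`).
#' @export
estimate_D <- function(track, fit_lags = 4, dt = NULL,
                       min_frames = 5, max_frames = 150) {
  n <- nrow(track)
  res <- data.frame(n_frames = n, D_prime = NA_real_, r_squared = NA_real_,
                    slope = NA_real_, intercept = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (n < min_frames) { res$flag <- "too_short"; return(res) }
  if (n > max_frames) { res$flag <- "too_long"; return(res) }
  m <- compute_msd(track, dt = dt)
  k <- min(fit_lags, nrow(m))
  tt <- m$t_lag_s[seq_len(k)]; yy <- m$msd_um2[seq_len(k)]
  if (k == 1) {
    slope <- yy / tt; intercept <- 0; r2 <- 1
  } else {
    mx <- mean(tt); my <- mean(yy)
    sxx <- sum((tt - mx)^2)
    slope <- sum((tt - mx) * (yy - my)) / sxx
    intercept <- my - slope * mx
    ssr <- sum((yy - intercept - slope * tt)^2)
    sst <- sum((yy - my)^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
  }
  res$slope <- slope; res$intercept <- intercept; res$r_squared <- r2
  if (slope <= 0) {
    res$D_prime <- 1e-4
    res$flag <- "nonpositive_slope"
  } else {
    res$D_prime <- slope / 4
  }
  res
}

#' Per-track diffusion coefficients for a track set
#'
#' Applies [estimate_D()] to every track of a [link_tracks()] result.
#'
#' @param tracks a `track_set` (or any data.frame with `track_id`,
#'   `frame`, `x_um`, `y_um`).
#' @param dt frame interval (s); taken from the linking config when
#'   available.
#' @inheritParams estimate_D
#' @return data.frame with one row per track (`track_id` plus the
#'   [estimate_D()] columns).
#' @export
estimate_D_tracks <- function(tracks, fit_lags = 4, dt = NULL,
                              min_frames = 5, max_frames = 150) {
  if (is.null(dt)) {
    cfg <- attr(tracks, "config")
    if (!is.null(cfg)) dt <- cfg$frame_interval_s
  }
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  rows <- lapply(names(idx), function(id) {
    r <- estimate_D(tracks[idx[[id]], , drop = FALSE], fit_lags = fit_lags,
                    dt = dt, min_frames = min_frames, max_frames = max_frames)
    cbind(data.frame(track_id = as.integer(id)), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter per-track diffusion results into a distribution
#'
#' Applies the standard inclusion gates — track length within
#' `[min_frames, max_frames]` frames and MSD fit quality
#' `r_squared >= min_r2` (all bounds inclusive) — and returns the
#' retained per-molecule `D'` values with per-gate exclusion counts.
#' Tracks flagged for non-positive slope pass the gates but are excluded
#' from `log10_D` summaries (counted separately).
#'
#' @param results output of [estimate_D_tracks()].
#' @param min_r2 minimum MSD fit R² (default 0.8).
#' @param min_frames,max_frames inclusive track-length gates (5 and 150).
#' @param condition label stored with the distribution.
#' @return An object of class `diffusion_distribution`: list with the
#'   retained `data`, `log10_D` values, `condition` and `counts`.
#' @export
filter_results <- function(results, min_r2 = 0.8, min_frames = 5,
                           max_frames = 150, condition = "condition") {
  n_in <- nrow(results)
  short <- results$n_frames < min_frames
  long <- results$n_frames > max_frames
  lowr2 <- !short & !long &
    (is.na(results$r_squared) | results$r_squared < min_r2)
  keep <- !short & !long & !lowr2
  kept <- results[keep, , drop = FALSE]
  flagged <- kept$flag == "nonpositive_slope"
  structure(list(
    condition = condition,
    data = kept,
    log10_D = log10(kept$D_prime[!flagged]),
    counts = list(n_input = n_in, n_kept = nrow(kept),
                  n_too_short = sum(short), n_too_long = sum(long),
                  n_low_r2 = sum(lowr2), n_flagged_slope = sum(flagged))),
    class = "diffusion_distribution")
}

#' @export
print.diffusion_distribution <- function(x, ...) {
  cat(sprintf("<diffusion_distribution> %s: %d/%d tracks kept (median D' %.3g um^2/s)\n",
              x$condition, x$counts$n_kept, x$counts$n_input,
              median(10^x$log10_D)))
  invisible(x)
}
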