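# shared fixtures, all generated in code

catalog <- preset_catalog()

fast_acq <- function(n_frames = 1500, density = 0.3, ...) {
  acquisition_config("fast", n_frames = n_frames, density_per_um2 = density,
                     ...)
}

slow_acq <- function(n_frames = 3000, density = 0.10, ...) {
  acquisition_config("slow", n_frames = n_frames, density_per_um2 = density,
                     ...)
}

# straight synthetic track: positions are exact, frames consecutive
line_track <- function(n, d = 0.1, dt = 0.01) {
  data.frame(frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
             x_um = (0:(n - 1)) * d, y_um = 0)
}

# exhaustive minimum-cost maximum-cardinality matching oracle
brute_force_assignment <- function(cost, allowed) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- list(card = -1L, cost = Inf)
  recurse <- function(i, used, card, tot) {
    if (i > nr) {
      if (card > best$card || (card == best$card && tot < best$cost))
        best <<- list(card = card, cost = tot)
      return(invisible())
    }
    # upper bound pruning on cardinality
    recurse(i + 1L, used, card, tot)  # row i unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, tot + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nc), 0L, 0)
  best
}

# cost and cardinality of the package's per-frame-pair assignment
package_assignment <- function(cost, allowed) {
  sel <- nucspt:::.assign_frame(cost, allowed)
  idx <- which(!is.na(sel))
  list(card = length(idx),
       cost = if (length(idx)) sum(cost[cbind(sel[idx], idx)]) else 0)
}

# synthetic iid two-state jump data (lag 1) for estimator checks
synthetic_jumps <- function(n, F_bound, D_free, D_bound = 0.005,
                            sigma = 0.035, dt = 0.01) {
  bound <- runif(n) < F_bound
  v <- ifelse(bound, 4 * (D_bound * dt + sigma^2), 4 * (D_free * dt + sigma^2))
  r <- sqrt(-v * log(runif(n)))
  structure(list(jumps = list(r), dt = dt, max_lag = 1, n_total = n,
                 gate_um = NULL),
            class = "jump_data")
}

# durations drawn from a frame-quantized double-exponential event mixture
synthetic_durations <- function(n, f_long, tau_s, tau_l, dt = 0.5) {
  long <- runif(n) < f_long
  tau <- ifelse(long, tau_l, tau_s)
  (1 + rgeom(n, 1 - exp(-dt / tau))) * dt
}
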