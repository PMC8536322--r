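#' @importFrom rlang %||% abort .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd quantile rnorm runif rpois rbinom pnorm approx
#'   t.test wilcox.test uniroot
NULL

# Derive a reproducible per-trial seed from a root seed and a counter.
# Arithmetic kept in doubles (< 2^53) so the map is exact; result < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + as.double(i) * 95279 + 11) %%
               2147483629)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Minimum-jerk position fraction s(tau) on [0, 1]; clamped outside.
mj_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Peak speed of a minimum-jerk movement of amplitude `amp` (mm) and
# duration `dur` (ms), in mm/ms: 1.875 * amp / dur.
mj_peak_speed <- function(amp, dur) 1.875 * amp / dur

# Invert s(tau) = s_target on [0, 1] (s is strictly increasing there).
mj_s_inv <- function(s_target) {
  if (s_target <= 0) return(0)
  if (s_target >= 1) return(1)
  uniroot(function(tau) mj_s(tau) - s_target, c(0, 1), tol = 1e-10)$root
}

first_or_na <- function(x) if (length(x)) x[[1]] else NA_real_

#' Build a uniformly sampled trajectory tibble
#'
#' Trajectories are plain tibbles with columns `t` (ms, uniform spacing),
#' `x`, `y` (mm, origin at the center-target center, y up). They are stored
#' in the `trajectory` list-column of a trials tibble.
#'
#' @param t Numeric vector of sample times (ms), uniformly spaced.
#' @param x,y Numeric coordinate vectors (mm).
#' @return A tibble with columns `t`, `x`, `y`.
#' @export
trajectory <- function(t, x, y) {
  if (length(t) < 2) abort("a trajectory needs at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("trajectory coordinates must be finite")
  }
  dt <- diff(t)
  if (any(dt <= 0)) abort("trajectory times must be strictly increasing")
  tibble(t = as.double(t), x = as.double(x), y = as.double(y))
}

trajectory_period <- function(traj) {
  dt <- diff(traj$t)
  stats::median(dt)
}

#' Resample a trajectory to a uniform sample period
#'
#' Linear interpolation onto a uniform grid spanning the original time range.
#' Used when loaded timestamps are irregular.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y`).
#' @param sample_period Target sample period (ms).
#' @return A trajectory tibble on the uniform grid.
#' @export
resample_trajectory <- function(traj, sample_period = 1) {
  tt <- seq(traj$t[1], traj$t[nrow(traj)], by = sample_period)
  trajectory(
    t = tt,
    x = approx(traj$t, traj$x, xout = tt, rule = 2)$y,
    y = approx(traj$t, traj$y, xout = tt, rule = 2)$y
  )
}

is_uniform <- function(t, tol = 1e-6) {
  dt <- diff(t)
  max(dt) - min(dt) <= tol * stats::median(dt)
}
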