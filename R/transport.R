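#' Build a vascular release schedule
#'
#' The same total dose enters the tissue from the capillary over either
#' 1 minute ("fast" release, a bolus-like local injection) or 3 hours
#' ("slow" release, continuous intravenous extravasation). The total is
#' apportioned over simulation steps by the cumulative-floor rule
#' `cum_i = floor(total * i / n_steps)`, which is deterministic, sums exactly
#' to `total`, and keeps the cumulative count within one molecule of the
#' ideal constant rate at all times.
#'
#' @param total number of molecules to release (>= 1).
#' @param scheme `"fast"` (60 s) or `"slow"` (10,800 s).
#' @param dt simulation time step (s); must not exceed the release duration.
#' @param duration optional explicit release duration (s), overriding the
#'   scheme's default.
#' @return an object of class `release_schedule`: list with `total`,
#'   `scheme`, `duration`, `dt` and `per_step_counts` (one integer per step
#'   of the release window).
#' @export
build_release_schedule <- function(total, scheme = c("slow", "fast"), dt,
                                   duration = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(total) || total < 1) stop("total must be a positive count")
  total <- as.integer(round(total))
  if (is.null(duration)) duration <- if (scheme == "fast") 60 else 10800
  if (dt <= 0) stop("dt must be positive")
  if (dt > duration) stop("dt must not exceed the release duration")
  n <- ceiling(duration / dt)
  cum <- floor(total * seq_len(n) / n)
  structure(list(total = total, scheme = scheme, duration = duration, dt = dt,
                 per_step_counts = as.integer(diff(c(0L, cum)))),
            class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf("<release_schedule> %d molecules over %g s (%s), dt = %g s, %d steps\n",
              x$total, x$duration, x$scheme, x$dt, length(x$per_step_counts)))
  invisible(x)
}

#' Cumulative molecules released by a given time
#'
#' @param schedule a `release_schedule`.
#' @param t time in seconds.
#' @return integer count released at or before `t`.
#' @export
cumulative_released <- function(schedule, t) {
  i <- pmin(floor(t / schedule$dt), length(schedule$per_step_counts))
  vapply(i, function(k) {
    if (k < 1) 0L else as.integer(sum(schedule$per_step_counts[seq_len(k)]))
  }, integer(1))
}

#' Propose Brownian displacements
#'
#' Interstitial transport is Brownian motion with effective diffusion
#' coefficient `D`: each axis receives an independent Gaussian displacement
#' with standard deviation `sqrt(2 * D * dt)` (Euler-Maruyama). Proposals do
#' not yet account for domain boundaries or cell membranes. A fixed-step
#' variant (`mode = "fixed"`) moves every molecule by exactly
#' `sqrt(4 * D * dt)` in a uniform random direction; it converges to the same
#' diffusion limit and exists for sensitivity checks.
#'
#' @param positions n x 2 matrix of current positions (um).
#' @param D diffusion coefficient in um^2/s.
#' @param dt time step (s).
#' @param mode `"gaussian"` (default) or `"fixed"`.
#' @return n x 2 matrix of proposed positions.
#' @export
brownian_step <- function(positions, D, dt, mode = c("gaussian", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(D >= 0, dt > 0)
  positions <- rbind(positions)
  n <- nrow(positions)
  if (mode == "gaussian") {
    sd <- sqrt(2 * D * dt)
    positions + matrix(stats::rnorm(2 * n, sd = sd), ncol = 2)
  } else {
    len <- sqrt(4 * D * dt) # matches the 2D mean squared displacement 4*D*dt
    ang <- stats::runif(n, 0, 2 * pi)
    positions + len * cbind(cos(ang), sin(ang))
  }
}

#' Apply domain boundary conditions to proposed positions
#'
#' Crossing the right edge (`x > width`) clears the molecule from the tissue
#' (outflow); crossings of the left (vessel), top, or bottom edges reflect
#' specularly back into the domain, iterating until the position is inside.
#'
#' @param current n x 2 matrix of pre-move positions (inside the domain).
#' @param proposed n x 2 matrix of proposed positions.
#' @param domain a `tissue_domain` (only `width`/`height` are used).
#' @return list with `position` (n x 2 matrix; rows of cleared molecules are
#'   `NA`) and `cleared` (logical vector).
#' @export
apply_boundaries <- function(current, proposed, domain) {
  proposed <- rbind(proposed)
  out <- cpp_apply_boundaries(proposed, domain$width, domain$height)
  out$position[out$cleared, ] <- NA_real_
  out
}
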