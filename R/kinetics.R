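#' Fit one-phase association kinetics
#'
#' Fits the standard one-phase association model
#' `B(t) = B0 + (Bmax - B0) * (1 - exp(-k * t))`
#' to a receptor-saturation time series by bounded nonlinear least squares
#' (Levenberg-Marquardt, multistart). `B0` is the saturation at t = 0, `Bmax`
#' the plateau, and `k` the reaction rate constant (1/min when `t` is in
#' minutes). The coefficient of determination is
#' `r2 = 1 - SS_res / SS_tot`.
#'
#' A constant series is degenerate: the fit returns `B0 = Bmax` with `k`
#' flagged unidentifiable.
#'
#' @param t times (min), >= 0.
#' @param B saturation values (%), same length as `t`.
#' @param fix_b0 optional fixed value for `B0` (e.g. 0); `NULL` leaves it free.
#' @return an object of class `association_fit`: list with `B0`, `Bmax`, `k`,
#'   `r2`, `n`, `k_unidentifiable` and the fitted `predict` function.
#' @export
fit_one_phase_association <- function(t, B, fix_b0 = NULL) {
  stopifnot(length(t) == length(B), length(t) >= 4, all(t >= 0))
  if (max(B) - min(B) < sqrt(.Machine$double.eps)) {
    fit <- list(B0 = B[1], Bmax = B[1], k = NA_real_, r2 = NA_real_,
                n = length(t), k_unidentifiable = TRUE,
                predict = local({ b <- B[1]; function(t) rep(b, length(t)) }))
    class(fit) <- "association_fit"
    return(fit)
  }

  b0_start <- if (is.null(fix_b0)) B[which.min(t)] else fix_b0
  bmax_start <- B[which.max(t)]
  # log-linear transform for a rate-constant starting value
  k0 <- {
    span <- bmax_start - b0_start
    frac <- (B - b0_start) / ifelse(span == 0, 1, span)
    ok <- frac > 0.05 & frac < 0.95 & t > 0
    if (sum(ok) >= 2) {
      fit0 <- stats::lm(log(1 - frac[ok]) ~ t[ok] + 0)
      max(-unname(stats::coef(fit0)[1]), 1e-6)
    } else 0.02
  }
  starts <- unique(c(k0, 0.005, 0.02, 0.1, 0.5))

  best <- NULL
  for (k_init in starts) {
    fit <- if (is.null(fix_b0)) {
      .try_nls(B ~ B0 + (Bmax - B0) * (1 - exp(-k * t)),
               data = data.frame(t = t, B = B),
               start = list(B0 = b0_start, Bmax = bmax_start, k = k_init),
               lower = c(B0 = -Inf, Bmax = -Inf, k = 1e-8))
    } else {
      .try_nls(B ~ b0 + (Bmax - b0) * (1 - exp(-k * t)),
               data = data.frame(t = t, B = B, b0 = fix_b0),
               start = list(Bmax = bmax_start, k = k_init),
               lower = c(Bmax = -Inf, k = 1e-8))
    }
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-10 ||
        (abs(rss - best$rss) <= 1e-10 &&
         unname(stats::coef(fit)["k"]) < best$k)) {
      cf <- stats::coef(fit)
      best <- list(rss = rss, k = unname(cf["k"]),
                   B0 = if (is.null(fix_b0)) unname(cf["B0"]) else fix_b0,
                   Bmax = unname(cf["Bmax"]))
    }
  }
  if (is.null(best)) stop("one-phase association fit failed to converge")

  r2 <- 1 - best$rss / sum((B - mean(B))^2)
  out <- list(B0 = best$B0, Bmax = best$Bmax, k = best$k, r2 = r2,
              n = length(t), k_unidentifiable = FALSE,
              predict = local({
                p <- best
                function(t) p$B0 + (p$Bmax - p$B0) * (1 - exp(-p$k * t))
              }))
  class(out) <- "association_fit"
  out
}

#' @export
print.association_fit <- function(x, ...) {
  if (x$k_unidentifiable) {
    cat(sprintf("<association_fit> constant series B = %.3g (k unidentifiable)\n", x$B0))
  } else {
    cat(sprintf("<association_fit> B0 = %.3g, Bmax = %.3g, k = %.4g /min, r2 = %.4f (n = %d)\n",
                x$B0, x$Bmax, x$k, x$r2, x$n))
  }
  invisible(x)
}

#' Time to reach a given fractional occupancy
#'
#' For a one-phase association fit, the smallest time at which
#' `B(t) - B0 >= frac * (Bmax - B0)`, in closed form
#' `t = -log(1 - frac) / k`. `frac = 0.9` gives the t90 used to evaluate
#' binding curves before their plateaus.
#'
#' @param fit an `association_fit`.
#' @param frac fraction in (0, 1).
#' @return time in the units of the fitted series (min).
#' @export
time_to_occupancy <- function(fit, frac = 0.9) {
  stopifnot(inherits(fit, "association_fit"), frac > 0, frac < 1)
  if (fit$k_unidentifiable) stop("rate constant unidentifiable: constant series")
  if (fit$Bmax <= fit$B0) stop("Bmax must exceed B0")
  -log(1 - frac) / fit$k
}

#' Fit the linear-scale specific-binding (Hill) curve
#'
#' Fits `B = Bmax * [L]^h / (K_D^h + [L]^h)` to saturation-versus-dose data.
#' `K_D` is the dose of half-maximal saturation for any Hill slope `h`; with
#' `h = 1` the curve is the rectangular hyperbola
#' `B = Bmax * [L] / (K_D + [L])`.
#'
#' @param L doses (molecule counts), >= 4 distinct values.
#' @param B saturations (%).
#' @return an object of class `binding_fit` with `Bmax`, `K_D`, `h`, `B0`
#'   (0 for this form), `r2`, `n`, `unidentifiable` and `predict`.
#' @export
fit_specific_binding_linear <- function(L, B) {
  stopifnot(length(L) == length(B), length(unique(L)) >= 4, all(L > 0))
  if (max(B) - min(B) < sqrt(.Machine$double.eps))
    return(.degenerate_binding_fit(B[1], length(L), log_form = FALSE))

  bmax0 <- max(B) * 1.05
  kd0 <- {
    half <- max(B) / 2
    i <- which(B >= half)[1]
    if (!is.na(i) && i > 1) stats::approx(B[(i - 1):i], L[(i - 1):i], xout = half)$y
    else stats::median(L)
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(L)

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- .try_nls(B ~ Bmax * L^h / (K_D^h + L^h),
                    data = data.frame(L = L, B = B),
                    start = list(Bmax = bmax0, K_D = kd0, h = h0),
                    lower = c(Bmax = 1e-8, K_D = 1e-8, h = 1e-3))
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(rss = rss, Bmax = unname(cf["Bmax"]),
                   K_D = unname(cf["K_D"]), h = unname(cf["h"]))
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge")

  r2 <- 1 - best$rss / sum((B - mean(B))^2)
  out <- list(Bmax = best$Bmax, K_D = best$K_D, h = best$h, B0 = 0,
              r2 = r2, n = length(L), unidentifiable = FALSE,
              log_form = FALSE,
              predict = local({
                p <- best
                function(L) p$Bmax * L^p$h / (p$K_D^p$h + L^p$h)
              }))
  class(out) <- "binding_fit"
  out
}

#' Fit the logarithmic-scale specific-binding sigmoid
#'
#' Fits the log(dose) sigmoid
#' `B = B0 + (Bmax - B0) / (1 + 10^(LogK_D - log10([L])))`,
#' an increasing sigmoid in `log10([L])` whose midpoint `(B0 + Bmax)/2` is
#' reached at `[L] = 10^LogK_D` (unit Hill slope).
#'
#' @param L doses, > 0, >= 4 distinct values.
#' @param B saturations (%).
#' @return an object of class `binding_fit` with `Bmax`, `K_D`
#'   (= 10^LogK_D), `h` (fixed at 1), `B0`, `r2`, `n` and `predict`.
#' @export
fit_specific_binding_log <- function(L, B) {
  stopifnot(length(L) == length(B), length(unique(L)) >= 4, all(L > 0))
  if (max(B) - min(B) < sqrt(.Machine$double.eps))
    return(.degenerate_binding_fit(B[1], length(L), log_form = TRUE))

  x <- log10(L)
  b0_0 <- min(B); bmax0 <- max(B)
  mid <- (b0_0 + bmax0) / 2
  lk0 <- {
    i <- which(B >= mid)[1]
    if (!is.na(i) && i > 1) stats::approx(B[(i - 1):i], x[(i - 1):i], xout = mid)$y
    else stats::median(x)
  }
  if (!is.finite(lk0)) lk0 <- stats::median(x)

  best <- NULL
  for (shift in c(-0.5, 0, 0.5)) {
    fit <- .try_nls(B ~ B0 + (Bmax - B0) / (1 + 10^(LogKD - x)),
                    data = data.frame(x = x, B = B),
                    start = list(B0 = b0_0, Bmax = bmax0, LogKD = lk0 + shift),
                    lower = c(B0 = -Inf, Bmax = -Inf, LogKD = -Inf))
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(rss = rss, B0 = unname(cf["B0"]), Bmax = unname(cf["Bmax"]),
                   LogKD = unname(cf["LogKD"]))
    }
  }
  if (is.null(best)) stop("log-dose sigmoid fit failed to converge")

  r2 <- 1 - best$rss / sum((B - mean(B))^2)
  out <- list(Bmax = best$Bmax, K_D = 10^best$LogKD, h = 1, B0 = best$B0,
              r2 = r2, n = length(L), unidentifiable = FALSE,
              log_form = TRUE,
              predict = local({
                p <- best
                function(L) p$B0 + (p$Bmax - p$B0) / (1 + 10^(p$LogKD - log10(L)))
              }))
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  form <- if (x$log_form) "log-dose sigmoid" else "Hill"
  if (x$unidentifiable) {
    cat(sprintf("<binding_fit> constant series B = %.3g (%s, unidentifiable)\n",
                x$Bmax, form))
  } else {
    cat(sprintf("<binding_fit> %s: Bmax = %.3g, K_D = %.4g, h = %.3g, r2 = %.4f (n = %d)\n",
                form, x$Bmax, x$K_D, x$h, x$r2, x$n))
  }
  invisible(x)
}

.degenerate_binding_fit <- function(b, n, log_form) {
  out <- list(Bmax = b, K_D = NA_real_, h = NA_real_, B0 = b, r2 = NA_real_,
              n = n, unidentifiable = TRUE, log_form = log_form,
              predict = local({ bb <- b; function(L) rep(bb, length(L)) }))
  class(out) <- "binding_fit"
  out
}

.try_nls <- function(formula, data, start, lower) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))),
    error = function(e) NULL)
}

#' Build a binding curve at the 90%-occupancy time
#'
#' For a fixed release scheme, affinity and diffusion coefficient, takes the
#' replicate-mean association series of each dose from a sweep result table,
#' fits one-phase association per dose, finds the time at which the
#' largest-dose fit reaches `frac` of its span (t90 by default), and
#' evaluates every dose's fitted curve at that common time. The resulting
#' saturation-versus-dose points are the input of
#' [fit_specific_binding_linear()] / [fit_specific_binding_log()].
#'
#' @param sweep_results table from [sweep_simulations()].
#' @param scheme,K_A,D the grid slice to use.
#' @param L_values doses to include (all must be present in the sweep).
#' @param frac occupancy fraction defining the evaluation time.
#' @return data frame with `L`, `B` (saturation % at t90) and attribute
#'   `t_eval_min`.
#' @export
build_binding_curve <- function(sweep_results, scheme, K_A, D,
                                L_values = sort(unique(sweep_results$L_total)),
                                frac = 0.9) {
  fits <- lapply(L_values, function(l) {
    sl <- sweep_results[sweep_results$scheme == scheme &
                          sweep_results$K_A == K_A &
                          sweep_results$D == D &
                          sweep_results$L_total == l, ]
    if (nrow(sl) == 0)
      stop("sweep results are missing dose [L] = ", l,
           " for scheme ", scheme, ", K_A ", K_A, ", D ", D)
    fit_one_phase_association(sl$t_min, sl$mean_saturation)
  })
  t_eval <- time_to_occupancy(fits[[length(fits)]], frac)
  B <- vapply(fits, function(f) f$predict(t_eval), numeric(1))
  out <- data.frame(L = L_values, B = B)
  attr(out, "t_eval_min") <- t_eval
  out
}
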