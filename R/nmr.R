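# From second-order orientational ACFs to NMR observables: exponential tail
# extension, cosine-transform spectral density, and the reduced spin-lattice
# relaxation rate in the susceptibility representation.

#' Group-specific tail-extension defaults
#'
#' Default `P_cut` and `n_approx` for the four CH2 vector classes: terminal
#' (0.04, 100), side (0.05, 100), inner-Gly (0.05, 100) and inner
#' (0.08, 1000).
#'
#' @param group one of `"terminal"`, `"side"`, `"innerGly"`, `"inner"`.
#' @return list with `P_cut` and `n_approx`.
#' @export
tail_defaults <- function(group = c("terminal", "side", "innerGly", "inner")) {
  group <- match.arg(group)
  list(P_cut = c(terminal = 0.04, side = 0.05, innerGly = 0.05, inner = 0.08)[[group]],
       n_approx = c(terminal = 100L, side = 100L, innerGly = 100L, inner = 1000L)[[group]])
}

#' Exponential tail extension of an orientational ACF
#'
#' Splits the ACF into a tabulated head (`1 >= P2(t) >= P_cut`) and an
#' analytic exponential tail. The tail time `tau_tail` comes from a
#' least-squares fit of `ln P2` versus `t` over the `n_approx` lags preceding
#' the first crossing of `P_cut`; the extension
#' `P(t) = P_splice * exp(-(t - t_splice)/tau_tail)` is anchored at the last
#' tabulated point before the crossing, so the two-part function is
#' continuous, and is followed until it decays below `1e-5`.
#'
#' @param acf a `dendri_acf` of order `P2` (or any decaying ACF).
#' @param P_cut cut level in (0, 1); see [tail_defaults()].
#' @param n_approx number of fit points before the crossing.
#' @return object of class `acf_tail`: list with `head` (tibble `lag`,
#'   `value`), `tau_tail`, `P_cut`, `n_approx`, `splice_lag`, `splice_value`,
#'   `dt` and the fit diagnostics. Supports [tidy()]/[glance()].
#' @export
extend_acf_tail <- function(acf, P_cut = 0.04, n_approx = 100L) {
  v <- acf$value; lag <- acf$lag
  if (P_cut <= 0 || P_cut >= 1) abort("P_cut must be in (0, 1).")
  cross <- which(v < P_cut)
  cross <- cross[cross > 1L]
  if (!length(cross)) abort("ACF never reaches P_cut within its lag range.")
  i_cross <- cross[1L]
  i_splice <- i_cross - 1L
  win <- seq.int(max(1L, i_splice - n_approx + 1L), i_splice)
  pos <- v[win] > 0
  if (!all(pos)) {
    warn("non-positive ACF values inside the fit window; window shrunk.")
    last_bad <- max(which(!pos))
    win <- win[(last_bad + 1L):length(win)]
    if (length(win) < 3L) abort("too few positive points to fit the tail slope.")
  }
  tt <- lag[win]; yy <- log(v[win])
  slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  if (!is.finite(slope) || slope >= 0) {
    abort("non-decaying ACF in the fit window; cannot extend tail.")
  }
  tau_tail <- -1 / slope
  res <- yy - mean(yy) - slope * (tt - mean(tt))
  rsq <- if (sum((yy - mean(yy))^2) > 0) 1 - sum(res^2) / sum((yy - mean(yy))^2) else 1
  structure(
    list(head = tibble(lag = lag[seq_len(i_splice)], value = v[seq_len(i_splice)]),
         tau_tail = tau_tail,
         P_cut = P_cut,
         n_approx = n_approx,
         splice_lag = lag[i_splice],
         splice_value = v[i_splice],
         dt = if (length(lag) > 1L) lag[2L] - lag[1L] else NA_real_,
         fit_points = length(win),
         fit_rsq = rsq),
    class = "acf_tail"
  )
}

#' @export
print.acf_tail <- function(x, ...) {
  cat(sprintf("<acf_tail> tau_tail = %.4g, splice at t = %.4g (P = %.4g), %d fit points\n",
              x$tau_tail, x$splice_lag, x$splice_value, x$fit_points))
  invisible(x)
}

#' @rdname extend_acf_tail
#' @param x an `acf_tail` object.
#' @param ... unused.
#' @export
tidy.acf_tail <- function(x, ...) {
  tibble(term = c("tau_tail", "splice_lag", "splice_value", "P_cut"),
         estimate = c(x$tau_tail, x$splice_lag, x$splice_value, x$P_cut))
}

#' @rdname extend_acf_tail
#' @export
glance.acf_tail <- function(x, ...) {
  tibble(tau_tail = x$tau_tail, fit_points = x$fit_points, r.squared = x$fit_rsq)
}

#' Evaluate the tail-extended ACF on a time grid
#'
#' @param x an `acf_tail`.
#' @param t times in the ACF's lag unit.
#' @return ACF values (head interpolated, exponential beyond the splice).
#' @export
eval_acf_tail <- function(x, t) {
  out <- numeric(length(t))
  inside <- t <= x$splice_lag
  if (any(inside)) out[inside] <- approx(x$head$lag, x$head$value, xout = t[inside])$y
  if (any(!inside)) {
    out[!inside] <- x$splice_value * exp(-(t[!inside] - x$splice_lag) / x$tau_tail)
  }
  out
}

#' Default angular-frequency grid
#'
#' 400 log-spaced points over 1e5 to 1e12 rad/s.
#'
#' @param n number of points.
#' @param from,to grid limits in rad/s.
#' @return numeric vector (rad/s).
#' @export
omega_grid_default <- function(n = 400L, from = 1e5, to = 1e12) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Spectral density by cosine transform of a tail-extended ACF
#'
#' `J(omega) = 2 * int_0^inf P2(t) cos(omega t) dt`. The tabulated head is
#' integrated by the trapezoidal rule; the exponential tail is transformed
#' analytically (its Lorentzian piece is exact), so the decays far beyond the
#' record contribute without truncation error. A fully numeric mode
#' integrates the evaluated two-part function instead.
#'
#' @param ext an `acf_tail` from [extend_acf_tail()], with lags in `time_unit`.
#' @param omega angular frequencies in rad/s (default [omega_grid_default()]).
#' @param time_unit unit of the ACF lags: `"ns"` (default), `"ps"` or `"s"`.
#' @param mode `"analytic_tail"` (default) or `"numeric"`.
#' @return tibble of class `spectral_density` with columns `omega` (rad/s)
#'   and `J` (seconds).
#' @export
spectral_density <- function(ext, omega = omega_grid_default(),
                             time_unit = c("ns", "ps", "s"),
                             mode = c("analytic_tail", "numeric")) {
  if (!length(omega)) abort("empty omega grid.")
  time_unit <- match.arg(time_unit)
  mode <- match.arg(mode)
  scale <- c(ns = 1e-9, ps = 1e-12, s = 1)[[time_unit]]
  t_head <- ext$head$lag * scale
  v_head <- ext$head$value
  ts <- ext$splice_lag * scale
  A <- ext$splice_value
  tau <- ext$tau_tail * scale
  J <- vapply(omega, function(w) {
    head_int <- cos_transform_linear(t_head, v_head, w)
    tail_int <- if (mode == "analytic_tail") {
      A * (tau * cos(w * ts) - w * tau^2 * sin(w * ts)) / (1 + (w * tau)^2)
    } else {
      t_tail <- seq(ts, ts + tau * log(A / 1e-5), length.out = 2048L)
      trapz(t_tail, A * exp(-(t_tail - ts) / tau) * cos(w * t_tail))
    }
    2 * (head_int + tail_int)
  }, numeric(1))
  out <- tibble(omega = omega, J = J)
  class(out) <- c("spectral_density", class(out))
  out
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L))) / 2

# exact cosine transform of the piecewise-linear interpolant of (x, y):
# int f cos(wt) dt = [f sin(wt)/w] + (f'/w^2)(cos(wb) - cos(wa)) per segment.
# Accurate at all frequencies (error is that of linear interpolation only);
# falls back to the trapezoidal rule in the non-oscillatory limit.
cos_transform_linear <- function(x, y, w) {
  if (w * max(x) < 1e-2) return(trapz(x, y * cos(w * x)))
  xs <- sin(w * x); xc <- cos(w * x)
  slopes <- diff(y) / diff(x)
  boundary <- (tail(y, -1L) * tail(xs, -1L) - head(y, -1L) * head(xs, -1L)) / w
  curvature <- slopes * (tail(xc, -1L) - head(xc, -1L)) / w^2
  sum(boundary + curvature)
}

#' Reduced spin-lattice relaxation rate (susceptibility representation)
#'
#' `1/T1H(omega) = omega * (J(omega) + 4 J(2 omega))`, evaluated from a
#' tail-extended ACF; the maximum position `omega_max` is the grid argmax
#' refined by a local quadratic fit in log-frequency. If the grid does not
#' bracket the maximum, the boundary value is reported with a warning.
#'
#' @inheritParams spectral_density
#' @param ext an `acf_tail`, or a function `J(omega)` returning the spectral
#'   density in seconds.
#' @return tibble of class `t1_curve` with columns `omega`, `invT1_reduced`;
#'   attribute `omega_max` (rad/s).
#' @export
reduced_t1 <- function(ext, omega = omega_grid_default(),
                       time_unit = c("ns", "ps", "s"),
                       mode = c("analytic_tail", "numeric")) {
  time_unit <- match.arg(time_unit)
  mode <- match.arg(mode)
  Jfun <- if (is.function(ext)) {
    ext
  } else {
    function(w) spectral_density(ext, w, time_unit = time_unit, mode = mode)$J
  }
  invT1 <- omega * (Jfun(omega) + 4 * Jfun(2 * omega))
  i <- which.max(invT1)
  if (i == 1L || i == length(omega)) {
    warn("grid does not bracket the susceptibility maximum; omega_max reported at the boundary.")
    omega_max <- omega[i]
  } else {
    lw <- log(omega[(i - 1L):(i + 1L)])
    fit <- lm(invT1[(i - 1L):(i + 1L)] ~ poly(lw, 2, raw = TRUE))
    b <- coef(fit)
    omega_max <- exp(-b[[2L]] / (2 * b[[3L]]))
  }
  out <- tibble(omega = omega, invT1_reduced = invT1)
  attr(out, "omega_max") <- omega_max
  class(out) <- c("t1_curve", class(out))
  out
}

#' Closed-form rotational relaxation curve (single-exponential ACF)
#'
#' For `P2(t) = exp(-t/tau_rot)` the spectral density is the Lorentzian
#' `J(omega) = 2 tau / (1 + (omega tau)^2)` and the reduced rate follows in
#' closed form:
#' `1/T1H = 2 omega tau/(1 + (omega tau)^2) + 8 omega tau/(1 + (2 omega tau)^2)`.
#' Its maximum sits at `omega_max * tau = 0.6158`.
#'
#' @param omega angular frequencies in rad/s.
#' @param tau_rot rotational correlation time.
#' @param time_unit unit of `tau_rot` (default ns).
#' @return a `t1_curve` tibble with exact `omega_max = 0.61580.../tau`.
#' @export
rotational_t1_closed_form <- function(omega = omega_grid_default(), tau_rot,
                                      time_unit = c("ns", "ps", "s")) {
  if (tau_rot <= 0) abort("tau_rot must be positive.")
  time_unit <- match.arg(time_unit)
  tau <- tau_rot * c(ns = 1e-9, ps = 1e-12, s = 1)[[time_unit]]
  x <- omega * tau
  invT1 <- 2 * x / (1 + x^2) + 8 * x / (1 + 4 * x^2)
  out <- tibble(omega = omega, invT1_reduced = invT1)
  attr(out, "omega_max") <- .x_t1_max / tau
  class(out) <- c("t1_curve", class(out))
  out
}

# argmax of 2x/(1+x^2) + 8x/(1+4x^2), precomputed to machine precision
.x_t1_max <- 0.61579508536436341

#' Physical 1/T1 temperature series at a fixed spectrometer frequency
#'
#' Converts reduced relaxation curves at several temperatures into physical
#' rates at the spectrometer frequency:
#' `1/T1 = (A0 / omega_H) * invT1_reduced(omega_H)`.
#'
#' @param curves_by_T named list of `t1_curve` objects; names are
#'   temperatures in kelvin.
#' @param omega_H spectrometer angular frequency in rad/s (default
#'   `2*pi*400e6`, a 400 MHz proton spectrometer).
#' @param A0 quantum-chemical prefactor in s^-2 (default 0.56e10, the
#'   theoretical CH2 value; 0.88e10 is the calibrated value used for pooled
#'   terminal+side groups).
#' @return tibble with columns `T`, `inv1000_T` (= 1000/T), `invT1_reduced`,
#'   `invT1_physical` (s^-1).
#' @export
temperature_series <- function(curves_by_T, omega_H = 2 * pi * 400e6,
                               A0 = 0.56e10) {
  if (is.null(names(curves_by_T)) || any(!nzchar(names(curves_by_T)))) {
    abort("`curves_by_T` must be named by temperature in kelvin.")
  }
  rows <- imap(curves_by_T, function(curve, Tname) {
    if (omega_H < min(curve$omega) || omega_H > max(curve$omega)) {
      abort("omega_H lies outside the curve's frequency grid.")
    }
    red <- approx(log(curve$omega), curve$invT1_reduced, xout = log(omega_H))$y
    Tk <- as.numeric(Tname)
    tibble(T = Tk, inv1000_T = 1000 / Tk, invT1_reduced = red,
           invT1_physical = A0 / omega_H * red)
  })
  dplyr::bind_rows(rows) |> arrange(.data$T)
}

#' Vector-count-weighted average of equivalent-class ACFs
#'
#' Pools ACFs of several vector classes (e.g. terminal and side CH2 groups)
#' into one, weighting each class by its number of averaged vectors.
#'
#' @param acfs list of `dendri_acf` objects on identical lag grids.
#' @return a pooled `dendri_acf`.
#' @export
pool_acfs <- function(acfs) {
  if (!length(acfs)) abort("no ACFs supplied.")
  lags <- acfs[[1L]]$lag
  for (a in acfs[-1L]) {
    if (!isTRUE(all.equal(a$lag, lags))) abort("ACFs are on different lag grids.")
  }
  w <- vapply(acfs, function(a) attr(a, "n_vectors") %||% 1L, numeric(1))
  vals <- Reduce(`+`, Map(function(a, wi) a$value * wi, acfs, w)) / sum(w)
  new_acf(lags, vals, attr(acfs[[1L]], "order"), n_vectors = sum(w))
}
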