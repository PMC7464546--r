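# Time-correlation machinery. All estimators average over every time origin
# with per-lag normalisation by (n - k), computed via FFT and validated
# against direct double loops in the test suite.

# lagged product sums S_k = sum_t x_t x_{t+k}, k = 0..max_lag, via FFT
lagged_product_sums <- function(x, max_lag) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2L * n))
  X <- fft(c(x, numeric(nfft - n)))
  s <- Re(fft(X * Conj(X), inverse = TRUE)) / nfft
  s[seq_len(max_lag + 1L)]
}

new_acf <- function(lags, values, order, n_vectors = 1L) {
  out <- tibble(lag = lags, value = values)
  attr(out, "order") <- order
  attr(out, "n_vectors") <- n_vectors
  class(out) <- c("dendri_acf", class(out))
  out
}

#' @export
print.dendri_acf <- function(x, ...) {
  cat(sprintf("<dendri_acf: %s> %d lags (0..%g), %d vector(s)\n",
              attr(x, "order"), nrow(x), max(x$lag), attr(x, "n_vectors")))
  NextMethod()
}

#' Normalised autocorrelation function of a scalar series
#'
#' `C(t) = (<x(s) x(s+t)> - <x>^2) / (<x^2> - <x>^2)`, averaged over all time
#' origins with per-lag normalisation by `n - k`; lags run to half the record
#' by default. `C(0) = 1` exactly.
#'
#' @param x numeric series (e.g. Rg^2 per frame), length >= 10.
#' @param dt time step between samples (the lag unit; use ns for relaxation
#'   work).
#' @param max_lag maximum lag index (default `floor(n/2)`).
#' @return a `dendri_acf` tibble (`lag`, `value`) with `order = "scalar"`.
#' @export
acf_scalar <- function(x, dt = 1, max_lag = NULL) {
  n <- length(x)
  if (n < 10L) abort("need at least 10 samples.")
  if (stats::var(x) == 0) abort("constant series: zero variance.")
  max_lag <- max_lag %||% (n %/% 2L)
  max_lag <- min(max_lag, n - 1L)
  s <- lagged_product_sums(x, max_lag)
  k <- 0:max_lag
  m_k <- s / (n - k)
  mu <- mean(x)
  v <- mean(x^2) - mu^2
  new_acf(k * dt, (m_k - mu^2) / v, "scalar")
}

# coerce vector input to a list of n x 3 matrices (one per equivalent vector)
as_vector_list <- function(vecs) {
  if (is.list(vecs)) return(lapply(vecs, as.matrix))
  if (is.matrix(vecs)) return(list(vecs))
  if (is.array(vecs) && length(dim(vecs)) == 3L) {
    return(lapply(seq_len(dim(vecs)[2L]), function(v) vecs[, v, ]))
  }
  abort("`vecs` must be an n x 3 matrix, an [n, n_vectors, 3] array, or a list of matrices.")
}

#' Orientational autocorrelation function (first or second Legendre order)
#'
#' For unit vectors `u(t)`:
#' order 1: `P1(t) = <u(s) . u(s+t)>`;
#' order 2: `P2(t) = <(3/2) (u(s) . u(s+t))^2 - 1/2>`.
#' Averaging runs over all time origins (per-lag normalisation by `n - k`)
#' and over all equivalent vectors supplied (e.g. all core-to-end paths, or
#' all HH vectors of a CH2 class).
#'
#' @param vecs an n x 3 matrix of one vector's time series, an
#'   `[n, n_vectors, 3]` array, or a list of n x 3 matrices. Vectors are
#'   normalised internally; a zero-length vector is an error.
#' @param order 1 or 2.
#' @param dt time step between frames (lag unit).
#' @param max_lag maximum lag index (default half the record).
#' @return a `dendri_acf` with `order = "P1"` or `"P2"`.
#' @export
acf_orientational <- function(vecs, order = 2, dt = 1, max_lag = NULL) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  vl <- as_vector_list(vecs)
  n <- nrow(vl[[1L]])
  max_lag <- max_lag %||% (n %/% 2L)
  max_lag <- min(max_lag, n - 1L)
  k <- 0:max_lag
  acc <- numeric(max_lag + 1L)
  for (u in vl) {
    nrm <- sqrt(rowSums(u^2))
    if (any(nrm == 0)) abort("zero-length vector encountered.")
    u <- u / nrm
    if (order == 1) {
      s <- lagged_product_sums(u[, 1L], max_lag) +
        lagged_product_sums(u[, 2L], max_lag) +
        lagged_product_sums(u[, 3L], max_lag)
      acc <- acc + s / (n - k)
    } else {
      # (u(t).u(t+k))^2 expands over the 6 unique component products
      s <- lagged_product_sums(u[, 1L]^2, max_lag) +
        lagged_product_sums(u[, 2L]^2, max_lag) +
        lagged_product_sums(u[, 3L]^2, max_lag) +
        2 * lagged_product_sums(u[, 1L] * u[, 2L], max_lag) +
        2 * lagged_product_sums(u[, 1L] * u[, 3L], max_lag) +
        2 * lagged_product_sums(u[, 2L] * u[, 3L], max_lag)
      acc <- acc + 1.5 * s / (n - k) - 0.5
    }
  }
  new_acf(k * dt, acc / length(vl), if (order == 1) "P1" else "P2",
          n_vectors = length(vl))
}

#' 1/e relaxation time of an ACF
#'
#' Time of the first downward crossing of `1/e`, linearly interpolated
#' between the bracketing lags. ACFs can be non-monotonic at long noisy lags,
#' so only the first crossing is used.
#'
#' @param acf a `dendri_acf`.
#' @return relaxation time in the ACF's lag unit.
#' @export
relaxation_time_1e <- function(acf) {
  v <- acf$value; lag <- acf$lag
  thr <- exp(-1)
  below <- which(v < thr)
  below <- below[below > 1L]
  if (!length(below)) {
    abort("ACF never decays below 1/e in the available lag range; a longer trajectory is needed.")
  }
  i <- below[1L]
  frac <- (v[i - 1L] - thr) / (v[i - 1L] - v[i])
  lag[i - 1L] + frac * (lag[i] - lag[i - 1L])
}

#' Whole-molecule rotation time from the first-order time
#'
#' For a rigid rotator `P2(t) = P1(t)^3`, so the second-order (rotational)
#' time is one third of the first-order 1/e time: `tau_rot = tau_P1 / 3`.
#'
#' @param tau_P1 first-order 1/e relaxation time (> 0).
#' @return `tau_P1 / 3` in the same unit.
#' @export
tau_rot_from_p1 <- function(tau_P1) {
  if (any(tau_P1 <= 0)) abort("tau_P1 must be positive.")
  tau_P1 / 3
}
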