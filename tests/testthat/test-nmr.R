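exp_acf <- function(tau, t_max = 5, dt = 0.002) {
  lags <- seq(0, t_max, by = dt)
  dendritraj:::new_acf(lags, exp(-lags / tau), "P2")
}

test_that("the tail fit recovers pure and dominant exponential times", {
  ext <- extend_acf_tail(exp_acf(1.0), P_cut = 0.04, n_approx = 100)
  expect_equal(ext$tau_tail, 1.0, tolerance = 1e-3)
  # the extension coincides with the true function beyond the splice
  tt <- seq(ext$splice_lag, ext$splice_lag + 3, by = 0.01)
  expect_equal(eval_acf_tail(ext, tt), exp(-tt / 1.0), tolerance = 1e-3)
  # continuity at the splice
  eps <- 1e-9
  expect_equal(eval_acf_tail(ext, ext$splice_lag - eps),
               eval_acf_tail(ext, ext$splice_lag + eps), tolerance = 1e-6)
  # biexponential: at P = 0.04 the slow mode dominates
  lags <- seq(0, 60, by = 0.005)
  bi <- dendritraj:::new_acf(lags, 0.5 * exp(-lags / 1) + 0.5 * exp(-lags / 10), "P2")
  extb <- extend_acf_tail(bi, P_cut = 0.04, n_approx = 100)
  expect_equal(extb$tau_tail, 10, tolerance = 0.02)
  expect_error(extend_acf_tail(exp_acf(1, t_max = 0.5), 0.04, 100), "reaches")
})

test_that("a noisy rotor ACF extends monotonically beyond the splice", {
  rt <- rigid_rotor_trajectory(0.5, n_frames = 15000, dt = 0.01,
                               n_vectors = 32, seed = 71)
  p2 <- acf_orientational(rotor_vectors(rt), 2, dt = 0.01, max_lag = 2000)
  ext <- extend_acf_tail(p2, P_cut = 0.04, n_approx = 100)
  expect_equal(ext$tau_tail, 1 / (6 * 0.5), tolerance = 0.1)
  tt <- seq(ext$splice_lag, ext$splice_lag + 5 * ext$tau_tail, by = 0.01)
  expect_true(all(diff(eval_acf_tail(ext, tt)) < 0))
})

test_that("the cosine transform of an exponential is its Lorentzian", {
  tau_s <- 1e-9                                  # tau = 1 ns
  ext <- extend_acf_tail(exp_acf(1.0), 0.04, 100)
  om <- exp(seq(log(1e-2), log(1e2), length.out = 160)) / tau_s
  J <- spectral_density(ext, om)$J
  expect_lt(max(abs(J - 2 * tau_s / (1 + (om * tau_s)^2)) /
                  (2 * tau_s / (1 + (om * tau_s)^2))), 0.005)
  # fully numeric route agrees with the analytic-tail route
  Jn <- spectral_density(ext, om, mode = "numeric")$J
  expect_equal(Jn, J, tolerance = 0.01)
  # fast-decay limit: J flat at 2 tau for omega tau << 1
  ext_fast <- extend_acf_tail(exp_acf(0.01, t_max = 0.5, dt = 5e-5), 0.04, 100)
  Jf <- spectral_density(ext_fast, c(1e5, 1e6, 1e7))$J
  expect_equal(Jf, rep(2 * 0.01e-9, 3), tolerance = 1e-3)
  expect_error(spectral_density(ext, numeric()), "empty")
})

test_that("the analytic tail transform is exact on the tail segment", {
  # a tail-only object: splice at 0 so the transform is the pure Lorentzian
  ext <- extend_acf_tail(exp_acf(1.0), 0.04, 100)
  ext$head <- ext$head[1, ]                       # degenerate head
  ext$splice_lag <- 0
  ext$splice_value <- 1
  om <- c(1e7, 1e8, 1e9, 1e10)
  J <- spectral_density(ext, om)$J
  expect_equal(J, 2 * ext$tau_tail * 1e-9 / (1 + (om * ext$tau_tail * 1e-9)^2),
               tolerance = 1e-12)
})

test_that("biexponential spectra are sums of Lorentzians", {
  lags <- seq(0, 60, by = 0.002)
  bi <- dendritraj:::new_acf(lags, 0.6 * exp(-lags / 0.5) + 0.4 * exp(-lags / 8), "P2")
  ext <- extend_acf_tail(bi, 0.04, 100)
  om <- exp(seq(log(1e6), log(1e11), length.out = 80))
  J <- spectral_density(ext, om)$J
  lor <- function(w, tau) 2 * tau / (1 + (w * tau)^2)
  Jan <- 0.6 * lor(om, 0.5e-9) + 0.4 * lor(om, 8e-9)
  expect_lt(max(abs(J - Jan) / Jan), 0.01)
})

test_that("the susceptibility curve matches the closed form and its maximum", {
  tau <- 1.0
  ext <- extend_acf_tail(exp_acf(tau), 0.04, 100)
  om <- omega_grid_default(300, 1e6, 1e12)
  t1 <- reduced_t1(ext, om)
  t1c <- rotational_t1_closed_form(om, tau)
  expect_lt(max(abs(t1$invT1_reduced - t1c$invT1_reduced) /
                  pmax(t1c$invT1_reduced, 1e-12)), 0.005)
  # omega -> 0 limit: the curve vanishes linearly in omega
  expect_lt(t1$invT1_reduced[1] / max(t1$invT1_reduced), 0.01)
  expect_equal(t1$invT1_reduced[1], 10 * om[1] * tau * 1e-9, tolerance = 0.01)
  expect_equal(attr(t1, "omega_max") * tau * 1e-9, 0.62, tolerance = 0.01)
  expect_equal(attr(t1c, "omega_max") * tau * 1e-9, 0.6158, tolerance = 1e-3)
  # brute-force maximisation of the closed form agrees
  brute <- optimize(function(x) 2 * x / (1 + x^2) + 8 * x / (1 + 4 * x^2),
                    c(0.1, 2), maximum = TRUE)$maximum
  expect_equal(attr(t1c, "omega_max") * tau * 1e-9, brute, tolerance = 1e-4)
})

test_that("relaxation curves obey dimensional scaling", {
  om <- omega_grid_default(100, 1e6, 1e11)
  c1 <- rotational_t1_closed_form(om, 2.0)
  c2 <- rotational_t1_closed_form(om / 4, 8.0)
  expect_equal(c1$invT1_reduced, c2$invT1_reduced, tolerance = 1e-12)
  expect_error(rotational_t1_closed_form(om, -1), "positive")
})

test_that("larger rotational times move the maximum to lower frequency", {
  om <- omega_grid_default(300, 1e6, 1e11)
  # whole-molecule times at body temperature for the two dendrimers (ns)
  tau_lys2lys <- tau_rot_from_p1(7.0)
  tau_lys2gly <- tau_rot_from_p1(2.1)
  w1 <- attr(rotational_t1_closed_form(om, tau_lys2lys), "omega_max")
  w2 <- attr(rotational_t1_closed_form(om, tau_lys2gly), "omega_max")
  expect_lt(w1, w2)
})

test_that("temperature series scale with A0 and follow Arrhenius motion", {
  om <- omega_grid_default(200, 1e7, 1e11)
  # Arrhenius times on the fast-motion side of the maximum (omega_H tau < 0.62)
  taus <- setNames(0.001 * exp(1200 / seq(280, 340, by = 20)),
                   seq(280, 340, by = 20))
  curves <- lapply(taus, function(tau) rotational_t1_closed_form(om, tau))
  ts1 <- temperature_series(curves, A0 = 0.56e10)
  ts2 <- temperature_series(curves, A0 = 1.12e10)
  expect_equal(ts2$invT1_physical, 2 * ts1$invT1_physical, tolerance = 1e-12)
  # fast-motion side (omega_H * tau < 0.62): rate rises with 1000/T
  omH <- 2 * pi * 400e6
  expect_true(all(taus * 1e-9 * omH < 0.62))
  expect_true(all(diff(ts1$invT1_physical[order(ts1$inv1000_T)]) > 0))
  # zero reduced rate maps to zero physical rate
  zero <- tibble::tibble(omega = om, invT1_reduced = rep(0, length(om)))
  class(zero) <- c("t1_curve", class(zero))
  expect_equal(temperature_series(list(`300` = zero))$invT1_physical, 0)
  expect_error(temperature_series(list(`300` = curves[[1]]),
                                  omega_H = 1e15), "outside")
  expect_error(temperature_series(setNames(curves, NULL)), "named")
})

test_that("the full rotor pipeline recovers the susceptibility maximum", {
  Dr <- 0.5
  tau2 <- 1 / (6 * Dr)
  rt <- rigid_rotor_trajectory(Dr, n_frames = 40000, dt = 0.005,
                               n_vectors = 48, seed = 72)
  p2 <- acf_orientational(rotor_vectors(rt), 2, dt = 0.005, max_lag = 4000)
  ext <- extend_acf_tail(p2, P_cut = 0.04, n_approx = 100)
  t1 <- reduced_t1(ext, omega_grid_default(300, 1e7, 1e11))
  expect_equal(attr(t1, "omega_max"), 0.6158 / (tau2 * 1e-9), tolerance = 0.05)
})

test_that("pooled ACFs are vector-count-weighted", {
  a1 <- dendritraj:::new_acf(0:10, exp(-(0:10) / 3), "P2", n_vectors = 3L)
  a2 <- dendritraj:::new_acf(0:10, exp(-(0:10) / 6), "P2", n_vectors = 1L)
  pooled <- pool_acfs(list(a1, a2))
  expect_equal(pooled$value, (3 * a1$value + a2$value) / 4)
  expect_equal(attr(pooled, "n_vectors"), 4)
  a3 <- dendritraj:::new_acf(seq(0, 5, 0.5), rep(1, 11), "P2")
  expect_error(pool_acfs(list(a1, a3)), "lag grids")
})
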