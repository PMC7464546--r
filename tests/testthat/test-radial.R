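make_topo <- function(groups, masses = 14, charges = 0) {
  n <- length(groups)
  system_topology(atom_table(seq_len(n), masses, charges, groups),
                  check_neutral = FALSE)
}

test_that("mass density is flat inside a uniform ball and conserves mass", {
  n <- 20000L
  R <- 2.0
  topo <- make_topo(rep("core", n), masses = 12)
  tr <- trajectory(0, list(sample_ball(n, R, seed = 31)), 10)
  prof <- mass_density_profile(tr, topo, dr = 0.1)
  expected <- 12 * n / (4 / 3 * pi * R^3)
  inside <- prof$r > 0.4 & prof$r < R - 0.2
  expect_lt(max(abs(prof$value[inside] - expected)) / expected, 0.15)
  expect_true(all(prof$value[prof$r > R + 0.1] == 0))
  # conservation: shell masses sum exactly to the selected mass
  expect_equal(sum(attr(prof, "shell_mass")), 12 * n)
})

test_that("a single centred atom lands in the innermost bin", {
  topo <- make_topo("core", masses = 12)
  tr <- trajectory(0, list(matrix(c(1, 1, 1), 1, 3)), 10)
  prof <- mass_density_profile(tr, topo, dr = 0.05)
  expect_equal(attr(prof, "shell_mass")[1], 12)
  expect_true(all(attr(prof, "shell_mass")[-1] == 0))
  expect_error(mass_density_profile(tr, topo, dr = 20), "half the cell")
})

test_that("terminal-nitrogen profiles count and locate the ends", {
  n <- 32L
  # a mass-dominant core pins the centre of mass at the origin
  topo <- make_topo(c("core", rep("terminal_N", n)), masses = c(1e6, rep(14, n)))
  shell <- rbind(c(0, 0, 0), sample_shell(n, 2.02, seed = 32))
  tr <- trajectory(0, list(shell), 10)
  prof <- terminal_nitrogen_profile(tr, topo, dr = 0.05)
  expect_equal(sum(prof$value), n)
  expect_equal(sum(prof$value > 0), 1L)
  expect_lt(abs(prof$r[which.max(prof$value)] - 2.02), 0.051)
  # Gaussian-smeared shell peaks within one bin of the shell radius
  set.seed(33)
  frames <- replicate(50, {
    sm <- shell
    sm[-1, ] <- sm[-1, ] + matrix(rnorm(3L * n, sd = 0.05), n, 3)
    sm
  }, simplify = FALSE)
  tr2 <- trajectory(seq_len(50), frames, 10)
  prof2 <- terminal_nitrogen_profile(tr2, topo, dr = 0.05)
  expect_lt(abs(prof2$r[which.max(prof2$value)] - 2.02), 0.1 + 1e-9)
  bad <- make_topo(rep("core", n))
  expect_error(terminal_nitrogen_profile(tr, bad, 0.05), "empty")
})

test_that("the ion-pair RDF is flat for ideal mixtures and peaks for contacts", {
  nN <- 30L; nC <- 30L; L <- 8
  topo <- make_topo(c(rep("terminal_N", nN), rep("counterion", nC)),
                    charges = c(rep(1, nN), rep(-1, nC)))
  set.seed(34)
  frames <- replicate(60, matrix(runif(3L * (nN + nC), 0, L), nN + nC, 3),
                      simplify = FALSE)
  tr <- trajectory(seq_len(60), frames, L)
  g <- ion_pair_rdf(tr, topo, dr = 0.2)
  far <- g$r > 1.0
  expect_lt(abs(mean(g$value[far]) - 1), 0.05)
  # constructed contacts at 0.32 nm dominate the first peak
  set.seed(35)
  frames2 <- replicate(20, {
    N <- matrix(runif(3L * nN, 1, L - 1), nN, 3)
    dirs <- matrix(rnorm(3L * nC), nC, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    rbind(N, N + 0.32 * dirs)
  }, simplify = FALSE)
  tr2 <- trajectory(seq_len(20), frames2, L)
  g2 <- ion_pair_rdf(tr2, topo, dr = 0.01)
  expect_equal(g2$r[which.max(g2$value)], 0.325, tolerance = 0.01)
  expect_error(ion_pair_rdf(tr, topo, cation_select = 1:5, counterion_select = 5:8),
               "overlap")
  expect_error(ion_pair_rdf(tr, topo, dr = 0.2, r_max = L), "minimum-image")
})

test_that("ion-pair counting is exclusive with deterministic tie-breaks", {
  topo <- make_topo(c("terminal_N", "terminal_N", "counterion"),
                    charges = c(1, 1, -1))
  # counterion equidistant from two cations exactly at the cutoff
  m <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 0))
  tr <- trajectory(0, list(m), 10)
  expect_equal(as.numeric(count_ion_pairs(tr, topo, r_pair = 1.0)), 1)
  expect_equal(attr(count_ion_pairs(tr, topo, r_pair = 1.0), "inclusive"), 2)
  # nothing within the cutoff
  expect_equal(as.numeric(count_ion_pairs(tr, topo, r_pair = 0.5)), 0)
  # k constructed contacts count exactly k
  nN <- 8L
  topo2 <- make_topo(c(rep("terminal_N", nN), rep("counterion", 5L)),
                     charges = c(rep(1, nN), rep(-1, 5L)))
  set.seed(36)
  frames <- replicate(4, {
    N <- matrix(runif(3L * nN, 2, 8), nN, 3)
    rbind(N, N[1:5, ] + 0.25 / sqrt(3))
  }, simplify = FALSE)
  tr2 <- trajectory(seq_len(4), frames, 10)
  expect_equal(as.numeric(count_ion_pairs(tr2, topo2, r_pair = 0.3)), 5)
})

test_that("first-peak cutoff finds the minimum after the contact peak", {
  edges <- seq(0, 1, by = 0.02)
  rc <- (head(edges, -1) + tail(edges, -1)) / 2
  g <- exp(-((rc - 0.3) / 0.05)^2) * 5 + 1 - exp(-((rc - 0.45) / 0.05)^2) * 0.8
  prof <- profile_from_bins(edges, g, "rdf")
  expect_equal(first_peak_cutoff(prof), 0.45, tolerance = 0.05)
  flat <- profile_from_bins(edges, rep(1, length(rc)), "rdf")
  expect_equal(first_peak_cutoff(flat), 0.4)
})

test_that("charge profiles respect electroneutrality and locate Q*", {
  nq <- 10L
  topo <- make_topo(c(rep("terminal_N", nq), rep("counterion", nq)),
                    charges = c(rep(1, nq), rep(-1, nq)))
  # counterions far outside all positive charges: plateau at Qbare
  m <- rbind(sample_shell(nq, 1.0, seed = 37), sample_shell(nq, 3.0, seed = 38))
  tr <- trajectory(0, list(m), 8)
  cp <- charge_profiles(tr, topo, dr = 0.1)
  expect_equal(cp$effective$Q_star, nq)
  expect_true(cp$effective$R_max > 1.0 && cp$effective$R_max < 3.0)
  expect_equal(sum(cp$q$value), 0, tolerance = 1e-12)
  expect_equal(cp$Q$value, cumsum(cp$q$value))
  expect_lt(abs(cp$Q$value[nrow(cp$Q)]), 1e-9)
  # full compensation at identical radii: q = 0 everywhere, Q* = 0
  m2 <- rbind(m[1:nq, ], m[1:nq, ] + 1e-6)
  cp2 <- charge_profiles(trajectory(0, list(m2), 8), topo, dr = 0.1)
  expect_true(all(abs(cp2$q$value) < 1e-12))
  expect_equal(cp2$effective$Q_star, 0)
  # non-neutral systems are rejected
  bad <- make_topo(c(rep("terminal_N", nq), rep("counterion", nq - 1L), "other"),
                   charges = c(rep(1, nq), rep(-1, nq - 1L), 0.5))
  expect_error(charge_profiles(tr, bad, dr = 0.1), "electroneutral")
})

test_that("profiles are invariant under rigid translation of the frames", {
  db <- dendrimer_beads("Lys-2Gly", seed = 39)
  tr <- db$frame
  shift <- c(0.8, -0.4, 0.3)
  tr2 <- tr
  tr2$coords <- list(sweep(tr$coords[[1]], 2, shift, "+"))
  p1 <- charge_profiles(tr, db$topology, dr = 0.1)
  p2 <- charge_profiles(tr2, db$topology, dr = 0.1)
  expect_equal(p1$q$value, p2$q$value, tolerance = 1e-12)
  d1 <- mass_density_profile(tr, db$topology, dr = 0.1)
  d2 <- mass_density_profile(tr2, db$topology, dr = 0.1)
  expect_equal(d1$value, d2$value, tolerance = 1e-12)
})

test_that("the Metropolis ensemble shows a double layer and monotone condensation", {
  mc <- counterion_mc(n_frames = 60, burn_in = 300, stride = 10, seed = 41)
  cp <- charge_profiles(mc$trajectory, mc$topology, dr = 0.5)
  # exactly one sign change among statistically meaningful bins
  v <- cp$q$value
  sig <- v[abs(v) > 0.05 * max(abs(v))]
  expect_equal(sum(diff(sign(sig)) != 0), 1L)
  expect_gt(sig[1], 0)
  expect_lt(sig[length(sig)], 0)
  # single interior maximum of the cumulative charge
  Qv <- cp$Q$value
  imax <- which.max(Qv)
  expect_true(imax > 1 && imax < length(Qv))
  # stronger coupling condenses more charge
  mc_weak <- suppressWarnings(counterion_mc(lambda_B = 0.3, n_frames = 40,
                                            burn_in = 250, stride = 10, seed = 42))
  mc_strong <- suppressWarnings(counterion_mc(lambda_B = 1.4, n_frames = 40,
                                              burn_in = 250, stride = 10, seed = 42))
  qs_weak <- charge_profiles(mc_weak$trajectory, mc_weak$topology, dr = 0.1)$effective$Q_star
  qs_strong <- charge_profiles(mc_strong$trajectory, mc_strong$topology, dr = 0.1)$effective$Q_star
  expect_gt(qs_weak, qs_strong)
})
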