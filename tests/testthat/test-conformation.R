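test_that("radius of gyration matches symmetry cases and the brute-force oracle", {
  expect_equal(radius_of_gyration(matrix(c(3, -1, 2), 1, 3), 5), 0)
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(radius_of_gyration(two, c(2, 2)), 0.5)
  set.seed(11)
  m <- matrix(rnorm(150), 50, 3)
  w <- runif(50, 0.5, 16)
  expect_equal(radius_of_gyration(m, w), oracle_rg(m, w), tolerance = 1e-12)
  expect_error(radius_of_gyration(m[0, , drop = FALSE], 1), "empty")
})

test_that("Rg is invariant under rigid motions and alpha under scaling", {
  set.seed(12)
  m <- matrix(rnorm(90), 30, 3)
  w <- runif(30, 1, 12)
  Rm <- random_rotation(3)
  m2 <- sweep(m %*% Rm, 2, c(5, -2, 1), "+")
  expect_equal(radius_of_gyration(m, w), radius_of_gyration(m2, w),
               tolerance = 1e-10)
  a1 <- gyration_tensor_asphericity(m)$alpha
  a2 <- gyration_tensor_asphericity(m * 3.7)$alpha
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("gyration tensor hits the sphere and line limits", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  gt <- gyration_tensor_asphericity(octa)
  expect_equal(gt$Ix, gt$Iy)
  expect_equal(gt$Iy, gt$Iz)
  expect_equal(gt$alpha, 0)
  line <- cbind(seq(-2, 2, length.out = 9), 0, 0)
  expect_equal(gyration_tensor_asphericity(line)$alpha, 1)
  shell <- sample_shell(1e4, 1.0, seed = 13)
  expect_lt(gyration_tensor_asphericity(shell)$alpha, 0.01)
  # eigenvalues descending and summing to the unweighted Rg^2
  set.seed(14)
  m <- matrix(rnorm(60), 20, 3)
  gt2 <- gyration_tensor_asphericity(m)
  expect_true(gt2$Ix >= gt2$Iy && gt2$Iy >= gt2$Iz && gt2$Iz >= 0)
  expect_equal(gt2$Ix + gt2$Iy + gt2$Iz, radius_of_gyration(m, 1)^2,
               tolerance = 1e-12)
})

test_that("Kirkwood radius matches pair, shell and brute-force results", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(kirkwood_hydrodynamic_radius(two), 2.0)
  shell <- sample_shell(2000, 1.5, seed = 15)
  expect_equal(kirkwood_hydrodynamic_radius(shell), 1.5, tolerance = 0.01)
  set.seed(16)
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(kirkwood_hydrodynamic_radius(m), oracle_rh(m), tolerance = 1e-12)
  expect_lt(kirkwood_hydrodynamic_radius(m), max(dist(m)))
  expect_error(kirkwood_hydrodynamic_radius(rbind(m, m[1, ])), "coincident")
})

test_that("shell Rh converges to the shell radius with N", {
  errs <- vapply(c(50, 500, 5000), function(n) {
    abs(kirkwood_hydrodynamic_radius(sample_shell(n, 2.0, seed = n)) - 2.0)
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("the sampled rigid ball reproduces the impenetrable-sphere limit", {
  R <- 1.8
  ball <- sample_ball(1e5, R, seed = 17)
  rg <- radius_of_gyration(ball, 1)
  # geometric (Stokes) radius over Rg for the homogeneous rigid sphere
  expect_equal(R / rg, 1.29, tolerance = 0.02)
  expect_equal(rigid_sphere_radius(rg), R, tolerance = 0.01)
})

test_that("end-group radius matches closed forms and the oracle", {
  shell <- sample_shell(16, 2.0, seed = 18)
  expect_equal(end_group_radius(shell, 1:16, c(0, 0, 0)), 2.0)
  mixed <- rbind(sample_shell(8, 1, seed = 19), sample_shell(8, 3, seed = 20))
  expect_equal(end_group_radius(mixed, 1:16, c(0, 0, 0)), sqrt(5),
               tolerance = 1e-12)
  set.seed(21)
  m <- matrix(rnorm(30), 10, 3)
  cen <- c(0.3, -0.2, 0.5)
  expect_equal(end_group_radius(m, 1:10, cen), oracle_re(m, 1:10, cen),
               tolerance = 1e-12)
  expect_error(end_group_radius(m, integer(), cen), "empty")
})

test_that("rigid-sphere radii reproduce the tabulated conversions", {
  expect_equal(round(rigid_sphere_radius(2.04), 2), 2.63)
  expect_equal(round(rigid_sphere_radius(1.27), 2), 1.64)
  expect_equal(rigid_sphere_radius(0), 0)
  expect_error(rigid_sphere_radius(-1), "non-negative")
})

test_that("fluctuation statistics reproduce the relative-size arithmetic", {
  s1 <- c(1.7, 2.3, 2.0, 2.0)           # min 1.7, max 2.3, mean 2.0
  f1 <- rg_fluctuation_stats(s1)
  expect_equal(f1$relative, 0.30)
  expect_equal(f1$magnitude, 0.6)
  s2 <- c(0.9, 1.8, 1.35)               # min 0.9, max 1.8, mean 1.35
  expect_equal(round(rg_fluctuation_stats(s2)$relative, 2), 0.67)
  expect_equal(rg_fluctuation_stats(rep(1.3, 5))$relative, 0)
  expect_error(rg_fluctuation_stats(1.0), "two samples")
})

test_that("spacer distributions integrate to one and resolve structure", {
  # rigid spacers all at 0.7 nm
  mk_frame <- function(d) {
    rbind(c(0, 0, 0), c(d, 0, 0), c(0, 2, 0), c(d, 2, 0))
  }
  tr <- trajectory(0:4, replicate(5, mk_frame(0.7), simplify = FALSE), 10)
  sp <- rbind(c(1, 2), c(3, 4))
  g <- spacer_length_distribution(tr, sp, bin_width = 0.05)
  expect_equal(sum(g$value) * attr(g, "dr"), 1, tolerance = 1e-12)
  expect_lt(abs(g$r[which.max(g$value)] - 0.7), 0.051)
  expect_equal(sum(g$value > 0), 1L)
  # Gaussian-chain spacers: |end-to-end| follows the Maxwell distribution
  set.seed(22)
  sigma <- 0.25
  frames <- replicate(400, {
    ends <- matrix(rnorm(6, sd = sigma), 2, 3)
    rbind(c(0, 0, 0), ends[1, ], c(5, 5, 5), ends[2, ] + c(5, 5, 5))
  }, simplify = FALSE)
  tr2 <- trajectory(seq_len(400), frames, 20)
  d <- unlist(lapply(frames, function(m) {
    c(sqrt(sum((m[2, ] - m[1, ])^2)), sqrt(sum((m[4, ] - m[3, ])^2)))
  }))
  maxwell_cdf <- function(q) pchisq((q / sigma)^2, df = 3)
  ks <- suppressWarnings(ks.test(d, maxwell_cdf))
  expect_gt(ks$p.value, 0.01)
  g2 <- spacer_length_distribution(tr2, sp, bin_width = 0.02)
  expect_equal(sum(g2$value) * attr(g2, "dr"), 1, tolerance = 1e-12)
  # two populations with distinct means give two local maxima
  frames3 <- replicate(200, rbind(c(0, 0, 0), c(0.4, 0, 0),
                                  c(3, 3, 3), c(3, 3, 4.4)), simplify = FALSE)
  tr3 <- trajectory(seq_len(200), frames3, 20)
  g3 <- spacer_length_distribution(tr3, sp, bin_width = 0.05)
  nz <- which(g3$value > 0)
  expect_equal(length(nz), 2L)                       # two separated modes
  expect_gt(diff(g3$r[nz]), 0.5)
  expect_error(spacer_length_distribution(tr3, rbind(c(1, 99)), 0.05), "undefined")
})

test_that("per-frame shape summaries agree with the single-frame primitives", {
  db <- dendrimer_beads("Lys-2Gly", seed = 23)
  sh <- shape_summary(db$frame, db$topology)
  atoms <- db$topology$atoms
  dend <- which(atoms$group != "counterion")
  m <- db$frame$coords[[1]]
  expect_equal(sh$Rg, radius_of_gyration(m, atoms$mass, dend))
  expect_equal(sh$Rh, kirkwood_hydrodynamic_radius(m, dend))
  expect_equal(sh$R_sphere, sqrt(5 / 3) * sh$Rg)
  expect_equal(sh$Rh_over_Rg, sh$Rh / sh$Rg)
  expect_true(sh$alpha >= 0 && sh$alpha <= 1)
})
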