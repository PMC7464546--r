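#' Radius of gyration
#'
#' Mass-weighted RMS distance of the selected atoms from their own centre of
#' mass: `Rg = sqrt( sum(m_i r_i^2) / M )`.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param masses atom masses (amu); a scalar gives the unweighted variant.
#' @param select optional integer row indices.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = 1, select = NULL) {
  if (!is.null(select)) {
    coords <- coords[select, , drop = FALSE]
    if (length(masses) > 1L) masses <- masses[select]
  }
  if (nrow(coords) == 0L) abort("empty selection.")
  if (length(masses) == 1L) masses <- rep(masses, nrow(coords))
  M <- sum(masses)
  if (M <= 0) abort("zero total mass.")
  com <- colSums(coords * masses) / M
  d2 <- rowSums(sweep(coords, 2L, com)^2)
  sqrt(sum(masses * d2) / M)
}

#' Gyration tensor eigenvalues and asphericity
#'
#' Unweighted gyration tensor `A_uv = (1/N) sum (u_i - u_c)(v_i - v_c)` with
#' eigenvalues `Ix >= Iy >= Iz` and the asphericity
#' `alpha = 1 - 3 (IxIy + IxIz + IyIz) / (Ix + Iy + Iz)^2`, which is 0 for a
#' sphere and 1 for a line. Collinear configurations are allowed (alpha = 1).
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param select optional integer row indices.
#' @return a one-row tibble with columns `Ix`, `Iy`, `Iz` (nm^2) and `alpha`.
#' @export
gyration_tensor_asphericity <- function(coords, select = NULL) {
  if (!is.null(select)) coords <- coords[select, , drop = FALSE]
  n <- nrow(coords)
  if (n == 0L) abort("empty selection.")
  cen <- colMeans(coords)
  d <- sweep(coords, 2L, cen)
  A <- crossprod(d) / n
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 0)
  s <- sum(ev)
  alpha <- if (s > 0) 1 - 3 * (ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]) / s^2 else 0
  tibble(Ix = ev[1], Iy = ev[2], Iz = ev[3], alpha = min(max(alpha, 0), 1))
}

#' Kirkwood hydrodynamic radius
#'
#' `Rh = 1 / < 1/r_ij >` with the average over all unordered atom pairs in
#' the selection. Approximates the Stokes radius of a near-spherical object.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param select optional integer row indices.
#' @return Rh in nm.
#' @export
kirkwood_hydrodynamic_radius <- function(coords, select = NULL) {
  if (!is.null(select)) coords <- coords[select, , drop = FALSE]
  n <- nrow(coords)
  if (n < 2L) abort("Kirkwood Rh needs at least two atoms.")
  d <- as.matrix(stats::dist(coords))
  lo <- d[lower.tri(d)]
  zero <- which(lo == 0)
  if (length(zero)) {
    pairs <- which(lower.tri(d), arr.ind = TRUE)[zero[1L], ]
    abort(sprintf("coincident atoms in Rh selection (rows %d and %d).",
                  pairs[2L], pairs[1L]))
  }
  1 / mean(1 / lo)
}

#' End-group radius
#'
#' RMS distance of terminal reference atoms from the dendrimer centre of
#' mass: `Re = sqrt( (1/Nt) sum r_i^2 )`.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param terminal_select integer row indices of the terminal reference atoms.
#' @param center length-3 centre (nm), usually the dendrimer centre of mass.
#' @return Re in nm.
#' @export
end_group_radius <- function(coords, terminal_select, center) {
  if (!length(terminal_select)) abort("empty terminal selection.")
  d2 <- rowSums(sweep(coords[terminal_select, , drop = FALSE], 2L, center)^2)
  sqrt(mean(d2))
}

#' Rigid-sphere boundary radius
#'
#' Radius of the homogeneous rigid sphere with the same radius of gyration:
#' `sqrt(5/3) * Rg`.
#'
#' @param Rg radius of gyration (nm), non-negative.
#' @return nm.
#' @export
rigid_sphere_radius <- function(Rg) {
  if (any(Rg < 0)) abort("Rg must be non-negative.")
  sqrt(5 / 3) * Rg
}

#' Size-fluctuation statistics of an Rg time series
#'
#' The fluctuation magnitude is the observed max - min of the series (the
#' convention used for dendrimer size fluctuations), and the relative
#' fluctuation is magnitude / mean. The standard deviation is reported
#' alongside.
#'
#' @param rg numeric Rg series (nm), length >= 2.
#' @return one-row tibble: `mean`, `min`, `max`, `magnitude`, `relative`, `sd`.
#' @export
rg_fluctuation_stats <- function(rg) {
  if (length(rg) < 2L) abort("need at least two samples.")
  m <- mean(rg)
  if (m == 0) abort("zero mean size; relative fluctuation undefined.")
  tibble(mean = m, min = min(rg), max = max(rg),
         magnitude = max(rg) - min(rg),
         relative = (max(rg) - min(rg)) / m,
         sd = sd(rg))
}

#' Per-frame shape summary of a trajectory
#'
#' Computes, for every frame, the mass-weighted radius of gyration, the
#' unweighted gyration-tensor eigenvalues and asphericity, the Kirkwood
#' hydrodynamic radius, the end-group radius (if terminal atoms are tagged)
#' and the derived rigid-sphere radius and Rh/Rg ratio.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology`; the dendrimer selection is every
#'   non-counterion atom.
#' @param rh_select optional row indices for the Rh double sum (default: all
#'   dendrimer atoms).
#' @return tibble with one row per frame: `time`, `Rg`, `Ix`, `Iy`, `Iz`,
#'   `alpha`, `Rh`, `Re`, `R_sphere`, `Rh_over_Rg`.
#' @export
shape_summary <- function(traj, topology, rh_select = NULL) {
  atoms <- topology$atoms
  dend <- which(atoms$group != "counterion")
  term <- which(atoms$group == "terminal_N")
  rh_select <- rh_select %||% dend
  rows <- purrr::map2(traj$coords, traj$time, function(m, t) {
    com <- center_of_mass(m, atoms$mass, dend)
    rg <- radius_of_gyration(m, atoms$mass, dend)
    gt <- gyration_tensor_asphericity(m, dend)
    rh <- kirkwood_hydrodynamic_radius(m, rh_select)
    re <- if (length(term)) end_group_radius(m, term, com) else NA_real_
    tibble(time = t, Rg = rg, Ix = gt$Ix, Iy = gt$Iy, Iz = gt$Iz,
           alpha = gt$alpha, Rh = rh, Re = re,
           R_sphere = rigid_sphere_radius(rg), Rh_over_Rg = rh / rg)
  })
  dplyr::bind_rows(rows)
}

#' Spacer end-to-end distance distribution
#'
#' Histogram of end-to-end distances of spacer segments, pooled over all
#' frames and all spacers (i.e. over subgenerations); normalised so that
#' `sum(g(d) * bin_width) = 1`.
#'
#' @param traj a `dendri_trajectory`.
#' @param spacers two-column matrix or data frame of atom *row indices*
#'   (start branching atom, end branching atom), one row per spacer.
#' @param bin_width histogram bin width in nm.
#' @param d_max upper histogram edge (default: max observed distance).
#' @return a `radial_profile` tibble (`r` = bin centre, `value` = density).
#' @export
spacer_length_distribution <- function(traj, spacers, bin_width, d_max = NULL) {
  if (bin_width <= 0) abort("bin_width must be positive.")
  spacers <- as.matrix(spacers)
  nat <- n_atoms(traj)
  if (any(spacers < 1L | spacers > nat)) abort("undefined spacer atom index.")
  d <- unlist(purrr::map(traj$coords, function(m) {
    sqrt(rowSums((m[spacers[, 1L], , drop = FALSE] -
                    m[spacers[, 2L], , drop = FALSE])^2))
  }))
  d_max <- d_max %||% (max(d) + bin_width)
  edges <- seq(0, d_max + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = edges, plot = FALSE)
  new_radial_profile(edges, h$density, kind = "count",
                     frames_averaged = nrow(traj))
}
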