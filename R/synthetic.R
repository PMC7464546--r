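# Deterministic generators producing inputs with the statistical structure
# the analysis assumes: rigid-rotor vector trajectories with prescribed
# rotational diffusion, Metropolis counterion ensembles around a charged
# sphere, bead dendrimer topologies with the study compositions, and
# hydrogen-bond geometry fixtures. Every generator takes a mandatory seed and
# is a pure function of its arguments (bit-identical repeat runs); the
# caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) abort("a seed is mandatory for every generator.")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Uniform samples in a ball / on a spherical shell
#'
#' @param n number of points.
#' @param R radius (nm).
#' @param seed RNG seed (mandatory).
#' @return n x 3 matrix.
#' @export
sample_ball <- function(n, R, seed) {
  with_seed(seed, {
    u <- matrix(rnorm(3L * n), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    u * (R * runif(n)^(1 / 3))
  })
}

#' @rdname sample_ball
#' @export
sample_shell <- function(n, R, seed) {
  with_seed(seed, {
    u <- matrix(rnorm(3L * n), ncol = 3L)
    R * u / sqrt(rowSums(u^2))
  })
}

#' Rigid-rotor vector trajectory (isotropic rotational diffusion)
#'
#' Evolves `n_vectors` independent unit vectors by small random rotations:
#' each step applies a rotation vector with i.i.d. Gaussian components of
#' variance `2 * Dr * dt` (axis uniform on the sphere, squared angle with
#' mean `6 Dr dt`) via Rodrigues' formula, then renormalises. In the
#' small-step limit this is exact isotropic rotational diffusion with
#' coefficient `Dr`, so the ensemble orientational ACFs decay as
#' `P1(t) = exp(-2 Dr t)` and `P2(t) = exp(-6 Dr t)`.
#'
#' @param Dr rotational diffusion coefficient in rad^2/ns (> 0).
#' @param n_frames number of stored frames.
#' @param dt time step in ns; `Dr * dt < 0.05` is required for stability.
#' @param n_vectors number of independent vectors (default 64).
#' @param seed RNG seed (mandatory).
#' @return a `dendri_trajectory` whose "coordinates" are the unit vectors
#'   (one row per vector); `time` is in ps.
#' @export
rigid_rotor_trajectory <- function(Dr, n_frames, dt, n_vectors = 64L, seed) {
  if (Dr < 0) abort("Dr must be non-negative.")
  if (Dr * dt >= 0.05) abort("unstable step size: require Dr * dt < 0.05.")
  with_seed(seed, {
    u <- matrix(rnorm(3L * n_vectors), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    sigma <- sqrt(2 * Dr * dt)
    frames <- vector("list", n_frames)
    frames[[1L]] <- u
    if (n_frames > 1L && sigma > 0) {
      for (k in 2:n_frames) {
        w <- matrix(rnorm(3L * n_vectors, sd = sigma), ncol = 3L)
        theta <- sqrt(rowSums(w^2))
        a <- w / theta
        ct <- cos(theta); st <- sin(theta)
        adotu <- rowSums(a * u)
        axu <- cbind(a[, 2L] * u[, 3L] - a[, 3L] * u[, 2L],
                     a[, 3L] * u[, 1L] - a[, 1L] * u[, 3L],
                     a[, 1L] * u[, 2L] - a[, 2L] * u[, 1L])
        u <- u * ct + axu * st + a * (adotu * (1 - ct))
        u <- u / sqrt(rowSums(u^2))
        frames[[k]] <- u
      }
    } else if (n_frames > 1L) {
      for (k in 2:n_frames) frames[[k]] <- u
    }
    trajectory(times = (seq_len(n_frames) - 1L) * dt * 1000, coords = frames,
               cell_edge = 10)
  })
}

#' Extract the vector array from a rotor trajectory
#'
#' @param traj a trajectory whose frames hold one row per vector.
#' @return numeric array `[n_frames, n_vectors, 3]` for [acf_orientational()].
#' @export
rotor_vectors <- function(traj) {
  nv <- n_atoms(traj)
  arr <- array(0, dim = c(nrow(traj), nv, 3L))
  for (k in seq_len(nrow(traj))) arr[k, , ] <- traj$coords[[k]]
  arr
}

# dimensionless (units of kBT) interaction of a -1 point charge with a +Q
# charge smeared uniformly in a sphere of radius R
macroion_potential <- function(r, Q, R, lambda_B) {
  ifelse(r >= R, -lambda_B * Q / r, -lambda_B * Q * (3 * R^2 - r^2) / (2 * R^3))
}

#' Total energy of a counterion configuration (kBT units)
#'
#' Pairwise counterion repulsion `lambda_B / r_ij` plus the attraction of
#' each counterion to the uniformly charged macroion sphere. Used by the
#' Metropolis sampler; exposed so configurations can be checked against
#' independent double-loop evaluations.
#'
#' @param coords n x 3 counterion coordinates (nm), macroion centred at the
#'   origin.
#' @param Q macroion charge (e).
#' @param R_sphere macroion radius (nm).
#' @param lambda_B Bjerrum length (nm).
#' @return energy in kBT.
#' @export
mc_energy <- function(coords, Q, R_sphere, lambda_B) {
  n <- nrow(coords)
  r <- sqrt(rowSums(coords^2))
  e <- sum(macroion_potential(r, Q, R_sphere, lambda_B))
  if (n > 1L) {
    d <- stats::dist(coords)
    e <- e + lambda_B * sum(1 / d)
  }
  e
}

#' Metropolis counterion ensemble around a fixed charged sphere
#'
#' Samples point counterions (charge -1) confined to a cubic cell centred on
#' a macroion of charge `+Q` distributed uniformly in a sphere of radius
#' `R_sphere`. The Coulomb energy is in units of `kBT` via the Bjerrum
#' length; interactions are direct (non-periodic) within the cell, matching
#' the finite-cell `psi(D) = 0` framing of the potential analysis. The
#' macroion is represented in the output as `Q` unit-charge beads at fixed
#' positions sampled uniformly in the sphere, so downstream charge profiles
#' see both species.
#'
#' @param Q macroion bare charge in e (default 44).
#' @param R_sphere macroion radius in nm (default 3.14).
#' @param cell_edge cubic cell edge in nm (default 7.5).
#' @param lambda_B Bjerrum length in nm (default 0.7).
#' @param n_counterions number of counterions; must equal `Q`
#'   (electroneutrality).
#' @param n_frames stored decorrelated frames (default 100).
#' @param burn_in equilibration sweeps before recording (default 400).
#' @param stride sweeps between stored frames (default 20).
#' @param step maximum displacement per move in nm (default 0.6).
#' @param seed RNG seed (mandatory).
#' @return list with `trajectory` (a `dendri_trajectory`; first `Q` rows are
#'   macroion beads, the rest counterions), `topology` (a
#'   `dendri_topology`), and `acceptance` (move acceptance rate).
#' @export
counterion_mc <- function(Q = 44, R_sphere = 3.14, cell_edge = 7.5,
                          lambda_B = 0.7, n_counterions = Q,
                          n_frames = 100L, burn_in = 400L, stride = 20L,
                          step = 0.6, seed) {
  if (n_counterions != Q) abort("electroneutrality requires n_counterions == Q.")
  if (R_sphere >= cell_edge * sqrt(3) / 2) abort("macroion larger than the cell.")
  with_seed(seed, {
    half <- cell_edge / 2
    n <- n_counterions
    beads <- sample_ball(Q, R_sphere, seed = seed + 1L)
    x <- matrix(runif(3L * n, -half, half), ncol = 3L)
    acc <- 0L; tries <- 0L
    frames <- vector("list", n_frames)
    times <- numeric(n_frames)
    stored <- 0L
    total_sweeps <- burn_in + n_frames * stride
    for (sw in seq_len(total_sweeps)) {
      for (i in seq_len(n)) {
        prop <- x[i, ] + runif(3L, -step, step)
        if (any(abs(prop) > half)) next    # confined to the cell
        tries <- tries + 1L
        others <- x[-i, , drop = FALSE]
        d_old <- sqrt(rowSums(sweep(others, 2L, x[i, ])^2))
        d_new <- sqrt(rowSums(sweep(others, 2L, prop)^2))
        dE <- lambda_B * (sum(1 / d_new) - sum(1 / d_old)) +
          macroion_potential(sqrt(sum(prop^2)), Q, R_sphere, lambda_B) -
          macroion_potential(sqrt(sum(x[i, ]^2)), Q, R_sphere, lambda_B)
        if (dE <= 0 || runif(1L) < exp(-dE)) {
          x[i, ] <- prop
          acc <- acc + 1L
        }
      }
      if (sw > burn_in && (sw - burn_in) %% stride == 0L) {
        stored <- stored + 1L
        frames[[stored]] <- rbind(beads, x)
        times[stored] <- stored
      }
    }
    rate <- acc / tries
    if (rate < 0.1 || rate > 0.9) {
      warn(sprintf("MC acceptance rate %.2f outside [0.1, 0.9]; adjust `step`.", rate))
    }
    atoms <- atom_table(
      atom_id = seq_len(Q + n),
      mass = c(rep(14.007, Q), rep(35.45, n)),
      charge = c(rep(1, Q), rep(-1, n)),
      group = c(rep("terminal_N", Q), rep("counterion", n))
    )
    list(
      trajectory = trajectory(times, frames, cell_edge),
      topology = system_topology(atoms),
      acceptance = rate
    )
  })
}

# residue masses (amu) used by the bead builder
.bead_mass <- c(lys = 128.17, gly = 57.05, terminal_N = 16.02, core = 129.18)

#' Bead dendrimer topology and embedding
#'
#' Builds a second-generation bead dendrimer: a core lysine bead branching
#' twice per branching point through three subgenerations, with a
#' two-residue spacer inserted before every branching point and terminal
#' lysine (8 terminal residues, each carrying two charged terminal-N beads,
#' i.e. 16 charged end groups). The `"Lys-2Lys"` preset gives every inserted
#' residue a +1 side charge (`Qbare = +44`); `"Lys-2Gly"` leaves insertions
#' neutral (`Qbare = +16`). Counterions (charge -1) equal to `Qbare` are
#' scattered in the cell. The embedding is a self-avoiding random walk with
#' the given bond length.
#'
#' @param preset `"Lys-2Lys"` or `"Lys-2Gly"`.
#' @param n_subgenerations branching shells (default 2; 0 is a degenerate
#'   spec and errors).
#' @param bond_length bead bond length in nm (default 0.35).
#' @param cell_edge cubic cell edge in nm (default 7.5).
#' @param seed RNG seed (mandatory).
#' @return list with `topology` (a `dendri_topology`) and `frame`
#'   (a one-frame `dendri_trajectory`).
#' @export
dendrimer_beads <- function(preset = c("Lys-2Lys", "Lys-2Gly"),
                            n_subgenerations = 2L, bond_length = 0.35,
                            cell_edge = 7.5, seed) {
  preset <- match.arg(preset)
  if (n_subgenerations < 1L) abort("degenerate spec: a single core bead has no terminals.")
  spacer_charged <- preset == "Lys-2Lys"
  spacer_mass <- if (spacer_charged) .bead_mass[["lys"]] else .bead_mass[["gly"]]
  spacer_group <- if (spacer_charged) "side_ch2" else "innerGly_ch2"

  id <- 0L
  rows <- list()
  bonds <- list()
  add_bead <- function(mass, charge, group, residue, parent = NA_integer_) {
    id <<- id + 1L
    rows[[id]] <<- tibble(atom_id = id, mass = mass, charge = charge,
                          group = group, residue = residue)
    bonds[[id]] <<- if (is.na(parent)) integer() else parent
    id
  }
  core <- add_bead(.bead_mass[["core"]], 0, "core", "core")
  grow <- function(parent, level) {
    for (b in 1:2) {
      # two-residue spacer
      s1 <- add_bead(spacer_mass, if (spacer_charged) 1 else 0, spacer_group,
                     "inserted", parent)
      s2 <- add_bead(spacer_mass, if (spacer_charged) 1 else 0, spacer_group,
                     "inserted", s1)
      if (level < n_subgenerations) {
        br <- add_bead(.bead_mass[["lys"]], 0, "inner_ch2", "branching", s2)
        grow(br, level + 1L)
      } else {
        term <- add_bead(.bead_mass[["lys"]], 0, "terminal_ch2", "terminal", s2)
        add_bead(.bead_mass[["terminal_N"]], 1, "terminal_N", "terminal", term)
        add_bead(.bead_mass[["terminal_N"]], 1, "terminal_N", "terminal", term)
      }
    }
  }
  grow(core, 0L)
  atoms <- dplyr::bind_rows(rows)
  Qbare <- sum(atoms$charge)
  n_ci <- as.integer(round(Qbare))
  ci_ids <- id + seq_len(n_ci)
  atoms <- dplyr::bind_rows(atoms, tibble(
    atom_id = ci_ids, mass = 35.45, charge = -1,
    group = "counterion", residue = "counterion"))
  bonds <- c(bonds, rep(list(integer()), n_ci))
  atoms <- atom_table(atoms$atom_id, atoms$mass, atoms$charge, atoms$group,
                      bonded = bonds, residue = atoms$residue)
  topo <- system_topology(atoms)

  with_seed(seed, {
    n_dend <- id
    half <- cell_edge / 2
    pos <- matrix(NA_real_, nrow(atoms), 3L)
    pos[core, ] <- 0
    place <- function(i, parent) {
      for (attempt in 1:200) {
        dir <- rnorm(3L); dir <- dir / sqrt(sum(dir^2))
        cand <- pos[parent, ] + bond_length * dir
        if (any(abs(cand) > half)) next
        placed <- pos[seq_len(nrow(pos)), , drop = FALSE]
        placed <- placed[stats::complete.cases(placed), , drop = FALSE]
        if (nrow(placed) == 0L ||
            min(sqrt(rowSums(sweep(placed, 2L, cand)^2))) > 0.20) {
          pos[i, ] <<- cand
          return(TRUE)
        }
      }
      pos[i, ] <<- pos[parent, ] + bond_length * c(0, 0, 1)  # last resort
      TRUE
    }
    for (i in seq_len(n_dend)[-core]) place(i, bonds[[i]][1L])
    for (i in ci_ids) {
      repeat {
        cand <- runif(3L, -half, half)
        dmin <- min(sqrt(rowSums(sweep(pos[seq_len(n_dend), , drop = FALSE],
                                       2L, cand)^2)))
        if (dmin > 0.3) { pos[i, ] <- cand; break }
      }
    }
    list(topology = topo,
         frame = trajectory(times = 0, coords = list(pos), cell_edge = cell_edge))
  })
}

#' Hydrogen-bond geometry fixture
#'
#' Builds a trajectory in which frame `k` contains exactly `schedule[k]`
#' donor/hydrogen/acceptor triples satisfying the geometric criterion, plus
#' three decoy triples per frame that each violate exactly one rule: one at
#' donor-acceptor distance 0.40 nm (angle 0), one at 45 degrees (distance
#' 0.34 nm), and one exactly at the 0.35 nm boundary (excluded by the strict
#' inequality).
#'
#' @param schedule integer vector of intended bond counts per frame.
#' @param seed RNG seed (mandatory; randomises triple placement and
#'   orientation).
#' @return list with `trajectory` and `topology`.
#' @export
hbond_fixture <- function(schedule, seed) {
  n_slots <- max(schedule, 1L)
  n_triples <- n_slots + 3L   # scheduled slots + 3 decoys
  # atoms per triple: donor, hydrogen, acceptor
  atoms <- atom_table(
    atom_id = seq_len(3L * n_triples),
    mass = rep(c(14.007, 1.008, 15.999), n_triples),
    charge = 0,
    group = rep(c("donor", "hydrogen", "acceptor"), n_triples),
    bonded = unlist(lapply(seq_len(n_triples) - 1L, function(k) {
      base <- 3L * k
      list(integer(), base + 1L, integer())   # H bonded to its donor
    }), recursive = FALSE)
  )
  topo <- system_topology(atoms)
  with_seed(seed, {
    rot_z_to <- function(dir) {            # rotation taking +x to dir
      dir <- dir / sqrt(sum(dir^2))
      axis <- c(0, -dir[3L], dir[2L])      # x cross dir
      s <- sqrt(sum(axis^2)); cth <- dir[1L]
      if (s < 1e-12) return(diag(3) * sign(cth))
      a <- axis / s
      K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L)
      diag(3) + K * s + K %*% K * (1 - cth)
    }
    place_triple <- function(origin, d_da, angle_deg) {
      dir <- rnorm(3L); dir <- dir / sqrt(sum(dir^2))
      Rm <- rot_z_to(dir)
      th <- angle_deg * pi / 180
      # local: D at 0, H along +x at 0.1, A at distance d_da under angle th
      local <- rbind(c(0, 0, 0),
                     c(0.1, 0, 0),
                     d_da * c(cos(th), sin(th), 0))
      sweep(local %*% t(Rm), 2L, origin, "+")
    }
    frames <- lapply(seq_along(schedule), function(k) {
      m <- matrix(0, 3L * n_triples, 3L)
      for (j in seq_len(n_triples)) {
        if (j == n_triples) {
          # boundary decoy kept unrotated at the origin so the donor-acceptor
          # distance evaluates to exactly d_max under IEEE arithmetic
          m[3L * (j - 1L) + 1:3, ] <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.35, 0, 0))
          next
        }
        origin <- c((j - 1L) %% 4L, ((j - 1L) %/% 4L) %% 4L,
                    (j - 1L) %/% 16L) * 4 + 4
        geom <- if (j <= schedule[k]) {
          c(0.30, 10)                       # qualifying: close and near-collinear
        } else if (j <= n_slots) {
          c(0.80, 10)                       # idle slot: too far
        } else if (j == n_slots + 1L) {
          c(0.40, 0)                        # decoy: distance violation only
        } else if (j == n_slots + 2L) {
          c(0.34, 45)                       # decoy: angle violation only
        } else {
          c(0.35, 0)                        # decoy: exactly at the boundary
        }
        m[3L * (j - 1L) + 1:3, ] <- place_triple(origin, geom[1L], geom[2L])
      }
      m
    })
    list(trajectory = trajectory(seq_along(schedule), frames, cell_edge = 20),
         topology = topo)
  })
}
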