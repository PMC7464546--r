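# Radial profiles: binned functions of distance from the dendrimer centre of
# mass. All profiles share one tibble layout (`r` = bin centre, `value`) with
# the bin edges, kind and frame count carried as attributes.

new_radial_profile <- function(bin_edges, values, kind, frames_averaged,
                               extra = list()) {
  stopifnot(length(values) == length(bin_edges) - 1L)
  out <- tibble(r = (head(bin_edges, -1L) + tail(bin_edges, -1L)) / 2,
                value = as.numeric(values))
  attr(out, "bin_edges") <- bin_edges
  attr(out, "dr") <- bin_edges[2L] - bin_edges[1L]
  attr(out, "kind") <- kind
  attr(out, "frames_averaged") <- frames_averaged
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("radial_profile", class(out))
  out
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile: %s> %d bins, dr = %g nm, %d frame(s)\n",
              attr(x, "kind"), nrow(x), attr(x, "dr"),
              attr(x, "frames_averaged")))
  NextMethod()
}

# shared binning driver: fun(coords, com) returns list(r = distances, w = weights)
radial_accumulate <- function(traj, topology, dr, r_max, fun) {
  if (dr <= 0) abort("dr must be positive.")
  if (dr > min(traj$cell_edge) / 2) abort("dr exceeds half the cell edge.")
  edges <- seq(0, r_max + dr, by = dr)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  atoms <- topology$atoms
  dend <- which(atoms$group != "counterion")
  for (k in seq_len(nrow(traj))) {
    m <- traj$coords[[k]]
    com <- center_of_mass(m, atoms$mass, dend)
    rw <- fun(m, com)
    bin <- findInterval(rw$r, edges, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin <= nb
    acc <- acc + as.numeric(tapply(rw$w[keep], factor(bin[keep], levels = seq_len(nb)),
                                   sum, default = 0))
  }
  list(edges = edges, mean_per_frame = acc / nrow(traj))
}

#' Radial mass density profile
#'
#' Mass density as a function of distance from the dendrimer centre of mass:
#' shell mass divided by shell volume `4 pi r^2 dr`, averaged over frames.
#' Units are amu/nm^3; multiply by `amu_per_nm3_to_g_cm3()` for g/cm^3.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology`.
#' @param dr bin width in nm (default 0.02).
#' @param select row indices of the atoms to include (default: all
#'   non-counterion atoms, hydrogens included).
#' @param r_max outer radius (default: half cell diagonal, so everything in
#'   the cell is binned and shell masses sum to the selected mass).
#' @return a `radial_profile` (`kind = "mass_density"`).
#' @export
mass_density_profile <- function(traj, topology, dr = 0.02, select = NULL,
                                 r_max = NULL) {
  atoms <- topology$atoms
  select <- select %||% which(atoms$group != "counterion")
  if (!length(select)) abort("empty selection.")
  r_max <- r_max %||% (sqrt(3) * max(traj$cell_edge) / 2)
  w <- atoms$mass[select]
  res <- radial_accumulate(traj, topology, dr, r_max, function(m, com) {
    list(r = sqrt(rowSums(sweep(m[select, , drop = FALSE], 2L, com)^2)), w = w)
  })
  centers <- (head(res$edges, -1L) + tail(res$edges, -1L)) / 2
  dens <- res$mean_per_frame / (4 * pi * centers^2 * dr)
  new_radial_profile(res$edges, dens, "mass_density", nrow(traj),
                     extra = list(shell_mass = res$mean_per_frame,
                                  selected_mass = sum(w)))
}

#' Conversion factor amu/nm^3 -> g/cm^3
#' @return scalar conversion factor (~1.6605e-3).
#' @export
amu_per_nm3_to_g_cm3 <- function() 1 / .const$NA_ * 1e21

#' Radial count profile of terminal nitrogens
#'
#' Mean number of terminal-nitrogen atoms per radial bin, as a function of
#' distance from the dendrimer centre of mass. Per frame the bin counts sum
#' to the number of terminal nitrogens.
#'
#' @inheritParams mass_density_profile
#' @param select row indices of terminal nitrogens (default: atoms tagged
#'   `terminal_N`).
#' @return a `radial_profile` (`kind = "count"`).
#' @export
terminal_nitrogen_profile <- function(traj, topology, dr = 0.02, select = NULL,
                                      r_max = NULL) {
  atoms <- topology$atoms
  select <- select %||% which(atoms$group == "terminal_N")
  if (!length(select)) abort("empty terminal-nitrogen selection.")
  r_max <- r_max %||% (sqrt(3) * max(traj$cell_edge) / 2)
  res <- radial_accumulate(traj, topology, dr, r_max, function(m, com) {
    list(r = sqrt(rowSums(sweep(m[select, , drop = FALSE], 2L, com)^2)),
         w = rep(1, length(select)))
  })
  new_radial_profile(res$edges, res$mean_per_frame, "count", nrow(traj))
}

# minimum-image pairwise distances between two coordinate sets in a cubic cell
pair_distances_mic <- function(a, b, L) {
  out <- matrix(0, nrow(a), nrow(b))
  for (d in 1:3) {
    dd <- outer(a[, d], b[, d], "-")
    dd <- dd - L * round(dd / L)
    out <- out + dd^2
  }
  sqrt(out)
}

#' Ion-pair radial distribution function
#'
#' Standard pair RDF between charged dendrimer nitrogens and counterions:
#' the distance histogram over all N+/counterion pairs (minimum image),
#' normalised by the shell volume `4 pi r^2 dr` and by the ideal pair density
#' `n_pairs / V_cell`, averaged over frames. For an ideal mixture g(r) -> 1.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology`.
#' @param cation_select,counterion_select row indices (defaults: groups
#'   `terminal_N` plus any positively charged dendrimer atom; `counterion`).
#' @param dr bin width in nm (default 0.01).
#' @param r_max outer radius, must not exceed half the cell edge.
#' @return a `radial_profile` (`kind = "rdf"`).
#' @export
ion_pair_rdf <- function(traj, topology, cation_select = NULL,
                         counterion_select = NULL, dr = 0.01, r_max = NULL) {
  atoms <- topology$atoms
  cation_select <- cation_select %||%
    which(atoms$group != "counterion" & atoms$charge > 0)
  counterion_select <- counterion_select %||% which(atoms$group == "counterion")
  if (!length(cation_select) || !length(counterion_select)) {
    abort("empty cation or counterion selection.")
  }
  if (length(intersect(cation_select, counterion_select))) {
    abort("cation and counterion selections overlap.")
  }
  L <- min(traj$cell_edge)
  r_max <- r_max %||% (L / 2)
  if (r_max > L / 2 + 1e-12) abort("r_max exceeds half the cell edge (minimum-image violation).")
  if (dr <= 0) abort("dr must be positive.")
  edges <- seq(0, r_max + dr, by = dr)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (k in seq_len(nrow(traj))) {
    m <- traj$coords[[k]]
    d <- pair_distances_mic(m[cation_select, , drop = FALSE],
                            m[counterion_select, , drop = FALSE],
                            traj$cell_edge[k])
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin <= nb
    acc <- acc + tabulate(bin[keep], nbins = nb)
  }
  centers <- (head(edges, -1L) + tail(edges, -1L)) / 2
  n_pairs <- length(cation_select) * length(counterion_select)
  rho_pair <- n_pairs / mean(traj$cell_edge^3)
  g <- (acc / nrow(traj)) / (4 * pi * centers^2 * dr) / rho_pair
  new_radial_profile(edges, g, "rdf", nrow(traj))
}

#' First-peak integration cutoff from an RDF
#'
#' Position of the first local minimum of g(r) after its first maximum; used
#' as the contact (ion-pair) cutoff. Falls back to `fallback` when no
#' interior minimum exists.
#'
#' @param rdf a `radial_profile` of kind `rdf`.
#' @param fallback cutoff used when no minimum is found (nm).
#' @return cutoff radius in nm.
#' @export
first_peak_cutoff <- function(rdf, fallback = 0.4) {
  v <- rdf$value; r <- rdf$r
  imax <- which(diff(sign(diff(v))) < 0) + 1L
  imax <- imax[v[imax] > 1]          # a real peak, not noise about g=1
  if (!length(imax)) return(fallback)
  i0 <- imax[1L]
  imin <- which(diff(sign(diff(v[i0:length(v)]))) > 0) + i0
  if (!length(imin)) return(fallback)
  r[imin[1L]]
}

#' Mean number of ion pairs per frame
#'
#' A counterion forms an ion pair when it lies within `r_pair` of a charged
#' dendrimer nitrogen. Counting is exclusive: each counterion is assigned to
#' its nearest cation (ties broken toward the lower atom row index) and
#' counted once. The inclusive pair count (all cation/counterion pairs within
#' the cutoff) is returned as attribute `inclusive`.
#'
#' @inheritParams ion_pair_rdf
#' @param r_pair contact cutoff in nm (e.g. from [first_peak_cutoff()]).
#' @return mean exclusive pair count per frame (numeric scalar) with
#'   attributes `inclusive` and `per_frame`.
#' @export
count_ion_pairs <- function(traj, topology, r_pair, cation_select = NULL,
                            counterion_select = NULL) {
  if (r_pair <= 0) abort("r_pair must be positive.")
  atoms <- topology$atoms
  cation_select <- cation_select %||%
    which(atoms$group != "counterion" & atoms$charge > 0)
  counterion_select <- counterion_select %||% which(atoms$group == "counterion")
  if (!length(cation_select) || !length(counterion_select)) {
    abort("empty cation or counterion selection.")
  }
  excl <- incl <- numeric(nrow(traj))
  for (k in seq_len(nrow(traj))) {
    d <- pair_distances_mic(traj$coords[[k]][cation_select, , drop = FALSE],
                            traj$coords[[k]][counterion_select, , drop = FALSE],
                            traj$cell_edge[k])
    nearest <- apply(d, 2L, min)
    excl[k] <- sum(nearest <= r_pair)
    incl[k] <- sum(d <= r_pair)
  }
  out <- mean(excl)
  attr(out, "inclusive") <- mean(incl)
  attr(out, "per_frame") <- excl
  out
}

#' Net and cumulative radial charge profiles with effective charge
#'
#' Bins the net charge (positive dendrimer charges plus negative counterion
#' charges) by distance from the dendrimer centre of mass, averaged over
#' frames; the cumulative profile `Q(r)` is the running sum. The effective
#' charge `Q*` is the maximum of `Q(r)` and the effective radius `R_max` is
#' the bin centre at that maximum (ties toward smaller r; no smoothing). For
#' an electroneutral system the final cumulative charge is zero.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology`; input must be electroneutral.
#' @param dr bin width in nm (default 0.02).
#' @param r_max outer radius (default: half cell diagonal so the whole cubic
#'   cell is covered).
#' @return a list with elements `q` (per-bin net charge profile), `Q`
#'   (cumulative profile) and `effective` (one-row tibble `Q_star`, `R_max`).
#' @export
charge_profiles <- function(traj, topology, dr = 0.02, r_max = NULL) {
  atoms <- topology$atoms
  net <- sum(atoms$charge)
  if (abs(net) > 1e-9) {
    abort(sprintf("charge profiles require an electroneutral system (net %+0.4g e).", net))
  }
  sel <- which(atoms$charge != 0)
  if (!length(sel)) abort("no charged atoms.")
  r_max <- r_max %||% (sqrt(3) * max(traj$cell_edge) / 2)
  w <- atoms$charge[sel]
  res <- radial_accumulate(traj, topology, dr, r_max, function(m, com) {
    list(r = sqrt(rowSums(sweep(m[sel, , drop = FALSE], 2L, com)^2)), w = w)
  })
  q <- new_radial_profile(res$edges, res$mean_per_frame, "charge", nrow(traj))
  Qc <- new_radial_profile(res$edges, cumsum(res$mean_per_frame),
                           "cumulative_charge", nrow(traj))
  istar <- which.max(Qc$value)      # which.max takes the first (smallest r) tie
  list(q = q, Q = Qc,
       effective = tibble(Q_star = Qc$value[istar], R_max = Qc$r[istar]))
}
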