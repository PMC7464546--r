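# Geometric hydrogen-bond detection. A donor/hydrogen/acceptor triple is a
# bond when the donor-acceptor distance and the angular criterion both hold
# strictly. Two angle conventions are shipped (see `convention`).

#' Hydrogen-bond criterion
#'
#' @param d_max donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_max angular cutoff in degrees (default 30), strict.
#' @param convention `"donor"` (default): angle between the D->H and D->A
#'   directions must be below `angle_max` (the common hydrogen-donor-acceptor
#'   convention). `"linear"`: the deviation of the D-H...A angle from 180
#'   degrees must be below `angle_max`.
#' @return a list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_max = 30,
                            convention = c("donor", "linear")) {
  if (d_max <= 0) abort("d_max must be positive.")
  if (angle_max <= 0 || angle_max >= 90) abort("angle_max must be in (0, 90) degrees.")
  structure(list(d_max = d_max, angle_max = angle_max,
                 convention = match.arg(convention)),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in a single frame
#'
#' A triple (donor D, hydrogen H, acceptor A) is a bond iff
#' `dist(D, A) < d_max` and the angular criterion of the chosen convention
#' holds (both strict inequalities; boundary geometries are excluded). Each
#' hydrogen participates in at most one bond per frame: among qualifying
#' acceptors the closest (by D-A distance) wins, ties broken by the lower
#' acceptor row index.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param donors,hydrogens,acceptors integer row indices of candidate atoms.
#' @param hd_map integer vector, same length as `hydrogens`: the donor row
#'   index each hydrogen is covalently bonded to. May be derived from a
#'   topology with [hydrogen_donor_map()].
#' @param criterion an [hbond_criterion()].
#' @return tibble with columns `donor`, `hydrogen`, `acceptor`, `distance`
#'   (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(coords, donors, hydrogens, acceptors, hd_map,
                          criterion = hbond_criterion()) {
  if (length(hd_map) != length(hydrogens)) {
    abort("`hd_map` must give one donor per hydrogen.")
  }
  if (anyNA(hd_map) || !all(hd_map %in% donors)) {
    abort("hydrogen with no bonded donor in the donor selection.")
  }
  hits <- list()
  for (i in seq_along(hydrogens)) {
    h <- hydrogens[i]; d <- hd_map[i]
    da <- sweep(coords[acceptors, , drop = FALSE], 2L, coords[d, ])
    dist_da <- sqrt(rowSums(da^2))
    ok <- dist_da < criterion$d_max & acceptors != d & acceptors != h
    if (!any(ok)) next
    ang <- rep(NA_real_, length(acceptors))
    if (criterion$convention == "donor") {
      dh <- coords[h, ] - coords[d, ]
      cosang <- (da[ok, , drop = FALSE] %*% dh) /
        (dist_da[ok] * sqrt(sum(dh^2)))
      ang[ok] <- acosd(cosang)
    } else {
      hd <- coords[d, ] - coords[h, ]
      ha <- sweep(coords[acceptors[ok], , drop = FALSE], 2L, coords[h, ])
      cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
      ang[ok] <- 180 - acosd(cosang)
    }
    ok <- ok & ang < criterion$angle_max
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[order(dist_da[cand], acceptors[cand])][1L]
    hits[[length(hits) + 1L]] <- tibble(
      donor = d, hydrogen = h, acceptor = acceptors[best],
      distance = dist_da[best], angle = ang[best])
  }
  if (!length(hits)) {
    return(tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                  distance = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(hits)
}

acosd <- function(x) acos(pmin(pmax(x, -1), 1)) * 180 / pi

#' Donor map for every hydrogen
#'
#' Looks up, for each hydrogen row index, the single heavy atom it is bonded
#' to in the topology.
#'
#' @param topology a `dendri_topology`.
#' @param hydrogens integer row indices of hydrogens.
#' @return integer vector of donor row indices.
#' @export
hydrogen_donor_map <- function(topology, hydrogens) {
  atoms <- topology$atoms
  adj <- bond_adjacency(atoms)
  vapply(hydrogens, function(i) {
    nb <- adj[[i]]
    heavy <- match(nb, atoms$atom_id)
    heavy <- heavy[atoms$group[heavy] != "hydrogen"]
    if (length(heavy) != 1L) {
      abort(sprintf("hydrogen atom %d has no unique bonded donor.", atoms$atom_id[i]))
    }
    heavy
  }, integer(1))
}

#' Hydrogen-bond count distribution over a trajectory
#'
#' Counts bonds per frame and histograms the counts. `mode = "intra"` keeps
#' bonds whose donor and acceptor both belong to the solute partition;
#' `mode = "solute_water"` keeps bonds with exactly one partner in each
#' partition.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology` whose atoms carry `donor`, `hydrogen`
#'   and `acceptor` group tags.
#' @param criterion an [hbond_criterion()].
#' @param mode `"intra"` (default) or `"solute_water"`.
#' @param water_atoms integer row indices forming the water partition
#'   (default: atoms whose `residue` is `"water"`, if the column exists).
#' @return tibble of class `hbond_dist` with columns `n_bonds`, `count`,
#'   `p`; attributes `mean` and `per_frame`.
#' @export
hbond_count_distribution <- function(traj, topology,
                                     criterion = hbond_criterion(),
                                     mode = c("intra", "solute_water"),
                                     water_atoms = NULL) {
  mode <- match.arg(mode)
  atoms <- topology$atoms
  donors <- which(atoms$group == "donor")
  hydrogens <- which(atoms$group == "hydrogen")
  acceptors <- which(atoms$group == "acceptor")
  if (is.null(water_atoms)) {
    water_atoms <- if ("residue" %in% names(atoms)) {
      which(atoms$residue == "water")
    } else integer()
  }
  is_water <- seq_len(nrow(atoms)) %in% water_atoms
  hd <- hydrogen_donor_map(topology, hydrogens)
  counts <- vapply(traj$coords, function(m) {
    b <- detect_hbonds(m, donors, hydrogens, acceptors, hd, criterion)
    if (!nrow(b)) return(0L)
    dw <- is_water[b$donor]; aw <- is_water[b$acceptor]
    keep <- if (mode == "intra") !dw & !aw else xor(dw, aw)
    sum(keep)
  }, integer(1))
  tb <- tibble(n_bonds = sort(unique(counts))) |>
    mutate(count = vapply(.data$n_bonds, function(k) sum(counts == k), integer(1)),
           p = .data$count / length(counts))
  attr(tb, "mean") <- mean(counts)
  attr(tb, "per_frame") <- counts
  class(tb) <- c("hbond_dist", class(tb))
  tb
}
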