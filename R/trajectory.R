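#' Trajectory container
#'
#' A trajectory is a tibble with one row per frame: `time` (ps), `cell_edge`
#' (nm, cubic cell) and `coords` (list-column of N x 3 coordinate matrices in
#' nm). Frames must be strictly time-ordered with uniform spacing.
#'
#' @param times frame times in ps (strictly increasing, uniformly spaced).
#' @param coords list of N x 3 numeric matrices (nm).
#' @param cell_edge cubic cell edge(s) in nm (scalar or per frame).
#' @return a tibble of class `dendri_trajectory` with attribute `dt_output`
#'   (ps between stored frames).
#' @export
trajectory <- function(times, coords, cell_edge) {
  n <- length(times)
  if (n == 0L) abort("trajectory has no frames.")
  if (length(coords) != n) abort("`times` and `coords` lengths differ.")
  if (length(cell_edge) == 1L) cell_edge <- rep(cell_edge, n)
  if (any(cell_edge <= 0)) abort("cell_edge must be positive.")
  if (n > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) abort("frame times must be strictly increasing.")
    if (n > 2L && diff(range(dt)) > 1e-6 * max(dt)) {
      abort("frame times are not uniformly spaced (tolerance 1e-6).")
    }
    dt_out <- dt[1L]
  } else dt_out <- NA_real_
  nat <- vapply(coords, nrow, integer(1))
  if (length(unique(nat)) != 1L) abort("frames have differing atom counts.")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  out <- tibble(time = as.numeric(times), cell_edge = as.numeric(cell_edge),
                coords = coords)
  attr(out, "dt_output") <- dt_out
  class(out) <- c("dendri_trajectory", class(out))
  out
}

#' @export
print.dendri_trajectory <- function(x, ...) {
  cat(sprintf("<dendri_trajectory> %d frames x %d atoms, dt = %s ps, cell %.3g nm\n",
              nrow(x), n_atoms(x),
              format(attr(x, "dt_output")), x$cell_edge[1L]))
  invisible(x)
}

#' Number of atoms per frame
#' @param traj a `dendri_trajectory`.
#' @return integer.
#' @export
n_atoms <- function(traj) nrow(traj$coords[[1L]])

#' Read the plain-text trajectory dialect
#'
#' Each frame block: a header line `natoms cell_edge time` followed by
#' `natoms` lines `id x y z` (nm). Frames are re-sorted only in the sense of
#' being validated: non-monotonic time stamps are an error.
#'
#' @param path input file.
#' @param topology optional `dendri_topology`; the per-frame atom count must
#'   then match, and molecules are made whole across periodic boundaries
#'   using its bond graph (see [make_whole()]).
#' @param unwrap apply [make_whole()] when a topology with bonds is given
#'   (default `TRUE`).
#' @return a `dendri_trajectory`.
#' @export
read_xyz_frames <- function(path, topology = NULL, unwrap = TRUE) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  times <- numeric(); cells <- numeric(); coords <- list()
  while (i <= length(lines)) {
    hd <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
    if (length(hd) < 3L || is.na(hd[1L])) abort(sprintf("malformed frame header at line %d.", i))
    nat <- as.integer(hd[1L])
    block <- lines[(i + 1L):(i + nat)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 4L, byrow = TRUE)
    ord <- order(m[, 1L])
    coords[[length(coords) + 1L]] <- m[ord, 2:4, drop = FALSE]
    cells <- c(cells, hd[2L]); times <- c(times, hd[3L])
    i <- i + 1L + nat
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("non-monotonic time stamps in trajectory.")
  }
  if (!is.null(topology) && nrow(topology$atoms) != nrow(coords[[1L]])) {
    abort(sprintf("atom-count mismatch: topology has %d atoms, frames have %d.",
                  nrow(topology$atoms), nrow(coords[[1L]])))
  }
  tr <- trajectory(times, coords, cells)
  if (!is.null(topology) && unwrap) tr <- make_whole(tr, topology)
  tr
}

#' Write the plain-text trajectory dialect
#'
#' @param traj a `dendri_trajectory`.
#' @param path output file.
#' @param digits coordinate digits (default 6; read/write round trips to
#'   1e-3 nm or better).
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path, digits = 6) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ids <- seq_len(n_atoms(traj))
  for (k in seq_len(nrow(traj))) {
    m <- traj$coords[[k]]
    writeLines(sprintf("%d %.6g %.6g", nrow(m), traj$cell_edge[k], traj$time[k]), con)
    writeLines(sprintf("%d %.*f %.*f %.*f", ids, digits, m[, 1L],
                       digits, m[, 2L], digits, m[, 3L]), con)
  }
  invisible(path)
}

#' Alias for the documented loader name
#' @inheritParams read_xyz_frames
#' @export
load_trajectory <- function(path, topology = NULL, unwrap = TRUE) {
  read_xyz_frames(path, topology, unwrap)
}

#' Re-assemble molecules across periodic boundaries
#'
#' Performs a breadth-first traversal of the bond graph in every frame and
#' shifts each atom by integer cell vectors so bonded neighbours sit in the
#' same periodic image. Unbonded atoms (e.g. counterions) are then wrapped
#' into the cubic cell centred on the dendrimer centre of mass, so all radial
#' observables see the nearest periodic image of every ion.
#'
#' @param traj a `dendri_trajectory`.
#' @param topology a `dendri_topology` carrying the bond graph.
#' @return the unwrapped trajectory.
#' @export
make_whole <- function(traj, topology) {
  atoms <- topology$atoms
  adj_ids <- bond_adjacency(atoms)
  idx <- match(unlist(adj_ids), atoms$atom_id)
  adj <- split(idx, rep(seq_along(adj_ids), lengths(adj_ids)))
  adj <- lapply(seq_len(nrow(atoms)), function(i) adj[[as.character(i)]] %||% integer())
  not_ci <- atoms$group != "counterion"
  mass <- atoms$mass
  traj$coords <- purrr::map2(traj$coords, traj$cell_edge, function(m, L) {
    m <- unwrap_bonded(m, adj, L)
    com <- colSums(m[not_ci, , drop = FALSE] * mass[not_ci]) / sum(mass[not_ci])
    # wrap every unbonded atom to the image nearest the dendrimer COM
    loose <- which(lengths(adj) == 0L)
    if (length(loose)) {
      d <- sweep(m[loose, , drop = FALSE], 2L, com)
      shift <- -L * round(d / L)
      hit <- shift != 0   # leave in-cell atoms bit-identical
      m[loose, ][hit] <- (m[loose, , drop = FALSE] + shift)[hit]
    }
    m
  })
  traj
}

# BFS over connected components; shift each newly visited atom next to parent
unwrap_bonded <- function(m, adj, L) {
  n <- nrow(m)
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root] || !length(adj[[root]])) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in adj[[i]]) {
        if (visited[j]) next
        d <- m[j, ] - m[i, ]
        m[j, ] <- m[j, ] - L * round(d / L)
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  m
}

#' Mass-weighted centre of mass of a selection
#'
#' @param coords N x 3 matrix (nm).
#' @param masses atom masses (amu); recycled scalar allowed.
#' @param select integer row indices (default all).
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(coords, masses, select = NULL) {
  if (!is.null(select)) {
    coords <- coords[select, , drop = FALSE]
    if (length(masses) > 1L) masses <- masses[select]
  }
  if (length(masses) == 1L) masses <- rep(masses, nrow(coords))
  M <- sum(masses)
  if (M <= 0) abort("zero total mass in centre-of-mass selection.")
  colSums(coords * masses) / M
}

#' Discard an initial equilibration window
#'
#' @param traj a `dendri_trajectory`.
#' @param discard_ps time (ps) to drop from the start (default 0).
#' @return the truncated trajectory.
#' @export
discard_equilibration <- function(traj, discard_ps = 0) {
  if (discard_ps <= 0) return(traj)
  keep <- traj$time >= traj$time[1L] + discard_ps
  if (!any(keep)) abort("equilibration window discards every frame.")
  out <- traj[keep, ]
  attr(out, "dt_output") <- attr(traj, "dt_output")
  class(out) <- class(traj)
  out
}
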