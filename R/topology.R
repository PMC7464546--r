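#' Atom table constructor
#'
#' Builds and validates the per-atom table used by [system_topology()]. One
#' row per atom with mass (amu), partial/formal charge (elementary charge
#' units), a structural group tag and bond partners.
#'
#' @param atom_id integer atom identifiers (unique).
#' @param mass atomic/bead masses in amu; must be positive.
#' @param charge charges in units of the elementary charge.
#' @param group group tag; one of `r paste(.group_levels, collapse = ", ")`.
#'   Unknown atoms should be tagged `"other"`.
#' @param bonded list of integer vectors of bonded `atom_id`s (symmetric
#'   bonds; each pair may be listed on either or both atoms).
#' @param name optional atom names.
#' @param residue optional residue labels (e.g. `"inserted"`, `"terminal"`).
#' @return a tibble of class `dendri_atoms`.
#' @export
atom_table <- function(atom_id, mass, charge, group = "other",
                       bonded = NULL, name = NULL, residue = NULL) {
  n <- length(atom_id)
  if (n == 0L) abort("empty system: no atoms supplied.")
  atom_id <- as.integer(atom_id)
  if (anyDuplicated(atom_id)) abort("duplicated atom_id values.")
  if (length(mass) == 1L) mass <- rep(mass, n)
  if (length(charge) == 1L) charge <- rep(charge, n)
  if (length(group) == 1L) group <- rep(group, n)
  bad_mass <- which(!is.finite(mass) | mass <= 0)
  if (length(bad_mass)) {
    abort(paste0("missing or non-positive mass for atom(s): ",
                 paste(atom_id[head(bad_mass, 5L)], collapse = ", ")))
  }
  if (any(!is.finite(charge))) {
    abort(paste0("missing charge for atom(s): ",
                 paste(atom_id[head(which(!is.finite(charge)), 5L)], collapse = ", ")))
  }
  bad_grp <- setdiff(unique(group), .group_levels)
  if (length(bad_grp)) abort(paste0("unknown group tag(s): ", paste(bad_grp, collapse = ", ")))
  if (is.null(bonded)) bonded <- rep(list(integer()), n)
  bonded <- lapply(bonded, as.integer)
  tb <- tibble(
    atom_id = atom_id,
    mass = as.numeric(mass),
    charge = as.numeric(charge),
    group = group,
    bonded = bonded
  )
  if (!is.null(name)) tb$name <- name
  if (!is.null(residue)) tb$residue <- residue
  class(tb) <- c("dendri_atoms", class(tb))
  tb
}

#' System topology
#'
#' Bundles the atom table with molecule-level bookkeeping: total dendrimer
#' mass `M`, bare charge `Qbare` (sum of non-counterion charges), terminal
#' group counts/charges and the counterion count. Electroneutral systems must
#' satisfy `n_counterions == Qbare` (each counterion carries charge -1).
#'
#' @param atoms a `dendri_atoms` table from [atom_table()].
#' @param nins,qins number and total charge of inserted spacer residues, if
#'   known (bead generators fill these; defaults are derived from `residue`
#'   labels when present, else `NA`).
#' @param check_neutral if `TRUE` (default) a violation of electroneutrality
#'   is a hard error reporting the net charge.
#' @return an object of class `dendri_topology`: a list with elements
#'   `atoms`, `M`, `Qbare`, `Nend`, `Qend`, `Nins`, `Qins`, `n_counterions`.
#' @export
system_topology <- function(atoms, nins = NULL, qins = NULL, check_neutral = TRUE) {
  if (!inherits(atoms, "dendri_atoms")) {
    atoms <- atom_table(atoms$atom_id, atoms$mass, atoms$charge,
                        atoms$group %||% "other", atoms$bonded,
                        atoms$name, atoms$residue)
  }
  validate_hydrogen_bonding(atoms)
  is_ci <- atoms$group == "counterion"
  Qbare <- sum(atoms$charge[!is_ci])
  n_ci <- sum(is_ci)
  net <- sum(atoms$charge)
  if (check_neutral && abs(net) > 1e-9) {
    abort(sprintf("system is not electroneutral: net charge %+0.4g e.", net))
  }
  is_tn <- atoms$group == "terminal_N"
  if (is.null(nins) && "residue" %in% names(atoms)) {
    nins <- sum(atoms$residue == "inserted", na.rm = TRUE)
    if (is.null(qins)) qins <- sum(atoms$charge[atoms$residue == "inserted"], na.rm = TRUE)
  }
  structure(
    list(
      atoms = atoms,
      M = sum(atoms$mass[!is_ci]),
      Qbare = Qbare,
      Nend = sum(is_tn),
      Qend = sum(atoms$charge[is_tn]),
      Nins = nins %||% NA_integer_,
      Qins = qins %||% NA_real_,
      n_counterions = n_ci
    ),
    class = "dendri_topology"
  )
}

#' @export
print.dendri_topology <- function(x, ...) {
  cat("<dendri_topology>\n")
  cat(sprintf("  atoms: %d (counterions: %d)\n", nrow(x$atoms), x$n_counterions))
  cat(sprintf("  M = %.2f amu, Qbare = %+g e, Nend = %d (Qend = %+g e)\n",
              x$M, x$Qbare, x$Nend, x$Qend))
  if (!is.na(x$Nins)) cat(sprintf("  Nins = %d, Qins = %+g e\n", x$Nins, x$Qins))
  invisible(x)
}

# every hydrogen must be bonded to exactly one heavy atom
validate_hydrogen_bonding <- function(atoms) {
  hyd <- which(atoms$group == "hydrogen")
  if (!length(hyd)) return(invisible(TRUE))
  bond_map <- bond_adjacency(atoms)
  for (i in hyd) {
    nb <- bond_map[[i]]
    heavy <- nb[atoms$group[match(nb, atoms$atom_id)] != "hydrogen"]
    if (length(heavy) != 1L) {
      abort(sprintf("hydrogen atom %d is bonded to %d heavy atoms (expected exactly 1).",
                    atoms$atom_id[i], length(heavy)))
    }
  }
  invisible(TRUE)
}

# symmetric adjacency (list indexed by row, values are atom_ids)
bond_adjacency <- function(atoms) {
  n <- nrow(atoms)
  ids <- atoms$atom_id
  adj <- rep(list(integer()), n)
  for (i in seq_len(n)) {
    for (j in atoms$bonded[[i]]) {
      k <- match(j, ids)
      if (is.na(k)) abort(sprintf("atom %d lists a bond to unknown atom %d.", ids[i], j))
      adj[[i]] <- c(adj[[i]], j)
      adj[[k]] <- c(adj[[k]], ids[i])
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Apply a group configuration to a topology's atoms
#'
#' A group config maps group tags to explicit atom-id vectors or to name
#' patterns (regular expressions matched against the atom `name` column).
#' Assignment is idempotent; atoms matched by no rule keep/become `"other"`.
#'
#' @param atoms a `dendri_atoms` table.
#' @param group_config named list: `tag = c(ids...)` or
#'   `tag = list(pattern = "regex")`.
#' @return the atom table with its `group` column reassigned.
#' @export
assign_groups <- function(atoms, group_config) {
  if (is.null(group_config) || !length(group_config)) return(atoms)
  bad <- setdiff(names(group_config), .group_levels)
  if (length(bad)) abort(paste0("unknown group tag(s) in config: ", paste(bad, collapse = ", ")))
  grp <- rep("other", nrow(atoms))
  for (tag in names(group_config)) {
    rule <- group_config[[tag]]
    if (is.list(rule) && !is.null(rule$pattern)) {
      if (!"name" %in% names(atoms)) abort("name-pattern group rules need a `name` column.")
      hit <- grepl(rule$pattern, atoms$name)
    } else {
      hit <- atoms$atom_id %in% as.integer(unlist(rule))
    }
    already <- hit & grp != "other" & grp != tag
    if (any(already)) {
      abort(sprintf("group config assigns atom %d to both '%s' and '%s'.",
                    atoms$atom_id[which(already)[1L]], grp[which(already)[1L]], tag))
    }
    grp[hit] <- tag
  }
  atoms$group <- grp
  atoms
}

#' Load a system topology from file
#'
#' Reads a structure file plus an optional group configuration and returns a
#' validated [system_topology()]. Supported formats: a plain-text/CSV atom
#' table (columns `atom_id, mass, charge[, name, residue]`, optional `bonds`
#' column of space-separated partner ids), PDB (via the bio3d package, masses
#' from element symbols) and GRO (names/residues only; masses and charges
#' must come from the group config's `masses`/`charges` entries).
#'
#' @param path structure file (`.csv`/`.tsv`/`.txt`, `.pdb`, `.gro`).
#' @param group_config optional path to a YAML group config or a named list;
#'   top-level key `groups:` maps tags to ids/patterns; optional `nins`,
#'   `qins` metadata keys.
#' @param check_neutral passed to [system_topology()].
#' @return a `dendri_topology`.
#' @export
load_system <- function(path, group_config = NULL, check_neutral = TRUE) {
  if (!file.exists(path)) abort(paste0("topology file not found: ", path))
  cfg <- read_group_config(group_config)
  ext <- tolower(tools::file_ext(path))
  atoms <- switch(ext,
    "pdb" = read_pdb_atoms(path),
    "gro" = read_gro_atoms(path, cfg),
    read_atom_csv(path)
  )
  if (nrow(atoms) == 0L) abort("empty system")
  if (!is.null(cfg$groups)) atoms <- assign_groups(atoms, cfg$groups)
  system_topology(atoms, nins = cfg$nins, qins = cfg$qins,
                  check_neutral = check_neutral)
}

read_group_config <- function(group_config) {
  if (is.null(group_config)) return(list())
  if (is.character(group_config)) {
    if (!file.exists(group_config)) abort(paste0("group config not found: ", group_config))
    yaml::read_yaml(group_config)
  } else {
    group_config
  }
}

read_atom_csv <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("atom_id", "mass", "charge")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("atom table missing column(s): ", paste(miss, collapse = ", ")))
  bonded <- if ("bonds" %in% names(df)) {
    b <- as.character(df$bonds)
    b[is.na(b)] <- ""
    lapply(strsplit(b, "[ ;]+"), function(v) as.integer(v[nzchar(v) & v != "NA"]))
  } else NULL
  atom_table(df$atom_id, df$mass, df$charge,
             group = if ("group" %in% names(df)) df$group else "other",
             bonded = bonded, name = df$name, residue = df$residue)
}

# minimal element masses for PDB import
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, CL = 35.45, NA_ = 22.99, K = 39.098)

read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB topologies requires the 'bio3d' package.")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1, 1), at$elesy)))
  elt[elt == "NA"] <- "NA_"
  mass <- .element_mass[elt]
  if (anyNA(mass)) {
    abort(paste0("missing mass (unknown element) for atom(s): ",
                 paste(at$eleno[head(which(is.na(mass)), 5L)], collapse = ", ")))
  }
  chg <- suppressWarnings(as.numeric(at$charge))
  chg[is.na(chg)] <- 0
  atom_table(at$eleno, mass, chg, name = trimws(at$elety), residue = trimws(at$resid))
}

# GRO fixed-width: resnum(5) resname(5) atomname(5) atomnum(5) x y z (nm)
read_gro_atoms <- function(path, cfg = list()) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2L]))
  rec <- lines[3L:(2L + n)]
  name <- trimws(substr(rec, 11, 15))
  id <- as.integer(substr(rec, 16, 20))
  residue <- trimws(substr(rec, 6, 10))
  mass <- cfg$masses[name]
  if (is.null(cfg$masses) || anyNA(mass)) {
    abort(paste0("missing masses for GRO atoms; supply `masses:` in the group config (first offender: ",
                 name[which(is.na(mass))[1L] %||% 1L], ")."))
  }
  charge <- if (!is.null(cfg$charges)) {
    ch <- cfg$charges[name]; ch[is.na(ch)] <- 0; ch
  } else rep(0, n)
  atom_table(id, as.numeric(mass), as.numeric(charge), name = name, residue = residue)
}

#' Coordinates of a GRO structure file
#'
#' @param path GRO file.
#' @return list with `coords` (N x 3 matrix, nm) and `cell_edge` (nm).
#' @export
read_gro_coords <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2L]))
  rec <- lines[3L:(2L + n)]
  xyz <- do.call(rbind, lapply(rec, function(l) {
    as.numeric(c(substr(l, 21, 28), substr(l, 29, 36), substr(l, 37, 44)))
  }))
  box <- as.numeric(strsplit(trimws(lines[3L + n]), "\\s+")[[1L]])
  list(coords = xyz, cell_edge = box[1L])
}
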