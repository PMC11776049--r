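#' Domain containers shared across the toolkit
#'
#' The toolkit works in the GRO/TOP unit system: coordinates in nm, times in
#' ns, masses in amu, charges in units of the elementary charge, energies in
#' kJ/mol. The z axis is the bilayer normal and the mass-weighted membrane
#' centre of mass (COM) is the reference origin for restraints and profiles.
#' Boxes are orthorhombic; triclinic input is rejected.
#'
#' A `system_frame` holds one configuration: an atom table
#' (`resid`, `resname`, `name`, `x`, `y`, `z`, optional velocities), the box
#' vector `c(Lx, Ly, Lz)` and a molecule table (`molid`, `species`, `first`,
#' `n`) derived from consecutive runs of identical `(resid, resname)`.
#'
#' @param atoms data.frame with columns `resid`, `resname`, `name`, `x`, `y`,
#'   `z` and optionally `vx`, `vy`, `vz`.
#' @param box numeric length-3 orthorhombic box (nm); all components > 0.
#' @param time frame time in ns (`NA` when unknown).
#' @param title free-text title line.
#' @return An object of class `system_frame`.
#' @export
system_frame <- function(atoms, box, time = NA_real_, title = "splitmem frame") {
  stopifnot(is.data.frame(atoms))
  need <- c("resid", "resname", "name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_splitmem("atoms table missing columns: ",
                                  paste(miss, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_splitmem("box must be three positive finite lengths (orthorhombic)")
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z)))
    stop_splitmem("non-finite atom coordinates")
  rownames(atoms) <- NULL
  fr <- structure(list(atoms = atoms, box = box, time = as.numeric(time),
                       title = title),
                  class = "system_frame")
  fr$molecules <- derive_molecules(atoms)
  fr
}

# molecule table from runs of identical (resid, resname)
derive_molecules <- function(atoms) {
  n <- nrow(atoms)
  if (n == 0L)
    return(data.frame(molid = integer(), species = character(),
                      first = integer(), n = integer()))
  key <- paste(atoms$resid, atoms$resname, sep = "\r")
  new_mol <- c(TRUE, key[-1L] != key[-n])
  molid <- cumsum(new_mol)
  first <- which(new_mol)
  data.frame(molid = seq_along(first),
             species = atoms$resname[first],
             first = first,
             n = diff(c(first, n + 1L)),
             stringsAsFactors = FALSE)
}

#' @export
print.system_frame <- function(x, ...) {
  cat(sprintf("<system_frame> %d atoms, %d molecules, box %.3f x %.3f x %.3f nm",
              nrow(x$atoms), nrow(x$molecules),
              x$box[1L], x$box[2L], x$box[3L]),
      if (is.finite(x$time)) sprintf(", t = %g ns", x$time) else "", "\n",
      sep = "")
  invisible(x)
}

#' Multi-frame trajectory container
#'
#' Stores coordinates as an `n_atoms x 3 x n_frames` array plus per-frame
#' boxes and times; atom metadata is shared across frames (uniform atom
#' count). Times must be strictly increasing.
#'
#' @param frames list of `system_frame` objects with identical atom tables.
#' @return Object of class `trajectory`.
#' @export
as_trajectory <- function(frames) {
  if (inherits(frames, "trajectory")) return(frames)
  if (inherits(frames, "system_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  n <- nrow(frames[[1L]]$atoms)
  for (fr in frames)
    if (nrow(fr$atoms) != n)
      stop_splitmem("trajectory frames differ in atom count")
  coords <- array(0, dim = c(n, 3L, length(frames)))
  box <- matrix(0, nrow = length(frames), ncol = 3L)
  times <- numeric(length(frames))
  for (i in seq_along(frames)) {
    a <- frames[[i]]$atoms
    coords[, , i] <- cbind(a$x, a$y, a$z)
    box[i, ] <- frames[[i]]$box
    times[i] <- frames[[i]]$time
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  if (any(diff(times) <= 0))
    stop_splitmem("frame times must be strictly increasing")
  structure(list(coords = coords, box = box, times = times,
                 atoms = frames[[1L]]$atoms[, c("resid", "resname", "name")],
                 molecules = frames[[1L]]$molecules,
                 title = frames[[1L]]$title),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, t = %g..%g ns\n",
              n_frames(x), nrow(x$atoms), x$times[1L],
              x$times[length(x$times)]))
  invisible(x)
}

#' @rdname as_trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame of a trajectory as a `system_frame`
#' @param traj a `trajectory`.
#' @param i frame number (1-based).
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  atoms <- traj$atoms
  atoms$x <- traj$coords[, 1L, i]
  atoms$y <- traj$coords[, 2L, i]
  atoms$z <- traj$coords[, 3L, i]
  system_frame(atoms, traj$box[i, ], time = traj$times[i], title = traj$title)
}

# coerce frame-or-trajectory to trajectory
as_traj_input <- function(x) {
  if (inherits(x, "trajectory")) x else as_trajectory(x)
}

# species names treated as membrane lipids by default (incl. split moieties)
LIPID_SPECIES <- c("POPC", "POPS", "POPE", "POPA", "PSM", "CHL",
                   "POPCH", "POPCT", "POPSH", "POPST", "POPEH", "POPET",
                   "POPAH", "POPAT", "PSMH", "PSMT")

default_lipid_selection <- function(atoms) {
  which(atoms$resname %in% LIPID_SPECIES)
}

#' Mass-weighted membrane centre of mass along z
#'
#' @param frame a `system_frame`.
#' @param lipid_selection atom selection defining the membrane (indices,
#'   logical mask, or `list(resname=, name=)`); defaults to all atoms whose
#'   residue name is a known lipid or split-moiety species.
#' @param masses numeric per-atom masses (amu) for the whole frame; by
#'   default inferred from the leading element letter of each atom name.
#' @return z coordinate of the membrane COM, nm.
#' @export
membrane_com <- function(frame, lipid_selection = NULL, masses = NULL) {
  atoms <- frame$atoms
  idx <- if (is.null(lipid_selection)) default_lipid_selection(atoms)
         else resolve_selection(atoms, lipid_selection)
  if (length(idx) == 0L) stop_splitmem("membrane selection is empty")
  m <- if (is.null(masses)) guess_mass(atoms$name[idx]) else masses[idx]
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0)
    stop_splitmem("zero total mass in membrane selection")
  sum(m * atoms$z[idx]) / tot
}

#' Assign lipids to upper/lower leaflets
#'
#' Each lipid (or split moiety) is labelled by the sign of
#' `z(anchor) - z(membrane COM)`. A lipid whose anchor sits exactly at the
#' COM is assigned `upper` and a warning is emitted.
#'
#' @param frame a `system_frame`.
#' @param anchor_atom_names named character vector, species -> anchor atom
#'   name. Default anchors: `P` for whole lipids and split heads, `C2` for
#'   split tails, `O3` for cholesterol.
#' @param lipid_selection membrane selection for the COM (see
#'   [membrane_com()]).
#' @return data.frame with `molid`, `species`, `leaflet` (factor
#'   upper/lower) for every lipid molecule; membrane COM in attribute
#'   `"z_com"`.
#' @export
assign_leaflets <- function(frame, anchor_atom_names = NULL,
                            lipid_selection = NULL) {
  anchors <- default_anchor_names()
  if (!is.null(anchor_atom_names))
    anchors[names(anchor_atom_names)] <- anchor_atom_names
  mols <- frame$molecules
  lip <- mols[mols$species %in% union(LIPID_SPECIES, names(anchors)), ,
              drop = FALSE]
  if (nrow(lip) == 0L) stop_splitmem("frame contains no lipid molecules")
  zc <- membrane_com(frame, lipid_selection)
  atoms <- frame$atoms
  zanchor <- numeric(nrow(lip))
  for (i in seq_len(nrow(lip))) {
    sp <- lip$species[i]
    an <- anchors[sp]
    if (is.na(an))
      stop_splitmem("no anchor atom declared for species ", sp)
    rng <- lip$first[i]:(lip$first[i] + lip$n[i] - 1L)
    hit <- rng[atoms$name[rng] == an]
    if (length(hit) != 1L)
      stop_splitmem("anchor atom ", an, " not found exactly once in ",
                    sp, " molecule ", lip$molid[i])
    zanchor[i] <- atoms$z[hit]
  }
  dz <- zanchor - zc
  if (any(dz == 0))
    warning("lipid anchor exactly at membrane COM: assigned to upper leaflet")
  res <- data.frame(molid = lip$molid, species = lip$species,
                    leaflet = factor(ifelse(dz >= 0, "upper", "lower"),
                                     levels = c("upper", "lower")),
                    z_anchor = zanchor,
                    stringsAsFactors = FALSE)
  attr(res, "z_com") <- zc
  res
}

default_anchor_names <- function() {
  a <- c(POPC = "P", POPS = "P", POPE = "P", POPA = "P", PSM = "P",
         CHL = "O3")
  heads <- paste0(c("POPC", "POPS", "POPE", "POPA", "PSM"), "H")
  tails <- paste0(c("POPC", "POPS", "POPE", "POPA", "PSM"), "T")
  a[heads] <- "P"
  a[tails] <- "C2"
  a
}

#' Validated per-leaflet membrane composition
#'
#' @param counts named integer vector or list, species -> lipids per leaflet.
#' @param declared_total expected sum over species (per leaflet); if the
#'   counts do not add up the error reports the difference.
#' @return Object of class `membrane_composition` (named integer vector with
#'   a `total` attribute).
#' @export
composition_from_counts <- function(counts, declared_total) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop_splitmem("composition counts must be named by species")
  if (any(counts < 0)) stop_splitmem("composition counts must be >= 0")
  s <- sum(counts)
  if (s != declared_total)
    stop_splitmem(sprintf(
      "composition sums to %d, declared total is %d (difference %+d)",
      s, declared_total, s - declared_total))
  structure(as.integer(counts), names = names(counts),
            total = as.integer(declared_total),
            class = "membrane_composition")
}
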