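#' Synthetic-data generators
#'
#' Deterministic toy bilayers, Brownian lateral-diffusion trajectories and
#' ideal all-trans chains, so every operation in the toolkit is testable
#' without running molecular dynamics. All generators are pure functions of
#' their arguments and seed.
#'
#' @name fixtures
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# all-trans zigzag geometry constants: C-C 0.153 nm, angle 109.47 deg
CC_BOND <- 0.153
TETRA_DEG <- 109.47

zigzag_offsets <- function(n) {
  th <- TETRA_DEG * pi / 180
  b <- CC_BOND * sin(th / 2)            # axis step
  a <- CC_BOND * cos(th / 2) / 2        # alternating perpendicular offset
  cbind(x = a * (-1)^(seq_len(n) - 1L), y = 0, z = -b * (seq_len(n) - 1L))
}

# template coordinates for one upper-leaflet lipid, P at the origin,
# tails pointing towards negative z (the midplane)
fixture_lipid_template <- function(species) {
  topo <- fixture_topology(species)
  nm <- topo$atoms$atom
  pos <- matrix(NA_real_, nrow = length(nm), ncol = 3L,
                dimnames = list(nm, c("x", "y", "z")))
  setpos <- function(name, x, y, z) pos[name, ] <<- c(x, y, z)
  if (species != "POPA") {
    setpos("N", 0.20, 0, 0)            # P->N in-plane
    setpos("C13", 0.28, 0.07, 0.02); setpos("C14", 0.28, -0.07, 0.02)
    setpos("C15", 0.34, 0, -0.05)
    setpos("C12", 0.14, 0.05, -0.04); setpos("C11", 0.08, -0.04, 0.05)
    setpos("O12", 0.04, -0.02, -0.04)
    setpos("H11A", 0.10, -0.10, 0.10); setpos("H11B", 0.03, -0.08, 0.12)
    setpos("H12A", 0.17, 0.11, -0.09); setpos("H12B", 0.10, 0.10, 0.02)
    setpos("H13A", 0.33, 0.12, 0.06); setpos("H14A", 0.33, -0.12, 0.06)
    setpos("H15A", 0.40, 0.04, -0.09)
  } else {
    setpos("O12", 0.06, -0.03, 0.05)
    setpos("H13A", 0.02, 0.13, 0.10)
  }
  setpos("P", 0, 0, 0)
  setpos("O13", -0.05, 0.06, 0.06); setpos("O14", -0.08, -0.06, 0.03)
  setpos("O11", 0, 0, -0.14)
  setpos("C1", 0, 0, -0.25)
  setpos("H1A", -0.09, 0.03, -0.28)
  # tail: C2 continues the zigzag from C1
  setpos("C2", 0.0883, 0, -0.375)
  setpos("C3", 0.02, 0.09, -0.45)
  setpos("O21", 0.16, -0.08, -0.43); setpos("C21", 0.14, -0.06, -0.55)
  setpos("O22", 0.06, -0.10, -0.61)
  setpos("O31", 0.02, 0.12, -0.58); setpos("C31", -0.06, 0.19, -0.63)
  setpos("O32", -0.15, 0.24, -0.58)
  zz <- zigzag_offsets(12L)
  for (i in 2:13) {
    pos[sprintf("C2%d", i), ] <- c(0.12, -0.05, -0.62) + zz[i - 1L, ]
    pos[sprintf("C3%d", i), ] <- c(-0.10, 0.16, -0.70) + zz[i - 1L, ]
  }
  if (anyNA(pos)) stop_splitmem("template incomplete for ", species)
  pos
}

fixture_chl_template <- function() {
  topo <- fixture_topology("CHL")
  nm <- topo$atoms$atom
  z <- c(0, 0.06, -0.10, -0.25, -0.40, -0.60, -0.80, -1.00)
  cbind(x = c(0, 0.05, 0.03, -0.03, 0.03, -0.03, 0.03, -0.03),
        y = 0, z = z)
}

#' Build a deterministic toy bilayer
#'
#' Lipids are placed on a square lattice at the target area per lipid with
#' idealized all-trans tails pointing to the midplane, phosphorus atoms on
#' the two head planes at `+/- head_offset` from the midplane, in-plane
#' P->N vectors, and a water slab above and below (water oxygen plus two
#' dummy hydrogens). The frame is centred at `z = Lz/2`. Species are mixed
#' over the lattice with a seeded shuffle; a fixed seed gives byte-identical
#' output.
#'
#' @param composition named per-leaflet lipid counts (species -> count),
#'   e.g. `c(POPC = 64)`; see [composition_from_counts()].
#' @param apl target area per lipid, nm^2 (box side = `sqrt(n * apl)`).
#' @param head_offset distance of the P planes from the midplane, nm;
#'   bilayer thickness measured on P atoms equals `2 * head_offset`.
#' @param waters_per_lipid water molecules per lipid (total, split evenly
#'   between the two slabs).
#' @param box_z box height, nm; default `2 * head_offset + 2.4`.
#' @param neutralize add Na+ counterions to cancel net lipid charge.
#' @param seed RNG seed for the lattice shuffle.
#' @return list with `frame` (a `system_frame`) and `topologies` (named
#'   list of [molecule_topology()] for every species present).
#' @export
build_bilayer <- function(composition = c(POPC = 64), apl = 0.658,
                          head_offset = 1.9, waters_per_lipid = 6,
                          box_z = NULL, neutralize = TRUE, seed = 1L) {
  composition <- composition[composition > 0]
  if (!length(composition) || any(composition <= 0))
    stop_splitmem("composition counts must be positive")
  n <- sum(composition)
  L <- sqrt(n * apl)
  nside <- ceiling(sqrt(n))
  spacing <- L / nside
  if (nside * nside < n)
    stop_splitmem("lattice cannot host ", n, " lipids")
  box_z <- box_z %||% (2 * head_offset + 2.4)
  zmid <- box_z / 2
  species_order <- names(composition)
  topo_species <- unique(c(species_order, "SOL"))
  lipid_seq <- with_seed(seed, {
    list(upper = sample(rep(species_order, composition)),
         lower = sample(rep(species_order, composition)))
  })
  templates <- setNames(lapply(species_order, function(sp)
    if (sp == "CHL") fixture_chl_template() else fixture_lipid_template(sp)),
    species_order)
  topos <- setNames(lapply(topo_species, fixture_topology), topo_species)

  blocks <- list(); resid <- 0L
  add_mol <- function(sp, coords) {
    resid <<- resid + 1L
    blocks[[length(blocks) + 1L]] <<- data.frame(
      resid = resid, resname = sp, name = rownames(coords) %||%
        topos[[sp]]$atoms$atom,
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE)
  }
  place_leaflet <- function(seq_sp, sign) {
    for (i in seq_along(seq_sp)) {
      sp <- seq_sp[i]
      ix <- (i - 1L) %% nside
      iy <- (i - 1L) %/% nside
      tmpl <- templates[[sp]]
      xyz <- tmpl
      xyz[, 3L] <- sign * (tmpl[, 3L] + head_offset) + zmid
      xyz[, 1L] <- tmpl[, 1L] + (ix + 0.5) * spacing
      xyz[, 2L] <- tmpl[, 2L] + (iy + 0.5) * spacing
      rownames(xyz) <- topos[[sp]]$atoms$atom
      add_mol(sp, xyz)
    }
  }
  place_leaflet(lipid_seq$upper, +1)
  place_leaflet(lipid_seq$lower, -1)

  # water slabs above/below the membrane
  nw <- round(waters_per_lipid * 2 * n)   # both leaflets' lipids counted
  nw_slab <- ceiling(nw / 2)
  slab_lo <- zmid + head_offset + 0.35
  slab_hi <- box_z - 0.15
  place_waters <- function(nw_slab, zlo, zhi) {
    if (nw_slab <= 0L) return()
    nxy <- ceiling(sqrt(nw_slab / max(1, floor((zhi - zlo) / 0.31))))
    nz <- ceiling(nw_slab / (nxy * nxy))
    k <- 0L
    for (iz in seq_len(nz)) for (iy in seq_len(nxy)) for (ix in seq_len(nxy)) {
      if (k >= nw_slab) return()
      k <- k + 1L
      o <- c((ix - 0.5) * L / nxy, (iy - 0.5) * L / nxy,
             zlo + (iz - 0.5) * (zhi - zlo) / nz)
      xyz <- rbind(OW = o, HW1 = o + c(0.08, 0, 0.06),
                   HW2 = o + c(-0.08, 0, 0.06))
      add_mol("SOL", xyz)
    }
  }
  place_waters(nw_slab, slab_lo, slab_hi)
  place_waters(nw - nw_slab, 0.15, zmid - head_offset - 0.35)

  # counterions in the upper water region
  if (neutralize) {
    qlip <- sum(vapply(c(lipid_seq$upper, lipid_seq$lower),
                       function(sp) total_charge(topos[[sp]]), 0.0))
    nna <- as.integer(round(-qlip))
    if (nna > 0L) {
      topos[["NA"]] <- fixture_topology("NA")
      for (i in seq_len(nna))
        add_mol("NA", matrix(c(0.25 + (i - 1L) * 0.35 %% L, 0.25,
                               box_z - 0.3), 1, 3,
                             dimnames = list("NA", NULL)))
    } else if (nna < 0L) {
      topos[["CL"]] <- fixture_topology("CL")
      for (i in seq_len(-nna))
        add_mol("CL", matrix(c(0.25 + (i - 1L) * 0.35 %% L, 0.25,
                               box_z - 0.3), 1, 3,
                             dimnames = list("CL", NULL)))
    }
  }

  atoms <- do.call(rbind, blocks)
  frame <- system_frame(atoms, c(L, L, box_z), time = 0,
                        title = "splitmem fixture bilayer")
  list(frame = frame, topologies = topos,
       composition = composition, apl = apl, head_offset = head_offset,
       seed = seed)
}

#' Brownian lateral-diffusion trajectory
#'
#' Each particle performs an independent 2D random walk in xy with per-step
#' displacements drawn from a Gaussian with variance `2 * D_target * dt`
#' per axis; z is fixed at mid-box. Positions are wrapped into the box; the
#' true unwrapped coordinates are kept in the `unwrapped` attribute of the
#' returned trajectory. This is the closed-form oracle for the Einstein
#' relation machinery: the expected lateral MSD is exactly
#' `4 * D_target * tau`.
#'
#' @param n_particles number of particles (one single-atom molecule each).
#' @param D_target lateral diffusion coefficient, nm^2/ns.
#' @param dt frame spacing, ns.
#' @param n_frames number of frames.
#' @param box numeric length-3 box, nm.
#' @param seed RNG seed.
#' @return A `trajectory`.
#' @export
brownian_trajectory <- function(n_particles = 500, D_target = 0.05,
                                dt = 0.1, n_frames = 2000,
                                box = c(12, 12, 6), seed = 42L) {
  stopifnot(n_particles > 0, D_target >= 0, dt > 0, n_frames >= 2)
  box <- as.numeric(box)
  sd_step <- sqrt(2 * D_target * dt)
  row_cumsum <- function(m) if (ncol(m) == 1L) m else t(apply(m, 1L, cumsum))
  pos <- with_seed(seed, {
    x0 <- runif(n_particles, 0, box[1L])
    y0 <- runif(n_particles, 0, box[2L])
    dx <- matrix(rnorm(n_particles * (n_frames - 1L), sd = sd_step),
                 nrow = n_particles)
    dy <- matrix(rnorm(n_particles * (n_frames - 1L), sd = sd_step),
                 nrow = n_particles)
    list(x = cbind(x0, x0 + row_cumsum(dx)),
         y = cbind(y0, y0 + row_cumsum(dy)))
  })
  coords <- array(0, dim = c(n_particles, 3L, n_frames))
  unwrapped <- coords
  for (i in seq_len(n_frames)) {
    unwrapped[, 1L, i] <- pos$x[, i]
    unwrapped[, 2L, i] <- pos$y[, i]
    unwrapped[, 3L, i] <- box[3L] / 2
    coords[, 1L, i] <- wrap_coord(pos$x[, i], box[1L])
    coords[, 2L, i] <- wrap_coord(pos$y[, i], box[2L])
    coords[, 3L, i] <- box[3L] / 2
  }
  traj <- structure(list(
    coords = coords,
    box = matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE),
    times = (seq_len(n_frames) - 1L) * dt,
    atoms = data.frame(resid = seq_len(n_particles), resname = "BRW",
                       name = "P1", stringsAsFactors = FALSE),
    molecules = data.frame(molid = seq_len(n_particles), species = "BRW",
                           first = seq_len(n_particles), n = 1L,
                           stringsAsFactors = FALSE),
    title = "splitmem brownian fixture"), class = "trajectory")
  attr(traj, "unwrapped") <- unwrapped
  traj
}

#' Ideal all-trans chain with reconstructed hydrogens
#'
#' Carbons form an all-trans zigzag with 109.47 degree angles and 0.153 nm
#' C-C bonds along the given orientation; two ideal tetrahedral hydrogens
#' are attached to every interior carbon.
#'
#' @param n_carbons chain length (>= 3).
#' @param orientation chain axis direction (length-3), default +z.
#' @param origin position of the first carbon.
#' @return list with `carbons` (n x 3 matrix, rownames C1..Cn) and
#'   `hydrogens` (named list, carbon -> 2 x 3 matrix).
#' @export
ideal_chain <- function(n_carbons = 12L, orientation = c(0, 0, 1),
                        origin = c(0, 0, 0)) {
  stopifnot(n_carbons >= 3L)
  zz <- zigzag_offsets(n_carbons)
  carbons <- cbind(zz[, 1L], zz[, 2L], -zz[, 3L])  # grow along +z
  rot <- rotation_to(c(0, 0, 1), orientation)
  carbons <- carbons %*% t(rot)
  carbons <- sweep(carbons, 2L, origin, `+`)
  rownames(carbons) <- sprintf("C%d", seq_len(n_carbons))
  hyd <- list()
  for (i in 2:(n_carbons - 1L)) {
    h <- reconstruct_hydrogens(carbons[i - 1L, ], carbons[i, ],
                               carbons[i + 1L, ])
    hyd[[sprintf("C%d", i)]] <- h
  }
  list(carbons = carbons, hydrogens = hyd)
}

# rotation matrix taking unit(a) onto unit(b)
rotation_to <- function(a, b) {
  a <- a / vec_norm(a); b <- b / vec_norm(b)
  v <- vec_cross(a, b); c_ <- sum(a * b)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite direction: rotate pi about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) vec_cross(a, c(1, 0, 0)) else vec_cross(a, c(0, 1, 0))
    p <- p / vec_norm(p)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# ideal tetrahedral H positions on a methylene carbon given its two
# bonded carbon neighbours; C-H bond 0.109 nm
reconstruct_hydrogens <- function(rprev, rc, rnext, ch_bond = 0.109) {
  a <- rprev - rc; a <- a / vec_norm(a)
  b <- rnext - rc; b <- b / vec_norm(b)
  u <- -(a + b)
  nu <- vec_norm(u)
  if (nu < 1e-10)
    stop_splitmem("collinear carbon neighbours: cannot reconstruct hydrogens")
  u <- u / nu
  w <- vec_cross(a, b); w <- w / vec_norm(w)
  half <- (TETRA_DEG / 2) * pi / 180
  h1 <- rc + ch_bond * (u * cos(half) + w * sin(half))
  h2 <- rc + ch_bond * (u * cos(half) - w * sin(half))
  rbind(h1, h2)
}
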