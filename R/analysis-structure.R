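# Structural validation observables: density profiles, acyl-chain order
# parameters, P-N angle, area per lipid, thickness, RDF.

# build a (resname, atom name) -> mass lookup from topologies, falling back
# to element guessing
mass_lookup <- function(atoms, topologies = NULL) {
  m <- guess_mass(atoms$name)
  if (!is.null(topologies)) {
    for (topo in topologies) {
      key <- atoms$resname == topo$name
      if (!any(key)) next
      mm <- setNames(topo$atoms$mass, topo$atoms$atom)
      hit <- key & atoms$name %in% names(mm)
      m[hit] <- mm[atoms$name[hit]]
    }
  }
  m
}

#' Mass density profile along the bilayer normal
#'
#' Per frame, the z coordinates of each selection are re-centred on the
#' membrane centre of mass, histogrammed with the given bin width, and
#' converted to kg/m^3 via the bin volume `Lx * Ly * bin_width`; profiles
#' are averaged over frames.
#'
#' @param x `system_frame` or `trajectory`.
#' @param selections named list of atom selections (see [membrane_com()]).
#' @param bin_width bin width, nm.
#' @param topologies optional topologies for exact masses.
#' @param lipid_selection membrane selection used for the COM centring.
#' @return Object of class `density_profile`: data.frame with `z` (bin
#'   centres, nm, relative to the membrane COM) and one density column per
#'   selection (kg/m^3).
#' @export
density_profile <- function(x, selections, bin_width = 0.1,
                            topologies = NULL, lipid_selection = NULL) {
  stopifnot(bin_width > 0)
  traj <- as_traj_input(x)
  masses <- mass_lookup(traj$atoms, topologies)
  sel_idx <- lapply(selections, function(s)
    resolve_selection(traj$atoms, s))
  if (any(lengths(sel_idx) == 0L))
    stop_splitmem("empty selection in density_profile: ",
                  paste(names(selections)[lengths(sel_idx) == 0L],
                        collapse = ", "))
  half <- max(traj$box[, 3L]) / 2
  edges <- seq(-half, half, by = bin_width)
  if (edges[length(edges)] < half) edges <- c(edges, edges[length(edges)] + bin_width)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  acc <- matrix(0, nrow = length(centers), ncol = length(selections))
  nf <- n_frames(traj)
  for (i in seq_len(nf)) {
    fr <- traj_frame(traj, i)
    zc <- membrane_com(fr, lipid_selection, masses = masses)
    vol <- fr$box[1L] * fr$box[2L] * bin_width
    for (s in seq_along(sel_idx)) {
      idx <- sel_idx[[s]]
      dz <- min_image(fr$atoms$z[idx] - zc, fr$box[3L])
      dz <- pmin(pmax(dz, edges[1L] + 1e-12), edges[length(edges)] - 1e-12)
      bin <- findInterval(dz, edges, rightmost.closed = TRUE)
      agg <- rowsum(masses[idx], bin)
      sums <- numeric(length(centers))
      sums[as.integer(rownames(agg))] <- agg[, 1L]
      acc[, s] <- acc[, s] + sums / vol
    }
  }
  dens <- acc / nf * AMU_PER_NM3_TO_KG_M3
  out <- data.frame(z = centers)
  for (s in seq_along(selections)) out[[names(selections)[s]]] <- dens[, s]
  structure(out, class = c("density_profile", "data.frame"),
            bin_width = bin_width)
}

#' Acyl-chain deuterium order parameters
#'
#' `S_CD(i) = <(3 cos^2 theta - 1) / 2>` with theta the angle between each
#' C_i-H vector and the bilayer normal (+z), averaged over lipids, frames
#' and the hydrogens of each carbon. `hydrogen_mode = "reconstructed"`
#' builds ideal tetrahedral hydrogens from the C_(i-1), C_i, C_(i+1)
#' positions (only interior carbons are reported); `"explicit"` uses real
#' hydrogen atoms named in the chain definitions.
#'
#' @param x `system_frame` or `trajectory`.
#' @param chain_definitions named list: species -> list of chains, each a
#'   character vector of carbon names in chain order (e.g.
#'   `list(SN1 = c("C32", ...), SN2 = c("C22", ...))`); for explicit mode
#'   add a `hydrogens` element mapping carbon name -> hydrogen names.
#' @param hydrogen_mode `"reconstructed"` or `"explicit"`.
#' @param normal bilayer normal, default `+z`.
#' @return data.frame `species`, `chain`, `index` (carbon position in the
#'   declared sequence), `carbon`, `scd`.
#' @export
order_parameters <- function(x, chain_definitions = default_chain_definitions(),
                             hydrogen_mode = c("reconstructed", "explicit"),
                             normal = c(0, 0, 1)) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  traj <- as_traj_input(x)
  normal <- normal / vec_norm(normal)
  mols <- traj$molecules
  out <- list()
  for (sp in names(chain_definitions)) {
    cd <- chain_definitions[[sp]]
    chains <- cd[setdiff(names(cd), "hydrogens")]
    smols <- mols[mols$species == sp, , drop = FALSE]
    if (nrow(smols) == 0L) next
    for (ch in names(chains)) {
      carbons <- chains[[ch]]
      # resolve atom rows per molecule once
      rows <- matrix(NA_integer_, nrow = nrow(smols), ncol = length(carbons))
      for (mi in seq_len(nrow(smols))) {
        rng <- smols$first[mi]:(smols$first[mi] + smols$n[mi] - 1L)
        hit <- match(carbons, traj$atoms$name[rng])
        if (anyNA(hit))
          stop_splitmem("carbon ", paste(carbons[is.na(hit)], collapse = ","),
                        " missing in ", sp, " molecule ", smols$molid[mi])
        rows[mi, ] <- rng[hit]
      }
      idx_range <- if (hydrogen_mode == "reconstructed")
        2:(length(carbons) - 1L) else seq_along(carbons)
      sums <- numeric(length(carbons)); counts <- numeric(length(carbons))
      for (f in seq_len(n_frames(traj))) {
        co <- traj$coords[, , f]
        for (mi in seq_len(nrow(smols))) {
          for (ci in idx_range) {
            rc <- co[rows[mi, ci], ]
            if (hydrogen_mode == "reconstructed") {
              H <- reconstruct_hydrogens(co[rows[mi, ci - 1L], ], rc,
                                         co[rows[mi, ci + 1L], ])
            } else {
              hn <- cd$hydrogens[[carbons[ci]]]
              if (is.null(hn)) next
              rng <- smols$first[mi]:(smols$first[mi] + smols$n[mi] - 1L)
              hrow <- rng[match(hn, traj$atoms$name[rng])]
              if (anyNA(hrow))
                stop_splitmem("hydrogen ", paste(hn, collapse = ","),
                              " missing in ", sp, " molecule ",
                              smols$molid[mi])
              H <- co[hrow, , drop = FALSE]
            }
            ch_vec <- sweep(H, 2L, rc)
            cth <- (ch_vec %*% normal) /
              sqrt(rowSums(ch_vec * ch_vec))
            sums[ci] <- sums[ci] + sum((3 * cth^2 - 1) / 2)
            counts[ci] <- counts[ci] + length(cth)
          }
        }
      }
      keep <- counts > 0
      out[[length(out) + 1L]] <- data.frame(
        species = sp, chain = ch, index = which(keep),
        carbon = carbons[keep], scd = sums[keep] / counts[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop_splitmem("no declared chains present in the system")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("order_parameter_profile", "data.frame"))
}

#' Default fixture chain definitions (SN1 = C32..C313, SN2 = C22..C213)
#' @param species species to cover.
#' @export
default_chain_definitions <- function(species = c(FIXTURE_PHOSPHOLIPIDS,
                                                  paste0(substr(FIXTURE_PHOSPHOLIPIDS, 1, 4), "T"))) {
  def <- list(SN1 = sprintf("C3%d", 2:13), SN2 = sprintf("C2%d", 2:13))
  setNames(rep(list(def), length(species)), species)
}

#' Headgroup P-N angle
#'
#' Angle between the P -> N vector of each lipid and the outward normal of
#' its leaflet (+z for the upper leaflet, -z for the lower), in degrees.
#' An in-plane P-N vector scores 90 degrees in both leaflets. Species
#' without a nitrogen (e.g. phosphatidic acid) are skipped with a warning.
#'
#' @param x `system_frame` or `trajectory`.
#' @param leaflets optional leaflet assignment (recomputed per frame by
#'   default).
#' @return list with `angles` (data.frame `frame`, `molid`, `species`,
#'   `leaflet`, `angle_deg`) and `mean` (degrees).
#' @export
pn_angle <- function(x, leaflets = NULL) {
  traj <- as_traj_input(x)
  mols <- traj$molecules
  lip <- mols[mols$species %in% LIPID_SPECIES, , drop = FALSE]
  if (!nrow(lip)) stop_splitmem("no lipid molecules found")
  has_pn <- logical(nrow(lip))
  prow <- integer(nrow(lip))
  nrowv <- integer(nrow(lip))
  skipped <- character()
  for (i in seq_len(nrow(lip))) {
    rng <- lip$first[i]:(lip$first[i] + lip$n[i] - 1L)
    p <- rng[traj$atoms$name[rng] == "P"]
    n <- rng[traj$atoms$name[rng] == "N"]
    if (length(p) == 1L && length(n) == 1L) {
      has_pn[i] <- TRUE; prow[i] <- p; nrowv[i] <- n
    } else skipped <- c(skipped, lip$species[i])
  }
  if (length(skipped))
    warning("species without P-N pair skipped: ",
            paste(unique(skipped), collapse = ", "))
  if (!any(has_pn)) stop_splitmem("no lipid carries both P and N atoms")
  res <- list()
  for (f in seq_len(n_frames(traj))) {
    fr <- traj_frame(traj, f)
    lf <- if (is.null(leaflets)) assign_leaflets(fr) else leaflets
    lab <- setNames(as.character(lf$leaflet), lf$molid)
    co <- traj$coords[, , f]
    v <- co[nrowv[has_pn], , drop = FALSE] - co[prow[has_pn], , drop = FALSE]
    vn <- sqrt(rowSums(v * v))
    out_sign <- ifelse(lab[as.character(lip$molid[has_pn])] == "upper", 1, -1)
    cth <- (v[, 3L] / vn) * out_sign
    cth <- pmin(pmax(cth, -1), 1)
    res[[f]] <- data.frame(frame = f, molid = lip$molid[has_pn],
                           species = lip$species[has_pn],
                           leaflet = lab[as.character(lip$molid[has_pn])],
                           angle_deg = acos(cth) * 180 / pi,
                           stringsAsFactors = FALSE)
  }
  angles <- do.call(rbind, res)
  rownames(angles) <- NULL
  list(angles = angles, mean = mean(angles$angle_deg))
}

#' Area per lipid
#'
#' Per frame, the xy box area divided by the number of lipids per leaflet.
#'
#' @param x `system_frame` or `trajectory`.
#' @param n_per_leaflet lipids per leaflet (> 0).
#' @return list with `series` (data.frame `time`, `apl` nm^2), `mean` and
#'   `se` (standard error of the frame mean).
#' @export
area_per_lipid <- function(x, n_per_leaflet) {
  if (n_per_leaflet <= 0) stop_splitmem("n_per_leaflet must be > 0")
  traj <- as_traj_input(x)
  apl <- traj$box[, 1L] * traj$box[, 2L] / n_per_leaflet
  list(series = data.frame(time = traj$times, apl = apl),
       mean = mean(apl),
       se = stats::sd(apl) / sqrt(length(apl)))
}

#' Bilayer thickness from reference atoms
#'
#' Per frame, `|mean z(upper references) - mean z(lower references)|`,
#' with references split by the sign of their z relative to the membrane
#' COM.
#'
#' @param x `system_frame` or `trajectory`.
#' @param reference_atom_names atom names used as references (e.g. `"P"`,
#'   `c("P", "N")`, or `"C2"`).
#' @param lipid_selection membrane selection for the COM.
#' @return data.frame `time`, `thickness` (nm).
#' @export
thickness <- function(x, reference_atom_names = "P", lipid_selection = NULL) {
  traj <- as_traj_input(x)
  lip <- default_lipid_selection(traj$atoms)
  ref <- intersect(which(traj$atoms$name %in% reference_atom_names), lip)
  if (!length(ref)) stop_splitmem("no reference atoms found")
  th <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fr <- traj_frame(traj, f)
    zc <- membrane_com(fr, lipid_selection)
    z <- fr$atoms$z[ref]
    up <- z >= zc
    if (!any(up) || all(up))
      stop_splitmem("reference atoms found in only one leaflet")
    th[f] <- abs(mean(z[up]) - mean(z[!up]))
  }
  data.frame(time = traj$times, thickness = th)
}

#' Radial distribution function
#'
#' Standard pair-distance histogram between two selections normalized by
#' the ideal-gas expectation: spherical shells for `mode = "3D"`
#' (minimum-image distances in all three dimensions), annuli for
#' `mode = "lateral_2D"` (xy distances only).
#'
#' @param x `system_frame` or `trajectory`.
#' @param sel_A,sel_B atom selections.
#' @param r_max maximum distance, nm; must not exceed half the smallest
#'   relevant box dimension.
#' @param dr bin width, nm.
#' @param mode `"3D"` or `"lateral_2D"`.
#' @return data.frame `r` (bin centres), `g`; raw pair counts in attribute
#'   `"counts"`.
#' @export
rdf <- function(x, sel_A, sel_B, r_max, dr = 0.02,
                mode = c("3D", "lateral_2D")) {
  mode <- match.arg(mode)
  traj <- as_traj_input(x)
  iA <- resolve_selection(traj$atoms, sel_A)
  iB <- resolve_selection(traj$atoms, sel_B)
  if (!length(iA) || !length(iB)) stop_splitmem("empty RDF selection")
  box_min <- if (mode == "3D") min(traj$box) else min(traj$box[, 1:2])
  if (r_max > box_min / 2 + 1e-9)
    stop_splitmem("r_max exceeds half the smallest box dimension (",
                  format(box_min / 2), " nm)")
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  counts <- numeric(length(centers))
  same <- identical(sort(iA), sort(iB))
  nf <- n_frames(traj)
  vol_acc <- 0
  for (f in seq_len(nf)) {
    co <- traj$coords[, , f]
    b <- traj$box[f, ]
    dx <- min_image(outer(co[iA, 1L], co[iB, 1L], `-`), b[1L])
    dy <- min_image(outer(co[iA, 2L], co[iB, 2L], `-`), b[2L])
    d2 <- dx^2 + dy^2
    if (mode == "3D") {
      dz <- min_image(outer(co[iA, 3L], co[iB, 3L], `-`), b[3L])
      d2 <- d2 + dz^2
    }
    d <- sqrt(d2)
    if (same) d[cbind(seq_along(iA), seq_along(iB))] <- Inf
    d <- d[d < r_max]
    if (length(d)) {
      bin <- findInterval(d, edges, rightmost.closed = TRUE)
      tb <- tabulate(bin, nbins = length(centers))
      counts <- counts + tb
    }
    vol_acc <- vol_acc + if (mode == "3D") prod(b) else b[1L] * b[2L]
  }
  nB_eff <- if (same) length(iB) - 1L else length(iB)
  mean_vol <- vol_acc / nf
  rho <- nB_eff / mean_vol
  shell <- if (mode == "3D")
    4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  else pi * (edges[-1L]^2 - edges[-length(edges)]^2)
  g <- counts / (nf * length(iA) * rho * shell)
  structure(data.frame(r = centers, g = g),
            class = c("rdf_profile", "data.frame"), counts = counts,
            mode = mode)
}
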