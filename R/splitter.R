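#' Declaration of how one lipid species is cut into head and tail
#'
#' The cut is the glycerol C1-C2 carbon-carbon bond: the head moiety keeps
#' the phosphate/choline fragment plus glycerol C1, the tail moiety keeps
#' the C2-bearing fragment with both acyl chains. Both cut ends are capped
#' by a massless, charge-free, non-interacting virtual site (V1 on the
#' head, V2 on the tail) bonded to the cut-side atom so the cut valence is
#' preserved. For sphingomyelin-like species without a glycerol the same
#' mechanism applies at the declared backbone bond.
#'
#' @param species lipid species name.
#' @param cut_bond length-2 character, `c(head_side, tail_side)` atom names.
#' @param head_atoms,tail_atoms disjoint atom-name sets covering the
#'   species' atoms.
#' @param head_anchor,tail_anchor anchor atom names used for restraints and
#'   merge-junction distances (default: the two cut-bond atoms).
#' @param head_resname,tail_resname residue names of the split moieties
#'   (<= 5 characters for GRO).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(species, cut_bond = c("C1", "C2"),
                       head_atoms, tail_atoms,
                       head_anchor = cut_bond[1L],
                       tail_anchor = cut_bond[2L],
                       head_resname = moiety_resname(species, "head"),
                       tail_resname = moiety_resname(species, "tail")) {
  head_atoms <- as.character(head_atoms)
  tail_atoms <- as.character(tail_atoms)
  if (length(intersect(head_atoms, tail_atoms)))
    stop_splitmem("head and tail atom sets overlap: ",
                  paste(intersect(head_atoms, tail_atoms), collapse = ", "))
  if (!cut_bond[1L] %in% head_atoms || !cut_bond[2L] %in% tail_atoms)
    stop_splitmem("cut bond endpoints must lie in head and tail sets")
  structure(list(species = species, cut_bond = cut_bond,
                 head_atoms = head_atoms, tail_atoms = tail_atoms,
                 head_anchor = head_anchor, tail_anchor = tail_anchor,
                 head_resname = head_resname, tail_resname = tail_resname),
            class = "split_spec")
}

#' @rdname split_spec
#' @param role `"head"` or `"tail"`.
#' @export
moiety_resname <- function(species, role) {
  paste0(substr(species, 1L, 4L), if (role == "head") "H" else "T")
}

#' Derive a split spec from molecular connectivity
#'
#' Removes the cut bond and partitions the atoms into the two connected
#' components of the bond graph; the component containing the head-side
#' cut atom becomes the head.
#'
#' @param topology a [molecule_topology()].
#' @param cut_bond `c(head_side, tail_side)` atom names.
#' @param ... passed to [split_spec()].
#' @export
derive_split_spec <- function(topology, cut_bond = c("C1", "C2"), ...) {
  nm <- topology$atoms$atom
  iH <- match(cut_bond[1L], nm)
  iT <- match(cut_bond[2L], nm)
  if (is.na(iH) || is.na(iT))
    stop_splitmem("cut bond atoms not found in ", topology$name, ": ",
                  paste(cut_bond[c(is.na(iH), is.na(iT))], collapse = ", "))
  b <- topology$bonds
  cut_row <- which((b$ai == iH & b$aj == iT) | (b$ai == iT & b$aj == iH))
  if (!length(cut_row))
    stop_splitmem("cut bond ", cut_bond[1L], "-", cut_bond[2L],
                  " absent from topology ", topology$name)
  adj <- lapply(seq_along(nm), function(i) integer())
  for (r in setdiff(seq_len(nrow(b)), cut_row)) {
    adj[[b$ai[r]]] <- c(adj[[b$ai[r]]], b$aj[r])
    adj[[b$aj[r]]] <- c(adj[[b$aj[r]]], b$ai[r])
  }
  comp <- function(start) {
    seen <- logical(length(nm)); queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    which(seen)
  }
  head_idx <- comp(iH)
  if (iT %in% head_idx)
    stop_splitmem("cut bond is not a bridge in ", topology$name,
                  ": head and tail are still connected")
  tail_idx <- setdiff(seq_along(nm), head_idx)
  split_spec(topology$name, cut_bond,
             head_atoms = nm[sort(head_idx)], tail_atoms = nm[sort(tail_idx)],
             ...)
}

#' Default split specs for the fixture lipid species
#' @param species character vector of phospholipid species.
#' @export
default_split_specs <- function(species = FIXTURE_PHOSPHOLIPIDS) {
  setNames(lapply(species, function(sp)
    derive_split_spec(fixture_topology(sp))), species)
}

#' Cut one lipid topology into head and tail moieties
#'
#' Every original atom lands in exactly one moiety with unchanged name,
#' mass, charge and type; the cut bond is removed; each moiety gains one
#' virtual site (`V1` on the head, `V2` on the tail: mass 0, charge 0,
#' non-interacting type `VS`) bonded to its cut-side atom with the cut
#' bond's original parameters. Bonded terms entirely inside one moiety are
#' kept; bonds, pairs, angles, dihedrals and exclusions spanning the cut
#' are dropped. Virtual-site geometric parameters are left `NA` until
#' fitted against a frame (see [split_system()]).
#'
#' @param topology a [molecule_topology()].
#' @param spec a [split_spec()].
#' @return list with `head` and `tail` [molecule_topology()] objects.
#' @export
split_lipid <- function(topology, spec) {
  nm <- topology$atoms$atom
  missing_names <- setdiff(c(spec$head_atoms, spec$tail_atoms), nm)
  if (length(missing_names))
    stop_splitmem("split spec names not found in ", topology$name, ": ",
                  paste(missing_names, collapse = ", "))
  if (!setequal(c(spec$head_atoms, spec$tail_atoms), nm))
    stop_splitmem("split spec does not cover all atoms of ", topology$name,
                  ": missing ",
                  paste(setdiff(nm, c(spec$head_atoms, spec$tail_atoms)),
                        collapse = ", "))
  iH <- match(spec$cut_bond[1L], nm)
  iT <- match(spec$cut_bond[2L], nm)
  b <- topology$bonds
  cut_row <- which((b$ai == iH & b$aj == iT) | (b$ai == iT & b$aj == iH))
  if (!length(cut_row))
    stop_splitmem("cut bond ", spec$cut_bond[1L], "-", spec$cut_bond[2L],
                  " absent from topology ", topology$name)
  cut_params <- b$params[cut_row[1L]]
  cut_funct <- b$funct[cut_row[1L]]

  make_moiety <- function(role) {
    keep_names <- if (role == "head") spec$head_atoms else spec$tail_atoms
    resname <- if (role == "head") spec$head_resname else spec$tail_resname
    vname <- if (role == "head") "V1" else "V2"
    cut_atom <- spec$cut_bond[if (role == "head") 1L else 2L]
    keep <- which(nm %in% keep_names)          # original order preserved
    newidx <- rep(NA_integer_, length(nm))
    newidx[keep] <- seq_along(keep)
    atoms <- topology$atoms[keep, , drop = FALSE]
    atoms$nr <- seq_len(nrow(atoms))
    atoms$cgnr <- seq_len(nrow(atoms))
    atoms$resname <- resname
    vs_nr <- nrow(atoms) + 1L
    atoms <- rbind(atoms, data.frame(
      nr = vs_nr, type = "VS", resnr = 1L, resname = resname,
      atom = vname, cgnr = vs_nr, charge = 0, mass = 0,
      stringsAsFactors = FALSE))
    remap <- function(tab, cols) {
      if (is.null(tab) || nrow(tab) == 0L) return(tab)
      inside <- rep(TRUE, nrow(tab))
      for (cc in cols) inside <- inside & !is.na(newidx[tab[[cc]]])
      tab <- tab[inside, , drop = FALSE]
      for (cc in cols) tab[[cc]] <- newidx[tab[[cc]]]
      rownames(tab) <- NULL
      tab
    }
    bonds <- remap(b[-cut_row, , drop = FALSE], c("ai", "aj"))
    cut_i <- match(cut_atom, atoms$atom)
    bonds <- rbind(bonds, data.frame(ai = cut_i, aj = vs_nr,
                                     funct = cut_funct, params = cut_params,
                                     stringsAsFactors = FALSE))
    # virtual-site construction: cut atom + its bonded neighbours inside
    # the moiety; 3-atom out-of-plane construction when possible, 2-atom
    # linear construction for terminal cuts
    nb <- unique(c(bonds$aj[bonds$ai == cut_i], bonds$ai[bonds$aj == cut_i]))
    nb <- sort(setdiff(nb, vs_nr))
    vs2 <- NULL; vs3 <- NULL
    if (length(nb) >= 2L) {
      vs3 <- data.frame(site = vs_nr, ai = cut_i, aj = nb[1L], ak = nb[2L],
                        funct = 4L, c1 = NA_real_, c2 = NA_real_,
                        c3 = NA_real_)
    } else if (length(nb) == 1L) {
      vs2 <- data.frame(site = vs_nr, ai = cut_i, aj = nb[1L], funct = 1L,
                        c1 = NA_real_)
    } else {
      stop_splitmem("cut atom ", cut_atom, " has no bonded neighbour in the ",
                    role, " moiety of ", topology$name)
    }
    molecule_topology(resname, atoms,
                      bonds = bonds,
                      pairs = remap(topology$pairs, c("ai", "aj")),
                      angles = remap(topology$angles, c("ai", "aj", "ak")),
                      dihedrals = remap(topology$dihedrals,
                                        c("ai", "aj", "ak", "al")),
                      exclusions = remap(topology$exclusions, c("ai", "aj")),
                      virtual_sites2 = vs2, virtual_sites3 = vs3,
                      nrexcl = topology$nrexcl)
  }
  list(head = make_moiety("head"), tail = make_moiety("tail"))
}

# ---- virtual-site geometry ----------------------------------------------

#' Place a virtual site from its constructing atoms
#'
#' 2-atom linear construction (`funct 1`): `r = ri + a (rj - ri)`.
#' 3-atom out-of-plane construction (`funct 4`):
#' `r = ri + a rij + b rik + c (rij x rik)`. The construction is exactly
#' equivariant under rigid rotation and translation of the moiety.
#'
#' @param coords n x 3 coordinate matrix of the moiety (row order = atom
#'   order in the moiety topology).
#' @param vsite one-row virtual-site table (from a split moiety topology).
#' @return length-3 position of the site, nm.
#' @export
place_virtual_site <- function(coords, vsite) {
  ri <- coords[vsite$ai, ]
  rj <- coords[vsite$aj, ]
  if (!is.null(vsite$ak) && !is.na(vsite$ak)) {
    rk <- coords[vsite$ak, ]
    rij <- rj - ri; rik <- rk - ri
    cr <- vec_cross(rij, rik)
    if (vec_norm(cr) < 1e-10)
      stop_splitmem("collinear constructing atoms for out-of-plane ",
                    "virtual-site construction")
    return(ri + vsite$c1 * rij + vsite$c2 * rik + vsite$c3 * cr)
  }
  ri + vsite$c1 * (rj - ri)
}

# fit construction parameters so the site lands on `target`
fit_vsite_params <- function(coords, vsite, target) {
  ri <- coords[vsite$ai, ]
  rj <- coords[vsite$aj, ]
  if (!is.null(vsite$ak) && !is.na(vsite$ak)) {
    rk <- coords[vsite$ak, ]
    rij <- rj - ri; rik <- rk - ri
    cr <- vec_cross(rij, rik)
    M <- cbind(rij, rik, cr)
    if (abs(det(M)) < 1e-12)
      stop_splitmem("collinear constructing atoms for out-of-plane ",
                    "virtual-site construction")
    p <- solve(M, target - ri)
    vsite$c1 <- p[1L]; vsite$c2 <- p[2L]; vsite$c3 <- p[3L]
  } else {
    rij <- rj - ri
    vsite$c1 <- sum((target - ri) * rij) / sum(rij * rij)
  }
  vsite
}

# ---- system-level split --------------------------------------------------

#' Split every phospholipid of a system into head and tail molecules
#'
#' Real-atom coordinates are unchanged; each virtual site is initialised at
#' the position of the removed bonded neighbour (so a freshly split frame
#' is geometrically identical to the original). Output molecule ordering is
#' stable and documented: all heads in original lipid order, then all tails
#' in the same order, then the untouched species in their original order.
#' Virtual-site geometric parameters per moiety species are fitted from the
#' first molecule of that species in the input frame.
#'
#' @param x a `system_frame` or the list returned by [build_bilayer()].
#' @param topologies named list of [molecule_topology()] per species
#'   (ignored when `x` carries its own).
#' @param specs named list of [split_spec()] per phospholipid species;
#'   default: derived from the topologies via [derive_split_spec()] for
#'   species that have a `C1-C2` bond and are not skipped.
#' @param skip_species species passed through untouched (water, ions,
#'   cholesterol, proteins).
#' @return Object of class `split_system`: list with `frame` (split
#'   `system_frame`), `topologies` (moiety + untouched), `index_map`
#'   (old/new atom indices; `NA` old index for virtual sites),
#'   `original_topologies`, `specs`, and `charge_report` (net charge per
#'   moiety species).
#' @export
split_system <- function(x, topologies = NULL, specs = NULL,
                         skip_species = c("SOL", "NA", "CL", "CHL")) {
  if (is.list(x) && !inherits(x, "system_frame") && !is.null(x$frame)) {
    topologies <- topologies %||% x$topologies
    x <- x$frame
  }
  stopifnot(inherits(x, "system_frame"), !is.null(topologies))
  mols <- x$molecules
  present <- unique(mols$species)
  if (is.null(specs)) {
    cand <- setdiff(intersect(present, names(topologies)), skip_species)
    cand <- cand[vapply(cand, function(sp) {
      topo <- topologies[[sp]]
      all(c("C1", "C2") %in% topo$atoms$atom)
    }, TRUE)]
    specs <- setNames(lapply(cand, function(sp)
      derive_split_spec(topologies[[sp]])), cand)
  }
  moieties <- unlist(lapply(specs, function(s)
    c(s$head_resname, s$tail_resname)))
  if (any(present %in% moieties))
    stop_splitmem("species already split: ",
                  paste(intersect(present, moieties), collapse = ", "))
  not_covered <- setdiff(present, c(names(specs), skip_species))
  if (length(not_covered))
    stop_splitmem("lipid species lacking a split spec and not skipped: ",
                  paste(not_covered, collapse = ", "))

  atoms <- x$atoms
  lipid_mols <- mols[mols$species %in% names(specs), , drop = FALSE]
  other_mols <- mols[!mols$species %in% names(specs), , drop = FALSE]

  # split topologies, vsite params fitted from the first molecule of each
  # species in this frame
  split_topos <- list()
  for (sp in unique(lipid_mols$species)) {
    st <- split_lipid(topologies[[sp]], specs[[sp]])
    m1 <- lipid_mols[lipid_mols$species == sp, ][1L, ]
    rng <- m1$first:(m1$first + m1$n - 1L)
    co <- as.matrix(atoms[rng, c("x", "y", "z")])
    rownames(co) <- atoms$name[rng]
    for (role in c("head", "tail")) {
      topo <- st[[role]]
      keep <- topo$atoms$atom[topo$atoms$type != "VS"]
      mco <- co[keep, , drop = FALSE]
      target <- co[specs[[sp]]$cut_bond[if (role == "head") 2L else 1L], ]
      if (!is.null(topo$virtual_sites3))
        topo$virtual_sites3[1L, ] <- fit_vsite_params(
          mco, topo$virtual_sites3[1L, ], target)
      if (!is.null(topo$virtual_sites2))
        topo$virtual_sites2[1L, ] <- fit_vsite_params(
          mco, topo$virtual_sites2[1L, ], target)
      st[[role]] <- topo
    }
    split_topos[[sp]] <- st
  }

  blocks <- list(); map <- list(); resid <- 0L
  emit <- function(df, old_idx) {
    resid <<- resid + 1L
    df$resid <- resid
    blocks[[length(blocks) + 1L]] <<- df
    map[[length(map) + 1L]] <<- old_idx
  }
  moiety_block <- function(mrow, role) {
    sp <- mrow$species
    spec <- specs[[sp]]
    topo <- split_topos[[sp]][[role]]
    rng <- mrow$first:(mrow$first + mrow$n - 1L)
    keep_names <- topo$atoms$atom[topo$atoms$type != "VS"]
    sel <- rng[match(keep_names, atoms$name[rng])]
    partner <- rng[match(spec$cut_bond[if (role == "head") 2L else 1L],
                         atoms$name[rng])]
    vpos <- as.numeric(atoms[partner, c("x", "y", "z")])
    resname <- topo$name
    df <- data.frame(resid = 0L, resname = resname,
                     name = c(keep_names, if (role == "head") "V1" else "V2"),
                     x = c(atoms$x[sel], vpos[1L]),
                     y = c(atoms$y[sel], vpos[2L]),
                     z = c(atoms$z[sel], vpos[3L]),
                     stringsAsFactors = FALSE)
    emit(df, c(sel, NA_integer_))
  }
  for (i in seq_len(nrow(lipid_mols))) moiety_block(lipid_mols[i, ], "head")
  for (i in seq_len(nrow(lipid_mols))) moiety_block(lipid_mols[i, ], "tail")
  for (i in seq_len(nrow(other_mols))) {
    rng <- other_mols$first[i]:(other_mols$first[i] + other_mols$n[i] - 1L)
    emit(atoms[rng, c("resid", "resname", "name", "x", "y", "z")], rng)
  }
  new_atoms <- do.call(rbind, blocks)
  rownames(new_atoms) <- NULL
  old_index <- unlist(map)
  index_map <- data.frame(new_index = seq_len(nrow(new_atoms)),
                          old_index = old_index)
  out_topos <- list()
  for (sp in names(split_topos)) {
    out_topos[[split_topos[[sp]]$head$name]] <- split_topos[[sp]]$head
    out_topos[[split_topos[[sp]]$tail$name]] <- split_topos[[sp]]$tail
  }
  for (sp in unique(other_mols$species))
    if (!is.null(topologies[[sp]])) out_topos[[sp]] <- topologies[[sp]]
  charge_report <- vapply(out_topos, total_charge, 0.0)
  frame <- system_frame(new_atoms, x$box, time = x$time,
                        title = paste(x$title, "(split)"))
  structure(list(frame = frame, topologies = out_topos,
                 index_map = index_map,
                 original_topologies = topologies[names(specs)],
                 specs = specs,
                 lipid_order = lipid_mols[, c("molid", "species")],
                 charge_report = charge_report),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("<split_system> %d molecules (%d split lipids), %d atoms\n",
              nrow(x$frame$molecules), nrow(x$lipid_order),
              nrow(x$frame$atoms)))
  invisible(x)
}
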