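#' Flat-bottomed layer restraint specification
#'
#' One planar (layer-along-z) flat-bottomed potential measured on the
#' distance `d = |z - z_ref|` from the membrane centre of mass:
#' zero inside the well and harmonic, `U = k/2 (d - r0)^2`, outside
#' (`d > r0`); the inverted variant is harmonic inside (`d < r0`) and zero
#' outside, confining water away from the membrane interior.
#'
#' @param selection named atom group the restraint acts on
#'   (`C1_heads`, `C2_tails`, `water_O`, or custom).
#' @param k force constant, kJ mol^-1 nm^-2 (>= 0).
#' @param r0 offset distance from the membrane COM along z, nm (> 0).
#' @param inverted logical; see above.
#' @param reference_mode `"initial_frame_COM"` (reference z pinned to the
#'   membrane COM of the frame supplied at emission time) or `"fixed_z"`.
#' @return Object of class `restraint_spec`.
#' @export
restraint_spec <- function(selection, k, r0, inverted = FALSE,
                           reference_mode = c("initial_frame_COM",
                                              "fixed_z")) {
  if (k < 0) stop_splitmem("restraint force constant must be >= 0")
  if (r0 <= 0) stop_splitmem("restraint offset r0 must be > 0")
  structure(list(selection = selection, k = k, r0 = r0,
                 inverted = inverted,
                 reference_mode = match.arg(reference_mode)),
            class = "restraint_spec")
}

#' Published restraint parameter sets
#'
#' Mixed membranes: water oxygens get an inverted flat-bottomed well at
#' 2.5 kJ/mol, 2.5 nm; C1 head anchors 10 kJ/mol at 3.3 nm; C2 tail
#' anchors 50 kJ/mol at 1.0 nm. Pure POPC uses a tighter 2.8 nm head
#' restraint; the water and C2 entries are unchanged.
#'
#' @param system_kind `"mixed"` or `"pure_POPC"`.
#' @return named list of [restraint_spec()]: `water_O`, `C1_heads`,
#'   `C2_tails`.
#' @export
default_restraints <- function(system_kind = c("mixed", "pure_POPC")) {
  system_kind <- match.arg(system_kind)
  r0_head <- if (system_kind == "pure_POPC") 2.8 else 3.3
  list(
    water_O = restraint_spec("water_O", k = 2.5, r0 = 2.5, inverted = TRUE),
    C1_heads = restraint_spec("C1_heads", k = 10, r0 = r0_head),
    C2_tails = restraint_spec("C2_tails", k = 50, r0 = 1.0))
}

#' Evaluate a flat-bottomed layer potential
#'
#' @param z atom z coordinate(s), nm (vectorised).
#' @param z_ref reference z (membrane COM), nm.
#' @param spec a [restraint_spec()].
#' @return list with `energy` (kJ/mol) and `force_z`
#'   (kJ mol^-1 nm^-1, the exact `-dU/dz`); both continuous at `d = r0`.
#' @export
flat_bottom_energy <- function(z, z_ref, spec) {
  d <- abs(z - z_ref)
  s <- sign(z - z_ref)          # dd/dz
  if (!spec$inverted) {
    ex <- pmax(d - spec$r0, 0)
    U <- 0.5 * spec$k * ex^2
    F <- -spec$k * ex * s
  } else {
    ex <- pmax(spec$r0 - d, 0)
    U <- 0.5 * spec$k * ex^2
    F <- spec$k * ex * s
  }
  list(energy = U, force_z = F)
}

# map the named groups to atom indices of a split frame
restraint_group_indices <- function(split, group) {
  frame <- split$frame
  atoms <- frame$atoms
  specs <- split$specs
  heads <- vapply(specs, function(s) s$head_resname, "")
  tails <- vapply(specs, function(s) s$tail_resname, "")
  if (group == "water_O")
    return(which(atoms$resname == "SOL" & atoms$name == "OW"))
  if (group == "C1_heads") {
    idx <- integer()
    for (s in specs)
      idx <- c(idx, which(atoms$resname == s$head_resname &
                            atoms$name == s$head_anchor))
    return(sort(idx))
  }
  if (group == "C2_tails") {
    idx <- integer()
    for (s in specs)
      idx <- c(idx, which(atoms$resname == s$tail_resname &
                            atoms$name == s$tail_anchor))
    return(sort(idx))
  }
  stop_splitmem("unknown restraint group: ", group)
}

#' Emit restraint files for a split system
#'
#' `mode = "posres"` adds flat-bottomed `[ position_restraints ]` entries
#' (funct 2, layer-along-z geometry `g = 8`, negative `r` for the inverted
#' well) to the affected moiety/water topologies, with the reference z
#' pinned to the membrane COM of the supplied frame — an engine-format
#' approximation of the instantaneous-COM reference, which is documented in
#' the emitted manifest. `mode = "pull"` writes a COM-pull text block that
#' stays relative to the membrane group. An NDX file with the three groups
#' and a YAML manifest are always written.
#'
#' @param split a `split_system`.
#' @param restraints named list of [restraint_spec()] (default
#'   [default_restraints()] for a mixed system).
#' @param dir output directory.
#' @param mode `"posres"` or `"pull"`.
#' @return (invisibly) list of written paths plus the updated topologies.
#' @export
emit_restraint_files <- function(split, restraints = default_restraints(),
                                 dir = ".", mode = c("posres", "pull")) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frame <- split$frame
  z_com <- membrane_com(frame)
  groups <- lapply(names(restraints), function(g)
    restraint_group_indices(split, g))
  names(groups) <- names(restraints)
  for (g in names(groups))
    if (!length(groups[[g]]))
      stop_splitmem("restraint selection '", g, "' is empty")
  paths <- list()
  ndx_path <- file.path(dir, "restraints.ndx")
  write_ndx(groups, ndx_path)
  paths$ndx <- ndx_path

  topologies <- split$topologies
  if (mode == "posres") {
    for (g in names(restraints)) {
      spec <- restraints[[g]]
      r_emit <- if (spec$inverted) -spec$r0 else spec$r0
      affected <- if (g == "water_O") {
        list(SOL = "OW")
      } else {
        role <- if (g == "C1_heads") "head" else "tail"
        out <- list()
        for (s in split$specs) {
          rn <- if (role == "head") s$head_resname else s$tail_resname
          out[[rn]] <- if (role == "head") s$head_anchor else s$tail_anchor
        }
        out
      }
      for (rn in names(affected)) {
        topo <- topologies[[rn]]
        if (is.null(topo)) next
        ai <- which(topo$atoms$atom == affected[[rn]])
        pr <- data.frame(ai = ai, funct = 2L,
                         params = sprintf("8 %.4f %.4f", r_emit, spec$k),
                         stringsAsFactors = FALSE)
        topo$position_restraints <- rbind(topo$position_restraints, pr)
        topologies[[rn]] <- topo
      }
    }
    for (rn in names(topologies)) {
      p <- file.path(dir, paste0(rn, "_posres.itp"))
      write_itp(topologies[[rn]], p)
      paths[[paste0("itp_", rn)]] <- p
    }
  } else {
    pull <- c("pull                     = yes",
              sprintf("pull-ngroups             = %d", length(restraints) + 1L),
              "pull-group1-name         = membrane")
    i <- 1L
    for (g in names(restraints)) {
      i <- i + 1L
      spec <- restraints[[g]]
      pull <- c(pull,
                sprintf("pull-group%d-name         = %s", i, g),
                sprintf("pull-coord%d-groups       = 1 %d", i - 1L, i),
                sprintf("pull-coord%d-geometry     = flat-bottom%s",
                        i - 1L, if (spec$inverted) "-high" else ""),
                sprintf("pull-coord%d-dim          = N N Y", i - 1L),
                sprintf("pull-coord%d-init         = %.4f",
                        i - 1L, if (spec$inverted) -spec$r0 else spec$r0),
                sprintf("pull-coord%d-k            = %.4f", i - 1L, spec$k))
    }
    p <- file.path(dir, "pull_restraints.mdp")
    writeLines(pull, p)
    paths$pull <- p
  }
  manifest <- c(
    "restraint_manifest:",
    sprintf("  mode: %s", mode),
    sprintf("  reference_z_com: %.6f", z_com),
    "  note: posres references are pinned to the emission frame COM;",
    "    pull mode stays relative to the instantaneous membrane COM",
    "  restraints:")
  for (g in names(restraints)) {
    spec <- restraints[[g]]
    manifest <- c(manifest,
                  sprintf("    - selection: %s", g),
                  sprintf("      k: %.4f", spec$k),
                  sprintf("      r0: %.4f", spec$r0),
                  sprintf("      inverted: %s",
                          if (spec$inverted) "true" else "false"),
                  sprintf("      n_atoms: %d", length(groups[[g]])))
  }
  mp <- file.path(dir, "restraints.yaml")
  writeLines(manifest, mp)
  paths$manifest <- mp
  invisible(list(paths = paths, topologies = topologies, groups = groups,
                 z_com = z_com))
}
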