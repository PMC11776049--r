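#' Reunite split heads and tails into whole lipids
#'
#' Pairing is per (leaflet, lipid type) class — a POPS tail is never glued
#' to a POPC head and cross-leaflet pairing is never produced. The junction
#' distance between the C1 and C2 anchor atoms (the atoms that were bonded)
#' is computed with the minimum-image convention in xy and a plain
#' difference in z. The default strategy follows the closest-head rule:
#' all candidate head-tail distances sorted ascending, pairs accepted in
#' order, skipping already-used partners; `"optimal"` computes the
#' minimum-total-distance assignment (Hungarian algorithm). Equal distances
#' are broken by (head id, tail id) lexicographic order.
#'
#' @param split a `split_system` (its frame may have been moved/simulated).
#' @param strategy `"greedy"` or `"optimal"`.
#' @param leaflets optional precomputed leaflet assignment
#'   (see [assign_leaflets()]); recomputed from the frame by default.
#' @return Object of class `merge_plan`: `pairs` (data.frame `head_mol`,
#'   `tail_mol`, `distance`, `leaflet`, `species`), `unmatched` (empty on
#'   success) and `max_junction_distance`.
#' @export
plan_merge <- function(split, strategy = c("greedy", "optimal"),
                       leaflets = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(split, "split_system"))
  frame <- split$frame
  atoms <- frame$atoms
  mols <- frame$molecules
  specs <- split$specs
  if (is.null(leaflets)) leaflets <- assign_leaflets(frame)
  leaf <- setNames(as.character(leaflets$leaflet), leaflets$molid)
  box <- frame$box

  anchor_of <- function(mrow, name) {
    rng <- mrow$first:(mrow$first + mrow$n - 1L)
    hit <- rng[atoms$name[rng] == name]
    if (length(hit) != 1L)
      stop_splitmem("anchor ", name, " not found in molecule ", mrow$molid)
    c(atoms$x[hit], atoms$y[hit], atoms$z[hit])
  }

  pairs <- list(); unmatched <- list()
  for (sp in names(specs)) {
    s <- specs[[sp]]
    hmols <- mols[mols$species == s$head_resname, , drop = FALSE]
    tmols <- mols[mols$species == s$tail_resname, , drop = FALSE]
    for (lf in c("upper", "lower")) {
      h <- hmols[leaf[as.character(hmols$molid)] == lf, , drop = FALSE]
      t <- tmols[leaf[as.character(tmols$molid)] == lf, , drop = FALSE]
      if (nrow(h) == 0L && nrow(t) == 0L) next
      if (nrow(h) != nrow(t))
        stop_splitmem(sprintf(
          "head/tail count mismatch in class (%s, %s): %d heads vs %d tails",
          sp, lf, nrow(h), nrow(t)))
      hp <- t(vapply(seq_len(nrow(h)), function(i)
        anchor_of(h[i, ], s$head_anchor), numeric(3)))
      tp <- t(vapply(seq_len(nrow(t)), function(i)
        anchor_of(t[i, ], s$tail_anchor), numeric(3)))
      D <- junction_distance_matrix(hp, tp, box)
      idx <- switch(strategy,
                    greedy = greedy_assignment(D),
                    optimal = hungarian_assignment(D))
      for (i in seq_along(idx)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          head_mol = h$molid[i], tail_mol = t$molid[idx[i]],
          distance = D[i, idx[i]], leaflet = lf, species = sp,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(head_mol = integer(), tail_mol = integer(),
               distance = numeric(), leaflet = character(),
               species = character())
  pairs <- pairs[order(pairs$head_mol), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched = list(),
                 max_junction_distance = if (nrow(pairs)) max(pairs$distance)
                 else 0,
                 strategy = strategy),
            class = "merge_plan")
}

# distances: minimum image in xy, plain difference in z
junction_distance_matrix <- function(hp, tp, box) {
  dx <- outer(hp[, 1L], tp[, 1L], `-`)
  dy <- outer(hp[, 2L], tp[, 2L], `-`)
  dz <- outer(hp[, 3L], tp[, 3L], `-`)
  dx <- min_image(dx, box[1L])
  dy <- min_image(dy, box[2L])
  sqrt(dx^2 + dy^2 + dz^2)
}

# accept pairs in ascending distance order, deterministic tie-break by
# (row, col) lexicographic order
greedy_assignment <- function(D) {
  n <- nrow(D)
  ord <- order(D, row(D), col(D))
  used_r <- logical(n); used_c <- logical(n)
  out <- integer(n); taken <- 0L
  for (k in ord) {
    i <- row(D)[k]; j <- col(D)[k]
    if (used_r[i] || used_c[j]) next
    used_r[i] <- TRUE; used_c[j] <- TRUE
    out[i] <- j
    taken <- taken + 1L
    if (taken == n) break
  }
  out
}

# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials);
# returns the column assigned to each row, minimising total cost.
# Columns are offset by +1 so "column 0" (the virtual start) is index 1.
hungarian_assignment <- function(D) {
  n <- nrow(D)
  if (n == 0L) return(integer())
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, v[1] is column 0
  p <- integer(n + 1L)       # p[j+1]: row matched to column j, 0 = none
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- D[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

#' Rebuild whole lipids from a merge plan
#'
#' Virtual sites are removed, the cut bond and every original intra-lipid
#' bonded term are restored from the stored pre-split topology, atoms are
#' reordered to the original species atom order, and real-atom coordinates
#' are untouched. Whole lipids are emitted in head-molecule order, followed
#' by the untouched species in their original order, so merging a freshly
#' split, unmoved system reproduces the original frame exactly.
#'
#' @param split a `split_system`.
#' @param plan a `merge_plan` (default: greedy plan computed on the spot).
#' @return list with `frame` (whole `system_frame`) and `topologies`
#'   (original species topologies plus untouched species).
#' @export
apply_merge <- function(split, plan = plan_merge(split)) {
  stopifnot(inherits(split, "split_system"))
  frame <- split$frame
  atoms <- frame$atoms
  mols <- frame$molecules
  if (length(plan$unmatched))
    stop_splitmem("merge plan has unmatched moieties")
  bad <- setdiff(c(plan$pairs$head_mol, plan$pairs$tail_mol), mols$molid)
  if (length(bad))
    stop_splitmem("merge plan references unknown molecule ids: ",
                  paste(bad, collapse = ", "))
  specs <- split$specs
  orig <- split$original_topologies

  blocks <- list(); resid <- 0L
  take <- function(molid, names_wanted) {
    m <- mols[mols$molid == molid, ]
    rng <- m$first:(m$first + m$n - 1L)
    sel <- rng[match(names_wanted, atoms$name[rng])]
    if (anyNA(sel))
      stop_splitmem("atoms ", paste(names_wanted[is.na(sel)], collapse = ", "),
                    " missing from molecule ", molid)
    atoms[sel, c("name", "x", "y", "z")]
  }
  for (r in seq_len(nrow(plan$pairs))) {
    pr <- plan$pairs[r, ]
    s <- specs[[pr$species]]
    topo <- orig[[pr$species]]
    # reorder to the original species atom order
    alldf <- rbind(take(pr$head_mol, intersect(topo$atoms$atom, s$head_atoms)),
                   take(pr$tail_mol, intersect(topo$atoms$atom, s$tail_atoms)))
    alldf <- alldf[match(topo$atoms$atom, alldf$name), , drop = FALSE]
    resid <- resid + 1L
    blocks[[length(blocks) + 1L]] <- data.frame(
      resid = resid, resname = pr$species, name = alldf$name,
      x = alldf$x, y = alldf$y, z = alldf$z, stringsAsFactors = FALSE)
  }
  moieties <- unlist(lapply(specs, function(s)
    c(s$head_resname, s$tail_resname)))
  others <- mols[!mols$species %in% moieties, , drop = FALSE]
  for (i in seq_len(nrow(others))) {
    rng <- others$first[i]:(others$first[i] + others$n[i] - 1L)
    resid <- resid + 1L
    df <- atoms[rng, c("resname", "name", "x", "y", "z")]
    df <- cbind(resid = resid, df)
    blocks[[length(blocks) + 1L]] <- df
  }
  new_atoms <- do.call(rbind, blocks)
  rownames(new_atoms) <- NULL
  topologies <- c(orig,
                  split$topologies[setdiff(unique(others$species),
                                           names(orig))])
  merged <- system_frame(new_atoms, frame$box, time = frame$time,
                         title = sub(" \\(split\\)$", "", frame$title))
  list(frame = merged, topologies = topologies, plan = plan)
}

#' Flag strained junctions after reunification
#'
#' Pairs whose junction distance exceeds the threshold leave the system out
#' of equilibrium after the cut bond is restored; the report lists them
#' (sorted descending by distance) and recommends minimisation and a short
#' re-equilibration with headgroup positions fixed so the acyl tails relax
#' towards their heads. When `posres_dir` is given, per-species
#' `[ position_restraints ]` files fixing all head-moiety atoms are written
#' to support that recipe.
#'
#' @param plan a `merge_plan`.
#' @param threshold junction distance threshold, nm.
#' @param split the `split_system` (needed only for `posres_dir`).
#' @param posres_dir optional output directory for headgroup restraint
#'   files.
#' @param k_posres force constant for the headgroup restraints,
#'   kJ mol^-1 nm^-2.
#' @return Object of class `strain_report`: `flagged` (data.frame, sorted
#'   descending by distance), `threshold`, `recommendation`.
#' @export
strain_report <- function(plan, threshold = 0.3, split = NULL,
                          posres_dir = NULL, k_posres = 1000) {
  flagged <- plan$pairs[plan$pairs$distance > threshold, , drop = FALSE]
  flagged <- flagged[order(-flagged$distance), , drop = FALSE]
  rownames(flagged) <- NULL
  rec <- if (nrow(flagged))
    paste0(nrow(flagged), " junction(s) exceed ", threshold,
           " nm: minimise, then re-equilibrate with headgroup positions ",
           "fixed so the acyl tails move toward their heads")
  else "all junctions within threshold; no re-equilibration required"
  paths <- NULL
  if (!is.null(posres_dir) && !is.null(split)) {
    dir.create(posres_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (s in split$specs) {
      topo <- split$topologies[[s$head_resname]]
      if (is.null(topo)) next
      ai <- topo$atoms$nr[topo$atoms$type != "VS"]
      topo$position_restraints <- data.frame(
        ai = ai, funct = 1L,
        params = sprintf("%.1f %.1f %.1f", k_posres, k_posres, k_posres),
        stringsAsFactors = FALSE)
      p <- file.path(posres_dir, paste0(s$head_resname, "_fix.itp"))
      write_itp(topo, p)
      paths <- c(paths, p)
    }
  }
  structure(list(flagged = flagged, threshold = threshold,
                 recommendation = rec, posres_files = paths),
            class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat("<strain_report>", x$recommendation, "\n")
  if (nrow(x$flagged)) print(utils::head(x$flagged, 10L))
  invisible(x)
}
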