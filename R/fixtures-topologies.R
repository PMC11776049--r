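# Simplified but structurally faithful per-species topologies for the
# synthetic fixtures. Atom names preserve the roles the toolkit touches
# (P, N, glycerol C1/C2, chain carbons, water O); atom counts and charges
# are reduced stand-ins for the real all-atom force field, which is never
# required by the test suite.

FIXTURE_PHOSPHOLIPIDS <- c("POPC", "POPS", "POPE", "PSM", "POPA")

# head fragment: phosphocholine (or phosphate for PA) + glycerol C1; 20 atoms
# for PC-like species. Tail fragment: glycerol C2/C3, two esters, two
# 12-carbon acyl chains; 32 atoms. Cut bond: C1-C2.
fixture_head_atoms <- function(species) {
  if (species == "POPA") {
    # phosphatidic acid: bare phosphate headgroup, no nitrogen
    nm <- c("P", "O13", "O14", "O11", "O12", "C1", "H1A", "H13A")
    q <- c(1.5, -0.8, -0.8, -0.45, -0.45, 0, 0, 0)   # net -1.0
  } else {
    nm <- c("N", "C13", "C14", "C15", "C12", "C11", "P", "O13", "O14",
            "O11", "O12", "C1", "H11A", "H11B", "H12A", "H12B",
            "H13A", "H14A", "H15A", "H1A")
    q <- c(1.0, 0, 0, 0, 0, 0, 1.5, -0.8, -0.8, -0.45, -0.45, 0,
           0, 0, 0, 0, 0, 0, 0, 0)                    # net 0.0
    if (species == "POPS") q[9] <- -1.8               # net -1.0, serine-like
  }
  data.frame(atom = nm, charge = q, stringsAsFactors = FALSE)
}

fixture_tail_atoms <- function() {
  core <- c("C2", "C3", "O21", "C21", "O22", "O31", "C31", "O32")
  qcore <- c(0, 0, 0, 0.7, -0.7, 0, 0.7, -0.7)
  sn2 <- sprintf("C2%d", 2:13)
  sn1 <- sprintf("C3%d", 2:13)
  data.frame(atom = c(core, sn2, sn1),
             charge = c(qcore, rep(0, 24)),
             stringsAsFactors = FALSE)
}

fixture_lipid_bonds <- function(species) {
  hb <- if (species == "POPA") {
    list(c("P", "O13"), c("P", "O14"), c("P", "O11"), c("P", "O12"),
         c("O11", "C1"), c("C1", "H1A"), c("O13", "H13A"))
  } else {
    list(c("N", "C13"), c("N", "C14"), c("N", "C15"), c("N", "C12"),
         c("C12", "C11"), c("C11", "O12"), c("O12", "P"),
         c("P", "O13"), c("P", "O14"), c("P", "O11"), c("O11", "C1"),
         c("C11", "H11A"), c("C11", "H11B"), c("C12", "H12A"),
         c("C12", "H12B"), c("C13", "H13A"), c("C14", "H14A"),
         c("C15", "H15A"), c("C1", "H1A"))
  }
  tb <- c(list(c("C2", "C3"), c("C2", "O21"), c("O21", "C21"),
               c("C21", "O22"), c("C21", "C22"),
               c("C3", "O31"), c("O31", "C31"), c("C31", "O32"),
               c("C31", "C32")),
          lapply(2:12, function(i) c(sprintf("C2%d", i), sprintf("C2%d", i + 1))),
          lapply(2:12, function(i) c(sprintf("C3%d", i), sprintf("C3%d", i + 1))))
  list(head = hb, tail = tb, cut = c("C1", "C2"))
}

#' Build the simplified fixture topology for one species
#'
#' Supported species: the five phospholipids (`POPC`, `POPS`, `POPE`,
#' `PSM`, `POPA`), cholesterol (`CHL`), water (`SOL`) and the monatomic
#' ions `NA`/`CL`. Phospholipids have 52 pseudo-atoms (44 for POPA), a
#' neutral net charge for PC/PE/SM and -1 e for PS/PA, and carry the cut
#' bond `C1-C2` plus bonded terms that span the cut so the splitter's
#' drop rules are exercised.
#'
#' @param species species name.
#' @return A [molecule_topology()].
#' @export
fixture_topology <- function(species) {
  if (species %in% FIXTURE_PHOSPHOLIPIDS) {
    h <- fixture_head_atoms(species)
    t <- fixture_tail_atoms()
    at <- rbind(h, t)
    atoms <- data.frame(nr = seq_len(nrow(at)),
                        type = paste0(substr(at$atom, 1, 1), "F"),
                        resnr = 1L, resname = species, atom = at$atom,
                        cgnr = seq_len(nrow(at)), charge = at$charge,
                        mass = guess_mass(at$atom),
                        stringsAsFactors = FALSE)
    bl <- fixture_lipid_bonds(species)
    nm2idx <- function(nms) match(nms, atoms$atom)
    allb <- c(bl$head, list(bl$cut), bl$tail)
    bonds <- data.frame(
      ai = vapply(allb, function(b) nm2idx(b[1]), 0L),
      aj = vapply(allb, function(b) nm2idx(b[2]), 0L),
      funct = 1L, params = "0.15300 265265.0",
      stringsAsFactors = FALSE)
    ang <- if (species == "POPA")
      list(c("O11", "C1", "C2"), c("C1", "C2", "C3"), c("C1", "C2", "O21"),
           c("O13", "P", "O14"), c("C2", "C3", "O31"), c("C21", "C22", "C23"))
    else
      list(c("O11", "C1", "C2"), c("C1", "C2", "C3"), c("C1", "C2", "O21"),
           c("N", "C12", "C11"), c("O12", "P", "O11"),
           c("C2", "C3", "O31"), c("C21", "C22", "C23"))
    angles <- data.frame(
      ai = vapply(ang, function(a) nm2idx(a[1]), 0L),
      aj = vapply(ang, function(a) nm2idx(a[2]), 0L),
      ak = vapply(ang, function(a) nm2idx(a[3]), 0L),
      funct = 1L, params = "111.0 530.0", stringsAsFactors = FALSE)
    dih <- list(c("O11", "C1", "C2", "C3"), c("C1", "C2", "C3", "O31"))
    dihedrals <- data.frame(
      ai = vapply(dih, function(a) nm2idx(a[1]), 0L),
      aj = vapply(dih, function(a) nm2idx(a[2]), 0L),
      ak = vapply(dih, function(a) nm2idx(a[3]), 0L),
      al = vapply(dih, function(a) nm2idx(a[4]), 0L),
      funct = 3L, params = "", stringsAsFactors = FALSE)
    pairs <- data.frame(ai = nm2idx("O11"), aj = nm2idx("C3"),
                        funct = 1L, params = "", stringsAsFactors = FALSE)
    return(molecule_topology(species, atoms, bonds = bonds, pairs = pairs,
                             angles = angles, dihedrals = dihedrals))
  }
  if (species == "CHL") {
    nm <- c("O3", "H3", "C3", "C5", "C10", "C13", "C17", "C20")
    atoms <- data.frame(nr = 1:8, type = paste0(substr(nm, 1, 1), "F"),
                        resnr = 1L, resname = "CHL", atom = nm,
                        cgnr = 1:8, charge = 0, mass = guess_mass(nm),
                        stringsAsFactors = FALSE)
    bonds <- data.frame(ai = c(1L, 1L, 3L, 4L, 5L, 6L, 7L),
                        aj = c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
                        funct = 1L, params = "0.15300 265265.0",
                        stringsAsFactors = FALSE)
    return(molecule_topology("CHL", atoms, bonds = bonds))
  }
  if (species == "SOL") {
    atoms <- data.frame(nr = 1:3, type = c("OW", "HW", "HW"), resnr = 1L,
                        resname = "SOL", atom = c("OW", "HW1", "HW2"),
                        cgnr = 1L, charge = c(-0.8476, 0.4238, 0.4238),
                        mass = c(15.999, 1.008, 1.008),
                        stringsAsFactors = FALSE)
    bonds <- data.frame(ai = c(1L, 1L), aj = c(2L, 3L), funct = 1L,
                        params = "0.10000 345000.0", stringsAsFactors = FALSE)
    return(molecule_topology("SOL", atoms, bonds = bonds))
  }
  if (species %in% c("NA", "CL")) {
    atoms <- data.frame(nr = 1L, type = species, resnr = 1L,
                        resname = species, atom = species, cgnr = 1L,
                        charge = if (species == "NA") 1.0 else -1.0,
                        mass = if (species == "NA") 22.990 else 35.453,
                        stringsAsFactors = FALSE)
    return(molecule_topology(species, atoms))
  }
  stop_splitmem("no fixture topology for species ", species)
}

#' Named list of fixture topologies
#' @param species character vector of species names.
#' @export
fixture_topologies <- function(species = c(FIXTURE_PHOSPHOLIPIDS, "CHL",
                                           "SOL", "NA", "CL")) {
  setNames(lapply(species, fixture_topology), species)
}
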