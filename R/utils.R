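# Internal helpers: unit constants, vector geometry, periodic boundaries,
# atom selection. All public quantities are nm / ns / amu / e / kJ/mol.

# amu/nm^3 -> kg/m^3
AMU_PER_NM3_TO_KG_M3 <- 1.66053906660

# default element masses (amu) keyed by leading element letter of an atom name
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, V = 0.0)

guess_mass <- function(atom_name) {
  el <- sub("^[0-9]*", "", atom_name)
  el <- substr(el, 1L, 1L)
  m <- .element_masses[el]
  ifelse(is.na(m), 0.0, unname(m))
}

#' @noRd
stop_splitmem <- function(..., class = "splitmem_error") {
  stop(errorCondition(paste0(...), class = c(class, "splitmem_error")))
}

vec_norm <- function(v) sqrt(sum(v * v))

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Minimum-image difference along one periodic axis
#' @noRd
min_image <- function(d, L) d - L * round(d / L)

#' Wrap coordinates into [0, L)
#' @noRd
wrap_coord <- function(x, L) x - L * floor(x / L)

# selection: integer indices into an atom table by resname / atom name /
# explicit indices; NULL criteria are ignored, criteria combine with AND.
select_atoms <- function(atoms, name = NULL, resname = NULL, index = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(name))    keep <- keep & atoms$name %in% name
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  idx <- which(keep)
  if (!is.null(index)) idx <- intersect(idx, index)
  idx
}

# resolve a "selection" argument: integer vector, logical vector, or a list
# of criteria for select_atoms()
resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.list(selection)) {
    return(select_atoms(atoms,
                        name = selection$name,
                        resname = selection$resname,
                        index = selection$index))
  }
  stop_splitmem("cannot interpret selection of class ", class(selection)[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
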