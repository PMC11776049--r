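#' Molecule topology container
#'
#' Mirrors one GROMACS `[ moleculetype ]` block: an atom table
#' (`nr`, `type`, `resnr`, `resname`, `atom`, `cgnr`, `charge`, `mass`),
#' bonded-term tables (`bonds`, `pairs`, `angles`, `dihedrals`,
#' `exclusions`, each with 1-based `ai..al`, `funct` and a verbatim
#' `params` string), virtual-site tables and `[ position_restraints ]`.
#' Unknown sections are carried as opaque text and re-emitted verbatim, so
#' force-field files survive a read/modify/write cycle untouched.
#'
#' @param name molecule species name.
#' @param atoms atom table (see above); `mass` may be `NA` (force-field
#'   default), virtual sites must carry mass 0 and charge 0.
#' @param bonds,pairs,angles,dihedrals,exclusions bonded-term tables; may
#'   be `NULL` for empty.
#' @param virtual_sites2 table `site, ai, aj, funct, a`.
#' @param virtual_sites3 table `site, ai, aj, ak, funct, c1, c2, c3`.
#' @param position_restraints table `ai, funct, params`.
#' @param nrexcl exclusion depth.
#' @param extra named list of verbatim unknown sections.
#' @return Object of class `molecule_topology`.
#' @export
molecule_topology <- function(name, atoms,
                              bonds = NULL, pairs = NULL, angles = NULL,
                              dihedrals = NULL, exclusions = NULL,
                              virtual_sites2 = NULL, virtual_sites3 = NULL,
                              position_restraints = NULL,
                              nrexcl = 3L, extra = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("nr", "type", "resname", "atom", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_splitmem("topology atoms missing columns: ",
                                  paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$nr))
    stop_splitmem("duplicate atom indices in moleculetype ", name)
  if (is.null(atoms$mass)) atoms$mass <- guess_mass(atoms$atom)
  if (is.null(atoms$resnr)) atoms$resnr <- 1L
  if (is.null(atoms$cgnr)) atoms$cgnr <- seq_len(nrow(atoms))
  if (any(atoms$mass < 0, na.rm = TRUE))
    stop_splitmem("negative atomic mass in moleculetype ", name)
  nat <- nrow(atoms)
  check_idx <- function(tab, cols, what) {
    if (is.null(tab) || nrow(tab) == 0L) return(empty_bonded(cols))
    for (cc in cols)
      if (any(tab[[cc]] < 1L | tab[[cc]] > nat))
        stop_splitmem("bonded term index out of range in [", what,
                      "] of moleculetype ", name)
    if (is.null(tab$params)) tab$params <- ""
    tab
  }
  obj <- structure(list(
    name = name, nrexcl = as.integer(nrexcl), atoms = atoms,
    bonds = check_idx(bonds, c("ai", "aj"), "bonds"),
    pairs = check_idx(pairs, c("ai", "aj"), "pairs"),
    angles = check_idx(angles, c("ai", "aj", "ak"), "angles"),
    dihedrals = check_idx(dihedrals, c("ai", "aj", "ak", "al"), "dihedrals"),
    exclusions = check_idx(exclusions, c("ai", "aj"), "exclusions"),
    virtual_sites2 = virtual_sites2,
    virtual_sites3 = virtual_sites3,
    position_restraints = position_restraints,
    extra = extra), class = "molecule_topology")
  obj
}

empty_bonded <- function(cols) {
  out <- as.data.frame(setNames(rep(list(integer()), length(cols)), cols))
  out$funct <- integer()
  out$params <- character()
  out
}

#' Net charge of a molecule topology (elementary charges)
#' @param topology a `molecule_topology`.
#' @export
total_charge <- function(topology) sum(topology$atoms$charge)

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("<molecule_topology> %s: %d atoms, %d bonds, charge %+.4f e\n",
              x$name, nrow(x$atoms), nrow(x$bonds), total_charge(x)))
  invisible(x)
}

KNOWN_SECTIONS <- c("moleculetype", "atoms", "bonds", "pairs", "angles",
                    "dihedrals", "exclusions", "virtual_sites2",
                    "virtual_sites3", "position_restraints",
                    "system", "molecules", "defaults", "atomtypes",
                    "constraints", "settles")

# ---- parsing -------------------------------------------------------------

strip_comment <- function(line) sub(";.*$", "", line)

parse_top_lines <- function(lines, source = "<topology>") {
  sec <- NA_character_
  mols <- list()
  cur <- NULL          # accumulating moleculetype sections
  header_extra <- list()
  system_name <- NULL
  molecules <- list()
  flush_mol <- function() {
    if (!is.null(cur)) mols[[length(mols) + 1L]] <<- finish_moleculetype(cur)
    cur <<- NULL
  }
  for (ln in lines) {
    raw <- ln
    if (grepl("^\\s*#", ln)) {
      # preprocessor directives are recorded verbatim, never evaluated
      tgt <- if (is.null(cur)) "header" else "mol"
      if (tgt == "header")
        header_extra[["_preprocessor"]] <-
          c(header_extra[["_preprocessor"]], raw)
      else cur$extra[["_preprocessor"]] <- c(cur$extra[["_preprocessor"]], raw)
      next
    }
    line <- trimws(strip_comment(ln))
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^\\[\\s*([A-Za-z0-9_]+)\\s*\\]$", line))[[1L]]
    if (length(m) == 2L) {
      sec <- m[2L]
      if (!sec %in% KNOWN_SECTIONS)
        warning("unknown topology section [", sec, "] in ", source,
                ": passed through verbatim")
      if (sec == "moleculetype") {
        flush_mol()
        cur <- list(sections = list(), extra = list())
      }
      next
    }
    if (is.na(sec))
      stop_splitmem("topology parse error in ", source,
                    ": data before any [section]: '", line, "'")
    if (sec %in% c("defaults", "atomtypes") ||
        (!sec %in% KNOWN_SECTIONS)) {
      if (is.null(cur))
        header_extra[[sec]] <- c(header_extra[[sec]], raw)
      else cur$extra[[sec]] <- c(cur$extra[[sec]], raw)
    } else if (sec == "system") {
      system_name <- paste(c(system_name, line), collapse = " ")
    } else if (sec == "molecules") {
      f <- strsplit(line, "\\s+")[[1L]]
      molecules[[length(molecules) + 1L]] <-
        data.frame(name = f[1L], count = as.integer(f[2L]),
                   stringsAsFactors = FALSE)
    } else {
      if (is.null(cur))
        stop_splitmem("section [", sec, "] before [moleculetype] in ", source)
      cur$sections[[sec]] <- c(cur$sections[[sec]], line)
    }
  }
  flush_mol()
  list(molecules_types = mols,
       system = system_name,
       molecules = if (length(molecules)) do.call(rbind, molecules) else NULL,
       header_extra = header_extra)
}

finish_moleculetype <- function(cur) {
  s <- cur$sections
  if (is.null(s$moleculetype))
    stop_splitmem("[moleculetype] section without name line")
  mt <- strsplit(s$moleculetype[1L], "\\s+")[[1L]]
  name <- mt[1L]
  nrexcl <- if (length(mt) > 1L) as.integer(mt[2L]) else 3L
  atoms <- parse_atoms_section(s$atoms %||% character(), name)
  molecule_topology(
    name, atoms,
    bonds = parse_bonded(s$bonds, 2L),
    pairs = parse_bonded(s$pairs, 2L),
    angles = parse_bonded(s$angles, 3L),
    dihedrals = parse_bonded(s$dihedrals, 4L),
    exclusions = parse_exclusions(s$exclusions),
    virtual_sites2 = parse_vsites(s$virtual_sites2, 2L),
    virtual_sites3 = parse_vsites(s$virtual_sites3, 3L),
    position_restraints = parse_posres(s$position_restraints),
    nrexcl = nrexcl, extra = cur$extra)
}

parse_atoms_section <- function(lines, molname) {
  if (!length(lines)) stop_splitmem("moleculetype ", molname, " has no atoms")
  f <- strsplit(lines, "\\s+")
  n <- lengths(f)
  if (any(n < 7L))
    stop_splitmem("malformed [atoms] line in moleculetype ", molname)
  data.frame(
    nr = as.integer(vapply(f, `[`, "", 1L)),
    type = vapply(f, `[`, "", 2L),
    resnr = as.integer(vapply(f, `[`, "", 3L)),
    resname = vapply(f, `[`, "", 4L),
    atom = vapply(f, `[`, "", 5L),
    cgnr = as.integer(vapply(f, `[`, "", 6L)),
    charge = as.numeric(vapply(f, `[`, "", 7L)),
    mass = vapply(seq_along(f), function(i)
      if (n[i] >= 8L) as.numeric(f[[i]][8L]) else NA_real_, 0.0),
    stringsAsFactors = FALSE)
}

parse_bonded <- function(lines, nidx) {
  cols <- c("ai", "aj", "ak", "al")[seq_len(nidx)]
  if (is.null(lines) || !length(lines)) return(empty_bonded(cols))
  f <- strsplit(lines, "\\s+")
  if (any(lengths(f) < nidx + 1L))
    stop_splitmem("bonded line with too few fields: '", lines[1L], "'")
  out <- as.data.frame(setNames(lapply(seq_len(nidx), function(k)
    as.integer(vapply(f, `[`, "", k))), cols))
  out$funct <- as.integer(vapply(f, `[`, "", nidx + 1L))
  out$params <- vapply(f, function(v)
    paste(v[-seq_len(nidx + 1L)], collapse = " "), "")
  out
}

parse_exclusions <- function(lines) {
  if (is.null(lines) || !length(lines)) return(empty_bonded(c("ai", "aj")))
  # each line: ai followed by one or more excluded partners; flatten to pairs
  out <- list()
  for (ln in lines) {
    v <- as.integer(strsplit(ln, "\\s+")[[1L]])
    if (length(v) < 2L) stop_splitmem("malformed exclusion line: '", ln, "'")
    out[[length(out) + 1L]] <- data.frame(ai = v[1L], aj = v[-1L])
  }
  out <- do.call(rbind, out)
  out$funct <- 1L
  out$params <- ""
  out
}

parse_vsites <- function(lines, ncon) {
  if (is.null(lines) || !length(lines)) return(NULL)
  f <- strsplit(lines, "\\s+")
  base <- data.frame(site = as.integer(vapply(f, `[`, "", 1L)))
  for (k in seq_len(ncon))
    base[[c("ai", "aj", "ak")[k]]] <- as.integer(vapply(f, `[`, "", 1L + k))
  base$funct <- as.integer(vapply(f, `[`, "", 2L + ncon))
  pars <- lapply(f, function(v) as.numeric(v[-seq_len(2L + ncon)]))
  np <- max(lengths(pars), 1L)
  for (k in seq_len(np))
    base[[paste0("c", k)]] <- vapply(pars, function(p)
      if (length(p) >= k) p[k] else NA_real_, 0.0)
  base
}

parse_posres <- function(lines) {
  if (is.null(lines) || !length(lines)) return(NULL)
  f <- strsplit(lines, "\\s+")
  data.frame(ai = as.integer(vapply(f, `[`, "", 1L)),
             funct = as.integer(vapply(f, `[`, "", 2L)),
             params = vapply(f, function(v)
               paste(v[-(1:2)], collapse = " "), ""),
             stringsAsFactors = FALSE)
}

#' Read a GROMACS ITP file into a molecule topology
#'
#' Parses the supported section subset; unknown sections are kept verbatim
#' (with a warning) and survive a write round trip. `#include` and `#ifdef`
#' lines are recorded but never expanded or evaluated.
#'
#' @param path file path (`.itp`, optionally gzipped).
#' @return A `molecule_topology` (first moleculetype in the file).
#' @export
read_itp <- function(path) {
  if (!file.exists(path)) stop_splitmem("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  parsed <- parse_top_lines(readLines(con, warn = FALSE), source = path)
  if (!length(parsed$molecules_types))
    stop_splitmem("no [moleculetype] found in ", path)
  parsed$molecules_types[[1L]]
}

#' Read a GROMACS TOP file (system + molecule list + inline moleculetypes)
#'
#' @param path file path.
#' @return Object of class `top_model`: list with `molecule_types` (named
#'   list of `molecule_topology`), `system` (title), `molecules`
#'   (data.frame name/count) and verbatim `header_extra` sections.
#' @export
read_top <- function(path) {
  if (!file.exists(path)) stop_splitmem("file not found: ", path)
  parsed <- parse_top_lines(readLines(path, warn = FALSE), source = path)
  mt <- parsed$molecules_types
  names(mt) <- vapply(mt, function(m) m$name, "")
  structure(list(molecule_types = mt, system = parsed$system,
                 molecules = parsed$molecules,
                 header_extra = parsed$header_extra),
            class = "top_model")
}

# ---- writing -------------------------------------------------------------

format_moleculetype <- function(top) {
  out <- c("[ moleculetype ]",
           sprintf("%-8s %d", top$name, top$nrexcl), "",
           "[ atoms ]")
  a <- top$atoms
  out <- c(out, sprintf("%6d %-8s %5d %-6s %-6s %5d %10.4f %10.4f",
                        a$nr, a$type, a$resnr, a$resname, a$atom, a$cgnr,
                        a$charge, ifelse(is.na(a$mass), 0, a$mass)))
  emit_bonded <- function(tab, header, nidx) {
    if (is.null(tab) || nrow(tab) == 0L) return(character())
    idx <- as.matrix(tab[, c("ai", "aj", "ak", "al")[seq_len(nidx)],
                         drop = FALSE])
    body <- apply(cbind(idx, tab$funct), 1L, function(v)
      paste(sprintf("%6d", v), collapse = ""))
    body <- paste0(body, ifelse(nzchar(tab$params),
                                paste0("   ", tab$params), ""))
    c("", sprintf("[ %s ]", header), body)
  }
  out <- c(out,
           emit_bonded(top$bonds, "bonds", 2L),
           emit_bonded(top$pairs, "pairs", 2L),
           emit_bonded(top$angles, "angles", 3L),
           emit_bonded(top$dihedrals, "dihedrals", 4L))
  if (!is.null(top$virtual_sites2) && nrow(top$virtual_sites2)) {
    v <- top$virtual_sites2
    out <- c(out, "", "[ virtual_sites2 ]",
             sprintf("%6d%6d%6d%6d %12.6f", v$site, v$ai, v$aj, v$funct, v$c1))
  }
  if (!is.null(top$virtual_sites3) && nrow(top$virtual_sites3)) {
    v <- top$virtual_sites3
    pcols <- grep("^c[0-9]+$", names(v), value = TRUE)
    body <- vapply(seq_len(nrow(v)), function(i) {
      p <- unlist(v[i, pcols])
      p <- p[!is.na(p)]
      paste0(sprintf("%6d%6d%6d%6d%6d", v$site[i], v$ai[i], v$aj[i],
                     v$ak[i], v$funct[i]),
             paste(sprintf(" %12.6f", p), collapse = ""))
    }, "")
    out <- c(out, "", "[ virtual_sites3 ]", body)
  }
  if (!is.null(top$exclusions) && nrow(top$exclusions))
    out <- c(out, "", "[ exclusions ]",
             sprintf("%6d%6d", top$exclusions$ai, top$exclusions$aj))
  if (!is.null(top$position_restraints) && nrow(top$position_restraints)) {
    p <- top$position_restraints
    out <- c(out, "", "[ position_restraints ]",
             sprintf("%6d%6d   %s", p$ai, p$funct, p$params))
  }
  for (nm in setdiff(names(top$extra), "_preprocessor"))
    out <- c(out, "", sprintf("[ %s ]", nm), top$extra[[nm]])
  if (!is.null(top$extra[["_preprocessor"]]))
    out <- c(out, "", top$extra[["_preprocessor"]])
  out
}

#' Write a molecule topology as an ITP file
#' @param topology a `molecule_topology`.
#' @param path output path.
#' @export
write_itp <- function(topology, path) {
  writeLines(format_moleculetype(topology), path)
  invisible(path)
}

#' Write a TOP file
#' @param top a `top_model` (see [read_top()]).
#' @param path output path.
#' @export
write_top <- function(top, path) {
  out <- character()
  for (nm in names(top$header_extra)) {
    if (nm == "_preprocessor") out <- c(out, top$header_extra[[nm]], "")
    else out <- c(out, sprintf("[ %s ]", nm), top$header_extra[[nm]], "")
  }
  for (mt in top$molecule_types)
    out <- c(out, format_moleculetype(mt), "")
  out <- c(out, "[ system ]", top$system %||% "splitmem system", "",
           "[ molecules ]",
           sprintf("%-10s %6d", top$molecules$name, top$molecules$count))
  writeLines(out, path)
  invisible(path)
}
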