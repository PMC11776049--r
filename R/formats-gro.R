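#' Read a GRO coordinate file (single or multi frame)
#'
#' Fixed-column GRO: title, atom count, atom lines
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f` plus optional `%8.4f` velocities) and a
#' box line. Concatenated frames yield a [as_trajectory()] object; frame
#' times are taken from a `t=` field in the title when present. Only
#' orthorhombic boxes are accepted. Gzip-compressed files (`.gz`) are
#' handled transparently.
#'
#' @param path file path.
#' @return A `system_frame` (one frame) or a `trajectory` (several frames).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop_splitmem("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  frames <- list()
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    if (!nzchar(trimws(lines[i])) && i == nline) break
    title <- lines[i]
    if (i + 1L > nline)
      stop_splitmem("truncated GRO file at line ", i, ": missing atom count")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0)
      stop_splitmem("GRO parse error at line ", i + 1L,
                    ": expected atom count, got '", lines[i + 1L], "'")
    if (i + 1L + nat + 1L > nline)
      stop_splitmem("truncated GRO file: frame at line ", i, " declares ",
                    nat, " atoms but file ends early")
    body <- lines[(i + 2L):(i + 1L + nat)]
    atoms <- parse_gro_atoms(body, first_line = i + 2L)
    boxline <- lines[i + 2L + nat]
    box <- parse_gro_box(boxline, line_no = i + 2L + nat)
    tm <- NA_real_
    mt <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(mt)) tm <- as.numeric(sub("t=\\s*", "", mt))
    frames[[length(frames) + 1L]] <-
      system_frame(atoms, box, time = tm, title = sub("\\s+$", "", title))
    i <- i + 3L + nat
  }
  if (length(frames) == 0L) stop_splitmem("empty GRO file: ", path)
  if (length(frames) == 1L) frames[[1L]] else as_trajectory(frames)
}

parse_gro_atoms <- function(body, first_line) {
  nc <- nchar(body)
  if (any(nc < 44L)) {
    bad <- which(nc < 44L)[1L]
    stop_splitmem("GRO parse error at line ", first_line + bad - 1L,
                  ": atom line shorter than 44 columns")
  }
  resid <- suppressWarnings(as.integer(substr(body, 1L, 5L)))
  resname <- trimws(substr(body, 6L, 10L))
  name <- trimws(substr(body, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(body, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(body, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(body, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z) |
                 resname == "" | name == "")[1L]
  if (!is.na(bad))
    stop_splitmem("GRO parse error at line ", first_line + bad - 1L,
                  ": column misalignment")
  atoms <- data.frame(resid = resid, resname = resname, name = name,
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  if (all(nc >= 68L)) {
    vx <- suppressWarnings(as.numeric(substr(body, 45L, 52L)))
    vy <- suppressWarnings(as.numeric(substr(body, 53L, 60L)))
    vz <- suppressWarnings(as.numeric(substr(body, 61L, 68L)))
    if (!anyNA(vx) && !anyNA(vy) && !anyNA(vz)) {
      atoms$vx <- vx; atoms$vy <- vy; atoms$vz <- vz
    }
  }
  atoms
}

parse_gro_box <- function(boxline, line_no) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(boxline), "\\s+")[[1L]]))
  if (anyNA(v) || !(length(v) %in% c(3L, 9L)))
    stop_splitmem("GRO parse error at line ", line_no, ": bad box line")
  if (length(v) == 9L && any(v[4:9] != 0))
    stop_splitmem("triclinic box at line ", line_no,
                  ": only orthorhombic boxes are supported")
  v[1:3]
}

#' Write a GRO coordinate file
#'
#' Deterministic fixed-column writer; output is re-readable by [read_gro()]
#' and standard MD tooling. Velocities are written only when present in the
#' input (never fabricated). A trajectory is written as concatenated frames
#' with `t=` stamped into each title.
#'
#' @param x a `system_frame` or `trajectory`.
#' @param path output path.
#' @export
write_gro <- function(x, path) {
  if (inherits(x, "trajectory")) {
    txt <- unlist(lapply(seq_len(n_frames(x)),
                         function(i) format_gro_frame(traj_frame(x, i))))
  } else {
    txt <- format_gro_frame(x)
  }
  writeLines(txt, path)
  invisible(path)
}

format_gro_frame <- function(frame) {
  a <- frame$atoms
  if (any(nchar(a$name) > 5L) || any(nchar(a$resname) > 5L))
    stop_splitmem("atom/residue names longer than 5 characters")
  if (any(abs(c(a$x, a$y, a$z)) >= 9999.9995))
    stop_splitmem("coordinate overflows the %8.3f GRO field")
  title <- sub("\\s+t=.*$", "", frame$title)
  if (is.finite(frame$time)) title <- sprintf("%s t= %.5f", title, frame$time)
  has_vel <- all(c("vx", "vy", "vz") %in% names(a))
  atomnr <- seq_len(nrow(a)) %% 100000L
  resid <- a$resid %% 100000L
  lines <- if (has_vel) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
            resid, a$resname, a$name, atomnr, a$x, a$y, a$z,
            a$vx, a$vy, a$vz)
  } else {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid, a$resname, a$name, atomnr, a$x, a$y, a$z)
  }
  c(title, sprintf("%5d", nrow(a)), lines,
    sprintf("%10.5f%10.5f%10.5f", frame$box[1L], frame$box[2L], frame$box[3L]))
}

#' Read a PDB file (ATOM/HETATM/CRYST1 subset)
#'
#' Coordinates are converted from Angstrom to nm. Only the first MODEL is
#' read; a missing CRYST1 record is an error (the toolkit needs a box).
#'
#' @param path file path.
#' @return A `system_frame`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_splitmem("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  cryst <- lines[startsWith(lines, "CRYST1")]
  if (!length(cryst)) stop_splitmem("PDB file has no CRYST1 record: ", path)
  abc <- as.numeric(c(substr(cryst[1L], 7, 15), substr(cryst[1L], 16, 24),
                      substr(cryst[1L], 25, 33))) / 10
  ang <- as.numeric(c(substr(cryst[1L], 34, 40), substr(cryst[1L], 41, 47),
                      substr(cryst[1L], 48, 54)))
  if (any(abs(ang - 90) > 1e-6))
    stop_splitmem("triclinic CRYST1: only orthorhombic boxes are supported")
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop_splitmem("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    resid = as.integer(substr(rec, 23, 26)),
    resname = trimws(substr(rec, 18, 21)),
    name = trimws(substr(rec, 13, 16)),
    x = as.numeric(substr(rec, 31, 38)) / 10,
    y = as.numeric(substr(rec, 39, 46)) / 10,
    z = as.numeric(substr(rec, 47, 54)) / 10,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$resid))
    stop_splitmem("PDB parse error: malformed ATOM record")
  system_frame(atoms, abc, title = paste("read from", basename(path)))
}

#' Write a PDB file (ATOM/CRYST1 subset)
#' @param frame a `system_frame`.
#' @param path output path.
#' @export
write_pdb <- function(frame, path) {
  a <- frame$atoms
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            frame$box[1L] * 10, frame$box[2L] * 10, frame$box[3L] * 10,
            90, 90, 90),
    sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(nrow(a)) %% 100000L, substr(a$name, 1, 4),
            substr(a$resname, 1, 4), a$resid %% 10000L,
            a$x * 10, a$y * 10, a$z * 10),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a GROMACS NDX index file
#'
#' @param groups named list, group name -> sorted 1-based atom indices.
#'   Empty groups are written with a warning. 15 indices per line.
#' @param path output path.
#' @export
write_ndx <- function(groups, path) {
  out <- character()
  for (nm in names(groups)) {
    idx <- as.integer(groups[[nm]])
    if (length(idx) == 0L)
      warning("NDX group '", nm, "' is empty")
    if (is.unsorted(idx)) stop_splitmem("NDX group '", nm, "' is not sorted")
    out <- c(out, sprintf("[ %s ]", nm))
    if (length(idx)) {
      split_rows <- split(idx, (seq_along(idx) - 1L) %/% 15L)
      out <- c(out, vapply(split_rows, paste, "", collapse = " "))
    }
  }
  writeLines(out, path)
  invisible(path)
}
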