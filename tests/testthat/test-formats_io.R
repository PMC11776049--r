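test_that("read_gro parses hand-written frames and round-trips", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "toy frame t= 1.50000",
    "    3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "OW", 1, 1.0, 2.0, 3.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "HW1", 2, 1.1, 2.0, 3.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "HW2", 3, 0.9, 2.0, 3.0),
    "   5.00000   5.00000   5.00000"), f)
  fr <- read_gro(f)
  expect_s3_class(fr, "system_frame")
  expect_equal(nrow(fr$atoms), 3L)
  expect_equal(fr$box, c(5, 5, 5))
  expect_equal(fr$time, 1.5)
  expect_equal(fr$atoms$x, c(1.0, 1.1, 0.9))
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, f2)
  expect_identical(trimws(readLines(f), "right"),
                   trimws(readLines(f2), "right"))
})

test_that("multi-frame GRO becomes a trajectory with title times", {
  bl <- small_bilayer()
  f <- withr::local_tempfile(fileext = ".gro")
  fr1 <- bl$frame
  fr2 <- bl$frame; fr2$time <- 0.5
  write_gro(as_trajectory(list(fr1, fr2)), f)
  tr <- read_gro(f)
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$times, c(0, 0.5))
})

test_that("GRO reader rejects malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".gro")
  atom_line <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1, "SOL", "OW", 1, 1.0, 2.0, 3.0)
  writeLines(c("truncated", "    5", atom_line), f)
  expect_error(read_gro(f), "truncated")
  writeLines(c("bad box", "    1", atom_line,
               "   5.0   5.0   5.0   0.0   0.0   1.0   0.0   0.0   0.0"), f)
  expect_error(read_gro(f), "triclinic")
  writeLines(c("bad atom", "    1",
               sub("   2.000", "   x.xxx", atom_line, fixed = TRUE),
               "   5.0   5.0   5.0"), f)
  expect_error(read_gro(f), "line 3")
})

test_that("velocities are preserved, never fabricated", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("v frame", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                       1, "SOL", "OW", 1, 1.0, 2.0, 3.0, 0.1, -0.2, 0.3),
               "   5.00000   5.00000   5.00000"), f)
  fr <- read_gro(f)
  expect_equal(fr$atoms$vx, 0.1)
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, f2)
  expect_match(readLines(f2)[3], "0.3000$")
  # frame without velocities writes none
  fr$atoms$vx <- fr$atoms$vy <- fr$atoms$vz <- NULL
  write_gro(system_frame(fr$atoms, fr$box), f2)
  expect_equal(nchar(readLines(f2)[3]), 44L)
})

test_that("write_gro rejects field-width overflow", {
  atoms <- data.frame(resid = 1, resname = "ION", name = "NA",
                      x = 12345.0, y = 0, z = 0)
  expect_error(write_gro(system_frame(atoms, c(2, 2, 2)),
                         withr::local_tempfile()), "overflow")
})

test_that("ITP round trip: minimal molecule and fixture lipid", {
  f <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ moleculetype ]", "MINI 3", "[ atoms ]",
               "1 CT 1 MINI C1 1 0.10 12.0",
               "2 CT 1 MINI C2 2 -0.20 12.0",
               "3 CT 1 MINI C3 3 0.10 12.0",
               "4 CT 1 MINI C4 4 0.00 12.0",
               "[ bonds ]", "1 2 1 0.153 1000",
               "2 3 1 0.153 1000", "3 4 1 0.153 1000"), f)
  topo <- read_itp(f)
  expect_equal(nrow(topo$atoms), 4L)
  expect_equal(nrow(topo$bonds), 3L)
  expect_equal(total_charge(topo), 0.0, tolerance = 1e-9)
  # read -> write -> read fixed point
  f2 <- withr::local_tempfile(fileext = ".itp")
  write_itp(topo, f2)
  topo2 <- read_itp(f2)
  f3 <- withr::local_tempfile(fileext = ".itp")
  write_itp(topo2, f3)
  expect_identical(readLines(f2), readLines(f3))
  # fixture POPC: declared atom count and neutrality
  pf <- withr::local_tempfile(fileext = ".itp")
  write_itp(fixture_topology("POPC"), pf)
  popc <- read_itp(pf)
  expect_equal(nrow(popc$atoms), 52L)
  expect_equal(total_charge(popc), 0.0, tolerance = 1e-6)
})

test_that("ITP parser flags structural errors and passes unknowns through", {
  f <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ moleculetype ]", "BAD 3", "[ atoms ]",
               "1 CT 1 BAD C1 1 0.0 12.0",
               "1 CT 1 BAD C2 2 0.0 12.0"), f)
  expect_error(read_itp(f), "duplicate")
  writeLines(c("[ moleculetype ]", "BAD 3", "[ atoms ]",
               "1 CT 1 BAD C1 1 0.0 12.0",
               "[ bonds ]", "1 7 1"), f)
  expect_error(read_itp(f), "out of range")
  writeLines(c("[ moleculetype ]", "OK 3", "[ atoms ]",
               "1 CT 1 OK C1 1 0.0 12.0",
               "[ funkysection ]", "some opaque line 1 2 3"), f)
  expect_warning(topo <- read_itp(f), "funkysection")
  f2 <- withr::local_tempfile(fileext = ".itp")
  write_itp(topo, f2)
  expect_true(any(grepl("funkysection", readLines(f2))))
  expect_true(any(grepl("some opaque line 1 2 3", readLines(f2))))
})

test_that("write_ndx formats groups at 15 indices per line", {
  f <- withr::local_tempfile(fileext = ".ndx")
  write_ndx(list(C1_heads = 1:3), f)
  expect_identical(readLines(f), c("[ C1_heads ]", "1 2 3"))
  write_ndx(list(big = 1:20), f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  expect_equal(length(strsplit(lines[2], " ")[[1]]), 15L)
  expect_warning(write_ndx(list(empty = integer()), f), "empty")
  write_ndx(list(), f)
  expect_equal(length(readLines(f)), 0L)
})

test_that("PDB subset reader/writer round-trips coordinates in nm", {
  bl <- small_bilayer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(bl$frame, f)
  fr <- read_pdb(f)
  expect_equal(nrow(fr$atoms), nrow(bl$frame$atoms))
  expect_equal(fr$box, bl$frame$box, tolerance = 1e-4)
  expect_equal(fr$atoms$z, round(bl$frame$atoms$z, 4), tolerance = 1e-4)
})
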