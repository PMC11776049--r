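# hand-built trajectory helpers
linear_traj <- function(v = c(0.2, 0.1), n = 20, dt = 0.5, box = c(50, 50, 10)) {
  frames <- lapply(seq_len(n) - 1L, function(i) {
    atoms <- data.frame(resid = 1L, resname = "BRW", name = "P1",
                        x = 1 + v[1] * i * dt, y = 1 + v[2] * i * dt, z = 5)
    system_frame(atoms, box, time = i * dt)
  })
  as_trajectory(frames)
}

test_that("lateral MSD: ballistic and stationary closed forms", {
  v <- c(0.2, 0.1)
  tr <- linear_traj(v)
  m <- lateral_msd(tr)
  expect_equal(m$msd, sum(v^2) * m$lag^2, tolerance = 1e-9)
  still <- linear_traj(c(0, 0))
  expect_lt(max(abs(lateral_msd(still)$msd)), 1e-12)
  expect_error(lateral_msd(linear_traj(n = 2), selection = integer()),
               "empty")
})

test_that("FFT MSD agrees with the brute-force oracle", {
  set.seed(5)
  for (N in c(8, 33, 100)) {
    x <- cumsum(rnorm(N))
    expect_equal(splitmem:::msd_fft_1d(x), splitmem:::msd_brute_1d(x),
                 tolerance = 1e-9)
  }
})

test_that("MSD unwraps periodic crossings", {
  # particle drifting through the boundary of a small box
  n <- 30; box <- c(2, 2, 5)
  frames <- lapply(seq_len(n) - 1L, function(i) {
    atoms <- data.frame(resid = 1L, resname = "BRW", name = "P1",
                        x = (0.5 + 0.15 * i) %% 2, y = 1, z = 2.5)
    system_frame(atoms, box, time = i * 1.0)
  })
  m <- lateral_msd(as_trajectory(frames))
  expect_equal(m$msd, (0.15 * m$lag)^2, tolerance = 1e-9)
})

test_that("fit_diffusion applies the lateral Einstein relation", {
  msd <- data.frame(lag = seq(0, 100, by = 1), msd = 0.4 * seq(0, 100, 1))
  d <- fit_diffusion(msd, c(10, 90))
  expect_equal(d$D, 0.1, tolerance = 1e-12)
  flat <- data.frame(lag = seq(0, 100, 1), msd = 2)
  expect_equal(fit_diffusion(flat, c(10, 90))$D, 0)
  expect_error(fit_diffusion(msd, c(200, 300)), "window")
})

test_that("Brownian fixture diffusion is recovered within 10%", {
  traj <- brownian_trajectory(n_particles = 500, D_target = 0.05,
                              dt = 0.1, n_frames = 2000, seed = 42)
  m <- lateral_msd(traj, max_lag = 100)
  d <- fit_diffusion(m, window = c(5, 50))
  expect_lt(abs(d$D - 0.05) / 0.05, 0.10)
  expect_true(is.finite(d$D_err))
})

test_that("diffusion_time and speedup reproduce their closed forms", {
  expect_equal(diffusion_time(1, 2), 0.001)            # 1 ns
  expect_error(diffusion_time(0), "D > 0")
  expect_equal(speedup(2, 2), 1)
  expect_error(speedup(1, 0), "zero")
})

test_that("density profile units, flatness and symmetry", {
  # single atom of mass m in a 1x1x10 box, 1 nm bins:
  # density = m / (1 nm^3) = m * 1.66054 kg/m^3
  atoms <- data.frame(resid = 1L, resname = "POPC", name = "P",
                      x = 0.5, y = 0.5, z = 5.5)
  fr <- system_frame(atoms, c(1, 1, 10))
  dp <- density_profile(fr, list(p = list(name = "P")), bin_width = 1)
  m_p <- 30.974
  expect_equal(sum(dp$p), m_p * 1.66053906660, tolerance = 1e-6)
  # uniform slab is flat within 3 sigma Poisson noise
  set.seed(9)
  n <- 4000
  wat <- data.frame(resid = seq_len(n), resname = "SOL", name = "OW",
                    x = runif(n, 0, 3), y = runif(n, 0, 3),
                    z = runif(n, 0, 6))
  frw <- system_frame(wat, c(3, 3, 6))
  dpw <- density_profile(frw, list(w = list(name = "OW")), bin_width = 0.5,
                         lipid_selection = seq_len(n))
  counts_per_bin <- n / length(dpw$z)
  rel_sd <- stats::sd(dpw$w) / mean(dpw$w)
  expect_lt(rel_sd, 3 / sqrt(counts_per_bin))
  # fixture bilayer: symmetric profile and mass conservation
  bl <- small_bilayer()
  dpl <- density_profile(bl$frame, list(lip = list(resname = c("POPC", "POPS"))),
                         bin_width = 0.2, topologies = bl$topologies)
  prof <- dpl$lip
  expect_lt(max(abs(prof - rev(prof))), 0.05 * max(prof) + 1e-12)
  # integral x box area = selected mass per frame (+-1%)
  area <- bl$frame$box[1] * bl$frame$box[2]
  integral <- sum(prof) * attr(dpl, "bin_width") * area / 1.66053906660
  sel_mass <- sum(splitmem:::mass_lookup(bl$frame$atoms, bl$topologies)[
    bl$frame$atoms$resname %in% c("POPC", "POPS")])
  expect_equal(integral, sel_mass, tolerance = 0.01)
})

test_that("order parameters hit the exact geometric limits", {
  # all-trans chain along z, reconstructed hydrogens: S_CD = -0.5 exactly
  ch <- ideal_chain(12)
  atoms <- data.frame(resid = 1L, resname = "POPCT",
                      name = sprintf("C2%d", 2:13),
                      x = ch$carbons[, 1] + 2, y = ch$carbons[, 2] + 2,
                      z = ch$carbons[, 3] + 1)
  fr <- system_frame(atoms, c(4, 4, 6))
  op <- order_parameters(fr, list(POPCT = list(SN2 = sprintf("C2%d", 2:13))))
  expect_equal(op$scd, rep(-0.5, nrow(op)), tolerance = 1e-6)
  # explicit hydrogens along z while the chain lies in the plane: S_CD = +1
  atoms2 <- data.frame(resid = 1L, resname = "XLIP",
                       name = c("CA", "CB", "CC", "HA"),
                       x = c(1, 1.15, 1.30, 1.15), y = 1,
                       z = c(1, 1.05, 1, 1.05 + 0.109))
  fr2 <- system_frame(atoms2, c(3, 3, 3))
  op2 <- order_parameters(
    fr2, list(XLIP = list(SN1 = c("CA", "CB", "CC"),
                          hydrogens = list(CB = "HA"))),
    hydrogen_mode = "explicit")
  expect_equal(op2$scd[op2$carbon == "CB"], 1.0, tolerance = 1e-9)
  # isotropically rotated rigid chains average to zero (Monte-Carlo oracle
  # of the orientational average; uniform rotations via QR of a Gaussian)
  set.seed(31)
  base <- ideal_chain(8)$carbons
  frames <- lapply(1:400, function(i) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    co <- base %*% t(R)
    atoms <- data.frame(resid = 1L, resname = "POPCT",
                        name = sprintf("C2%d", 2:9),
                        x = co[, 1] + 10, y = co[, 2] + 10, z = co[, 3] + 10)
    system_frame(atoms, c(20, 20, 20), time = i - 1)
  })
  opi <- order_parameters(as_trajectory(frames),
                          list(POPCT = list(SN2 = sprintf("C2%d", 2:9))))
  # per carbon: 400 independent frames; Var[P2(cos theta)] = 1/5
  expect_lt(max(abs(opi$scd)), 3 * sqrt(0.2 / 400))
})

test_that("order parameters error on missing carbons", {
  bl <- small_bilayer()
  expect_error(order_parameters(bl$frame,
                                list(POPC = list(SN1 = c("C32", "NOPE", "C34")))),
               "NOPE")
})

test_that("P-N angle convention", {
  mk <- function(nvec, z0 = 6) {
    atoms <- rbind(
      data.frame(resid = 1L, resname = "POPC", name = "P",
                 x = 2, y = 2, z = z0),
      data.frame(resid = 1L, resname = "POPC", name = "N",
                 x = 2 + nvec[1], y = 2 + nvec[2], z = z0 + nvec[3]),
      data.frame(resid = 2L, resname = "POPC", name = "P",
                 x = 2, y = 2, z = 2),
      data.frame(resid = 2L, resname = "POPC", name = "N",
                 x = 2.3, y = 2, z = 2))
    system_frame(atoms, c(4, 4, 8))
  }
  r <- pn_angle(mk(c(0, 0, 1)))
  up <- r$angles[r$angles$leaflet == "upper", ]
  expect_equal(up$angle_deg, 0, tolerance = 1e-9)
  r2 <- pn_angle(mk(c(1, 0, 0)))
  expect_equal(r2$angles$angle_deg, c(90, 90), tolerance = 1e-9)
  # fixture bilayer is built with in-plane P->N vectors
  bl <- small_bilayer()
  expect_warning(rb <- pn_angle(bl$frame), regexp = NA)
  expect_equal(rb$mean, 90, tolerance = 1e-6)
  # species lacking N are skipped with a warning
  bla <- build_bilayer(c(POPC = 4, POPA = 4), waters_per_lipid = 1, seed = 5)
  expect_warning(ra <- pn_angle(bla$frame), "POPA")
  expect_equal(ra$mean, 90, tolerance = 1e-6)
})

test_that("area per lipid arithmetic", {
  atoms <- data.frame(resid = 1L, resname = "POPC", name = "P",
                      x = 1, y = 1, z = 1)
  fr <- system_frame(atoms, c(8, 8, 10))
  expect_equal(area_per_lipid(fr, 64)$mean, 1.0)
  fr2 <- system_frame(atoms, c(6.4912, 6.4912, 10))
  expect_equal(area_per_lipid(fr2, 64)$mean, 6.4912^2 / 64)
  tr <- as_trajectory(list(fr, system_frame(atoms, c(8, 8, 10), time = 1)))
  r <- area_per_lipid(tr, 64)
  expect_equal(r$se, 0)
  expect_error(area_per_lipid(fr, 0), "> 0")
})

test_that("thickness from reference planes", {
  atoms <- data.frame(resid = 1:2, resname = "POPC", name = "P",
                      x = 1, y = 1, z = c(7, 3))
  fr <- system_frame(atoms, c(4, 4, 10))
  expect_equal(thickness(fr, "P", lipid_selection = 1:2)$thickness, 4.0)
  # rigid translation leaves thickness unchanged
  atoms$z <- atoms$z + 0.8
  fr2 <- system_frame(atoms, c(4, 4, 10))
  expect_equal(thickness(fr2, "P", lipid_selection = 1:2)$thickness, 4.0)
  # fixture: head planes at +-1.9 nm
  bl <- small_bilayer()
  expect_equal(thickness(bl$frame, "P")$thickness, 3.8, tolerance = 1e-6)
  # one-leaflet references rejected: both P sit above the membrane COM
  oneside <- data.frame(resid = 1:3, resname = "POPC",
                        name = c("P", "P", "C313"),
                        x = 1, y = 1, z = c(7, 8, 0.5))
  expect_error(thickness(system_frame(oneside, c(4, 4, 10)), "P"),
               "one leaflet")
})

test_that("RDF normalisation: ideal gas, single pair, count conservation", {
  set.seed(2)
  n <- 500
  atoms <- data.frame(resid = seq_len(n), resname = "GAS", name = "X",
                      x = runif(n, 0, 6), y = runif(n, 0, 6),
                      z = runif(n, 0, 6))
  fr <- system_frame(atoms, c(6, 6, 6))
  g <- rdf(fr, NULL, NULL, r_max = 2.9, dr = 0.1)
  tail_bins <- g$g[g$r > 1]
  expect_equal(mean(tail_bins), 1, tolerance = 0.05)
  # two particles: single occupied bin at their distance
  two <- data.frame(resid = 1:2, resname = "GAS", name = "X",
                    x = c(1, 2.2), y = 1, z = 1)
  g2 <- rdf(system_frame(two, c(6, 6, 6)), NULL, NULL, r_max = 2.9, dr = 0.1)
  counts <- attr(g2, "counts")
  expect_equal(sum(counts), 2)   # ordered pairs
  expect_equal(g2$r[which(counts > 0)], 1.25)
  # halving dr conserves total pair count
  g3 <- rdf(fr, NULL, NULL, r_max = 2.9, dr = 0.05)
  expect_equal(sum(attr(g3, "counts")), sum(attr(g, "counts")))
  expect_error(rdf(fr, NULL, NULL, r_max = 4), "half")
})

test_that("observables are invariant under rigid motions", {
  bl <- small_bilayer()
  fr <- bl$frame
  shifted <- fr$atoms
  shifted$x <- shifted$x + 0.4; shifted$y <- shifted$y - 0.2
  shifted$z <- shifted$z + 0.3
  fr2 <- system_frame(shifted, fr$box)
  expect_equal(pn_angle(fr2)$mean, pn_angle(fr)$mean, tolerance = 1e-9)
  expect_equal(thickness(fr2, "P")$thickness, thickness(fr, "P")$thickness,
               tolerance = 1e-9)
  # MSD invariant under rotation about z
  traj <- brownian_trajectory(30, 0.05, 0.2, 60, seed = 3)
  m1 <- lateral_msd(traj)
  rot <- traj
  th <- 0.7
  x <- traj$coords[, 1, ]; y <- traj$coords[, 2, ]
  rot$coords[, 1, ] <- cos(th) * x - sin(th) * y
  rot$coords[, 2, ] <- sin(th) * x + cos(th) * y
  attr(rot, "unwrapped") <- NULL
  un <- attr(traj, "unwrapped")
  rot$coords[, 1, ] <- cos(th) * un[, 1, ] - sin(th) * un[, 2, ]
  rot$coords[, 2, ] <- sin(th) * un[, 1, ] + cos(th) * un[, 2, ]
  m2 <- lateral_msd(rot)
  expect_equal(m2$msd, m1$msd, tolerance = 1e-9)
})
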