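#' Lateral mean squared displacement
#'
#' Per-molecule lateral (xy) centres of mass are tracked across frames,
#' unwrapped over the periodic boundaries, and averaged over molecules and
#' all time origins: `msd(tau) = <|r_xy(t + tau) - r_xy(t)|^2>`. The
#' averaging uses the FFT-based O(n log n) algorithm; a brute-force
#' reference implementation is kept internally for cross-checks.
#'
#' @param traj a `trajectory` (uniform frame spacing required).
#' @param selection atom selection (see [membrane_com()]); each touched
#'   molecule contributes the COM of its selected atoms. Default: all
#'   atoms.
#' @param max_lag largest lag time, ns; default half the trajectory length.
#' @param drift_correction `"none"` (default), `"system_com"` (subtract the
#'   per-frame COM of the selection) or `"leaflet_com"` (subtract per-frame
#'   leaflet COMs, leaflets fixed from the first frame).
#' @param masses optional per-atom masses for the COM weighting; inferred
#'   from atom names by default.
#' @return Object of class `msd_series`: data.frame `lag` (ns), `msd`
#'   (nm^2), `n_origins`; per-molecule curves in attribute `"per_molecule"`.
#' @export
lateral_msd <- function(traj, selection = NULL,
                        max_lag = NULL,
                        drift_correction = c("none", "system_com",
                                             "leaflet_com"),
                        masses = NULL) {
  drift_correction <- match.arg(drift_correction)
  traj <- as_traj_input(traj)
  nf <- n_frames(traj)
  if (nf < 2L) stop_splitmem("MSD needs at least two frames")
  dts <- diff(traj$times)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop_splitmem("MSD requires uniformly spaced frames")
  dt <- dts[1L]
  idx <- resolve_selection(traj$atoms, selection)
  if (!length(idx)) stop_splitmem("MSD selection is empty")
  com <- molecule_com_series(traj, idx, masses)   # n_mol x 2 x nf, unwrapped
  n_mol <- dim(com)[1L]
  if (drift_correction == "system_com") {
    for (d in 1:2) {
      drift <- colMeans(com[, d, , drop = FALSE][, 1L, ])
      com[, d, ] <- sweep(com[, d, , drop = FALSE][, 1L, ], 2L, drift)
    }
  } else if (drift_correction == "leaflet_com") {
    leaf <- assign_leaflets(traj_frame(traj, 1L))
    mol_ids <- as.integer(dimnames(com)[[1L]])
    lab <- setNames(as.character(leaf$leaflet), leaf$molid)[as.character(mol_ids)]
    if (anyNA(lab))
      stop_splitmem("leaflet drift correction: selection contains ",
                    "non-lipid molecules")
    for (lf in unique(lab)) {
      rows <- which(lab == lf)
      for (d in 1:2) {
        drift <- colMeans(com[rows, d, , drop = FALSE][, 1L, , drop = FALSE])
        com[rows, d, ] <- sweep(com[rows, d, , drop = FALSE][, 1L, ],
                                2L, drift)
      }
    }
  }
  max_lag_frames <- if (is.null(max_lag)) (nf - 1L) %/% 2L
                    else min(nf - 1L, floor(max_lag / dt + 1e-9))
  per_mol <- matrix(0, nrow = max_lag_frames + 1L, ncol = n_mol)
  for (m in seq_len(n_mol)) {
    mx <- msd_fft_1d(com[m, 1L, ])
    my <- msd_fft_1d(com[m, 2L, ])
    per_mol[, m] <- (mx + my)[seq_len(max_lag_frames + 1L)]
  }
  lags <- (0:max_lag_frames) * dt
  out <- data.frame(lag = lags,
                    msd = rowMeans(per_mol),
                    n_origins = (nf - 0:max_lag_frames) * n_mol)
  out$msd[1L] <- 0
  structure(out, class = c("msd_series", "data.frame"),
            per_molecule = per_mol, dt = dt)
}

# per-molecule COM (selected atoms only), unwrapped across PBC by
# nearest-image continuity between consecutive frames
molecule_com_series <- function(traj, idx, masses = NULL) {
  atoms <- traj$atoms
  m <- if (is.null(masses)) guess_mass(atoms$name[idx]) else masses[idx]
  m[m <= 0] <- 1e-12     # virtual sites never dominate a COM
  molid_per_atom <- rep(traj$molecules$molid, traj$molecules$n)
  grp <- molid_per_atom[idx]
  mol_ids <- unique(grp)
  nf <- n_frames(traj)
  # unwrap selected atom coordinates along frames
  un <- attr(traj, "unwrapped")
  xy <- array(0, dim = c(length(idx), 2L, nf))
  for (d in 1:2) {
    co <- traj$coords[idx, d, , drop = FALSE][, 1L, , drop = FALSE]
    co <- matrix(co, nrow = length(idx))
    if (!is.null(un)) {
      co <- matrix(un[idx, d, , drop = FALSE][, 1L, , drop = FALSE],
                   nrow = length(idx))
    } else if (nf > 1L) {
      L <- traj$box[, d]
      dco <- co[, -1L, drop = FALSE] - co[, -nf, drop = FALSE]
      dco <- dco - rep(L[-1L], each = nrow(dco)) *
        round(dco / rep(L[-1L], each = nrow(dco)))
      co <- cbind(co[, 1L], co[, 1L] +
                    if (ncol(dco) == 1L) dco else t(apply(dco, 1L, cumsum)))
    }
    xy[, d, ] <- co
  }
  wsum <- tapply(m, grp, sum)
  com <- array(0, dim = c(length(mol_ids), 2L, nf),
               dimnames = list(mol_ids, NULL, NULL))
  for (d in 1:2) {
    wco <- xy[, d, , drop = FALSE][, 1L, , drop = FALSE] * m
    wco <- matrix(wco, nrow = length(idx))
    sums <- rowsum(wco, grp, reorder = FALSE)
    com[, d, ] <- sums / as.numeric(wsum[rownames(sums)])
  }
  dimnames(com)[[1L]] <- rownames(rowsum(matrix(0, length(idx), 1L), grp,
                                         reorder = FALSE))
  com
}

# FFT-based MSD of one 1D coordinate series, all time origins
msd_fft_1d <- function(x) {
  N <- length(x)
  # S2 via autocorrelation
  fx <- stats::fft(c(x, rep(0, N)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(N)] / (2 * N)
  S2 <- ac / (N - 0:(N - 1L))
  # S1 via the standard recursion
  D <- x * x
  Q <- 2 * sum(D)
  S1 <- numeric(N)
  for (tau in 0:(N - 1L)) {
    if (tau > 0L) Q <- Q - D[tau] - D[N - tau + 1L]
    S1[tau + 1L] <- Q / (N - tau)
  }
  S1 - 2 * S2
}

# brute-force MSD oracle (quadratic; used by the test suite only)
msd_brute_1d <- function(x) {
  N <- length(x)
  vapply(0:(N - 1L), function(tau) {
    if (tau == 0L) return(0)
    mean((x[(1L + tau):N] - x[seq_len(N - tau)])^2)
  }, 0.0)
}

#' Fit the lateral diffusion coefficient from an MSD curve
#'
#' Least-squares line on `msd` vs lag restricted to the fit window; the
#' lateral (2D) Einstein relation gives `D = slope / 4`. The uncertainty is
#' a two-halves block estimate: the tracked molecules are split into two
#' halves, the fit repeated on each, and `D_err = |D1 - D2| / 2` (for a
#' single molecule the window is split in time instead).
#'
#' @param msd an `msd_series` from [lateral_msd()], or a data.frame with
#'   `lag` and `msd` columns.
#' @param window `c(t_min, t_max)` fit window, ns; the published analysis
#'   fits 50-400 ns of simulation time where the MSD curve is linear.
#' @return Object of class `diffusion_result`: list `D` (nm^2/ns), `D_err`,
#'   `fit_window`, `n_points`.
#' @export
fit_diffusion <- function(msd, window = c(50, 400)) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  rows <- which(msd$lag >= window[1L] & msd$lag <= window[2L])
  if (length(rows) < 2L)
    stop_splitmem("fit window [", window[1L], ", ", window[2L],
                  "] ns contains fewer than 2 MSD points")
  fit <- stats::lm.fit(cbind(1, msd$lag[rows]), msd$msd[rows])
  D <- unname(fit$coefficients[2L]) / 4
  D_err <- NA_real_
  pm <- attr(msd, "per_molecule")
  fit_sub <- function(y, lags) {
    f <- stats::lm.fit(cbind(1, lags), y)
    unname(f$coefficients[2L]) / 4
  }
  if (!is.null(pm) && ncol(pm) >= 2L) {
    half <- seq_len(ncol(pm) %/% 2L)
    D1 <- fit_sub(rowMeans(pm[rows, half, drop = FALSE]), msd$lag[rows])
    D2 <- fit_sub(rowMeans(pm[rows, -half, drop = FALSE]), msd$lag[rows])
    D_err <- abs(D1 - D2) / 2
  } else if (length(rows) >= 4L) {
    h <- rows[seq_len(length(rows) %/% 2L)]
    D1 <- fit_sub(msd$msd[h], msd$lag[h])
    D2 <- fit_sub(msd$msd[setdiff(rows, h)], msd$lag[setdiff(rows, h)])
    D_err <- abs(D1 - D2) / 2
  }
  structure(list(D = max(D, 0), D_err = D_err, fit_window = window,
                 n_points = length(rows)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("D = %.4g nm^2/ns (err %.2g), window %g-%g ns\n",
              x$D, x$D_err, x$fit_window[1L], x$fit_window[2L]))
  invisible(x)
}

#' Time to diffuse a given average lateral displacement
#'
#' From the 2D Einstein relation, the simulation time for a mean squared
#' displacement of `displacement^2` is `tau = displacement^2 / (4 D)`.
#' With the default 20 nm displacement this reproduces the published
#' per-system diffusion times from the corresponding D values.
#'
#' @param D lateral diffusion coefficient, nm^2/ns (> 0).
#' @param displacement average lateral displacement, nm.
#' @return tau in microseconds.
#' @export
diffusion_time <- function(D, displacement = 20) {
  if (any(D <= 0)) stop_splitmem("diffusion_time requires D > 0")
  displacement^2 / (4 * D) / 1000
}

#' Diffusion speedup ratio of the split model
#'
#' @param D_split,D_standard lateral diffusion coefficients (same units,
#'   both > 0).
#' @return `D_split / D_standard` to 3 significant figures.
#' @export
speedup <- function(D_split, D_standard) {
  if (any(D_standard == 0)) stop_splitmem("zero denominator in speedup")
  if (any(D_split <= 0) || any(D_standard < 0))
    stop_splitmem("speedup requires positive diffusion coefficients")
  signif(D_split / D_standard, 3)
}
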