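# Solvation structure and dynamics: radial distribution functions,
# geometric hydrogen-bond counting, and lateral diffusion from MSD.

#' Radial distribution function g(r)
#'
#' Minimum-image A-B distances histogrammed per frame and normalised by
#' the ideal-gas expectation: shell volume (exact spherical shells) times
#' the instantaneous number density of B partners, so an uncorrelated
#' homogeneous system gives g = 1 at every r.  Identical atoms appearing
#' in both selections are excluded as self pairs, and the partner density
#' is reduced accordingly.
#'
#' @param traj a [trajectory()]
#' @param a_indices,b_indices atom index vectors
#' @param r_max maximum distance, Angstrom; must not exceed half the
#'   smallest box edge of any frame
#' @param dr bin width, Angstrom
#' @return data.frame of class `"rdf_result"`: `r` (bin middle), `g`;
#'   attributes `n_frames`, `rho_B` (mean partner density, A^-3)
#' @export
rdf <- function(traj, a_indices, b_indices, r_max, dr = 0.1) {
  if (dr <= 0) stop("dr must be > 0")
  half_min <- min(traj$boxes) / 2
  if (r_max > half_min + 1e-9) {
    stop(sprintf("r_max = %g A exceeds half the smallest box edge (%g A)",
                 r_max, half_min))
  }
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  overlap <- sum(a_indices %in% b_indices) / length(a_indices)
  n_partners <- length(b_indices) - overlap     # partners available per A
  g <- numeric(nb)
  rho_acc <- 0
  for (fi in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , fi]
    box <- traj$boxes[fi, ]
    counts <- .rdf_frame_counts(xyz, box, a_indices, b_indices, edges)
    rho <- n_partners / prod(box)               # instantaneous box volume
    rho_acc <- rho_acc + rho
    g <- g + counts / (length(a_indices) * rho * shell)
  }
  nf <- n_frames(traj)
  structure(data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                       g = g / nf),
            n_frames = nf, rho_B = rho_acc / nf,
            class = c("rdf_result", "data.frame"))
}

.rdf_frame_counts <- function(xyz, box, a_indices, b_indices, edges) {
  dx <- outer(xyz[a_indices, 1], xyz[b_indices, 1], "-")
  dy <- outer(xyz[a_indices, 2], xyz[b_indices, 2], "-")
  dz <- outer(xyz[a_indices, 3], xyz[b_indices, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- dz - box[3] * round(dz / box[3])
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(a_indices %in% b_indices)) {
    self <- outer(a_indices, b_indices, "==")
    d[self] <- Inf
  }
  nb <- length(edges) - 1L
  b <- findInterval(d[d <= edges[nb + 1L]], edges, rightmost.closed = TRUE)
  tabulate(pmin(pmax(b, 1L), nb), nbins = nb)
}

#' Count geometric hydrogen bonds in a frame
#'
#' A hydrogen bond is counted for each (donor D, hydrogen H, acceptor A)
#' triple with minimum-image H...A distance at most `d_cut` and D-H...A
#' angle (at the hydrogen) at least `angle_cut`.  Every hydrogen must be
#' mapped to its covalent donor.
#'
#' @param fr a [frame()]
#' @param hydrogens hydrogen atom indices
#' @param donor_of integer vector parallel to `hydrogens`: the donor atom
#'   index of each hydrogen
#' @param acceptors acceptor atom indices
#' @param d_cut H...A distance cutoff, Angstrom
#' @param angle_cut D-H...A angle cutoff, degrees
#' @return integer count
#' @export
hbond_count <- function(fr, hydrogens, donor_of, acceptors,
                        d_cut = 2.5, angle_cut = 150) {
  if (length(donor_of) != length(hydrogens) || anyNA(donor_of)) {
    stop("every hydrogen must be mapped to a donor")
  }
  count <- 0L
  for (i in seq_along(hydrogens)) {
    h <- fr$xyz[hydrogens[i], ]
    dvec <- minimum_image(fr$xyz[donor_of[i], ] - h, fr$box)
    avec <- minimum_image(sweep(fr$xyz[acceptors, , drop = FALSE], 2, h),
                          fr$box)
    dist <- sqrt(rowSums(avec^2))
    ok <- dist <= d_cut & acceptors != donor_of[i] & dist > 0
    if (!any(ok)) next
    ca <- (avec[ok, , drop = FALSE] %*% dvec) /
      (dist[ok] * sqrt(sum(dvec^2)))
    ang <- acos(pmin(1, pmax(-1, ca))) * 180 / pi
    count <- count + sum(ang >= angle_cut)
  }
  count
}

#' Map water hydrogens to their donor oxygens
#'
#' Pairs every `water_H` atom with the `water_O` of the same residue.
#'
#' @param top a [topology()]
#' @return list with `hydrogens` and `donor_of` index vectors
#' @export
water_donor_map <- function(top) {
  hyd <- which(has_role(top, "water_H"))
  oxy <- which(has_role(top, "water_O"))
  if (!length(hyd) || !length(oxy)) stop("no water atoms tagged")
  o_of_res <- setNames(oxy, top$atoms$residue_index[oxy])
  donor_of <- o_of_res[as.character(top$atoms$residue_index[hyd])]
  if (anyNA(donor_of)) stop("unmapped water hydrogen (no oxygen in residue)")
  list(hydrogens = hyd, donor_of = unname(donor_of))
}

# Exact all-time-origin MSD of one signal via the FFT autocorrelation
# identity (Calandrini et al. scheme): O(n log n) instead of O(n^2).
.msd_1d <- function(x) {
  n <- length(x)
  fx <- stats::fft(c(x, rep(0, n)))
  s2 <- Re(stats::fft(Mod(fx)^2, inverse = TRUE))[1:n] / (2 * n)
  d <- x^2
  q <- 2 * sum(d)
  out <- numeric(n)
  for (m in 0:(n - 1L)) {
    if (m > 0L) q <- q - d[m] - d[n - m + 1L]
    out[m + 1L] <- q / (n - m) - 2 * s2[m + 1L] / (n - m)
  }
  out
}

#' Lateral diffusion coefficient from mean-squared displacement
#'
#' MSD in the xy plane, averaged over the selected particles and over all
#' time origins (stride 1, computed exactly via FFT autocorrelation).  The
#' diffusion coefficient follows from the Einstein relation for two
#' dimensions, `D = slope / 4`, with the slope from an ordinary
#' least-squares fit over the requested lag window, reported in cm^2 s^-1.
#' Requires unwrapped coordinates: displacement across a wrapped boundary
#' is meaningless, so a wrapped trajectory is an error.
#'
#' @param traj a [trajectory()] with `unwrapped = TRUE`
#' @param indices particle atom indices
#' @param fit_window c(lo, hi) lag-time window for the fit, ns; default is
#'   10% to 50% of the maximum available lag
#' @param max_lag_frac largest lag considered, as a fraction of the
#'   trajectory length
#' @return object of class `"msd_result"`: `lag` (ns), `msd` (A^2),
#'   `fit_window`, `D_cm2_s`, `D_se_cm2_s`
#' @export
lateral_diffusion <- function(traj, indices, fit_window = NULL,
                              max_lag_frac = 0.5) {
  if (!isTRUE(traj$unwrapped)) {
    stop("trajectory coordinates are wrapped; MSD requires unwrapped coordinates")
  }
  nf <- n_frames(traj)
  dts <- diff(traj$times)
  if (diff(range(dts)) > 1e-9 * max(dts)) stop("frame times must be uniform")
  dt <- dts[1]
  msd <- numeric(nf)
  for (a in indices) {
    msd <- msd + .msd_1d(traj$coords[a, 1, ]) + .msd_1d(traj$coords[a, 2, ])
  }
  msd <- msd / length(indices)
  keep <- seq_len(max(2L, floor(nf * max_lag_frac)))
  lag <- (keep - 1L) * dt
  msd <- msd[keep]
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * max(lag)
  sel <- lag >= fit_window[1] & lag <= fit_window[2]
  if (sum(sel) < 2L) stop("fit window contains fewer than 2 lags")
  fit <- stats::lm(msd[sel] ~ lag[sel])
  slope <- unname(stats::coef(fit)[2])                 # A^2 / ns
  se <- summary(fit)$coefficients[2, 2]
  conv <- 1e-16 / 1e-9                                 # A^2/ns -> cm^2/s
  structure(list(lag = lag, msd = msd, fit_window = fit_window,
                 D_cm2_s = slope / 4 * conv, D_se_cm2_s = se / 4 * conv),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> D = %.4g +/- %.2g cm^2/s (fit %g..%g ns, %d lags)\n",
              x$D_cm2_s, x$D_se_cm2_s, x$fit_window[1], x$fit_window[2],
              length(x$lag)))
  invisible(x)
}
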