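# Weighted histogram analysis method (WHAM) for umbrella sampling, PMF
# anchoring, and barrier decomposition.
#
# The self-consistent equations solved here are the standard ones for
# harmonic biases w_i(z) = 0.5 k_i (z - c_i)^2:
#
#   P(z_b) = sum_i n_ib / sum_i N_i exp[(f_i - w_i(z_b)) / kBT]
#   exp(-f_i / kBT) = sum_b P(z_b) exp(-w_i(z_b) / kBT)
#
# iterated until max_i |delta f_i| < tolerance, then F(z_b) = -kBT ln P(z_b).

#' WHAM configuration
#'
#' @param bin_width histogram bin width, Angstrom
#' @param tolerance convergence threshold on max |delta f_i|, kcal mol-1
#' @param max_iterations iteration cap
#' @param min_samples bins with fewer total samples are reported as
#'   undefined (NA free energy), never zero-filled
#' @param range optional c(lo, hi) histogram range, Angstrom; default is the
#'   window-centre range padded by 2 A
#' @return object of class `"wham_config"`
#' @export
wham_config <- function(bin_width = 0.2, tolerance = 1e-6,
                        max_iterations = 1e5, min_samples = 10,
                        range = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (tolerance <= 0) stop("tolerance must be > 0")
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iterations = max_iterations, min_samples = min_samples,
                 range = range),
            class = "wham_config")
}

# Histogram counts per window over shared bin edges; samples outside the
# range are dropped (and excluded from N_i).
.window_histograms <- function(windows, edges) {
  nb <- length(edges) - 1L
  counts <- matrix(0, length(windows), nb)
  for (i in seq_along(windows)) {
    s <- windows[[i]]$samples
    s <- s[s >= edges[1] & s <= edges[nb + 1L]]
    b <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), nb)
    counts[i, ] <- tabulate(b, nbins = nb)
  }
  counts
}

#' Combine umbrella windows into a potential of mean force
#'
#' From-scratch WHAM for harmonic (or absent) biases.  All windows must
#' share one temperature, and every adjacent pair of windows (ordered by
#' centre) must share at least one occupied histogram bin; a sampling gap
#' is reported as an error naming the offending pair rather than producing
#' a silently disconnected profile.
#'
#' @param windows list of [umbrella_window()]
#' @param config a [wham_config()]
#' @param weights optional list of per-sample weights (same shape as the
#'   window sample vectors); used by the Bayesian bootstrap
#' @return object of class `"pmf_profile"`: bin centres `z`, free energy
#'   `F` (kcal mol-1, NA on under-sampled bins), per-bin `counts`, the
#'   window `overlap` report, and a `convergence` record
#' @export
wham <- function(windows, config = wham_config(), weights = NULL) {
  stopifnot(length(windows) >= 1L)
  temps <- vapply(windows, function(w) w$temperature, numeric(1))
  if (diff(range(temps)) > 1e-9) {
    stop("all windows must share one temperature")
  }
  kT <- kB_kcal * temps[1]
  centers <- vapply(windows, function(w) w$center, numeric(1))
  rng <- config$range
  if (is.null(rng)) rng <- range(centers) + c(-2, 2)
  edges <- seq(rng[1], rng[2], by = config$bin_width)
  if (edges[length(edges)] < rng[2] - 1e-12) {
    edges <- c(edges, edges[length(edges)] + config$bin_width)
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(mids)

  if (is.null(weights)) {
    counts <- .window_histograms(windows, edges)
  } else {
    counts <- matrix(0, length(windows), nb)
    for (i in seq_along(windows)) {
      s <- windows[[i]]$samples; wt <- weights[[i]]
      keep <- s >= edges[1] & s <= edges[nb + 1L]
      b <- pmin(pmax(findInterval(s[keep], edges, rightmost.closed = TRUE), 1L), nb)
      counts[i, ] <- as.numeric(tapply(wt[keep], factor(b, levels = seq_len(nb)),
                                       sum, default = 0))
    }
  }
  Ni <- rowSums(counts)
  if (any(Ni == 0)) stop("window(s) with no samples inside the histogram range")

  # overlap check between centre-adjacent windows
  ord <- order(centers)
  occupied <- counts > 0
  overlap <- integer(length(windows) - 1L)
  if (length(windows) > 1L) {
    for (j in seq_len(length(windows) - 1L)) {
      a <- ord[j]; b <- ord[j + 1L]
      overlap[j] <- sum(occupied[a, ] & occupied[b, ])
      if (overlap[j] == 0L) {
        stop(sprintf(
          "umbrella windows at %.3f and %.3f A share no occupied bin (sampling gap)",
          centers[a], centers[b]))
      }
    }
  }

  # bias Boltzmann factors at bin centres: B[i, b] = exp(-w_i(z_b)/kT)
  ks <- vapply(windows, function(w) w$force_constant, numeric(1))
  W <- 0.5 * outer(ks, rep(1, nb)) *
    (outer(centers, mids, function(c, z) (z - c)))^2
  B <- exp(-W / kT)

  ntot <- colSums(counts)
  f <- rep(0, length(windows))
  iter <- 0L
  delta <- Inf
  repeat {
    iter <- iter + 1L
    denom <- colSums((Ni * exp(f / kT)) * B)
    P <- ntot / denom
    P <- P / sum(P)
    f_new <- -kT * log(as.numeric(B %*% P))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < config$tolerance || iter >= config$max_iterations) break
  }
  if (delta >= config$tolerance) {
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 iter, delta))
  }
  F <- -kT * log(P)
  F[ntot < config$min_samples] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  structure(list(z = mids, F = F, counts = ntot, edges = edges,
                 temperature = temps[1], window_f = f,
                 overlap = if (length(windows) > 1L)
                   data.frame(center_lo = centers[ord][-length(centers)],
                              center_hi = centers[ord][-1],
                              shared_bins = overlap) else NULL,
                 convergence = list(iterations = iter, final_delta = delta),
                 anchor_region = NULL),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins over [%.2f, %.2f] A, %d defined; %s\n",
              length(x$z), min(x$edges), max(x$edges), sum(!is.na(x$F)),
              if (is.null(x$anchor_region)) "unanchored"
              else sprintf("anchored on [%.1f, %.1f] A",
                           x$anchor_region[1], x$anchor_region[2])))
  if (!is.null(x$convergence)) {
    cat(sprintf("  WHAM: %d iterations, final max|df| = %.2g kcal/mol\n",
                x$convergence$iterations, x$convergence$final_delta))
  }
  invisible(x)
}

#' Construct a PMF profile directly from bin values
#'
#' Used for analytically constructed landscapes (barrier-arithmetic checks)
#' and for adapting external profiles.
#'
#' @param z bin centres, Angstrom
#' @param F free energy per bin, kcal mol-1 (NA = undefined)
#' @param counts per-bin sample counts (default: marked fully sampled)
#' @param temperature K
#' @return a `"pmf_profile"`
#' @export
pmf_profile <- function(z, F, counts = NULL, temperature = 303.15) {
  stopifnot(length(z) == length(F))
  if (is.null(counts)) counts <- ifelse(is.na(F), 0L, .Machine$integer.max)
  dz <- if (length(z) > 1L) diff(z)[1] else 1
  structure(list(z = z, F = F, counts = counts,
                 edges = c(z - dz / 2, z[length(z)] + dz / 2),
                 temperature = temperature, window_f = NULL, overlap = NULL,
                 convergence = NULL, anchor_region = NULL),
            class = "pmf_profile")
}

#' Anchor a PMF so a reference region has zero mean free energy
#'
#' The conventional gauge for permeation profiles sets the bulk-water
#' plateau to zero, so that negative free energy inside the membrane reads
#' directly as a favourable partitioning.  Idempotent, and invariant under
#' any constant shift of the input.
#'
#' @param profile a `"pmf_profile"`
#' @param region c(lo, hi) anchor interval, Angstrom
#' @return the shifted profile
#' @export
anchor_pmf <- function(profile, region = c(30, 35)) {
  sel <- profile$z >= region[1] & profile$z <= region[2] & !is.na(profile$F)
  if (!any(sel)) stop("anchor region [", region[1], ", ", region[2],
                      "] A contains no occupied bin")
  profile$F <- profile$F - mean(profile$F[sel])
  profile$anchor_region <- region
  profile
}

#' Decompose an anchored PMF into permeation barriers
#'
#' With the bulk-water plateau at zero: `dG1` is the interfacial entry
#' barrier (highest free energy in the interfacial search region, floored
#' at 0 when the profile descends monotonically), `dG2` the depth of the
#' global minimum below water (the partitioning free energy), and `dG3`
#' the midplane barrier, the cost of hopping between leaflets from the
#' favourable position.
#'
#' @param profile an anchored `"pmf_profile"` (see [anchor_pmf()])
#' @param interfacial_region c(lo, hi) search interval for the entry
#'   barrier, Angstrom
#' @param plateau_region kept for the report; the anchor interval
#' @return object of class `"barrier_report"` with `dG1`, `dG2`, `dG3`
#'   (kcal mol-1) and `z_min` (Angstrom)
#' @export
extract_barriers <- function(profile, interfacial_region = c(15, 30),
                             plateau_region = c(30, 35)) {
  if (is.null(profile$anchor_region)) {
    stop("profile must be anchored first (see anchor_pmf)")
  }
  ok <- !is.na(profile$F)
  if (!any(ok)) stop("profile has no defined bins")
  inter <- ok & profile$z >= interfacial_region[1] &
    profile$z <= interfacial_region[2]
  if (!any(inter)) stop("interfacial search region contains no defined bin")
  dG1 <- max(0, max(profile$F[inter]))
  imin <- which(ok)[which.min(profile$F[ok])]
  Fmin <- profile$F[imin]
  dG2 <- -Fmin
  mid <- which(ok & abs(profile$z) == min(abs(profile$z[ok])))[1]
  if (abs(profile$z[mid]) > diff(profile$edges[1:2])) {
    stop("profile support does not reach the bilayer midplane (z = 0)")
  }
  dG3 <- profile$F[mid] - Fmin
  structure(list(dG1 = dG1, dG2 = dG2, dG3 = dG3, z_min = profile$z[imin],
                 interfacial_region = interfacial_region,
                 plateau_region = plateau_region),
            class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<barrier_report> entry dG1 = %.3f, partitioning dG2 = %.3f, ",
    "midplane dG3 = %.3f kcal/mol; minimum at z = %.2f A\n"),
    x$dG1, x$dG2, x$dG3, x$z_min))
  invisible(x)
}

#' Full umbrella-sampling pipeline: windows on disk to PMF and barriers
#'
#' Reads a window metadata file, runs [wham()], anchors the profile, and
#' extracts the barrier decomposition, returning convergence and
#' histogram-overlap diagnostics alongside.  Optionally attaches Bayesian
#' bootstrap errors: each resample draws Dirichlet weights over every
#' window's samples and re-solves WHAM.
#'
#' @param meta_path windows metadata file (see [write_windows()])
#' @param config a [wham_config()]
#' @param anchor_region,interfacial_region region defaults as in
#'   [anchor_pmf()] / [extract_barriers()]
#' @param n_boot Bayesian bootstrap resamples (0 = off, the default)
#' @return list: `profile`, `barriers`, `overlap`, `convergence`, and
#'   `F_se` (per-bin bootstrap standard errors) when `n_boot > 0`
#' @export
pmf_pipeline <- function(meta_path, config = wham_config(),
                         anchor_region = c(30, 35),
                         interfacial_region = c(15, 30), n_boot = 0) {
  windows <- read_windows(meta_path)
  prof <- wham(windows, config)
  prof <- anchor_pmf(prof, anchor_region)
  bars <- extract_barriers(prof, interfacial_region, anchor_region)
  out <- list(profile = prof, barriers = bars, overlap = prof$overlap,
              convergence = prof$convergence)
  if (n_boot > 0) {
    Fb <- matrix(NA_real_, n_boot, length(prof$z))
    for (b in seq_len(n_boot)) {
      wts <- lapply(windows, function(w) {
        n <- length(w$samples)
        g <- stats::rexp(n)
        g / sum(g) * n
      })
      pb <- try(anchor_pmf(wham(windows, config, weights = wts),
                           anchor_region), silent = TRUE)
      if (!inherits(pb, "try-error")) Fb[b, ] <- pb$F
    }
    out$F_se <- apply(Fb, 2, stats::sd, na.rm = TRUE)
  }
  out
}
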