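# Biased overdamped Langevin sampling of umbrella windows, window-centre
# grids, and the plain-text window/metadata file convention.

#' Arithmetic grid of umbrella window centres
#'
#' Inclusive grid from `z_start` to `z_end`.  The range must be an integer
#' multiple of the spacing (to 1e-8 A); anything else is an error rather
#' than a silently clipped grid.
#'
#' @param z_start,z_end endpoints, Angstrom (either order)
#' @param spacing window spacing, Angstrom (> 0)
#' @return numeric vector of centres, ordered from `z_start` to `z_end`
#' @export
window_centers <- function(z_start, z_end, spacing) {
  if (spacing <= 0) stop("spacing must be > 0")
  span <- abs(z_end - z_start)
  n <- span / spacing
  if (abs(n - round(n)) > 1e-8) {
    stop("window range ", z_start, "..", z_end,
         " is not commensurate with spacing ", spacing)
  }
  seq(z_start, z_end, length.out = round(n) + 1L)
}

#' Construct an umbrella window
#'
#' One biased time series of the reaction coordinate together with its bias
#' parameters.  `force_constant = 0` denotes an unbiased window (plain
#' Boltzmann sampling), which WHAM handles as a degenerate case.
#'
#' @param center bias centre, Angstrom
#' @param force_constant harmonic bias force constant, kcal mol-1 A-2 (>= 0)
#' @param temperature K
#' @param samples reaction-coordinate samples, Angstrom
#' @param sample_interval time between stored samples, ns
#' @return object of class `"umbrella_window"`
#' @export
umbrella_window <- function(center, force_constant, temperature, samples,
                            sample_interval = 1) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(center = center, force_constant = force_constant,
                 temperature = temperature, samples = as.numeric(samples),
                 sample_interval = sample_interval),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> c = %.2f A, k = %.3g kcal/mol/A^2, T = %.2f K, %d samples\n",
              x$center, x$force_constant, x$temperature, length(x$samples)))
  invisible(x)
}

# Largest stable time step for the drift-vs-noise criterion used below.
.max_stable_dt <- function(pot, centers, force_constant, temperature,
                           gamma) {
  kT <- kB_kcal * temperature
  lo <- min(centers) - 5; hi <- max(centers) + 5
  grid <- seq(lo, hi, length.out = 2001L)
  # bias force bound: 4 thermal standard deviations from the centre
  f_bias <- if (force_constant > 0) 4 * sqrt(kT * force_constant) else 0
  f_max <- max(abs(potential_grad(pot, grid))) + f_bias
  if (f_max == 0) return(Inf)
  # drift dt*F/gamma < 0.5 * noise width sqrt(2 kT dt / gamma)
  kT * gamma / (2 * f_max^2)
}

#' Sample umbrella windows with overdamped Langevin dynamics
#'
#' Euler-Maruyama update
#' `z <- z - (dt/gamma) d/dz[U(z) + 0.5 k (z - c)^2] + sqrt(2 kBT dt/gamma) xi`,
#' with `xi` standard normal.  The time step is validated against a
#' drift-versus-noise stability criterion: the maximum deterministic drift
#' per step must stay below half the per-step thermal displacement, else an
#' error reports the largest admissible `dt`.  All noise is drawn from R's
#' RNG stream, so a single `set.seed()` (or the `seed` argument) makes the
#' whole window set bit-reproducible.
#'
#' @param pot a [potential_spec()]
#' @param centers window centres, Angstrom
#' @param force_constant bias force constant, kcal mol-1 A-2
#' @param temperature K
#' @param dt integration step, ns
#' @param n_steps steps per window (before burn-in removal)
#' @param burn_in steps discarded from the start (default 10% of `n_steps`)
#' @param gamma friction, kcal mol-1 A-2 ns (only kBT/gamma matters)
#' @param stride keep every `stride`-th post-burn-in sample
#' @param seed optional integer seed (calls `set.seed`)
#' @return list of [umbrella_window()] objects, one per centre
#' @export
generate_langevin_windows <- function(pot, centers, force_constant,
                                      temperature, dt = 0.02,
                                      n_steps = 1e5,
                                      burn_in = round(0.1 * n_steps),
                                      gamma = 1, stride = 1L, seed = NULL) {
  stopifnot(inherits(pot, "potential_spec"))
  if (!is.null(seed)) set.seed(seed)
  dt_max <- .max_stable_dt(pot, centers, force_constant, temperature, gamma)
  if (dt >= dt_max) {
    stop(sprintf(
      "unstable time step dt = %g ns: drift per step exceeds half the thermal width; use dt < %.3g ns",
      dt, dt_max))
  }
  kT <- kB_kcal * temperature
  lapply(centers, function(cc) {
    s <- langevin_overdamped(pot$heights, pot$centers, pot$widths,
                             force_constant, cc, kT, gamma, dt,
                             as.integer(n_steps), as.integer(burn_in), cc,
                             as.integer(stride))
    umbrella_window(cc, force_constant, temperature, s,
                    sample_interval = dt * stride)
  })
}

#' Write umbrella windows as plain-text files plus a metadata file
#'
#' One two-column file (time ns, reaction coordinate Angstrom) per window,
#' plus `windows.meta` with one line per window:
#' `<path> <center A> <force constant kcal/mol/A^2> <temperature K>` —
#' the conventional umbrella-sampling metadata layout.
#'
#' @param windows list of [umbrella_window()]
#' @param dir output directory
#' @return path of the metadata file
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    fn <- sprintf("window_%03d.dat", i)
    tt <- seq_along(w$samples) * w$sample_interval
    data.table::fwrite(data.table::data.table(time = tt, z = w$samples),
                       file.path(dir, fn), sep = " ", col.names = FALSE)
    meta[i] <- sprintf("%s %.6f %.6f %.4f", fn, w$center, w$force_constant,
                       w$temperature)
  }
  meta_path <- file.path(dir, "windows.meta")
  writeLines(meta, meta_path)
  meta_path
}

#' Read umbrella windows from a metadata file
#'
#' @param meta_path path to a `windows.meta` file (see [write_windows()]);
#'   window paths are resolved relative to its directory
#' @return list of [umbrella_window()]
#' @export
read_windows <- function(meta_path) {
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  base <- dirname(meta_path)
  lines <- readLines(meta_path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3L) stop("malformed metadata line: ", sQuote(ln))
    path <- if (file.exists(f[1])) f[1] else file.path(base, f[1])
    if (!file.exists(path)) stop("window file not found: ", f[1])
    dat <- data.table::fread(path, header = FALSE)
    umbrella_window(as.numeric(f[2]), as.numeric(f[3]),
                    if (length(f) >= 4L) as.numeric(f[4]) else 303.15,
                    dat[[2]],
                    sample_interval = if (nrow(dat) > 1L) dat[[1]][2] - dat[[1]][1] else 1)
  })
}
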