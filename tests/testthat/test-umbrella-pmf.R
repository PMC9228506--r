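# WHAM self-consistency, anchoring, barrier decomposition and the
# windows-on-disk pipeline.

test_that("an unbiased window reduces WHAM to Boltzmann inversion", {
  pot <- potential_spec(heights = c(1.5, -2), centers = c(2, -3),
                        widths = c(1.5, 2))
  set.seed(141)
  s <- boltzmann_rejection_sample(pot, 2e5, 303.15, -10, 10)
  w <- umbrella_window(0, 0, 303.15, s)
  prof <- wham(list(w), wham_config(range = c(-10, 10)))
  ok <- !is.na(prof$F) & prof$counts >= 200
  ex <- exact_pmf(pot, prof$z[ok], 303.15)$F
  dev <- (prof$F[ok] - ex) - mean(prof$F[ok] - ex)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("flat landscapes give flat profiles within counting noise", {
  # i.i.d. biased samples: for U = 0 each window samples its own Gaussian
  set.seed(151)
  k <- 2; temp <- 303.15; kT <- kB_kcal * temp
  sdv <- sqrt(kT / k)
  windows <- lapply(0:8, function(c0)
    umbrella_window(c0, k, temp, rnorm(2e4, c0, sdv)))
  prof <- wham(windows, wham_config(min_samples = 200))
  ok <- !is.na(prof$F)
  dev <- prof$F[ok] - mean(prof$F[ok])
  noise <- kT / sqrt(prof$counts[ok])
  expect_true(all(abs(dev) <= 3 * pmax(noise, 0.01)))
})

test_that("duplicated windows equal one window with doubled samples", {
  set.seed(161)
  s <- rnorm(5000, 10, 0.6)
  wA <- list(umbrella_window(10, 2, 303.15, s),
             umbrella_window(10, 2, 303.15, s))
  wB <- list(umbrella_window(10, 2, 303.15, c(s, s)))
  cfg <- wham_config(range = c(7, 13))
  pA <- wham(wA, cfg); pB <- wham(wB, cfg)
  expect_equal(pA$F, pB$F, tolerance = 1e-9)
})

test_that("windows with a sampling gap are rejected, naming the gap", {
  wA <- umbrella_window(0, 10, 303.15, rnorm(1000, 0, 0.2))
  wB <- umbrella_window(10, 10, 303.15, rnorm(1000, 10, 0.2))
  expect_error(wham(list(wA, wB)), "no occupied bin")
})

test_that("anchoring is idempotent, gauge-invariant and region-checked", {
  z <- seq(0, 35, 0.5)
  prof <- pmf_profile(z, sin(z / 5) + 2)
  a1 <- anchor_pmf(prof, c(30, 35))
  expect_equal(mean(a1$F[a1$z >= 30]), 0, tolerance = 1e-12)
  a2 <- anchor_pmf(a1, c(30, 35))
  expect_equal(a2$F, a1$F, tolerance = 1e-12)
  shifted <- prof; shifted$F <- prof$F + 7.3
  expect_equal(anchor_pmf(shifted, c(30, 35))$F, a1$F, tolerance = 1e-12)
  expect_error(anchor_pmf(prof, c(100, 110)), "no occupied bin")
})

test_that("barrier decomposition is exact on constructed profiles", {
  # plateau 0 beyond 30 A, peak 2.14 at 20, minimum -5 at 12, F(0) = -4
  # linear segments through (35, 0), (30, 0), (20, 2.14), (12, -5), (0, -4)
  z <- seq(0, 35, 0.1)
  F <- ifelse(z >= 30, 0,
       ifelse(z >= 20, 2.14 * (30 - z) / 10,
       ifelse(z >= 12, 2.14 + (z - 20) * 7.14 / 8,
              -5 + (12 - z) / 12)))
  prof <- anchor_pmf(pmf_profile(z, F), c(30, 35))
  b <- extract_barriers(prof, interfacial_region = c(15, 30))
  expect_equal(b$dG1, 2.14, tolerance = 1e-9)
  expect_equal(b$dG2, 5.0, tolerance = 1e-9)
  expect_equal(b$dG3, 1.0, tolerance = 1e-9)
  expect_equal(b$z_min, 12, tolerance = 1e-9)
  # monotonically decreasing profile has no entry barrier
  mono <- anchor_pmf(pmf_profile(z, -(35 - z) / 7), c(30, 35))
  expect_equal(extract_barriers(mono, c(15, 30))$dG1, 0)
  expect_error(extract_barriers(pmf_profile(z, F), c(15, 30)), "anchored")
})

test_that("a symmetric double-well landscape has the constructed midplane offset", {
  pot <- potential_spec(heights = c(-3, -3), centers = c(-10, 10),
                        widths = c(3, 3))
  z <- seq(-20, 20, 0.2)
  ex <- exact_pmf(pot, z, 303.15)
  prof <- pmf_profile(z, ex$F)
  prof <- anchor_pmf(prof, c(16, 20))
  b <- extract_barriers(prof, interfacial_region = c(12, 20))
  u <- potential_energy(pot, c(0, 10))
  expect_equal(b$dG3, u[1] - u[2], tolerance = 1e-9)
  expect_equal(abs(b$z_min), 10, tolerance = 0.2)
})

test_that("WHAM recovers a barrier landscape from Langevin windows", {
  pot <- permeation_landscape()
  cen <- window_centers(35, 0, 1)
  w <- generate_langevin_windows(pot, cen, 2.39, 303.15, dt = 0.005,
                                 n_steps = 4e5, seed = 171)
  prof <- anchor_pmf(wham(w), c(30, 35))
  ok <- !is.na(prof$F) & prof$counts >= 200
  exF <- anchored_exact_pmf(pot, prof$z[ok], 303.15)
  expect_lt(sqrt(mean((prof$F[ok] - exF)^2)), 0.25)
  b <- extract_barriers(prof)
  expect_equal(b$z_min, 12, tolerance = 1)
})

test_that("convergence is monotone in tolerance and sample size helps", {
  pot <- potential_spec(heights = 2, centers = 5, widths = 2)
  cen <- window_centers(10, 0, 1)
  w <- generate_langevin_windows(pot, cen, 2.39, 303.15, dt = 0.005,
                                 n_steps = 2e4, seed = 181)
  tight <- wham(w, wham_config(tolerance = 1e-7))
  loose <- wham(w, wham_config(tolerance = 1e-6))
  expect_lte(loose$convergence$iterations, tight$convergence$iterations)
  # more sampling lowers the seed-averaged RMS error against the exact PMF
  rms <- matrix(NA_real_, 10, 2)
  for (sd in 1:10) {
    ps <- lapply(c(2e4, 8e4), function(ns)
      wham(generate_langevin_windows(pot, cen, 2.39, 303.15, dt = 0.005,
                                     n_steps = ns, seed = 300 + sd),
           wham_config(min_samples = 100)))
    common <- !is.na(ps[[1]]$F) & !is.na(ps[[2]]$F) & ps[[1]]$counts >= 200
    rms[sd, ] <- vapply(ps, function(p) {
      ex <- exact_pmf(pot, p$z[common], 303.15)$F
      dev <- (p$F[common] - ex) - mean(p$F[common] - ex)
      sqrt(mean(dev^2))
    }, numeric(1))
  }
  expect_lt(mean(rms[, 2]), mean(rms[, 1]))
})

test_that("the windows-on-disk pipeline runs end to end", {
  pot <- permeation_landscape()
  cen <- window_centers(35, 0, 1)
  w <- generate_langevin_windows(pot, cen, 2.39, 303.15, dt = 0.005,
                                 n_steps = 3e4, seed = 191)
  d <- withr::local_tempdir()
  meta <- write_windows(w, d)
  res <- pmf_pipeline(meta, wham_config(min_samples = 5))
  expect_s3_class(res$profile, "pmf_profile")
  expect_s3_class(res$barriers, "barrier_report")
  expect_equal(nrow(res$overlap), 35L)
  expect_true(all(res$overlap$shared_bins >= 1L))
  expect_true(res$convergence$final_delta < 1e-6)
  # windows read back equal the windows written (to text precision)
  w2 <- read_windows(meta)
  expect_equal(w2[[1]]$center, w[[1]]$center)
  expect_equal(w2[[10]]$samples, w[[10]]$samples, tolerance = 1e-6)
  # a missing window file is named in the error
  lines <- readLines(meta)
  lines[3] <- sub("window_003.dat", "missing_window.dat", lines[3])
  writeLines(lines, meta)
  expect_error(pmf_pipeline(meta), "missing_window.dat")
})

test_that("Bayesian bootstrap errors are finite and modest", {
  set.seed(201)
  k <- 2; temp <- 303.15
  windows <- lapply(seq(0, 6, 1), function(c0)
    umbrella_window(c0, k, temp, rnorm(4000, c0, sqrt(kB_kcal * temp / k))))
  d <- withr::local_tempdir()
  meta <- write_windows(windows, d)
  res <- pmf_pipeline(meta, wham_config(min_samples = 100),
                      anchor_region = c(5, 7), interfacial_region = c(3, 7),
                      n_boot = 8)
  ok <- !is.na(res$profile$F)
  expect_true(all(is.finite(res$F_se[ok])))
  expect_lt(stats::median(res$F_se[ok]), 0.2)
})
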