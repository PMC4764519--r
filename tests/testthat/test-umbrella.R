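ff <- forcefield_params()

test_that("plan_windows counts, stiffness rule and normalisation", {
  w <- plan_windows(27, -5, dz = 2)
  expect_equal(nrow(w), 17)
  expect_equal(range(w$center), c(-5, 27))
  ## default stiffness: SD = dz/2  =>  k = 4 kBT / dz^2
  w15 <- plan_windows(0, 6, dz = 1.5)
  expect_equal(w15$stiffness[1], 4 * kBT(300) / 1.5^2, tolerance = 1e-6)
  expect_equal(w15$stiffness[1], 4.43, tolerance = 0.01)
  ## reversed ends give the same normalised set
  expect_equal(plan_windows(-5, 27, dz = 2)$center, w$center)
  ## spacing larger than the span: single window
  expect_equal(nrow(plan_windows(0, 1, dz = 5)), 1)
  expect_error(plan_windows(0, 1, dz = -1), "positive")
})

test_that("a free cargo samples its bias window correctly", {
  topo <- free_particle(center = c(0, 0, 2), D = 2)
  w <- list(center = 2, stiffness = 25, lateral_stiffness = 50,
            n_steps = 2e5, equilibration_steps = 2e4, seed = 6)
  ws <- run_window(topo, w, ff, langevin_params(300, 0.02, 2, seed = 6))
  n_eff <- length(ws$samples) / 20          # generous correlation allowance
  expect_equal(mean(ws$samples), 2,
               tolerance = 3 * stats::sd(ws$samples) / sqrt(n_eff) / 2)
  ## Boltzmann variance kBT / k
  expect_equal(stats::var(ws$samples), kBT(300) / 25, tolerance = 0.1)
  expect_false(ws$flagged)
  ws2 <- run_window(topo, w, ff, langevin_params(300, 0.02, 2, seed = 6))
  expect_identical(ws$samples, ws2$samples)
})

test_that("WHAM recovers a flat PMF from one unbiased window", {
  with_seed(8, z <- runif(5000, -1, 1))
  wins <- data.frame(center = 0, stiffness = 1e-9)
  pmf <- wham(list(z), wins, bin_width = 0.2, n_boot = 10)
  sel <- is.finite(pmf$G) & abs(pmf$z) < 0.9
  expect_lt(max(pmf$G[sel]) - min(pmf$G[sel]), 0.3)
})

test_that("WHAM recovers a harmonic PMF to better than 0.2 kJ/mol RMSD", {
  kappa <- 4
  Uh <- function(z) 0.5 * kappa * z^2
  wins <- plan_windows(-2, 2, dz = 0.5, n_steps = 0, seed = 1)
  samples <- lapply(seq_len(nrow(wins)), function(i)
    sample_biased_boltzmann(Uh, wins$center[i], wins$stiffness[i], 6000,
                            zlim = c(-3, 3), seed = 40 + i))
  pmf <- wham(samples, wins, bin_width = 0.1, n_boot = 0)
  sel <- is.finite(pmf$G) & abs(pmf$z) <= 1.8
  ref <- Uh(pmf$z[sel]); ref <- ref - mean(ref)
  G <- pmf$G[sel]; G <- G - mean(G)
  expect_lt(sqrt(mean((G - ref)^2)), 0.2)
})

test_that("WHAM errors name non-overlap and non-convergence", {
  wins <- data.frame(center = c(0, 5), stiffness = c(100, 100))
  expect_error(wham(list(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1)), wins,
                    bin_width = 0.2, n_boot = 0),
               "no histogram overlap")
  wins2 <- data.frame(center = c(0, 0.5), stiffness = c(10, 10))
  with_seed(2, s <- list(rnorm(500, 0, 0.3), rnorm(500, 0.5, 0.3)))
  expect_error(wham(s, wins2, bin_width = 0.1, max_iter = 2, n_boot = 0),
               "did not converge")
})

test_that("PMF is invariant under splitting a window's samples in two", {
  Uh <- function(z) 2 * z^2
  wins <- plan_windows(-1.5, 1.5, dz = 0.5, n_steps = 0, seed = 1)
  samples <- lapply(seq_len(nrow(wins)), function(i)
    sample_biased_boltzmann(Uh, wins$center[i], wins$stiffness[i], 4000,
                            zlim = c(-2.5, 2.5), seed = 70 + i))
  pmf1 <- wham(samples, wins, bin_width = 0.1, n_boot = 0)
  ## split window 4 into two halves with the same bias
  s2 <- c(samples[1:3], list(samples[[4]][1:2000], samples[[4]][2001:4000]),
          samples[5:7])
  wins2 <- rbind(wins[1:3, ], wins[4, ], wins[4, ], wins[5:7, ])
  pmf2 <- wham(s2, wins2, bin_width = 0.1, n_boot = 0)
  sel <- is.finite(pmf1$G) & is.finite(pmf2$G)
  d <- (pmf1$G - mean(pmf1$G[sel])) - (pmf2$G - mean(pmf2$G[sel]))
  expect_lt(max(abs(d[sel])), 1e-4)
})

test_that("doubling the bin width moves the barrier less than its uncertainty", {
  Udw <- function(z) 5 * (z^2 - 1)^2
  wins <- plan_windows(-1.6, 1.6, dz = 0.4, n_steps = 0, seed = 1)
  samples <- lapply(seq_len(nrow(wins)), function(i)
    sample_biased_boltzmann(Udw, wins$center[i], wins$stiffness[i], 6000,
                            zlim = c(-2.2, 2.2), seed = 90 + i))
  barrier <- function(bw) {
    pmf <- wham(samples, wins, bin_width = bw, n_boot = 10, boot_seed = 4)
    sel <- is.finite(pmf$G)
    i0 <- which.min(abs(pmf$z))
    list(b = pmf$G[i0] - min(pmf$G[sel]), se = max(pmf$se[sel], na.rm = TRUE))
  }
  b1 <- barrier(0.08); b2 <- barrier(0.16)
  expect_lt(abs(b1$b - b2$b), 2 * max(b1$se, b2$se))
})

test_that("convergence report compares campaigns and regrids when needed", {
  p1 <- pmf_profile(seq(-1, 1, 0.1), seq(-1, 1, 0.1)^2)
  rep0 <- convergence_report(list(a = p1, b = p1))
  expect_equal(rep0$max_abs_diff, 0)
  ## low vs 16x sampling: Monte-Carlo error shrinks (averaged over repeats)
  Uh <- function(z) 3 * z^2
  wins <- plan_windows(-1.5, 1.5, dz = 0.5, n_steps = 0, seed = 1)
  draw <- function(n, off) lapply(seq_len(nrow(wins)), function(i)
    sample_biased_boltzmann(Uh, wins$center[i], wins$stiffness[i], n,
                            zlim = c(-2.5, 2.5), seed = off + i))
  ana <- function(p) {
    sel <- is.finite(p$G) & abs(p$z) <= 1.6   # compare the well-sampled span
    sqrt(mean((p$G[sel] - mean(p$G[sel]) -
               (Uh(p$z[sel]) - mean(Uh(p$z[sel]))))^2))
  }
  err_lo <- mean(sapply(c(200, 400, 1200), function(off)
    ana(wham(draw(250, off), wins, bin_width = 0.15, n_boot = 0))))
  err_hi <- mean(sapply(c(600, 800, 1400), function(off)
    ana(wham(draw(6000, off), wins, bin_width = 0.15, n_boot = 0))))
  expect_lt(err_hi, err_lo)
  ## disjoint grids are regridded with a warning
  p_shift <- pmf_profile(seq(-1.05, 0.95, 0.1), seq(-1.05, 0.95, 0.1)^2)
  expect_warning(rep2 <- convergence_report(list(a = p1, b = p_shift)),
                 "regrid")
  expect_true(is.finite(rep2$max_abs_diff))
})
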