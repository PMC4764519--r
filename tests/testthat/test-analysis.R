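test_that("energy barrier statistic: means, dispersion and invariances", {
  z <- seq(-10, 30, by = 0.5)
  flat <- pmf_profile(z, rep(2, length(z)))
  expect_equal(energy_barrier(flat)$G, 0)
  ## piecewise-constant: 12 on the core, 0 on the reference
  piece <- pmf_profile(z, ifelse(abs(z) <= 5, 12, 0))
  expect_equal(energy_barrier(piece)$G, 12)
  expect_equal(energy_barrier(piece)$dispersion, 0)
  ## invariant under adding any constant
  shifted <- pmf_profile(z, piece$G + 7.3)
  expect_equal(energy_barrier(shifted)$G, 12)
  ## missing coverage errors name the interval
  short <- pmf_profile(seq(-6, 6, 0.5), rep(0, 25))
  expect_error(energy_barrier(short), "reference")
  expect_error(energy_barrier(pmf_profile(21:27, rep(0, 7))), "core")
  ## custom intervals (fixture scale)
  expect_equal(energy_barrier(piece, core = c(-2, 2),
                              reference = c(8, 10))$G, 12)
})

test_that("density map normalises single beads and conserves mass", {
  geom <- scaffold_geometry(pore_diameter = 20, pore_half_height = 5)
  topo <- npcbarrier:::bare_topology(matrix(c(2, 0, 0), 1, 3))
  topo$geometry <- geom
  map <- density_map(list(matrix(c(2, 0, 0), 1, 3)), topo, dr = 0.5, dz = 0.5)
  nz <- which(map$density > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1)
  r_c <- map$r[nz[1]]
  expect_equal(map$density[nz], 120 / (2 * pi * r_c * 0.5 * 0.5))
  expect_equal(density_map_mass(map), 120, tolerance = 1e-9)

  ## uniform beads in a cylinder: flat profile within Poisson noise
  with_seed(3, {
    n <- 20000
    r <- sqrt(runif(n)) * 8
    phi <- runif(n, 0, 2 * pi)
    fr <- cbind(r * cos(phi), r * sin(phi), runif(n, -4, 4))
  })
  topo2 <- npcbarrier:::bare_topology(fr)
  topo2$geometry <- geom
  map2 <- density_map(list(fr), topo2, dr = 1, dz = 8, r_max = 8,
                      z_range = c(-4, 4))
  dens <- map2$density[map2$r < 7.5, 1]
  expect_lt(stats::sd(dens) / mean(dens), 0.15)
  expect_equal(density_map_mass(map2), n * 120, tolerance = 1e-6)
  expect_error(density_map(list(), topo2), "empty")
})

test_that("density map accumulates out-of-grid beads in the overflow", {
  topo <- npcbarrier:::bare_topology(matrix(c(1, 0, 0, 50, 0, 0), 2, 3, TRUE))
  topo$geometry <- scaffold_geometry(20, 5)
  map <- density_map(list(topo$pos), topo, r_max = 10)
  expect_equal(map$overflow_mass, 120)
  expect_equal(density_map_mass(map), 240, tolerance = 1e-9)
})

test_that("barrier curve locates the kBT crossing by interpolation", {
  ## G(D) = 0.42 D^2 crossing kBT = 2.494 at D* = sqrt(2.494/0.42)
  z <- seq(-10, 30, 0.5)
  mk <- function(G) pmf_profile(z, ifelse(abs(z) <= 5, G, 0))
  D <- c(1, 2, 3, 4)
  pmfs <- setNames(lapply(D, function(d) mk(0.42 * d^2)), D)
  ## fine grid so linear interpolation matches the closed form
  Dfine <- seq(2.3, 2.6, 0.01)
  pmfs_fine <- setNames(lapply(Dfine, function(d) mk(0.42 * d^2)), Dfine)
  bc <- barrier_curve(pmfs_fine)
  expect_equal(bc$D_star, sqrt(2.494 / 0.42), tolerance = 1e-3)
  expect_true(all(diff(bc$table$G) > 0))
  ## all barriers below threshold: no crossing
  low <- barrier_curve(setNames(lapply(c(1, 2), function(d) mk(0.1 * d)),
                                c(1, 2)))
  expect_true(is.na(low$D_star))
  expect_length(low$crossings, 0)
  expect_error(barrier_curve(pmfs[1]), "two diameters")
})

test_that("radial PMF of an empty pore is flat until the wall", {
  ff <- forcefield_params()
  geom <- scaffold_geometry(pore_diameter = 16, pore_half_height = 4)
  sc <- build_scaffold(geom)
  topo <- graft_nups(sc, nup_anchors(character(0), numeric(0), numeric(0),
                                     integer(0), character(0))[0, ],
                     c(s = "FSFG"), seed = 1)
  topo <- add_cargo(topo, make_inert_cargo(3), center = c(0, 0, 0),
                    mass_scale = 0.2)
  wins <- plan_windows(0, 4, dz = 1, stiffness = 30, n_steps = 24000,
                       equilibration = 0.2, seed = 5)
  prof <- radial_pmf_campaign(topo, wins, z_plane = 0, angles = c(0, 180),
                              ld = langevin_params(300, 0.02, 1, seed = 2),
                              sample_every = 10, n_boot = 0)
  for (p in prof) {
    sel <- is.finite(p$G) & p$z >= 0 & p$z <= 3.5
    expect_lt(max(abs(p$G[sel])), 1.5)       # flat inside the open pore
  }
  ## the two opposite directions agree on a symmetric system (common grid)
  g0 <- prof[["0"]]; g180 <- prof[["180"]]
  zz <- seq(0.5, 3, by = 0.25)
  a0 <- approx(g0$z, g0$G, zz)$y
  a180 <- approx(g180$z, g180$G, zz)$y
  ok <- is.finite(a0) & is.finite(a180)
  expect_lt(mean(abs(a0[ok] - a180[ok])), 1.0)
})
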