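ff <- forcefield_params()

test_that("harmonic bond energy matches closed form and has exact forces", {
  pos <- matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE)
  res <- bond_energy(pos, matrix(c(1, 2), 1), ff)
  expect_equal(res$energy, 0)
  expect_equal(max(abs(res$forces)), 0)

  pos2 <- matrix(c(0, 0, 0, 0.48, 0, 0), 2, 3, byrow = TRUE)
  res2 <- bond_energy(pos2, matrix(c(1, 2), 1), ff)
  expect_equal(res2$energy, 0.5 * 8000 * 0.1^2, tolerance = 1e-10)

  expect_error(bond_energy(pos, matrix(c(1, 3), 1), ff), "topology error")

  chain <- random_chain_topology(5, seed = 3)
  expect_lt(gradient_error(chain, ff, terms = 1L), 1e-6)
})

test_that("backbone stiffness uses the tables and is zero for short chains", {
  pos <- matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(backbone_stiffness_energy(pos, list(1:2), ff)$energy, 0)

  ## collinear 3-bead chain: energy equals the bending table value at pi
  pos3 <- matrix(c(0, 0, 0, 0.38, 0, 0, 0.76, 0, 0), 3, 3, byrow = TRUE)
  e <- backbone_stiffness_energy(pos3, list(1:3), ff)$energy
  bt <- ff$bend_table
  expect_equal(e, bt$y[length(bt$y)], tolerance = 1e-6)

  chain <- random_chain_topology(6, seed = 11)
  expect_lt(gradient_error(chain, ff, terms = 6L), 1e-5)
})

test_that("hydrophobic pair has the stated well depth, cutoff and symmetry", {
  ## binding spot vs Phe: well depth at the LJ minimum is eps_max = 5.2
  rmin <- 2^(1 / 6) * 0.6
  expect_equal(hydrophobic_pair_energy(rmin, 5.2, 0.6)$energy, -5.2,
               tolerance = 2e-3)
  expect_equal(hydrophobic_pair_energy(rmin, 5.2, 0.6)$force, 0,
               tolerance = 1e-8)
  ## exactly zero at and beyond the cutoff
  expect_identical(hydrophobic_pair_energy(c(2.5, 3, 10), 5.2, 0.6)$energy,
                   c(0, 0, 0))
  ## eps = 0: pure repulsion everywhere
  r <- seq(0.3, 2.4, by = 0.01)
  expect_true(all(hydrophobic_pair_energy(r, 0, 0.6)$energy >= 0))
  ## symmetric in the pair: eps_ij built from h_i * h_j commutes trivially,
  ## and the engine gives identical energy with beads swapped
  topo <- npcbarrier:::bare_topology(matrix(c(0, 0, 0, 0.7, 0, 0), 2, 3, TRUE))
  topo$hyd <- c(0.3, 0.9)
  e1 <- compute_energy(topo, ff)$total
  topo$hyd <- c(0.9, 0.3)
  expect_equal(compute_energy(topo, ff)$total, e1)
})

test_that("screened electrostatics obey sign, cutoff and zero-charge rules", {
  expect_identical(electrostatic_pair_energy(seq(0.5, 6, 0.5), 0, 1, ff)$energy,
                   rep(0, 12))
  expect_identical(electrostatic_pair_energy(c(5, 6), 1, 1, ff)$energy, c(0, 0))
  like <- electrostatic_pair_energy(0.5, 1, 1, ff)
  expect_gt(like$energy, 0)
  expect_gt(like$force, 0)    # repulsive
  unlike <- electrostatic_pair_energy(0.5, 1, -1, ff)
  expect_lt(unlike$energy, 0)
})

test_that("excluded volume is zero at contact and repulsive inside", {
  res <- excluded_volume_energy(c(2.5, 3.0, 2.25), 2.5)
  expect_equal(res$energy[1:2], c(0, 0))
  expect_equal(res$force[1:2], c(0, 0))
  expect_gt(res$energy[3], 0)
  expect_gt(res$force[3], 0)   # pushes apart
})

test_that("forces are the exact negative gradient for full random systems", {
  for (seed in c(1, 2)) {
    chain <- random_chain_topology(6, seed = seed)
    expect_lt(gradient_error(chain, ff), 1e-5)
  }
})

test_that("nonbonded energy is invariant under rigid rotation + translation", {
  chain <- random_chain_topology(8, seed = 5)
  e0 <- compute_energy(chain, ff)$total
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  chain$pos <- chain$pos %*% R + matrix(c(2, -1, 3), 8, 3, byrow = TRUE)
  expect_equal(compute_energy(chain, ff)$total, e0, tolerance = 1e-9)
})

test_that("engine nonbonded terms equal the R scalar pair sums (dual route)", {
  with_seed(21, {
    n <- 12
    topo <- npcbarrier:::bare_topology(matrix(runif(3 * n, 0, 2.5), n, 3))
    topo$hyd <- runif(n)
    topo$charge <- sample(c(-1, 0, 1), n, replace = TRUE)
  })
  eng <- compute_energy(topo, ff, terms = 8L)
  manual <- 0
  for (i in 1:(nrow(topo$pos) - 1)) for (j in (i + 1):nrow(topo$pos)) {
    r <- sqrt(sum((topo$pos[i, ] - topo$pos[j, ])^2))
    manual <- manual +
      hydrophobic_pair_energy(r, ff$eps_max * topo$hyd[i] * topo$hyd[j],
                              topo$evr[i] + topo$evr[j], ff$vdw_cutoff,
                              eps_rep = ff$eps_max)$energy +
      electrostatic_pair_energy(r, topo$charge[i], topo$charge[j], ff)$energy
  }
  ## engine stores pair parameters in single precision; allow for that
  expect_equal(eng$total, manual, tolerance = 1e-6)
})

test_that("residue table covers the alphabet with F at the scale maximum", {
  res <- load_residue_table()
  expect_setequal(setdiff(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "J"),
                          res$code), character(0))
  expect_equal(res["F", "hydrophobicity"], 1.0)
  expect_equal(res["F", "hydrophobicity"], max(res$hydrophobicity))
  expect_true(all(res$bead_radius > 0))
  ## parameter validation
  expect_error(forcefield_params(coulomb_cutoff = 1), "coulomb_cutoff")
  expect_error(forcefield_params(eps_max = -1), "eps_max")
})
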