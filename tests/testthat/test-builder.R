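ff <- forcefield_params()

test_that("scaffold is exactly eightfold symmetric and walls sit outside L/2", {
  geom <- scaffold_geometry(pore_diameter = 20, pore_half_height = 5.1)
  sc <- build_scaffold(geom)
  th <- 2 * pi / geom$symmetry_order
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- unclass(sc) %*% R
  ## rotating by 45 deg permutes the bead set
  d <- as.matrix(dist(rbind(unclass(sc), rot)))
  n <- nrow(sc)
  nearest <- apply(d[1:n, (n + 1):(2 * n), drop = FALSE], 2, min)
  expect_lt(max(nearest), 1e-9)
  expect_true(all(sqrt(sc[, 1]^2 + sc[, 2]^2) >= geom$pore_diameter / 2))
  expect_error(scaffold_geometry(pore_diameter = 4, scaffold_bead_diameter = 5),
               "exceed")
})

test_that("inert cargo follows the printed sigma_c / r_c formulas", {
  c1 <- make_inert_cargo(4.2)
  expect_equal(c1$kind, "single")
  expect_equal(c1$sigma_c, 2.4)
  c2 <- make_inert_cargo(2.0)
  expect_equal(c2$sigma_c, 1.3)
  c3 <- make_inert_cargo(10)
  expect_equal(c3$kind, "composite")
  expect_equal(c3$sigma_c, 2.5)
  expect_equal(c3$r_c, 10 / 2 - 2.2)
  expect_error(make_inert_cargo(-1), "positive")
})

test_that("composite repulsive surface is spherical within 5 percent", {
  for (D in c(6, 10, 14)) {
    spec <- make_inert_cargo(D)
    with_seed(17, {
      u <- matrix(rnorm(3000), 1000, 3)
      u <- u / sqrt(rowSums(u^2))
    })
    eff <- npcbarrier:::composite_effective_radius(spec$directions, spec$r_c,
                                                   spec$sigma_c, u)
    target <- D / 2 + 0.3
    expect_lt(max(abs(eff - target)) / target, 0.05)
  }
})

test_that("Kap complex places spots on the equator stripe at spacing d", {
  kap <- make_kap_complex(10, 7, 1.3)
  expect_equal(nrow(kap$spots), 7)
  expect_equal(sqrt(rowSums(kap$spots^2)), rep(5, 7))   # on the surface
  ## adjacent-spot chord for d = 1.3 on a D = 10 sphere
  chord <- sqrt(sum((kap$spots[2, ] - kap$spots[1, ])^2))
  expect_equal(chord, 10 * sin(1.3 / 10), tolerance = 1e-9)
  expect_error(make_kap_complex(10, 30, 1.3), "stripe")
  expect_error(make_kap_complex(10, 3, -1), "positive")
})

test_that("Kap complex with n = 0 is energetically identical to inert cargo", {
  probe <- npcbarrier:::bare_topology(matrix(c(5.1, 0, 0.4), 1, 3))
  probe$hyd <- 1
  t_in <- add_cargo(probe, make_inert_cargo(10), center = c(0, 0, 0))
  t_kap <- add_cargo(probe, make_kap_complex(10, 0, 1.3), center = c(0, 0, 0))
  e_in <- compute_energy(t_in, ff)
  e_kap <- compute_energy(t_kap, ff)
  expect_identical(e_in$total, e_kap$total)
  expect_identical(e_in$components, e_kap$components)
})

test_that("grafting counts beads, fixes anchors and is seed-deterministic", {
  geom <- scaffold_geometry(pore_diameter = 20, pore_half_height = 5.1)
  seqs <- c(s50 = paste(rep("FSFGS", 10), collapse = ""))
  anchors <- nup_anchors("NupX", 0, 10, 8L, "s50")
  topo <- graft_nups(NULL, anchors, seqs, seed = 4, geom = geom)
  expect_equal(sum(topo$mobile == 1), 8 * 50)
  expect_equal(sum(topo$mobile == 0), 8)          # fixed grafting beads
  topo2 <- graft_nups(NULL, anchors, seqs, seed = 4, geom = geom)
  expect_identical(topo$pos, topo2$pos)
  topo3 <- graft_nups(NULL, anchors, seqs, seed = 5, geom = geom)
  expect_false(identical(topo$pos, topo3$pos))
  ## zero anchors: scaffold only
  sc <- build_scaffold(geom)
  t0 <- graft_nups(sc, anchors[0, ], seqs, seed = 1)
  expect_equal(nrow(t0$pos), nrow(sc))
  ## two rings of 8 -> 16 grafting sites
  a2 <- nup_anchors(c("NupX", "NupY"), c(-2, 2), c(10, 10), c(8L, 8L),
                    c("s50", "s50"))
  t2 <- graft_nups(NULL, a2, seqs, seed = 1, geom = geom)
  expect_equal(sum(t2$mobile == 0), 16)
  ## overlapping anchors are rejected (radius 0 collapses a ring to a point)
  bad <- nup_anchors("A", 0, 0, 8L, "s50")
  expect_error(graft_nups(NULL, bad, seqs, seed = 1, geom = geom), "overlap")
})

test_that("minimal variant removes exactly the seven listed Nups", {
  removed <- c("Nup42", "Nup159", "Nup1", "Nup60", "Nup100", "Nsp1", "Nup145")
  all9 <- nup_anchors(c(removed, "Nup57", "Nic96"), seq(-4, 4, by = 1),
                      rep(10, 9), rep(8L, 9), rep("s", 9))
  mv <- make_minimal_variant(all9)
  expect_setequal(mv$nup_name, c("Nup57", "Nic96"))
  ## count bookkeeping: kept + removed = wildtype
  expect_equal(nrow(mv) + sum(all9$nup_name %in% removed), nrow(all9))
  ## empty and no-op cases
  expect_equal(nrow(make_minimal_variant(all9[0, ])), 0)
  only_others <- all9[all9$nup_name %in% c("Nup57", "Nic96"), ]
  expect_warning(res <- make_minimal_variant(only_others), "ignored")
  expect_equal(res, only_others)
})

test_that("synthetic fixture is deterministic with FG-like statistics", {
  fx <- generate_synthetic_fixture(scale = 1 / 3, seed = 9)
  expect_equal(fx$geometry$pore_diameter, 20)
  expect_true(all(nchar(fx$sequences) >= 50 & nchar(fx$sequences) <= 100))
  expect_true(all(fx$stats$fg_fraction >= 0.10 & fx$stats$fg_fraction <= 0.15))
  expect_true(all(fx$stats$net_charge == 0))
  fx2 <- generate_synthetic_fixture(scale = 1 / 3, seed = 9)
  expect_identical(fx$sequences, fx2$sequences)
  expect_false(identical(
    fx$sequences, generate_synthetic_fixture(scale = 1 / 3, seed = 10)$sequences))
  expect_error(generate_synthetic_fixture(scale = 0), "scale")
})
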