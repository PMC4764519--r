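test_that("hydrophobic contact measure X = n a / (pi D)", {
  expect_equal(hydrophobic_measure(0, 10), 0)
  expect_equal(hydrophobic_measure(7, 10, 0.6), 4.2 / (10 * pi))
  expect_equal(hydrophobic_measure(7, 10, 0.6), 0.13369, tolerance = 1e-4)
  ## doubling D halves X
  expect_equal(hydrophobic_measure(5, 20), hydrophobic_measure(5, 10) / 2)
  expect_error(hydrophobic_measure(3, 0), "positive")
  expect_error(hydrophobic_measure(-1, 10), ">= 0")
})

test_that("fit_f recovers the quadratic size coefficient", {
  D <- c(2, 4.2, 6, 7.3, 10)
  exact <- data.frame(D = D, G = 3 * (D / 60)^2)
  f <- fit_f(exact, L = 60)
  expect_equal(f$a1, 3, tolerance = 1e-12)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)
  zero <- fit_f(data.frame(D = D, G = rep(0, 5)), L = 60)
  expect_equal(zero$a1, 0)
  expect_error(fit_f(exact[1, , drop = FALSE]), "two")
  ## noisy recovery within 5% over 100 replicates, at a realistic coefficient
  ## (a1 ~ 380 reproduces a ~10 kJ/mol barrier for D = 10 nm in a 60 nm pore)
  D6 <- c(2, 4.2, 6, 7.3, 10, 12)
  with_seed(12, {
    a1hat <- replicate(100, {
      noisy <- data.frame(D = D6, G = 378 * (D6 / 60)^2 + rnorm(6, sd = 0.1))
      fit_f(noisy, L = 60)$a1
    })
  })
  expect_lt(abs(mean(a1hat) - 378) / 378, 0.05)
  expect_lt(stats::sd(a1hat) / 378, 0.05)
})

test_that("fit_g recovers the hydrophobic-reduction polynomial", {
  true <- transport_model_params(a1 = 40, b0 = 0.5, b1 = 30, b2 = 120, L = 60)
  n <- c(0, 3, 7, 11)
  tab <- data.frame(n = n, G = predict_G(10, n, true))
  g <- fit_g(tab, transport_model_params(a1 = 40, L = 60), D = 10)
  expect_equal(c(g$b0, g$b1, g$b2), c(0.5, 30, 120), tolerance = 1e-8)
  ## with consistent f and an n = 0 point, b0 is (near) zero
  tab0 <- data.frame(n = n, G = predict_G(10, n, transport_model_params(
    a1 = 40, b0 = 0, b1 = 25, b2 = 100, L = 60)))
  g0 <- fit_g(tab0, transport_model_params(a1 = 40, L = 60), D = 10)
  expect_equal(g0$b0, 0, tolerance = 1e-8)
  gc0 <- fit_g(tab0, transport_model_params(a1 = 40, L = 60), D = 10,
               constrain_b0_zero = TRUE)
  expect_identical(gc0$b0, 0)
  expect_error(fit_g(tab[1:2, ], true), "three")
  expect_error(fit_g(data.frame(n = c(2, 2, 2), G = 1:3), true), "degenerate")
})

test_that("full round trip: noisy tables -> fits -> parameters within 10%", {
  ## b0 = 0 so the inert branch is exactly f(D'), as the model assumes when
  ## f is fitted on the n = 0 barrier table
  true <- list(a1 = 378, b0 = 0, b1 = 28, b2 = 110)
  p_true <- transport_model_params(true$a1, true$b0, true$b1, true$b2, L = 60)
  D <- c(2, 4.2, 6, 7.3, 10, 12)
  n <- c(0, 2, 4, 6, 8, 10)
  with_seed(31, {
    est <- replicate(100, {
      td <- data.frame(D = D, G = predict_G(D, 0, p_true) + rnorm(6, sd = 0.1))
      tn <- data.frame(n = n, G = predict_G(10, n, p_true) + rnorm(6, sd = 0.1))
      f <- fit_f(td, L = 60)
      g <- fit_g(tn, f, D = 10)
      c(f$a1, g$b0, g$b1, g$b2)
    })
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - true$a1) / true$a1, 0.10)
  expect_lt(abs(m[3] - true$b1) / true$b1, 0.10)
  expect_lt(abs(m[4] - true$b2) / true$b2, 0.10)
  expect_lt(abs(m[2] - true$b0), 0.2)        # b0 is near zero on its own scale
  ## predictions reproduce the training points within the fit residuals
  td <- data.frame(D = D, G = predict_G(D, 0, p_true))
  f <- fit_f(td, L = 60)
  expect_equal(predict_G(D, 0, f$params), td$G, tolerance = 1e-10)
})

test_that("predict_G composes f and g as stated", {
  p <- transport_model_params(a1 = 50, b0 = 0, b1 = 20, b2 = 80, L = 60)
  expect_equal(predict_G(6, 0, p), 50 * (6 / 60)^2)
  expect_true(all(predict_G(6, 0, transport_model_params(30, L = 60)) >= 0))
  ## G decreases with n while g is increasing
  G <- predict_G(10, 0:12, p)
  expect_true(all(diff(G) < 0))
})

test_that("transport regimes split at +/- kBT and are monotone in G", {
  kT <- kBT(300)
  expect_equal(transport_regime(0), "transported")
  expect_equal(transport_regime(10.5), "expelled")
  expect_equal(transport_regime(-5), "trapped")
  expect_equal(transport_regime(c(kT, -kT)), rep("transported", 2))
  sweep <- transport_regime(seq(8, -8, by = -0.25))
  expect_false(is.unsorted(match(sweep, c("expelled", "transported", "trapped"))))
  expect_error(transport_regime(NA_real_), "finite")
})

test_that("energy map grid, n = 0 row and strip boundaries", {
  p <- transport_model_params(a1 = 45, b0 = 0.3, b1 = 25, b2 = 95, L = 60)
  em <- energy_map(seq(2, 20, length.out = 10), 0:15, p)
  expect_equal(em$G[, 1], p$a1 * (em$D / 60)^2 - p$b0)
  em2 <- energy_map(seq(2, 20, length.out = 10), 0:15, p)
  expect_identical(em, em2)                   # pure function
  ## strip boundary n(D) solves G = +kBT; compare with a root finder
  kT <- kBT(300)
  for (D in seq(6, 20, length.out = 10)) {
    gD <- function(n) predict_G(D, n, p) - kT
    if (gD(0) > 0) {
      root <- stats::uniroot(gD, c(0, 60), tol = 1e-10)$root
      Gat <- predict_G(D, root, p)
      expect_equal(Gat, kT, tolerance = 1e-6)
    }
  }
  expect_error(energy_map(c(-1, 2), 0:3, p), "positive")
})
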