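## Closed-form transport model: G(D, n) = f(D') - g(X), with D' = D/L,
## f(D') = a1 D'^2, g(X) = b2 X^2 + b1 X + b0, X = n a / (pi D).

#' Hydrophobic contact measure X
#'
#' `X = n a / (pi D)`: the fraction of the cargo circumference covered by
#' `n` binding spots of diameter `a`.
#'
#' @param n number of binding spots (>= 0).
#' @param D cargo diameter, nm.
#' @param a binding-spot diameter, nm.
#' @return dimensionless X (vectorised over `n` and `D`).
#' @export
hydrophobic_measure <- function(n, D, a = 0.6) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(n < 0)) stop("n must be >= 0")
  n * a / (pi * D)
}

#' Transport model parameters
#'
#' @param a1 quadratic size coefficient, kJ/mol.
#' @param b0,b1,b2 coefficients of the hydrophobic-reduction polynomial,
#'   kJ/mol.
#' @param L pore diameter used to normalise D, nm.
#' @param a binding-spot diameter, nm.
#' @param kBT_ref thermal energy, kJ/mol.
#' @return object of class `TransportModelParams`.
#' @export
transport_model_params <- function(a1, b0 = 0, b1 = 0, b2 = 0, L = 60, a = 0.6,
                                   kBT_ref = kBT(300)) {
  if (L <= 0 || a <= 0) stop("L and a must be positive")
  structure(list(a1 = a1, b0 = b0, b1 = b1, b2 = b2, L = L, a = a,
                 kBT = kBT_ref), class = "TransportModelParams")
}

#' @export
print.TransportModelParams <- function(x, ...) {
  cat(sprintf("Transport model G(D,n) = a1 (D/L)^2 - (b2 X^2 + b1 X + b0)\n"))
  cat(sprintf("  a1 = %.4g, b0 = %.4g, b1 = %.4g, b2 = %.4g kJ/mol; L = %g nm, a = %g nm\n",
              x$a1, x$b0, x$b1, x$b2, x$L, x$a))
  invisible(x)
}

#' Fit the size term f(D') = a1 D'^2
#'
#' Least squares on barriers of inert (n = 0) cargoes:
#' `a1 = argmin sum (G - a1 (D/L)^2)^2`.
#'
#' @param barriers data.frame with columns `D` (nm) and `G` (kJ/mol); an
#'   optional `dispersion` column enables 1/dispersion^2 weighting.
#' @param L pore diameter, nm.
#' @param weighted use inverse-variance weights if dispersions are present.
#' @return list with `a1`, `residuals` and `params`
#'   (a [transport_model_params()] with only `a1` set).
#' @export
fit_f <- function(barriers, L = 60, weighted = FALSE) {
  if (nrow(barriers) < 2) stop("need at least two (D, G) points")
  Dp2 <- (barriers$D / L)^2
  w <- if (weighted && !is.null(barriers$dispersion) &&
           all(barriers$dispersion > 0)) 1 / barriers$dispersion^2
       else rep(1, nrow(barriers))
  a1 <- sum(w * barriers$G * Dp2) / sum(w * Dp2^2)
  res <- barriers$G - a1 * Dp2
  list(a1 = a1, residuals = res,
       params = transport_model_params(a1 = a1, L = L))
}

#' Fit the hydrophobic reduction g(X)
#'
#' With f already fitted, fits `g(X) = b2 X^2 + b1 X + b0` by least squares
#' to `f(D') - G` over barriers measured at fixed diameter `D` and varying
#' spot count `n`.
#'
#' @param barriers data.frame with columns `n` and `G` (kJ/mol).
#' @param f_params result of [fit_f()] (or a `TransportModelParams` with
#'   `a1`).
#' @param D cargo diameter of the series, nm.
#' @param a binding-spot diameter, nm.
#' @param constrain_b0_zero force `g(0) = 0` so `G(D, 0) = f(D')` exactly.
#' @return list with `b0`, `b1`, `b2`, `residuals` and the full `params`.
#' @export
fit_g <- function(barriers, f_params, D = 10, a = 0.6,
                  constrain_b0_zero = FALSE) {
  if (nrow(barriers) < 3) stop("need at least three (n, G) points")
  p <- if (inherits(f_params, "TransportModelParams")) f_params else f_params$params
  X <- hydrophobic_measure(barriers$n, D, a)
  if (max(X) - min(X) < 1e-12) stop("degenerate design: all X equal")
  y <- p$a1 * (D / p$L)^2 - barriers$G
  if (constrain_b0_zero) {
    fit <- stats::lm(y ~ 0 + X + I(X^2))
    b <- c(0, coef(fit)[["X"]], coef(fit)[["I(X^2)"]])
  } else {
    fit <- stats::lm(y ~ X + I(X^2))
    b <- c(coef(fit)[["(Intercept)"]], coef(fit)[["X"]], coef(fit)[["I(X^2)"]])
  }
  params <- transport_model_params(a1 = p$a1, b0 = b[1], b1 = b[2], b2 = b[3],
                                   L = p$L, a = a)
  list(b0 = b[1], b1 = b[2], b2 = b[3], residuals = stats::residuals(fit),
       params = params)
}

#' Predict the energy barrier G(D, n)
#'
#' `G = a1 (D/L)^2 - (b2 X^2 + b1 X + b0)` with `X = n a / (pi D)`.
#'
#' @param D cargo diameter(s), nm.
#' @param n binding-spot count(s).
#' @param params a `TransportModelParams`.
#' @return predicted barrier(s), kJ/mol.
#' @export
predict_G <- function(D, n, params) {
  X <- hydrophobic_measure(n, D, params$a)
  params$a1 * (D / params$L)^2 - (params$b2 * X^2 + params$b1 * X + params$b0)
}

#' Classify the transport regime
#'
#' Efficient transport happens in the strip |G| <= kBT: above it the cargo
#' is expelled by the barrier, below it the pore becomes an energy well that
#' traps the cargo.
#'
#' @param G barrier value(s), kJ/mol.
#' @param kBT_ref thermal energy, kJ/mol.
#' @return character vector: "expelled", "transported" or "trapped".
#' @export
transport_regime <- function(G, kBT_ref = kBT(300)) {
  if (any(!is.finite(G))) stop("G must be finite")
  ifelse(G > kBT_ref, "expelled", ifelse(G < -kBT_ref, "trapped", "transported"))
}

#' Energy map over diameter and spot count
#'
#' Evaluates G(D, n) on a grid and labels each cell's transport regime,
#' reproducing the contour-map view of the model: the transported band lies
#' between the +kBT and -kBT iso-lines.
#'
#' @param D_grid,n_grid positive grids.
#' @param params a `TransportModelParams`.
#' @return list with `D`, `n`, `G` (length(D) x length(n)) and `regime`
#'   (same shape, character).
#' @export
energy_map <- function(D_grid, n_grid, params) {
  if (any(D_grid <= 0) || any(n_grid < 0)) stop("grids must be positive")
  G <- outer(D_grid, n_grid, function(D, n) predict_G(D, n, params))
  regime <- matrix(transport_regime(as.numeric(G), params$kBT),
                   length(D_grid), length(n_grid))
  list(D = D_grid, n = n_grid, G = G, regime = regime)
}
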