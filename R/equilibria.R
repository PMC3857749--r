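#' Coefficients of the endemic-equilibrium cubic
#'
#' Substituting the R-nullcline \eqn{R = (mI + k)/(d+\gamma)} into the
#' equilibrium condition of the reduced system yields
#' \deqn{f(I) = \alpha(d+m) I^3
#'   + \left[\frac{\beta(d+\gamma+m)}{d+\gamma} + (k - pA)\alpha\right] I^2
#'   + \left[d+m+\frac{\beta k}{d+\gamma} - \beta N_0\right] I + k - pA.}
#' Endemic equilibria are the positive roots of `f` that map into the
#' feasible region `D`. The leading coefficient is always positive and the
#' constant term `k - pA = pA (R0 - 1)` changes sign exactly at `R0 = 1`.
#'
#' @param params a [sirs_params()] object.
#' @return an object of class `sirs_cubic`: list with fields `c3`, `c2`, `c1`,
#'   `c0` (descending powers).
#' @export
cubic_coefficients <- function(params) {
  stopifnot(inherits(params, "sirs_params"))
  d <- params$d; m <- params$m; g <- params$gamma
  pA <- compute_pA(params); N0 <- compute_N0(params)
  structure(list(
    c3 = params$alpha * (d + m),
    c2 = params$beta * (d + g + m) / (d + g) + (params$k - pA) * params$alpha,
    c1 = d + m + params$beta * params$k / (d + g) - params$beta * N0,
    c0 = params$k - pA
  ), class = "sirs_cubic")
}

#' Evaluate the equilibrium cubic
#' @param coeffs a `sirs_cubic` from [cubic_coefficients()].
#' @param I evaluation points (vectorized).
#' @return `f(I)`.
#' @export
eval_cubic <- function(coeffs, I) {
  stopifnot(inherits(coeffs, "sirs_cubic"))
  ((coeffs$c3 * I + coeffs$c2) * I + coeffs$c1) * I + coeffs$c0
}

# all three roots of the (monic-normalized) cubic via companion-matrix
# eigenvalues; stable near double roots, unlike the closed-form solution
cubic_roots <- function(coeffs) {
  a <- coeffs$c2 / coeffs$c3
  b <- coeffs$c1 / coeffs$c3
  c0 <- coeffs$c0 / coeffs$c3
  comp <- matrix(c(0, 0, -c0,
                   1, 0, -b,
                   0, 1, -a), nrow = 3, byrow = TRUE)
  eigen(comp, only.values = TRUE)$values
}

#' Find and classify the endemic equilibria
#'
#' Solves the cubic of [cubic_coefficients()] (companion-matrix eigenvalues),
#' keeps roots that are real to tolerance (`|Im| <= 1e-9 (1 + |Re|)`), maps
#' each to an equilibrium through the R-nullcline `R_e = (m I_e + k)/(d+gamma)`
#' and flags membership in `D`. Real roots closer together than
#' `1e-7 * N0` are merged and reported once with multiplicity 2 (saddle-node
#' tangency). When `R0 < 1` the unique in-domain root is additionally checked
#' against the analytic bracket `(pA - k)/(d + m) < I_e < N0`.
#'
#' @param params a [sirs_params()] object.
#' @param r0_tol half-width of the `|R0 - 1|` band reported as regime
#'   `"threshold"`.
#' @return an object of class `sirs_equilibria`: list with `R0`, `regime`
#'   (`"unique_endemic"`, `"one_or_two_endemic"` or `"threshold"`),
#'   `equilibria` (data frame `I`, `R`, `residual_f`, `residual_rhs`,
#'   `in_domain`, `multiplicity`, `in_bracket`, sorted by `I`), `roots` (all
#'   three complex roots) and `vieta_residuals`.
#' @examples
#' eq <- find_equilibria(example_params())
#' subset(eq$equilibria, in_domain)
#' @export
find_equilibria <- function(params, r0_tol = 1e-9) {
  stopifnot(inherits(params, "sirs_params"))
  co <- cubic_coefficients(params)
  R0 <- compute_R0(params)
  N0 <- compute_N0(params)
  pA <- compute_pA(params)
  roots <- cubic_roots(co)

  real_mask <- abs(Im(roots)) <= 1e-9 * (1 + abs(Re(roots)))
  Ire <- sort(Re(roots[real_mask]))

  # merge double roots (within 1e-7 * N0)
  I_vals <- numeric(0); mult <- integer(0)
  for (r in Ire) {
    if (length(I_vals) > 0L && abs(r - I_vals[length(I_vals)]) <= 1e-7 * N0) {
      mult[length(mult)] <- mult[length(mult)] + 1L
      I_vals[length(I_vals)] <- (I_vals[length(I_vals)] + r) / 2
    } else {
      I_vals <- c(I_vals, r); mult <- c(mult, 1L)
    }
  }

  dg <- params$d + params$gamma
  R_vals <- (params$m * I_vals + params$k) / dg
  resid_f <- abs(eval_cubic(co, I_vals))
  resid_rhs <- vapply(seq_along(I_vals), function(i)
    max(abs(rhs_reduced(c(I_vals[i], R_vals[i]), params))), numeric(1))
  dom <- vapply(seq_along(I_vals), function(i)
    I_vals[i] > 0 && in_domain(c(I_vals[i], R_vals[i]), params), logical(1))

  bracket <- rep(NA, length(I_vals))
  regime <- if (abs(R0 - 1) <= r0_tol) "threshold"
            else if (R0 < 1) "unique_endemic" else "one_or_two_endemic"
  if (regime == "unique_endemic") {
    lo <- (pA - params$k) / (params$d + params$m)
    bracket <- I_vals > lo & I_vals < N0
  }

  eqs <- data.frame(I = I_vals, R = R_vals,
                    residual_f = resid_f, residual_rhs = resid_rhs,
                    in_domain = dom, multiplicity = mult,
                    in_bracket = bracket)

  structure(list(R0 = R0, regime = regime, equilibria = eqs, roots = roots,
                 vieta_residuals = vieta_check(co, roots, params),
                 params = params),
            class = "sirs_equilibria")
}

#' @export
print.sirs_equilibria <- function(x, ...) {
  cat(sprintf("Endemic equilibria (R0 = %.6g, regime: %s)\n", x$R0, x$regime))
  print(x$equilibria, digits = 6)
  cat(sprintf("Vieta residuals: %.3g, %.3g\n",
              x$vieta_residuals[1], x$vieta_residuals[2]))
  invisible(x)
}

#' In-domain equilibria as a list of (I, R) pairs
#'
#' Convenience accessor: the rows of `find_equilibria(params)$equilibria`
#' with `in_domain = TRUE`, each as a named numeric `(I, R)`, ascending in I.
#'
#' @param params a [sirs_params()] object.
#' @return list of named numeric vectors (possibly empty).
#' @export
endemic_equilibria <- function(params) {
  eqs <- find_equilibria(params)$equilibria
  eqs <- eqs[eqs$in_domain, , drop = FALSE]
  lapply(seq_len(nrow(eqs)), function(i) c(I = eqs$I[i], R = eqs$R[i]))
}

#' Vieta identities of the equilibrium cubic
#'
#' With elementary symmetric functions `e1 = I1+I2+I3`,
#' `e2 = I1 I2 + I1 I3 + I2 I3`, `e3 = I1 I2 I3` of the three roots, the
#' coefficients imply two exact identities:
#' \deqn{\frac{\beta}{\alpha(d+m)}\left(\frac{A}{d} - \frac{k}{d+\gamma}\right)
#'   = \frac{1}{\alpha} - e_2, \qquad
#'   \frac{\beta}{\alpha(d+m)}\left(1 + \frac{m}{d+\gamma}\right)
#'   = \alpha e_3 - e_1.}
#' Both residuals vanish algebraically; on well-scaled inputs they stay below
#' about 1e-8 and act as a regression guard on the root solver.
#'
#' @param coeffs a `sirs_cubic` from [cubic_coefficients()].
#' @param roots the three (complex) roots of the cubic.
#' @param params the [sirs_params()] the coefficients came from; the
#'   left-hand sides are formed from the raw rates, independently of the
#'   coefficients the roots were solved from.
#' @return numeric length 2: absolute residuals of the two identities.
#' @export
vieta_check <- function(coeffs, roots, params) {
  stopifnot(inherits(coeffs, "sirs_cubic"), length(roots) == 3L,
            inherits(params, "sirs_params"))
  e1 <- sum(roots)
  e2 <- roots[1] * roots[2] + roots[1] * roots[3] + roots[2] * roots[3]
  e3 <- roots[1] * roots[2] * roots[3]
  d <- params$d; m <- params$m; g <- params$gamma
  pref <- params$beta / (params$alpha * (d + m))
  lhs1 <- pref * (params$A / params$d - params$k / (d + g))
  lhs2 <- pref * (1 + m / (d + g))
  as.numeric(c(Mod(lhs1 - (1 / params$alpha - e2)),
               Mod(lhs2 - (params$alpha * e3 - e1))))
}
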