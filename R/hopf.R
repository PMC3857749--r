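#' Linearization of the rescaled system at an equilibrium
#'
#' Entries of the Jacobian of the time-rescaled field at `(I*, R*)`:
#' \deqn{a_{11} = \beta(N_0 - 2I_* - R_*) - (d+m)(1+3\alpha I_*^2)
#'   - 2 pA \alpha (R_0 - 1) I_*,}
#' \deqn{a_{12} = -\beta I_*, \quad a_{21} = m (1+\alpha I_*^2), \quad
#'   a_{22} = -(d+\gamma)(1+\alpha I_*^2).}
#' The `a21` entry uses the equilibrium identity
#' \eqn{m I_* - (d+\gamma) R_* + k = 0}, so the input must be an equilibrium.
#'
#' @param eq numeric `(I, R)`, an in-domain equilibrium.
#' @param params a [sirs_params()] object.
#' @param residual_tol as in [jacobian_reduced()].
#' @return named numeric `(a11, a12, a21, a22)`.
#' @export
linearization_entries <- function(eq, params, residual_tol = 1e-6) {
  stopifnot(inherits(params, "sirs_params"))
  s <- as_state2(eq)
  res <- max(abs(rhs_reduced(s, params)))
  if (res > residual_tol * max(1, compute_pA(params)))
    stop(sprintf("linearization_entries(): (%.6g, %.6g) is not an equilibrium (residual %.3g)",
                 s[["I"]], s[["R"]], res), call. = FALSE)
  I <- s[["I"]]; R <- s[["R"]]
  pA <- compute_pA(params); N0 <- compute_N0(params)
  R0 <- compute_R0(params)
  q <- 1 + params$alpha * I^2
  c(a11 = params$beta * (N0 - 2 * I - R) -
        (params$d + params$m) * (1 + 3 * params$alpha * I^2) -
        2 * pA * params$alpha * (R0 - 1) * I,
    a12 = -params$beta * I,
    a21 = params$m * q,
    a22 = -(params$d + params$gamma) * q)
}

#' Trace-zero Hopf-candidate diagnostics at an equilibrium
#'
#' Populates the full diagnostic report for the rescaled-system linearization
#' at `eq`: the four entries, the trace residual `|a11 + a22|`, the quantity
#' \deqn{\delta = (d+\gamma)^2 (1+\alpha I_*^2)^2 - m \beta I_* (1+\alpha I_*^2),}
#' `omega = sqrt(delta)` (when `delta > 0`), the Lyapunov number of
#' [lyapunov_sigma()], and the two gating booleans: `delta_condition`
#' (\eqn{(d+\gamma)^2(1+\alpha I_*^2) > m\beta I_*}) and `hopf_point`
#' (trace residual within `tol` relative AND `delta_condition`).
#'
#' **Caveat** (see the vignette): `delta` equals *minus* the determinant of
#' the linearization at trace zero, so `delta_condition = TRUE` together with
#' trace zero actually certifies a hyperbolic saddle (eigenvalues
#' \eqn{\pm\sqrt\delta}), not a center. A genuine Hopf point requires
#' `det > 0`, i.e. `delta < 0`. The report therefore also carries `trace`,
#' `det` and `genuine_hopf = (trace_residual small AND det > 0)`.
#'
#' @param eq numeric `(I, R)`, an in-domain equilibrium.
#' @param params a [sirs_params()] object.
#' @param tol relative tolerance on the trace-zero condition (default 1e-3:
#'   bifurcation parameters printed to 5 digits put the trace within about
#'   1e-4 of zero).
#' @return an object of class `sirs_hopf`.
#' @export
hopf_condition <- function(eq, params, tol = 1e-3) {
  a <- linearization_entries(eq, params)
  s <- as_state2(eq)
  I <- s[["I"]]
  d <- params$d; g <- params$gamma
  q <- 1 + params$alpha * I^2
  delta <- (d + g)^2 * q^2 - params$m * params$beta * I * q
  trace_residual <- abs(a[["a11"]] + a[["a22"]])
  delta_condition <- (d + g)^2 * q > params$m * params$beta * I
  tr <- a[["a11"]] + a[["a22"]]
  dt <- a[["a11"]] * a[["a22"]] - a[["a12"]] * a[["a21"]]
  trace_ok <- trace_residual <= tol * (1 + abs(a[["a11"]]))
  sigma <- lyapunov_sigma(eq, params)
  crit_tol <- 1e-10
  structure(list(
    equilibrium = s,
    a11 = a[["a11"]], a12 = a[["a12"]], a21 = a[["a21"]], a22 = a[["a22"]],
    trace = tr, det = dt,
    trace_residual = trace_residual,
    delta = delta,
    omega = if (delta > 0) sqrt(delta) else NA_real_,
    sigma = sigma,
    delta_condition = delta_condition,
    hopf_point = trace_ok && delta_condition,
    genuine_hopf = trace_ok && dt > 0,
    criticality = if (abs(sigma) <= crit_tol) "degenerate"
                  else if (sigma > 0) "subcritical" else "supercritical",
    tol = tol
  ), class = "sirs_hopf")
}

#' @export
print.sirs_hopf <- function(x, ...) {
  cat(sprintf("Hopf diagnostics at (I*, R*) = (%.6g, %.6g)\n",
              x$equilibrium[["I"]], x$equilibrium[["R"]]))
  cat(sprintf("  a11 = %.6g  a12 = %.6g  a21 = %.6g  a22 = %.6g\n",
              x$a11, x$a12, x$a21, x$a22))
  cat(sprintf("  trace = %.3g (residual %.3g), det = %.6g\n",
              x$trace, x$trace_residual, x$det))
  cat(sprintf("  delta = %.6g (condition %s), omega = %.6g\n",
              x$delta, x$delta_condition, x$omega))
  cat(sprintf("  sigma = %.6g (%s)\n", x$sigma, x$criticality))
  cat(sprintf("  hopf_point (trace-zero + delta condition): %s\n", x$hopf_point))
  cat(sprintf("  genuine_hopf (trace-zero + det > 0): %s\n", x$genuine_hopf))
  invisible(x)
}

#' First Lyapunov (focal) number, closed form
#'
#' \deqn{\sigma = \frac{1}{16}\left[\frac{2\alpha(d+\gamma)}{\beta I_*}
#'   - 6\alpha(d+m)\right].}
#' Sign convention: `sigma > 0` is reported as subcritical (an unstable cycle
#' surrounds the equilibrium), `sigma < 0` supercritical. The closed form is
#' the normative value; [focal_value_crosscheck()] provides an independent
#' numerical estimate from the transformed vector field.
#'
#' @param eq numeric `(I, R)` equilibrium, or a single positive number taken
#'   as `I*` directly.
#' @param params a [sirs_params()] object.
#' @return scalar sigma.
#' @export
lyapunov_sigma <- function(eq, params) {
  stopifnot(inherits(params, "sirs_params"))
  I <- if (length(eq) == 1L) as.numeric(eq) else as_state2(eq)[["I"]]
  if (!is.finite(I) || I <= 0)
    stop("lyapunov_sigma(): I* must be strictly positive", call. = FALSE)
  a <- params$alpha
  (2 * a * (params$d + params$gamma) / (params$beta * I) -
     6 * a * (params$d + params$m)) / 16
}

# central-difference partials of a bivariate vector field g(u, v) -> c(g1, g2)
# orders used by the focal-value formula; h is the stencil width
field_partials <- function(g, h) {
  G <- array(NA_real_, dim = c(5, 5, 2))
  for (iu in -2:2) for (iv in -2:2) G[iu + 3, iv + 3, ] <- g(iu * h, iv * h)
  v <- function(iu, iv, c) G[iu + 3, iv + 3, c]
  list(
    d2 = function(c, which) switch(which,
      uu = (v(1, 0, c) - 2 * v(0, 0, c) + v(-1, 0, c)) / h^2,
      vv = (v(0, 1, c) - 2 * v(0, 0, c) + v(0, -1, c)) / h^2,
      uv = (v(1, 1, c) - v(1, -1, c) - v(-1, 1, c) + v(-1, -1, c)) / (4 * h^2)),
    d3 = function(c, which) switch(which,
      uuu = (v(2, 0, c) - 2 * v(1, 0, c) + 2 * v(-1, 0, c) - v(-2, 0, c)) / (2 * h^3),
      vvv = (v(0, 2, c) - 2 * v(0, 1, c) + 2 * v(0, -1, c) - v(0, -2, c)) / (2 * h^3),
      uvv = ((v(1, 1, c) - 2 * v(1, 0, c) + v(1, -1, c)) -
             (v(-1, 1, c) - 2 * v(-1, 0, c) + v(-1, -1, c))) / (2 * h^3),
      uuv = ((v(1, 1, c) - 2 * v(0, 1, c) + v(-1, 1, c)) -
             (v(1, -1, c) - 2 * v(0, -1, c) + v(-1, -1, c))) / (2 * h^3))
  )
}

# the planar focal-value combination of second/third partials of (F1, F2);
# with_omega divides the quadratic block by omega (the standard weighting)
focal_value_formula <- function(p, omega = 1) {
  cubic <- p$d3(1, "uuu") + p$d3(1, "uvv") + p$d3(2, "uuv") + p$d3(2, "vvv")
  quad <- p$d2(1, "uv") * (p$d2(1, "uu") + p$d2(1, "vv")) -
          p$d2(2, "uv") * (p$d2(2, "uu") + p$d2(2, "vv")) -
          p$d2(1, "uu") * p$d2(2, "uu") + p$d2(1, "vv") * p$d2(2, "vv")
  (cubic + quad / omega) / 16
}

#' Numerical focal-value cross-check
#'
#' Rebuilds the `(u, v)` coordinates of the trace-zero normal-form chain
#' (shift `x = I - I*`, `y = R - R*`; `X = x`, `Y = a11 x + a12 y`;
#' `u = -X`, `v = Y/sqrt(delta)`) directly from [rhs_rescaled()], then
#' evaluates the focal-value combination of second and third partial
#' derivatives of the transformed field by central differences. Linear terms
#' do not enter the formula, so no subtraction of the linear part is needed.
#'
#' Because the linear part in these coordinates is \eqn{(-\sqrt\delta v,
#' -\sqrt\delta u)} — a symmetric saddle form, not a rotation — the value
#' returned for `delta > 0` is a formula evaluation with no dynamical
#' meaning; it is exposed to quantify the discrepancy against
#' [lyapunov_sigma()] (see the vignette). `uv_field` of the returned object
#' gives the transformed field for further inspection.
#'
#' @param eq numeric `(I, R)` equilibrium.
#' @param params a [sirs_params()] object.
#' @param h finite-difference stencil width in the `(u, v)` chart.
#' @param weighted if TRUE, apply the standard `1/omega` weighting to the
#'   quadratic block (`omega = sqrt(delta)`); FALSE evaluates the unweighted
#'   combination.
#' @return list with `sigma_estimate`, `sigma_closed_form`, `delta`,
#'   `linear_part` (2x2 matrix of the transformed linearization) and
#'   `uv_field`.
#' @export
focal_value_crosscheck <- function(eq, params, h = 1e-3, weighted = FALSE) {
  stopifnot(inherits(params, "sirs_params"))
  s <- as_state2(eq)
  hc <- hopf_condition(s, params)
  if (!is.finite(hc$delta) || hc$delta <= 0)
    stop("focal_value_crosscheck(): transformation requires delta > 0",
         call. = FALSE)
  sd <- sqrt(hc$delta)
  a11 <- hc$a11; a12 <- hc$a12
  Istar <- s[["I"]]; Rstar <- s[["R"]]
  uv_field <- function(u, v) {
    x <- -u
    y <- (sd * v - a11 * x) / a12
    f <- rhs_rescaled(c(Istar + x, Rstar + y), params)
    c(-f[["dI"]], (a11 * f[["dI"]] + a12 * f[["dR"]]) / sd)
  }
  # measured linear part (central differences)
  lin <- matrix(NA_real_, 2, 2)
  hl <- 1e-6
  lin[, 1] <- (uv_field(hl, 0) - uv_field(-hl, 0)) / (2 * hl)
  lin[, 2] <- (uv_field(0, hl) - uv_field(0, -hl)) / (2 * hl)
  p <- field_partials(uv_field, h)
  est <- focal_value_formula(p, omega = if (weighted) sd else 1)
  list(sigma_estimate = est,
       sigma_closed_form = lyapunov_sigma(s, params),
       delta = hc$delta,
       linear_part = lin,
       uv_field = uv_field)
}

#' Numerical first Lyapunov coefficient at a genuine Hopf point
#'
#' For an equilibrium whose linearization has (near-)zero trace and positive
#' determinant — a genuine Hopf candidate — transforms the reduced field to
#' the standard rotational normal-form chart (`u = x`,
#' `v = -(J11 x + J12 y)/omega`, `omega = sqrt(det)`, giving linear part
#' `(-omega v, omega u)`) and evaluates the Guckenheimer–Holmes first
#' Lyapunov coefficient by central differences. Its sign determines true
#' criticality: positive means subcritical (unstable cycle on the stable
#' side of the bifurcation).
#'
#' @param eq numeric `(I, R)` equilibrium.
#' @param params a [sirs_params()] object.
#' @param h finite-difference stencil width (in the scaled chart).
#' @return list with `l1` (the coefficient), `omega`, `trace`, `det`.
#' @export
first_lyapunov_coefficient <- function(eq, params, h = 1e-3) {
  stopifnot(inherits(params, "sirs_params"))
  s <- as_state2(eq)
  J <- jacobian_reduced(s, params)
  dt <- det(J)
  if (dt <= 0)
    stop("first_lyapunov_coefficient(): requires det(J) > 0", call. = FALSE)
  omega <- sqrt(dt)
  Istar <- s[["I"]]; Rstar <- s[["R"]]
  Tm <- matrix(c(1, 0, -J[1, 1] / omega, -J[1, 2] / omega), 2, byrow = TRUE)
  Ti <- solve(Tm)
  g <- function(u, v) {
    xy <- Ti %*% c(u, v)
    f <- rhs_reduced(c(Istar + xy[1], Rstar + xy[2]), params)
    as.numeric(Tm %*% f)
  }
  p <- field_partials(g, h)
  list(l1 = focal_value_formula(p, omega = omega),
       omega = omega, trace = sum(diag(J)), det = dt)
}
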