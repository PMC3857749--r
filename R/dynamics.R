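variant_id <- function(variant) {
  match(variant, c("full", "reduced", "rescaled")) - 1L
}

#' Integrate a model variant
#'
#' Adaptive Dormand-Prince 5(4) integration (embedded error control, FSAL)
#' of the full 3-D system, the reduced planar system, or the time-rescaled
#' planar system. `direction = "backward"` integrates the time-reversed field;
#' the returned `t` column is always the elapsed (non-negative, increasing)
#' time along the computed orbit.
#'
#' @param params a [sirs_params()] object.
#' @param init initial state: `(I, R)` for planar variants, `(S, I, R)` for
#'   the full system.
#' @param variant `"reduced"` (default), `"rescaled"` or `"full"`.
#' @param t_end final time (> 0); ignored when `times` is given.
#' @param n_out number of equally spaced output times on `[0, t_end]`
#'   (default 501).
#' @param times explicit strictly increasing output grid starting at 0.
#' @param direction `"forward"` or `"backward"`.
#' @param rtol,atol integrator tolerances (defaults 1e-9, 1e-12).
#' @return an object of class `sirs_trajectory`: a data frame with column `t`
#'   and one column per compartment, with attributes `variant`, `direction`,
#'   `rtol`, `atol` and `params`.
#' @examples
#' tr <- integrate_sirs(example_params(), c(2, 1), t_end = 50)
#' tail(tr, 2)
#' @export
integrate_sirs <- function(params, init,
                           variant = c("reduced", "rescaled", "full"),
                           t_end = NULL, n_out = 501L, times = NULL,
                           direction = c("forward", "backward"),
                           rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "sirs_params"))
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0)
      stop("integrate_sirs(): t_end must be positive", call. = FALSE)
    times <- seq(0, t_end, length.out = n_out)
  }
  if (times[1] != 0) times <- c(0, times)
  init <- if (is.list(init)) unlist(init) else as.numeric(init)
  dim_needed <- if (variant == "full") 3L else 2L
  if (length(init) != dim_needed)
    stop(sprintf("integrate_sirs(): variant '%s' needs a state of length %d",
                 variant, dim_needed), call. = FALSE)
  states <- .dp45_path(variant_id(variant), init, params_vector(params),
                       times, rtol, atol, direction == "backward")
  cols <- if (variant == "full") c("S", "I", "R") else c("I", "R")
  colnames(states) <- cols
  out <- data.frame(t = times, states)
  attr(out, "variant") <- variant
  attr(out, "direction") <- direction
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  attr(out, "params") <- params
  class(out) <- c("sirs_trajectory", "data.frame")
  out
}

# cubic-Hermite interpolation of a component between two samples, plus root
# of (R - level) in the bracket; derivatives from the (direction-adjusted)
# model field give O(dt^4) crossing accuracy
hermite_val <- function(t0, t1, y0, y1, d0, d1, t) {
  h <- t1 - t0; s <- (t - t0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s);       h11 <- s^2 * (s - 1)
  h00 * y0 + h * h10 * d0 + h01 * y1 + h * h11 * d1
}

field_for <- function(variant, direction, params) {
  base <- if (variant == "rescaled") rhs_rescaled else rhs_reduced
  sgn <- if (direction == "backward") -1 else 1
  function(state) sgn * base(state, params)
}

#' Detect an unstable periodic orbit by backward-time return maps
#'
#' An unstable (repelling) limit cycle is attracting for the time-reversed
#' flow. Starting from `eq + displacement`, the time-reversed rescaled (or
#' reduced) field is integrated in chunks; crossings of the Poincare section
#' `{R = R_section}` in a fixed direction are located by cubic-Hermite
#' refinement between dense samples, and the return map `I_n -> I_(n+1)` on
#' the section is monitored. Convergence is declared when successive
#' same-direction crossings satisfy `|I_(n+1) - I_n| < residual_tol`; the
#' period is the elapsed time between them. The orbit is then resampled over
#' one period for the amplitude and the winding number about `eq`.
#'
#' Failure modes are reported, not raised: the trajectory leaving the
#' feasible region `D`, the return map not converging within `max_returns`
#' crossings or `max_time` time units, or the backward orbit collapsing onto
#' an equilibrium.
#'
#' @param params a [sirs_params()] object.
#' @param eq numeric `(I, R)`: the equilibrium the candidate cycle encircles
#'   (for a subcritical Hopf scenario, the focus with `sigma > 0` context).
#' @param variant planar variant to integrate (default `"rescaled"`).
#' @param displacement added to `eq` for the starting point (default
#'   `c(0.01, 0)`).
#' @param section_R the section level (default `R_e` of `eq`).
#' @param residual_tol return-map convergence tolerance (default 1e-7).
#' @param max_returns bound on section crossings examined (default 200).
#' @param max_time bound on total backward time (default 2000).
#' @param dt sampling interval used for crossing detection (default 0.005).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `sirs_cycle`: list with `found`, `period`,
#'   `section_point`, `amplitude_I`, `return_map_residual`, `winding_number`,
#'   `enclosed_equilibrium`, `n_returns`, `diagnostic`, `orbit` (one-period
#'   trajectory when found), `crossings` (I values of the same-direction
#'   section crossings).
#' @export
find_unstable_cycle <- function(params, eq,
                                variant = c("rescaled", "reduced"),
                                displacement = c(0.01, 0),
                                section_R = NULL,
                                residual_tol = 1e-7,
                                max_returns = 200L,
                                max_time = 2000,
                                dt = 0.005,
                                rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "sirs_params"))
  variant <- match.arg(variant)
  eq <- as_state2(eq)
  if (is.null(section_R)) section_R <- eq[["R"]]
  N0 <- compute_N0(params)
  fail <- function(diag, crossings = numeric(0), n = 0L)
    structure(list(found = FALSE, period = NA_real_, section_point = NULL,
                   amplitude_I = NA_real_, return_map_residual = NA_real_,
                   winding_number = NA_integer_,
                   enclosed_equilibrium = eq, n_returns = n,
                   diagnostic = diag, orbit = NULL, crossings = crossings),
              class = "sirs_cycle")

  f <- field_for(variant, "backward", params)
  state <- eq + displacement
  if (!in_domain(state, params))
    return(fail("starting point outside D"))

  t_chunk <- 50
  t_off <- 0
  cross_dir <- 0            # sign of dR/dt (backward field) at crossings kept
  cross_t <- numeric(0)     # refined crossing times (global backward time)
  cross_I <- numeric(0)

  while (t_off < max_time) {
    n_sub <- max(2L, ceiling(t_chunk / dt) + 1L)
    tr <- tryCatch(
      integrate_sirs(params, state, variant = variant, t_end = t_chunk,
                     n_out = n_sub, direction = "backward",
                     rtol = rtol, atol = atol),
      error = function(e) e)
    if (inherits(tr, "error"))
      return(fail(paste("integration failed:", conditionMessage(tr)),
                  cross_I, length(cross_I)))
    bad <- tr$I <= -1e-8 * N0 | tr$R <= -1e-8 * N0 |
           tr$I + tr$R >= N0 * (1 + 1e-8)
    if (any(bad)) {
      i_bad <- which(bad)[1]
      return(fail(sprintf("trajectory left D at backward time %.4g",
                          t_off + tr$t[i_bad]), cross_I, length(cross_I)))
    }
    # collapse onto an equilibrium?
    endf <- max(abs(f(c(tr$I[n_sub], tr$R[n_sub]))))
    if (endf < 1e-12 * max(1, compute_pA(params)))
      return(fail("backward orbit collapsed onto an equilibrium",
                  cross_I, length(cross_I)))

    g <- tr$R - section_R
    idx <- which(g[-n_sub] * g[-1] < 0)
    for (i in idx) {
      st0 <- c(tr$I[i], tr$R[i]); st1 <- c(tr$I[i + 1], tr$R[i + 1])
      d0 <- f(st0); d1 <- f(st1)
      if (cross_dir == 0) cross_dir <- sign(d0[["dR"]])
      if (sign(d0[["dR"]]) != cross_dir) next
      root <- stats::uniroot(function(tt)
        hermite_val(tr$t[i], tr$t[i + 1], st0[2], st1[2],
                    d0[["dR"]], d1[["dR"]], tt) - section_R,
        lower = tr$t[i], upper = tr$t[i + 1], tol = 1e-13)$root
      Ic <- hermite_val(tr$t[i], tr$t[i + 1], st0[1], st1[1],
                        d0[["dI"]], d1[["dI"]], root)
      cross_t <- c(cross_t, t_off + root)
      cross_I <- c(cross_I, Ic)
      n <- length(cross_I)
      if (n >= 2L &&
          abs(cross_I[n] - cross_I[n - 1]) < residual_tol) {
        period <- cross_t[n] - cross_t[n - 1]
        return(finish_cycle(params, variant, eq,
                            section_point = c(I = cross_I[n], R = section_R),
                            period = period,
                            residual = abs(cross_I[n] - cross_I[n - 1]),
                            crossings = cross_I, rtol = rtol, atol = atol))
      }
      if (n >= max_returns)
        return(fail("return map did not converge within max_returns",
                    cross_I, n))
    }
    state <- c(tr$I[n_sub], tr$R[n_sub])
    t_off <- t_off + t_chunk
  }
  fail("max_time exhausted without return-map convergence",
       cross_I, length(cross_I))
}

# resample one period from the converged section point, measure amplitude and
# winding number about the enclosed equilibrium
finish_cycle <- function(params, variant, eq, section_point, period,
                         residual, crossings, rtol, atol) {
  orbit <- integrate_sirs(params, section_point, variant = variant,
                          t_end = period, n_out = 2001L,
                          direction = "backward", rtol = rtol, atol = atol)
  # orientation depends on traversal direction (backward time flips it);
  # the report carries the encirclement count
  wn <- abs(winding_number(cbind(orbit$I, orbit$R), eq))
  structure(list(found = TRUE, period = period,
                 section_point = section_point,
                 amplitude_I = max(orbit$I) - min(orbit$I),
                 return_map_residual = residual,
                 winding_number = wn,
                 enclosed_equilibrium = eq,
                 n_returns = length(crossings),
                 diagnostic = "return map converged",
                 orbit = orbit, crossings = crossings),
            class = "sirs_cycle")
}

#' @export
print.sirs_cycle <- function(x, ...) {
  cat("Periodic-orbit search (backward-time Poincare return map)\n")
  cat(sprintf("  found: %s (%s)\n", x$found, x$diagnostic))
  if (x$found) {
    cat(sprintf("  period = %.8g, amplitude_I = %.6g\n",
                x$period, x$amplitude_I))
    cat(sprintf("  section point (I, R) = (%.8g, %.8g), residual = %.3g\n",
                x$section_point[["I"]], x$section_point[["R"]],
                x$return_map_residual))
    cat(sprintf("  winding number about (%.6g, %.6g): %d\n",
                x$enclosed_equilibrium[["I"]], x$enclosed_equilibrium[["R"]],
                x$winding_number))
  }
  invisible(x)
}

#' Winding number of a closed path about a point
#'
#' Sum of wrapped angle increments along the path divided by `2*pi`, rounded
#' to the nearest integer.
#'
#' @param path two-column matrix of points along the (closed) path.
#' @param center the reference point `(x, y)`.
#' @return integer winding number.
#' @export
winding_number <- function(path, center) {
  stopifnot(is.matrix(path), ncol(path) == 2L)
  th <- atan2(path[, 2] - center[[2]], path[, 1] - center[[1]])
  dth <- diff(th)
  dth <- ((dth + pi) %% (2 * pi)) - pi
  as.integer(round(sum(dth) / (2 * pi)))
}

#' Check forward invariance of the feasible region D
#'
#' Integrates `n_starts` seeded uniform starts in `D` forward to `t_end`
#' (reduced variant) and reports whether every sampled state satisfies
#' `I > -eps`, `R > -eps`, `I + R < N0 + eps` with `eps = 1e-8 * N0`.
#' Integration blow-up (possible once an orbit has left `D`, where the
#' reduced field is no longer meaningful) counts as a violation.
#'
#' Note `D` is genuinely forward-invariant only when `R0 <= 1`: for `R0 > 1`
#' the reduced field has `I' = pA - k < 0` along `I = 0+`, and orbits below
#' the stable manifold of the saddle exit through `I = 0`.
#'
#' @param params a [sirs_params()] object.
#' @param n_starts number of random starts (default 20).
#' @param t_end forward horizon (default 500).
#' @param seed RNG seed (default 20131121).
#' @param n_out sample points per trajectory checked against the bounds.
#' @return logical: TRUE iff all starts stayed in (the closure of) `D`.
#' @export
check_invariance <- function(params, n_starts = 20L, t_end = 500,
                             seed = 20131121, n_out = 501L) {
  stopifnot(inherits(params, "sirs_params"))
  N0 <- compute_N0(params)
  eps <- 1e-8 * N0
  starts <- random_starts(params, n_starts, seed)
  for (i in seq_len(n_starts)) {
    tr <- tryCatch(
      integrate_sirs(params, starts[i, ], variant = "reduced",
                     t_end = t_end, n_out = n_out),
      error = function(e) NULL)
    if (is.null(tr)) return(FALSE)
    if (any(tr$I <= -eps) || any(tr$R <= -eps) || any(tr$I + tr$R >= N0 + eps))
      return(FALSE)
  }
  TRUE
}

#' Seeded uniform starting points inside D
#'
#' @param params a [sirs_params()] object.
#' @param n number of points.
#' @param seed RNG seed.
#' @return an `n` x 2 matrix with columns `I`, `R`, every row in `D`.
#' @export
random_starts <- function(params, n, seed = 20131121) {
  N0 <- compute_N0(params)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  I <- stats::runif(n, min = 1e-6 * N0, max = N0 * (1 - 1e-6))
  R <- stats::runif(n, min = 1e-6 * N0, max = N0 - I)
  cbind(I = I, R = R)
}
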