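# Independent numerical oracles used across the suite. These deliberately do
# NOT reuse the package's closed forms: Jacobians come from central
# differences of the field, roots from sign scans, divergences from
# differentiating the multiplied field directly.

param_names_for_tests <- function() {
  c("A", "d", "beta", "m", "gamma", "alpha", "p", "k")
}

# the parameter set bundled as inst/extdata/bifurcation_example.yaml,
# constructed in code so fixture and tests cannot drift apart silently
example_params_manual <- function() {
  sirs_params(A = 4.4236, d = 0.1, beta = 0.01, m = 0.1,
              gamma = 0.1, alpha = 0.3995, p = 0.01, k = 0.1)
}

# central-difference Jacobian of a vector field f(state) at x
fd_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- pmax(1e-6, 1e-7 * abs(x))
  J <- matrix(NA_real_, length(f(x)), n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}

# roots of the equilibrium cubic in (0, N0) by sign scan + uniroot refinement
grid_scan_roots <- function(coeffs, N0, n_grid = 20001L) {
  I <- seq(1e-9, N0, length.out = n_grid)
  fv <- eval_cubic(coeffs, I)
  idx <- which(fv[-n_grid] * fv[-1] < 0)
  vapply(idx, function(i)
    stats::uniroot(function(x) eval_cubic(coeffs, x),
                   lower = I[i], upper = I[i + 1], tol = 1e-13)$root,
    numeric(1))
}

# numerical divergence of the Dulac-multiplied reduced field; five-point
# stencils (O(h^4)) keep truncation below round-off even where the 1/I terms
# make the field steep
fd_dulac_divergence <- function(state, params, h_rel = 1e-4) {
  I0 <- state[[1]]; R0v <- state[[2]]
  mul <- function(I, R) {
    f <- rhs_reduced(c(I, R), params)
    D <- (1 + params$alpha * I^2) / I
    c(D * f[["dI"]], D * f[["dR"]])
  }
  hI <- h_rel * min(max(1e-3, abs(I0)), abs(I0) / 2)
  hR <- h_rel * max(1, abs(R0v))
  d5 <- function(fm2, fm1, fp1, fp2, h) (fm2 - 8 * fm1 + 8 * fp1 - fp2) / (12 * h)
  d5(mul(I0 - 2 * hI, R0v)[1], mul(I0 - hI, R0v)[1],
     mul(I0 + hI, R0v)[1], mul(I0 + 2 * hI, R0v)[1], hI) +
    d5(mul(I0, R0v - 2 * hR)[2], mul(I0, R0v - hR)[2],
       mul(I0, R0v + hR)[2], mul(I0, R0v + 2 * hR)[2], hR)
}

# max distance from points `pts` to the polyline through `line` (rows);
# used for orbit comparison after the two time parametrizations diverge
dist_to_polyline <- function(pts, line) {
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  max(apply(pts, 1, function(p) {
    ap <- sweep(a, 2, p, "-")
    tt <- pmin(1, pmax(0, -(ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) / len2))
    dx <- ap[, 1] + tt * ab[, 1]; dy <- ap[, 2] + tt * ab[, 2]
    sqrt(min(dx^2 + dy^2))
  }))
}
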