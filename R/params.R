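#' Construct and validate a model parameter set
#'
#' Bundles the eight positive constants of the SIRS model with saturated
#' incidence \eqn{\beta S I/(1+\alpha I^2)} and constant treatment capacity
#' \eqn{k}: recruitment `A` (split `(1-p)A` susceptible, `pA` infective),
#' natural death rate `d`, transmission constant `beta`, recovery rate `m`,
#' immunity-loss rate `gamma`, incidence-inhibition parameter `alpha`
#' (1/individuals^2), infective recruitment fraction `p` (strictly inside
#' (0,1)), and treatment constant `k` (individuals/time).
#'
#' Derived quantities are never stored: use [compute_N0()] (carrying capacity
#' `A/d`), [compute_R0()] (treatment-to-inflow threshold `k/(pA)`) and
#' [compute_pA()].
#'
#' @param A recruitment rate (individuals/time), > 0.
#' @param d natural death rate (1/time), > 0.
#' @param beta transmission proportionality constant, > 0.
#' @param m recovery rate (1/time), > 0.
#' @param gamma rate of immunity loss (1/time), > 0.
#' @param alpha inhibition parameter (1/individuals^2), > 0.
#' @param p fraction of recruitment entering the infective class, in (0,1).
#' @param k constant treatment capacity (individuals/time), > 0.
#'
#' @return An object of class `sirs_params` (a named list of the eight
#'   primitive fields).
#' @examples
#' pr <- sirs_params(A = 4.4236, d = 0.1, beta = 0.01, m = 0.1,
#'                   gamma = 0.1, alpha = 0.3995, p = 0.01, k = 0.1)
#' compute_R0(pr)
#' @export
sirs_params <- function(A, d, beta, m, gamma, alpha, p, k) {
  fields <- list(A = A, d = d, beta = beta, m = m,
                 gamma = gamma, alpha = alpha, p = p, k = k)
  validate_sirs_params(fields)
  structure(fields, class = "sirs_params")
}

param_names <- function() c("A", "d", "beta", "m", "gamma", "alpha", "p", "k")

validate_sirs_params <- function(x) {
  missing <- setdiff(param_names(), names(x))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (nm in param_names()) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  # endpoints excluded: the model has positive recruitment into BOTH classes
  if (x$p >= 1)
    stop("parameter 'p' must lie strictly inside (0, 1) (got ", x$p, ")",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sirs_params <- function(x, ...) {
  cat("SIRS model parameters (saturated incidence + constant treatment)\n")
  vals <- unlist(x[param_names()])
  cat(paste0("  ", format(param_names(), width = 6), " = ",
             format(vals, digits = 7), collapse = "\n"), "\n")
  cat(sprintf("  derived: N0 = A/d = %.6g, R0 = k/(pA) = %.6g\n",
              compute_N0(x), compute_R0(x)))
  invisible(x)
}

#' Asymptotic total population size
#'
#' Total population obeys \eqn{N' = A - dN}, so \eqn{N \to N_0 = A/d}.
#'
#' @param params a [sirs_params()] object.
#' @return `A/d` (individuals).
#' @export
compute_N0 <- function(params) {
  stopifnot(inherits(params, "sirs_params"))
  params$A / params$d
}

#' Treatment-capacity threshold R0 = k/(pA)
#'
#' The ratio of the constant treatment capacity `k` to the constant inflow of
#' infectives `pA`. It governs the equilibrium structure of the reduced model:
#' for `R0 < 1` there is a unique endemic equilibrium (globally stable); for
#' `R0 > 1` the constant term of the equilibrium cubic changes sign and zero,
#' one or two endemic equilibria may remain in the feasible region. Note this
#' is *not* the classical basic reproduction number.
#'
#' @param params a [sirs_params()] object.
#' @return dimensionless threshold `k/(p*A)`.
#' @export
compute_R0 <- function(params) {
  stopifnot(inherits(params, "sirs_params"))
  params$k / (params$p * params$A)
}

#' Constant inflow of infectives
#' @param params a [sirs_params()] object.
#' @return `p*A` (individuals/time).
#' @export
compute_pA <- function(params) {
  stopifnot(inherits(params, "sirs_params"))
  params$p * params$A
}

# parameter vector in the fixed order used by the C++ integrator
params_vector <- function(params) {
  unlist(params[param_names()], use.names = FALSE)
}

#' Bundled bifurcation example parameter set
#'
#' The parameter set shipped in `inst/extdata/bifurcation_example.yaml`
#' (`A = 4.4236`, `d = k = gamma = 0.1`, `beta = 0.01`, `m = 0.1`,
#' `alpha = 0.3995`, `p = 0.01`). It has `R0 = 2.2606` and two endemic
#' equilibria, `E1 = (0.25, 0.625)` and `E2 = (1.3505, 1.1752)`. The trace of
#' the Jacobian at `E1` was tuned (via `A`) to vanish, but `det J(E1) < 0`,
#' so `E1` is a hyperbolic saddle and the set carries no periodic orbit; see
#' the package vignette for the full analysis.
#'
#' @return a [sirs_params()] object.
#' @seealso [cycle_example_params()] for a set with a genuine unstable cycle.
#' @export
example_params <- function() {
  load_config(system.file("extdata", "bifurcation_example.yaml",
                          package = "treatSIRS"))
}

#' Synthetic parameter set with a genuine unstable limit cycle
#'
#' A parameter set constructed by numerical search (it does not come from any
#' published table, hence "synthetic"): the larger endemic equilibrium
#' undergoes a genuine subcritical Hopf bifurcation at `gamma ~ 0.0539`
#' (trace zero with positive determinant, first Lyapunov coefficient
#' `+0.314`). At the shipped `gamma = 0.058` the focus is stable and is
#' encircled by an unstable limit cycle of period about 1.225 time units,
#' detectable with [find_unstable_cycle()].
#'
#' @return a [sirs_params()] object.
#' @export
cycle_example_params <- function() {
  sirs_params(A = 2.88, d = 0.0108, beta = 2.82, m = 8.83,
              gamma = 0.058, alpha = 0.00102, p = 0.916, k = 6.59)
}
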