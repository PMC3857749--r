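#' Constant-capacity treatment function
#'
#' \eqn{h(I) = k} for `I > 0` and `0` for `I = 0`: a community treats at its
#' full constant capacity whenever any infectives are present.
#'
#' @param I number of infectives, >= 0 (vectorized).
#' @param k treatment capacity, > 0.
#' @return `k` where `I > 0`, `0` where `I == 0`.
#' @export
treatment <- function(I, k) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("treatment(): I must be finite and non-negative", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("treatment(): k must be a single positive number", call. = FALSE)
  ifelse(I > 0, k, 0)
}

as_state2 <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (length(state) != 2L || any(!is.finite(state)))
    stop("state must be two finite numbers (I, R)", call. = FALSE)
  stats::setNames(as.numeric(state), c("I", "R"))
}

#' Right-hand side of the reduced planar system
#'
#' On the invariant plane `S = N0 - I - R` the model reduces to
#' \deqn{I' = pA - k + \beta I (N_0 - I - R)/(1+\alpha I^2) - (d+m) I,}
#' \deqn{R' = mI - (d+\gamma)R + k.}
#' Treatment is fixed at `k` because the feasible region `D` excludes `I = 0`.
#'
#' @param state numeric `(I, R)`.
#' @param params a [sirs_params()] object.
#' @return named numeric `(dI, dR)`.
#' @export
rhs_reduced <- function(state, params) {
  stopifnot(inherits(params, "sirs_params"))
  s <- as_state2(state)
  I <- s[["I"]]; R <- s[["R"]]
  pA <- compute_pA(params); N0 <- compute_N0(params)
  q <- 1 + params$alpha * I^2
  c(dI = pA - params$k + params$beta * I * (N0 - I - R) / q -
        (params$d + params$m) * I,
    dR = params$m * I - (params$d + params$gamma) * R + params$k)
}

#' Right-hand side of the rescaled planar system
#'
#' The reduced field multiplied by the positive factor \eqn{1+\alpha I^2}
#' (orbital equivalence: same orbits and equilibria, reparametrized time):
#' \deqn{I' = \beta I (N_0-I-R) - (d+m) I (1+\alpha I^2) + (1-R_0) pA (1+\alpha I^2),}
#' \deqn{R' = [mI - (d+\gamma)R + pA R_0](1+\alpha I^2),}
#' using \eqn{pA R_0 = k}.
#'
#' @inheritParams rhs_reduced
#' @return named numeric `(dI, dR)`.
#' @export
rhs_rescaled <- function(state, params) {
  stopifnot(inherits(params, "sirs_params"))
  s <- as_state2(state)
  I <- s[["I"]]; R <- s[["R"]]
  pA <- compute_pA(params); N0 <- compute_N0(params)
  R0 <- compute_R0(params)
  q <- 1 + params$alpha * I^2
  c(dI = params$beta * I * (N0 - I - R) -
        (params$d + params$m) * I * q + (1 - R0) * pA * q,
    dR = (params$m * I - (params$d + params$gamma) * R + pA * R0) * q)
}

#' Right-hand side of the full three-compartment system
#'
#' \deqn{S' = (1-p)A - \beta I S/(1+\alpha I^2) - dS + \gamma R,}
#' \deqn{I' = pA + \beta I S/(1+\alpha I^2) - (d+m) I - h(I),}
#' \deqn{R' = mI - (d+\gamma)R + h(I),}
#' with the branched treatment function [treatment()]. The derivatives sum to
#' \eqn{A - d(S+I+R)} identically.
#'
#' @param state numeric `(S, I, R)`, each >= 0.
#' @param params a [sirs_params()] object.
#' @return named numeric `(dS, dI, dR)`.
#' @export
rhs_full <- function(state, params) {
  stopifnot(inherits(params, "sirs_params"))
  if (is.list(state)) state <- unlist(state)
  if (length(state) != 3L || any(!is.finite(state)) || any(state < 0))
    stop("state must be three finite non-negative numbers (S, I, R)",
         call. = FALSE)
  S <- state[[1]]; I <- state[[2]]; R <- state[[3]]
  h <- treatment(I, params$k)
  inc <- params$beta * I * S / (1 + params$alpha * I^2)
  c(dS = (1 - params$p) * params$A - inc - params$d * S + params$gamma * R,
    dI = params$p * params$A + inc - (params$d + params$m) * I - h,
    dR = params$m * I - (params$d + params$gamma) * R + h)
}

#' Membership in the feasible region D
#'
#' `D = {(I, R): I > 0, R > 0, I + R < N0}`. A small slack (default
#' `1e-12 * max(1, N0)`) keeps boundary-grazing round-off from flipping the
#' verdict.
#'
#' @inheritParams rhs_reduced
#' @param slack absolute tolerance applied to the three strict inequalities.
#' @return logical.
#' @export
in_domain <- function(state, params, slack = NULL) {
  s <- as_state2(state)
  N0 <- compute_N0(params)
  if (is.null(slack)) slack <- 1e-12 * max(1, N0)
  s[["I"]] > -slack && s[["R"]] > -slack && s[["I"]] + s[["R"]] < N0 + slack
}
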