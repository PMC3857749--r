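#' Random valid parameter sets in a prescribed R0 regime
#'
#' Draws each rate (`A, d, beta, m, gamma, alpha`) log-uniformly from
#' `[1e-3, 10]` and `p` uniformly inside `(0, 1)`, discards draws with
#' `N0 = A/d > 1e4`, then resamples `k` (log-uniform on the same range) until
#' the requested regime holds (`R0 < 1` or `R0 > 1`). Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param regime `"R0_below_1"` or `"R0_above_1"`.
#' @param seed RNG seed (default 20131121).
#' @param n number of parameter sets (>= 1).
#' @return a list of `n` [sirs_params()] objects.
#' @export
random_params <- function(regime = c("R0_below_1", "R0_above_1"),
                          seed = 20131121, n = 1L) {
  regime <- match.arg(regime)
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lo <- log(1e-3); hi <- log(10)
  draw_rate <- function() exp(stats::runif(1, lo, hi))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      A <- draw_rate(); d <- draw_rate()
      if (A / d > 1e4) next
      beta <- draw_rate(); m <- draw_rate(); gamma <- draw_rate()
      alpha <- draw_rate()
      p <- stats::runif(1, 0.005, 0.995)
      k <- NA_real_
      for (try in 1:1000) {
        kk <- draw_rate()
        R0 <- kk / (p * A)
        if ((regime == "R0_below_1" && R0 < 1) ||
            (regime == "R0_above_1" && R0 > 1)) { k <- kk; break }
      }
      if (is.na(k)) next
      out[[i]] <- sirs_params(A = A, d = d, beta = beta, m = m, gamma = gamma,
                              alpha = alpha, p = p, k = k)
      break
    }
  }
  out
}
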