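test_that("full-system total population follows the closed form exactly", {
  pr <- example_params_manual()
  N0 <- compute_N0(pr)
  for (start in list(c(10, 2, 3), c(50, 10, 20), c(30, 5, 5))) {
    tr <- integrate_sirs(pr, start, variant = "full", t_end = 200,
                         n_out = 101)
    N <- tr$S + tr$I + tr$R
    Nexact <- N0 + (sum(start) - N0) * exp(-pr$d * tr$t)
    expect_lt(max(abs(N - Nexact) / Nexact), 1e-6)
  }
})

test_that("full system reports step collapse at the I = 0 treatment switch", {
  # with R0 > 1 the constant-treatment branch makes I = 0 a Filippov sliding
  # boundary of the full system; orbits that reach it cannot be continued by
  # a smooth integrator and the failure is explicit
  pr <- example_params_manual()
  expect_error(
    integrate_sirs(pr, c(0.5, 0.1, 0.2), variant = "full", t_end = 200,
                   n_out = 101),
    "step size collapsed")
})

test_that("reduced and rescaled variants trace the same curve in (I, R)", {
  pr <- example_params_manual()
  tr1 <- integrate_sirs(pr, c(2, 1), t_end = 100, n_out = 4001)
  tr2 <- integrate_sirs(pr, c(2, 1), variant = "rescaled", t_end = 100,
                        n_out = 4001)
  A <- cbind(tr1$I, tr1$R); B <- cbind(tr2$I, tr2$R)
  # symmetric polyline distance (time parametrizations differ, orbits agree)
  expect_lt(max(dist_to_polyline(A[seq(1, 4001, 40), ], B),
                dist_to_polyline(B[seq(1, 4001, 40), ], A)), 1e-4)
})

test_that("forward-then-backward integration returns to the start", {
  pr <- example_params_manual()
  start <- c(2, 1)
  tr <- integrate_sirs(pr, start, t_end = 10, n_out = 11,
                       rtol = 1e-11, atol = 1e-13)
  end <- c(tr$I[11], tr$R[11])
  back <- integrate_sirs(pr, end, t_end = 10, n_out = 11,
                         direction = "backward", rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(c(back$I[11], back$R[11]) - start)), 1e-6)
})

test_that("trajectory object: monotone times, attributes, D-invariance for R0<1", {
  pr <- random_params("R0_below_1", seed = 131, n = 1)[[1]]
  st <- random_starts(pr, 1, seed = 4)[1, ]
  tr <- integrate_sirs(pr, st, t_end = 300, n_out = 601)
  expect_s3_class(tr, "sirs_trajectory")
  expect_true(all(diff(tr$t) > 0))
  expect_identical(attr(tr, "variant"), "reduced")
  N0 <- compute_N0(pr)
  expect_true(all(tr$I > -1e-8 * N0 & tr$R > -1e-8 * N0 &
                    tr$I + tr$R < N0 * (1 + 1e-8)))
  expect_error(integrate_sirs(pr, c(1, 2, 3), t_end = 1), "length 2")
  expect_error(integrate_sirs(pr, c(1, 2), t_end = -1), "positive")
})

test_that("check_invariance: TRUE for R0 < 1, FALSE for the example set (R0 > 1)", {
  sets <- random_params("R0_below_1", seed = 141, n = 3)
  for (pr in sets)
    expect_true(check_invariance(pr, n_starts = 10L, t_end = 300))
  # R0 > 1 has I' < 0 along I = 0+: orbits below the saddle's stable
  # manifold exit D, so invariance genuinely fails for the example set
  expect_false(check_invariance(example_params_manual(),
                                n_starts = 20L, t_end = 500))
})

test_that("unstable cycle on the synthetic set: detection, geometry, stability sides", {
  pr <- cycle_example_params()
  eqs <- endemic_equilibria(pr)
  expect_identical(length(eqs), 2L)
  focus <- eqs[[2]]
  expect_identical(classify_local(jacobian_reduced(focus, pr)),
                   "stable_focus")
  cyc <- find_unstable_cycle(pr, focus)
  expect_true(cyc$found)
  expect_lt(cyc$return_map_residual, 1e-7)
  expect_identical(cyc$winding_number, 1L)
  expect_equal(cyc$period, 1.2253, tolerance = 1e-3)
  expect_gt(cyc$amplitude_I, 1)

  # geometric convergence of the return map in backward time
  resid <- abs(diff(cyc$crossings))
  resid <- resid[resid > 0]
  if (length(resid) >= 3) {
    ratios <- resid[-1] / resid[-length(resid)]
    expect_lt(stats::median(ratios), 1)
  }

  # tolerance robustness: halving rtol/atol moves the period < 1e-4 relative
  cyc2 <- find_unstable_cycle(pr, focus, rtol = 5e-10, atol = 5e-13)
  expect_lt(abs(cyc2$period - cyc$period) / cyc$period, 1e-4)

  # forward orbit from just inside the cycle spirals toward the focus
  inside <- focus + 0.8 * (cyc$section_point - focus)
  trin <- integrate_sirs(pr, inside, variant = "rescaled", t_end = 60,
                         n_out = 1201)
  d_in <- sqrt((trin$I - focus[["I"]])^2 + (trin$R - focus[["R"]])^2)
  expect_lt(tail(d_in, 1), 0.2 * d_in[1])

  # forward orbit from just outside leaves the cycle's neighborhood (and may
  # blow up in finite time once far from D, so probe in short chunks)
  outside <- focus + 1.1 * (cyc$section_point - focus)
  amp0 <- sqrt(sum((outside - focus)^2))
  state <- outside; dmax <- 0; blew_up <- FALSE
  for (chunk in 1:40) {
    trout <- tryCatch(
      integrate_sirs(pr, state, variant = "rescaled", t_end = 0.25,
                     n_out = 26),
      error = function(e) NULL)
    if (is.null(trout)) { blew_up <- TRUE; break }
    d_out <- sqrt((trout$I - focus[["I"]])^2 + (trout$R - focus[["R"]])^2)
    dmax <- max(dmax, max(d_out))
    if (dmax > 3 * amp0) break
    state <- c(trout$I[26], trout$R[26])
  }
  expect_true(blew_up || dmax > 3 * amp0)
})

test_that("cycle search reports honest failure modes", {
  # the bundled example set has no periodic orbit at all (E1 is a saddle);
  # the backward orbit leaves D and the report says so
  pr <- example_params_manual()
  E1 <- endemic_equilibria(pr)[[1]]
  cyc <- find_unstable_cycle(pr, E1)
  expect_false(cyc$found)
  expect_match(cyc$diagnostic, "left D|converge|collapsed")
  # start outside D rejected up front
  pc <- cycle_example_params()
  focus <- endemic_equilibria(pc)[[2]]
  cyc2 <- find_unstable_cycle(pc, focus,
                              displacement = c(compute_N0(pc), 0))
  expect_false(cyc2$found)
  expect_match(cyc2$diagnostic, "outside D")
})

test_that("random_starts are seeded, reproducible and inside D", {
  pr <- example_params_manual()
  a <- random_starts(pr, 50, seed = 9)
  b <- random_starts(pr, 50, seed = 9)
  expect_identical(a, b)
  N0 <- compute_N0(pr)
  expect_true(all(a[, 1] > 0 & a[, 2] > 0 & rowSums(a) < N0))
})
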