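test_that("evolve honors trivial and closed-form cases", {
  pre <- preset3()
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, pre$system, pre$exchange)
  rho <- initialState(pre)
  expect_identical(evolve(rho, gen, 0), rho)
  expect_error(evolve(rho, gen, -1), "non-negative")
  # quarter Rabi period on an isolated carbon: <Sz> passes through zero
  sysC <- spinSystem(list(spinSpec("C1", "13C")))
  HC <- rotatingFrameHamiltonian(sysC, couplingNetwork(sysC), 121,
                                 driveSpec("13C", 10, 0))
  genC <- buildGenerator(HC, sysC, NULL)
  alpha <- matrix(c(1, 0, 0, 0), 2, 2) + 0i
  out <- evolve(alpha, genC, 0.025)
  expect_equal(polarization(out, sysC, "C1", "z"), 0, tolerance = 1e-10)
  # full Rabi period returns to +z
  out2 <- evolve(alpha, genC, 0.1)
  expect_equal(polarization(out2, sysC, "C1", "z"), 1, tolerance = 1e-9)
})

test_that("matching amplitude outperforms a detuned amplitude", {
  pre <- preset3()
  rho <- initialState(pre)
  pol_at_amp <- function(amp) {
    H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut,
                                  driveSpec("13C", amp, 0))
    out <- evolve(rho, buildGenerator(H, pre$system, pre$exchange), 10,
                  method = "superop")
    abs(polarization(out, pre$system, "C1", "x"))
  }
  expect_gt(pol_at_amp(10.5), pol_at_amp(20))
})

test_that("propagation paths agree to high accuracy on the 3-spin model", {
  pre <- preset3()
  drv <- driveSpec("13C", 9, 3)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, pre$system, pre$exchange)
  rho <- initialState(pre)
  r_dense <- evolve(rho, gen, 1.3, method = "superop")
  r_krylov <- evolve(rho, gen, 1.3, method = "krylov")
  expect_lt(maxAbsDiff(r_dense, r_krylov), 1e-9)
  r_split <- evolve(rho, gen, 1.3, method = "split", dt = 1e-4)
  expect_lt(maxAbsDiff(r_dense, r_split), 1e-7)
})

test_that("time-independent flows satisfy the semigroup property", {
  pre <- preset3()
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, pre$system, pre$exchange)
  rho <- initialState(pre)
  one_shot <- evolve(rho, gen, 1.0, method = "krylov")
  two_step <- evolve(evolve(rho, gen, 0.3, method = "krylov"), gen, 0.7,
                     method = "krylov")
  expect_lt(maxAbsDiff(one_shot, two_step), 1e-8)
  # coherent-only path is a single exact rotation for any t
  gen0 <- buildGenerator(H, pre$system, NULL)
  a <- evolve(rho, gen0, 2.13)
  b <- evolve(evolve(rho, gen0, 1.4), gen0, 0.73)
  expect_lt(maxAbsDiff(a, b), 1e-11)
})

test_that("timeseries reuses the state and keeps the trace", {
  pre <- preset3()
  sys <- pre$system
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(sys, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, sys, pre$exchange)
  rho <- initialState(pre)
  times <- seq(0.5, 40, by = 2)
  curve <- evolveTimeseries(rho, gen, times,
                            function(r) polarization(r, sys, "C1", "x"),
                            method = "krylov")
  expect_s3_class(curve, "buildUpCurve")
  expect_equal(nrow(curve), length(times))
  expect_true(all(abs(attr(curve, "state_traces") - 1) < 1e-8))
  # build-up envelope: |x| grows to its plateau with at most small ripples
  v <- abs(curve$value)
  plateau <- max(v)
  running_max <- cummax(v)
  expect_true(all(v >= running_max - 0.05 * plateau))
  # a state commuting with a drive-free, exchange-free H stays constant
  Hfree <- labHamiltonian(sys, pre$couplings, pre$b0_ut)
  genfree <- buildGenerator(Hfree, sys, NULL)
  mix <- mixedDensity(sys)
  c2 <- evolveTimeseries(mix, genfree, c(1, 2, 5),
                         function(r) polarization(r, sys, "C1", "z"))
  expect_equal(c2$value, rep(0, 3), tolerance = 1e-12)
  expect_error(evolveTimeseries(rho, gen, numeric(0), length), "empty")
  expect_error(evolveTimeseries(rho, gen, c(2, 1), length), "increasing")
})

test_that("complex matrix exponential matches series and eigen references", {
  set.seed(11)
  A <- matrix(stats::rnorm(36) + 1i * stats::rnorm(36), 6, 6)
  E <- expmComplex(A)
  # reference by scaling the exact 1x1-free series: eigen route for a
  # diagonalizable random matrix
  eg <- eigen(A)
  Eref <- eg$vectors %*% diag(exp(eg$values)) %*% solve(eg$vectors)
  expect_lt(maxAbsDiff(E, Eref), 1e-10 * max(abs(Eref)))
  # group property exp(A) exp(-A) = I
  expect_lt(maxAbsDiff(E %*% expmComplex(-A), diag(6)), 1e-10)
})
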