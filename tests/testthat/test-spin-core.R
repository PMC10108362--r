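test_that("embedded spin operators obey the spin-1/2 algebra", {
  pre <- preset6()
  sys <- pre$system
  for (lab in c("Ha", "M2", "C1")) {
    Ix <- spinOperator(sys, lab, "x")
    Iy <- spinOperator(sys, lab, "y")
    Iz <- spinOperator(sys, lab, "z")
    expect_lt(maxAbsDiff(Ix %*% Iy - Iy %*% Ix, 1i * Iz), 1e-12)
    expect_lt(abs(sum(diag(Iz))), 1e-12)
    # Tr(Iz^2) = 2^(N-2)
    expect_equal(Re(sum(diag(Iz %*% Iz))), sys$dim / 4, tolerance = 1e-12)
  }
  expect_error(spinOperator(sys, "nope", "z"), "unknown spin label")
})

test_that("operators on distinct spins commute", {
  sys <- preset3()$system
  pairs <- list(c("Ha", "Hb"), c("Ha", "C1"), c("Hb", "C1"))
  for (p in pairs) {
    for (ax1 in c("x", "y", "z")) {
      for (ax2 in c("x", "z")) {
        A <- spinOperator(sys, p[1], ax1)
        B <- spinOperator(sys, p[2], ax2)
        expect_lt(maxAbsDiff(A %*% B, B %*% A), 1e-13)
      }
    }
  }
})

test_that("singlet density has singlet correlations and no net polarization", {
  pre <- preset6()
  rho <- singletDensity(pre$system, c("Ha", "Hb"))
  expect_no_error(assertDensity(rho))
  expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-12)
  dot12 <- dotCouplingOperator(pre$system, "Ha", "Hb")
  expect_equal(expectation(rho, dot12), -0.75, tolerance = 1e-12)
  for (lab in c("Ha", "Hb")) {
    expect_equal(polarization(rho, pre$system, lab, "z"), 0,
                 tolerance = 1e-12)
  }
  expect_error(singletDensity(pre$system, c("Ha", "Ha")), "distinct")
})

test_that("partial trace recovers factors, reduces singlets, keeps trace", {
  pre <- preset3()
  sys <- pre$system
  # product state: explicit factor recovery
  pA <- matrix(c(0.7, 0.1 + 0.05i, 0.1 - 0.05i, 0.3), 2, 2)
  rest <- diag(4) / 4
  rho <- embedDensity(sys, list(list(labels = "C1", state = pA),
                                list(labels = c("Ha", "Hb"), state = rest)))
  expect_lt(maxAbsDiff(partialTrace(rho, sys, "C1"), pA), 1e-13)
  # singlet pair traces to a maximally mixed single spin
  rho_s <- singletDensity(sys, c("Ha", "Hb"))
  red <- partialTrace(rho_s, sys, "Ha")
  expect_lt(maxAbsDiff(red, diag(2) / 2), 1e-13)
  # trace preservation
  expect_equal(Re(sum(diag(partialTrace(rho_s, sys, c("Ha", "C1"))))), 1,
               tolerance = 1e-12)
  expect_error(partialTrace(rho_s, sys, character()), "non-empty")
})

test_that("singlet preparation and hydride-pair reduction are consistent", {
  pre <- preset6()
  sys <- pre$system
  rho <- singletDensity(sys, c("Ha", "Hb"))
  pair <- partialTrace(rho, sys, c("Ha", "Hb"))
  expect_lt(maxAbsDiff(pair, singletProjector2()), 1e-13)
  # re-preparing from the reduction is idempotent
  rho2 <- singletDensity(sys, c("Ha", "Hb"),
                         rest_state = partialTrace(rho, sys,
                                                   c("M1", "M2", "M3", "C1")))
  expect_lt(maxAbsDiff(rho, rho2), 1e-13)
})

test_that("the pyruvate preset carries the published parameterization", {
  pre <- preset6()
  J <- unclass(pre$couplings)
  expect_equal(J["Ha", "Hb"], -10.5)
  expect_equal(J["Ha", "C1"], 0.06)
  expect_equal(J["Hb", "C1"], 0)
  expect_equal(unname(J["C1", c("M1", "M2", "M3")]), rep(1.2, 3))
  expect_equal(pre$exchange$tau_ir_s, 0.031)
  expect_equal(pre$b0_ut, 121)
  expect_equal(pre$system$n_spins, 6L)
  expect_equal(pre$system$dim, 64L)
  shifts <- vapply(pre$system$spins, `[[`, numeric(1), "shift_ppm")
  names(shifts) <- pre$system$labels
  expect_equal(unname(shifts["Hb"] - shifts["Ha"]), 2)
  # reduced fixture keeps the transfer-relevant couplings
  p3 <- preset3()
  expect_equal(p3$system$n_spins, 3L)
  expect_equal(unclass(p3$couplings)["Ha", "Hb"], -10.5)
})

test_that("preset round-trips through the config representation", {
  pre <- preset6()
  cfg <- presetToConfig(pre)
  expect_setequal(names(cfg), c("spins", "couplings_hz", "tau_ir_s", "b0_ut"))
  path <- tempfile(fileext = ".yaml")
  saveConfig(cfg, path)
  back <- loadConfig(path)
  expect_equal(unclass(back$preset$couplings), unclass(pre$couplings))
  expect_equal(back$preset$exchange$tau_ir_s, pre$exchange$tau_ir_s)
  expect_equal(back$preset$b0_ut, pre$b0_ut)
  expect_equal(back$preset$system$labels, pre$system$labels)
  unlink(path)
})
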