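test_that("replacement map resets the hydride pair to the feed state", {
  pre <- preset6()
  sys <- pre$system
  model <- pre$exchange
  # start from an arbitrary correlated valid state
  H <- labHamiltonian(sys, pre$couplings, pre$b0_ut)
  rho <- evolve(initialState(pre),
                buildGenerator(H, sys, NULL), 0.013)
  out <- replacementMap(rho, sys, model)
  expect_lt(maxAbsDiff(partialTrace(out, sys, model$labels), model$fed),
            1e-12)
  # idempotence and trace preservation
  expect_lt(maxAbsDiff(replacementMap(out, sys, model), out), 1e-12)
  expect_equal(Re(sum(diag(out))), Re(sum(diag(rho))), tolerance = 1e-12)
  # substrate part is untouched
  keep <- setdiff(sys$labels, model$labels)
  expect_lt(maxAbsDiff(partialTrace(out, sys, keep),
                       partialTrace(rho, sys, keep)), 1e-12)
  bad <- exchangeModel(0.031, c("Qx", "Qy"))
  expect_error(replacementMap(rho, sys, bad), "missing")
})

test_that("fed-state parameterization by singlet fraction is physical", {
  m1 <- exchangeModel(0.031, c("Ha", "Hb"), singlet_fraction = 1)
  expect_lt(maxAbsDiff(m1$fed, singletProjector2()), 1e-12)
  m0 <- exchangeModel(0.031, c("Ha", "Hb"), singlet_fraction = 0.25)
  expect_lt(maxAbsDiff(m0$fed, diag(4) / 4), 1e-12)  # f = 1/4 is unpolarized
  expect_error(exchangeModel(-1, c("Ha", "Hb")), "must be > 0")
  expect_error(exchangeModel(0.031, c("Ha", "Hb"), singlet_fraction = 1.2),
               "singlet_fraction")
})

test_that("generator reduces to the pure commutator without exchange", {
  pre <- preset3()
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  rho <- initialState(pre)
  gen_inf <- buildGenerator(H, pre$system, model = NULL)
  lhs <- applyGenerator(gen_inf, rho)
  rhs <- -2i * pi * (H %*% rho - rho %*% H)
  expect_lt(maxAbsDiff(lhs, rhs), 1e-12)
  # very long lifetime approaches the same limit
  gen_slow <- buildGenerator(H, pre$system,
                             exchangeModel(1e12, c("Ha", "Hb")))
  expect_lt(maxAbsDiff(applyGenerator(gen_slow, rho), rhs), 1e-9)
})

test_that("exchange refills the singlet with the closed-form saturation law", {
  # H = 0: d rho/dt = (M(rho) - rho)/tau has the explicit solution
  # rho(t) = e^{-t/tau} rho0 + (1 - e^{-t/tau}) M(rho0); starting from
  # triplet |T+> the hydride singlet population after t = tau is 1 - 1/e
  pre <- preset3()
  sys <- pre$system
  tplus <- c(1, 0, 0, 0)  # |alpha alpha> on the pair
  rho0 <- embedDensity(sys, list(
    list(labels = c("Ha", "Hb"), state = (tplus %o% tplus) + 0i),
    list(labels = "C1", state = diag(2) / 2)))
  H0 <- matrix(0i, sys$dim, sys$dim)
  gen <- buildGenerator(H0, sys, pre$exchange)
  rho_t <- evolve(rho0, gen, pre$exchange$tau_ir_s, method = "superop")
  pair <- partialTrace(rho_t, sys, c("Ha", "Hb"))
  svec <- c(0, 1, -1, 0) / sqrt(2)
  pop <- Re(sum(Conj(svec) * (pair %*% svec)))
  expect_equal(pop, 1 - exp(-1), tolerance = 1e-9)
})

test_that("superoperator matrix has dimension d^2 and matches the action", {
  pre <- preset3()
  drv <- driveSpec("13C", 8, 2)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, pre$system, pre$exchange)
  L <- superoperatorMatrix(gen)
  expect_equal(dim(L), c(64L, 64L))
  rho <- initialState(pre)
  expect_lt(maxAbsDiff(matrix(L %*% as.vector(rho), 8, 8),
                       applyGenerator(gen, rho)), 1e-10)
  # trace annihilation: columns of L sum to zero under the trace functional
  d <- pre$system$dim
  tr_vec <- as.vector(diag(d) + 0i)
  expect_lt(max(abs(Conj(tr_vec) %*% L)), 1e-9)
  # the full 6-spin superoperator would be 4096^2; the dense path refuses it
  pre6 <- preset6()
  H6 <- labHamiltonian(pre6$system, pre6$couplings, pre6$b0_ut)
  expect_error(superoperatorMatrix(buildGenerator(H6, pre6$system,
                                                  pre6$exchange)),
               "d = 64")
})

test_that("equal hydride-carbon couplings give no transfer channel", {
  # when both J_HC are equal the transfer element (their difference over 4)
  # vanishes, so singlet hydrogen generates no 13C order of any kind
  pre <- preset3()
  sys <- pre$system
  J_sym <- couplingNetwork(sys, list(list("Ha", "Hb", -10.5),
                                     list("Ha", "C1", 0.06),
                                     list("Hb", "C1", 0.06)))
  rho <- initialState(pre)
  for (settings in list(c(10.5, 0), c(8.57, 6.06), c(15, -3))) {
    drv <- driveSpec("13C", settings[1], settings[2])
    H <- rotatingFrameHamiltonian(sys, J_sym, pre$b0_ut, drv)
    gen <- buildGenerator(H, sys, pre$exchange)
    out <- evolve(rho, gen, 10, method = "superop")
    expect_lt(abs(polarization(out, sys, "C1", "x")), 1e-9)
    expect_lt(abs(polarization(out, sys, "C1", "y")), 1e-9)
    expect_lt(abs(polarization(crusher(out), sys, "C1", "z")), 1e-9)
  }
})

test_that("generated polarization is linear in the fed singlet excess", {
  pre <- preset3()
  sys <- pre$system
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(sys, pre$couplings, pre$b0_ut, drv)
  rho <- initialState(pre)
  pol_at <- function(f) {
    model <- exchangeModel(0.031, c("Ha", "Hb"), singlet_fraction = f)
    out <- evolve(rho, buildGenerator(H, sys, model), 5, method = "superop")
    polarization(out, sys, "C1", "x")
  }
  p1 <- pol_at(1)
  p075 <- pol_at(0.75)
  p025 <- pol_at(0.25)
  # proportional to (f - 1/4); note the initial state still carries a pure
  # singlet, whose contribution decays within a few tau and is common
  expect_equal(p075 / p1, (0.75 - 0.25) / (1 - 0.25), tolerance = 0.02)
  expect_lt(abs(p025 / p1), 0.02)
})

test_that("states stay trace-one, Hermitian and positive over 10 s", {
  pre <- preset3()
  drv <- driveSpec("13C", 10.5, 0)
  H <- rotatingFrameHamiltonian(pre$system, pre$couplings, pre$b0_ut, drv)
  gen <- buildGenerator(H, pre$system, pre$exchange)
  rho <- initialState(pre)
  for (t in c(0.5, 2, 10)) {
    out <- evolve(rho, gen, t, method = "krylov")
    expect_lt(abs(Re(sum(diag(out))) - 1), 1e-8)
    expect_lt(maxAbsDiff(out, Conj(t(out))), 1e-8)
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})
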