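# State propagation under an evolution generator.
#
# Three propagation paths are provided:
#   * "split"   -- Strang splitting between the coherent flow (exact phase
#                  evolution in the Hamiltonian eigenbasis) and the exchange/
#                  damping flow, whose one-step propagator is available in
#                  closed form because the replacement map is idempotent:
#                  exp(t R) rho = e^{-t/tau} rho + (1 - e^{-t/tau}) M(rho).
#                  Every sub-step is completely positive and exactly
#                  trace-preserving; the splitting error is O(dt^2).
#   * "krylov"  -- Arnoldi approximation of the exact exponential action of
#                  the full generator on vec(rho); matrix-free.
#   * "superop" -- dense matrix exponential of the full superoperator (small
#                  systems only); the independent exact path.

#' Propagate a state for a fixed time
#'
#' @param state Density matrix.
#' @param generator An [buildGenerator()] result.
#' @param t Evolution time in s (>= 0).
#' @param method `"auto"`, `"split"`, `"krylov"` or `"superop"`. `"auto"`
#'   uses the single exact eigenbasis rotation when there is no exchange or
#'   damping, the dense superoperator exponential for Hilbert dimension
#'   <= 8, and split-step propagation otherwise.
#' @param dt Split-step size in s (default 1e-3).
#' @param tol Krylov truncation tolerance.
#' @return The propagated density matrix.
#' @export
evolve <- function(state, generator, t,
                   method = c("auto", "split", "krylov", "superop"),
                   dt = 1e-3, tol = 1e-10) {
  method <- match.arg(method)
  if (!is.finite(t) || t < 0) stop("t must be non-negative")
  if (t == 0) return(state)
  dissipative <- !is.null(generator$model) || generator$damping_rate > 0
  if (method == "auto") {
    method <- if (!dissipative) "split"            # single exact rotation
              else if (generator$dim <= 8) "superop"
              else "krylov"
  }
  switch(method,
         split   = evolveSplit(state, generator, t, dt),
         krylov  = evolveKrylov(state, generator, t, tol),
         superop = evolveSuperop(state, generator, t))
}

evolveSplit <- function(state, generator, t, dt) {
  V <- generator$evectors
  Vh <- Conj(t(V))
  lam <- generator$evalues
  dissipative <- !is.null(generator$model) || generator$damping_rate > 0
  if (!dissipative) {
    # coherent flow is exact in one step for any t
    phase <- exp(-2i * pi * lam * t)
    sig <- Vh %*% state %*% V
    sig <- sig * (phase %o% Conj(phase))
    return(V %*% sig %*% Vh)
  }
  nfull <- floor(t / dt + 1e-9)
  rem <- t - nfull * dt
  steps <- c(rep(dt, nfull), if (rem > 1e-12) rem)
  rho <- state
  last_h <- -1
  Ph <- NULL
  for (h in steps) {
    if (h != last_h) {
      ph <- exp(-2i * pi * lam * (h / 2))
      Ph <- ph %o% Conj(ph)
      if (!is.null(generator$model)) {
        a_ex <- exp(-h / generator$model$tau_ir_s)
      }
      if (generator$damping_rate > 0) {
        a_dmp <- exp(-h * generator$damping_rate)
      }
      last_h <- h
    }
    sig <- (Vh %*% rho %*% V) * Ph
    rho <- V %*% sig %*% Vh
    if (!is.null(generator$model)) {
      rho <- a_ex * rho + (1 - a_ex) *
        replacementMap(rho, generator$system, generator$model)
    }
    if (generator$damping_rate > 0) {
      rho <- a_dmp * rho +
        (1 - a_dmp) * diag(generator$dim) / generator$dim
    }
    sig <- (Vh %*% rho %*% V) * Ph
    rho <- V %*% sig %*% Vh
  }
  rho
}

evolveSuperop <- function(state, generator, t) {
  L <- superoperatorMatrix(generator, max_dim = 16)
  d <- generator$dim
  U <- expmComplex(L * t)
  matrix(U %*% as.vector(state), d, d)
}

# Spectral-norm upper bound for the generator (rad/s).
generatorNormBound <- function(generator) {
  nb <- 4 * pi * max(abs(generator$evalues))
  if (!is.null(generator$model)) nb <- nb + 2 / generator$model$tau_ir_s
  if (generator$damping_rate > 0) nb <- nb + 2 * generator$damping_rate
  nb
}

evolveKrylov <- function(state, generator, t, tol = 1e-10, m = 30) {
  d <- generator$dim
  v <- as.vector(state)
  gfun <- function(x) {
    as.vector(applyGenerator(generator, matrix(x, d, d)))
  }
  nb <- max(generatorNormBound(generator), 1e-12)
  t_done <- 0
  tau <- min(t, max(10 / nb, t / 1024))
  while (t_done < t) {
    tau <- min(tau, t - t_done)
    res <- krylovStep(gfun, v, tau, m, tol)
    while (!res$ok && tau > t * 1e-12) {
      tau <- tau / 2
      res <- krylovStep(gfun, v, tau, m, tol)
    }
    v <- res$v
    t_done <- t_done + tau
    tau <- tau * 1.3
  }
  matrix(v, d, d)
}

# One Arnoldi exponential step: approximates exp(tau*G) v in the Krylov
# subspace of dimension <= m, with an a-posteriori error estimate.
krylovStep <- function(gfun, v, tau, m, tol) {
  n <- length(v)
  beta <- sqrt(Re(sum(Conj(v) * v)))
  if (beta == 0) return(list(v = v, ok = TRUE))
  V <- matrix(0i, n, m + 1L)
  Hm <- matrix(0i, m + 1L, m)
  V[, 1] <- v / beta
  mk <- m
  breakdown <- FALSE
  for (j in seq_len(m)) {
    w <- gfun(V[, j])
    hj <- crossprod(Conj(V[, seq_len(j), drop = FALSE]), w)
    w <- w - V[, seq_len(j), drop = FALSE] %*% hj
    # one re-orthogonalization pass for stability
    hj2 <- crossprod(Conj(V[, seq_len(j), drop = FALSE]), w)
    w <- w - V[, seq_len(j), drop = FALSE] %*% hj2
    hj <- hj + hj2
    Hm[seq_len(j), j] <- hj
    hnext <- sqrt(Re(sum(Conj(w) * w)))
    Hm[j + 1L, j] <- hnext
    if (hnext < 1e-14) { mk <- j; breakdown <- TRUE; break }
    if (j < m) V[, j + 1L] <- w / hnext
  }
  Hk <- Hm[seq_len(mk), seq_len(mk), drop = FALSE]
  E <- expmComplex(tau * Hk)
  y <- E[, 1]
  err <- if (breakdown) 0 else abs(tau * Hm[mk + 1L, mk] * y[mk]) * beta
  ok <- breakdown || err <= max(tol * beta, 1e-300) * 10
  vout <- beta * (V[, seq_len(mk), drop = FALSE] %*% y)
  list(v = as.vector(vout), ok = ok, err = err)
}

#' Matrix exponential of a complex square matrix
#'
#' Scaling-and-squaring with a (13,13) Pade approximant; used for small
#' superoperators and Krylov Hessenberg factors.
#'
#' @param A Complex square matrix.
#' @return `exp(A)`.
#' @export
expmComplex <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1, 1]), 1, 1))
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 5.4)))
  As <- A / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  Id <- diag(n) + 0i
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- As %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
               b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * Id)
  Vm <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
        b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * Id
  F <- solve(Vm - U, Vm + U)
  if (s > 0) for (i in seq_len(s)) F <- F %*% F
  F
}

#' Piecewise-constant lab-frame propagation with a time-dependent drive
#'
#' Integrates the generalized Liouville-von Neumann equation when the
#' Hamiltonian oscillates in time (lab-frame CW drive), using
#' piecewise-constant Hamiltonian steps interleaved (Strang) with the exact
#' exchange/damping step. The step size resolves the fastest frequency
#' present with at least `steps_per_period` samples.
#'
#' @param state Density matrix.
#' @param system A [spinSystem()].
#' @param couplings A [couplingNetwork()].
#' @param b0_ut Static field (uT).
#' @param drive A [driveSpec()] (may be `NULL` for a static Hamiltonian).
#' @param model Optional [exchangeModel()].
#' @param t Total evolution time (s).
#' @param steps_per_period Samples per period of the fastest frequency
#'   (default 50).
#' @return Propagated density matrix.
#' @export
evolveLabFrame <- function(state, system, couplings, b0_ut, drive, model,
                           t, steps_per_period = 50) {
  if (t < 0) stop("t must be non-negative")
  if (t == 0) return(state)
  if (is.null(drive)) {
    H <- labHamiltonian(system, couplings, b0_ut)
    gen <- buildGenerator(H, system, model)
    return(evolve(state, gen, t, method = if (system$dim <= 8 &&
                                              !is.null(model)) "superop"
                                          else "split"))
  }
  fmax <- max(vapply(system$spins, spinLarmor, numeric(1), b0_ut = b0_ut),
              larmorFrequency(drive$target_isotope, b0_ut) + drive$offset_hz,
              abs(unclass(couplings)), drive$amplitude_hz)
  f_drive <- larmorFrequency(drive$target_isotope, b0_ut) + drive$offset_hz
  # choose the step as an exact divisor of the drive period so that the
  # piecewise-constant propagators repeat and can be cached over one period
  n_sub <- max(1L, ceiling(steps_per_period * fmax / f_drive))
  dt <- 1 / (f_drive * n_sub)
  n <- floor(t / dt + 1e-9)
  rem <- t - n * dt
  stepProp <- function(h, tm) {
    H <- labHamiltonian(system, couplings, b0_ut, drive, t = tm)
    eg <- eigen(H, symmetric = TRUE)
    ph <- exp(-2i * pi * eg$values * h)
    V <- eg$vectors + 0i
    (V * rep(ph, each = nrow(V))) %*% Conj(t(V))  # one-step unitary
  }
  # per-period cache of the piecewise-constant step unitaries (the drive
  # phase repeats exactly every n_sub steps)
  fullU <- vector("list", n_sub)
  for (idx in seq_len(n_sub)) {
    if (idx > n) break
    fullU[[idx]] <- stepProp(dt, (idx - 0.5) * dt)
  }
  # the exchange step is much slower than the drive period, so it is
  # interleaved every `q` coherent steps (Strang: half-exchange on either
  # side of each coherent block); coherent blocks are pre-multiplied.
  q <- min(n_sub, max(1L, floor((if (!is.null(model))
    model$tau_ir_s else Inf) / (500 * dt))))
  if (!is.finite(q) || is.null(model)) q <- n_sub
  blockCache <- vector("list", n_sub)
  getBlock <- function(start_idx, len) {
    full <- len == q && !is.null(blockCache[[start_idx]])
    if (full) return(blockCache[[start_idx]])
    B <- fullU[[start_idx]]
    ii <- start_idx
    for (s in seq_len(len - 1L)) {
      ii <- (ii %% n_sub) + 1L
      B <- fullU[[ii]] %*% B
    }
    if (len == q) blockCache[[start_idx]] <<- B
    B
  }
  exch <- function(rho, h) {
    if (is.null(model) || h <= 0) return(rho)
    a <- exp(-h / model$tau_ir_s)
    a * rho + (1 - a) * replacementMap(rho, system, model)
  }
  rho <- state
  k <- 0L
  idx <- 1L
  while (k < n) {
    len <- min(q, n - k)
    B <- getBlock(idx, len)
    rho <- exch(rho, len * dt / 2)
    rho <- B %*% rho %*% Conj(t(B))
    rho <- exch(rho, len * dt / 2)
    k <- k + len
    idx <- ((idx + len - 1L) %% n_sub) + 1L
  }
  if (rem > 1e-12) {
    U <- stepProp(rem, n * dt + rem / 2)
    rho <- exch(rho, rem / 2)
    rho <- U %*% rho %*% Conj(t(U))
    rho <- exch(rho, rem / 2)
  }
  rho
}

#' Time series of an observable along the evolution
#'
#' Propagates sequentially through an increasing time grid, reusing the state
#' between grid points, and records a scalar observable at each time.
#'
#' @param state Initial density matrix.
#' @param generator An [buildGenerator()] result.
#' @param times Strictly increasing, non-negative time grid (s).
#' @param observable Function of the density matrix returning a scalar.
#' @param ... Passed to [evolve()].
#' @return A [buildUpCurve()] with one value per time.
#' @export
evolveTimeseries <- function(state, generator, times, observable, ...) {
  if (length(times) == 0L) stop("empty time grid")
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  rho <- state
  tprev <- 0
  vals <- numeric(length(times))
  states_trace <- numeric(length(times))
  for (i in seq_along(times)) {
    rho <- evolve(rho, generator, times[i] - tprev, ...)
    tprev <- times[i]
    vals[i] <- observable(rho)
    states_trace[i] <- Re(sum(diag(rho)))
  }
  curve <- buildUpCurve(times, vals)
  attr(curve, "state_traces") <- states_trace
  attr(curve, "final_state") <- rho
  curve
}

#' Long-time (quasi-steady) state
#'
#' Obtained by propagation for `horizon_factor` times the characteristic
#' build-up time estimate, not by null-space solving: the exchange generator
#' can have slow near-degenerate modes and only finite-time values are
#' physically reported.
#'
#' @param state Initial density matrix.
#' @param generator An [buildGenerator()] result.
#' @param t_hyp_estimate Characteristic build-up time (s), default 26.
#' @param horizon_factor Multiple of the estimate to propagate (default 10).
#' @param ... Passed to [evolve()].
#' @return Density matrix after the long horizon.
#' @export
steadyState <- function(state, generator, t_hyp_estimate = 26,
                        horizon_factor = 10, ...) {
  evolve(state, generator, horizon_factor * t_hyp_estimate, ...)
}
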