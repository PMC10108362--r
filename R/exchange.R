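# Parahydrogen chemical-exchange superoperator.
#
# Hydrogen exchange on the active Ir complex is modeled as a deterministic
# first-order process at rate 1/tau_Ir: the two hydride spins are replaced by
# a fresh hydrogen pair in a fixed feed state (pure parahydrogen singlet by
# default), while the substrate stays bound.

#' Chemical-exchange model for the bound hydrogen pair
#'
#' @param tau_ir_s Lifetime of the active complex between hydrogen-exchange
#'   events (s, > 0); `1/tau_ir_s` is the exchange rate.
#' @param labels Labels of the exchanged spins (default the hydride pair).
#' @param singlet_fraction For a two-spin exchange group, the singlet
#'   fraction f of the fed hydrogen:
#'   `fed = f |S><S| + (1 - f)/3 * sum_i |T_i><T_i|`. Default 1 (pure
#'   parahydrogen). Ignored when `fed` is given.
#' @param fed Optional explicit density matrix of the fed state on the
#'   exchanged spins (unit trace, Hermitian).
#' @return An `exchangeModel` list.
#' @export
exchangeModel <- function(tau_ir_s, labels = c("Ha", "Hb"),
                          singlet_fraction = 1, fed = NULL) {
  if (!is.finite(tau_ir_s) || tau_ir_s <= 0) stop("tau_ir_s must be > 0")
  if (is.null(fed)) {
    if (length(labels) != 2L) {
      stop("`fed` must be supplied when the exchange group is not a pair")
    }
    f <- singlet_fraction
    if (!is.finite(f) || f < 0 || f > 1) {
      stop("singlet_fraction must be in [0, 1]")
    }
    ps <- singletProjector2()
    fed <- f * ps + (1 - f) / 3 * (diag(4) - ps)
  }
  dfed <- 2L^length(labels)
  if (!identical(dim(fed), c(as.integer(dfed), as.integer(dfed)))) {
    stop("fed state dimension does not match the exchange group")
  }
  if (abs(Re(sum(diag(fed))) - 1) > 1e-9 ||
      max(abs(fed - Conj(t(fed)))) > 1e-9) {
    stop("fed state must have unit trace and be Hermitian")
  }
  structure(list(tau_ir_s = tau_ir_s, labels = labels, fed = fed + 0i,
                 singlet_fraction = if (is.null(fed)) NA_real_
                                    else singlet_fraction),
            class = "exchangeModel")
}

#' Hydrogen-replacement map
#'
#' The composition of the dissociation map (partial trace over the exchanged
#' spins, leaving the substrate-only density) with the association map
#' (tensor product with the fed hydrogen state), re-embedded in the original
#' spin ordering. The map is trace-preserving and idempotent.
#'
#' @param state Density matrix on the full space.
#' @param system A [spinSystem()].
#' @param model An [exchangeModel()].
#' @return Density matrix with the exchanged spins reset to the feed state.
#' @export
replacementMap <- function(state, system, model) {
  rest <- setdiff(system$labels, model$labels)
  if (length(rest) == system$n_spins) {
    stop("exchange labels missing from system: ",
         paste(model$labels, collapse = ", "))
  }
  if (length(rest) == 0L) return(model$fed * Re(sum(diag(state))))
  reduced <- partialTrace(state, system, keep = rest)
  embedDensity(system, list(
    list(labels = model$labels, state = model$fed),
    list(labels = rest, state = reduced)
  ))
}

#' Full evolution generator
#'
#' The generalized Liouville-von Neumann generator
#' \deqn{\dot\rho = -2\pi i [H, \rho]
#'       + \tau_{Ir}^{-1}(\hat\Sigma\hat\Pi\rho - \rho)
#'       (+ \text{optional uniform damping})}
#' with `H` in Hz. `\hat\Sigma\hat\Pi` is the hydrogen replacement map of
#' [replacementMap()]. The optional damping relaxes toward the maximally
#' mixed state at the given rate (off by default; experimental polarization
#' magnitudes are instead matched by post-hoc reporting scale factors).
#'
#' @param H Hermitian Hamiltonian matrix in Hz.
#' @param system A [spinSystem()].
#' @param model Optional [exchangeModel()]; `NULL` disables exchange.
#' @param damping_rate Optional uniform damping rate (1/s) toward `I/d`.
#' @return An `evolutionGenerator` object (with a cached eigendecomposition
#'   of `H` for the split-step propagator).
#' @export
buildGenerator <- function(H, system, model = NULL, damping_rate = 0) {
  if (max(abs(H - Conj(t(H)))) > 1e-9 * max(1, max(abs(H)))) {
    stop("H must be Hermitian")
  }
  if (!identical(nrow(H), system$dim) && nrow(H) != system$dim) {
    stop("H dimension does not match the spin system")
  }
  if (!is.null(model)) {
    if (!all(model$labels %in% system$labels)) {
      stop("exchange labels missing from system: ",
           paste(setdiff(model$labels, system$labels), collapse = ", "))
    }
  }
  if (damping_rate < 0) stop("damping_rate must be >= 0")
  eg <- eigen(H, symmetric = TRUE)
  structure(list(H = H, system = system, model = model,
                 damping_rate = damping_rate,
                 evalues = eg$values, evectors = eg$vectors + 0i,
                 dim = system$dim),
            class = "evolutionGenerator")
}

#' @export
print.evolutionGenerator <- function(x, ...) {
  cat("evolutionGenerator on d =", x$dim, "\n")
  cat("  coherent: ||H|| =", signif(max(abs(x$evalues)), 4), "Hz (spectral)\n")
  if (!is.null(x$model)) {
    cat("  exchange: tau_Ir =", x$model$tau_ir_s, "s on {",
        paste(x$model$labels, collapse = ", "), "}\n")
  } else cat("  exchange: none\n")
  if (x$damping_rate > 0) cat("  damping:", x$damping_rate, "1/s\n")
  invisible(x)
}

#' Action of the generator on a state
#'
#' @param generator An [buildGenerator()] result.
#' @param state Density matrix.
#' @return The time derivative `d rho / d t` (1/s).
#' @export
applyGenerator <- function(generator, state) {
  out <- -2i * pi * (generator$H %*% state - state %*% generator$H)
  if (!is.null(generator$model)) {
    k <- 1 / generator$model$tau_ir_s
    out <- out +
      k * (replacementMap(state, generator$system, generator$model) - state)
  }
  if (generator$damping_rate > 0) {
    d <- generator$dim
    out <- out + generator$damping_rate *
      (diag(d) / d - state)
  }
  out
}

#' Dense superoperator matrix of a generator
#'
#' Builds the `d^2 x d^2` matrix representation (column-major `vec`
#' convention) of the full generator. Intended for small systems where dense
#' matrix exponentials are the exact cross-check path.
#'
#' @param generator An [buildGenerator()] result.
#' @param max_dim Guard on the Hilbert dimension (default 16).
#' @return Complex `d^2 x d^2` matrix.
#' @export
superoperatorMatrix <- function(generator, max_dim = 16) {
  d <- generator$dim
  if (d > max_dim) {
    stop("dense superoperator requested for d = ", d, " (> ", max_dim, ")")
  }
  Id <- diag(d) + 0i
  H <- generator$H
  L <- -2i * pi * (kronecker(Id, H) - kronecker(t(H), Id))
  if (!is.null(generator$model)) {
    k <- 1 / generator$model$tau_ir_s
    M <- matrix(0i, d^2, d^2)
    for (j in seq_len(d^2)) {
      E <- matrix(0i, d, d)
      E[j] <- 1
      M[, j] <- as.vector(replacementMap(E, generator$system,
                                         generator$model))
    }
    L <- L + k * (M - diag(d^2))
  }
  if (generator$damping_rate > 0) {
    r <- generator$damping_rate
    L <- L - r * diag(d^2) + r * as.vector(Id / d) %o% as.vector(Id)
  }
  L
}
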