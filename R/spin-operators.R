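# Spin-1/2 operator algebra on the big-endian product basis.

pauliHalf <- function(axis) {
  switch(axis,
         x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
         y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
         z = matrix(c(0.5, 0, 0, -0.5), 2, 2),
         e = diag(2) + 0i,
         stop("unknown axis: ", axis))
}

#' Single-spin operator embedded in the full product space
#'
#' @param system A [spinSystem()].
#' @param label Spin label.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Complex `d x d` matrix (`d = 2^N`) acting as the spin-1/2 operator
#'   on the named spin and as identity on all others.
#' @export
spinOperator <- function(system, label, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  k <- spinIndex(system, label)
  op <- matrix(1 + 0i, 1, 1)
  for (i in seq_len(system$n_spins)) {
    op <- kronecker(op, if (i == k) pauliHalf(axis) else diag(2) + 0i)
  }
  op
}

# Product of single-spin operators on distinct spins (identity elsewhere);
# `ops` is a named list label -> axis.
productOperator <- function(system, ops) {
  op <- matrix(1 + 0i, 1, 1)
  for (i in seq_len(system$n_spins)) {
    lab <- system$labels[i]
    fac <- if (lab %in% names(ops)) pauliHalf(ops[[lab]]) else diag(2) + 0i
    op <- kronecker(op, fac)
  }
  op
}

# Scalar-product coupling operator I_i . I_j embedded in the full space.
dotCouplingOperator <- function(system, label_i, label_j) {
  acc <- matrix(0i, system$dim, system$dim)
  for (ax in c("x", "y", "z")) {
    ops <- list()
    ops[[label_i]] <- ax
    ops[[label_j]] <- ax
    acc <- acc + productOperator(system, ops)
  }
  acc
}

# 0-based big-endian bit of `idx` for spin position p in an N-spin system.
spinBit <- function(idx, p, n) {
  (idx %/% 2L^(n - p)) %% 2L
}

# Index table for partial traces / embeddings: for kept positions `keep_pos`
# (subset of 1..N, declared order) returns a dk x dt integer matrix F with
# F[a, t] = 1-based full index whose kept bits spell a-1 (big-endian over
# keep_pos) and traced bits spell t-1 (big-endian over the complement).
subsystemIndexTable <- function(n, keep_pos) {
  trace_pos <- setdiff(seq_len(n), keep_pos)
  dk <- 2L^length(keep_pos)
  dt <- 2L^length(trace_pos)
  a <- 0:(dk - 1L)
  t <- 0:(dt - 1L)
  fa <- integer(dk)
  for (k in seq_along(keep_pos)) {
    fa <- fa + spinBit(a, k, length(keep_pos)) * 2L^(n - keep_pos[k])
  }
  ft <- integer(dt)
  for (k in seq_along(trace_pos)) {
    ft <- ft + spinBit(t, k, length(trace_pos)) * 2L^(n - trace_pos[k])
  }
  outer(fa, ft, `+`) + 1L
}

#' Partial trace of a density matrix
#'
#' Traces out all spins not in `keep`; the reduced matrix is returned on the
#' big-endian product basis of the kept spins in their declared order.
#'
#' @param state Density matrix on the full product space.
#' @param system A [spinSystem()].
#' @param keep Character vector of labels to keep (non-empty).
#' @return Reduced density matrix of dimension `2^length(keep)`.
#' @export
partialTrace <- function(state, system, keep) {
  if (length(keep) == 0L) stop("`keep` must be a non-empty set of labels")
  keep_pos <- sort(vapply(keep, spinIndex, integer(1), system = system))
  if (length(keep_pos) == system$n_spins) return(state)
  FF <- subsystemIndexTable(system$n_spins, keep_pos)
  dk <- nrow(FF)
  out <- matrix(0i, dk, dk)
  for (t in seq_len(ncol(FF))) {
    out <- out + state[FF[, t], FF[, t], drop = FALSE]
  }
  out
}

# Tensor-embed densities given on disjoint label groups into the declared
# basis order. `parts` is a list of list(labels = ..., state = ...) covering
# every spin exactly once.
embedDensity <- function(system, parts) {
  labs <- unlist(lapply(parts, `[[`, "labels"))
  if (!setequal(labs, system$labels) || anyDuplicated(labs)) {
    stop("parts must cover every spin exactly once")
  }
  big <- matrix(1 + 0i, 1, 1)
  for (p in parts) big <- kronecker(big, p$state + 0i)
  # big is ordered big-endian over `labs`; permute basis to declared order.
  n <- system$n_spins
  pos_in_labs <- match(system$labels, labs)
  idx <- 0:(system$dim - 1L)
  src <- integer(system$dim)
  for (p in seq_len(n)) {
    src <- src + spinBit(idx, p, n) * 2L^(n - pos_in_labs[p])
  }
  perm <- src + 1L
  big[perm, perm, drop = FALSE]
}

# 4x4 two-spin singlet projector |S><S| on the big-endian pair basis.
singletProjector2 <- function() {
  s <- c(0, 1, -1, 0) / sqrt(2)
  (s %o% s) + 0i
}

#' Density matrix with a singlet pair
#'
#' Prepares the two named spins in the parahydrogen singlet state
#' \eqn{|S\rangle = (|\alpha\beta\rangle - |\beta\alpha\rangle)/\sqrt{2}};
#' the remaining spins are maximally mixed unless `rest_state` is supplied.
#'
#' @param system A [spinSystem()].
#' @param pair Two distinct spin labels.
#' @param rest_state Optional density matrix for the remaining spins (in
#'   their declared order); default maximally mixed.
#' @return Density matrix on the full space (unit trace, Hermitian).
#' @export
singletDensity <- function(system, pair, rest_state = NULL) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("`pair` must be two distinct spin labels")
  }
  rest <- setdiff(system$labels, pair)
  if (length(rest) == 0L) return(singletProjector2())
  if (is.null(rest_state)) {
    dr <- 2L^length(rest)
    rest_state <- diag(dr) / dr
  }
  embedDensity(system, list(
    list(labels = pair, state = singletProjector2()),
    list(labels = rest, state = rest_state)
  ))
}

#' Maximally mixed state on the full product space
#' @param system A [spinSystem()].
#' @return The identity density matrix `I/d`.
#' @export
mixedDensity <- function(system) {
  diag(system$dim) / system$dim + 0i
}

# Validity checks used by tests and constructors.
assertDensity <- function(state, tol_trace = 1e-9, tol_herm = 1e-9,
                          tol_pos = 1e-8) {
  tr <- Re(sum(diag(state)))
  if (abs(tr - 1) > tol_trace) stop("density matrix trace != 1: ", tr)
  if (max(abs(state - Conj(t(state)))) > tol_herm) {
    stop("density matrix not Hermitian")
  }
  ev <- eigen(state, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_pos) stop("density matrix has negative eigenvalue")
  invisible(TRUE)
}

# Real expectation value Tr(rho O) for Hermitian O.
expectation <- function(state, op) {
  Re(sum(state * t(op)))
}
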