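# Gyromagnetic ratios in MHz/T (equivalently Hz/uT), CODATA-rounded.
.GAMMA <- c("1H" = 42.577, "13C" = 10.7084)

#' Gyromagnetic ratio of a supported isotope
#'
#' @param isotope `"1H"` or `"13C"`.
#' @return Gyromagnetic ratio in MHz/T (numerically equal to Hz/uT).
#' @export
gyromagneticRatio <- function(isotope) {
  if (!isotope %in% names(.GAMMA)) {
    stop("unknown isotope: ", isotope, " (supported: ",
         paste(names(.GAMMA), collapse = ", "), ")")
  }
  unname(.GAMMA[isotope])
}

#' Specification of a single spin-1/2 nucleus
#'
#' @param label Unique spin label.
#' @param isotope `"1H"` or `"13C"`.
#' @param gamma Gyromagnetic ratio in MHz/T; defaults to the tabulated value
#'   for the isotope.
#' @param shift_ppm Chemical shift in ppm (relative to the bare-isotope
#'   Larmor frequency).
#' @return A `spinSpec` list.
#' @export
spinSpec <- function(label, isotope, gamma = gyromagneticRatio(isotope),
                     shift_ppm = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!isotope %in% c("1H", "13C")) stop("unknown isotope: ", isotope)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive and finite")
  if (!is.finite(shift_ppm)) stop("shift_ppm must be finite")
  structure(list(label = label, isotope = isotope, gamma = gamma,
                 shift_ppm = shift_ppm), class = "spinSpec")
}

#' A multi-spin system of spin-1/2 nuclei
#'
#' The product basis is ordered big-endian over the declared spin list: the
#' first declared spin is the most significant qubit, and for each spin
#' \eqn{|\alpha\rangle} (the +z Zeeman eigenstate) precedes
#' \eqn{|\beta\rangle}.
#'
#' @param spins List of [spinSpec()] objects in declared basis order.
#' @param roles Named character vector mapping role names (e.g. `hydride_a`,
#'   `hydride_b`, `carbon`, `methyl_1`) to spin labels.
#' @return A `spinSystem` object.
#' @export
spinSystem <- function(spins, roles = character()) {
  stopifnot(is.list(spins), length(spins) >= 1L)
  if (!all(vapply(spins, inherits, logical(1), "spinSpec"))) {
    stop("all elements of `spins` must be spinSpec objects")
  }
  labels <- vapply(spins, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate spin labels")
  if (length(roles)) {
    bad <- setdiff(roles, labels)
    if (length(bad)) stop("role labels not in system: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(spins = spins, labels = labels, roles = roles,
                 n_spins = length(spins), dim = 2L^length(spins)),
            class = "spinSystem")
}

#' @export
print.spinSystem <- function(x, ...) {
  cat("spinSystem: ", x$n_spins, " spin-1/2 nuclei (Hilbert dimension ",
      x$dim, ")\n", sep = "")
  for (s in x$spins) {
    role <- names(x$roles)[x$roles == s$label]
    cat(sprintf("  %-4s %-4s gamma=%8.4f MHz/T  shift=%g ppm%s\n",
                s$label, s$isotope, s$gamma, s$shift_ppm,
                if (length(role)) paste0("  [", role, "]") else ""))
  }
  invisible(x)
}

spinIndex <- function(system, label) {
  i <- match(label, system$labels)
  if (is.na(i)) stop("unknown spin label: ", label)
  i
}

roleLabel <- function(system, role) {
  if (!role %in% names(system$roles)) stop("system has no role: ", role)
  unname(system$roles[[role]])
}

#' Scalar J-coupling network
#'
#' @param system A [spinSystem()].
#' @param pairs Data frame or list of `(label_i, label_j, J_hz)` triples; or a
#'   full symmetric matrix in Hz with dimnames equal to the spin labels.
#' @return A symmetric coupling matrix (Hz) with zero diagonal, class
#'   `couplingNetwork`.
#' @export
couplingNetwork <- function(system, pairs = NULL) {
  n <- system$n_spins
  J <- matrix(0, n, n, dimnames = list(system$labels, system$labels))
  if (is.matrix(pairs)) {
    if (!identical(dim(pairs), dim(J))) stop("coupling matrix dimension mismatch")
    J[] <- pairs
    if (max(abs(J - t(J))) > 1e-12) stop("coupling matrix must be symmetric")
    diag(J) <- 0
  } else if (!is.null(pairs)) {
    if (is.data.frame(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
    for (p in pairs) {
      p <- as.list(p)
      i <- spinIndex(system, as.character(p[[1]]))
      j <- spinIndex(system, as.character(p[[2]]))
      if (i == j) stop("self-coupling not allowed: ", p[[1]])
      J[i, j] <- J[j, i] <- as.numeric(p[[3]])
    }
  }
  structure(J, class = c("couplingNetwork", "matrix"))
}

#' The pyruvate-SABRE parameter preset
#'
#' Returns the six-spin model of the catalyst-bound 1-13C-pyruvate SABRE
#' complex: two parahydrogen-derived hydrides, three methyl protons and one
#' carboxylate 13C, with the couplings that dominate transfer at microtesla
#' field: hydride-hydride J = -10.5 Hz, one hydride-13C coupling of 0.06 Hz
#' (the other zero), and 1.2 Hz from 13C to each methyl proton. The complex
#' lifetime is tau_Ir = 31 ms and the working field 121 uT. The hydrides
#' differ in chemical shift by 2 ppm (about 0.01 Hz at this field).
#'
#' @param reduced If `TRUE`, return the reduced three-spin model (two
#'   hydrides + 13C, methyl protons omitted) used as a fast fixture.
#' @return List with elements `system` ([spinSystem()]), `couplings`
#'   ([couplingNetwork()]), `exchange` ([exchangeModel()]) and `b0_ut`
#'   (static field, uT).
#' @export
presetPyruvateSabre <- function(reduced = FALSE) {
  hyd <- list(spinSpec("Ha", "1H", shift_ppm = 0),
              spinSpec("Hb", "1H", shift_ppm = 2))
  carbon <- spinSpec("C1", "13C", shift_ppm = 0)
  if (reduced) {
    spins <- c(hyd, list(carbon))
    roles <- c(hydride_a = "Ha", hydride_b = "Hb", carbon = "C1")
  } else {
    spins <- c(hyd, list(spinSpec("M1", "1H"), spinSpec("M2", "1H"),
                         spinSpec("M3", "1H"), carbon))
    roles <- c(hydride_a = "Ha", hydride_b = "Hb",
               methyl_1 = "M1", methyl_2 = "M2", methyl_3 = "M3",
               carbon = "C1")
  }
  system <- spinSystem(spins, roles)
  pairs <- list(list("Ha", "Hb", -10.5), list("Ha", "C1", 0.06))
  if (!reduced) {
    pairs <- c(pairs, list(list("C1", "M1", 1.2), list("C1", "M2", 1.2),
                           list("C1", "M3", 1.2)))
  }
  couplings <- couplingNetwork(system, pairs)
  list(system = system,
       couplings = couplings,
       exchange = exchangeModel(0.031, c("Ha", "Hb")),
       b0_ut = 121)
}
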