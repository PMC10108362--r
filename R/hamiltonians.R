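# Lab-frame and doubly rotating-frame Hamiltonians.
#
# All Hamiltonians are returned in frequency units (Hz); the 2*pi factor is
# applied once, inside the evolution generator.

#' Larmor frequency of an isotope at a given static field
#'
#' @param isotope `"1H"` or `"13C"`.
#' @param field_ut Static field in uT (non-negative).
#' @param gamma Gyromagnetic ratio in MHz/T; defaults to the tabulated value.
#' @return Frequency in Hz.
#' @export
larmorFrequency <- function(isotope, field_ut,
                            gamma = gyromagneticRatio(isotope)) {
  if (!is.numeric(field_ut) || any(field_ut < 0)) {
    stop("field_ut must be non-negative")
  }
  gamma * field_ut
}

#' Continuous-wave drive specification
#'
#' A weak transverse CW (SLIC / LIGHT-SABRE) irradiation near the Larmor
#' frequency of the target isotope.
#'
#' @param target_isotope Isotope the drive addresses (`"13C"` or `"1H"`).
#' @param amplitude_hz Nutation frequency of the target isotope (Hz, >= 0).
#' @param offset_hz Frequency offset from the bare target Larmor frequency
#'   (Hz); positive means the drive is above the Larmor frequency.
#' @param phase_rad Drive phase in radians (0 = along rotating-frame x).
#' @return A `driveSpec` list; `field_ut` holds the equivalent rotating-frame
#'   field amplitude `amplitude_hz / gamma_target`.
#' @export
driveSpec <- function(target_isotope = "13C", amplitude_hz, offset_hz = 0,
                      phase_rad = 0) {
  if (!is.finite(amplitude_hz) || amplitude_hz < 0) {
    stop("amplitude_hz must be non-negative")
  }
  gam <- gyromagneticRatio(target_isotope)
  structure(list(target_isotope = target_isotope,
                 amplitude_hz = amplitude_hz,
                 offset_hz = offset_hz,
                 phase_rad = phase_rad,
                 field_ut = amplitude_hz / gam),
            class = "driveSpec")
}

# Shifted Larmor frequency (Hz) of spin i at field b0_ut.
spinLarmor <- function(spin, b0_ut) {
  spin$gamma * b0_ut * (1 + spin$shift_ppm * 1e-6)
}

#' Lab-frame Hamiltonian
#'
#' Zeeman terms \eqn{-\nu_{0i} I_{zi}}, full (non-secular) scalar couplings
#' \eqn{J_{ij}\, \mathbf{I}_i\cdot\mathbf{I}_j}, and, when a drive is given,
#' a linearly oscillating transverse field sampled at time `t`:
#' \eqn{2\nu_1 (\gamma_i/\gamma_\mathrm{target}) \cos(2\pi f t + \phi) I_{xi}}
#' on every spin. The result is in Hz; it is time-dependent whenever a drive
#' is present.
#'
#' @param system A [spinSystem()].
#' @param couplings A [couplingNetwork()] (Hz).
#' @param b0_ut Static field in uT.
#' @param drive Optional [driveSpec()].
#' @param t Time (s) at which to sample the oscillating drive term.
#' @return Hermitian complex matrix (Hz).
#' @export
labHamiltonian <- function(system, couplings, b0_ut, drive = NULL, t = 0) {
  if (!identical(dim(unclass(couplings)), c(system$n_spins, system$n_spins))) {
    stop("coupling matrix dimension does not match the spin system")
  }
  d <- system$dim
  H <- matrix(0i, d, d)
  for (i in seq_len(system$n_spins)) {
    nu0 <- spinLarmor(system$spins[[i]], b0_ut)
    if (nu0 != 0) {
      H <- H - nu0 * spinOperator(system, system$labels[i], "z")
    }
  }
  J <- unclass(couplings)
  for (i in seq_len(system$n_spins - 1L)) {
    for (j in (i + 1L):system$n_spins) {
      if (J[i, j] != 0) {
        H <- H + J[i, j] *
          dotCouplingOperator(system, system$labels[i], system$labels[j])
      }
    }
  }
  if (!is.null(drive)) {
    f_drive <- larmorFrequency(drive$target_isotope, b0_ut) + drive$offset_hz
    gam_t <- gyromagneticRatio(drive$target_isotope)
    amp_t <- 2 * drive$amplitude_hz *
      cos(2 * pi * f_drive * t + drive$phase_rad)
    for (i in seq_len(system$n_spins)) {
      w <- system$spins[[i]]$gamma / gam_t
      H <- H + amp_t * w * spinOperator(system, system$labels[i], "x")
    }
  }
  H
}

#' Doubly rotating-frame Hamiltonian under a CW drive
#'
#' Each isotope is transformed at its own reference frequency: the target
#' isotope at the drive frequency (bare Larmor + offset), every other isotope
#' at its bare Larmor frequency. The rotating-wave approximation keeps the
#' co-rotating drive component on target-isotope spins only. Homonuclear
#' couplings are kept in full; heteronuclear couplings are truncated to their
#' secular \eqn{I_z S_z} part, which requires the Larmor separation to exceed
#' `truncation_threshold` times the coupling — otherwise the construction
#' signals that lab-frame propagation must be used.
#'
#' @inheritParams labHamiltonian
#' @param drive A [driveSpec()] (required).
#' @param truncation_threshold Minimum ratio of heteronuclear frequency
#'   separation to |J| for secular truncation (default 100).
#' @return Hermitian, time-independent complex matrix (Hz).
#' @export
rotatingFrameHamiltonian <- function(system, couplings, b0_ut, drive,
                                     truncation_threshold = 100) {
  if (is.null(drive)) stop("rotating-frame construction requires a drive")
  if (truncation_threshold <= 1) stop("truncation_threshold must exceed 1")
  d <- system$dim
  H <- matrix(0i, d, d)
  f_drive <- larmorFrequency(drive$target_isotope, b0_ut) + drive$offset_hz
  for (i in seq_len(system$n_spins)) {
    sp <- system$spins[[i]]
    nu_ref <- if (sp$isotope == drive$target_isotope) f_drive
              else larmorFrequency(sp$isotope, b0_ut, sp$gamma)
    resid <- spinLarmor(sp, b0_ut) - nu_ref
    if (resid != 0) {
      H <- H - resid * spinOperator(system, sp$label, "z")
    }
  }
  J <- unclass(couplings)
  for (i in seq_len(system$n_spins - 1L)) {
    for (j in (i + 1L):system$n_spins) {
      if (J[i, j] == 0) next
      li <- system$labels[i]; lj <- system$labels[j]
      same <- system$spins[[i]]$isotope == system$spins[[j]]$isotope
      if (same) {
        H <- H + J[i, j] * dotCouplingOperator(system, li, lj)
      } else {
        sep <- abs(spinLarmor(system$spins[[i]], b0_ut) -
                   spinLarmor(system$spins[[j]], b0_ut))
        if (sep <= truncation_threshold * abs(J[i, j])) {
          stop("secular truncation invalid for pair (", li, ", ", lj,
               "): Larmor separation ", signif(sep, 4),
               " Hz <= ", truncation_threshold, " x |J|; use the lab frame")
        }
        ops <- list(); ops[[li]] <- "z"; ops[[lj]] <- "z"
        H <- H + J[i, j] * productOperator(system, ops)
      }
    }
  }
  nu1 <- drive$amplitude_hz
  if (nu1 != 0) {
    cx <- cos(drive$phase_rad); sy <- sin(drive$phase_rad)
    for (i in seq_len(system$n_spins)) {
      if (system$spins[[i]]$isotope != drive$target_isotope) next
      lab <- system$labels[i]
      H <- H + nu1 * cx * spinOperator(system, lab, "x")
      if (sy != 0) H <- H + nu1 * sy * spinOperator(system, lab, "y")
    }
  }
  H
}
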