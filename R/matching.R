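# Analytic matching-condition theory for the two CW transfer mechanisms.
#
# In the doubly rotating frame the hydride pair is dominated by J_HH, so the
# singlet/triplet basis {S0, T0, T+, T-} is natural; the target 13C is
# quantized either along the CW field (x, on resonance) or along the tilted
# effective field (off resonance). The transfer-relevant physics lives in
# 2x2 blocks whose off-diagonal element is Delta J_CH / 4, the difference of
# the two hydride-carbon couplings divided by four.

#' The magic angle of z-polarization transfer
#'
#' Numerically maximizes `sin(2 theta) * sin(theta)` over `(0, 90)` degrees.
#' The maximizer is `atan(sqrt(2)) = 54.7356...` degrees: the tilt of the
#' effective CW field at which off-resonance LIGHT-SABRE generates the most
#' z-polarization.
#'
#' @param tol Optimization tolerance in degrees (default 1e-6).
#' @return The maximizing angle in degrees.
#' @export
magicAngle <- function(tol = 1e-6) {
  obj <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sin(2 * th) * sin(th)
  }
  stats::optimize(obj, interval = c(0, 90), maximum = TRUE, tol = tol)$maximum
}

#' Effective-field tilt and magnitude of a CW drive
#'
#' @param amplitude_hz CW amplitude (Hz, >= 0).
#' @param offset_hz Offset from resonance (Hz).
#' @return A `tiltedFrame` list with `theta_deg` (tilt of the 13C
#'   quantization axis from z, in `[0, 90]`) and `nu_eff_hz`
#'   (`sqrt(offset^2 + amplitude^2)`).
#' @export
tiltedFrame <- function(amplitude_hz, offset_hz) {
  if (amplitude_hz < 0) stop("amplitude_hz must be >= 0")
  nu_eff <- sqrt(offset_hz^2 + amplitude_hz^2)
  theta <- if (nu_eff == 0) 0
           else atan2(amplitude_hz, abs(offset_hz)) * 180 / pi
  structure(list(theta_deg = theta, nu_eff_hz = nu_eff),
            class = "tiltedFrame")
}

#' Effective 2x2 block of the x-polarization transfer
#'
#' The on-resonance transfer block in the basis
#' `{|S0 X->, |T0 X+>}` (hydride singlet/central triplet times 13C states
#' anti-parallel/parallel to the CW field). Projected from the full
#' rotating-frame Hamiltonian, the diagonal elements are
#' `-3 J_HH / 4 - nu_A / 2` and `J_HH / 4 + nu_A / 2`, so the diagonal gap
#' `J_HH + nu_A` closes at the matching condition `nu_A = -J_HH`; the
#' off-diagonal element is `(J_HC_a - J_HC_b) / 4` independent of the drive.
#' A frequency offset does not enter this block (it couples the X states to
#' each other outside the block); the block describes the on-resonance
#' mechanism and the full simulation is authoritative off resonance.
#'
#' @param J_HH Hydride-hydride coupling (Hz, negative for pyruvate SABRE).
#' @param J_HC_a,J_HC_b The two hydride-13C couplings (Hz).
#' @param nu_A CW amplitude (Hz).
#' @param delta_nu CW offset (Hz); accepted for interface symmetry,
#'   does not enter the block elements.
#' @return An `effectiveBlock`: list with `matrix` (2x2, Hz, labeled),
#'   `diagonal_gap` and `off_diagonal`.
#' @export
xTransferBlock <- function(J_HH, J_HC_a, J_HC_b, nu_A, delta_nu = 0) {
  off <- (J_HC_a - J_HC_b) / 4
  d1 <- -3 * J_HH / 4 - nu_A / 2
  d2 <- J_HH / 4 + nu_A / 2
  m <- matrix(c(d1, off, off, d2), 2, 2,
              dimnames = list(c("S0X-", "T0X+"), c("S0X-", "T0X+")))
  structure(list(matrix = m, diagonal_gap = d2 - d1,
                 off_diagonal = off),
            class = "effectiveBlock")
}

#' Matching condition for z-polarization transfer
#'
#' Off-resonance irradiation tilts the 13C effective field by `theta`; the
#' level matching requires the effective field magnitude `nu_eff = -J_HH`,
#' and transfer into z-magnetization is maximized at the magic angle. The
#' returned amplitude/offset pair decomposes `nu_eff` along the tilt:
#' `delta_nu = nu_eff cos(theta)`, `nu_A = nu_eff sin(theta)`.
#'
#' @param J_HH Hydride-hydride coupling (Hz, must be negative).
#' @param theta_deg Tilt angle in degrees; default the magic angle.
#' @return List with `delta_nu_hz`, `nu_A_hz`, `nu_eff_hz`, `theta_deg`.
#' @export
zTransferCondition <- function(J_HH, theta_deg = NULL) {
  if (J_HH >= 0) stop("J_HH must be negative")
  if (is.null(theta_deg)) theta_deg <- magicAngle()
  if (theta_deg <= 0 || theta_deg >= 90) {
    stop("theta_deg must lie strictly between 0 and 90 degrees")
  }
  nu_eff <- -J_HH
  th <- theta_deg * pi / 180
  list(delta_nu_hz = nu_eff * cos(th),
       nu_A_hz = nu_eff * sin(th),
       nu_eff_hz = nu_eff,
       theta_deg = theta_deg)
}

#' SABRE-SHEATH matching field
#'
#' The static-field analogue of the CW matching condition: polarization
#' transfer by level anti-crossing requires the heteronuclear Larmor
#' separation to equal the hydride-hydride coupling,
#' `(gamma_H - gamma_C) B0 = |J_HH|`.
#'
#' @param J_HH Hydride-hydride coupling (Hz, non-zero).
#' @param gamma_h,gamma_c Gyromagnetic ratios (MHz/T).
#' @return Matching field in uT.
#' @export
sheathMatchingField <- function(J_HH, gamma_h = gyromagneticRatio("1H"),
                                gamma_c = gyromagneticRatio("13C")) {
  if (J_HH == 0) stop("J_HH must be non-zero")
  abs(J_HH) / (gamma_h - gamma_c)
}

#' Validate the analytic block against the full Hamiltonian
#'
#' Projects the full rotating-frame Hamiltonian of the reduced three-spin
#' system onto the `{|S0 X->, |T0 X+>}` basis and compares the matrix
#' elements with [xTransferBlock()].
#'
#' @param preset A reduced preset as from `presetPyruvateSabre(reduced =
#'   TRUE)`.
#' @param drive A [driveSpec()].
#' @return List with the projected and analytic elements and
#'   `max_abs_diff_hz`.
#' @export
blockVsFullCheck <- function(preset = presetPyruvateSabre(reduced = TRUE),
                             drive) {
  system <- preset$system
  if (system$n_spins != 3L) stop("blockVsFullCheck expects the 3-spin model")
  H <- rotatingFrameHamiltonian(system, preset$couplings, preset$b0_ut,
                                drive)
  # basis: big-endian over (Ha, Hb, C1); carbon least significant
  s0 <- c(0, 1, -1, 0) / sqrt(2)   # (|ab> - |ba>)/sqrt2 on the hydride pair
  t0 <- c(0, 1, 1, 0) / sqrt(2)
  xm <- c(1, -1) / sqrt(2)         # |X-> = (|a> - |b>)/sqrt2
  xp <- c(1, 1) / sqrt(2)
  v1 <- as.vector(kronecker(s0, xm)) + 0i     # |S0 X->
  v2 <- as.vector(kronecker(t0, xp)) + 0i     # |T0 X+>
  proj <- function(u, v) sum(Conj(u) * as.vector(H %*% v))
  J <- unclass(preset$couplings)
  blk <- xTransferBlock(J_HH = J["Ha", "Hb"],
                        J_HC_a = J["Ha", "C1"], J_HC_b = J["Hb", "C1"],
                        nu_A = drive$amplitude_hz,
                        delta_nu = drive$offset_hz)
  full_off <- proj(v1, v2)
  full_gap <- Re(proj(v2, v2) - proj(v1, v1))
  list(off_diagonal_full_hz = full_off,
       off_diagonal_block_hz = blk$off_diagonal,
       diagonal_gap_full_hz = full_gap,
       diagonal_gap_block_hz = blk$diagonal_gap,
       max_abs_diff_hz = max(abs(full_off - blk$off_diagonal),
                             abs(full_gap - blk$diagonal_gap)))
}

#' Matching-condition report
#'
#' Tabulates the analytic CW and static-field matching conditions for a
#' given coupling set.
#'
#' @param J_HH Hydride-hydride coupling (Hz, negative).
#' @param J_HC_a,J_HC_b Hydride-carbon couplings (Hz).
#' @return Data frame with one row per condition.
#' @export
matchingReport <- function(J_HH = -10.5, J_HC_a = 0.06, J_HC_b = 0) {
  zc <- zTransferCondition(J_HH)
  data.frame(
    mechanism = c("x_transfer", "z_transfer", "sheath"),
    amplitude_hz = c(-J_HH, zc$nu_A_hz, NA),
    offset_hz = c(0, zc$delta_nu_hz, NA),
    field_ut = c(NA, NA, sheathMatchingField(J_HH)),
    theta_deg = c(90, zc$theta_deg, NA),
    transfer_element_hz = c((J_HC_a - J_HC_b) / 4, (J_HC_a - J_HC_b) / 4, NA),
    stringsAsFactors = FALSE
  )
}
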