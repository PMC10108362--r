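# Experimental protocol emulation: LIGHT-SABRE (CW drive at 121 uT) and
# SABRE-SHEATH (sub-uT static field), with the three readout schemes
# (direct transverse detection; crusher + 90 degree pulses; SEPP).

#' Protocol specification
#'
#' @param mode `"light_sabre"` or `"sheath"`.
#' @param t_hyp_s Hyperpolarization (CW or low-field dwell) time, s, >= 0.
#' @param b0_ut Static working field for LIGHT-SABRE (uT, default 121).
#' @param drive A [driveSpec()] (LIGHT-SABRE only).
#' @param polarization_field_ut Polarization field for SHEATH
#'   (uT, default 0.36).
#' @param readout `"direct_transverse"`, `"crusher_90"` or `"sepp"`.
#' @return A `protocolSpec` list.
#' @export
protocolSpec <- function(mode = c("light_sabre", "sheath"), t_hyp_s,
                         b0_ut = 121, drive = NULL,
                         polarization_field_ut = 0.36,
                         readout = c("direct_transverse", "crusher_90",
                                     "sepp")) {
  mode <- match.arg(mode)
  readout <- match.arg(readout)
  if (!is.finite(t_hyp_s) || t_hyp_s < 0) stop("t_hyp_s must be >= 0")
  if (mode == "light_sabre") {
    if (is.null(drive)) stop("light_sabre mode requires a drive")
  } else {
    if (!is.finite(polarization_field_ut) || polarization_field_ut < 0) {
      stop("polarization_field_ut must be >= 0")
    }
  }
  structure(list(mode = mode, t_hyp_s = t_hyp_s, b0_ut = b0_ut,
                 drive = drive,
                 polarization_field_ut = polarization_field_ut,
                 readout = readout),
            class = "protocolSpec")
}

#' Initial state of the active SABRE complex
#'
#' Fresh parahydrogen singlet on the hydride pair; substrate spins
#' maximally mixed (thermal polarization at microtesla fields is
#' negligible, ~1e-9).
#'
#' @param preset Preset list as from [presetPyruvateSabre()].
#' @return Density matrix.
#' @export
initialState <- function(preset) {
  singletDensity(preset$system,
                 c(roleLabel(preset$system, "hydride_a"),
                   roleLabel(preset$system, "hydride_b")))
}

# Ideal crusher gradient: projection onto the diagonal of the lab Zeeman
# product basis. Removes every coherence, retains z- and zz-orders.
crusher <- function(state) {
  out <- matrix(0i, nrow(state), ncol(state))
  diag(out) <- diag(state)
  out
}

# Ideal instantaneous pulse: rotation by `angle` about `axis` on every spin
# of the given isotopes.
applyPulse <- function(state, system, isotopes, angle_rad, axis = "y") {
  U <- matrix(1 + 0i, 1, 1)
  c2 <- cos(angle_rad / 2)
  s2 <- sin(angle_rad / 2)
  u1 <- c2 * diag(2) - 2i * s2 * pauliHalf(axis)
  for (i in seq_len(system$n_spins)) {
    U <- kronecker(U, if (system$spins[[i]]$isotope %in% isotopes) u1
                      else diag(2) + 0i)
  }
  U %*% state %*% Conj(t(U))
}

# Evolve the prepared complex for t_hyp under the protocol physics.
protocolEvolve <- function(spec, preset, state = initialState(preset),
                           dt = 1e-3, method = "auto") {
  if (spec$t_hyp_s == 0) return(state)
  if (spec$mode == "light_sabre") {
    H <- rotatingFrameHamiltonian(preset$system, preset$couplings,
                                  spec$b0_ut, spec$drive)
    gen <- buildGenerator(H, preset$system, preset$exchange)
    evolve(state, gen, spec$t_hyp_s, method = method, dt = dt)
  } else {
    evolveLabFrame(state, preset$system, preset$couplings,
                   spec$polarization_field_ut, drive = NULL,
                   model = preset$exchange, t = spec$t_hyp_s)
  }
}

#' Run a hyperpolarization protocol
#'
#' Evolves the freshly loaded complex for `t_hyp_s` under the protocol's
#' generator, applies the readout, and returns polarization records for the
#' observables that readout exposes:
#' \describe{
#'   \item{direct_transverse}{transverse (x) 13C polarization along the CW
#'     phase, measured without further pulses.}
#'   \item{crusher_90}{ideal crusher (diagonal projection in the Zeeman
#'     product basis) followed by 90 degree pulses on 1H and 13C;
#'     longitudinal (z) records for every spin are returned.}
#'   \item{sepp}{crusher, 90 degree pulse on 1H only, then 180 degree pulses
#'     on both channels; the 13C-methyl zz record plus the resulting
#'     in-phase 1H transverse observable are returned.}
#' }
#'
#' @param spec A [protocolSpec()].
#' @param preset Preset list as from [presetPyruvateSabre()].
#' @param state Optional initial state (default [initialState()]).
#' @param dt Split-step size (s) for the propagation.
#' @param method Propagation method passed to [evolve()].
#' @return Named list of [polarizationRecord()] objects; the final density
#'   matrix is attached as attribute `state`.
#' @export
runProtocol <- function(spec, preset, state = initialState(preset),
                        dt = 1e-3, method = "auto") {
  system <- preset$system
  rho <- protocolEvolve(spec, preset, state, dt = dt, method = method)
  carbon <- roleLabel(system, "carbon")
  records <- list()
  if (spec$readout == "direct_transverse") {
    records$x_C <- polarizationRecord(
      "x", carbon, polarization(rho, system, carbon, "x"), "13C")
  } else if (spec$readout == "crusher_90") {
    rho_c <- crusher(rho)
    for (i in seq_len(system$n_spins)) {
      lab <- system$labels[i]
      records[[paste0("z_", lab)]] <- polarizationRecord(
        "z", lab, polarization(rho_c, system, lab, "z"),
        system$spins[[i]]$isotope)
    }
    rho <- applyPulse(rho_c, system, c("1H", "13C"), pi / 2)
  } else { # sepp
    rho_c <- crusher(rho)
    methyl <- if ("methyl_1" %in% names(system$roles)) {
      roleLabel(system, "methyl_1")
    } else {
      roleLabel(system, "hydride_a")
    }
    records$zz_CH <- polarizationRecord(
      "zz", c(carbon, methyl), twoSpinOrder(rho_c, system, c(carbon, methyl)),
      "13C")
    rho <- applyPulse(rho_c, system, "1H", pi / 2)
    rho <- applyPulse(rho, system, c("1H", "13C"), pi)
    records$x_H_inphase <- polarizationRecord(
      "x", methyl, polarization(rho, system, methyl, "x"), "1H")
  }
  attr(records, "state") <- rho
  records
}

#' Two-dimensional amplitude/offset polarization scan
#'
#' Repeats the LIGHT-SABRE protocol over a grid of CW amplitudes and
#' offsets. The state after `t_hyp_s` is evolved once per grid point and all
#' three spin-order maps (x, z, zz) are read from it.
#'
#' @param spec Template [protocolSpec()] (light_sabre); its drive supplies
#'   the target isotope and phase.
#' @param amplitude_hz Amplitude grid (Hz, non-empty).
#' @param offset_hz Offset grid (Hz, non-empty).
#' @param preset Preset list.
#' @param dt Split-step size (s).
#' @param method Propagation method passed to [evolve()].
#' @param progress Print a dot every 10 grid points.
#' @return A `scanResult`: grids, named list `maps` of
#'   `length(amplitude_hz) x length(offset_hz)` matrices for kinds
#'   `x`, `z`, `zz`, and per-kind `argmax` metadata (`amplitude_hz`,
#'   `offset_hz`, `value`, located by largest absolute value).
#' @export
scan2d <- function(spec, amplitude_hz, offset_hz, preset, dt = 1e-3,
                   method = "auto", progress = FALSE) {
  if (!length(amplitude_hz) || !length(offset_hz)) stop("empty scan grid")
  if (spec$mode != "light_sabre") stop("scan2d requires light_sabre mode")
  system <- preset$system
  carbon <- roleLabel(system, "carbon")
  methyl <- if ("methyl_1" %in% names(system$roles)) {
    roleLabel(system, "methyl_1")
  } else NULL
  na <- length(amplitude_hz); no <- length(offset_hz)
  maps <- list(x = matrix(NA_real_, na, no), z = matrix(NA_real_, na, no),
               zz = matrix(NA_real_, na, no))
  rho0 <- initialState(preset)
  k <- 0
  for (ia in seq_len(na)) {
    for (io in seq_len(no)) {
      drv <- driveSpec(spec$drive$target_isotope, amplitude_hz[ia],
                       offset_hz[io], spec$drive$phase_rad)
      sp <- spec
      sp$drive <- drv
      rho <- protocolEvolve(sp, preset, rho0, dt = dt, method = method)
      maps$x[ia, io] <- polarization(rho, system, carbon, "x")
      rho_c <- crusher(rho)
      maps$z[ia, io] <- polarization(rho_c, system, carbon, "z")
      maps$zz[ia, io] <- if (is.null(methyl)) NA_real_
        else twoSpinOrder(rho_c, system, c(carbon, methyl))
      k <- k + 1
      if (progress && k %% 10 == 0) cat(".")
    }
  }
  if (progress) cat("\n")
  argmax <- lapply(maps, function(m) {
    if (all(is.na(m))) return(NULL)
    ij <- which(abs(m) == max(abs(m), na.rm = TRUE), arr.ind = TRUE)[1, ]
    list(amplitude_hz = amplitude_hz[ij[1]], offset_hz = offset_hz[ij[2]],
         value = m[ij[1], ij[2]])
  })
  structure(list(amplitude_hz = amplitude_hz, offset_hz = offset_hz,
                 maps = maps, argmax = argmax, t_hyp_s = spec$t_hyp_s),
            class = "scanResult")
}

#' @export
print.scanResult <- function(x, ...) {
  cat("scanResult:", length(x$amplitude_hz), "amplitudes x",
      length(x$offset_hz), "offsets, t_hyp =", x$t_hyp_s, "s\n")
  for (k in names(x$argmax)) {
    a <- x$argmax[[k]]
    if (is.null(a)) next
    cat(sprintf("  %-2s |max| = %.3g at (nu_A = %g Hz, offset = %g Hz)\n",
                k, a$value, a$amplitude_hz, a$offset_hz))
  }
  invisible(x)
}

#' Scan result to long-format data frame
#'
#' @param x A `scanResult`.
#' @return Data frame with columns `amplitude_hz`, `offset_hz`, `kind`,
#'   `value`.
#' @export
scanToDataFrame <- function(x) {
  out <- do.call(rbind, lapply(names(x$maps), function(k) {
    m <- x$maps[[k]]
    data.frame(amplitude_hz = rep(x$amplitude_hz, times = ncol(m)),
               offset_hz = rep(x$offset_hz, each = nrow(m)),
               kind = k, value = as.vector(m), stringsAsFactors = FALSE)
  }))
  out[order(out$amplitude_hz, out$offset_hz, out$kind), , drop = FALSE]
}

#' Polarization build-up over hyperpolarization time
#'
#' Runs the protocol observable over a grid of `t_hyp` values. Because the
#' generator is time-independent the state is propagated sequentially
#' through the grid.
#'
#' @param spec Template [protocolSpec()].
#' @param t_hyp_s Increasing, non-negative time grid (s).
#' @param preset Preset list.
#' @param kind Observable kind: `"x"` (default for light_sabre) or `"z"`
#'   (default for sheath).
#' @param dt Split-step size (s).
#' @return A [buildUpCurve()].
#' @export
buildupScan <- function(spec, t_hyp_s, preset,
                        kind = if (spec$mode == "sheath") "z" else "x",
                        dt = 1e-3) {
  if (!length(t_hyp_s)) stop("empty t_hyp grid")
  if (any(diff(t_hyp_s) <= 0) || any(t_hyp_s < 0)) {
    stop("t_hyp_s must be non-negative and strictly increasing")
  }
  system <- preset$system
  carbon <- roleLabel(system, "carbon")
  obs <- function(rho) {
    if (kind == "x") polarization(rho, system, carbon, "x")
    else polarization(crusher(rho), system, carbon, "z")
  }
  if (spec$mode == "light_sabre") {
    H <- rotatingFrameHamiltonian(system, preset$couplings, spec$b0_ut,
                                  spec$drive)
  } else {
    H <- labHamiltonian(system, preset$couplings, spec$polarization_field_ut)
  }
  gen <- buildGenerator(H, system, preset$exchange)
  t0 <- t_hyp_s[1] == 0
  times <- if (t0) t_hyp_s[-1] else t_hyp_s
  rho0 <- initialState(preset)
  curve <- evolveTimeseries(rho0, gen, times, obs, method = "auto", dt = dt)
  if (t0) {
    curve <- buildUpCurve(t_hyp_s, c(obs(rho0), curve$value))
  }
  attr(curve, "kind") <- kind
  curve
}
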