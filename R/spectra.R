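# Broadband ultralow-field spectrum synthesis.
#
# Emulates broadband (SQUID-style) detection: the FID is the expectation of
# a gamma-weighted sum of single-quantum lowering operators over the chosen
# isotopes, sampled under the full generator (including exchange, which
# produces the lifetime broadening / multiplet collapse), then apodized and
# Fourier transformed.

#' Simulate a broadband FID and spectrum
#'
#' @param state Initial density matrix (e.g. a polarized state).
#' @param generator Lab-frame [buildGenerator()] result (no drive; the
#'   Hamiltonian must be time-independent during acquisition).
#' @param system A [spinSystem()].
#' @param duration Acquisition length (s).
#' @param dwell Dwell time (s); must satisfy Nyquist for every detected
#'   Larmor frequency.
#' @param b0_ut Static field (uT), used only for the Nyquist check.
#' @param detect_weights Named per-isotope detection weights, e.g.
#'   `c("13C" = 1)`; each detected spin contributes
#'   `weight * gamma * (I_x - i I_y)`.
#' @param apodization_hz Lorentzian line broadening applied to the FID
#'   (Hz, default 0.1), kept small so that exchange effects dominate the
#'   lineshape.
#' @param substeps Split sub-steps per dwell interval for the dissipative
#'   part (default 4).
#' @param min_peak_frac Peaks below this fraction of the tallest magnitude
#'   peak are not reported (default 0.05).
#' @param zero_fill Zero-filling factor applied before the Fourier transform
#'   (default 4); interpolates the frequency grid so peak positions and
#'   heights are not quantized to the raw resolution `1/duration`.
#' @return A `spectrumRecord`: list with `frequency_hz`, `amplitude`
#'   (complex spectrum), `fid`, `time_s`, and `lines` (data frame with
#'   `center_hz`, `height`, `fwhm_hz`).
#' @export
simulateSpectrum <- function(state, generator, system, duration, dwell,
                             b0_ut, detect_weights = c("13C" = 1),
                             apodization_hz = 0.1, substeps = 4,
                             min_peak_frac = 0.05, zero_fill = 4) {
  isotopes <- vapply(system$spins, `[[`, character(1), "isotope")
  detected <- isotopes[isotopes %in% names(detect_weights)]
  if (!length(detected)) stop("no detected spins for the given weights")
  numax <- max(vapply(system$spins[isotopes %in% names(detect_weights)],
                      spinLarmor, numeric(1), b0_ut = b0_ut))
  if (dwell > 1 / (2 * numax)) {
    stop("dwell ", dwell, " s violates Nyquist for detected Larmor ",
         signif(numax, 5), " Hz (need <= ", signif(1 / (2 * numax), 4), " s)")
  }
  d <- system$dim
  det <- matrix(0i, d, d)
  for (i in seq_len(system$n_spins)) {
    iso <- isotopes[i]
    if (!iso %in% names(detect_weights)) next
    w <- detect_weights[[iso]] * system$spins[[i]]$gamma
    det <- det + w * (spinOperator(system, system$labels[i], "x") -
                        1i * spinOperator(system, system$labels[i], "y"))
  }
  n <- floor(duration / dwell)
  times <- (0:(n - 1)) * dwell
  fid <- complex(n)
  rho <- state
  fid[1] <- sum(det * t(rho))
  step_dt <- dwell / substeps
  for (k in 2:n) {
    rho <- evolveSplit(rho, generator, dwell, dt = step_dt)
    fid[k] <- sum(det * t(rho))
  }
  apo <- exp(-pi * apodization_hz * times)
  nz <- n * max(1L, as.integer(zero_fill))
  spec <- stats::fft(c(fid * apo, complex(nz - n)))
  freq <- (0:(nz - 1)) / (nz * dwell)
  keep <- freq <= 1 / (2 * dwell)
  rec <- structure(list(frequency_hz = freq[keep],
                        amplitude = spec[keep],
                        fid = fid, time_s = times,
                        apodization_hz = apodization_hz),
                   class = "spectrumRecord")
  rec$lines <- measureLines(rec$frequency_hz, Mod(rec$amplitude),
                            min_peak_frac = min_peak_frac)
  rec
}

#' Locate peaks and measure linewidths in a magnitude spectrum
#'
#' Local maxima above `min_peak_frac` of the global maximum are reported
#' with their full width at half maximum, obtained by linear interpolation
#' of the half-height crossings.
#'
#' @param frequency_hz Increasing frequency axis.
#' @param magnitude Non-negative spectrum magnitude.
#' @param min_peak_frac Peak report threshold relative to the maximum.
#' @return Data frame with `center_hz`, `height`, `fwhm_hz`.
#' @export
measureLines <- function(frequency_hz, magnitude, min_peak_frac = 0.05) {
  n <- length(magnitude)
  if (n < 3L) return(data.frame(center_hz = numeric(0), height = numeric(0),
                                fwhm_hz = numeric(0)))
  thr <- min_peak_frac * max(magnitude)
  is_peak <- which(magnitude[2:(n - 1)] > magnitude[1:(n - 2)] &
                   magnitude[2:(n - 1)] >= magnitude[3:n]) + 1L
  is_peak <- is_peak[magnitude[is_peak] >= thr]
  out <- lapply(is_peak, function(p) {
    half <- magnitude[p] / 2
    i <- p
    while (i > 1 && magnitude[i - 1] < magnitude[i] &&
           magnitude[i - 1] > half) i <- i - 1
    fl <- if (i > 1 && magnitude[i - 1] <= half) {
      stats::approx(magnitude[c(i - 1, i)], frequency_hz[c(i - 1, i)],
                    xout = half)$y
    } else NA_real_
    j <- p
    while (j < n && magnitude[j + 1] < magnitude[j] &&
           magnitude[j + 1] > half) j <- j + 1
    fr <- if (j < n && magnitude[j + 1] <= half) {
      stats::approx(magnitude[c(j + 1, j)], frequency_hz[c(j + 1, j)],
                    xout = half)$y
    } else NA_real_
    data.frame(center_hz = frequency_hz[p], height = magnitude[p],
               fwhm_hz = fr - fl)
  })
  do.call(rbind, c(out, list(data.frame(center_hz = numeric(0),
                                        height = numeric(0),
                                        fwhm_hz = numeric(0)))))
}

#' @export
print.spectrumRecord <- function(x, ...) {
  cat("spectrumRecord:", length(x$frequency_hz), "points, ",
      signif(max(x$frequency_hz), 5), "Hz bandwidth\n")
  if (nrow(x$lines)) {
    cat("  lines:\n")
    print(x$lines, row.names = FALSE)
  }
  invisible(x)
}

#' Export a spectrum to CSV
#'
#' Columns `frequency_hz`, `real`, `imag`.
#'
#' @param record A `spectrumRecord`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
writeSpectrumCsv <- function(record, path) {
  df <- data.frame(frequency_hz = record$frequency_hz,
                   real = Re(record$amplitude),
                   imag = Im(record$amplitude))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
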