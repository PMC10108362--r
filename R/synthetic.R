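# Seeded generators for experiment-like synthetic data.
#
# These stand in for the SQUID measurements: noisy mono-exponential build-up
# curves, noisy 2D polarization scan maps, and high-SNR spectra with sub-Hz
# lines. Noise is i.i.d. Gaussian (the measurements report only an SNR, so
# the simplest exchangeable model is used); every generator is a pure
# function of its parameters and seed.

#' Gaussian noise specification
#'
#' @param sigma Standard deviation (same units as the signal, >= 0).
#' @param seed Integer seed for reproducibility (or `NULL`).
#' @return A `noiseSpec` list.
#' @export
noiseSpec <- function(sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = "gaussian", sigma = sigma, seed = seed),
            class = "noiseSpec")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a noisy mono-exponential build-up curve
#'
#' The defaults emulate the observed 13C polarization build-up: plateau
#' 1.1 % (averaged basis), time constants around 16-26 s, 12 points over
#' [0, 80] s.
#'
#' @param p_max Plateau polarization fraction (default 0.011).
#' @param T_hyp_s Build-up time constant (s, > 0).
#' @param times Sampling times (s); default 12 points over [0, 80] s.
#' @param noise A [noiseSpec()].
#' @return A [buildUpCurve()] with attribute `truth`.
#' @export
genBuildup <- function(p_max = 0.011, T_hyp_s,
                       times = seq(0, 80, length.out = 12),
                       noise = noiseSpec(0, NULL)) {
  if (!is.finite(T_hyp_s) || T_hyp_s <= 0) stop("T_hyp_s must be > 0")
  mean_vals <- p_max * (1 - exp(-times / T_hyp_s))
  vals <- if (noise$sigma > 0 || !is.null(noise$seed)) {
    withSeed(noise$seed,
             mean_vals + stats::rnorm(length(times), 0, noise$sigma))
  } else mean_vals
  curve <- buildUpCurve(times, vals)
  attr(curve, "truth") <- list(p_max = p_max, T_hyp_s = T_hyp_s,
                               sigma = noise$sigma)
  curve
}

#' Add measurement noise to a scan map
#'
#' Adds i.i.d. Gaussian noise to every grid point of every map, preserving
#' grids and metadata (argmax metadata is recomputed from the noisy maps).
#'
#' @param scan A `scanResult` from [scan2d()].
#' @param noise A [noiseSpec()].
#' @return A noisy `scanResult`.
#' @export
genScanMap <- function(scan, noise) {
  if (!inherits(scan, "scanResult")) stop("scan must be a scanResult")
  out <- scan
  out$maps <- withSeed(noise$seed, lapply(scan$maps, function(m) {
    if (all(is.na(m))) return(m)
    m + stats::rnorm(length(m), 0, noise$sigma)
  }))
  out$argmax <- lapply(out$maps, function(m) {
    if (all(is.na(m))) return(NULL)
    ij <- which(abs(m) == max(abs(m), na.rm = TRUE), arr.ind = TRUE)[1, ]
    list(amplitude_hz = out$amplitude_hz[ij[1]],
         offset_hz = out$offset_hz[ij[2]], value = m[ij[1], ij[2]])
  })
  out
}

#' Generate a synthetic Lorentzian spectrum
#'
#' Sum of Lorentzian lines plus white noise scaled so the tallest peak to
#' noise-RMS ratio equals `snr` (single-shot SQUID spectra reach SNR above
#' 8000 with linewidths below 0.3 Hz).
#'
#' @param centers_hz Line centers (Hz).
#' @param amplitudes Peak heights (recycled; default 1).
#' @param fwhm_hz Full width at half maximum of each line (Hz, > 0).
#' @param snr Peak/noise-RMS ratio; `Inf` for noiseless.
#' @param frequency_hz Frequency axis; default covers the lines with margin
#'   at 0.01 Hz resolution.
#' @param seed Integer seed.
#' @return A `spectrumRecord` (real amplitudes) with measured `lines`.
#' @export
genSpectrum <- function(centers_hz, amplitudes = 1, fwhm_hz, snr = Inf,
                        frequency_hz = NULL, seed = NULL) {
  if (!is.finite(fwhm_hz) || fwhm_hz <= 0) stop("fwhm_hz must be > 0")
  amplitudes <- rep_len(amplitudes, length(centers_hz))
  if (is.null(frequency_hz)) {
    span <- max(centers_hz) - min(centers_hz) + 20 * fwhm_hz
    frequency_hz <- seq(min(centers_hz) - span / 2,
                        max(centers_hz) + span / 2, by = min(0.01, fwhm_hz / 20))
  }
  hw <- fwhm_hz / 2
  signal <- rowSums(vapply(seq_along(centers_hz), function(i) {
    amplitudes[i] * hw^2 / ((frequency_hz - centers_hz[i])^2 + hw^2)
  }, numeric(length(frequency_hz))))
  if (is.finite(snr)) {
    sigma <- max(signal) / snr
    signal <- withSeed(seed,
                       signal + stats::rnorm(length(signal), 0, sigma))
  }
  rec <- structure(list(frequency_hz = frequency_hz,
                        amplitude = signal + 0i,
                        fid = NULL, time_s = NULL,
                        snr = snr),
                   class = "spectrumRecord")
  rec$lines <- measureLines(frequency_hz, pmax(signal, 0),
                            min_peak_frac = 0.2)
  rec
}
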