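# Configuration round-trip, run manifests, and output writing.

.CONFIG_KEYS <- c("spins", "couplings_hz", "tau_ir_s", "b0_ut",
                  "singlet_fraction", "protocol", "scan", "buildup",
                  "seed", "system")
.PROTOCOL_KEYS <- c("mode", "t_hyp_s", "readout", "drive",
                    "polarization_field_ut")
.DRIVE_KEYS <- c("target_isotope", "amplitude_hz", "offset_hz", "phase_rad")

#' Serialize a preset to a plain configuration list
#'
#' @param preset Preset list as from [presetPyruvateSabre()].
#' @return List with keys `spins`, `couplings_hz`, `tau_ir_s`, `b0_ut`.
#' @export
presetToConfig <- function(preset) {
  system <- preset$system
  spins <- lapply(system$spins, function(s) {
    role <- names(system$roles)[system$roles == s$label]
    list(label = s$label, isotope = s$isotope, gamma = s$gamma,
         shift_ppm = s$shift_ppm,
         role = if (length(role)) role else NULL)
  })
  J <- unclass(preset$couplings)
  couplings <- list()
  for (i in seq_len(nrow(J) - 1L)) {
    for (j in (i + 1L):ncol(J)) {
      if (J[i, j] != 0) {
        couplings[[length(couplings) + 1L]] <-
          list(spins = c(rownames(J)[i], colnames(J)[j]), J_hz = J[i, j])
      }
    }
  }
  list(spins = spins, couplings_hz = couplings,
       tau_ir_s = preset$exchange$tau_ir_s, b0_ut = preset$b0_ut)
}

# Rebuild a preset from the config list (falling back to the pyruvate preset
# for any missing block).
configToPreset <- function(config) {
  base_reduced <- identical(config$system, "reduced3")
  if (is.null(config$spins)) {
    preset <- presetPyruvateSabre(reduced = base_reduced)
  } else {
    spins <- lapply(config$spins, function(s) {
      spinSpec(s$label, s$isotope,
               gamma = if (is.null(s$gamma)) gyromagneticRatio(s$isotope)
                       else s$gamma,
               shift_ppm = if (is.null(s$shift_ppm)) 0 else s$shift_ppm)
    })
    roles <- character()
    for (s in config$spins) {
      if (!is.null(s$role)) roles[s$role] <- s$label
    }
    system <- spinSystem(spins, roles)
    pairs <- lapply(config$couplings_hz, function(cp) {
      list(cp$spins[[1]], cp$spins[[2]], cp$J_hz)
    })
    preset <- list(system = system,
                   couplings = couplingNetwork(system, pairs),
                   exchange = NULL, b0_ut = 121)
  }
  if (!is.null(config$tau_ir_s)) {
    if (!is.numeric(config$tau_ir_s) || config$tau_ir_s <= 0) {
      stop("config key tau_ir_s must be a positive number")
    }
    f <- if (is.null(config$singlet_fraction)) 1 else config$singlet_fraction
    preset$exchange <- exchangeModel(
      config$tau_ir_s,
      c(roleLabel(preset$system, "hydride_a"),
        roleLabel(preset$system, "hydride_b")),
      singlet_fraction = f)
  } else if (is.null(preset$exchange)) {
    preset$exchange <- exchangeModel(
      0.031, c(roleLabel(preset$system, "hydride_a"),
               roleLabel(preset$system, "hydride_b")))
  }
  if (!is.null(config$b0_ut)) {
    if (!is.numeric(config$b0_ut) || config$b0_ut < 0) {
      stop("config key b0_ut must be a non-negative number")
    }
    preset$b0_ut <- config$b0_ut
  }
  preset
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming the offending
#' key), applies the pyruvate-SABRE preset defaults for anything omitted,
#' and returns the validated specification. An empty file yields the full
#' preset defaults (121 uT, tau_Ir = 31 ms, the pyruvate J set).
#'
#' @param path Path to a YAML config file.
#' @return A `sabreConfig` list with elements `preset`, `protocol`, `scan`,
#'   `buildup`, `seed`, `raw`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$protocol)) {
    unknown <- setdiff(names(raw$protocol), .PROTOCOL_KEYS)
    if (length(unknown)) {
      stop("unknown config key: protocol.", unknown[1])
    }
    if (!is.null(raw$protocol$drive)) {
      unknown <- setdiff(names(raw$protocol$drive), .DRIVE_KEYS)
      if (length(unknown)) {
        stop("unknown config key: protocol.drive.", unknown[1])
      }
    }
  }
  preset <- configToPreset(raw)
  protocol <- NULL
  if (!is.null(raw$protocol)) {
    p <- raw$protocol
    drive <- if (!is.null(p$drive)) {
      driveSpec(
        target_isotope = if (is.null(p$drive$target_isotope)) "13C"
                         else p$drive$target_isotope,
        amplitude_hz = p$drive$amplitude_hz,
        offset_hz = if (is.null(p$drive$offset_hz)) 0 else p$drive$offset_hz,
        phase_rad = if (is.null(p$drive$phase_rad)) 0 else p$drive$phase_rad)
    } else NULL
    protocol <- protocolSpec(
      mode = if (is.null(p$mode)) "light_sabre" else p$mode,
      t_hyp_s = if (is.null(p$t_hyp_s)) 10 else p$t_hyp_s,
      b0_ut = preset$b0_ut,
      drive = drive,
      polarization_field_ut = if (is.null(p$polarization_field_ut)) 0.36
                              else p$polarization_field_ut,
      readout = if (is.null(p$readout)) "direct_transverse" else p$readout)
  }
  structure(list(preset = preset, protocol = protocol,
                 scan = raw$scan, buildup = raw$buildup,
                 seed = raw$seed, raw = raw),
            class = "sabreConfig")
}

#' Save a configuration list as YAML
#'
#' @param config A plain list (e.g. from [presetToConfig()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run bit-for-bit with the same
#' build: the configuration echo, seed, package version, timestamp, and the
#' list of output files.
#'
#' @param config Configuration list (echoed verbatim).
#' @param seed Integer seed used for the run.
#' @param outputs Character vector of output file names.
#' @return A `runManifest` list.
#' @export
runManifest <- function(config, seed, outputs = character()) {
  structure(list(
    tool = "sabresim",
    version = as.character(utils::packageVersion("sabresim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = outputs), class = "runManifest")
}

#' Write run outputs
#'
#' Tabular results go to CSV with deterministic column order and full
#' double precision; manifests and fit results go to JSON.
#'
#' @param results Named list; supported classes: `scanResult`,
#'   `buildUpCurve`, `spectrumRecord`, `fitResult`, list of
#'   `polarizationRecord`, data frames.
#' @param manifest A [runManifest()] (written as `manifest.json`).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
writeOutputs <- function(results, manifest, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir)
  }
  written <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "scanResult")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      df <- scanToDataFrame(x)
      utils::write.csv(format(df, digits = 17, trim = TRUE), p,
                       row.names = FALSE, quote = FALSE)
    } else if (inherits(x, "buildUpCurve") || is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(format(as.data.frame(x), digits = 17, trim = TRUE),
                       p, row.names = FALSE, quote = FALSE)
    } else if (inherits(x, "spectrumRecord")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      writeSpectrumCsv(x, p)
    } else if (inherits(x, "fitResult")) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      writeFitJson(x, p)
    } else if (is.list(x) && length(x) &&
               all(vapply(x, inherits, logical(1), "polarizationRecord"))) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      writePolarizationCsv(x, p)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    }
    written <- c(written, p)
  }
  manifest$outputs <- basename(written)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mp, auto_unbox = TRUE, digits = NA)
  invisible(c(written, mp))
}
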