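# Shared fixtures: the reduced 3-spin model is the fast oracle system; the
# quartet system (one 13C J-coupled to three equivalent protons) exercises
# multiplet structure and exchange narrowing.

preset3 <- function(...) presetPyruvateSabre(reduced = TRUE)
preset6 <- function(...) presetPyruvateSabre()

quartetSystem <- function(J = 1.2) {
  system <- spinSystem(list(spinSpec("H1", "1H"), spinSpec("H2", "1H"),
                            spinSpec("H3", "1H"), spinSpec("C1", "13C")),
                       c(carbon = "C1"))
  couplings <- couplingNetwork(system, list(
    list("C1", "H1", J), list("C1", "H2", J), list("C1", "H3", J)))
  list(system = system, couplings = couplings)
}

# Carbon prepared with transverse coherence, protons mixed: the detection
# state for spectrum fixtures.
carbonCoherenceState <- function(system) {
  labs <- system$labels
  carbon <- labs[vapply(system$spins, `[[`, character(1), "isotope") == "13C"]
  psi <- c(1, 1) / sqrt(2)
  rest <- setdiff(labs, carbon)
  embedDensity(system, list(
    list(labels = carbon, state = (psi %o% Conj(psi)) + 0i),
    list(labels = rest, state = diag(2^length(rest)) / 2^length(rest))))
}

maxAbsDiff <- function(a, b) max(abs(a - b))
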