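# shared fixtures: small scenes keep the unit tests fast; the acceptance
# tests use the full default scene

smallScene <- function(...) {
  base <- list(shape = c(128, 128, 9), unitsPerCell = 10,
               nucleoliPerCell = 1, nucleoplasmicFoci = 30)
  do.call(sceneConfig, utils::modifyList(base, list(...)))
}

noiseFreeScene <- function(...) {
  args <- utils::modifyList(list(poissonGain = 0, readNoiseSD = 0),
                            list(...))
  do.call(smallScene, args)
}

# match detected units to planted ground truth by xy distance
matchUnits <- function(units, truth, radius = 2) {
  if (nrow(units) == 0 || nrow(truth) == 0)
    return(list(recall = 0, precision = NA_real_, dist = numeric(0)))
  d2 <- outer(units$x, truth$x, "-")^2 + outer(units$y, truth$y, "-")^2
  list(recall = mean(apply(d2, 2, min) <= radius^2),
       precision = mean(apply(d2, 1, min) <= radius^2),
       dist = sqrt(apply(d2, 2, min)))
}

# per-seed CV / dominant period / correlation of a simulated run
simulatedRunStats <- function(cfg, npCfg, seed) {
  tab <- simulateTraces(cfg, npCfg, seed = seed)
  tcNuc <- assembleTimecourse(tab, "nucleolar")
  tcNp <- assembleTimecourse(tab, "nucleoplasmic")
  pg <- fourierPeriodogram(tcNuc)
  list(cvNuc = coefficientOfVariation(tcNuc),
       cvNp = coefficientOfVariation(tcNp),
       dom = dominantPeriod(pg),
       maxAmp = max(amplitudes(pg)),
       r = compartmentCorrelation(tcNuc, tcNp))
}
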