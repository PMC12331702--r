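# Shared fixtures: everything is generated in code at test time.

# Coarse 200-band grid: keeps unit tests fast while spanning the
# visible/NIR/SWIR structure of the full 2000-band grid.
coarseGrid <- function() seq(400, 2390, by = 10)

coarseConstants <- function(seed = 5) {
  syntheticOpticalConstants(coarseGrid(), seed = seed)
}

# A tiny but physically sensible optical-constants CSV on disk.
writeConstantsCSV <- function(path, wl = c(500, 700, 900),
                              n = c(1.4, 1.39, 1.38)) {
  df <- data.frame(
    wavelength_nm = wl, n = n,
    k_ab = c(0.02, 0.05, 0.001), k_cx = c(0.03, 0.001, 0.001),
    k_an = c(0.02, 0.005, 0.001), k_bp = c(0.4, 0.1, 0.05),
    k_w = c(0.001, 0.01, 0.3), k_m = c(0.001, 0.002, 0.05)
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Small labeled table with two "datasets" for protocol tests.
twoDomainTable <- function(n_per = 50, seed = 9) {
  oc <- coarseConstants()
  a <- generateCorpus(n = n_per, constants = oc, seed = seed, domain = "D1")
  b <- generateCorpus(n = n_per, constants = oc, seed = seed + 1, domain = "D2")
  list(a = a, b = b)
}

# Oracle runner: predicts the true traits of the test rows.
oracleRunner <- function(train, test, seed) traits(test)

# Reference single-air-bounded-layer reflectance/transmittance,
# written independently of leafRT for the N = 1 identity check.
singleLayerRT <- function(params, constants, alpha_deg = 40) {
  k <- absorptionSpectrum(params, constants)
  tau <- elementaryTransmission(k)
  nidx <- refractiveIndex(constants)
  talf <- tav(alpha_deg, nidx)
  t12 <- tav(90, nidx)
  t21 <- t12 / nidx^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- (1 - talf) + r21 * tau * Ta
  list(reflectance = Ra, transmittance = Ta)
}
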