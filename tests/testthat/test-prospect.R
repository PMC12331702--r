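# Forward radiative-transfer core: optical-constant I/O, interface
# transmissivity, elementary-layer transmission, plate-model spectra.

test_that("optical-constants CSV loading validates schema and ordering", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeConstantsCSV(path)
  oc <- loadOpticalConstants(path)
  expect_s4_class(oc, "OpticalConstants")
  expect_length(wavelengths(oc), 3L)
  expect_equal(colnames(absorptionCoefficients(oc)),
    c("k_ab", "k_cx", "k_an", "k_bp", "k_w", "k_m"))

  # missing column
  df <- utils::read.csv(path)
  df$k_w <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(loadOpticalConstants(p2), "k_w")

  # duplicated wavelength
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeConstantsCSV(p3, wl = c(500, 700, 700))
  expect_error(loadOpticalConstants(p3), "ordering")

  # negative coefficient with row index in the message
  df <- utils::read.csv(path)
  df$k_ab[2] <- -0.1
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p4, row.names = FALSE)
  expect_error(loadOpticalConstants(p4), "row 2")

  # refractive index below 1
  df <- utils::read.csv(path)
  df$n[1] <- 0.9
  p5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p5, row.names = FALSE)
  expect_error(loadOpticalConstants(p5), "refractive")

  # unsorted but valid rows are sorted on load
  df <- utils::read.csv(path)
  p6 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[c(3, 1, 2), ], p6, row.names = FALSE)
  expect_equal(wavelengths(loadOpticalConstants(p6)), c(500, 700, 900))
})

test_that("optical constants round-trip through write/load", {
  oc <- coarseConstants()
  path <- withr::local_tempfile(fileext = ".csv")
  writeOpticalConstants(oc, path)
  oc2 <- loadOpticalConstants(path)
  expect_equal(wavelengths(oc2), wavelengths(oc))
  expect_equal(absorptionCoefficients(oc2), absorptionCoefficients(oc),
    tolerance = 1e-12)
})

test_that("synthetic constants are deterministic, physical, and band-shaped", {
  a <- syntheticOpticalConstants(seed = 7)
  b <- syntheticOpticalConstants(seed = 7)
  expect_identical(absorptionCoefficients(a), absorptionCoefficients(b))
  expect_identical(refractiveIndex(a), refractiveIndex(b))

  d <- syntheticOpticalConstants(seed = 8)
  expect_false(identical(absorptionCoefficients(a), absorptionCoefficients(d)))

  for (s in 1:5) {
    oc <- syntheticOpticalConstants(seed = s)
    k <- absorptionCoefficients(oc)
    expect_true(all(k >= 0))
    expect_true(all(refractiveIndex(oc) >= 1.3 & refractiveIndex(oc) <= 1.5))
    # chlorophyll band: strong at its red peak, negligible deep in the SWIR
    expect_gt(k[wavelengths(oc) == 670, "k_ab"], k[wavelengths(oc) == 1600, "k_ab"])
  }
  expect_error(syntheticOpticalConstants(numeric(0)), "empty")
})

test_that("tav matches an independent adaptive-quadrature oracle", {
  # oracle: adaptive quadrature of the Fresnel definition (distinct
  # from the package's fixed-node Gauss-Legendre rule)
  tavOracle <- function(alpha_deg, n) {
    a <- alpha_deg * pi / 180
    tF <- function(th) {
      vapply(th, function(x) {
        if (abs(n - 1) < 1e-12) return(1)
        if (x < 1e-12) return(1 - ((n - 1) / (n + 1))^2)
        tht <- asin(min(sin(x) / n, 1))
        rs <- (sin(x - tht) / sin(x + tht))^2
        rp <- (tan(x - tht) / tan(x + tht))^2
        1 - (rs + rp) / 2
      }, numeric(1))
    }
    num <- stats::integrate(function(th) tF(th) * sin(th) * cos(th), 0, a,
      rel.tol = 1e-12)$value
    num / (sin(a)^2 / 2)
  }
  expect_equal(tav(90, 1), 1.0, tolerance = 1e-12)
  for (alpha in c(40, 59, 90)) {
    for (n in c(1, 1.2, 1.4, 1.6)) {
      expect_equal(tav(alpha, n), tavOracle(alpha, n), tolerance = 1e-6)
    }
  }
  # more refractive-index mismatch, more interface reflection
  expect_gt(tav(90, 1.2), tav(90, 1.5))
  # vectorized over n
  expect_equal(tav(40, c(1.2, 1.4)), c(tav(40, 1.2), tav(40, 1.4)))
  expect_error(tav(0, 1.4), "domain")
  expect_error(tav(91, 1.4), "domain")
  expect_error(tav(40, 0.9), "domain")
})

test_that("exponential integral and elementary transmission match quadrature", {
  # E1 oracle by adaptive quadrature of its definition
  e1Oracle <- function(x) {
    stats::integrate(function(t) exp(-t) / t, x, Inf, rel.tol = 1e-13)$value
  }
  for (x in c(0.05, 0.5, 1, 1.5, 4, 20)) {
    expect_equal(expintE1(x), e1Oracle(x), tolerance = 1e-10)
  }
  expect_error(expintE1(0), "domain")

  expect_identical(elementaryTransmission(0), 1)
  expect_lt(elementaryTransmission(50), 1e-10)
  # tau(1) = (1-1)e^-1 + 1*E1(1) = E1(1)
  expect_equal(elementaryTransmission(1), e1Oracle(1), tolerance = 1e-8)
  k <- seq(0, 10, by = 0.05)
  tau <- elementaryTransmission(k)
  expect_true(all(diff(tau) < 0))
  expect_true(all(tau > 0 & tau <= 1))
  expect_error(elementaryTransmission(-0.1), "domain")
})

test_that("absorption spectrum is the N-scaled concentration-weighted sum", {
  oc <- coarseConstants()
  p0 <- leafParams(N = 1.4, Cab = 0, Ccx = 0, Can = 0, Cbp = 0, Cw = 0, Cm = 0)
  expect_true(all(absorptionSpectrum(p0, oc) == 0))

  p1 <- leafParams(N = 1.4, Cab = 30, Ccx = 5, Can = 1.5, Cbp = 0.5, Cw = 0.02, Cm = 0.006)
  p2 <- leafParams(N = 1.4, Cab = 60, Ccx = 10, Can = 3, Cbp = 1, Cw = 0.04, Cm = 0.012)
  expect_equal(absorptionSpectrum(p2, oc), 2 * absorptionSpectrum(p1, oc),
    tolerance = 1e-12)

  # single wavelength, hand arithmetic: 0.1 * 50 / 2 = 2.5
  oc1 <- OpticalConstants(700, 1.4,
    k_ab = 0.1, k_cx = 0, k_an = 0, k_bp = 0, k_w = 0, k_m = 0)
  ph <- leafParams(N = 2, Cab = 50, Ccx = 0, Can = 0, Cbp = 0, Cw = 0, Cm = 0)
  expect_equal(absorptionSpectrum(ph, oc1), 2.5, tolerance = 1e-12)
})

test_that("plate model conserves energy and hits its analytic limits", {
  oc <- coarseConstants()
  # no absorber: R + T = 1 everywhere
  p0 <- leafParams(N = 1.7, Cab = 0, Ccx = 0, Can = 0, Cbp = 0, Cw = 0, Cm = 0)
  rt0 <- leafRT(p0, oc)
  expect_lt(max(abs(1 - rt0$reflectance - rt0$transmittance)), 1e-8)

  # N = 1 equals the independently coded single-layer result
  p1 <- leafParams(N = 1, Cab = 40, Ccx = 8, Can = 1.5, Cbp = 0.3, Cw = 0.02, Cm = 0.006)
  rt1 <- leafRT(p1, oc)
  ref <- singleLayerRT(p1, oc)
  expect_equal(rt1$reflectance, ref$reflectance, tolerance = 1e-10)
  expect_equal(rt1$transmittance, ref$transmittance, tolerance = 1e-10)

  # strong absorber: transmission collapses, output stays finite
  pk <- leafParams(N = 1.5, Cab = 100, Cbp = 1, Cw = 0.05, Cm = 0.009)
  rtk <- leafRT(pk, oc)
  expect_true(all(is.finite(rtk$reflectance) & is.finite(rtk$transmittance)))
  expect_lt(min(rtk$transmittance[wavelengths(oc) > 1900 & wavelengths(oc) < 2000]), 1e-3)

  # degenerate n = 1 grid: no interface, pure absorber stack
  ocu <- OpticalConstants(c(500, 600), 1,
    k_ab = c(0.5, 0.1), k_cx = c(0, 0), k_an = c(0, 0),
    k_bp = c(0, 0), k_w = c(0, 0), k_m = c(0, 0))
  pu <- leafParams(N = 2, Cab = 2)
  rtu <- leafRT(pu, ocu)
  tau <- elementaryTransmission(c(0.5, 0.1))
  expect_equal(rtu$reflectance, c(0, 0), tolerance = 1e-12)
  expect_equal(rtu$transmittance, tau^2, tolerance = 1e-10)
})

test_that("reflectance falls with chlorophyll and transmittance with water", {
  oc <- coarseConstants()
  wl <- wavelengths(oc)
  i670 <- which.min(abs(wl - 670))
  i1940 <- which.min(abs(wl - 1940))
  iface <- ppada:::plateInterface(oc, 40)

  r670 <- vapply(seq(5, 95, by = 10), function(cab) {
    leafRT(leafParams(N = 1.5, Cab = cab, Cw = 0.02, Cm = 0.005), oc,
      interface = iface)$reflectance[i670]
  }, numeric(1))
  expect_true(all(diff(r670) < 0))

  t1940 <- vapply(seq(0.01, 0.05, by = 0.005), function(cw) {
    leafRT(leafParams(N = 1.5, Cab = 40, Cw = cw, Cm = 0.005), oc,
      interface = iface)$transmittance[i1940]
  }, numeric(1))
  expect_true(all(diff(t1940) < 0))
})

test_that("parameters map to traits with the stated units", {
  p <- leafParams(N = 1.3, Cab = 50, Ccx = 10, Can = 1.5, Cbp = 0.2, Cw = 0.02, Cm = 0.005)
  tr <- paramsToTraits(p)
  expect_equal(tr$CHL, 50)
  expect_equal(tr$EWT, 0.02) # 1 g/cm^3 water density: identity on numerals
  expect_equal(tr$LMA, 0.005)
  expect_equal(unname(attr(tr, "units")["EWT"]), "g/cm^2")

  m <- rbind(p, p)
  trm <- paramsToTraits(m)
  expect_equal(nrow(trm), 2L)

  expect_error(leafParams(N = 0.5), "N")
  expect_error(leafParams(Cab = -1), "non-negative")
})
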