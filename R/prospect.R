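#' Default 1-nm wavelength grid
#'
#' 400..2399 nm inclusive at 1-nm step: 2000 bands. The upper edge is
#' 2399 so that the band count matches the 2000-band spectra consumed
#' by the encoder; any strictly increasing grid is accepted elsewhere.
#'
#' @return integer vector of wavelengths (nm).
#' @export
defaultGrid <- function() 400:2399

## Run code under a private RNG stream without disturbing the caller's.
localSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Read a leaf optical-constants table
#'
#' Expects a CSV with header columns `wavelength_nm`, `n`, `k_ab`,
#' `k_cx`, `k_an`, `k_bp`, `k_w`, `k_m` (the layout of the public
#' PROSPECT-D coefficient distribution). Rows are sorted by wavelength;
#' duplicate wavelengths are an ordering error.
#'
#' @param path CSV file path.
#' @return an [OpticalConstants-class].
#' @export
loadOpticalConstants <- function(path) {
  if (!file.exists(path)) stop("optical constants file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "n", COEF_NAMES)
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  if (anyDuplicated(df$wavelength_nm)) {
    dup <- df$wavelength_nm[duplicated(df$wavelength_nm)][1]
    stop("ordering error: wavelengths not strictly increasing (duplicate ", dup, " nm)")
  }
  bad_n <- which(df$n < 1 | !is.finite(df$n))
  if (length(bad_n)) {
    stop("validation error: refractive index < 1 or non-finite at row ", bad_n[1])
  }
  k <- as.matrix(df[, COEF_NAMES])
  bad_k <- which(k < 0 | !is.finite(k), arr.ind = TRUE)
  if (nrow(bad_k)) {
    stop(
      "validation error: negative or non-finite coefficient at row ",
      bad_k[1, 1], " (", COEF_NAMES[bad_k[1, 2]], ")"
    )
  }
  OpticalConstants(df$wavelength_nm, df$n, coefficients = k)
}

#' Write an optical-constants table to CSV
#'
#' @param constants an [OpticalConstants-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOpticalConstants <- function(constants, path) {
  df <- data.frame(
    wavelength_nm = wavelengths(constants),
    n = refractiveIndex(constants),
    absorptionCoefficients(constants),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

gaussBand <- function(wl, center, width, amp) {
  amp * exp(-0.5 * ((wl - center) / width)^2)
}

#' Synthetic leaf optical constants
#'
#' A download-free stand-in for the real PROSPECT-D coefficient tables,
#' built from Gaussian absorption bands at the physiologically expected
#' positions: chlorophyll peaks near 670 and 480 nm, carotenoids near
#' 490 nm, anthocyanins near 550 nm, water bands near 970, 1200, 1450
#' and 1940 nm with a rising far-SWIR tail, a broad dry-matter ramp
#' beyond 1700 nm with cellulose-like features near 2100 and 2300 nm,
#' and brown pigments decaying from 400 nm. The refractive index falls
#' smoothly from about 1.45 to 1.33 across the grid. Band amplitudes
#' and centers receive a small seeded jitter so that distinct seeds
#' give distinct but physically sensible tables.
#'
#' @param grid wavelength grid (nm); default [defaultGrid()].
#' @param seed integer; identical seeds give identical tables.
#' @return an [OpticalConstants-class].
#' @export
syntheticOpticalConstants <- function(grid = defaultGrid(), seed = 1L) {
  if (length(grid) < 1L) stop("empty wavelength grid")
  wl <- as.numeric(grid)
  localSeed(seed, {
    j <- function(lo = 0.92, hi = 1.08) stats::runif(1, lo, hi)
    s <- function(sd = 4) stats::rnorm(1, 0, sd)
    k_ab <- gaussBand(wl, 670 + s(), 38 * j(), 0.065 * j()) +
      gaussBand(wl, 480 + s(), 32 * j(), 0.045 * j())
    k_cx <- gaussBand(wl, 490 + s(), 28 * j(), 0.055 * j()) +
      gaussBand(wl, 460 + s(), 22 * j(), 0.030 * j())
    k_an <- gaussBand(wl, 550 + s(), 34 * j(), 0.050 * j())
    k_bp <- 0.6 * j() * exp(-(wl - 400) / (300 * j()))
    k_w <- gaussBand(wl, 970 + s(), 45 * j(), 1.2 * j()) +
      gaussBand(wl, 1200 + s(), 55 * j(), 2.5 * j()) +
      gaussBand(wl, 1450 + s(), 60 * j(), 35 * j()) +
      gaussBand(wl, 1940 + s(), 70 * j(), 120 * j()) +
      gaussBand(wl, 2500, 180 * j(), 45 * j())
    k_m <- 40 * j() / (1 + exp(-(wl - 1700 - s(10)) / 150)) +
      gaussBand(wl, 2100 + s(), 60 * j(), 18 * j()) +
      gaussBand(wl, 2300 + s(), 50 * j(), 14 * j())
    n <- 1.33 + 0.12 * exp(-(wl - 400) / 1200)
    OpticalConstants(wl, pmin(pmax(n, 1.3), 1.5),
      k_ab = k_ab, k_cx = k_cx, k_an = k_an,
      k_bp = k_bp, k_w = k_w, k_m = k_m
    )
  })
}

fresnelT <- function(theta, n) {
  # transmissivity 1 - (rho_s + rho_p)/2 for light entering a medium of
  # index n (n >= 1, so no total internal reflection on entry);
  # elementwise over recycled theta/n
  len <- max(length(theta), length(n))
  theta <- rep_len(theta, len)
  n <- rep_len(n, len)
  tf <- numeric(len)
  unit <- abs(n - 1) < 1e-12
  tiny <- theta < 1e-9 & !unit
  tf[unit] <- 1
  tf[tiny] <- 1 - ((n[tiny] - 1) / (n[tiny] + 1))^2
  g <- !unit & !tiny
  if (any(g)) {
    th <- theta[g]
    ng <- n[g]
    tht <- asin(pmin(sin(th) / ng, 1))
    rs <- (sin(th - tht) / sin(th + tht))^2
    rp <- (tan(th - tht) / tan(th + tht))^2
    tf[g] <- 1 - (rs + rp) / 2
  }
  tf
}

#' Average transmissivity of a dielectric interface
#'
#' Transmissivity of an air/leaf interface averaged over an isotropic
#' incidence cone of half-angle `alpha_deg`, from Fresnel theory:
#' \deqn{tav(\alpha, n) = \frac{\int_0^\alpha t_F(\theta, n)
#'   \sin\theta\cos\theta\, d\theta}{\int_0^\alpha \sin\theta\cos\theta
#'   \, d\theta}}
#' evaluated by 64-node Gauss-Legendre quadrature. Vectorized over `n`.
#'
#' @param alpha_deg cone half-angle in degrees, in (0, 90].
#' @param n refractive index (scalar or vector), all >= 1.
#' @return average transmissivity in (0, 1], same length as `n`.
#' @export
tav <- function(alpha_deg, n) {
  if (length(alpha_deg) != 1L || !is.finite(alpha_deg) ||
    alpha_deg <= 0 || alpha_deg > 90) {
    stop("domain error: alpha_deg must be in (0, 90]")
  }
  if (any(n < 1)) stop("domain error: refractive index must be >= 1")
  alpha <- alpha_deg * pi / 180
  gl <- pracma::gaussLegendre(64, 0, alpha)
  w <- gl$w * sin(gl$x) * cos(gl$x)
  den <- sin(alpha)^2 / 2
  ln <- length(n)
  tf <- matrix(fresnelT(rep(gl$x, ln), rep(n, each = 64L)), 64L, ln)
  colSums(tf * w) / den
}

#' Exponential integral E1
#'
#' Vectorized \eqn{E_1(x) = \int_x^\infty e^{-t}/t \, dt} for x > 0:
#' power series for x <= 1, modified-Lentz continued fraction for
#' x > 1; absolute accuracy better than 1e-12 on both branches.
#'
#' @param x positive values (vectorized).
#' @return E1(x), same length as `x`.
#' @export
expintE1 <- function(x) {
  if (any(x <= 0 | !is.finite(x))) stop("domain error: x must be finite and > 0")
  out <- numeric(length(x))
  small <- x <= 1
  if (any(small)) {
    xs <- x[small]
    s <- 0
    term <- rep(1, length(xs))
    for (m in 1:30) {
      term <- term * xs / m # x^m / m!
      s <- s + (-1)^(m + 1) * term / m
    }
    out[small] <- -0.577215664901532861 - log(xs) + s
  }
  big <- !small
  if (any(big)) {
    xb <- x[big]
    # E1(x) = exp(-x) / (x + 1 - 1/(x + 3 - 4/(x + 5 - 9/(...))))
    b <- xb + 1
    c <- rep(1e308, length(xb))
    d <- 1 / b
    h <- d
    for (i in 1:80) {
      an <- -i * i
      b <- b + 2
      d <- 1 / (an * d + b)
      c <- b + an / c
      h <- h * d * c
    }
    out[big] <- exp(-xb) * h
  }
  out
}

#' Elementary-layer isotropic transmission
#'
#' Fraction of isotropic radiation transmitted through one elementary
#' absorbing layer with absorption depth `k`:
#' \eqn{\tau(k) = (1 - k) e^{-k} + k^2 E_1(k)}, with \eqn{E_1} the
#' exponential integral and \eqn{\tau(0) = 1} by continuity.
#'
#' @param k non-negative absorption per wavelength (vectorized).
#' @return transmission in (0, 1], strictly decreasing in `k`.
#' @export
elementaryTransmission <- function(k) {
  if (any(k < 0 | !is.finite(k))) stop("domain error: k must be finite and >= 0")
  tau <- rep(1, length(k))
  pos <- k > 0
  if (any(pos)) {
    kp <- k[pos]
    tau[pos] <- pmax((1 - kp) * exp(-kp) + kp^2 * expintE1(kp), 0)
  }
  tau
}

#' Validate and assemble PROSPECT-D leaf parameters
#'
#' The seven inputs of the generalized plate model: structure index N
#' (unitless, >= 1, possibly non-integer), chlorophyll a+b `Cab`
#' (ug/cm^2), carotenoids `Ccx` (ug/cm^2), anthocyanins `Can`
#' (ug/cm^2), brown pigments `Cbp` (unitless), water depth `Cw` (cm)
#' and dry matter `Cm` (g/cm^2).
#'
#' @param N,Cab,Ccx,Can,Cbp,Cw,Cm scalar parameters.
#' @return named numeric vector of length 7.
#' @export
leafParams <- function(N = 1.5, Cab = 40, Ccx = 10, Can = 1.5,
                       Cbp = 0.1, Cw = 0.01, Cm = 0.005) {
  p <- c(N = N, Cab = Cab, Ccx = Ccx, Can = Can, Cbp = Cbp, Cw = Cw, Cm = Cm)
  if (any(!is.finite(p))) stop("leaf parameters must be finite")
  if (p["N"] < 1) stop("structure index N must be >= 1")
  if (any(p[-1] < 0)) stop("concentrations must be non-negative")
  p
}

#' Total absorption spectrum of one elementary layer
#'
#' Concentration-weighted sum of the specific absorption coefficients,
#' spread over the N elementary layers:
#' \deqn{k(\lambda) = (C_{ab} k_{ab} + C_{cx} k_{cx} + C_{an} k_{an} +
#'   C_{bp} k_{bp} + C_w k_w + C_m k_m) / N}
#'
#' @param params a [leafParams()] vector.
#' @param constants an [OpticalConstants-class].
#' @return non-negative vector on the constants grid.
#' @export
absorptionSpectrum <- function(params, constants) {
  params <- leafParams(
    params[["N"]], params[["Cab"]], params[["Ccx"]], params[["Can"]],
    params[["Cbp"]], params[["Cw"]], params[["Cm"]]
  )
  conc <- params[c("Cab", "Ccx", "Can", "Cbp", "Cw", "Cm")]
  drop(absorptionCoefficients(constants) %*% conc) / params[["N"]]
}

#' Precompute interface transmissivities for the plate model
#'
#' The four interface quantities of the first (air-bounded) plate and
#' the internal plates: `talf` = tav(alpha, n) for directional
#' incidence, `t12` = tav(90, n) for diffuse incidence, `t21` =
#' t12 / n^2 for the leaf-to-air direction, plus their reflective
#' complements. These depend only on the constants and the incidence
#' angle, so they can be shared across leaves.
#'
#' @param constants an [OpticalConstants-class].
#' @param alpha_deg incidence cone half-angle (degrees).
#' @return list with `talf`, `ralf`, `t12`, `r12`, `t21`, `r21`.
#' @export
plateInterface <- function(constants, alpha_deg = 40) {
  nidx <- refractiveIndex(constants)
  talf <- tav(alpha_deg, nidx)
  t12 <- tav(90, nidx)
  t21 <- t12 / nidx^2
  list(
    talf = talf, ralf = 1 - talf,
    t12 = t12, r12 = 1 - t12,
    t21 = t21, r21 = 1 - t21
  )
}

#' Leaf reflectance and transmittance via the generalized plate model
#'
#' PROSPECT-D forward model: one air-bounded layer receiving light
#' within an incidence cone of half-angle `alpha_deg` (interface
#' transmissivities from [tav()], internal transmission from
#' [elementaryTransmission()]), stacked with N - 1 further layers
#' through the Stokes composition for a pile of identical plates. N
#' may be non-integer; the Stokes exponents are then real powers. The
#' absorption-free limit (r + t -> 1) switches to the analytic limit
#' form so no NaN can arise.
#'
#' @param params a [leafParams()] vector.
#' @param constants an [OpticalConstants-class].
#' @param alpha_deg incidence cone half-angle (degrees); default 40,
#'   the PROSPECT convention for a leaf surface.
#' @param interface optional precomputed [plateInterface()] (reused
#'   across leaves sharing the same constants and incidence angle).
#' @return list with `wavelength_nm`, `reflectance`, `transmittance`.
#' @export
leafRT <- function(params, constants, alpha_deg = 40, interface = NULL) {
  k <- absorptionSpectrum(params, constants)
  tau <- elementaryTransmission(k)
  N <- params[["N"]]

  if (is.null(interface)) interface <- plateInterface(constants, alpha_deg)
  talf <- interface$talf
  ralf <- interface$ralf
  t12 <- interface$t12
  r12 <- interface$r12
  t21 <- interface$t21
  r21 <- interface$r21

  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- ralf + r21 * tau * Ta
  t <- t12 * tau * t21 / denom
  r <- r12 + r21 * tau * t

  Rsub <- numeric(length(t))
  Tsub <- numeric(length(t))

  lossless <- (r + t) >= 1 - 1e-12
  if (any(lossless)) {
    tl <- t[lossless]
    Tsub[lossless] <- tl / (tl + (1 - tl) * (N - 1))
    Rsub[lossless] <- 1 - Tsub[lossless]
  }
  rest <- !lossless
  mirror0 <- rest & r < 1e-12 # no interface reflection (n = 1)
  if (any(mirror0)) {
    Rsub[mirror0] <- 0
    Tsub[mirror0] <- t[mirror0]^(N - 1)
  }
  opaque <- rest & !mirror0 & t < 1e-200
  if (any(opaque)) {
    Rsub[opaque] <- r[opaque]
    Tsub[opaque] <- 0
  }
  gen <- rest & !mirror0 & !opaque
  if (any(gen)) {
    rg <- r[gen]
    tg <- t[gen]
    D <- sqrt(pmax((1 + rg + tg) * (1 + rg - tg) * (1 - rg + tg) * (1 - rg - tg), 0))
    a <- (1 + rg^2 - tg^2 + D) / (2 * rg)
    b <- (1 - rg^2 + tg^2 + D) / (2 * tg)
    ib <- b^(-(N - 1)) # b >= 1, so ib in (0, 1]: overflow-safe form
    Rsub[gen] <- a * (1 - ib^2) / (a^2 - ib^2)
    Tsub[gen] <- (a^2 - 1) * ib / (a^2 - ib^2)
  }

  den <- 1 - Rsub * r
  Tfull <- Ta * Tsub / den
  Rfull <- Ra + Ta * Rsub * t / den
  list(
    wavelength_nm = wavelengths(constants),
    reflectance = Rfull,
    transmittance = Tfull
  )
}

#' Convert plate-model parameters to functional traits
#'
#' CHL is the chlorophyll a+b content Cab directly; EWT is the water
#' depth Cw converted to areal water mass at unit water density
#' (1 g/cm^3), so the mapping is numerically the identity; LMA is the
#' dry matter content Cm directly.
#'
#' @param params a [leafParams()] vector or an n x 7 parameter matrix.
#' @return data.frame with columns CHL (ug/cm^2), EWT (g/cm^2) and LMA
#'   (g/cm^2); units attached as `attr(, "units")`.
#' @export
paramsToTraits <- function(params) {
  if (is.null(dim(params))) params <- matrix(params, 1, dimnames = list(NULL, names(params)))
  out <- data.frame(
    CHL = params[, "Cab"],
    EWT = params[, "Cw"] * 1, # rho_water = 1 g/cm^3
    LMA = params[, "Cm"]
  )
  attr(out, "units") <- c(CHL = "ug/cm^2", EWT = "g/cm^2", LMA = "g/cm^2")
  out
}
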