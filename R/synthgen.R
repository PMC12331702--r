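#' Parameter sampling ranges for the plate model
#'
#' Per-parameter (low, high) bounds used by [latinHypercube()]. The
#' defaults are the typical biological ranges for the seven inputs:
#' N 1.0-1.9, Cab 0.1-100 ug/cm^2, Ccx 1.0-25.0 ug/cm^2, Can 1.2-1.8
#' ug/cm^2, Cbp 0.01-1.0, Cw 0.01-0.05 cm, Cm 0.004-0.009 g/cm^2.
#'
#' @param ... named length-2 numeric vectors overriding individual
#'   parameter ranges, e.g. `Cab = c(20, 80)`.
#' @return 7 x 2 matrix with rownames N, Cab, Ccx, Can, Cbp, Cw, Cm
#'   and columns `low`, `high`.
#' @export
prospectRanges <- function(...) {
  r <- rbind(
    N = c(1.0, 1.9),
    Cab = c(0.1, 100),
    Ccx = c(1.0, 25.0),
    Can = c(1.2, 1.8),
    Cbp = c(0.01, 1.0),
    Cw = c(0.01, 0.05),
    Cm = c(0.004, 0.009)
  )
  colnames(r) <- c("low", "high")
  over <- list(...)
  bad <- setdiff(names(over), PARAM_NAMES)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) r[nm, ] <- as.numeric(over[[nm]])
  if (any(r[, "low"] >= r[, "high"])) {
    stop("degenerate range: low must be < high for every parameter")
  }
  r
}

#' Latin hypercube sample of plate-model parameters
#'
#' Stratified uniform sampling: for each of the seven dimensions,
#' exactly one sample falls in each of the n equal-width bins of
#' \[low, high), with uniform position within the bin and independent
#' random bin permutations per dimension (no correlation control).
#'
#' @param ranges a [prospectRanges()] matrix.
#' @param n number of samples (>= 1).
#' @param seed integer seed; identical seeds give identical designs.
#' @return n x 7 matrix with columns N, Cab, Ccx, Can, Cbp, Cw, Cm.
#' @export
latinHypercube <- function(ranges = prospectRanges(), n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  u <- localSeed(seed, lhs::randomLHS(as.integer(n), nrow(ranges)))
  lo <- ranges[, "low"]
  hi <- ranges[, "high"]
  x <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(x) <- rownames(ranges)
  x
}

#' Generate a synthetic spectra-trait corpus
#'
#' Draws `n` parameter sets by Latin hypercube sampling, runs the
#' plate model forward for each, optionally adds i.i.d. Gaussian noise
#' to the reflectance (clipped to \[0, 1\]), and attaches the traits
#' derived from the parameters. The sampled parameter matrix is kept
#' in `metadata(x)$params` so traits can be re-derived exactly.
#'
#' @param ranges a [prospectRanges()] matrix.
#' @param n corpus size; the full-scale pretraining corpus uses 20000.
#' @param constants an [OpticalConstants-class].
#' @param seed integer seed (sampling and noise).
#' @param noise_sd additive Gaussian noise sd in reflectance units
#'   (default 0: clean physics).
#' @param alpha_deg incidence cone half-angle for [leafRT()].
#' @param domain domain label for all rows (default "synthetic").
#' @return a [SpectraSet-class] with `n` leaves.
#' @export
generateCorpus <- function(ranges = prospectRanges(), n = 20000,
                           constants, seed = 1L, noise_sd = 0,
                           alpha_deg = 40, domain = "synthetic") {
  if (n < 1) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  params <- latinHypercube(ranges, n, seed = seed)
  interface <- plateInterface(constants, alpha_deg)
  nb <- length(wavelengths(constants))
  refl <- matrix(0, nrow = n, ncol = nb)
  for (i in seq_len(n)) {
    refl[i, ] <- leafRT(params[i, ], constants,
      alpha_deg = alpha_deg, interface = interface
    )$reflectance
  }
  if (noise_sd > 0) {
    noise <- localSeed(deriveSeed(seed, 1L), matrix(stats::rnorm(n * nb, 0, noise_sd), n, nb))
    refl <- pmin(pmax(refl + noise, 0), 1)
  }
  SpectraSet(
    reflectance = refl,
    wavelength_nm = wavelengths(constants),
    traits = paramsToTraits(params),
    domain = domain,
    sample_id = sprintf("%s_s%d_%05d", domain, seed, seq_len(n)),
    params = params
  )
}

#' Domain-shift configuration
#'
#' Describes how a synthetic target domain differs from the source
#' domain: shifted/narrowed parameter ranges, a per-band multiplicative
#' gain, an additive offset, Gaussian sensor noise, and spectral
#' smoothing — emulating the between-dataset variability of real
#' multi-ecosystem, multi-instrument leaf spectra collections.
#'
#' @param source_ranges sampling ranges of the source domain.
#' @param target_ranges sampling ranges of the target domain.
#' @param gain multiplicative gain, scalar or per-band vector (> 0).
#' @param offset additive reflectance offset, scalar or per-band.
#' @param noise_sd Gaussian noise sd in reflectance units (>= 0).
#' @param smooth_fwhm Gaussian smoothing kernel FWHM in nm (0 = none).
#' @param n_source,n_target per-domain sample counts (>= 1).
#' @param fewshot_frac fraction of target rows flagged as the labeled
#'   few-shot subset (default 0.1).
#' @param seed integer seed.
#' @return a list of class `DomainShiftConfig`.
#' @export
domainShiftConfig <- function(source_ranges = prospectRanges(),
                              target_ranges = prospectRanges(),
                              gain = 1, offset = 0, noise_sd = 0,
                              smooth_fwhm = 0, n_source = 500,
                              n_target = 500, fewshot_frac = 0.1,
                              seed = 1L) {
  if (any(gain <= 0)) stop("gain must be > 0")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  if (n_source < 1 || n_target < 1) stop("sample counts must be >= 1")
  if (fewshot_frac < 0 || fewshot_frac > 1) stop("fewshot_frac must be in [0, 1]")
  structure(
    list(
      source_ranges = source_ranges, target_ranges = target_ranges,
      gain = gain, offset = offset, noise_sd = noise_sd,
      smooth_fwhm = smooth_fwhm, n_source = n_source,
      n_target = n_target, fewshot_frac = fewshot_frac,
      seed = as.integer(seed)
    ),
    class = "DomainShiftConfig"
  )
}

gaussSmooth <- function(x, fwhm, step = 1) {
  # row-wise Gaussian smoothing with edge renormalization
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / step
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  ones <- rep(1, ncol(x))
  norm <- stats::filter(ones, kern, sides = 2)
  sm <- t(apply(x, 1, function(r) {
    v <- stats::filter(r, kern, sides = 2)
    as.numeric(v / norm)
  }))
  edge <- which(is.na(sm[1, ]))
  if (length(edge)) {
    # renormalized partial kernel at the edges
    for (jj in edge) {
      idx <- max(1, jj - half):min(ncol(x), jj + half)
      kk <- kern[idx - jj + half + 1]
      sm[, jj] <- as.numeric(x[, idx, drop = FALSE] %*% (kk / sum(kk)))
    }
  }
  sm
}

#' Generate a matched source/target domain pair
#'
#' The source table is a clean corpus from `source_ranges`; the target
#' table is drawn from the (possibly shifted) `target_ranges` and then
#' distorted by per-band gain, offset, Gaussian smoothing and additive
#' noise, finally clipped to \[0, 1\]. A seeded random subset of target
#' rows is flagged `fewshot` for use as the labeled target data during
#' adaptation.
#'
#' @param cfg a [domainShiftConfig()].
#' @param constants an [OpticalConstants-class].
#' @param alpha_deg incidence cone half-angle for [leafRT()].
#' @return list with elements `source` and `target`, both
#'   [SpectraSet-class] objects.
#' @export
makeDomainPair <- function(cfg, constants, alpha_deg = 40) {
  stopifnot(inherits(cfg, "DomainShiftConfig"))
  src <- generateCorpus(cfg$source_ranges, cfg$n_source, constants,
    seed = deriveSeed(cfg$seed, 2L), alpha_deg = alpha_deg, domain = "source"
  )
  tgt <- generateCorpus(cfg$target_ranges, cfg$n_target, constants,
    seed = deriveSeed(cfg$seed, 3L), alpha_deg = alpha_deg, domain = "target"
  )
  nb <- nrow(tgt)
  refl <- reflectance(tgt)
  refl <- sweep(refl, 2, rep_len(cfg$gain, nb), "*")
  refl <- sweep(refl, 2, rep_len(cfg$offset, nb), "+")
  refl <- gaussSmooth(refl, cfg$smooth_fwhm)
  if (cfg$noise_sd > 0) {
    refl <- refl + localSeed(
      deriveSeed(cfg$seed, 4L),
      matrix(stats::rnorm(length(refl), 0, cfg$noise_sd), nrow(refl), ncol(refl))
    )
  }
  refl <- pmin(pmax(refl, 0), 1)
  nfew <- round(cfg$fewshot_frac * cfg$n_target)
  few <- rep(FALSE, cfg$n_target)
  if (nfew > 0) {
    few[localSeed(deriveSeed(cfg$seed, 5L), sample.int(cfg$n_target, nfew))] <- TRUE
  }
  target <- SpectraSet(
    reflectance = refl,
    wavelength_nm = wavelengths(tgt),
    traits = traits(tgt),
    domain = "target",
    sample_id = colData(tgt)$sample_id,
    fewshot = few,
    params = metadata(tgt)$params
  )
  list(source = src, target = target)
}

## Deterministic per-stage seed fan-out from one global seed (kept
## below 2^31 so it is a valid R integer seed).
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %% 2147483629)
}
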