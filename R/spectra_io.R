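META_COLS <- c("sample_id", "dataset", "domain", "labeled", "fewshot", TRAIT_NAMES)

#' Read a wide spectra-trait CSV
#'
#' Reads the wide-table dialect used by public leaf spectral libraries:
#' one row per leaf, an id column, an optional `dataset`/`domain`
#' column, optional CHL/EWT/LMA trait columns, and one reflectance
#' column per band whose header is the band wavelength in nm.
#' Reflectance slightly outside \[0, 1\] (within 0.01, i.e. sensor
#' noise) is clipped; larger excursions are a validation error.
#'
#' @param path CSV path.
#' @return a [SpectraSet-class]; rows lacking any trait are unlabeled.
#' @export
readSpectraTable <- function(path) {
  if (!file.exists(path)) stop("spectra table not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE, header = TRUE)
  hdr <- colnames(df)
  wl <- suppressWarnings(as.numeric(hdr))
  is_band <- !is.na(wl)
  unknown <- hdr[!is_band & !hdr %in% META_COLS]
  if (length(unknown)) {
    stop("schema error: unparseable band header(s): ", paste(unknown, collapse = ", "))
  }
  if (sum(is_band) < 1) stop("schema error: no band columns found")
  ord <- order(wl[is_band])
  refl <- as.matrix(df[, which(is_band)[ord], drop = FALSE])
  wl <- wl[is_band][ord]
  if (any(!is.finite(refl))) stop("validation error: missing/non-finite reflectance")
  if (any(refl < -0.01 | refl > 1.01)) {
    stop("validation error: reflectance outside [-0.01, 1.01]")
  }
  refl <- pmin(pmax(refl, 0), 1)
  n <- nrow(df)
  id <- if ("sample_id" %in% hdr) as.character(df$sample_id) else sprintf("leaf_%04d", seq_len(n))
  dom <- if ("dataset" %in% hdr) {
    as.character(df$dataset)
  } else if ("domain" %in% hdr) as.character(df$domain) else "unknown"
  tr <- NULL
  if (all(TRAIT_NAMES %in% hdr)) {
    tr <- as.matrix(df[, TRAIT_NAMES])
  } else if (any(TRAIT_NAMES %in% hdr)) {
    tr <- matrix(NA_real_, n, 3, dimnames = list(NULL, TRAIT_NAMES))
    for (tn in intersect(TRAIT_NAMES, hdr)) tr[, tn] <- df[[tn]]
  }
  few <- if ("fewshot" %in% hdr) as.logical(df$fewshot) else FALSE
  SpectraSet(refl, wl, traits = tr, domain = dom, sample_id = id, fewshot = few)
}

#' Write a SpectraSet as a wide CSV
#'
#' Inverse of [readSpectraTable()]: full double precision, so a
#' write/read round trip preserves reflectance and traits.
#'
#' @param x a [SpectraSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectraTable <- function(x, path) {
  refl <- reflectance(x)
  colnames(refl) <- as.character(wavelengths(x))
  df <- data.frame(
    sample_id = colData(x)$sample_id,
    dataset = domainLabels(x),
    fewshot = fewShot(x),
    traits(x),
    refl,
    check.names = FALSE
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation of each leaf's reflectance onto `grid`; traits,
#' labels and metadata are unchanged. The grid must lie within the
#' table's wavelength span (no extrapolation).
#'
#' @param x a [SpectraSet-class].
#' @param grid target wavelengths (nm), strictly increasing.
#' @return a resampled [SpectraSet-class].
#' @export
resampleToGrid <- function(x, grid) {
  wl <- wavelengths(x)
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    stop("extrapolation error: grid outside the table's wavelength span")
  }
  if (length(grid) == length(wl) && all(grid == wl)) return(x)
  old <- reflectance(x)
  new <- t(apply(old, 1, function(r) stats::approx(wl, r, xout = grid)$y))
  SpectraSet(new, grid,
    traits = traits(x), domain = domainLabels(x),
    sample_id = colData(x)$sample_id, fewshot = fewShot(x),
    params = metadata(x)$params,
    standardized = isTRUE(metadata(x)$standardized)
  )
}

#' Per-band standardization statistics from a training split
#'
#' Means and standard deviations per band, computed on training rows
#' only so that later [standardize()] calls on validation/test rows
#' use no test-set information.
#'
#' @param train a [SpectraSet-class] with at least one leaf.
#' @return object of class `BandStats`: list with `wavelength_nm`,
#'   `mean`, `sd`.
#' @export
fitBandStats <- function(train) {
  if (ncol(train) < 1) stop("training table is empty")
  refl <- reflectance(train)
  structure(
    list(
      wavelength_nm = wavelengths(train),
      mean = colMeans(refl),
      sd = apply(refl, 2, stats::sd)
    ),
    class = "BandStats"
  )
}

#' Standardize spectra with frozen band statistics
#'
#' Per-band z-scoring using a [fitBandStats()] object (always fit on a
#' training split). Bands with zero spread are centered but not
#' scaled. The result is flagged `standardized` in its metadata, where
#' the statistics are kept so [unstandardize()] can invert exactly.
#'
#' @param x a [SpectraSet-class].
#' @param stats a `BandStats` object.
#' @return standardized [SpectraSet-class].
#' @export
standardize <- function(x, stats) {
  stopifnot(inherits(stats, "BandStats"))
  if (length(stats$mean) != nrow(x)) stop("band-count mismatch between table and stats")
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(reflectance(x), 2, stats$mean, "-"), 2, sd_safe, "/")
  out <- SpectraSet(z, wavelengths(x),
    traits = traits(x), domain = domainLabels(x),
    sample_id = colData(x)$sample_id, fewshot = fewShot(x),
    params = metadata(x)$params, standardized = TRUE
  )
  metadata(out)$band_stats <- stats
  out
}

#' Invert a standardization
#'
#' @param x a standardized [SpectraSet-class].
#' @param stats the `BandStats` used to standardize; defaults to the
#'   ones recorded in `metadata(x)`.
#' @return the de-standardized [SpectraSet-class].
#' @export
unstandardize <- function(x, stats = metadata(x)$band_stats) {
  stopifnot(inherits(stats, "BandStats"))
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  raw <- sweep(sweep(reflectance(x), 2, sd_safe, "*"), 2, stats$mean, "+")
  out <- SpectraSet(raw, wavelengths(x),
    traits = traits(x), domain = domainLabels(x),
    sample_id = colData(x)$sample_id, fewshot = fewShot(x),
    params = metadata(x)$params
  )
  out
}
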