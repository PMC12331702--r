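#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @import SummarizedExperiment
NULL

COEF_NAMES <- c("k_ab", "k_cx", "k_an", "k_bp", "k_w", "k_m")
PARAM_NAMES <- c("N", "Cab", "Ccx", "Can", "Cbp", "Cw", "Cm")
TRAIT_NAMES <- c("CHL", "EWT", "LMA")

#' OpticalConstants: leaf optical-constant tables
#'
#' Holds a strictly increasing wavelength grid together with the leaf
#' refractive index n(lambda) and one specific absorption coefficient
#' spectrum per biochemical constituent: chlorophyll a+b (`k_ab`),
#' carotenoids (`k_cx`), anthocyanins (`k_an`), brown pigments (`k_bp`),
#' water (`k_w`) and dry matter (`k_m`). These drive the generalized
#' plate model in [leafRT()].
#'
#' @slot wavelength_nm strictly increasing numeric grid (nm).
#' @slot n per-wavelength refractive index, all values >= 1.
#' @slot coefficients numeric matrix (length(grid) x 6) of non-negative
#'   specific absorption coefficients, columns `k_ab`, `k_cx`, `k_an`,
#'   `k_bp`, `k_w`, `k_m`.
#' @export
setClass("OpticalConstants",
  representation(
    wavelength_nm = "numeric",
    n = "numeric",
    coefficients = "matrix"
  )
)

setValidity("OpticalConstants", function(object) {
  wl <- object@wavelength_nm
  msgs <- character()
  if (length(wl) < 1L) msgs <- c(msgs, "empty wavelength grid")
  if (any(!is.finite(wl))) msgs <- c(msgs, "non-finite wavelengths")
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  }
  if (length(object@n) != length(wl)) {
    msgs <- c(msgs, "refractive index length differs from grid")
  }
  if (any(!is.finite(object@n)) || any(object@n < 1)) {
    msgs <- c(msgs, "refractive index must be finite and >= 1")
  }
  k <- object@coefficients
  if (nrow(k) != length(wl)) msgs <- c(msgs, "coefficient rows differ from grid")
  if (!identical(colnames(k), COEF_NAMES)) {
    msgs <- c(msgs, paste("coefficient columns must be", paste(COEF_NAMES, collapse = ", ")))
  }
  if (any(!is.finite(k)) || any(k < 0)) {
    msgs <- c(msgs, "coefficients must be finite and non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OpticalConstants object
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param n refractive index vector (recycled if scalar).
#' @param coefficients matrix with columns `k_ab`, `k_cx`, `k_an`,
#'   `k_bp`, `k_w`, `k_m`; or individual vectors via `...`.
#' @param ... alternatively, named coefficient vectors.
#' @return validated [OpticalConstants-class] object.
#' @export
OpticalConstants <- function(wavelength_nm, n, coefficients = NULL, ...) {
  wavelength_nm <- as.numeric(wavelength_nm)
  if (length(n) == 1L) n <- rep(as.numeric(n), length(wavelength_nm))
  if (is.null(coefficients)) {
    parts <- list(...)
    missing <- setdiff(COEF_NAMES, names(parts))
    if (length(missing)) {
      stop("missing coefficient column(s): ", paste(missing, collapse = ", "))
    }
    coefficients <- do.call(cbind, parts[COEF_NAMES])
  }
  coefficients <- as.matrix(coefficients)
  colnames(coefficients) <- colnames(coefficients) %||% COEF_NAMES
  rownames(coefficients) <- NULL
  new("OpticalConstants",
    wavelength_nm = wavelength_nm, n = as.numeric(n),
    coefficients = coefficients[, COEF_NAMES, drop = FALSE]
  )
}

setMethod("show", "OpticalConstants", function(object) {
  wl <- object@wavelength_nm
  cat(sprintf(
    "OpticalConstants: %d wavelengths [%g..%g nm], n in [%.3f, %.3f]\n",
    length(wl), min(wl), max(wl), min(object@n), max(object@n)
  ))
})

#' SpectraSet: spectra-trait tables as a SummarizedExperiment
#'
#' Rows are spectral bands (with `wavelength_nm` in `rowData`), columns
#' are leaves. The `"reflectance"` assay holds values in \[0, 1\];
#' `colData` carries the traits CHL (ug/cm^2), EWT (g/cm^2), LMA
#' (g/cm^2), a `domain` label, a `labeled` flag and a `fewshot` flag
#' marking the labeled target subset available during adaptation.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msgs <- character()
  if (!"reflectance" %in% assayNames(object)) {
    return("assay 'reflectance' is required")
  }
  if (!"wavelength_nm" %in% colnames(rowData(object))) {
    return("rowData must contain wavelength_nm")
  }
  wl <- rowData(object)$wavelength_nm
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  }
  refl <- assay(object, "reflectance")
  if (any(is.na(refl))) {
    msgs <- c(msgs, "NaN/NA in reflectance")
  } else if (!isTRUE(metadata(object)$standardized) && any(refl < 0 | refl > 1)) {
    msgs <- c(msgs, "reflectance outside [0, 1]")
  }
  cd <- colData(object)
  need <- c("domain", "labeled", "fewshot", TRAIT_NAMES)
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) msgs <- c(msgs, paste("colData missing:", paste(miss, collapse = ", ")))
  if (!length(msgs) && ncol(object) > 0) {
    tr <- as.matrix(cd[, TRAIT_NAMES, drop = FALSE])
    bad <- rowSums(is.na(tr)) > 0 & cd$labeled
    if (any(bad)) msgs <- c(msgs, "labeled rows must have all three traits")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectraSet
#'
#' @param reflectance n x b matrix (rows = leaves, columns = bands) or
#'   b x n matrix when `bands_as_rows = TRUE`; values in \[0, 1\].
#' @param wavelength_nm band wavelengths (nm), strictly increasing.
#' @param traits optional n x 3 matrix/data.frame with columns CHL, EWT,
#'   LMA; `NULL` for fully unlabeled sets.
#' @param domain per-leaf domain/dataset label (recycled if scalar).
#' @param sample_id per-leaf identifiers; autogenerated when `NULL`.
#' @param fewshot logical per-leaf flag marking the labeled target
#'   subset available for few-shot adaptation (default all `FALSE`).
#' @param params optional per-leaf simulator parameter matrix kept in
#'   `metadata(x)$params` (columns N, Cab, Ccx, Can, Cbp, Cw, Cm).
#' @param bands_as_rows set `TRUE` if `reflectance` is already b x n.
#' @param standardized set `TRUE` for z-scored (not \[0, 1\]) spectra.
#' @return a [SpectraSet-class].
#' @export
SpectraSet <- function(reflectance, wavelength_nm, traits = NULL,
                       domain = "unknown", sample_id = NULL,
                       fewshot = FALSE, params = NULL,
                       bands_as_rows = FALSE, standardized = FALSE) {
  refl <- as.matrix(reflectance)
  if (!bands_as_rows) refl <- t(refl)
  nb <- nrow(refl)
  ns <- ncol(refl)
  stopifnot(length(wavelength_nm) == nb)
  if (is.null(sample_id)) sample_id <- sprintf("leaf_%04d", seq_len(ns))
  if (is.null(traits)) {
    tr <- matrix(NA_real_, ns, 3, dimnames = list(NULL, TRAIT_NAMES))
    labeled <- rep(FALSE, ns)
  } else {
    tr <- as.matrix(as.data.frame(traits)[, TRAIT_NAMES, drop = FALSE])
    labeled <- rowSums(is.na(tr)) == 0
  }
  cd <- DataFrame(
    sample_id = sample_id,
    domain = rep_len(as.character(domain), ns),
    labeled = labeled,
    fewshot = rep_len(as.logical(fewshot), ns),
    CHL = tr[, "CHL"], EWT = tr[, "EWT"], LMA = tr[, "LMA"]
  )
  rownames(cd) <- sample_id
  colnames(refl) <- sample_id
  rownames(refl) <- sprintf("b%g", wavelength_nm)
  md <- list(trait_units = c(CHL = "ug/cm^2", EWT = "g/cm^2", LMA = "g/cm^2"))
  if (standardized) md$standardized <- TRUE
  if (!is.null(params)) md$params <- as.matrix(params)
  se <- SummarizedExperiment(
    assays = SimpleList(reflectance = refl),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelength_nm)),
    colData = cd,
    metadata = md
  )
  new("SpectraSet", se)
}

setMethod("show", "SpectraSet", function(object) {
  doms <- table(colData(object)$domain)
  cat(sprintf(
    "SpectraSet: %d leaves x %d bands [%g..%g nm]; labeled %d/%d\n",
    ncol(object), nrow(object),
    min(rowData(object)$wavelength_nm), max(rowData(object)$wavelength_nm),
    sum(colData(object)$labeled), ncol(object)
  ))
  cat("  domains:", paste(sprintf("%s(%d)", names(doms), doms), collapse = ", "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
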