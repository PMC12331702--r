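#' @rdname OpticalConstants-class
#' @param x an object.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname OpticalConstants-class
#' @export
setGeneric("refractiveIndex", function(x) standardGeneric("refractiveIndex"))

#' @rdname OpticalConstants-class
#' @export
setGeneric("absorptionCoefficients", function(x) standardGeneric("absorptionCoefficients"))

#' @rdname SpectraSet-class
#' @param x an object.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectraSet-class
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))

#' @rdname SpectraSet-class
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname SpectraSet-class
#' @export
setGeneric("isLabeled", function(x) standardGeneric("isLabeled"))

#' @rdname SpectraSet-class
#' @export
setGeneric("fewShot", function(x) standardGeneric("fewShot"))

#' @describeIn OpticalConstants-class the wavelength grid (nm).
#' @export
setMethod("wavelengths", "OpticalConstants", function(x) x@wavelength_nm)

#' @describeIn OpticalConstants-class the refractive index n(lambda).
#' @export
setMethod("refractiveIndex", "OpticalConstants", function(x) x@n)

#' @describeIn OpticalConstants-class matrix of the six specific
#'   absorption coefficient spectra.
#' @export
setMethod("absorptionCoefficients", "OpticalConstants", function(x) x@coefficients)

#' @describeIn SpectraSet-class the wavelength grid (nm).
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength_nm)

#' @describeIn SpectraSet-class n x b reflectance matrix (leaves in rows).
#' @export
setMethod("reflectance", "SpectraSet", function(x) t(assay(x, "reflectance")))

#' @describeIn SpectraSet-class n x 3 trait matrix (CHL, EWT, LMA), NA
#'   for unlabeled leaves.
#' @export
setMethod("traits", "SpectraSet", function(x) {
  as.matrix(as.data.frame(colData(x)[, TRAIT_NAMES, drop = FALSE]))
})

#' @describeIn SpectraSet-class per-leaf domain/dataset labels.
#' @export
setMethod("domainLabels", "SpectraSet", function(x) colData(x)$domain)

#' @describeIn SpectraSet-class logical: leaf has all three traits.
#' @export
setMethod("isLabeled", "SpectraSet", function(x) colData(x)$labeled)

#' @describeIn SpectraSet-class logical: leaf is in the few-shot
#'   labeled target subset.
#' @export
setMethod("fewShot", "SpectraSet", function(x) colData(x)$fewshot)
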