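#' @rdname GenotypeData-class
#' @param x a container object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname GenotypeData-class
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname PhenotypeData-class
#' @param x a container object.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname PhenotypeData-class
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))

#' @rdname StrainData-class
#' @param x a container object.
#' @export
setGeneric("strainProportions", function(x) standardGeneric("strainProportions"))

#' @rdname GRM-class
#' @param x a container object.
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname AssocResult-class
#' @param x a container object.
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname AssocResult-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname AssocResult-class
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))

#' @rdname AssocResult-class
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname TraitCorr-class
#' @param x a container object.
#' @export
setGeneric("corrMatrix", function(x) standardGeneric("corrMatrix"))

#' @rdname CMGWASResult-class
#' @param x a container object.
#' @export
setGeneric("qtlTable", function(x) standardGeneric("qtlTable"))

#' @rdname CMGWASResult-class
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))
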