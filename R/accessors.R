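#' @describeIn GenotypeData-class animals x variants dosage matrix.
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @describeIn GenotypeData-class per-variant metadata \code{data.frame}.
#' @export
setMethod("variantInfo", "GenotypeData", function(x) x@variants)

#' @describeIn GenotypeData-class \code{chrom:pos:ref:alt} variant keys.
#' @export
setMethod("variantKeys", "GenotypeData", function(x) x@variants$key)

#' @describeIn GenotypeData-class ordered animal identifiers.
#' @export
setMethod("animalIds", "GenotypeData", function(x) rownames(x@dosages))

#' @describeIn PhenotypeData-class ordered animal identifiers.
#' @export
setMethod("animalIds", "PhenotypeData", function(x) rownames(x@values))

#' @describeIn StrainData-class ordered animal identifiers.
#' @export
setMethod("animalIds", "StrainData", function(x) rownames(x@proportions))

#' @describeIn PhenotypeData-class trait names.
#' @export
setMethod("traitNames", "PhenotypeData", function(x) colnames(x@values))

#' @describeIn PhenotypeData-class animals x traits value matrix (NA = missing).
#' @export
setMethod("phenoValues", "PhenotypeData", function(x) x@values)

#' @describeIn StrainData-class animals x strains proportion matrix.
#' @export
setMethod("strainProportions", "StrainData", function(x) x@proportions)

#' @describeIn GRM-class the dense relationship matrix.
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)

#' @describeIn GRM-class keys of the variants used to build G.
#' @export
setMethod("variantKeys", "GRM", function(x) x@variantKeys)

#' @describeIn AssocResult-class variants x traits signed t matrix.
#' @export
setMethod("tValues", "AssocResult", function(x) x@t)

#' @describeIn AssocResult-class variants x traits P-value matrix.
#' @export
setMethod("pValues", "AssocResult", function(x) x@p)

#' @describeIn AssocResult-class variants x traits effect matrix.
#' @export
setMethod("effectSizes", "AssocResult", function(x) x@effect)

#' @describeIn AssocResult-class variants x traits standard-error matrix.
#' @export
setMethod("stdErrors", "AssocResult", function(x) x@se)

#' @describeIn AssocResult-class variant keys (rows of the matrices).
#' @export
setMethod("variantKeys", "AssocResult", function(x) rownames(x@t))

#' @describeIn AssocResult-class trait names (columns of the matrices).
#' @export
setMethod("traitNames", "AssocResult", function(x) colnames(x@t))

#' @describeIn TraitCorr-class the trait correlation matrix V.
#' @export
setMethod("corrMatrix", "TraitCorr", function(x) x@V)

#' @describeIn CMGWASResult-class selected putative causal variants.
#' @export
setMethod("qtlTable", "CMGWASResult", function(x) x@qtl)

#' @describeIn CMGWASResult-class per-cycle audit log.
#' @export
setMethod("auditLog", "CMGWASResult", function(x) x@audit)

setMethod("show", "GenotypeData", function(object) {
  v <- object@variants
  cat(sprintf("GenotypeData: %d animals x %d variants on %d chromosome(s)\n",
              nrow(object@dosages), ncol(object@dosages),
              length(unique(v$chrom))))
})

setMethod("show", "PhenotypeData", function(object) {
  nm <- colSums(!is.na(object@values))
  cat(sprintf("PhenotypeData: %d animals x %d traits (records per trait: %d-%d)\n",
              nrow(object@values), ncol(object@values), min(nm), max(nm)))
})

setMethod("show", "StrainData", function(object) {
  cat(sprintf("StrainData: %d animals x %d strains\n",
              nrow(object@proportions), ncol(object@proportions)))
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d animals, %d variants (MAF > %g), mean diag %.3f\n",
              nrow(object@matrix), length(object@variantKeys),
              object@mafThreshold, mean(diag(object@matrix))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(paste0("VarianceComponents (n = %d): sigmaG2 = %.4g, ",
                     "sigmaQ2 = %.4g, sigmaE2 = %.4g\n"),
              object@n, object@sigmaG, object@sigmaQ, object@sigmaE))
  cat(sprintf("  logLik %.4f after %d iterations; converged: %s%s\n",
              object@logLik, object@iterations, object@converged,
              if (object@boundary) "; boundary/identifiability warning" else ""))
})

setMethod("show", "AssocResult", function(object) {
  cat(sprintf("AssocResult: %d variants x %d traits (records per trait: %s)\n",
              nrow(object@t), ncol(object@t),
              paste(range(object@nUsed), collapse = "-")))
})

setMethod("show", "TraitCorr", function(object) {
  cat(sprintf("TraitCorr: %d traits over >= %d variants%s\n",
              nrow(object@V), object@nVariants,
              if (object@floored) " (eigenvalue floor applied)" else ""))
})

setMethod("show", "CMGWASResult", function(object) {
  cat(sprintf("CMGWASResult: %d independent putative causal variants in %d cycle(s)\n",
              nrow(object@qtl), max(c(0L, object@audit$cycle))))
})
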