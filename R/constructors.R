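#' Build a GenotypeData object from a dosage matrix and variant metadata
#'
#' @param dosages numeric matrix, animals x variants, entries in \code{[0,2]}
#'   (NA allowed). Row names are animal ids.
#' @param chrom,pos,ref,alt,id per-variant metadata vectors (\code{id} may be
#'   missing; defaults to the variant key).
#' @return A validated \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(dosages, chrom, pos, ref, alt, id = NULL) {
  key <- sprintf("%s:%d:%s:%s", chrom, as.integer(pos), ref, alt)
  if (is.null(id)) id <- key
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  id = as.character(id), key = key,
                  stringsAsFactors = FALSE)
  dosages <- as.matrix(dosages)
  colnames(dosages) <- key
  new("GenotypeData", dosages = dosages, variants = v)
}

#' Build a PhenotypeData object
#'
#' @param values numeric matrix, animals x traits; NA marks a missing record.
#' @return A validated \linkS4class{PhenotypeData}.
#' @export
PhenotypeData <- function(values) new("PhenotypeData", values = as.matrix(values))

#' Build a StrainData object
#'
#' @param proportions numeric matrix, animals x strains, entries in [0,1].
#' @return A validated \linkS4class{StrainData}.
#' @export
StrainData <- function(proportions)
  new("StrainData", proportions = as.matrix(proportions))

#' Subset a GenotypeData by animals and/or variants
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param animals animal ids or indices (default: all).
#' @param variants variant keys or indices (default: all).
#' @return A \linkS4class{GenotypeData}.
#' @export
subsetGenotypes <- function(x, animals = NULL, variants = NULL) {
  d <- x@dosages
  v <- x@variants
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, v$key) else variants
    if (anyNA(j)) stop("unknown variant key(s)")
    # keep genomic order so position monotonicity is preserved
    j <- sort(j)
    d <- d[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
    rownames(v) <- NULL
  }
  if (!is.null(animals)) {
    i <- if (is.character(animals)) match(animals, rownames(d)) else animals
    if (anyNA(i)) stop("unknown animal id(s)")
    d <- d[i, , drop = FALSE]
  }
  new("GenotypeData", dosages = d, variants = v)
}

# Align genotype, phenotype and strain containers on their shared animals.
# Animals missing from any required input are dropped with a message, since
# the analysis operates on unbalanced records anyway.
alignAnimals <- function(genotypes, phenos = NULL, strains = NULL,
                         quiet = FALSE) {
  ids <- animalIds(genotypes)
  if (!is.null(phenos)) ids <- intersect(ids, animalIds(phenos))
  if (!is.null(strains)) ids <- intersect(ids, animalIds(strains))
  nDropped <- length(animalIds(genotypes)) - length(ids)
  if (length(ids) == 0L) stop("no animals shared across inputs")
  if (nDropped > 0L && !quiet)
    message(sprintf("dropping %d animal(s) not present in all inputs", nDropped))
  out <- list(genotypes = subsetGenotypes(genotypes, animals = ids))
  if (!is.null(phenos))
    out$phenos <- PhenotypeData(phenoValues(phenos)[ids, , drop = FALSE])
  if (!is.null(strains))
    out$strains <- StrainData(strainProportions(strains)[ids, , drop = FALSE])
  out
}
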