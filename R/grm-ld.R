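#' Alternative-allele frequency and MAF per variant
#'
#' Frequency is the mean dosage over non-missing entries divided by 2; MAF is
#' \code{min(freq, 1 - freq)}. Variants with no non-missing entries get
#' \code{NA} and are flagged for exclusion downstream.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @return \code{data.frame} with columns \code{key}, \code{freq}, \code{maf},
#'   \code{nMissing}, \code{allMissing}.
#' @export
alleleFreq <- function(genotypes) {
  d <- dosages(genotypes)
  if (nrow(d) < 1L) stop("need at least one animal")
  nm <- colSums(is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  allMissing <- nm == nrow(d)
  freq[allMissing] <- NA
  data.frame(key = variantKeys(genotypes), freq = unname(freq),
             maf = unname(pmin(freq, 1 - freq)), nMissing = unname(nm),
             allMissing = unname(allMissing), stringsAsFactors = FALSE)
}

#' Drop variants at or below a MAF threshold
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param mafThreshold variants are kept when MAF is strictly above this.
#' @return A \linkS4class{GenotypeData}.
#' @export
mafFilter <- function(genotypes, mafThreshold = 0.005) {
  af <- alleleFreq(genotypes)
  keep <- !af$allMissing & af$maf > mafThreshold
  if (!any(keep)) stop("no variant passes MAF > ", mafThreshold)
  subsetGenotypes(genotypes, variants = which(keep))
}

#' Build a VanRaden-style genomic relationship matrix
#'
#' Only variants with MAF strictly above \code{mafThreshold} enter the
#' construction. With \eqn{p_j} the alternative-allele frequency, each dosage
#' column is standardized as \eqn{w_{ij} = (d_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}}
#' and \eqn{G = WW'/m} over the \eqn{m} retained variants. Missing dosages
#' are mean-imputed (i.e. contribute 0 after centring).
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param mafThreshold MAF filter (default 0.005).
#' @return A \linkS4class{GRM}.
#' @export
buildGRM <- function(genotypes, mafThreshold = 0.005) {
  if (nrow(dosages(genotypes)) < 2L) stop("need at least two animals")
  af <- alleleFreq(genotypes)
  keep <- !af$allMissing & af$maf > mafThreshold
  if (!any(keep)) stop("no variant passes MAF > ", mafThreshold)
  d <- dosages(genotypes)[, keep, drop = FALSE]
  p <- af$freq[keep]
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  G <- tcrossprod(W) / ncol(W)
  new("GRM", matrix = G, variantKeys = af$key[keep],
      mafThreshold = mafThreshold)
}

#' Pairwise LD as squared dosage correlation
#'
#' Squared Pearson correlation of the two dosage vectors over the animals
#' non-missing at both variants (the genotype-count convention used by PLINK
#' \code{--r2} on unphased data). If either vector has zero variance over the
#' shared animals the LD is undefined; \code{NA} is returned and callers
#' treat it as \eqn{r^2 = 0}.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param a,b variant keys.
#' @return \eqn{r^2} in \code{[0, 1]}, or \code{NA} when undefined.
#' @export
ldR2 <- function(genotypes, a, b) {
  d <- dosages(genotypes)
  ia <- match(a, variantKeys(genotypes))
  ib <- match(b, variantKeys(genotypes))
  if (is.na(ia) || is.na(ib)) stop("unknown variant key")
  x <- d[, ia]; y <- d[, ib]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  min(cor(x, y)^2, 1)
}

#' LD of one anchor variant against a set of candidates
#'
#' Vectorized \code{ldR2} of \code{anchor} against each candidate. All
#' candidates must lie on the anchor's chromosome (cross-chromosome LD is not
#' meaningful for the selection rules this supports).
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param anchor anchor variant key.
#' @param candidates candidate variant keys (may be empty).
#' @return \code{data.frame} with columns \code{key} and \code{r2}
#'   (\code{NA} where LD is undefined).
#' @export
ldScan <- function(genotypes, anchor, candidates) {
  v <- variantInfo(genotypes)
  ia <- match(anchor, v$key)
  if (is.na(ia)) stop("unknown anchor variant")
  if (length(candidates) == 0L)
    return(data.frame(key = character(), r2 = numeric(),
                      stringsAsFactors = FALSE))
  ic <- match(candidates, v$key)
  if (anyNA(ic)) stop("unknown candidate variant key(s)")
  if (any(v$chrom[ic] != v$chrom[ia]))
    stop("candidates must lie on the anchor's chromosome")
  d <- dosages(genotypes)
  x <- d[, ia]
  r2 <- vapply(ic, function(j) {
    y <- d[, j]
    ok <- !is.na(x) & !is.na(y)
    xs <- x[ok]; ys <- y[ok]
    if (length(xs) < 2L || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    min(cor(xs, ys)^2, 1)
  }, numeric(1))
  data.frame(key = candidates, r2 = r2, stringsAsFactors = FALSE)
}
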