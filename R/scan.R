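# Per-variant GLS association in the rotated basis. All cross-products with
# V^{-1} are computed in bulk; each variant then costs a small Schur
# complement, so conditional scans reuse the same machinery by widening the
# fixed-effect block with the rotated conditioning dosages.

.scanCore <- function(ctx, ytil, vc, Stil, condTil = NULL) {
  a <- vc@sigmaG * ctx$d + vc@sigmaE
  op <- .vinvOp(a, ctx$Qtil, vc@sigmaQ)
  Fm <- cbind(ctx$xtil, condTil)
  VinvF <- op$apply(Fm)
  Gff <- crossprod(Fm, VinvF)
  GffInv <- tryCatch(solve(Gff), error = function(e)
    stop("conditioning set is collinear; cannot invert the fixed-effect block"))
  Gfy <- as.vector(crossprod(VinvF, ytil))
  VinvS <- op$apply(Stil)
  Gfs <- crossprod(Fm, VinvS)
  sVs <- colSums(Stil * VinvS)
  sVy <- as.vector(crossprod(VinvS, ytil))
  denom <- sVs - colSums(Gfs * (GffInv %*% Gfs))
  numer <- sVy - as.vector(crossprod(Gfs, GffInv %*% Gfy))
  list(denom = denom, numer = numer, sVs = sVs)
}

.assembleAssoc <- function(core, hasCond) {
  m <- length(core$denom)
  eff <- se <- tt <- pp <- rep(NA_real_, m)
  flag <- rep("", m)
  bad <- !is.finite(core$denom) | core$denom <= 0
  # collinearity with the fixed-effect block: essentially no residual
  # variance of the test dosage left in the V metric
  coll <- !bad & hasCond & core$denom < 1e-3 * core$sVs
  ok <- !bad & !coll
  eff[ok] <- core$numer[ok] / core$denom[ok]
  se[ok] <- sqrt(1 / core$denom[ok])
  tt[ok] <- eff[ok] / se[ok]
  pp[ok] <- 2 * pnorm(-abs(tt[ok]))
  pp[ok & pp < .Machine$double.xmin] <- .Machine$double.xmin
  flag[bad] <- "zero_variance"
  flag[coll] <- "collinear"
  list(effect = eff, se = se, t = tt, p = pp, flags = flag)
}

#' Mixed-model association scan for one trait
#'
#' Tests each variant, one at a time, as a fixed covariate in the model
#' \eqn{y = 1\mu + C\gamma + s\alpha + Qq + g + e}, where \eqn{C} holds the
#' dosages of the conditioning set (empty for an unconditional scan), under
#' the fixed covariance \eqn{V = G\sigma_g^2 + QQ'\sigma_q^2 + I\sigma_e^2}
#' given by previously estimated variance components. Effects and standard
#' errors come from the GLS normal equations; \eqn{t = \hat\alpha/SE} and
#' two-sided P-values use the standard normal reference.
#'
#' Variants with MAF at or below \code{mafThreshold}, with zero dosage
#' variance, or (in conditional scans) essentially collinear with the
#' conditioning set are skipped with a flag. Conditioning variants are not
#' re-tested. Missing dosages are mean-imputed.
#'
#' @param y named numeric phenotype vector (NA = missing record).
#' @param strains a \linkS4class{StrainData}.
#' @param grm a \linkS4class{GRM} (rows labelled or conformable with y).
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param vc \linkS4class{VarianceComponents} estimated for this trait.
#' @param conditioning character vector of variant keys fitted jointly as
#'   fixed covariates (default none).
#' @param mafThreshold scan MAF filter (default 0.005).
#' @return A one-trait \linkS4class{AssocResult} over all variants of
#'   \code{genotypes}.
#' @export
gwasScan <- function(y, strains, grm, genotypes, vc,
                     conditioning = character(), mafThreshold = 0.005) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by animal id")
  common <- intersect(intersect(ids, animalIds(genotypes)),
                      animalIds(strains))
  y <- y[common]
  geno <- subsetGenotypes(genotypes, animals = common)
  Q <- strainProportions(strains)[common, , drop = FALSE]
  G <- grmMatrix(grm)
  gi <- rownames(G)
  if (!is.null(gi)) G <- G[match(common, gi), match(common, gi), drop = FALSE]
  else if (nrow(G) != length(y)) stop("unlabelled GRM not conformable")
  keep <- !is.na(y)
  if (!any(keep)) stop("no non-missing records")
  S <- .imputedDosages(geno)
  ctx <- .mlmContext(G, keep, Q, S)
  ytil <- as.vector(crossprod(ctx$U, y[keep]))
  .runTraitScan(ctx, ytil, vc, geno, conditioning, mafThreshold,
                trait = "trait")
}

.imputedDosages <- function(genotypes) {
  S <- dosages(genotypes)
  if (anyNA(S)) {
    mu <- colMeans(S, na.rm = TRUE)
    idx <- which(is.na(S), arr.ind = TRUE)
    S[idx] <- mu[idx[, 2]]
  }
  S
}

# run one trait's scan given a prepared context; conditioning keys are
# looked up in the context's rotated dosage matrix
.runTraitScan <- function(ctx, ytil, vc, genotypes, conditioning,
                          mafThreshold, trait, variantSubset = NULL) {
  keys <- variantKeys(genotypes)
  testIdx <- if (is.null(variantSubset)) seq_along(keys)
             else match(variantSubset, keys)
  condIdx <- integer(0)
  if (length(conditioning)) {
    condIdx <- match(conditioning, keys)
    if (anyNA(condIdx)) stop("conditioning variant(s) not in genotypes")
  }
  scanIdx <- setdiff(testIdx, condIdx)
  core <- .scanCore(ctx, ytil, vc,
                    Stil = ctx$Stil[, scanIdx, drop = FALSE],
                    condTil = if (length(condIdx))
                      ctx$Stil[, condIdx, drop = FALSE] else NULL)
  res <- .assembleAssoc(core, hasCond = length(condIdx) > 0)
  m <- length(testIdx)
  out <- list(effect = rep(NA_real_, m), se = rep(NA_real_, m),
              t = rep(NA_real_, m), p = rep(NA_real_, m),
              flags = rep("", m))
  pos <- match(scanIdx, testIdx)
  for (f in c("effect", "se", "t", "p", "flags")) out[[f]][pos] <- res[[f]]
  out$flags[match(intersect(condIdx, testIdx), testIdx)] <- "conditioning"
  # MAF filter over the animals entering this trait's model
  maf <- ctx$mafKeep[testIdx]
  low <- maf <= mafThreshold & out$flags == ""
  for (f in c("effect", "se", "t", "p")) out[[f]][low] <- NA_real_
  out$flags[low] <- "maf"
  nm <- list(keys[testIdx], trait)
  new("AssocResult",
      effect = matrix(out$effect, ncol = 1, dimnames = nm),
      se = matrix(out$se, ncol = 1, dimnames = nm),
      t = matrix(out$t, ncol = 1, dimnames = nm),
      p = matrix(out$p, ncol = 1, dimnames = nm),
      nUsed = length(ytil),
      flags = matrix(out$flags, ncol = 1, dimnames = nm))
}
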