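# Engine shared by scanAllTraits and the conditional loop: aligns the
# inputs once, caches the GRM eigendecomposition and rotated dosage matrix
# per missingness pattern, and caches variance components and unconditional
# per-chromosome results per trait so that later cycles recompute only the
# chromosomes that gained conditioning variants.

.mlmEngine <- function(phenos, genotypes, strains, grm,
                       mafThreshold = 0.005, quiet = TRUE) {
  al <- alignAnimals(genotypes, phenos, strains, quiet = quiet)
  ids <- animalIds(al$genotypes)
  G <- grmMatrix(grm)
  gi <- rownames(G)
  if (!is.null(gi)) {
    if (!all(ids %in% gi)) stop("GRM does not cover all aligned animals")
    G <- G[match(ids, gi), match(ids, gi), drop = FALSE]
  } else if (nrow(G) != length(ids))
    stop("unlabelled GRM not conformable with the aligned animals")
  env <- new.env(parent = emptyenv())
  env$genotypes <- al$genotypes
  env$Y <- phenoValues(al$phenos)
  env$Q <- strainProportions(al$strains)
  env$G <- G
  env$S <- .imputedDosages(al$genotypes)
  env$mafThreshold <- mafThreshold
  env$contexts <- list()
  env$ytil <- list()
  env$vc <- list()
  env$uncond <- list()   # per trait: full-genome unconditional scan pieces
  env
}

.engineContext <- function(env, trait) {
  y <- env$Y[, trait]
  keep <- !is.na(y)
  if (!any(keep)) stop("trait '", trait, "' has no non-missing records")
  key <- paste(which(keep), collapse = ",")
  if (is.null(env$contexts[[key]]))
    env$contexts[[key]] <- .mlmContext(env$G, keep, env$Q, env$S)
  if (is.null(env$ytil[[trait]]))
    env$ytil[[trait]] <- as.vector(crossprod(env$contexts[[key]]$U, y[keep]))
  list(ctx = env$contexts[[key]], ytil = env$ytil[[trait]])
}

.engineVC <- function(env, trait, tol = 1e-6, maxIter = 200L) {
  if (is.null(env$vc[[trait]])) {
    ec <- .engineContext(env, trait)
    if (sum(ec$ctx$keep) < 30L)
      stop("trait '", trait, "' has fewer than 30 records")
    yk <- env$Y[ec$ctx$keep, trait]
    fit <- .remlSolve(ec$ytil, ec$ctx$xtil, ec$ctx$Qtil, ec$ctx$d,
                      var(yk), tol, maxIter, gIdentLike = ec$ctx$gIdentLike)
    env$vc[[trait]] <- new("VarianceComponents",
                           sigmaG = fit$theta[1], sigmaQ = fit$theta[2],
                           sigmaE = fit$theta[3], logLik = fit$ll,
                           n = sum(ec$ctx$keep), converged = fit$converged,
                           boundary = ec$ctx$gIdentLike,
                           iterations = fit$iterations)
  }
  env$vc[[trait]]
}

# scan one trait over a variant subset (keys), with conditioning keys;
# returns plain vectors aligned to the subset
.engineScan <- function(env, trait, variantSubset = NULL,
                        conditioning = character()) {
  ec <- .engineContext(env, trait)
  vc <- .engineVC(env, trait)
  res <- .runTraitScan(ec$ctx, ec$ytil, vc, env$genotypes, conditioning,
                       env$mafThreshold, trait, variantSubset = variantSubset)
  res
}

#' Single-trait mixed-model scans for all traits
#'
#' Runs \code{\link{estimateVarComp}} (once per trait, without any SNP in the
#' model) and the per-variant GLS scan for every trait, honouring each
#' trait's own set of non-missing records. Conditioning sets are applied per
#' chromosome: chromosomes without an entry are scanned unconditionally.
#'
#' @param phenos a \linkS4class{PhenotypeData}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param strains a \linkS4class{StrainData}.
#' @param grm a \linkS4class{GRM}.
#' @param conditioning named list: chromosome -> character vector of variant
#'   keys to fit jointly as fixed covariates on that chromosome.
#' @param mafThreshold scan MAF filter (default 0.005, the same default as
#'   the GRM filter).
#' @return An \linkS4class{AssocResult} over all variants and traits.
#' @export
scanAllTraits <- function(phenos, genotypes, strains, grm,
                          conditioning = list(), mafThreshold = 0.005) {
  env <- .mlmEngine(phenos, genotypes, strains, grm, mafThreshold)
  .engineScanAll(env, conditioning)
}

.engineScanAll <- function(env, conditioning = list()) {
  v <- variantInfo(env$genotypes)
  traits <- colnames(env$Y)
  m <- nrow(v)
  mats <- lapply(1:5, function(i)
    matrix(if (i < 5) NA_real_ else "", m, length(traits),
           dimnames = list(v$key, traits)))
  names(mats) <- c("effect", "se", "t", "p", "flags")
  nUsed <- integer(length(traits))
  for (ti in seq_along(traits)) {
    trait <- traits[ti]
    chromCond <- names(conditioning)[lengths(conditioning) > 0]
    # unconditional chromosomes come from the cached cycle-1 scan
    if (is.null(env$uncond[[trait]])) {
      full <- .engineScan(env, trait)
      env$uncond[[trait]] <- full
    }
    full <- env$uncond[[trait]]
    for (f in names(mats)) mats[[f]][, ti] <- slot(full, f)[, 1]
    for (ch in chromCond) {
      idx <- which(v$chrom == ch)
      part <- .engineScan(env, trait, variantSubset = v$key[idx],
                          conditioning = conditioning[[ch]])
      for (f in names(mats)) mats[[f]][idx, ti] <- slot(part, f)[, 1]
    }
    nUsed[ti] <- full@nUsed
  }
  new("AssocResult", effect = mats$effect, se = mats$se, t = mats$t,
      p = mats$p, nUsed = nUsed, flags = mats$flags)
}

#' Variance components for every trait of a phenotype table
#'
#' @inheritParams scanAllTraits
#' @return Named list of \linkS4class{VarianceComponents}, one per trait.
#' @export
estimateVarCompAll <- function(phenos, genotypes, strains, grm) {
  env <- .mlmEngine(phenos, genotypes, strains, grm)
  out <- lapply(colnames(env$Y), function(tr) .engineVC(env, tr))
  names(out) <- colnames(env$Y)
  out
}
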