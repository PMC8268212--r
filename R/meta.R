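#' Trait-by-trait correlation matrix of signed t-values
#'
#' Pairwise Pearson correlations of per-variant signed t-values between every
#' pair of traits, computed over all variants where both traits have a
#' defined t (the matrix V of the multi-trait statistic). If the resulting
#' matrix is not numerically positive definite, eigenvalues are floored at
#' \code{1e-6} and the matrix re-normalized to unit diagonal before
#' inversion.
#'
#' @param assoc an \linkS4class{AssocResult} (or a plain variants x traits
#'   signed-t matrix).
#' @param minShared minimum number of shared variants required for every
#'   trait pair (default 100).
#' @return A \linkS4class{TraitCorr}.
#' @export
traitCorr <- function(assoc, minShared = 100L) {
  tm <- if (is(assoc, "AssocResult")) tValues(assoc) else as.matrix(assoc)
  if (ncol(tm) < 2L) stop("need at least two traits")
  def <- !is.na(tm)
  shared <- crossprod(def)
  if (any(shared < minShared)) {
    bad <- which(shared < minShared, arr.ind = TRUE)[1, ]
    stop(sprintf("trait pair (%s, %s) shares only %d variants (< %d)",
                 colnames(tm)[bad[1]], colnames(tm)[bad[2]],
                 shared[bad[1], bad[2]], minShared))
  }
  V <- cor(tm, use = "pairwise.complete.obs")
  eig <- eigen(V, symmetric = TRUE)
  floored <- FALSE
  if (min(eig$values) < 1e-6) {
    floored <- TRUE
    vals <- pmax(eig$values, 1e-6)
    V <- eig$vectors %*% (vals * t(eig$vectors))
    D <- 1 / sqrt(diag(V))
    V <- V * (D %o% D)
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(colnames(tm), colnames(tm))
  new("TraitCorr", V = V, Vinv = solve(V), nVariants = as.integer(min(shared)),
      floored = floored)
}

#' Multi-trait meta-analysis chi-squared statistic
#'
#' For each variant, \eqn{\chi^2 = t' V^{-1} t} over the per-trait signed
#' t-values, with degrees of freedom equal to the number of traits, and the
#' corresponding upper-tail P-value. Traits where the variant was not tested
#' contribute per \code{missing}: \code{"zero"} (default) sets the entry to 0
#' with V unchanged — conservative, since it can only shrink the statistic —
#' while \code{"subset"} inverts the submatrix of V restricted to the
#' observed traits (df still the full trait count, for comparability across
#' variants).
#'
#' @param tmat variants x traits matrix of signed t (or an
#'   \linkS4class{AssocResult}).
#' @param V a \linkS4class{TraitCorr}.
#' @param missing how to handle untested traits: \code{"zero"} or
#'   \code{"subset"}.
#' @return \code{data.frame} with columns \code{key}, \code{chisq},
#'   \code{df}, \code{p}; variants with no tested trait get \code{NA}.
#' @export
multiTraitChisq <- function(tmat, V, missing = c("zero", "subset")) {
  missing <- match.arg(missing)
  if (is(tmat, "AssocResult")) tmat <- tValues(tmat)
  tmat <- as.matrix(tmat)
  nt <- ncol(tmat)
  stopifnot(nrow(corrMatrix(V)) == nt)
  anyDef <- rowSums(!is.na(tmat)) > 0
  chisq <- rep(NA_real_, nrow(tmat))
  if (missing == "zero" || !anyNA(tmat)) {
    tz <- tmat
    tz[is.na(tz)] <- 0
    chisq[anyDef] <- rowSums((tz %*% V@Vinv) * tz)[anyDef]
  } else {
    pat <- apply(!is.na(tmat), 1, paste, collapse = "")
    for (pp in unique(pat[anyDef])) {
      idx <- which(pat == pp & anyDef)
      obs <- which(!is.na(tmat[idx[1], ]))
      Vi <- solve(corrMatrix(V)[obs, obs, drop = FALSE])
      tz <- tmat[idx, obs, drop = FALSE]
      chisq[idx] <- rowSums((tz %*% Vi) * tz)
    }
  }
  data.frame(key = rownames(tmat), chisq = chisq, df = nt,
             p = pchisq(chisq, df = nt, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Closed-form false discovery rate from significance counts
#'
#' Evaluates \eqn{FDR = P(1 - A/T) / ((A/T)(1 - P))}, where \eqn{P} is the
#' significance threshold tested, \eqn{A} the number of variants significant
#' at that threshold and \eqn{T} the total number tested. With \eqn{A = 0}
#' the estimate is undefined and \code{NA} is returned; values above 1 are
#' returned as computed (callers may report them as ">100\%").
#'
#' @param p significance threshold in (0, 1).
#' @param A number of significant variants.
#' @param T total number of variants tested.
#' @return The FDR as a fraction.
#' @export
fdrFromCounts <- function(p, A, T) {
  stopifnot(p > 0, p < 1, T > 0, A >= 0)
  if (A > T) stop("A cannot exceed T")
  if (A == 0) return(NA_real_)
  frac <- A / T
  p * (1 - frac) / (frac * (1 - p))
}

#' Format an FDR fraction the way results tables print it
#'
#' @param fdr fraction from \code{\link{fdrFromCounts}}.
#' @param digits decimals in the percentage (default 1).
#' @return Character: e.g. \code{"0.4\%"}, \code{">100\%"} or \code{"NA"}.
#' @export
formatFdr <- function(fdr, digits = 1) {
  if (is.na(fdr)) return("NA")
  if (fdr > 1) return(">100%")
  paste0(formatC(round(100 * fdr, digits), format = "f", digits = digits), "%")
}

#' Genomic inflation factor (lambda)
#'
#' Median-based 1-df definition: each P-value is transformed to its 1-df
#' chi-squared quantile and the median is divided by the null median
#' \code{qchisq(0.5, 1)}.
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @param minP minimum count required (default 100).
#' @return lambda.
#' @export
inflationLambda <- function(pvalues, minP = 100L) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < minP) stop("need at least ", minP, " P-values")
  if (any(pvalues <= 0 | pvalues > 1)) stop("P-values must lie in (0, 1]")
  median(qchisq(pvalues, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Expected vs observed -log10 P for a Q-Q plot
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @return \code{data.frame} with \code{expected} and \code{observed}
#'   -log10(P), sorted ascending.
#' @export
qqData <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (any(pvalues <= 0 | pvalues > 1)) stop("P-values must lie in (0, 1]")
  n <- length(pvalues)
  data.frame(expected = sort(-log10((seq_len(n) - 0.5) / n)),
             observed = sort(-log10(pvalues)))
}
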