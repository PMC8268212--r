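#' @import methods
#' @importFrom stats cor median pchisq pnorm qchisq rnorm runif rexp rgeom
#'   sd var
#' @importFrom utils head
NULL

#' Animals-by-variants dosage matrix with variant metadata
#'
#' Container for allele dosages (counts of the alternative allele, in
#' \code{[0, 2]}) for a set of animals at a set of biallelic variants, with
#' per-variant chromosome, position and allele metadata. Rows are animals
#' (row names are animal identifiers), columns are variants (column names are
#' \code{chrom:pos:ref:alt} keys).
#'
#' @slot dosages numeric matrix, animals x variants, entries in \code{[0, 2]}
#'   or \code{NA}.
#' @slot variants \code{data.frame} with one row per variant and columns
#'   \code{chrom}, \code{pos} (1-based bp), \code{ref}, \code{alt}, \code{id},
#'   \code{key}.
#'
#' @details Positions must be strictly increasing within a chromosome and
#' variant keys unique; validity enforces both.
#'
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosages = "matrix", variants = "data.frame"))

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  v <- object@variants
  msgs <- character()
  need <- c("chrom", "pos", "ref", "alt", "id", "key")
  if (!all(need %in% names(v)))
    msgs <- c(msgs, paste("variants must have columns:", paste(need, collapse = ", ")))
  else {
    if (ncol(d) != nrow(v))
      msgs <- c(msgs, "ncol(dosages) must equal nrow(variants)")
    if (anyDuplicated(v$key))
      msgs <- c(msgs, "duplicate variant keys")
    for (ch in unique(v$chrom)) {
      p <- v$pos[v$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        msgs <- c(msgs, sprintf("positions not strictly increasing on %s", ch))
    }
  }
  if (is.null(rownames(d)))
    msgs <- c(msgs, "dosages must have animal ids as row names")
  else if (anyDuplicated(rownames(d)))
    msgs <- c(msgs, "duplicate animal ids")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msgs <- c(msgs, "dosages outside [0, 2]")
  if (length(msgs)) msgs else TRUE
})

#' Per-animal, per-trait pre-adjusted phenotypes
#'
#' Phenotype values are assumed pre-adjusted for fixed effects; missing
#' records are \code{NA}. Rows are animals, columns traits.
#'
#' @slot values numeric matrix, animals x traits, \code{NA} = missing record.
#' @exportClass PhenotypeData
setClass("PhenotypeData", representation(values = "matrix"))

setValidity("PhenotypeData", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have animal row names and trait column names")
  else {
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate trait names")
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate animal ids")
  }
  if (any(is.infinite(v))) msgs <- c(msgs, "non-finite phenotype values")
  if (length(msgs)) msgs else TRUE
})

#' Animal-by-strain proportion matrix (population structure)
#'
#' The Q matrix of within-breed structure: each row gives one animal's
#' proportions of ancestry from each strain. Entries in \code{[0, 1]}; row
#' sums may be below 1 when pedigree knowledge is partial.
#'
#' @slot proportions numeric matrix, animals x strains.
#' @exportClass StrainData
setClass("StrainData", representation(proportions = "matrix"))

setValidity("StrainData", function(object) {
  p <- object@proportions
  msgs <- character()
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msgs <- c(msgs, "proportions must have animal row names and strain column names")
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "strain proportions outside [0, 1]")
  rs <- rowSums(p)
  if (any(rs > 1 + 1e-6))
    msgs <- c(msgs, "strain proportion row sums exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' Genomic relationship matrix
#'
#' VanRaden-style GRM: \eqn{G = WW'/m} with columns of \eqn{W} centred at
#' \eqn{2p_j} and scaled by \eqn{\sqrt{2p_j(1-p_j)}}, built from the
#' \eqn{m} variants passing the MAF threshold.
#'
#' @slot matrix symmetric numeric matrix, animals x animals.
#' @slot variantKeys keys of variants used in the construction.
#' @slot mafThreshold MAF threshold applied (variants with MAF strictly above
#'   it are used).
#' @exportClass GRM
setClass("GRM", representation(matrix = "matrix", variantKeys = "character",
                               mafThreshold = "numeric"))

setValidity("GRM", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "GRM must be square")
  else if (max(abs(m - t(m))) > 1e-8) msgs <- c(msgs, "GRM must be symmetric")
  if (any(diag(m) <= 0)) msgs <- c(msgs, "GRM diagonal entries must be positive")
  if (length(msgs)) msgs else TRUE
})

#' REML variance components for one trait
#'
#' Components of the mixed model \eqn{y = 1\mu + Qq + g + e} with
#' \eqn{var(g) = G\sigma_g^2}, \eqn{var(q) = I\sigma_q^2} (covariance
#' contribution \eqn{QQ'\sigma_q^2}) and \eqn{var(e) = I\sigma_e^2}.
#'
#' @slot sigmaG genomic variance (squared phenotype units).
#' @slot sigmaQ strain-effect variance.
#' @slot sigmaE residual variance.
#' @slot logLik restricted log-likelihood at convergence.
#' @slot n number of records used.
#' @slot converged logical.
#' @slot boundary logical; \code{TRUE} when the model is unidentifiable
#'   (e.g. a GRM proportional to the identity makes \eqn{\sigma_g^2} and
#'   \eqn{\sigma_e^2} non-separable) or a component was pinned at zero.
#' @slot iterations iterations used.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigmaG = "numeric", sigmaQ = "numeric", sigmaE = "numeric",
                 logLik = "numeric", n = "integer", converged = "logical",
                 boundary = "logical", iterations = "integer"))

setValidity("VarianceComponents", function(object) {
  s <- c(object@sigmaG, object@sigmaQ, object@sigmaE)
  if (any(s < 0)) return("variance components must be non-negative")
  if (all(s == 0)) return("at least one variance component must be positive")
  TRUE
})

#' Per-variant, per-trait mixed-model association results
#'
#' Effect estimates, standard errors, signed t-values (\eqn{t = \hat\alpha /
#' SE}) and two-sided Wald P-values from the per-variant generalized
#' least-squares scan, stored as variants x traits matrices with shared
#' dimnames. \code{NA} marks variants skipped for a trait (below the MAF
#' threshold, zero variance, collinear with the conditioning set, or members
#' of the conditioning set itself).
#'
#' @slot effect,se,t,p numeric matrices, variants x traits.
#' @slot nUsed integer vector of records used per trait.
#' @slot flags character matrix of skip reasons ("" where tested).
#' @exportClass AssocResult
setClass("AssocResult",
  representation(effect = "matrix", se = "matrix", t = "matrix", p = "matrix",
                 nUsed = "integer", flags = "matrix"))

setValidity("AssocResult", function(object) {
  dims <- dim(object@t)
  for (s in c("effect", "se", "p", "flags"))
    if (!identical(dim(slot(object, s)), dims))
      return("all result matrices must share dimensions")
  ok <- !is.na(object@t)
  if (any(object@se[ok] <= 0)) return("SE must be positive where t is defined")
  pv <- object@p[ok]
  if (any(pv <= 0 | pv > 1)) return("P must lie in (0, 1]")
  if (any(sign(object@t[ok]) != sign(object@effect[ok]) &
          object@effect[ok] != 0))
    return("sign of t must match sign of the effect")
  TRUE
})

#' Trait-by-trait correlation matrix of signed t-values
#'
#' The matrix V whose inverse weights the multi-trait chi-squared statistic.
#' Computed over all variants with defined t in both traits of each pair;
#' repaired to positive definiteness by an eigenvalue floor when needed.
#'
#' @slot V correlation matrix, traits x traits.
#' @slot Vinv its inverse.
#' @slot nVariants minimum pairwise variant count used.
#' @slot floored logical; \code{TRUE} if the eigenvalue floor was applied.
#' @exportClass TraitCorr
setClass("TraitCorr",
  representation(V = "matrix", Vinv = "matrix", nVariants = "integer",
                 floored = "logical"))

setValidity("TraitCorr", function(object) {
  V <- object@V
  if (max(abs(V - t(V))) > 1e-8) return("V must be symmetric")
  if (max(abs(diag(V) - 1)) > 1e-6) return("V must have unit diagonal")
  TRUE
})

#' Result of a conditional multi-trait GWAS run
#'
#' @slot qtl \code{data.frame} of selected independent putative causal
#'   variants: key, chromosome, position, selection cycle, multi-trait
#'   chi-squared and P at selection, per-trait signed t profile at selection,
#'   LD-expansion members and span, nearest genes.
#' @slot audit per-cycle \code{data.frame}: cycle, number of significant
#'   variants, number selected, notes.
#' @slot assoc unconditional (cycle-1) \code{AssocResult}.
#' @slot traitCorr the \code{TraitCorr} used in every cycle.
#' @slot meta unconditional multi-trait results (\code{data.frame}).
#' @slot params list of thresholds used.
#' @exportClass CMGWASResult
setClass("CMGWASResult",
  representation(qtl = "data.frame", audit = "data.frame",
                 assoc = "AssocResult", traitCorr = "TraitCorr",
                 meta = "data.frame", params = "list"))
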