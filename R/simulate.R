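#' Configuration for the synthetic study generator
#'
#' Builds the configuration object consumed by \code{\link{simulateGenotypes}}
#' and \code{\link{simulateTraits}}. Defaults emulate a wool-sheep
#' multi-trait study at desk scale: 16 traits measured at two ages with
#' unbalanced records, three within-breed strains, block-structured LD and a
#' skewed MAF spectrum.
#'
#' @param nAnimals number of animals.
#' @param nChromosomes number of simulated autosomes.
#' @param variantsPerChromosome variants per chromosome.
#' @param meanBlockLength mean LD-block length in variants (geometric).
#' @param switchProb per-step haplotype switch probability within a block in
#'   \code{[0, 0.5]}: adjacent within-block allele correlation is
#'   \code{1 - 2*switchProb}, so 0 gives identical columns and 0.5 gives
#'   independent variants.
#' @param mafMin minimum realized MAF of emitted variants.
#' @param spacingBp fixed inter-variant spacing in bp.
#' @param nTraits number of traits.
#' @param traitNames trait names (defaults to 16 wool/breech acronyms).
#' @param heritability per-trait narrow-sense heritability (recycled).
#' @param strainVar strain-effect variance \eqn{\sigma_q^2} in squared
#'   phenotype units.
#' @param nStrains number of strains.
#' @param residualCor trait-by-trait residual correlation: a matrix, or a
#'   single exchangeable off-diagonal value.
#' @param missingness per-trait fraction of missing records (recycled);
#'   defaults to the unbalanced yearling/adult pattern of a two-age design
#'   (yearling traits nearly complete, adult traits roughly half missing).
#' @param qtl \code{data.frame} of planted QTL with columns \code{chrom}
#'   (chromosome index), \code{index} (variant index within the chromosome),
#'   \code{maf}, and a list/matrix column \code{effects} of per-trait effect
#'   sizes in phenotypic SD units — or \code{NULL} for a null simulation.
#' @param seed integer random seed.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(nAnimals = 2000, nChromosomes = 5,
                      variantsPerChromosome = 1000, meanBlockLength = 20,
                      switchProb = 0.1, mafMin = 0.01, spacingBp = 1000,
                      nTraits = 16, traitNames = NULL, heritability = 0.4,
                      strainVar = 0.05, nStrains = 3, residualCor = 0.3,
                      missingness = NULL, qtl = NULL, seed = 1) {
  if (is.null(traitNames)) {
    base <- c("ygfw", "agfw", "ycfw", "acfw", "ysl", "asl", "yfd", "afd",
              "ydcv", "adcv", "ycuv", "acuv", "yss", "ass", "ebwr", "ebcov")
    traitNames <- if (nTraits <= length(base)) base[seq_len(nTraits)]
                  else c(base, sprintf("trait%02d", seq_len(nTraits - length(base))))
  }
  stopifnot(length(traitNames) == nTraits)
  heritability <- rep_len(heritability, nTraits)
  if (any(heritability < 0 | heritability >= 1))
    stop("heritabilities must lie in [0, 1)")
  if (switchProb < 0 || switchProb > 0.5)
    stop("switchProb must lie in [0, 0.5]")
  if (is.null(missingness)) {
    # two-age design: yearling traits mostly recorded, adult traits ~half
    pat <- rep(c(0.08, 0.5), length.out = nTraits)
    pat[nTraits] <- min(pat[nTraits], 0.2)
    missingness <- pat
  }
  missingness <- rep_len(missingness, nTraits)
  if (length(residualCor) == 1L) {
    R <- matrix(residualCor, nTraits, nTraits)
    diag(R) <- 1
    residualCor <- R
  }
  if (!isSymmetric(unname(residualCor)) ||
      min(eigen(residualCor, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("residual correlation matrix must be symmetric positive definite")
  if (!is.null(qtl)) {
    if (anyDuplicated(paste(qtl$chrom, qtl$index)))
      stop("QTL positions must be unique")
    if (nrow(qtl) > nChromosomes * variantsPerChromosome)
      stop("more QTL than variants")
    if (any(qtl$chrom > nChromosomes | qtl$index > variantsPerChromosome |
            qtl$chrom < 1 | qtl$index < 1))
      stop("QTL position outside the simulated genome")
  }
  structure(list(nAnimals = nAnimals, nChromosomes = nChromosomes,
                 variantsPerChromosome = variantsPerChromosome,
                 meanBlockLength = meanBlockLength, switchProb = switchProb,
                 mafMin = mafMin, spacingBp = spacingBp, nTraits = nTraits,
                 traitNames = traitNames, heritability = heritability,
                 strainVar = strainVar, nStrains = nStrains,
                 residualCor = residualCor, missingness = missingness,
                 qtl = qtl, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Convenience builder for a pleiotropic QTL specification
#'
#' @param chrom chromosome index.
#' @param index variant index within the chromosome.
#' @param effects numeric vector of per-trait effects in phenotypic SD units.
#' @param maf allele frequency assigned to the QTL's LD block.
#' @return One-row \code{data.frame} suitable for \code{rbind}-ing into the
#'   \code{qtl} argument of \code{\link{simConfig}}.
#' @export
qtlSpec <- function(chrom, index, effects, maf = 0.3) {
  out <- data.frame(chrom = chrom, index = index, maf = maf)
  out$effects <- list(effects)
  out
}

# Markov-chain haplotype block: stationary Bernoulli(p) with adjacent-state
# correlation lambda = 1 - 2*switchProb.
.simBlock <- function(nHap, len, p, lambda) {
  x <- matrix(0L, nHap, len)
  x[, 1] <- as.integer(runif(nHap) < p)
  if (len > 1L) {
    p1 <- p + lambda * (1 - p)   # P(1 | 1)
    p0 <- p * (1 - lambda)       # P(1 | 0)
    for (j in 2:len) {
      u <- runif(nHap)
      x[, j] <- as.integer(ifelse(x[, j - 1] == 1L, u < p1, u < p0))
    }
  }
  x
}

#' Simulate block-structured genotype dosages
#'
#' Haplotypes are generated per LD block as stationary two-state Markov
#' chains sharing the block's allele frequency: within a block, adjacent
#' variants have allele correlation \code{1 - 2*switchProb}; across blocks
#' variants are independent. Two haplotypes per animal are summed to
#' dosages. Block allele frequencies are drawn log-uniformly on the minor
#' side so the MAF spectrum is skewed toward rare variants; any block whose
#' realized MAF falls below \code{mafMin} is redrawn.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypeData}; planted QTL variants sit in blocks
#'   whose frequency is pinned to the QTL's configured MAF.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nAnimals
  nHap <- 2L * n
  lambda <- 1 - 2 * config$switchProb
  # sampling floor keeps realized-MAF redraws rare at this sample size
  mafLo <- config$mafMin * 1.5 + 3 * sqrt(config$mafMin / nHap)
  mafLo <- min(max(mafLo, config$mafMin), 0.4)
  cols <- vector("list", config$nChromosomes)
  for (ch in seq_len(config$nChromosomes)) {
    m <- config$variantsPerChromosome
    lens <- integer(0)
    while (sum(lens) < m)
      lens <- c(lens, 1L + rgeom(1, 1 / config$meanBlockLength))
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - m)
    lens <- lens[lens > 0L]
    starts <- cumsum(c(1L, lens[-length(lens)]))
    qtlHere <- if (is.null(config$qtl))
      data.frame(index = integer(), maf = numeric())
    else config$qtl[config$qtl$chrom == ch, , drop = FALSE]
    blocks <- vector("list", length(lens))
    for (b in seq_along(lens)) {
      idx <- starts[b]:(starts[b] + lens[b] - 1L)
      qmatch <- if (nrow(qtlHere)) which(qtlHere$index %in% idx) else integer(0)
      for (attempt in 1:50) {
        maf <- if (length(qmatch)) qtlHere$maf[qmatch[1]]
               else exp(runif(1, log(mafLo), log(0.5)))
        p <- if (runif(1) < 0.5) maf else 1 - maf
        h1 <- .simBlock(n, lens[b], p, lambda)
        h2 <- .simBlock(n, lens[b], p, lambda)
        dos <- h1 + h2
        f <- colMeans(dos) / 2
        if (all(pmin(f, 1 - f) >= config$mafMin)) break
        if (attempt == 50) stop("could not reach the configured minimum MAF")
      }
      blocks[[b]] <- dos
    }
    cols[[ch]] <- do.call(cbind, blocks)
  }
  d <- do.call(cbind, cols)
  rownames(d) <- sprintf("animal%05d", seq_len(n))
  chrom <- rep(sprintf("chr%d", seq_len(config$nChromosomes)),
               each = config$variantsPerChromosome)
  pos <- rep(seq_len(config$variantsPerChromosome) * config$spacingBp,
             times = config$nChromosomes)
  GenotypeData(d, chrom = chrom, pos = pos, ref = "A", alt = "B")
}

# strain proportions: most animals purebred, the rest Dirichlet-mixed
.simStrains <- function(n, nStrains) {
  P <- matrix(0, n, nStrains,
              dimnames = list(sprintf("animal%05d", seq_len(n)),
                              sprintf("strain%d", seq_len(nStrains))))
  pure <- runif(n) < 0.7
  main <- sample.int(nStrains, n, replace = TRUE)
  P[cbind(which(pure), main[pure])] <- 1
  if (any(!pure)) {
    g <- matrix(rexp(sum(!pure) * nStrains), ncol = nStrains)
    P[!pure, ] <- g / rowSums(g)
  }
  P
}

#' Simulate correlated phenotypes with planted pleiotropic QTL
#'
#' Generates, for each trait, \eqn{y = \sum_q d_q \beta_{qt} + Qq + g + e}
#' on a unit-variance polygenic baseline: the polygenic term \eqn{g} is drawn
#' with covariance \eqn{h^2 G} from the realized GRM of the simulated
#' genotypes (independent across traits), the strain effect contributes
#' \eqn{QQ'\sigma_q^2}, and residuals are drawn with the configured
#' trait-by-trait correlation and variance \eqn{1 - h^2 - \sigma_q^2}.
#' QTL effects (in SD units of that baseline) are added on top.
#' Missingness is applied per trait completely at random.
#'
#' @param genotypes the \linkS4class{GenotypeData} from
#'   \code{\link{simulateGenotypes}} (same config).
#' @param config the \code{\link{simConfig}} object.
#' @param grm optional precomputed \linkS4class{GRM} of \code{genotypes}
#'   (built at MAF > 0.005 when omitted).
#' @return List with elements \code{phenos} (\linkS4class{PhenotypeData}),
#'   \code{strains} (\linkS4class{StrainData}), \code{grm} (the realized
#'   \linkS4class{GRM} used for the polygenic term) and \code{truth} (list
#'   with the planted-QTL table, per-trait true variance components, and the
#'   latent polygenic values).
#' @export
simulateTraits <- function(genotypes, config, grm = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  n <- nrow(dosages(genotypes))
  nt <- config$nTraits
  h2 <- config$heritability
  sigE2 <- 1 - h2 - config$strainVar
  if (any(sigE2 <= 0))
    stop("heritability + strainVar must be below 1 for every trait")
  Q <- .simStrains(n, config$nStrains)
  if (is.null(grm)) grm <- buildGRM(genotypes, mafThreshold = 0.005)
  G <- grmMatrix(grm)
  L <- chol(G + diag(1e-8 * mean(diag(G)), n))
  gmat <- crossprod(L, matrix(rnorm(n * nt), n, nt)) %*% diag(sqrt(h2), nt)
  qeff <- matrix(rnorm(config$nStrains * nt, sd = sqrt(config$strainVar)),
                 config$nStrains, nt)
  E <- matrix(rnorm(n * nt), n, nt) %*% chol(config$residualCor) %*%
       diag(sqrt(sigE2), nt)
  Y <- gmat + Q %*% qeff + E
  truthQtl <- NULL
  if (!is.null(config$qtl) && nrow(config$qtl)) {
    v <- variantInfo(genotypes)
    idxGlobal <- (config$qtl$chrom - 1L) * config$variantsPerChromosome +
                 config$qtl$index
    keys <- v$key[idxGlobal]
    B <- do.call(rbind, lapply(config$qtl$effects, rep_len, nt))
    Y <- Y + dosages(genotypes)[, idxGlobal, drop = FALSE] %*% B
    truthQtl <- data.frame(key = keys, chrom = v$chrom[idxGlobal],
                           pos = v$pos[idxGlobal], maf = config$qtl$maf,
                           stringsAsFactors = FALSE)
    truthQtl$effects <- lapply(seq_len(nrow(B)), function(i) B[i, ])
  }
  for (t in seq_len(nt)) {
    nMiss <- round(config$missingness[t] * n)
    if (nMiss > 0) Y[sample.int(n, nMiss), t] <- NA
  }
  dimnames(Y) <- list(rownames(dosages(genotypes)), config$traitNames)
  truth <- list(qtl = truthQtl,
                varComponents = data.frame(trait = config$traitNames,
                                           sigmaG = h2,
                                           sigmaQ = config$strainVar,
                                           sigmaE = sigE2),
                polygenic = gmat)
  list(phenos = PhenotypeData(Y), strains = StrainData(Q), grm = grm,
       truth = truth)
}

#' Simulate gene annotation over the simulated chromosomes
#'
#' Places genes uniformly at the configured density with exponential widths.
#' When a planted-QTL truth table is supplied, each QTL additionally gets one
#' gene overlapping it and (when the chromosome is long enough) one gene
#' more than 100 kb away, so nearest-gene window logic is exercised at both
#' extremes.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param density genes per Mb (0 gives an empty gene set).
#' @param seed random seed.
#' @param qtl optional planted-QTL \code{data.frame} (from the simulation
#'   truth) with \code{chrom} and \code{pos} columns.
#' @return A \code{GRanges} with a \code{name} metadata column.
#' @export
simulateGenes <- function(genotypes, density = 10, seed = 1, qtl = NULL) {
  set.seed(seed)
  v <- variantInfo(genotypes)
  out <- list()
  k <- 0L
  for (ch in unique(v$chrom)) {
    len <- max(v$pos[v$chrom == ch]) + 50000
    nGenes <- round(density * len / 1e6)
    if (nGenes > 0) {
      start <- sort(sample.int(len, nGenes, replace = TRUE))
      width <- pmax(200L, round(rexp(nGenes, 1 / 20000)))
      end <- pmin(start + width, len + 100000L)
      for (i in seq_len(nGenes)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, start = start[i], end = end[i],
                               name = sprintf("GENE%04d", k))
      }
    }
  }
  if (!is.null(qtl) && nrow(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      k <- k + 1L
      out[[k]] <- data.frame(chrom = qtl$chrom[i],
                             start = max(1L, qtl$pos[i] - 5000L),
                             end = qtl$pos[i] + 5000L,
                             name = sprintf("QGENE%03dIN", i))
      farStart <- qtl$pos[i] + 150000L
      if (farStart < 1e9) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = qtl$chrom[i], start = farStart,
                               end = farStart + 10000L,
                               name = sprintf("QGENE%03dFAR", i))
      }
    }
  }
  if (k == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$name <- df$name
  sort(gr, ignore.strand = TRUE)
}

#' Simulate a complete study
#'
#' Runs \code{\link{simulateGenotypes}}, \code{\link{simulateTraits}} and
#' \code{\link{simulateGenes}} under one configuration.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param geneDensity genes per Mb for the annotation track.
#' @return List with \code{genotypes}, \code{phenos}, \code{strains},
#'   \code{genes}, \code{grm}, \code{truth}.
#' @export
simulateStudy <- function(config, geneDensity = 10) {
  genotypes <- simulateGenotypes(config)
  tr <- simulateTraits(genotypes, config)
  genes <- simulateGenes(genotypes, density = geneDensity,
                         seed = config$seed + 2L, qtl = tr$truth$qtl)
  list(genotypes = genotypes, phenos = tr$phenos, strains = tr$strains,
       genes = genes, grm = tr$grm, truth = tr$truth)
}
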