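test_that("REML recovers simulated variance components across replicates", {
  est <- matrix(NA_real_, 8, 3)
  for (rep in 1:8) {
    cfg <- simConfig(nAnimals = 400, nChromosomes = 2,
                     variantsPerChromosome = 300, nTraits = 1,
                     heritability = 0.4, strainVar = 0.1, missingness = 0,
                     seed = 500 + rep)
    sim <- simulateStudy(cfg, geneDensity = 0)
    vc <- estimateVarComp(phenoValues(sim$phenos)[, 1], sim$strains, sim$grm,
                          grmIds = animalIds(sim$genotypes))
    expect_true(vc@converged)
    est[rep, ] <- c(vc@sigmaG, vc@sigmaQ, vc@sigmaE)
  }
  truth <- c(0.4, 0.1, 0.5)
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  for (j in 1:3)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se[j] + 0.02)
})

test_that("a pure-noise trait drives genomic and strain variance to the boundary", {
  cfg <- simConfig(nAnimals = 300, nChromosomes = 2,
                   variantsPerChromosome = 200, nTraits = 1,
                   heritability = 0, strainVar = 0, switchProb = 0.5,
                   missingness = 0, seed = 77)
  sim <- simulateStudy(cfg, geneDensity = 0)
  vc <- estimateVarComp(phenoValues(sim$phenos)[, 1], sim$strains, sim$grm,
                        grmIds = animalIds(sim$genotypes))
  expect_lt(vc@sigmaG, 0.12)
  expect_lt(vc@sigmaQ, 0.12)
  expect_lt(abs(vc@sigmaE + vc@sigmaG + vc@sigmaQ - 1), 0.2)
})

test_that("an identity GRM raises the identifiability boundary flag", {
  n <- 60
  set.seed(8)
  y <- rnorm(n)
  names(y) <- sprintf("a%04d", 1:n)
  Q <- matrix(runif(n * 2), n, 2,
              dimnames = list(names(y), c("s1", "s2")))
  Q <- Q / (2 * rowSums(Q))
  grm <- new("GRM", matrix = diag(n), variantKeys = character(),
             mafThreshold = 0.005)
  vc <- estimateVarComp(y, StrainData(Q), grm, grmIds = names(y))
  expect_true(vc@boundary)
})

test_that("fewer than 30 records is an error", {
  n <- 20
  y <- setNames(rnorm(n), sprintf("a%02d", 1:n))
  Q <- matrix(1, n, 1, dimnames = list(names(y), "s1"))
  grm <- new("GRM", matrix = diag(n) + 0.01, variantKeys = character(),
             mafThreshold = 0.005)
  expect_error(estimateVarComp(y, StrainData(Q), grm, grmIds = names(y)),
               "30")
})

test_that("GLS with zero genomic and strain variance reproduces OLS", {
  g <- independentGenotypes(120, 40, seed = 17)
  set.seed(18)
  y <- setNames(rnorm(120), animalIds(g))
  st <- StrainData(matrix(rep(c(1, 0), each = 60), 120, 1,
                          dimnames = list(animalIds(g), "s1")))
  grm <- buildGRM(g, 0.005)
  vc <- new("VarianceComponents", sigmaG = 0, sigmaQ = 0, sigmaE = 1,
            logLik = 0, n = 120L, converged = TRUE, boundary = FALSE,
            iterations = 0L)
  a <- gwasScan(y, st, grm, g, vc)
  d <- dosages(g)
  for (j in seq_len(ncol(d))) {
    fit <- summary(lm(y ~ d[, j]))$coefficients
    expect_equal(unname(effectSizes(a)[j, 1]), fit[2, 1], tolerance = 1e-8)
    # GLS SE under fixed sigmaE=1 equals the OLS SE divided by the
    # residual standard deviation (oracle identity)
    s <- summary(lm(y ~ d[, j]))$sigma
    expect_equal(unname(stdErrors(a)[j, 1]), fit[2, 2] / s, tolerance = 1e-8)
  }
})

test_that("t statistics are invariant to phenotype rescaling", {
  sim <- smallStudy()
  y <- phenoValues(sim$phenos)[, 1]
  vc <- estimateVarComp(y, sim$strains, sim$grm,
                        grmIds = animalIds(sim$genotypes))
  a1 <- gwasScan(y, sim$strains, sim$grm, sim$genotypes, vc)
  vc3 <- new("VarianceComponents", sigmaG = 9 * vc@sigmaG,
             sigmaQ = 9 * vc@sigmaQ, sigmaE = 9 * vc@sigmaE, logLik = 0,
             n = vc@n, converged = TRUE, boundary = FALSE, iterations = 0L)
  a3 <- gwasScan(3 * y, sim$strains, sim$grm, sim$genotypes, vc3)
  expect_equal(tValues(a3), tValues(a1), tolerance = 1e-10)
})

test_that("conditioning on the causal variant deflates its LD neighbours", {
  cfg <- simConfig(nAnimals = 600, nChromosomes = 1,
                   variantsPerChromosome = 300, nTraits = 1,
                   meanBlockLength = 30, switchProb = 0.05, missingness = 0,
                   qtl = qtlSpec(1, 150, 0.6, maf = 0.3), seed = 66)
  sim <- simulateStudy(cfg, geneDensity = 0)
  y <- phenoValues(sim$phenos)[, 1]
  vc <- estimateVarComp(y, sim$strains, sim$grm,
                        grmIds = animalIds(sim$genotypes))
  causal <- sim$truth$qtl$key
  a0 <- gwasScan(y, sim$strains, sim$grm, sim$genotypes, vc)
  a1 <- gwasScan(y, sim$strains, sim$grm, sim$genotypes, vc,
                 conditioning = causal)
  nb <- ldScan(sim$genotypes, causal,
               setdiff(variantKeys(sim$genotypes), causal))
  nb <- nb$key[!is.na(nb$r2) & nb$r2 > 0.5]
  expect_gt(length(nb), 3)
  chi0 <- tValues(a0)[nb, 1]^2
  chi1 <- tValues(a1)[nb, 1]^2
  expect_lt(median(chi1, na.rm = TRUE), median(chi0, na.rm = TRUE))
})

test_that("an uncorrelated conditioning covariate barely moves the statistics", {
  g <- independentGenotypes(500, 80, seed = 23)
  set.seed(24)
  y <- setNames(rnorm(500), animalIds(g))
  st <- StrainData(matrix(1, 500, 1, dimnames = list(animalIds(g), "s1")))
  grm <- buildGRM(g, 0.005)
  vc <- new("VarianceComponents", sigmaG = 0, sigmaQ = 0, sigmaE = 1,
            logLik = 0, n = 500L, converged = TRUE, boundary = FALSE,
            iterations = 0L)
  k <- variantKeys(g)
  a0 <- gwasScan(y, st, grm, g, vc)
  a1 <- gwasScan(y, st, grm, g, vc, conditioning = k[80])
  common <- k[1:79]
  dt <- tValues(a1)[common, 1] - tValues(a0)[common, 1]
  expect_lt(max(abs(dt)), 1)
  expect_lt(median(abs(dt)), 0.15)
})

test_that("a trait with no records errors naming the trait", {
  sim <- smallStudy()
  Y <- phenoValues(sim$phenos)
  Y[, 2] <- NA
  expect_error(scanAllTraits(PhenotypeData(Y), sim$genotypes, sim$strains,
                             sim$grm),
               colnames(Y)[2])
})

test_that("unconditioned chromosomes reuse cached results bit-identically", {
  sim <- smallStudy()
  env <- cmgwas:::.mlmEngine(sim$phenos, sim$genotypes, sim$strains, sim$grm)
  a0 <- cmgwas:::.engineScanAll(env)
  condKey <- variantKeys(sim$genotypes)[10]
  a1 <- cmgwas:::.engineScanAll(env, list(chr1 = condKey))
  idx <- variantInfo(sim$genotypes)$chrom != "chr1"
  expect_identical(tValues(a1)[idx, ], tValues(a0)[idx, ])
  expect_identical(pValues(a1)[idx, ], pValues(a0)[idx, ])
  # and the conditioning variant itself is flagged, not re-tested
  expect_true(is.na(tValues(a1)[condKey, 1]))
})
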