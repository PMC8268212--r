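test_that("seeded simulation runs are bit-reproducible", {
  cfg <- simConfig(nAnimals = 60, nChromosomes = 2,
                   variantsPerChromosome = 80, nTraits = 3, seed = 9)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(phenoValues(s1$phenos), phenoValues(s2$phenos))
  expect_identical(strainProportions(s1$strains),
                   strainProportions(s2$strains))
  expect_identical(s1$genes, s2$genes)
})

test_that("zero switch probability makes whole blocks perfectly correlated", {
  cfg <- simConfig(nAnimals = 80, nChromosomes = 1,
                   variantsPerChromosome = 40, meanBlockLength = 1000,
                   switchProb = 0, nTraits = 2, seed = 3)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  # a single block spans the chromosome: every column identical
  for (j in 2:ncol(d)) expect_equal(unname(d[, j]), unname(d[, 1]))
  expect_equal(ldR2(g, variantKeys(g)[1], variantKeys(g)[25]), 1)
})

test_that("switch probability 0.5 gives LD indistinguishable from independence", {
  cfg <- simConfig(nAnimals = 150, nChromosomes = 1,
                   variantsPerChromosome = 5000, meanBlockLength = 8,
                   switchProb = 0.5, nTraits = 2, mafMin = 0.05, seed = 5)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  m <- ncol(d)
  r2adj <- vapply(seq_len(m - 1), function(j) {
    suppressWarnings(cor(d[, j], d[, j + 1])^2)
  }, numeric(1))
  # independent-pair baseline with identical margins: permute one column of
  # each pair, which destroys any dependence
  set.seed(99)
  r2perm <- vapply(seq_len(m - 1), function(j) {
    suppressWarnings(cor(d[, j], sample(d[, j + 1]))^2)
  }, numeric(1))
  ok <- is.finite(r2adj) & is.finite(r2perm)
  tt <- t.test(r2adj[ok], r2perm[ok])
  expect_gt(tt$p.value, 0.01)
})

test_that("realized MAF respects the configured minimum", {
  cfg <- simConfig(nAnimals = 150, nChromosomes = 2,
                   variantsPerChromosome = 300, nTraits = 2,
                   mafMin = 0.02, seed = 13)
  g <- simulateGenotypes(cfg)
  expect_true(all(alleleFreq(g)$maf >= 0.02))
})

test_that("a planted QTL explains the 2pq beta^2 share of phenotypic variance", {
  cfg <- simConfig(nAnimals = 2000, nChromosomes = 1,
                   variantsPerChromosome = 200, nTraits = 1,
                   missingness = 0,
                   qtl = qtlSpec(1, 100, 0.5, maf = 0.3), seed = 21)
  sim <- simulateStudy(cfg)
  k <- sim$truth$qtl$key
  contrib <- dosages(sim$genotypes)[, k] * 0.5
  # oracle: var = 2 p q beta^2 = 2 * 0.3 * 0.7 * 0.25 = 0.105
  expect_lt(abs(var(contrib) - 0.105), 0.02)
  y <- phenoValues(sim$phenos)[, 1]
  expect_lt(abs(var(y) - (1 + 0.105)), 0.15)
})

test_that("requested heritability is realized in the polygenic term", {
  shares <- slopes <- numeric(0)
  for (rep in 1:8) {
    cfg <- simConfig(nAnimals = 250, nChromosomes = 2,
                     variantsPerChromosome = 150, nTraits = 2,
                     heritability = 0.4, strainVar = 0.05, missingness = 0,
                     seed = 100 + rep)
    sim <- simulateStudy(cfg)
    Y <- phenoValues(sim$phenos)
    gmat <- sim$truth$polygenic
    for (t in 1:2) {
      slopes <- c(slopes, unname(coef(lm(Y[, t] ~ gmat[, t]))[2]))
      shares <- c(shares, var(gmat[, t]) / var(Y[, t]))
    }
  }
  expect_lt(abs(mean(slopes) - 1), 0.1)
  expect_lt(abs(mean(shares) - 0.4), 0.06)
})

test_that("configured missingness produces the bookkept record counts", {
  cfg <- simConfig(nAnimals = 200, nChromosomes = 1,
                   variantsPerChromosome = 60, nTraits = 4,
                   missingness = c(0, 0.25, 0.5, 0.1), seed = 31)
  sim <- simulateStudy(cfg)
  expect_equal(unname(colSums(!is.na(phenoValues(sim$phenos)))),
               200L - round(c(0, 0.25, 0.5, 0.1) * 200))
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(nTraits = 2, heritability = 1.2), "heritabilit")
  expect_error(simConfig(nChromosomes = 1, variantsPerChromosome = 3,
                         nTraits = 2,
                         qtl = rbind(qtlSpec(1, 1, 0.5), qtlSpec(1, 2, 0.5),
                                     qtlSpec(1, 3, 0.5), qtlSpec(1, 4, 0.5))),
               "more QTL|outside")
  expect_error(simConfig(nTraits = 2, residualCor = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(simConfig(nTraits = 2,
                         qtl = rbind(qtlSpec(1, 5, 0.5), qtlSpec(1, 5, 0.4))),
               "unique")
})

test_that("gene simulation honours density, determinism and QTL coverage", {
  sim <- smallStudy()
  g0 <- simulateGenes(sim$genotypes, density = 0, seed = 1)
  expect_length(g0, 0L)
  g1 <- simulateGenes(sim$genotypes, density = 8, seed = 4,
                      qtl = sim$truth$qtl)
  g2 <- simulateGenes(sim$genotypes, density = 8, seed = 4,
                      qtl = sim$truth$qtl)
  expect_identical(g1, g2)
  for (i in seq_len(nrow(sim$truth$qtl))) {
    ann <- nearestGenes(g1, sim$truth$qtl$chrom[i], sim$truth$qtl$pos[i])
    expect_true(any(ann$distance == 0))          # an overlapping gene exists
    far <- nearestGenes(g1, sim$truth$qtl$chrom[i], sim$truth$qtl$pos[i],
                        window = 2e5)
    expect_true(any(far$distance > 1e5))         # and one beyond the window
  }
})
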