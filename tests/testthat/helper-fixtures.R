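# Shared fixtures, all built in code. Expensive simulations are cached per
# test run so several test files can reuse one dataset.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, maker) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- maker()
  .fixtureCache[[name]]
}

# deterministic toy genotypes: 4 animals x 5 variants on 2 chromosomes
tinyGenotypes <- function() {
  d <- rbind(c(0, 1, 2, 0, 1),
             c(1, 1, 1, 0, 0),
             c(2, 0, 0, 1, 2),
             c(0, 2, 1, 2, 1))
  rownames(d) <- paste0("a", 1:4)
  GenotypeData(d,
               chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
               pos = c(100L, 200L, 300L, 100L, 250L),
               ref = "A", alt = c("C", "G", "T", "C", "G"))
}

# independent Bernoulli dosage matrix wrapped as GenotypeData
independentGenotypes <- function(n, m, p = 0.3, seed = 1, chrom = "chr1") {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, p), n, m)
  rownames(d) <- sprintf("a%04d", seq_len(n))
  GenotypeData(d, chrom = chrom, pos = seq_len(m) * 100L, ref = "A", alt = "B")
}

# small pleiotropic study reused by mlm / cmgwas / io tests
smallStudy <- function() cachedFixture("smallStudy", function() {
  cfg <- simConfig(nAnimals = 400, nChromosomes = 3,
                   variantsPerChromosome = 250, nTraits = 4,
                   missingness = c(0.05, 0.3, 0.05, 0.3),
                   qtl = rbind(qtlSpec(1, 60, c(0.6, 0.6, -0.6, 0.5), maf = 0.3),
                               qtlSpec(2, 120, c(0.5, -0.5, 0.5, 0.5), maf = 0.25)),
                   seed = 42)
  sim <- simulateStudy(cfg)
  sim$config <- cfg
  sim
})
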