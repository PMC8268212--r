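# reference implementation of the greedy independence rule, used as an
# enumeration oracle against selectIndependent
greedyOracle <- function(meta, genotypes, pThr, r2Thr) {
  v <- variantInfo(genotypes)
  cand <- meta[!is.na(meta$p) & meta$p < pThr, ]
  cand$pos <- v$pos[match(cand$key, v$key)]
  cand$chrom <- v$chrom[match(cand$key, v$key)]
  picked <- character()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, ]
    cc <- cc[order(cc$p, cc$pos), ]
    while (nrow(cc) > 0) {
      top <- cc$key[1]
      picked <- c(picked, top)
      keep <- logical(nrow(cc))
      for (i in seq_len(nrow(cc))) {
        r2 <- ldR2(genotypes, top, cc$key[i])
        keep[i] <- !is.na(r2) && r2 <= r2Thr || is.na(r2)
      }
      keep[1] <- FALSE
      cc <- cc[keep, , drop = FALSE]
    }
  }
  picked
}

metaFor <- function(keys, p) data.frame(key = keys,
                                        chisq = qchisq(p, 16, lower.tail = FALSE),
                                        df = 16, p = p,
                                        stringsAsFactors = FALSE)

test_that("a single significant variant is selected, and LD twins collapse", {
  g <- independentGenotypes(100, 6, seed = 31)
  k <- variantKeys(g)
  p <- rep(0.5, 6)
  p[3] <- 1e-8
  sel <- selectIndependent(metaFor(k, p), g)
  expect_equal(sel$key, k[3])
  # near-duplicate column: only the more significant of the two survives
  d <- dosages(g)
  d[, 4] <- d[, 3]
  d[1, 4] <- min(d[1, 4] + 1, 2)
  g2 <- GenotypeData(d, chrom = variantInfo(g)$chrom, pos = variantInfo(g)$pos,
                     ref = "A", alt = "B")
  p2 <- rep(0.5, 6)
  p2[3] <- 1e-9
  p2[4] <- 1e-7
  sel2 <- selectIndependent(metaFor(variantKeys(g2), p2), g2)
  expect_equal(sel2$key, variantKeys(g2)[3])
})

test_that("greedy selection matches the enumeration oracle", {
  # three significant variants with r2(1,2) high, r2(1,3) and r2(2,3) low
  set.seed(41)
  n <- 400
  z1 <- rbinom(n, 2, 0.4)
  z2 <- ifelse(runif(n) < 0.75, z1, rbinom(n, 2, 0.4))   # correlated with z1
  z3 <- rbinom(n, 2, 0.4)                                # independent
  d <- cbind(z1, z2, z3)
  rownames(d) <- sprintf("a%04d", 1:n)
  g <- GenotypeData(d, chrom = "chr1", pos = c(100L, 200L, 300L),
                    ref = "A", alt = "B")
  k <- variantKeys(g)
  expect_gt(ldR2(g, k[1], k[2]), 0.1)
  expect_lt(ldR2(g, k[1], k[3]), 0.1)
  meta <- metaFor(k, c(1e-9, 1e-8, 1e-7))
  sel <- selectIndependent(meta, g)
  expect_setequal(sel$key, c(k[1], k[3]))
  expect_setequal(sel$key, greedyOracle(meta, g, 1e-5, 0.1))
  # and on a random pattern the oracle still agrees
  p <- 10^-runif(3, 4, 10)
  meta2 <- metaFor(k, p)
  expect_setequal(selectIndependent(meta2, g)$key,
                  greedyOracle(meta2, g, 1e-5, 0.1))
})

test_that("previously selected variants shield their LD neighbourhood", {
  set.seed(43)
  n <- 300
  z1 <- rbinom(n, 2, 0.4)
  z2 <- ifelse(runif(n) < 0.85, z1, rbinom(n, 2, 0.4))
  d <- cbind(z1, z2)
  rownames(d) <- sprintf("a%04d", 1:n)
  g <- GenotypeData(d, chrom = "chr1", pos = c(100L, 200L), ref = "A",
                    alt = "B")
  k <- variantKeys(g)
  expect_gt(ldR2(g, k[1], k[2]), 0.1)
  sel <- selectIndependent(metaFor(k, c(0.5, 1e-8)), g,
                           alreadySelected = k[1])
  expect_equal(nrow(sel), 0L)   # tagged by the earlier selection
})

test_that("LD expansion equals a brute-force pairwise filter", {
  sim <- smallStudy()
  a <- scanAllTraits(sim$phenos, sim$genotypes, sim$strains, sim$grm)
  V <- traitCorr(a)
  meta <- multiTraitChisq(a, V)
  sel <- selectIndependent(meta, sim$genotypes)
  expect_gt(nrow(sel), 0)
  exp <- expandLD(sel$key, meta, sim$genotypes)
  v <- variantInfo(sim$genotypes)
  sig <- meta$key[!is.na(meta$p) & meta$p < 1e-5]
  for (k in sel$key) {
    ch <- v$chrom[match(k, v$key)]
    pool <- setdiff(sig[v$chrom[match(sig, v$key)] == ch], k)
    brute <- pool[vapply(pool, function(q) {
      r2 <- ldR2(sim$genotypes, k, q)
      !is.na(r2) && r2 > 0.8
    }, logical(1))]
    expect_setequal(exp[[k]]$key, brute)
    ps <- v$pos[match(c(k, exp[[k]]$key), v$key)]
    expect_equal(attr(exp[[k]], "span"), max(ps) - min(ps))
  }
})

test_that("expansion of an isolated variant is a singleton with span zero", {
  g <- independentGenotypes(200, 5, seed = 51)
  k <- variantKeys(g)
  meta <- metaFor(k, c(1e-8, rep(0.5, 4)))
  exp <- expandLD(k[1], meta, g)
  expect_equal(nrow(exp[[k[1]]]), 0L)
  expect_equal(attr(exp[[k[1]]], "span"), 0)
})

test_that("a null simulation selects nothing and stops after one cycle", {
  cfg <- simConfig(nAnimals = 300, nChromosomes = 2,
                   variantsPerChromosome = 150, nTraits = 3,
                   missingness = 0.1, seed = 61)
  sim <- simulateStudy(cfg, geneDensity = 0)
  res <- runCMGWAS(sim$phenos, sim$genotypes, sim$strains, sim$grm)
  expect_equal(nrow(qtlTable(res)), 0L)
  expect_equal(nrow(auditLog(res)), 1L)
  expect_false(res@params$truncated)
})

test_that("the full loop recovers planted QTL and annotates them", {
  sim <- smallStudy()
  res <- runCMGWAS(sim$phenos, sim$genotypes, sim$strains, sim$grm,
                   genes = sim$genes)
  q <- qtlTable(res)
  expect_gt(nrow(q), 0)
  for (i in seq_len(nrow(sim$truth$qtl))) {
    tk <- sim$truth$qtl$key[i]
    sel <- q$key[q$chrom == sim$truth$qtl$chrom[i]]
    r2 <- vapply(sel, function(s) {
      r <- ldR2(sim$genotypes, s, tk); if (is.na(r)) 0 else r
    }, numeric(1))
    expect_true(any(r2 > 0.8))
  }
  # independence invariant: pairwise r2 <= 0.1 within chromosomes
  for (ch in unique(q$chrom)) {
    kk <- q$key[q$chrom == ch]
    if (length(kk) > 1)
      for (i in 1:(length(kk) - 1)) for (j in (i + 1):length(kk)) {
        r2 <- ldR2(sim$genotypes, kk[i], kk[j])
        expect_lte(ifelse(is.na(r2), 0, r2), 0.1)
      }
  }
  # pleiotropy profile columns and gene annotation are attached
  expect_true(all(paste0("t_", traitNames(sim$phenos)) %in% names(q)))
  expect_true(all(lengths(q$genes) > 0))
  # significant count in the audit never increases
  aud <- auditLog(res)
  expect_true(all(diff(aud$nSignificant) <= 0))
})

test_that("two same-chromosome QTL with low mutual LD are both discovered", {
  eff1 <- c(0.6, 0.6, -0.5, 0.5)
  eff2 <- c(0.5, -0.5, 0.5, 0.45)
  cfg <- simConfig(nAnimals = 800, nChromosomes = 1,
                   variantsPerChromosome = 500, nTraits = 4,
                   meanBlockLength = 25, switchProb = 0.08, missingness = 0,
                   qtl = rbind(qtlSpec(1, 150, eff1, maf = 0.3),
                               qtlSpec(1, 350, eff2, maf = 0.3)),
                   seed = 71)
  sim <- simulateStudy(cfg, geneDensity = 0)
  expect_lt(ldR2(sim$genotypes, sim$truth$qtl$key[1], sim$truth$qtl$key[2]),
            0.1)
  res <- runCMGWAS(sim$phenos, sim$genotypes, sim$strains, sim$grm)
  q <- qtlTable(res)
  for (tk in sim$truth$qtl$key) {
    r2 <- vapply(q$key, function(s) {
      r <- ldR2(sim$genotypes, s, tk); if (is.na(r)) 0 else r
    }, numeric(1))
    expect_true(any(r2 > 0.8))
  }
})
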