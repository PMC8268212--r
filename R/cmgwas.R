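#' Greedy per-chromosome selection of independent significant variants
#'
#' On each chromosome the most significant eligible variant (multi-trait
#' \eqn{P} below \code{pThreshold}) is picked; every significant variant with
#' \eqn{r^2} above \code{r2Threshold} to it — or to any previously selected
#' variant on that chromosome — is deemed to tag the same causal variant and
#' becomes ineligible; the next most significant eligible variant is then
#' picked, and so on until no eligible significant variant remains. Ties in
#' P are broken by smaller position, then lexicographically by alternative
#' allele. Undefined LD (zero dosage variance) counts as \eqn{r^2 = 0}.
#'
#' @param meta \code{data.frame} from \code{\link{multiTraitChisq}} covering
#'   the candidate variants.
#' @param genotypes the matching \linkS4class{GenotypeData}.
#' @param pThreshold multi-trait significance threshold (default 1e-5).
#' @param r2Threshold LD independence threshold (default 0.1).
#' @param alreadySelected keys selected in earlier cycles (never
#'   re-selected, and still shielding their LD neighbourhood).
#' @return \code{data.frame} of new selections: \code{key}, \code{chrom},
#'   \code{pos}, \code{chisq}, \code{p} (possibly empty).
#' @export
selectIndependent <- function(meta, genotypes, pThreshold = 1e-5,
                              r2Threshold = 0.1,
                              alreadySelected = character()) {
  v <- variantInfo(genotypes)
  idx <- match(meta$key, v$key)
  cand <- data.frame(key = meta$key, chrom = v$chrom[idx], pos = v$pos[idx],
                     alt = v$alt[idx], chisq = meta$chisq, p = meta$p,
                     stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$p) & cand$p < pThreshold &
               !(cand$key %in% alreadySelected), , drop = FALSE]
  out <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$p, cc$pos, cc$alt), , drop = FALSE]
    prev <- alreadySelected[alreadySelected %in%
                            v$key[v$chrom == ch]]
    for (pk in prev) {
      if (nrow(cc) == 0L) break
      r2 <- ldScan(genotypes, pk, cc$key)$r2
      r2[is.na(r2)] <- 0
      cc <- cc[r2 <= r2Threshold, , drop = FALSE]
    }
    while (nrow(cc) > 0L) {
      top <- cc[1, , drop = FALSE]
      out[[length(out) + 1L]] <- top[, c("key", "chrom", "pos", "chisq", "p")]
      cc <- cc[-1, , drop = FALSE]
      if (nrow(cc)) {
        r2 <- ldScan(genotypes, top$key, cc$key)$r2
        r2[is.na(r2)] <- 0
        cc <- cc[r2 <= r2Threshold, , drop = FALSE]
      }
    }
  }
  if (!length(out))
    return(data.frame(key = character(), chrom = character(),
                      pos = integer(), chisq = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strong-LD expansion of selected variants
#'
#' For each selected variant, collects every significant variant (from the
#' unconditional multi-trait results) on the same chromosome with \eqn{r^2}
#' above \code{r2Expand} to it. The region span is the bp distance between
#' the outermost members (0 for a singleton).
#'
#' @param selected character vector of selected variant keys.
#' @param meta unconditional (cycle-1) multi-trait results.
#' @param genotypes the matching \linkS4class{GenotypeData}.
#' @param r2Expand expansion threshold (default 0.8).
#' @param pThreshold significance threshold defining the candidate pool
#'   (default 1e-5).
#' @return Named list (one entry per selected key) of \code{data.frame}s
#'   with \code{key}, \code{r2}, plus attributes-free columns; each carries
#'   the span via \code{attr(x, "span")}.
#' @export
expandLD <- function(selected, meta, genotypes, r2Expand = 0.8,
                     pThreshold = 1e-5) {
  v <- variantInfo(genotypes)
  sig <- meta$key[!is.na(meta$p) & meta$p < pThreshold]
  out <- list()
  for (k in selected) {
    ch <- v$chrom[match(k, v$key)]
    pool <- setdiff(sig[v$chrom[match(sig, v$key)] == ch], k)
    mem <- data.frame(key = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
    if (length(pool)) {
      r2 <- ldScan(genotypes, k, pool)$r2
      keep <- !is.na(r2) & r2 > r2Expand
      mem <- data.frame(key = pool[keep], r2 = r2[keep],
                        stringsAsFactors = FALSE)
    }
    allPos <- v$pos[match(c(k, mem$key), v$key)]
    attr(mem, "span") <- max(allPos) - min(allPos)
    out[[k]] <- mem
  }
  out
}

#' Run the full conditional multi-trait GWAS
#'
#' Implements the stepwise loop: (1) unconditional single-trait scans for
#' all traits; (2) the trait correlation matrix V and the multi-trait
#' chi-squared; (3) greedy per-chromosome selection of independent
#' significant variants under the \eqn{r^2} independence rule; (4)
#' conditional single-trait scans, jointly fitting the selected variants,
#' only on chromosomes that have selections; (5) the multi-trait statistic
#' recomputed from the updated t-values, with selected variants keeping the
#' t-values they had when selected; (6) repeat until a cycle selects nothing
#' or \code{maxCycles} is reached. Selected variants are then expanded into
#' their strong-LD regions and annotated with nearby genes.
#'
#' V is computed once from the unconditional scan and reused in every cycle;
#' variance components are estimated once per trait and held fixed across
#' cycles. When a chromosome's conditioning set contains a pair with
#' \eqn{r^2 > 0.95}, the later-selected member is dropped from the joint fit
#' (it remains selected and reported) for numerical stability; this is noted
#' in the audit log.
#'
#' @param phenos a \linkS4class{PhenotypeData}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param strains a \linkS4class{StrainData}.
#' @param grm a \linkS4class{GRM}, or \code{NULL} to build one from
#'   \code{genotypes} at \code{mafThreshold}.
#' @param genes optional \code{GRanges} gene set for nearest-gene
#'   annotation.
#' @param pThreshold multi-trait significance threshold (default 1e-5).
#' @param r2Independence LD independence threshold (default 0.1).
#' @param r2Expand strong-LD expansion threshold (default 0.8).
#' @param mafThreshold MAF filter for the scan and default GRM (0.005).
#' @param maxCycles cycle cap (default 20).
#' @param geneWindow nearest-gene window in bp (default 100000).
#' @param quiet suppress progress messages.
#' @return A \linkS4class{CMGWASResult}.
#' @export
runCMGWAS <- function(phenos, genotypes, strains, grm = NULL, genes = NULL,
                      pThreshold = 1e-5, r2Independence = 0.1,
                      r2Expand = 0.8, mafThreshold = 0.005, maxCycles = 20L,
                      geneWindow = 100000L, quiet = TRUE) {
  if (is.null(grm)) grm <- buildGRM(genotypes, mafThreshold)
  env <- .mlmEngine(phenos, genotypes, strains, grm, mafThreshold,
                    quiet = quiet)
  geno <- env$genotypes
  traits <- colnames(env$Y)
  assoc1 <- .engineScanAll(env)
  V <- traitCorr(assoc1)
  meta1 <- multiTraitChisq(assoc1, V)
  tCurrent <- tValues(assoc1)
  metaCur <- meta1
  selected <- data.frame(key = character(), chrom = character(),
                         pos = integer(), chisq = numeric(), p = numeric(),
                         cycle = integer(), stringsAsFactors = FALSE)
  originalT <- matrix(NA_real_, 0, length(traits),
                      dimnames = list(NULL, traits))
  audit <- list()
  truncated <- FALSE
  for (cycle in seq_len(maxCycles)) {
    nSig <- sum(!is.na(metaCur$p) & metaCur$p < pThreshold &
                !(metaCur$key %in% selected$key))
    new <- selectIndependent(metaCur, geno, pThreshold, r2Independence,
                             alreadySelected = selected$key)
    note <- ""
    if (nrow(new)) {
      new$cycle <- cycle
      selected <- rbind(selected, new)
      originalT <- rbind(originalT,
                         tCurrent[new$key, , drop = FALSE])
      rownames(originalT) <- selected$key
    }
    audit[[cycle]] <- data.frame(cycle = cycle, nSignificant = nSig,
                                 nSelected = nrow(new), note = note,
                                 stringsAsFactors = FALSE)
    if (!nrow(new)) break
    if (cycle == maxCycles) {
      truncated <- TRUE
      audit[[cycle]]$note <- "max cycles reached with selections occurring"
      break
    }
    # conditional scans on chromosomes with selections
    conditioning <- split(selected$key, selected$chrom)
    dropNotes <- character()
    for (ch in names(conditioning)) {
      ck <- conditioning[[ch]]
      if (length(ck) > 1L) {
        keep <- ck[1]
        for (k in ck[-1]) {
          r2 <- ldScan(geno, k, keep)$r2
          r2[is.na(r2)] <- 0
          if (all(r2 <= 0.95)) keep <- c(keep, k)
          else dropNotes <- c(dropNotes,
                              sprintf("%s dropped from joint fit on %s (r2 > 0.95)",
                                      k, ch))
        }
        conditioning[[ch]] <- keep
      }
    }
    if (length(dropNotes))
      audit[[cycle]]$note <- paste(dropNotes, collapse = "; ")
    assocC <- .engineScanAll(env, conditioning)
    tCurrent <- tValues(assocC)
    # selected variants keep the t-values they had at selection
    tCurrent[selected$key, ] <- originalT[selected$key, , drop = FALSE]
    metaCur <- multiTraitChisq(tCurrent, V)
    if (!quiet)
      message(sprintf("cycle %d: %d significant, %d selected so far",
                      cycle, nSig, nrow(selected)))
  }
  auditDf <- do.call(rbind, audit)
  qtl <- selected[, c("key", "chrom", "pos", "cycle", "chisq", "p")]
  tsel <- originalT[selected$key, , drop = FALSE]
  for (tr in traits) qtl[[paste0("t_", tr)]] <- tsel[, tr]
  exp <- expandLD(selected$key, meta1, geno, r2Expand, pThreshold)
  qtl$ld_n <- vapply(exp[selected$key], nrow, integer(1))
  qtl$ld_span <- vapply(exp[selected$key], function(x)
    as.numeric(attr(x, "span")), numeric(1))
  qtl$ld_members <- lapply(exp[selected$key], function(x) x$key)
  if (!is.null(genes) && nrow(qtl)) {
    ann <- lapply(seq_len(nrow(qtl)), function(i)
      nearestGenes(genes, qtl$chrom[i], qtl$pos[i], window = geneWindow))
    qtl$genes <- lapply(ann, function(a)
      sprintf("%s^%s", a$name, formatC(a$distance / 1000, format = "fg")))
    qtl$gene_distances_bp <- lapply(ann, function(a) a$distance)
  } else {
    qtl$genes <- replicate(nrow(qtl), character(0), simplify = FALSE)
    qtl$gene_distances_bp <- replicate(nrow(qtl), numeric(0),
                                       simplify = FALSE)
  }
  rownames(qtl) <- NULL
  new("CMGWASResult", qtl = qtl, audit = auditDf, assoc = assoc1,
      traitCorr = V, meta = meta1,
      params = list(pThreshold = pThreshold,
                    r2Independence = r2Independence, r2Expand = r2Expand,
                    mafThreshold = mafThreshold, maxCycles = maxCycles,
                    geneWindow = geneWindow, truncated = truncated))
}
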