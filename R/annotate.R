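#' Genes within a window of a variant position
#'
#' Returns every gene whose interval lies within \code{window} bp of the
#' position, boundary inclusive (a gene ending exactly \code{window} bp away
#' is included). The distance is 0 when the position falls inside the gene
#' interval, otherwise the gap to the nearer interval end; strand is
#' ignored. Results are sorted by distance, then name.
#'
#' @param genes \code{GRanges} with a \code{name} metadata column.
#' @param chrom chromosome label of the variant.
#' @param pos 1-based position of the variant.
#' @param window window in bp on either side (default 100000).
#' @return \code{data.frame} with columns \code{name}, \code{distance} (bp)
#'   and \code{side} (\code{"within"}, \code{"upstream"} when the gene lies
#'   before the position, \code{"downstream"} after), possibly empty.
#' @export
nearestGenes <- function(genes, chrom, pos, window = 100000L) {
  empty <- data.frame(name = character(), distance = numeric(),
                      side = character(), stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(empty)
  onChr <- as.character(GenomicRanges::seqnames(genes)) == as.character(chrom)
  if (!any(onChr)) return(empty)
  g <- genes[onChr]
  st <- GenomicRanges::start(g)
  en <- GenomicRanges::end(g)
  within <- pos >= st & pos <= en
  dist <- ifelse(within, 0, ifelse(pos < st, st - pos, pos - en))
  keep <- dist <= window
  out <- data.frame(name = S4Vectors::mcols(g)$name[keep],
                    distance = as.numeric(dist[keep]),
                    side = ifelse(within[keep], "within",
                                  ifelse(pos > en[keep], "upstream",
                                         "downstream")),
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$name), , drop = FALSE]
}

#' Pleiotropy profile of one variant
#'
#' Masks a per-trait signed-t vector below a reporting threshold, the way
#' pleiotropic effect tables print only the significant entries.
#'
#' @param t named numeric vector of per-trait signed t-values (NA where the
#'   variant was not tested for a trait).
#' @param threshold reporting threshold on \code{|t|} (default 1.96; 2.0 is
#'   the other conventional choice). Entries with \code{|t|} at or above the
#'   threshold are kept.
#' @return List with \code{profile} (the masked vector) and \code{count}
#'   (number of traits passing).
#' @export
pleiotropyProfile <- function(t, threshold = 1.96) {
  if (all(is.na(t))) stop("t must be defined for at least one trait")
  profile <- t
  profile[!is.na(profile) & abs(profile) < threshold] <- NA
  list(profile = profile, count = sum(!is.na(profile)))
}
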