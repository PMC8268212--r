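#' Read a pre-adjusted phenotype table
#'
#' TSV with a header row; first column animal id, remaining columns one trait
#' each. Cells equal to \code{naToken} are treated as missing records.
#'
#' @param path file path.
#' @param naToken missing-value token (default \code{"NA"}).
#' @return A \linkS4class{PhenotypeData}.
#' @export
readPhenotypes <- function(path, naToken = "NA") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = naToken, colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("phenotype TSV must have an id column and >= 1 trait")
  ids <- as.character(dt[[1]])
  m <- dt[, -1, drop = FALSE]
  bad <- !vapply(m, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric phenotype cell(s) in trait(s): ",
         paste(names(m)[bad], collapse = ", "))
  m <- as.matrix(m)
  rownames(m) <- ids
  PhenotypeData(m)
}

#' Read a strain-proportion (Q) matrix
#'
#' TSV with header; first column animal id, remaining columns one strain each.
#'
#' @param path file path.
#' @return A \linkS4class{StrainData}.
#' @export
readStrains <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("strain proportions outside [0, 1] in ", path)
  StrainData(m)
}

#' Write / read a phenotype or strain table
#'
#' @param x a \linkS4class{PhenotypeData} or \linkS4class{StrainData}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(x, path) {
  m <- phenoValues(x)
  out <- data.frame(animal_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
writeStrains <- function(x, path) {
  m <- strainProportions(x)
  out <- data.frame(animal_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF3 is taken as is (records with \code{type == "gene"} are
#' kept when a type column is present). Gene names come from the BED name
#' column or the GFF3 \code{Name}/\code{ID} attribute.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"gff3"}; default guessed from the
#'   extension.
#' @return A \code{GRanges} with a \code{name} metadata column.
#' @export
readGenes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(mc) && any(mc$type == "gene"))
      gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(mc) && !all(is.na(mc$Name))) mc$Name else mc$ID
  } else nm <- mc$name
  nm <- as.character(nm)
  if (any(is.na(nm) | nm == "")) stop("gene records without a name in ", path)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$name <- nm
  out
}

#' Write gene intervals as BED
#'
#' @param genes a \code{GRanges} with a \code{name} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenesBed <- function(genes, path) {
  rtracklayer::export(genes, path, format = "BED")
  invisible(path)
}

#' Write and read association tables
#'
#' The association TSV is wide: one row per variant (key, chromosome,
#' position) followed by \code{effect_}, \code{se_}, \code{t_} and \code{p_}
#' columns for each trait.
#'
#' @param assoc an \linkS4class{AssocResult}.
#' @param genotypes the matching \linkS4class{GenotypeData} (for chromosome
#'   and position columns).
#' @param path output path.
#' @return \code{path} (write) or an \linkS4class{AssocResult} (read).
#' @export
writeAssocTable <- function(assoc, genotypes, path) {
  v <- variantInfo(genotypes)
  keys <- variantKeys(assoc)
  idx <- match(keys, v$key)
  tn <- traitNames(assoc)
  out <- data.frame(key = keys, chrom = v$chrom[idx], pos = v$pos[idx],
                    stringsAsFactors = FALSE)
  for (j in seq_along(tn)) {
    out[[paste0("effect_", tn[j])]] <- assoc@effect[, j]
    out[[paste0("se_", tn[j])]] <- assoc@se[, j]
    out[[paste0("t_", tn[j])]] <- assoc@t[, j]
    out[[paste0("p_", tn[j])]] <- assoc@p[, j]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeAssocTable
#' @param path file path to read.
#' @export
readAssocTable <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  tn <- sub("^t_", "", grep("^t_", names(dt), value = TRUE))
  pull <- function(prefix) {
    m <- as.matrix(dt[, paste0(prefix, tn), drop = FALSE])
    dimnames(m) <- list(dt$key, tn)
    m
  }
  new("AssocResult", effect = pull("effect_"), se = pull("se_"),
      t = pull("t_"), p = pull("p_"),
      nUsed = rep(NA_integer_, length(tn)),
      flags = matrix("", nrow(dt), length(tn), dimnames = list(dt$key, tn)))
}

#' Write the selected-QTL table
#'
#' One row per selected independent putative causal variant: key, chromosome,
#' position, selection cycle, multi-trait chi-squared and P, the per-trait
#' signed t profile with entries below the reporting threshold masked
#' (written as \code{NA}), the LD-expansion member count and region span in
#' bp, and the nearest genes. Genes are written both as a display column in
#' the \code{NAME^kb} convention (distance in kb as a superscript-style
#' suffix) and as a raw bp distance column.
#'
#' @param qtl the \code{data.frame} from \code{qtlTable()}.
#' @param path output path.
#' @param tThreshold reporting threshold for the signed-t profile
#'   (default 1.96).
#' @return \code{path}, invisibly.
#' @export
writeQtlTable <- function(qtl, path, tThreshold = 1.96) {
  tcols <- grep("^t_", names(qtl), value = TRUE)
  out <- qtl
  for (cc in tcols) {
    v <- out[[cc]]
    v[!is.na(v) & abs(v) < tThreshold] <- NA
    out[[cc]] <- v
  }
  listCols <- intersect(c("ld_members", "genes", "gene_distances_bp"), names(out))
  for (cc in listCols)
    out[[cc]] <- vapply(out[[cc]], function(z)
      paste(z, collapse = ";"), character(1))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
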