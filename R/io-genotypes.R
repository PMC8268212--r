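#' Read genotype dosages from VCF or a dosage TSV
#'
#' VCF records must be biallelic; the DS (dosage) FORMAT field is preferred
#' when present, otherwise GT genotypes are converted to counts of the
#' alternative allele (0/1/2). The dosage-TSV dialect has one animal per row:
#' first column the animal id, remaining columns one variant each with header
#' \code{chrom:pos:ref:alt}.
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"dosage"}; default guessed from the
#'   file extension.
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") .readGenotypesVcf(path) else .readGenotypesDosage(path)
}

.readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | is.na(alt) | alt == ""
  if (any(bad))
    stop("multiallelic or malformed VCF record(s) at: ",
         paste(head(paste0(fix[bad, "CHROM"], ":", fix[bad, "POS"]), 5),
               collapse = ", "))
  fmt <- vcf@gt[, 1]
  hasDS <- all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, logical(1)))
  if (hasDS) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(g) {
      a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
      vapply(a, function(x) {
        if (any(x == "." | is.na(x))) return(NA_real_)
        sum(x == "1")
      }, numeric(1))
    }
    d <- apply(gt, 2, cnt)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
    malformed <- !is.na(gt) & !grepl("^[01.]([/|][01.])?$", gt)
    if (any(malformed))
      stop("malformed GT field(s) in record(s): ",
           paste(head(rownames(gt)[rowSums(malformed) > 0], 5), collapse = ", "))
  }
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- NA
  GenotypeData(t(d), chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = alt,
               id = ifelse(is.na(id),
                           sprintf("%s:%s:%s:%s", fix[, "CHROM"], fix[, "POS"],
                                   fix[, "REF"], alt),
                           id))
}

.readGenotypesDosage <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("dosage TSV must have an id column and >= 1 variant")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric dosage entries in ", path)
  keys <- colnames(m)
  parts <- strsplit(keys, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("dosage TSV headers must be chrom:pos:ref:alt")
  rownames(m) <- ids
  GenotypeData(m,
               chrom = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, `[`, "", 2)),
               ref = vapply(parts, `[`, "", 3),
               alt = vapply(parts, `[`, "", 4))
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits GT fields when all dosages are integral and DS
#' otherwise; missing dosages become \code{./.} (GT) or \code{.} (DS).
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param path output path.
#' @param format \code{"vcf"} or \code{"dosage"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  d <- dosages(x)
  v <- variantInfo(x)
  if (format == "dosage") {
    out <- data.frame(animal_id = rownames(d), d, check.names = FALSE,
                      stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
    return(invisible(path))
  }
  integral <- all(is.na(d) | d == round(d))
  hdr <- c("##fileformat=VCFv4.2",
           if (integral) '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
           else '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    if (integral) {
      g <- c("0/0", "0/1", "1/1")[d[, j] + 1L]
      g[is.na(g)] <- "./."
      fmtTag <- "GT"
    } else {
      g <- formatC(d[, j], format = "g", digits = 15)
      g[is.na(d[, j])] <- "."
      fmtTag <- "DS"
    }
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", fmtTag, g), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
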