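#' Read a VCF into a genotype matrix
#'
#' Thin wrapper around [VariantAnnotation::readVcf()].  Diploid GT fields are
#' mapped to alternate-allele dosages (`0/0 -> 0`, `0/1`, `1/0 -> 1`,
#' `1/1 -> 2`); any genotype containing a missing allele (`.`) becomes `NA`,
#' phase separators are ignored.  Multiallelic records are retained as-is
#' (dosage = count of non-reference alleles); the biallelic filter is a
#' separate step, [apply_site_filters()].  Chromosome lengths are taken from
#' `##contig` header lines when present.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_subset optional character vector of sample IDs to keep.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT,
                 error = function(e) NULL)
  if (is.null(gt)) stop("VCF has no GT field: ", path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  qual <- VariantAnnotation::qual(vcf)
  samples <- colnames(gt)

  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, samples)
    if (length(missing_ids)) {
      stop("samples not in VCF: ", paste(missing_ids, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  dos <- .gt_to_dosage(gt, chrom, pos)

  ctg <- tryCatch(
    VariantAnnotation::meta(VariantAnnotation::header(vcf))$contig,
    error = function(e) NULL)
  if (!is.null(ctg) && nrow(ctg) > 0 && "length" %in% colnames(ctg)) {
    chrom_lengths <- stats::setNames(as.numeric(ctg$length), rownames(ctg))
  } else {
    # no contig headers: fall back to max observed position per chromosome
    chrom_lengths <- tapply(pos, chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
    if (length(chrom_lengths) == 0) chrom_lengths <- c(chrUnknown = 1)
  }
  present <- unique(chrom)
  absent <- setdiff(present, names(chrom_lengths))
  if (length(absent)) {
    extra <- tapply(pos[chrom %in% absent], chrom[chrom %in% absent], max)
    chrom_lengths <- c(chrom_lengths, stats::setNames(as.numeric(extra),
                                                      names(extra)))
  }

  genotype_matrix(samples = samples, chrom = chrom, pos = pos, ref = ref,
                  alt = alt, qual = as.numeric(qual), dosages = dos,
                  chrom_lengths = chrom_lengths)
}

# GT character matrix -> integer dosage matrix; errors name sample and site.
.gt_to_dosage <- function(gt, chrom, pos) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == "." | alleles == "")) return(NA_integer_)
    if (length(alleles) != 2) return(-1L)  # non-diploid sentinel
    sum(alleles != "0")
  }, integer(1))
  dos <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
                ncol = ncol(gt), dimnames = dimnames(gt))
  bad <- which(dos == -1L, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-diploid genotype '%s' for sample %s at %s:%d",
                 gt[bad[1, 1], bad[1, 2]], colnames(gt)[bad[1, 2]],
                 chrom[bad[1, 1]], pos[bad[1, 1]]))
  }
  storage.mode(dos) <- "integer"
  dos
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one record per site with `##contig` headers.  When the matrix
#' carries haplotypes (simulator output) genotypes are written phased
#' (`0|1`); otherwise dosages are written unphased, which requires biallelic
#' sites.  Missing dosages become `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=popgensweep-%s",
            as.character(utils::packageVersion("popgensweep"))),
    sprintf("##contig=<ID=%s,length=%d>", names(gm$chrom_lengths),
            as.integer(gm$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  if (n_sites(gm) == 0) return(invisible(path))

  if (!is.null(gm$haplotypes)) {
    h1 <- gm$haplotypes[, seq(1, ncol(gm$haplotypes), by = 2), drop = FALSE]
    h2 <- gm$haplotypes[, seq(2, ncol(gm$haplotypes), by = 2), drop = FALSE]
    gtm <- matrix(paste0(h1, "|", h2), nrow = nrow(h1))
  } else {
    if (any(lengths(gm$alt) > 1)) {
      stop("unphased dosage output supports biallelic sites only")
    }
    lut <- c("0/0", "0/1", "1/1")
    gtm <- matrix(lut[gm$dosages + 1L], nrow = n_sites(gm))
    gtm[is.na(gtm)] <- "./."
  }
  body <- paste(gm$chrom, gm$pos, ".", gm$ref,
                vapply(gm$alt, paste, "", collapse = ","),
                ifelse(is.na(gm$qual), ".", format(gm$qual, trim = TRUE)),
                ".", ".", "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
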