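#' Construct a genotype matrix
#'
#' The central container of the package: a sites-by-samples diploid
#' allele-dosage matrix together with site metadata.  Dosage is the count of
#' alternate alleles carried by a sample at a site (0, 1 or 2), `NA` marking a
#' missing call.  Sites are stored sorted by (chromosome, position) with the
#' chromosome order taken from `chrom_lengths`.
#'
#' @param samples character vector of sample IDs (column order of `dosages`).
#' @param chrom character vector of chromosome labels, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles.
#' @param alt list of character vectors of alternate alleles (one element per
#'   site; biallelic sites have length-1 elements).
#' @param qual numeric vector of Phred-scaled site quality scores (`NA` when
#'   absent).
#' @param dosages integer matrix, sites x samples, entries in `{0,1,2,NA}`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param haplotypes optional integer 0/1 matrix, sites x (2 * samples), with
#'   columns `<sample>_1`, `<sample>_2`; carried by the simulator so phased
#'   operations (sweep injection, phased VCF output) remain possible.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, chrom, pos, ref, alt, qual, dosages,
                            chrom_lengths, haplotypes = NULL) {
  stopifnot(is.character(samples), is.matrix(dosages))
  n_sites <- length(pos)
  if (length(chrom) != n_sites || nrow(dosages) != n_sites ||
      length(ref) != n_sites || length(alt) != n_sites ||
      length(qual) != n_sites) {
    stop("site metadata lengths disagree")
  }
  if (ncol(dosages) != length(samples)) {
    stop("dosage matrix has ", ncol(dosages), " columns for ",
         length(samples), " samples")
  }
  if (is.null(names(chrom_lengths)) || anyNA(chrom_lengths)) {
    stop("chrom_lengths must be a named vector without NAs")
  }
  if (!all(chrom %in% names(chrom_lengths))) {
    stop("sites on chromosomes absent from chrom_lengths")
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad)) stop("dosages outside {0,1,2,NA}")
  if (any(pos < 1)) stop("positions must be >= 1")

  ord <- order(match(chrom, names(chrom_lengths)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]
  alt <- alt[ord]; qual <- qual[ord]
  dosages <- dosages[ord, , drop = FALSE]
  if (!is.null(haplotypes)) haplotypes <- haplotypes[ord, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate (chrom, pos) sites")

  colnames(dosages) <- samples
  obj <- list(samples = samples, chrom = chrom, pos = as.integer(pos),
              ref = ref, alt = alt, qual = as.numeric(qual),
              dosages = dosages,
              chrom_lengths = chrom_lengths, haplotypes = haplotypes)
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(x$chrom_lengths)))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness %.3f%%; haplotypes %s\n", 100 * miss,
              if (is.null(x$haplotypes)) "absent" else "present"))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample IDs to keep (order respected), or NULL to keep all.
#' @param sites logical or integer index of sites to keep, or NULL.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, sites = NULL) {
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, gm$samples)
    if (length(missing_ids)) {
      stop("samples not in matrix: ", paste(missing_ids, collapse = ", "))
    }
    j <- match(samples, gm$samples)
    gm$dosages <- gm$dosages[, j, drop = FALSE]
    if (!is.null(gm$haplotypes)) {
      hj <- as.vector(rbind(2L * j - 1L, 2L * j))
      gm$haplotypes <- gm$haplotypes[, hj, drop = FALSE]
    }
    gm$samples <- samples
  }
  if (!is.null(sites)) {
    gm$chrom <- gm$chrom[sites]; gm$pos <- gm$pos[sites]
    gm$ref <- gm$ref[sites]; gm$alt <- gm$alt[sites]
    gm$qual <- gm$qual[sites]
    gm$dosages <- gm$dosages[sites, , drop = FALSE]
    if (!is.null(gm$haplotypes)) {
      gm$haplotypes <- gm$haplotypes[sites, , drop = FALSE]
    }
  }
  gm
}

#' Construct a population map
#'
#' Assigns samples to named groups (e.g. wild / landrace / cultivar, or the
#' demes of a simulation); all group-wise statistics are driven by it.
#'
#' @param assignment named character vector: `names()` are sample IDs, values
#'   are group labels.
#' @return an object of class `pop_map`.
#' @export
pop_map <- function(assignment) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be a named vector (sample -> group)")
  }
  if (anyDuplicated(names(assignment))) stop("duplicate sample IDs in map")
  obj <- list(assignment = assignment, groups = unique(unname(assignment)))
  class(obj) <- "pop_map"
  obj
}

#' @export
print.pop_map <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = x$groups))
  cat("pop_map:", length(x$assignment), "samples in",
      length(x$groups), "group(s)\n")
  for (g in x$groups) cat(sprintf("  %s: %d\n", g, tab[[g]]))
  invisible(x)
}

#' Samples belonging to one or more groups
#'
#' @param pm a `pop_map`.
#' @param groups group label(s).
#' @param gm optional `genotype_matrix`; when given, the result is
#'   intersected with its samples and an empty intersection is an error.
#' @return character vector of sample IDs.
#' @export
group_samples <- function(pm, groups, gm = NULL) {
  unknown <- setdiff(groups, pm$groups)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  }
  ids <- names(pm$assignment)[pm$assignment %in% groups]
  if (!is.null(gm)) {
    ids <- intersect(ids, gm$samples)
    if (!length(ids)) {
      stop("no samples of group(s) ", paste(groups, collapse = "+"),
           " present in the genotype matrix")
    }
  }
  ids
}

#' Read a two-column population map (sample TAB group)
#'
#' @param path TSV file with two columns and no header (a header line
#'   starting with `#` is tolerated).
#' @return a `pop_map`.
#' @export
read_pop_map <- function(path) {
  dt <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "group"),
                          colClasses = "character", comment.char = "#")
  pop_map(stats::setNames(dt$group, dt$sample))
}

#' Write a population map as TSV
#' @param pm a `pop_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(pm, path) {
  utils::write.table(
    data.frame(sample = names(pm$assignment), group = unname(pm$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome lengths from a two-column TSV (chrom TAB length)
#' @param path TSV file.
#' @return named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  dt <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"),
                          comment.char = "#")
  stats::setNames(dt$length, dt$chrom)
}
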