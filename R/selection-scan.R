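#' Weir-Cockerham (1984) per-site variance components, two populations
#'
#' Allele-count (haploid) formulation without the within-individual
#' component: for sample allele counts `n1`, `n2` and alternate-allele
#' frequencies `p1`, `p2`, returns the among-population component `a` and
#' within-population component `b`; the site-wise estimate is `a / (a + b)`
#' and windowed FST is the ratio of sums.  Vectorized; sites where either
#' group has fewer than 2 alleles return `NA` components.
#'
#' @param p1,p2 alternate-allele frequencies in the two groups.
#' @param n1,n2 effective allele counts in the two groups.
#' @return list with numeric vectors `a` (numerator) and `d` (denominator
#'   `a + b`).
#' @export
site_fst_wc <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * inner
  list(a = ifelse(ok, a, NA_real_), d = ifelse(ok, a + b, NA_real_))
}

#' Windowed FST + ROD scan between a wild and a domesticated pool
#'
#' For each window (default 100 kb with 10 kb step): FST as the
#' Weir-Cockerham ratio of sums over usable sites; per-bp diversity of each
#' pool via the diversity module; reduction of diversity
#' `rod = 1 - pi_dom / pi_wild` (NA where `pi_wild = 0`), plus the raw
#' ratio `pi_ratio = pi_wild / pi_dom`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param pm a [pop_map()].
#' @param wild group label(s) pooled as the wild reference.
#' @param dom group label(s) pooled as the domesticated contrast.
#' @param spec a [window_spec()], default `window_spec(1e5, 1e4)`.
#' @return data.table with columns chrom, start, end, n_sites, fst,
#'   pi_wild, pi_dom, rod, pi_ratio.
#' @export
window_scan <- function(gm, pm, wild, dom, spec = window_spec(1e5, 1e4)) {
  wild_ids <- group_samples(pm, wild, gm)
  dom_ids <- group_samples(pm, dom, gm)
  pool <- function(ids) {
    d <- gm$dosages[, ids, drop = FALSE]
    n <- 2 * rowSums(!is.na(d))
    list(freq = ifelse(n > 0, rowSums(d, na.rm = TRUE) / n, NA_real_),
         n = n)
  }
  aw <- pool(wild_ids)
  ad <- pool(dom_ids)
  comp <- site_fst_wc(aw$freq, aw$n, ad$freq, ad$n)

  win <- make_windows(gm$chrom_lengths, spec)
  win[, win_id := .I]
  usable <- which(!is.na(comp$a))
  if (length(usable)) {
    dt <- data.table::data.table(chrom = gm$chrom[usable],
                                 pos = gm$pos[usable],
                                 a = comp$a[usable], d = comp$d[usable])
    cl <- gm$chrom_lengths
    dt[, k_max := pmin(floor((pos - 1) / spec$step),
                       ceiling(cl[chrom] / spec$step) - 1)]
    dt[, k_min := pmax(0, ceiling((pos - spec$size) / spec$step))]
    expanded <- dt[rep(seq_len(.N), k_max - k_min + 1)]
    expanded[, k := sequence(dt$k_max - dt$k_min + 1L, from = dt$k_min)]
    expanded[, start := 1L + k * spec$step]
    agg <- expanded[, .(n_sites = .N, sum_a = sum(a), sum_d = sum(d)),
                    by = .(chrom, start)]
    win <- merge(win, agg, by = c("chrom", "start"), all.x = TRUE)
  } else {
    win[, `:=`(n_sites = NA_integer_, sum_a = NA_real_, sum_d = NA_real_)]
  }
  data.table::setorder(win, win_id)  # merge re-sorts by (chrom, start)
  win[is.na(n_sites), n_sites := 0L]
  win[, fst := ifelse(n_sites > 0 & !is.na(sum_d) & sum_d > 0,
                      sum_a / sum_d, NA_real_)]

  # pool pi vectors come back in win_id order
  dw <- .pool_window_pi(gm, wild_ids, spec)
  dd <- .pool_window_pi(gm, dom_ids, spec)
  win[, pi_wild := dw]
  win[, pi_dom := dd]
  win[, rod := ifelse(!is.na(pi_wild) & pi_wild > 0,
                      1 - pi_dom / pi_wild, NA_real_)]
  win[, pi_ratio := ifelse(!is.na(pi_dom) & pi_dom > 0,
                           pi_wild / pi_dom, NA_real_)]
  data.table::setorder(win, win_id)
  win[, c("chrom", "start", "end", "n_sites", "fst", "pi_wild", "pi_dom",
          "rod", "pi_ratio"), with = FALSE]
}

# per-window theta_pi for an explicit sample pool (bypasses pop_map labels)
.pool_window_pi <- function(gm, ids, spec) {
  d <- gm$dosages[, ids, drop = FALSE]
  n <- 2 * rowSums(!is.na(d))
  freq <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / n, NA_real_)
  w <- .window_site_stats(gm$chrom, gm$pos, freq, n, gm$chrom_lengths, spec)
  w$sum_pi / (w$end - w$start + 1)
}

#' Call selective-sweep regions from a window scan
#'
#' A window qualifies when all three criteria hold: `fst > fst_abs`,
#' `fst >=` the `fst_quantile` quantile of all defined window FST values
#' (closed at the boundary), and `rod > rod_min`.  Qualifying windows that
#' overlap or touch are merged into maximal regions.  Defaults are the
#' domestication-scan thresholds FST > 0.15, top 10% of FST, ROD > 0.2.
#'
#' @param windows output of [window_scan()].
#' @param fst_abs absolute FST threshold (exclusive).
#' @param fst_quantile quantile of defined window FST values (inclusive).
#' @param rod_min ROD threshold (exclusive).
#' @return data.table of regions: chrom, start, end, n_windows, max_fst,
#'   max_rod, with attributes `total_bp` and `fst_cutoff`.
#' @export
call_sweeps <- function(windows, fst_abs = 0.15, fst_quantile = 0.90,
                        rod_min = 0.2) {
  defined <- windows[!is.na(fst)]
  if (nrow(defined) == 0) {
    warning("all windows undefined; no sweep regions callable")
    empty <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), n_windows = integer(),
                                    max_fst = numeric(), max_rod = numeric())
    data.table::setattr(empty, "total_bp", 0)
    return(empty)
  }
  if (nrow(defined) < 10) {
    stop("fewer than 10 windows with defined FST; quantile not meaningful")
  }
  # type = 1 (inverse ECDF) makes the cutoff an observed value, so the
  # '>= cutoff' rule is closed on the boundary as documented
  cutoff <- stats::quantile(defined$fst, fst_quantile, names = FALSE,
                            type = 1)
  qual <- windows[!is.na(fst) & !is.na(rod) & fst > fst_abs &
                  fst >= cutoff & rod > rod_min]
  if (nrow(qual) == 0) {
    empty <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), n_windows = integer(),
                                    max_fst = numeric(), max_rod = numeric())
    data.table::setattr(empty, "total_bp", 0)
    data.table::setattr(empty, "fst_cutoff", cutoff)
    return(empty)
  }
  gr <- GenomicRanges::GRanges(qual$chrom,
                               IRanges::IRanges(qual$start, qual$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  idx <- S4Vectors::subjectHits(hits)
  regions <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    n_windows = as.integer(table(factor(idx, levels = seq_along(merged)))),
    max_fst = as.numeric(tapply(qual$fst[S4Vectors::queryHits(hits)], idx,
                                max)),
    max_rod = as.numeric(tapply(qual$rod[S4Vectors::queryHits(hits)], idx,
                                max)))
  data.table::setorder(regions, chrom, start)
  data.table::setattr(regions, "total_bp", sum(regions$end - regions$start + 1))
  data.table::setattr(regions, "fst_cutoff", cutoff)
  regions
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is converted from 0-based half-open to 1-based inclusive by
#' `rtracklayer`; for GFF3, records of type `gene` are kept when present.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return a `GRanges` with a `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- NULL
  for (f in c("ID", "gene_id", "Name", "name")) {
    if (f %in% colnames(md) && !all(is.na(md[[f]]))) {
      id <- as.character(md[[f]])
      break
    }
  }
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr)$gene_id <- id
  gr
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is assigned to every region its interval overlaps by at least
#' 1 bp (1-based inclusive coordinates on both sides).  Genes on
#' chromosomes absent from the regions' universe are skipped with a
#' warning.
#'
#' @param regions output of [call_sweeps()].
#' @param genes a `GRanges` with `gene_id` metadata (see
#'   [read_gene_annotation()]) or a path to a BED/GFF3 file.
#' @param chrom_lengths optional named vector defining known chromosomes;
#'   default: chromosomes seen in `regions`.
#' @return `regions` with a list-column `genes` and column `n_genes`.
#' @export
annotate_regions <- function(regions, genes, chrom_lengths = NULL) {
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  known <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(regions$chrom)
  off <- !(as.character(GenomicRanges::seqnames(genes)) %in% known)
  if (any(off)) {
    warning(sum(off), " gene(s) on unknown chromosomes skipped")
    genes <- genes[!off]
  }
  if (nrow(regions) == 0) {
    regions[, genes := list()]
    regions[, n_genes := integer()]
    return(regions)
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(rg, genes, minoverlap = 1L)
  gl <- split(S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions[, genes := lapply(gl, unique)]
  regions[, n_genes := vapply(genes, length, 0L)]
  regions
}

#' Write sweep regions as BED (0-based half-open) and TSV (1-based)
#'
#' @param regions annotated or raw output of [call_sweeps()].
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_sweep_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                      end = regions$end)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    out <- data.table::copy(regions)
    if ("genes" %in% names(out)) {
      out[, genes := vapply(genes, paste, "", collapse = ",")]
    }
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
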