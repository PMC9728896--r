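#' Apply site-retention filters
#'
#' Retains sites that satisfy, with strict inequalities, all of:
#' 1. biallelic (exactly one alternate allele),
#' 2. quality score `> qual_min`,
#' 3. missing rate (fraction of samples with a missing call) `< mr_max`,
#' 4. minor allele frequency, computed from non-missing calls, `> maf_min`.
#'
#' A site failing several rules is attributed to the first failing rule in
#' the fixed order biallelic, qual, missing-rate, maf, so the report always
#' reconciles: `n_input == n_kept + sum(n_dropped_by_rule)`.  Sites with a
#' missing quality score fail the qual rule; a site with all calls missing is
#' dropped by the missing-rate rule (MAF is never computed on zero calls).
#'
#' @param gm a [genotype_matrix()].
#' @param qual_min minimum quality score, exclusive (default 30).
#' @param mr_max maximum missing-call fraction, exclusive (default 0.25).
#' @param maf_min minimum minor allele frequency, exclusive (default 0.05).
#' @return list with elements `gm` (filtered matrix, site order preserved)
#'   and `report` (a `filter_report`: `n_input`, `n_kept`,
#'   `n_dropped_by_rule`).
#' @export
apply_site_filters <- function(gm, qual_min = 30, mr_max = 0.25,
                               maf_min = 0.05) {
  if (n_sites(gm) == 0) stop("empty genotype matrix")
  biallelic <- lengths(gm$alt) == 1L
  qual_ok <- !is.na(gm$qual) & gm$qual > qual_min
  mr <- rowMeans(is.na(gm$dosages))
  mr_ok <- mr < mr_max
  n_called <- rowSums(!is.na(gm$dosages))
  freq <- ifelse(n_called > 0,
                 rowSums(gm$dosages, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(freq, 1 - freq)
  maf_ok <- !is.na(maf) & maf > maf_min

  rules <- cbind(biallelic = biallelic, qual = qual_ok,
                 missing_rate = mr_ok, maf = maf_ok)
  keep <- rowSums(rules) == ncol(rules)
  first_fail <- apply(!rules, 1, function(z) which(z)[1])  # NA when kept
  drops <- table(factor(colnames(rules)[first_fail[!keep]],
                        levels = colnames(rules)))

  report <- structure(list(
    n_input = n_sites(gm), n_kept = sum(keep),
    n_dropped_by_rule = stats::setNames(as.integer(drops), names(drops))),
    class = "filter_report")
  list(gm = subset_genotypes(gm, sites = keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in, %d kept\n", x$n_input, x$n_kept))
  for (r in names(x$n_dropped_by_rule)) {
    cat(sprintf("  dropped by %s: %d\n", r, x$n_dropped_by_rule[[r]]))
  }
  invisible(x)
}

#' Per-site alternate-allele frequency within a group
#'
#' The frequency is computed over non-missing calls only:
#' `freq = sum(dosages) / (2 * non-missing samples)`; the effective allele
#' count `n = 2 * non-missing samples` accompanies it.  Sites with no called
#' sample in the group have `n = 0` and `freq = NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [pop_map()].
#' @param group group label present in `pm`.
#' @return list with numeric vectors `freq` and `n` (one entry per site).
#' @export
group_allele_freq <- function(gm, pm, group) {
  ids <- group_samples(pm, group, gm)
  d <- gm$dosages[, ids, drop = FALSE]
  n <- 2 * rowSums(!is.na(d))
  freq <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / n, NA_real_)
  list(freq = freq, n = n)
}
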