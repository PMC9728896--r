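#' Four-population ABBA-BABA D statistic from allele frequencies
#'
#' `d = sum((w - x) * (y - z)) / sum((w + x - 2*w*x) * (y + z - 2*y*z))`
#' over informative sites (denominator term > 0, all four frequencies
#' defined, outgroup effectively fixed).  For single haploid sequences this
#' equals `(nBABA - nABBA) / (nABBA + nBABA)`: positive values indicate
#' excess allele sharing between W and Y (or X and Z), negative between W
#' and Z (or X and Y) -- see [interpret_sign()].  Sites where the outgroup
#' frequency is further than `outgroup_tol` from 0 or 1 are excluded, since
#' the outgroup orients the ancestral allele.
#'
#' @param freq_w,freq_x,freq_y,freq_z per-site alternate-allele
#'   frequencies; Z is the outgroup.
#' @param outgroup_tol tolerance around 0/1 for the outgroup frequency
#'   (default 0.01).
#' @return list with `d`, per-site `num` and `den` (informative sites
#'   only), `site_index` (their positions in the input), `n_sites`.
#' @export
d_statistic <- function(freq_w, freq_x, freq_y, freq_z,
                        outgroup_tol = 0.01) {
  ok <- !is.na(freq_w) & !is.na(freq_x) & !is.na(freq_y) & !is.na(freq_z) &
    (freq_z <= outgroup_tol | freq_z >= 1 - outgroup_tol)
  num <- (freq_w - freq_x) * (freq_y - freq_z)
  den <- (freq_w + freq_x - 2 * freq_w * freq_x) *
    (freq_y + freq_z - 2 * freq_y * freq_z)
  keep <- which(ok & den > 0)
  if (!length(keep)) {
    return(list(d = NA_real_, num = numeric(0), den = numeric(0),
                site_index = integer(0), n_sites = 0L))
  }
  list(d = sum(num[keep]) / sum(den[keep]), num = num[keep],
       den = den[keep], site_index = keep, n_sites = length(keep))
}

#' Block-jackknife Z score for a ratio statistic
#'
#' Delete-one-block jackknife over contiguous genomic blocks: the statistic
#' is recomputed leaving each block out, the jackknife standard error is
#' taken over those leave-one-out values, and `z = d / SE`.  Degenerate
#' case: when every leave-one-out value is identical the SE is 0 and `z`
#' is `Inf` with the sign of `d` (flagged, not an error).
#'
#' @param num,den per-site numerator/denominator contributions.
#' @param block integer block id per site (contiguous genomic spans).
#' @return list with `z`, `se`, `d`, `n_blocks`, `degenerate`.
#' @export
jackknife_z <- function(num, den, block) {
  stopifnot(length(num) == length(den), length(num) == length(block))
  bn <- tapply(num, block, sum)
  bd <- tapply(den, block, sum)
  B <- length(bn)
  if (B < 10) {
    stop("only ", B, " non-empty jackknife blocks; use a smaller block size")
  }
  tot_n <- sum(bn); tot_d <- sum(bd)
  d_hat <- tot_n / tot_d
  loo <- (tot_n - bn) / (tot_d - bd)
  if (any(!is.finite(loo))) {
    stop("a jackknife block carries the entire denominator; ",
         "use a smaller block size")
  }
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  degenerate <- se == 0
  z <- if (degenerate) {
    if (d_hat == 0) 0 else sign(d_hat) * Inf
  } else {
    d_hat / se
  }
  list(z = z, se = se, d = d_hat, n_blocks = B, degenerate = degenerate)
}

#' Interpret the sign and significance of a D-statistic Z score
#'
#' For a quartet (W, X, Y, Z) with Z the outgroup: a positive Z score
#' indicates gene flow between W and Y or between X and Z; a negative Z
#' score indicates gene flow between W and Z or X and Y; the signal is
#' significant when the Z score is more than 3 or less than -3.
#'
#' @param d the D statistic.
#' @param z the jackknife Z score.
#' @return interpretation string.
#' @export
interpret_sign <- function(d, z) {
  if (is.na(z) || abs(z) <= 3) return("not significant")
  if (z > 3) "gene flow between W and Y or between X and Z; significant"
  else "gene flow between W and Z or X and Y; significant"
}

#' Four-population D test on a genotype matrix
#'
#' Computes group allele frequencies for the quartet, the D statistic over
#' informative sites, and a block-jackknife Z score over contiguous
#' genomic blocks.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param pm a [pop_map()].
#' @param quartet character vector of four group labels, ordered
#'   (W, X, Y, Z) with Z the outgroup.
#' @param block_size jackknife block span in bp (default 5e6); `NULL`
#'   chooses total-span / 20 (useful for short simulated chromosomes).
#'   An explicit block size yielding fewer than 10 blocks is an error.
#' @param outgroup_tol see [d_statistic()].
#' @return a `dstat_result`: list with `pops`, `d`, `z_score`, `se`,
#'   `n_blocks`, `n_sites`, `significant`, `direction`.
#' @export
d_test <- function(gm, pm, quartet, block_size = 5e6, outgroup_tol = 0.01) {
  stopifnot(length(quartet) == 4)
  fr <- lapply(quartet, function(g) group_allele_freq(gm, pm, g)$freq)
  ds <- d_statistic(fr[[1]], fr[[2]], fr[[3]], fr[[4]],
                    outgroup_tol = outgroup_tol)
  if (ds$n_sites == 0) stop("no informative sites for quartet")
  if (is.null(block_size)) {
    span <- sum(gm$chrom_lengths)
    block_size <- max(1, ceiling(span / 20))
  }
  chrom <- gm$chrom[ds$site_index]
  pos <- gm$pos[ds$site_index]
  block <- paste0(chrom, ":", (pos - 1) %/% block_size)
  jk <- jackknife_z(ds$num, ds$den, block)
  res <- list(pops = stats::setNames(quartet, c("W", "X", "Y", "Z")),
              d = ds$d, z_score = jk$z, se = jk$se, n_blocks = jk$n_blocks,
              n_sites = ds$n_sites,
              significant = is.finite(jk$z) && abs(jk$z) > 3 ||
                is.infinite(jk$z),
              direction = interpret_sign(ds$d, jk$z))
  class(res) <- "dstat_result"
  res
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D(%s) = %.4f, Z = %.2f (%d blocks, %d sites)\n",
              paste(x$pops, collapse = ", "), x$d, x$z_score, x$n_blocks,
              x$n_sites))
  cat("  ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Wright's island-model migrant number from FST
#'
#' `Nm = (1 - FST) / (4 * FST)`, defined for FST in (0, 1]; non-positive
#' FST implies effectively unbounded migration and returns `NA` with a
#' warning.
#'
#' @param fst FST estimate(s).
#' @return Nm value(s); `NA` where undefined.
#' @export
nm_from_fst <- function(fst) {
  out <- ifelse(!is.na(fst) & fst > 0 & fst <= 1,
                (1 - fst) / (4 * fst), NA_real_)
  if (any(!is.na(fst) & fst <= 0)) {
    warning("FST <= 0: Nm undefined (unbounded migration)")
  }
  out
}
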