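#' Sliding-window specification
#'
#' Windows start at 1, 1 + step, 1 + 2*step, ... on every chromosome; the
#' last window is truncated at the chromosome end and normalized by its true
#' length.  The defaults (10 kb windows, 5 kb step) are the diversity-scan
#' settings; the selection scan uses 100 kb / 10 kb.
#'
#' @param size window size (bp), > 0.
#' @param step step (bp), 0 < step <= size.
#' @return a `window_spec`.
#' @export
window_spec <- function(size = 10000, step = 5000) {
  stopifnot(size > 0, step > 0, step <= size)
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "window_spec")
}

#' Enumerate windows over chromosomes
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param spec a [window_spec()].
#' @return data.table with columns chrom, start, end (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, spec) {
  out <- lapply(names(chrom_lengths), function(cc) {
    len <- chrom_lengths[[cc]]
    starts <- seq(1L, as.integer(len), by = spec$step)
    data.table::data.table(chrom = cc, start = starts,
                           end = pmin(starts + spec$size - 1L,
                                      as.integer(len)))
  })
  data.table::rbindlist(out)
}

#' Tajima (1989) normalization constants
#'
#' @param n number of sampled haplotypes (>= 2; the D variance terms need
#'   n >= 4 to be usable in practice).
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# harmonic numbers a1(n) = sum_{i<n} 1/i, vectorized over n
.a1 <- function(n) {
  mx <- max(n, 2)
  h <- c(0, cumsum(1 / seq_len(mx - 1)))
  h[pmax(n, 1)]
}

#' Unbiased per-site heterozygosity
#'
#' `(n / (n - 1)) * 2 * freq * (1 - freq)`: the mean pairwise difference at
#' one site over the n observed alleles.  Vectorized; `NA` where `n < 2`.
#'
#' @param freq alternate-allele frequency in `[0, 1]`.
#' @param n effective allele count (2 x non-missing samples).
#' @return numeric vector of per-site pi values.
#' @export
site_pi <- function(freq, n) {
  ifelse(!is.na(freq) & n >= 2,
         n / (n - 1) * 2 * freq * (1 - freq), NA_real_)
}

# shared per-window aggregator: given per-site chrom/pos/freq/n restricted to
# one group, sum site_pi and Watterson contributions per window
.window_site_stats <- function(chrom, pos, freq, n, chrom_lengths, spec) {
  called <- !is.na(freq) & n >= 2
  seg <- called & freq > 0 & freq < 1
  dt <- data.table::data.table(chrom = chrom, pos = pos,
                               pi = ifelse(seg, site_pi(freq, n), 0),
                               wat = ifelse(seg, 1 / .a1(pmax(n, 2)), 0),
                               n_eff = n, seg = seg)
  dt <- dt[seg == TRUE]
  win <- make_windows(chrom_lengths, spec)
  win[, win_id := .I]
  if (nrow(dt) == 0) {
    agg <- data.table::data.table(win_id = integer(), S = integer(),
                                  sum_pi = numeric(), sum_wat = numeric(),
                                  mean_n = numeric(), min_n = numeric(),
                                  max_n = numeric())
  } else {
    # each site belongs to every window whose [start, end] contains it
    dt[, k_max := pmin(floor((pos - 1) / spec$step),
                       ceiling(chrom_lengths[chrom] / spec$step) - 1)]
    # smallest k with window start 1 + k*step >= pos - size + 1
    dt[, k_min := pmax(0, ceiling((pos - spec$size) / spec$step))]
    expanded <- dt[rep(seq_len(.N), k_max - k_min + 1)]
    expanded[, k := sequence(dt$k_max - dt$k_min + 1L, from = dt$k_min)]
    expanded[, start := 1L + k * spec$step]
    agg <- expanded[, .(S = .N, sum_pi = sum(pi), sum_wat = sum(wat),
                        mean_n = mean(n_eff), min_n = min(n_eff),
                        max_n = max(n_eff)),
                    by = .(chrom, start)]
    agg <- merge(win, agg, by = c("chrom", "start"), all.x = TRUE)
  }
  out <- merge(win, agg[, setdiff(names(agg), c("chrom", "start", "end")),
                        with = FALSE],
               by = "win_id", all.x = TRUE)
  out[is.na(S), `:=`(S = 0L, sum_pi = 0, sum_wat = 0)]
  out[, win_id := NULL]
  out[]
}

#' Windowed diversity statistics for one group
#'
#' Per window: theta-pi (sum of per-site unbiased heterozygosities divided
#' by window length in bp), Watterson's theta-w (sum over segregating sites
#' of `1 / a1(n_i)` divided by window length, with `a1` evaluated at each
#' site's effective allele count), Tajima's D, and SNP density.  Tajima's D
#' uses a single haplotype count per window, the rounded mean effective
#' allele count over segregating sites, and is `NA` when `S < 2` or that
#' count is `< 4`.  Windows where the effective allele count varies more
#' than two-fold are flagged in `n_varies`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param pm a [pop_map()].
#' @param group group label.
#' @param spec a [window_spec()] (default 10 kb / 5 kb).
#' @return data.table with columns chrom, start, end, group, n_snps,
#'   snp_per_kb, theta_pi, theta_w, tajimas_d, n_eff, n_varies.
#' @export
window_diversity <- function(gm, pm, group, spec = window_spec()) {
  af <- group_allele_freq(gm, pm, group)
  w <- .window_site_stats(gm$chrom, gm$pos, af$freq, af$n,
                          gm$chrom_lengths, spec)
  w[, len := end - start + 1]
  w[, `:=`(group = group, n_snps = S, snp_per_kb = 1000 * S / len,
           theta_pi = sum_pi / len, theta_w = sum_wat / len)]
  w[, tajimas_d := {
    nr <- round(mean_n)
    d <- rep(NA_real_, .N)
    ok <- which(S >= 2 & !is.na(nr) & nr >= 4)
    for (i in ok) {
      k <- tajima_constants(nr[i])
      vard <- k$e1 * S[i] + k$e2 * S[i] * (S[i] - 1)
      if (vard > 0) d[i] <- (sum_pi[i] - S[i] / k$a1) / sqrt(vard)
    }
    d
  }]
  w[, n_varies := !is.na(min_n) & max_n > 2 * min_n]
  data.table::setnames(w, "mean_n", "n_eff")
  w[, c("chrom", "start", "end", "group", "n_snps", "snp_per_kb",
        "theta_pi", "theta_w", "tajimas_d", "n_eff", "n_varies"),
    with = FALSE]
}

#' Genome-wide diversity summary for a group
#'
#' Window means weighted by window length, alongside unweighted means, plus
#' the genome-wide segregating-site count and SNP density computed directly
#' from the site table (not from overlapping windows, which would double
#' count).
#'
#' @inheritParams window_diversity
#' @return list: `n_snps`, `snp_per_kb`, `theta_pi`, `theta_w`,
#'   `tajimas_d`, and `unweighted` (means over windows).
#' @export
group_summary <- function(gm, pm, group, spec = window_spec()) {
  w <- window_diversity(gm, pm, group, spec)
  af <- group_allele_freq(gm, pm, group)
  seg <- !is.na(af$freq) & af$n >= 2 & af$freq > 0 & af$freq < 1
  len <- w$end - w$start + 1
  wmean <- function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * len[ok]) / sum(len[ok])
  }
  list(group = group, n_snps = sum(seg),
       snp_per_kb = 1000 * sum(seg) / sum(gm$chrom_lengths),
       theta_pi = wmean(w$theta_pi), theta_w = wmean(w$theta_w),
       tajimas_d = wmean(w$tajimas_d),
       unweighted = list(theta_pi = mean(w$theta_pi, na.rm = TRUE),
                         theta_w = mean(w$theta_w, na.rm = TRUE),
                         tajimas_d = mean(w$tajimas_d, na.rm = TRUE)))
}
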