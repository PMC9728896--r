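#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of dosage vectors over samples that are
#' non-missing at both sites.  `NA` when fewer than two shared samples
#' remain or either vector is constant on them.
#'
#' @param dosages_a,dosages_b numeric dosage vectors of equal length.
#' @return scalar r-squared, or `NA`.
#' @export
pair_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# r2 for an explicit pair list (i, j site indices), chunked and vectorized;
# X is the dosage matrix (sites x samples); chunks kept small so temporary
# samples x chunk matrices stay a few MB
.pair_r2_many <- function(X, i_idx, j_idx, chunk = 20000L) {
  np <- length(i_idx)
  out <- numeric(np)
  Xt <- t(X)  # samples x sites, one transpose up front
  storage.mode(Xt) <- "double"
  for (lo in seq(1, np, by = chunk)) {
    hi <- min(lo + chunk - 1L, np)
    A <- Xt[, i_idx[lo:hi], drop = FALSE]
    B <- Xt[, j_idx[lo:hi], drop = FALSE]
    M <- !is.na(A) & !is.na(B)
    A[!M] <- 0; B[!M] <- 0
    n <- colSums(M)
    sa <- colSums(A); sb <- colSums(B)
    saa <- colSums(A * A); sbb <- colSums(B * B)
    sab <- colSums(A * B)
    num <- (n * sab - sa * sb)^2
    den <- (n * saa - sa^2) * (n * sbb - sb^2)
    out[lo:hi] <- ifelse(n >= 2 & den > 0, num / den, NA_real_)
  }
  out
}

#' Distance-binned LD decay curve with half-decay distance
#'
#' All intra-chromosomal site pairs separated by at most `max_dist` bp
#' contribute their r-squared to the bin of their distance.  The curve is
#' the per-bin mean; the half-decay distance is where the (lightly
#' smoothed) curve first falls to half of its maximum bin mean, linearly
#' interpolated between the last bin above max/2 and the first at or below
#' it.  When the number of pairs exceeds `max_pairs` a uniform seeded
#' subsample is used and recorded in the result.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param pm optional [pop_map()] (with `group`) restricting samples.
#' @param group optional group label.
#' @param max_dist maximum pair separation (bp), default 200 kb.
#' @param bin_width bin width (bp), default 100.
#' @param max_pairs cap on the number of pairs (default 5e6).
#' @param smooth rolling-mean half-width in bins applied before locating
#'   the half-decay crossing (default 2, i.e. a 5-bin window); 0 disables.
#' @param seed seed for pair subsampling.
#' @return an `ld_decay_curve`: list with `bins` (data.table bin_mid_bp,
#'   mean_r2, n_pairs), `mean_r2`, `max_r2`, `half_distance_bp`,
#'   `n_pairs_total`, `subsampled`, `seed`.
#' @export
decay_curve <- function(gm, pm = NULL, group = NULL, max_dist = 2e5,
                        bin_width = 100, max_pairs = 5e6, smooth = 2,
                        seed = 1) {
  X <- gm$dosages
  if (!is.null(pm) && !is.null(group)) {
    X <- X[, group_samples(pm, group, gm), drop = FALSE]
  }
  # enumerate pairs per chromosome within max_dist
  i_all <- integer(0); j_all <- integer(0)
  for (cc in unique(gm$chrom)) {
    idx <- which(gm$chrom == cc)
    p <- gm$pos[idx]
    jmax <- findInterval(p + max_dist, p)
    reps <- pmax(jmax - seq_along(p), 0L)
    if (sum(reps) == 0) next
    ii <- rep(seq_along(p), reps)
    jj <- unlist(Map(function(a, b) if (b > a) (a + 1L):b else integer(0),
                     seq_along(p), jmax))
    i_all <- c(i_all, idx[ii]); j_all <- c(j_all, idx[jj])
  }
  n_total <- length(i_all)
  if (n_total == 0) {
    return(structure(list(bins = data.table::data.table(
      bin_mid_bp = numeric(), mean_r2 = numeric(), n_pairs = integer()),
      mean_r2 = NA_real_, max_r2 = NA_real_, half_distance_bp = NA_real_,
      n_pairs_total = 0L, subsampled = FALSE, seed = seed),
      class = "ld_decay_curve"))
  }
  subsampled <- n_total > max_pairs
  if (subsampled) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    keep <- sample.int(n_total, max_pairs)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    i_all <- i_all[keep]; j_all <- j_all[keep]
  }
  r2 <- .pair_r2_many(X, i_all, j_all)
  dist <- abs(gm$pos[j_all] - gm$pos[i_all])
  ok <- !is.na(r2)
  dt <- data.table::data.table(
    bin = pmax(1L, as.integer(ceiling(dist[ok] / bin_width))),
    r2 = r2[ok])
  bins <- dt[, .(mean_r2 = mean(r2), n_pairs = .N), by = bin]
  data.table::setorder(bins, bin)
  bins[, bin_mid_bp := (bin - 0.5) * bin_width]

  curve <- structure(list(
    bins = bins[, .(bin_mid_bp, mean_r2, n_pairs)],
    mean_r2 = mean(dt$r2), max_r2 = NA_real_,
    half_distance_bp = NA_real_, n_pairs_total = n_total,
    subsampled = subsampled, seed = seed), class = "ld_decay_curve")
  curve$max_r2 <- if (nrow(bins)) max(bins$mean_r2) else NA_real_
  curve$half_distance_bp <- half_decay_distance(curve, smooth = smooth)
  curve
}

#' Half-decay distance of an LD curve
#'
#' Distance at which the smoothed bin-mean r-squared first drops to half
#' of its maximum, scanning rightwards from the maximum and interpolating
#' linearly between the last bin above the target and the first at or
#' below it.  `NA` when the curve never reaches half of its maximum.
#'
#' @param curve an `ld_decay_curve` (or its `bins` table).
#' @param smooth rolling-mean half-width in bins (default 2).
#' @return distance in bp, or `NA`.
#' @export
half_decay_distance <- function(curve, smooth = 2) {
  bins <- if (inherits(curve, "ld_decay_curve")) curve$bins else curve
  if (nrow(bins) < 2) return(NA_real_)
  y <- bins$mean_r2
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    y <- as.numeric(y)
    # shrink the window at the edges instead of dropping them
    n <- length(y)
    for (i in which(is.na(y))) {
      lo <- max(1, i - smooth); hi <- min(n, i + smooth)
      y[i] <- mean(bins$mean_r2[lo:hi])
    }
  }
  imax <- which.max(y)
  target <- y[imax] / 2
  below <- which(y <= target & seq_along(y) > imax)
  if (!length(below)) return(NA_real_)
  i2 <- below[1]
  i1 <- i2 - 1L
  x1 <- bins$bin_mid_bp[i1]; x2 <- bins$bin_mid_bp[i2]
  y1 <- y[i1]; y2 <- y[i2]
  if (y1 == y2) return(x2)
  x1 + (y1 - target) / (y1 - y2) * (x2 - x1)
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  cat(sprintf(
    "ld_decay_curve: %d pairs%s, mean r2 %.4f, max bin mean %.4f\n",
    x$n_pairs_total, if (x$subsampled) " (subsampled)" else "",
    x$mean_r2, x$max_r2))
  cat(sprintf("  half-decay distance: %s bp\n",
              format(x$half_distance_bp)))
  invisible(x)
}

#' Mean r-squared over all counted pairs
#'
#' Unweighted mean over pair r-squared values within `max_dist`; equals the
#' n_pairs-weighted mean of the decay-curve bins.
#'
#' @inheritParams decay_curve
#' @return scalar mean r-squared.
#' @export
group_mean_r2 <- function(gm, pm = NULL, group = NULL, max_dist = 2e5,
                          max_pairs = 5e6, seed = 1) {
  decay_curve(gm, pm, group, max_dist = max_dist, max_pairs = max_pairs,
              seed = seed)$mean_r2
}
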