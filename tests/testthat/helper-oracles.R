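# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each statistic from first principles (enumeration over samples,
# alleles or site patterns) and never call the package's own implementations.

# mean pairwise difference at one site over explicit allele vectors
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  alleles <- unname(alleles)
  diff <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diff <- diff + (alleles[i] != alleles[j])
  }
  diff / choose(n, 2)
}

# expand a dosage vector into alleles (0/1), dropping missing samples
dosage_to_alleles <- function(d) {
  d <- d[!is.na(d)]
  unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
}

# window theta_pi by direct average pairwise difference over sites
oracle_window_pi <- function(dosages, window_len) {
  tot <- 0
  for (s in seq_len(nrow(dosages))) {
    al <- dosage_to_alleles(dosages[s, ])
    if (length(al) >= 2) tot <- tot + oracle_site_pi(al)
  }
  tot / window_len
}

# Weir & Cockerham (1984) two-population components, textbook transcription
# (haploid / allele-count form), scalar inputs
oracle_wc_fst <- function(p1, n1, p2, n2) {
  if (n1 < 2 || n2 < 2) return(c(a = NA, d = NA))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- ((n1 + n2) - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  h <- pbar * (1 - pbar) - ssq * (r - 1) / r
  a <- (nbar / nc) * (ssq - h / (nbar - 1))
  b <- (nbar / (nbar - 1)) * h
  c(a = a, d = a + b)
}

# r^2 from the covariance definition over shared non-missing samples
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  ca <- a - mean(a); cb <- b - mean(b)
  va <- sum(ca^2); vb <- sum(cb^2)
  if (va == 0 || vb == 0) return(NA_real_)
  sum(ca * cb)^2 / (va * vb)
}

# ABBA/BABA counting for haploid populations given 0/1 allele matrices
# (rows = sites, cols W,X,Y,Z): D = (nBABA - nABBA) / (nABBA + nBABA)
oracle_d_haploid <- function(m) {
  abba <- sum(m[, 1] == m[, 4] & m[, 2] == m[, 3] & m[, 1] != m[, 2])
  baba <- sum(m[, 1] == m[, 3] & m[, 2] == m[, 4] & m[, 1] != m[, 2])
  if (abba + baba == 0) return(NA_real_)
  (baba - abba) / (abba + baba)
}

# p-distance by exhaustive per-site minimum allele pairing
oracle_p_distance <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  if (!any(ok)) return(NA_real_)
  sum(abs(da[ok] - db[ok])) / (2 * sum(ok))
}

# brute-force interval overlap (1-based inclusive)
oracle_overlaps <- function(r_start, r_end, g_start, g_end) {
  r_start <= g_end & g_start <= r_end
}

# random dosage matrix with optional missingness; sites x samples
random_dosage_matrix <- function(n_sites, n_samples, miss = 0,
                                 chrom_len = 1e5) {
  d <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  pos <- sort(sample.int(chrom_len, n_sites))
  samples <- sprintf("s%02d", seq_len(n_samples))
  genotype_matrix(samples = samples, chrom = rep("chr1", n_sites),
                  pos = pos, ref = rep("A", n_sites),
                  alt = rep(list("T"), n_sites),
                  qual = rep(60, n_sites), dosages = d,
                  chrom_lengths = c(chr1 = chrom_len))
}

# the 6-site toy matrix in which exactly one site fails each filter rule
# (triallelic; qual 25; missing rate 0.30; MAF 0.02) and two sites pass
toy_filter_matrix <- function() {
  n <- 50  # 50 samples so MR/MAF values are exact
  mk <- function(dos) dos
  # site 3: 15/50 missing = 0.30 >= 0.25 -> missing-rate fail
  s3 <- c(rep(NA, 15), rep(1, 10), rep(0, 25))
  # site 4: MAF 0.02 -> 2 alt alleles among 100
  s4 <- c(2, rep(0, 49))
  # sites 5, 6 pass: MAF 0.2, qual high, no missing
  s5 <- c(rep(1, 20), rep(0, 30))
  s6 <- c(rep(2, 10), rep(0, 40))
  dos <- rbind(
    site1 = mk(rep(c(0, 1), 25)),    # triallelic (alt has 2 entries)
    site2 = mk(rep(c(1, 0), 25)),    # qual 25 -> qual fail
    site3 = s3, site4 = s4, site5 = s5, site6 = s6)
  genotype_matrix(
    samples = sprintf("s%02d", 1:n),
    chrom = rep("chr1", 6), pos = c(100, 200, 300, 400, 500, 600),
    ref = rep("A", 6),
    alt = list(c("T", "G"), "T", "T", "T", "T", "T"),
    qual = c(80, 25, 80, 80, 80, 80),
    dosages = unname(dos), chrom_lengths = c(chr1 = 1000))
}

# the toy filter matrix rendered as a 50-sample VCF (dosage -> GT strings;
# the triallelic site uses a 1/2 call for its dosage-2 sample)
write_toy_filter_vcf <- function(path) {
  gm <- toy_filter_matrix()
  gt_of <- function(d, multi = FALSE) {
    if (is.na(d)) return("./.")
    if (multi && d == 2) return("1/2")
    c("0/0", "0/1", "1/1")[d + 1]
  }
  rows <- vapply(seq_len(n_sites(gm)), function(s) {
    gts <- vapply(gm$dosages[s, ], gt_of, "",
                  multi = length(gm$alt[[s]]) > 1)
    paste(c(gm$chrom[s], gm$pos[s], ".", gm$ref[s],
            paste(gm$alt[[s]], collapse = ","), gm$qual[s], ".", ".",
            "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"),
    rows), path)
  path
}

# tiny deterministic 3-sample VCF exercising dosage coding and missing calls
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampleA", "sampleB", "sampleC", sep = "\t"),
    paste("chr1", "10", ".", "A", "T", "50", ".", ".", "GT",
          "0/0", "0/1", "./.", sep = "\t"),
    paste("chr1", "25", ".", "G", "C", "45", ".", ".", "GT",
          "1/1", "1|0", "0/0", sep = "\t"),
    paste("chr1", "40", ".", "C", "A,G", "20", ".", ".", "GT",
          "1/2", "0/0", "0/1", sep = "\t")), path)
  path
}
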