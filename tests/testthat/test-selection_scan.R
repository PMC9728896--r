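test_that("site_fst_wc matches fixed-difference and no-differentiation limits", {
  fixed <- site_fst_wc(1, 20, 0, 20)
  expect_equal(fixed$a / fixed$d, 1)
  same <- site_fst_wc(0.3, 20, 0.3, 40)
  expect_lte(same$a, 0)
  skip <- site_fst_wc(0.5, 1, 0.5, 20)
  expect_true(is.na(skip$a))
})

test_that("site_fst_wc equals an independent WC84 transcription", {
  set.seed(5)
  for (rep in 1:200) {
    n1 <- 2 * sample(2:30, 1); n2 <- 2 * sample(2:30, 1)
    p1 <- sample(0:n1, 1) / n1; p2 <- sample(0:n2, 1) / n2
    mine <- site_fst_wc(p1, n1, p2, n2)
    orc <- oracle_wc_fst(p1, n1, p2, n2)
    expect_equal(mine$a, unname(orc["a"]), tolerance = 1e-10)
    expect_equal(mine$d, unname(orc["d"]), tolerance = 1e-10)
  }
})

test_that("window_scan: identical pools give fst ~ 0 and rod = 0", {
  sim <- fix_two_deme()
  pm2 <- pop_map(setNames(rep(c("wildish", "domish"),
                              each = length(sim$gm$samples) / 2),
                          sim$gm$samples))
  # same samples on both sides via duplicated labels
  ids <- sim$gm$samples
  pm_same <- pop_map(setNames(rep("all", length(ids)), ids))
  sc <- window_scan(sim$gm, pm_same, "all", "all", window_spec(2e4, 2e4))
  # identical pools: s2 = 0 at every site, so the ratio of sums collapses
  # to the estimator's exact small negative offset -1/(nbar - 1)
  nbar <- 2 * length(ids)
  expect_true(all(abs(sc$fst + 1 / (nbar - 1)) < 1e-9 | is.na(sc$fst)))
  expect_true(all(abs(sc$fst) < 0.02, na.rm = TRUE))
  expect_true(all(abs(sc$rod) < 1e-12, na.rm = TRUE))
  expect_equal(sc$pi_wild, sc$pi_dom)
})

test_that("rod follows its definition and label swap maps it as 1 - 1/(1-rod)", {
  expect_equal(1 - 0.002 / 0.004, 0.5)  # definition sanity
  sim <- fix_two_deme()
  sc1 <- window_scan(sim$gm, sim$pm, "deme1", "deme2", window_spec(2e4, 2e4))
  sc2 <- window_scan(sim$gm, sim$pm, "deme2", "deme1", window_spec(2e4, 2e4))
  expect_equal(sc1$fst, sc2$fst, tolerance = 1e-10)
  ok <- !is.na(sc1$rod) & !is.na(sc2$rod) & sc1$rod < 1
  expect_equal(sc2$rod[ok], 1 - 1 / (1 - sc1$rod[ok]), tolerance = 1e-10)
  expect_equal(sc1$rod, 1 - sc1$pi_dom / sc1$pi_wild, tolerance = 1e-12)
})

test_that("window FST equals per-window brute-force recomputation", {
  sim <- fix_two_deme()
  sc <- window_scan(sim$gm, sim$pm, "deme1", "deme2", window_spec(2e4, 1e4))
  f1 <- group_allele_freq(sim$gm, sim$pm, "deme1")
  f2 <- group_allele_freq(sim$gm, sim$pm, "deme2")
  for (i in sample(nrow(sc), 5)) {
    rows <- which(sim$gm$chrom == sc$chrom[i] & sim$gm$pos >= sc$start[i] &
                  sim$gm$pos <= sc$end[i])
    comps <- t(vapply(rows, function(s) {
      oracle_wc_fst(f1$freq[s], f1$n[s], f2$freq[s], f2$n[s])
    }, c(a = 0, d = 0)))
    expect_equal(sc$fst[i], sum(comps[, "a"]) / sum(comps[, "d"]),
                 tolerance = 1e-9)
  }
})

test_that("window_scan keeps window order when chrom names sort non-numerically", {
  set.seed(41)
  # chr10 sorts before chr2 alphabetically; window order must not care
  cl <- c(chr2 = 6000, chr10 = 6000)
  ns <- 60
  chrom <- rep(names(cl), each = ns / 2)
  pos <- c(sort(sample.int(6000, ns / 2)), sort(sample.int(6000, ns / 2)))
  d <- matrix(sample(0:2, ns * 8, replace = TRUE), ns, 8)
  gm <- genotype_matrix(samples = sprintf("s%d", 1:8), chrom = chrom,
                        pos = pos, ref = rep("A", ns),
                        alt = rep(list("T"), ns), qual = rep(60, ns),
                        dosages = d, chrom_lengths = cl)
  pm <- pop_map(setNames(rep(c("w", "c"), 4), gm$samples))
  sc <- window_scan(gm, pm, "w", "c", window_spec(2000, 1000))
  f1 <- group_allele_freq(gm, pm, "w")
  f2 <- group_allele_freq(gm, pm, "c")
  for (i in seq_len(nrow(sc))) {
    rows <- which(gm$chrom == sc$chrom[i] & gm$pos >= sc$start[i] &
                  gm$pos <= sc$end[i])
    if (!length(rows)) next
    comps <- t(vapply(rows, function(s) {
      oracle_wc_fst(f1$freq[s], f1$n[s], f2$freq[s], f2$n[s])
    }, c(a = 0, d = 0)))
    if (!is.na(sc$fst[i])) {
      expect_equal(sc$fst[i], sum(comps[, "a"]) / sum(comps[, "d"]),
                   tolerance = 1e-9, label = paste("fst window", i))
    }
    L <- sc$end[i] - sc$start[i] + 1
    pw <- sum(vapply(rows, function(s) {
      al <- dosage_to_alleles(gm$dosages[s, seq(1, 8, 2)])
      if (length(al) >= 2) oracle_site_pi(al) else 0
    }, 0)) / L
    expect_equal(sc$pi_wild[i], pw, tolerance = 1e-9,
                 label = paste("pi window", i))
  }
})

test_that("call_sweeps merges qualifying windows and applies all 3 criteria", {
  win <- data.table::data.table(
    chrom = "chr1",
    start = seq(1L, by = 10000L, length.out = 10),
    end = seq(100000L, by = 10000L, length.out = 10),
    n_sites = 100L,
    fst = c(0.05, 0.08, 0.50, 0.55, 0.07, 0.06, 0.09, 0.10, 0.05, 0.04),
    pi_wild = 0.004, pi_dom = 0.004)
  win[, rod := c(0.0, 0.1, 0.6, 0.7, 0.0, 0.1, 0.0, 0.1, 0.0, 0.0)]
  win[, pi_ratio := 1]
  sw <- call_sweeps(win)
  # windows 3 and 4 overlap -> one merged region spanning their union
  expect_equal(nrow(sw), 1)
  expect_equal(sw$start, win$start[3])
  expect_equal(sw$end, win$end[4])
  expect_equal(sw$n_windows, 2L)
  expect_equal(sw$max_fst, 0.55)

  # all-zero FST -> no regions
  win0 <- data.table::copy(win)[, fst := 0][, rod := 0.5]
  expect_equal(nrow(call_sweeps(win0)), 0)

  # a high-FST window with low ROD never qualifies
  win2 <- data.table::copy(win)[3, rod := 0.1]
  sw2 <- call_sweeps(win2)
  expect_equal(sw2$n_windows, 1L)
  expect_equal(sw2$start, win$start[4])

  expect_error(call_sweeps(win[1:5]), "fewer than 10")
})

test_that("called genome fraction shrinks as thresholds rise", {
  sim <- fix_two_deme()
  sc <- window_scan(sim$gm, sim$pm, "deme1", "deme2", window_spec(2e4, 5e3))
  mb <- sapply(c(0.0, 0.1, 0.3), function(th) {
    sw <- call_sweeps(sc, fst_abs = th, fst_quantile = 0.5, rod_min = -Inf)
    sum(sw$end - sw$start + 1)
  })
  expect_true(all(diff(mb) <= 0))
})

test_that("annotate_regions overlap semantics match a brute-force check", {
  regions <- data.table::data.table(
    chrom = c("chr1", "chr1"), start = c(1000L, 5000L),
    end = c(2000L, 6000L), n_windows = 1L, max_fst = 0.5, max_rod = 0.5)
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(2001, 1990, 1500, 100),
                     c(2500, 2100, 5500, 200)))
  S4Vectors::mcols(genes)$gene_id <- c("abutting", "edge", "spanner", "off")
  expect_warning(
    out <- annotate_regions(data.table::copy(regions), genes,
                            chrom_lengths = c(chr1 = 10000)),
    "unknown chromosomes")
  # gene starting exactly at end+1 is NOT assigned
  expect_false("abutting" %in% out$genes[[1]])
  expect_true("edge" %in% out$genes[[1]])
  # gene spanning both regions appears in both
  expect_true(all(vapply(out$genes, function(g) "spanner" %in% g, TRUE)))

  set.seed(23)
  rr <- data.table::data.table(
    chrom = "chr1", start = sort(sample.int(5e4, 5)) * 10L)
  rr[, end := start + 3000L]
  rr[, c("n_windows", "max_fst", "max_rod") := .(1L, 0.5, 0.5)]
  gs <- sort(sample.int(5e5, 40))
  gg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, gs + 2000))
  S4Vectors::mcols(gg)$gene_id <- paste0("g", seq_along(gg))
  out2 <- annotate_regions(data.table::copy(rr), gg)
  for (i in seq_len(nrow(rr))) {
    hit <- oracle_overlaps(rr$start[i], rr$end[i], gs, gs + 2000)
    expect_setequal(out2$genes[[i]],
                    paste0("g", which(hit), recycle0 = TRUE))
  }
})
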