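test_that("fixed seed gives identical output; mu = 0 gives no sites", {
  cfg <- sim_config(seq_length = 5e4, mu = 1e-5, rec = 1e-5,
                    demes = c(pop = 30), seed = 9)
  a <- simulate_wf(cfg)
  b <- simulate_wf(cfg)
  expect_identical(a$gm$dosages, b$gm$dosages)
  expect_identical(a$gm$pos, b$gm$pos)
  expect_identical(a$gm$haplotypes, b$gm$haplotypes)

  c2 <- sim_config(seq_length = 5e4, mu = 1e-5, rec = 1e-5,
                   demes = c(pop = 30), seed = 10)
  expect_false(identical(simulate_wf(c2)$gm$pos, a$gm$pos))

  z <- simulate_wf(sim_config(seq_length = 5e4, mu = 0, rec = 1e-5,
                              demes = c(pop = 20), seed = 1))
  expect_equal(n_sites(z$gm), 0)
})

test_that("dosages, haplotypes and pop map are mutually consistent", {
  sim <- fix_single_deme()
  gm <- sim$gm
  odd <- seq(1, ncol(gm$haplotypes), by = 2)
  expect_equal(unname(gm$dosages),
               unname(gm$haplotypes[, odd] + gm$haplotypes[, odd + 1]))
  expect_true(all(gm$haplotypes %in% 0:1))
  expect_equal(names(sim$pm$assignment), gm$samples)
  # segregating sites only: every site polymorphic in the sample
  f <- rowMeans(gm$dosages) / 2
  expect_true(all(f > 0 & f < 1))
  expect_true(!is.unsorted(gm$pos[gm$chrom == "chr1"], strictly = TRUE))
})

test_that("config validation rejects bad migration, events and samples", {
  expect_error(sim_config(1e4, 1e-5, 0, demes = c(a = 10, b = 10),
                          migration = matrix(1.2, 2, 2)),
               "sum to <= 1")
  expect_error(sim_config(1e4, 1e-5, 0, demes = c(a = 10),
                          migration = matrix(0, 3, 3)), "must be 1x1")
  expect_error(sim_config(1e4, 1e-5, 0, demes = c(a = 10, b = 10),
                          events = list(
                            list(gen = 5, type = "bottleneck", deme = "a",
                                 size = 5),
                            list(gen = 1, type = "bottleneck", deme = "a",
                                 size = 8))),
               "generation order")
  expect_error(sim_config(1e4, 1e-5, 0, demes = c(a = 10),
                          sample_sizes = c(zz = 5)), "unknown demes")
  expect_warning(
    simulate_wf(sim_config(1e4, 1e-5, 0, demes = c(a = 20), burn_in = 50,
                           seed = 1)),
    "burn_in")
})

test_that("inject_sweep reduces diversity inside the interval only", {
  sim <- fix_single_deme()
  ids <- sim$gm$samples
  iv <- list(chrom = "chr1", start = 30001, end = 70000)
  inside <- function(gm) {
    rows <- gm$chrom == "chr1" & gm$pos >= iv$start & gm$pos <= iv$end
    f <- rowMeans(gm$dosages[rows, , drop = FALSE]) / 2
    n <- 2 * length(ids)
    sum(site_pi(f, rep(n, sum(rows))))
  }
  pre <- inside(sim$gm)

  # k = 1: interval monomorphic for the deme
  g1 <- inject_sweep(sim$gm, ids, iv, founder_count = 1, seed = 5)
  expect_equal(inside(g1), 0)
  rows <- g1$chrom == "chr1" & g1$pos >= iv$start & g1$pos <= iv$end
  expect_true(all(g1$dosages[rows, ] %in% c(0L, 2L)))
  # outside untouched
  expect_equal(g1$dosages[!rows, ], sim$gm$dosages[!rows, ])

  # k = 2 over seeded replicates never increases interval diversity
  for (s in 1:10) {
    g2 <- inject_sweep(sim$gm, ids, iv, founder_count = 2, seed = s)
    expect_lte(inside(g2), pre)
  }

  # identity case: k = 2 * |deme| leaves the matrix unchanged
  gid <- inject_sweep(sim$gm, ids, iv, founder_count = 2 * length(ids))
  expect_identical(gid$dosages, sim$gm$dosages)

  expect_error(inject_sweep(sim$gm, ids,
                            list(chrom = "chr1", start = 1, end = 2e5), 2),
               "outside chromosome")
  expect_error(inject_sweep(sim$gm, ids, iv, founder_count = 0), "founder")
})

test_that("four-pop simulator is exchangeable at f = 0 by construction", {
  sim <- simulate_four_pop(f = 0, N = 30, seq_length = 1e5, split_gens = 20,
                           sample_size = 10, seed = 3)
  expect_setequal(sim$pm$groups, c("W", "X", "Y", "Z"))
  expect_equal(sim$truth$admixture_fraction, 0)
  expect_equal(sim$truth$expected_d_sign, 0L)
  # swapping W and X negates d exactly (antisymmetry on real data)
  fw <- group_allele_freq(sim$gm, sim$pm, "W")$freq
  fx <- group_allele_freq(sim$gm, sim$pm, "X")$freq
  fy <- group_allele_freq(sim$gm, sim$pm, "Y")$freq
  fz <- group_allele_freq(sim$gm, sim$pm, "Z")$freq
  d1 <- d_statistic(fw, fx, fy, fz)$d
  d2 <- d_statistic(fx, fw, fy, fz)$d
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("equilibrium theta matches 4N mu within sampling error", {
  # scaled-down calibration: N = 50, theta = 0.002/bp over 40 windows
  sim <- simulate_wf(sim_config(seq_length = 2e5, mu = 1e-5, rec = 1e-5,
                                demes = c(pop = 50), seed = 21))
  w <- window_diversity(sim$gm, sim$pm, "pop")
  expect_gt(nrow(w), 35)
  theta <- 4 * 50 * 1e-5
  expect_lt(abs(mean(w$theta_pi) / theta - 1), 0.25)
  expect_lt(abs(mean(w$theta_w) / theta - 1), 0.25)
})
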