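# Seeded validation experiments: each runs the full estimator pipeline on
# simulations with known truth and reports recovery/calibration summaries.
# Both the test suite and scripts/acceptance.R drive these; all randomness
# derives deterministically from the `seed` argument.

.child_seed <- function(seed, i) (as.integer(seed) * 1013L + i * 7919L) %% 2100000000L

#' Equilibrium calibration of the diversity estimators
#'
#' Single-deme Wright-Fisher simulation at mutation-drift equilibrium;
#' windowed theta-pi and theta-w are compared with the configured
#' `4 N mu`, and mean Tajima's D with its neutral expectation of ~0.
#'
#' @param seed integer seed.
#' @param N diploid deme size.
#' @param seq_length chromosome length (bp); the default gives 201
#'   overlapping 10-kb windows.
#' @param mu,rec per-bp rates; defaults give `4 N mu = 0.005`.
#' @return list: `theta_true`, `pi_hat`, `w_hat`, `pi_rel_bias`,
#'   `w_rel_bias`, `tajima_mean`, `n_windows`, `n_snps`.
#' @export
experiment_equilibrium <- function(seed, N = 100, seq_length = 1005000,
                                   mu = 1.25e-5, rec = 1.25e-5) {
  sim <- simulate_wf(sim_config(seq_length = seq_length, mu = mu, rec = rec,
                                demes = c(pop = N), seed = seed))
  w <- window_diversity(sim$gm, sim$pm, "pop")
  theta <- 4 * N * mu
  list(theta_true = theta, pi_hat = mean(w$theta_pi),
       w_hat = mean(w$theta_w),
       pi_rel_bias = mean(w$theta_pi) / theta - 1,
       w_rel_bias = mean(w$theta_w) / theta - 1,
       tajima_mean = mean(w$tajimas_d, na.rm = TRUE),
       tajima_q05 = unname(stats::quantile(w$tajimas_d, 0.05, na.rm = TRUE)),
       tajima_q95 = unname(stats::quantile(w$tajimas_d, 0.95, na.rm = TRUE)),
       n_windows = nrow(w), n_snps = n_sites(sim$gm))
}

#' Island-model FST calibration against Wright's expectation
#'
#' Two-deme island model at the configured effective migrant number; the
#' genome-mean windowed Weir-Cockerham FST is compared with
#' `1 / (1 + 4 Nm)` and [nm_from_fst()] is applied to the realized value.
#'
#' @param seed integer seed.
#' @param Nm effective migrants per generation.
#' @param N deme size; `n_chrom` x `seq_length` bp are simulated.
#' @param n_chrom,seq_length genome layout.
#' @return list: `nm_true`, `fst_expected`, `fst_hat`, `fst_rel_err`,
#'   `nm_hat`, `nm_factor` (ratio of recovered to configured Nm).
#' @export
experiment_island_fst <- function(seed, Nm, N = 100, n_chrom = 4,
                                  seq_length = 2e5) {
  cfg <- island_pair_config(Nm, N = N, seq_length = seq_length,
                            mu = 1e-5, rec = 1e-5, n_chrom = n_chrom,
                            seed = seed)
  sim <- simulate_wf(cfg)
  sc <- window_scan(sim$gm, sim$pm, "deme1", "deme2", window_spec(1e5, 1e4))
  fst_hat <- mean(sc$fst, na.rm = TRUE)
  expected <- 1 / (1 + 4 * Nm)
  nm_hat <- nm_from_fst(fst_hat)
  list(nm_true = Nm, fst_expected = expected, fst_hat = fst_hat,
       fst_rel_err = fst_hat / expected - 1, nm_hat = nm_hat,
       nm_factor = nm_hat / Nm, n_windows = sum(!is.na(sc$fst)))
}

#' Sweep-recovery experiment with the three-criterion caller
#'
#' Replicated wild/domesticated simulations with a hard sweep injected
#' into the domesticated deme (`founder_count = 2`, 200-kb interval); the
#' caller runs with the published thresholds (FST > 0.15, top 10% of FST,
#' ROD > 0.2) and is scored on true-interval overlap and on the fraction
#' of the non-sweep genome covered by calls.
#'
#' @param seed integer seed.
#' @param n_rep number of replicates.
#' @param config_fn scenario constructor, by default
#'   [domestication_config()] with its defaults.
#' @return list: `recovery_rate`, `fp_fraction` (mean), `n_rep`,
#'   per-replicate vectors `hit` and `fp`.
#' @export
experiment_sweep_recovery <- function(seed, n_rep = 25,
                                      config_fn = domestication_config) {
  hit <- logical(n_rep); fp <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- .child_seed(seed, i)
    sim <- simulate_wf(config_fn(seed = s))
    L <- sim$gm$chrom_lengths[["chr1"]]
    iv <- list(chrom = "chr1", start = round(L / 2) + 1,
               end = round(L / 2) + 2e5)
    gm <- inject_sweep(sim$gm, group_samples(sim$pm, "dom"), iv,
                       founder_count = 2, seed = s + 1L)
    sc <- window_scan(gm, sim$pm, "wild", "dom")
    sw <- call_sweeps(sc)
    if (nrow(sw)) {
      ovl <- pmax(0, pmin(sw$end, iv$end) - pmax(sw$start, iv$start) + 1)
      hit[i] <- any(ovl > 0)
      outside <- sum(sw$end - sw$start + 1) - sum(ovl)
      fp[i] <- outside / (sum(sim$gm$chrom_lengths) - 2e5)
    }
  }
  list(recovery_rate = mean(hit), fp_fraction = mean(fp), n_rep = n_rep,
       hit = hit, fp = fp)
}

#' D-statistic calibration and power experiment
#'
#' Replicated four-population simulations at admixture fraction `f`; each
#' replicate runs [d_test()] on the quartet (W, X, Y, Z).  With `f = 0`
#' the |Z| > 3 rate estimates the false-positive rate; with `f > 0` it
#' estimates power, and the sign of D is checked against the configured
#' Y -> X flow direction (negative for this quartet ordering).
#'
#' @param seed integer seed.
#' @param f admixture fraction.
#' @param n_rep number of replicates.
#' @return list: `rate_sig`, `sign_correct_rate` (among significant
#'   replicates; `NA` when f = 0), `z_mean`, `z_sd`, `d_mean`, `n_rep`.
#' @export
experiment_dstat <- function(seed, f = 0, n_rep = 60) {
  z <- d <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_four_pop(f = f, N = 50, seq_length = 4e5, mu = 1e-5,
                             rec = 1e-5, split_gens = 40, sample_size = 20,
                             seed = .child_seed(seed, i))
    res <- d_test(sim$gm, sim$pm, c("W", "X", "Y", "Z"), block_size = NULL)
    z[i] <- res$z_score; d[i] <- res$d
  }
  sig <- abs(z) > 3
  list(rate_sig = mean(sig),
       sign_correct_rate = if (f > 0) mean(z[sig] < 0) else NA,
       z_mean = mean(z), z_sd = stats::sd(z), d_mean = mean(d),
       n_rep = n_rep)
}

#' LD half-decay monotonicity in the recombination rate
#'
#' For each replicate, three simulations differing only in the target
#' recombination rate (1e-8, 5e-8, 1e-7; see [ld_scenario_config()] for
#' the effective-size scaling) are run and the half-decay distances must
#' decrease strictly with the rate.  A curve that never decays to half of
#' its maximum within the examined span has a half-distance beyond the
#' span and is treated as infinite, so an undefined value in a
#' lower-recombination arm is consistent with the expected ordering while
#' one in a higher-recombination arm violates it.
#'
#' @param seed integer seed.
#' @param n_rep number of replicate triples.
#' @param rates target per-bp recombination rates, increasing.
#' @return list: `monotone_rate`, `half_dist` (n_rep x 3 matrix), `n_rep`.
#' @export
experiment_ld_monotone <- function(seed, n_rep = 10,
                                   rates = c(1e-8, 5e-8, 1e-7)) {
  hd <- matrix(NA_real_, n_rep, length(rates))
  for (i in seq_len(n_rep)) {
    s <- .child_seed(seed, i)
    for (j in seq_along(rates)) {
      sim <- simulate_wf(ld_scenario_config(rates[j], seed = s + j))
      hd[i, j] <- decay_curve(sim$gm, sim$pm, "pop", max_dist = 6e4,
                              bin_width = 500, max_pairs = 3e5,
                              smooth = 3, seed = s)$half_distance_bp
    }
  }
  mono <- apply(hd, 1, function(x) {
    x[is.na(x)] <- Inf   # no decay to half within the span: beyond it
    all(diff(x) < 0)
  })
  list(monotone_rate = mean(mono), half_dist = hd, n_rep = n_rep)
}

#' Bottleneck LD contrast experiment
#'
#' Each replicate simulates an ancestral deme plus a deme passed through a
#' strong bottleneck; the bottlenecked deme should show the longer LD
#' half-decay distance.  A bottleneck curve that never decays to half of
#' its maximum inside the examined span counts as longer (its LD extends
#' beyond the span) provided the ancestral half-distance is defined.
#'
#' @param seed integer seed.
#' @param n_rep number of replicates.
#' @param rec target recombination rate for both demes.
#' @return list: `longer_rate`, per-replicate `half_anc`, `half_bott`.
#' @export
experiment_ld_bottleneck <- function(seed, n_rep = 10, rec = 5e-8) {
  ha <- hb <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- .child_seed(seed, 500L + i)
    sim <- simulate_wf(ld_scenario_config(rec, bottleneck_frac = 0.1,
                                          bottleneck_gens = 80, seed = s))
    ha[i] <- decay_curve(sim$gm, sim$pm, "ancestral", max_dist = 6e4,
                         bin_width = 500, max_pairs = 3e5, smooth = 3,
                         seed = s)$half_distance_bp
    hb[i] <- decay_curve(sim$gm, sim$pm, "bottleneck", max_dist = 6e4,
                         bin_width = 500, max_pairs = 3e5, smooth = 3,
                         seed = s)$half_distance_bp
  }
  longer <- ifelse(is.na(hb), !is.na(ha), hb > ifelse(is.na(ha), Inf, ha))
  list(longer_rate = mean(longer), half_anc = ha, half_bott = hb,
       n_rep = n_rep)
}
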