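#' Configure a Wright-Fisher forward simulation
#'
#' Discrete-generation, multi-deme Wright-Fisher model with per-bp
#' infinite-sites mutation (collisions re-drawn), Poisson recombination with
#' uniform breakpoints, per-gamete migration, and demographic events
#' (bottleneck/resize, deme split, single-generation admixture pulse).
#' Chromosomes are simulated as independent realizations of the same
#' demography, which is exact for every neutral statistic this package
#' computes.
#'
#' Event generations are counted from the end of the burn-in: an event with
#' `gen = 0` fires in the first post-burn-in generation.  Demes created by a
#' `split` event must be declared in `demes` with `size` and are inactive
#' until their split fires.
#'
#' @param seq_length chromosome length (bp).
#' @param mu mutation rate per bp per generation.
#' @param rec recombination probability per bp per generation.
#' @param demes named integer vector of diploid deme sizes.  Names become
#'   group labels and sample-name prefixes.
#' @param migration square matrix of per-generation, per-gamete migration
#'   probabilities (row = receiving deme, column = source); off-diagonal row
#'   sums must be <= 1.  `NULL` means no migration.
#' @param events list of events, each a list with `gen` (generations after
#'   burn-in, >= 0), `type` (`"bottleneck"`, `"split"`, `"admixture"`),
#'   `deme`, and per type: `size` (bottleneck/split), `source` (split/
#'   admixture), `fraction` (admixture).
#' @param initial_demes deme names active at generation 0 (default: all demes
#'   that are not the target of a `split`).
#' @param burn_in generations before events; default `10 * max(demes)`.  A
#'   shorter burn-in is allowed but recorded as a warning in the truth.
#' @param post_burn generations simulated after burn-in (default: enough to
#'   cover the last event).
#' @param sample_sizes named integer vector of diploids sampled per deme
#'   (default: all individuals of every deme active at the end).
#' @param n_chrom number of chromosomes (independent replicates), default 1.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seq_length, mu, rec, demes, migration = NULL,
                       events = list(), initial_demes = NULL, burn_in = NULL,
                       post_burn = NULL, sample_sizes = NULL, n_chrom = 1,
                       seed = 1) {
  stopifnot(seq_length >= 1, mu >= 0, rec >= 0, length(demes) >= 1)
  if (is.null(names(demes)) || any(!nzchar(names(demes)))) {
    stop("demes must be a named vector")
  }
  D <- length(demes)
  if (is.null(migration)) migration <- matrix(0, D, D)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == D)) stop("migration must be ", D, "x", D)
  diag(migration) <- 0
  if (any(migration < 0) || any(rowSums(migration) > 1)) {
    stop("off-diagonal migration rows must be non-negative and sum to <= 1")
  }
  split_targets <- vapply(Filter(function(e) e$type == "split", events),
                          function(e) e$deme, "")
  if (is.null(initial_demes)) {
    initial_demes <- setdiff(names(demes), split_targets)
  }
  if (!length(initial_demes)) stop("no initially active deme")
  if (is.null(burn_in)) burn_in <- 10 * max(demes)
  ev_gens <- vapply(events, function(e) as.numeric(e$gen), 0)
  if (length(events)) {
    if (any(ev_gens < 0)) stop("event generations must be >= 0")
    if (is.unsorted(ev_gens)) stop("events must be in generation order")
  }
  if (is.null(post_burn)) {
    post_burn <- if (length(events)) max(ev_gens) + 1 else 0
  }
  if (length(events) && post_burn < max(ev_gens) + 1) {
    stop("post_burn ends before the last event")
  }
  if (is.null(sample_sizes)) sample_sizes <- demes
  missing_demes <- setdiff(names(sample_sizes), names(demes))
  if (length(missing_demes)) stop("sample_sizes for unknown demes")
  structure(list(seq_length = as.integer(seq_length), mu = mu, rec = rec,
                 demes = demes, migration = migration, events = events,
                 initial_demes = initial_demes,
                 burn_in = as.integer(burn_in),
                 post_burn = as.integer(post_burn),
                 sample_sizes = sample_sizes,
                 n_chrom = as.integer(n_chrom), seed = as.integer(seed)),
            class = "sim_config")
}

.encode_events <- function(config) {
  dn <- names(config$demes)
  type_code <- c(bottleneck = 0L, split = 1L, admixture = 2L)
  lapply(config$events, function(e) {
    if (!e$type %in% names(type_code)) stop("unknown event type: ", e$type)
    list(gen = as.integer(config$burn_in + e$gen + 1L),
         type = type_code[[e$type]],
         deme = match(e$deme, dn) - 1L,
         source = if (!is.null(e$source)) match(e$source, dn) - 1L else -1L,
         size = if (!is.null(e$size)) as.integer(e$size) else -1L,
         fraction = if (!is.null(e$fraction)) e$fraction else 0)
  })
}

#' Run a Wright-Fisher forward simulation
#'
#' @param config a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()] carrying phased
#'   haplotypes), `pm` (a [pop_map()] assigning samples to demes) and
#'   `truth` (a `sim_truth` list: `theta_per_site` = 4 N mu per deme,
#'   `migration`, `sweep_interval`, `admixture_fraction`, `founder_count`,
#'   `warnings`).
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dn <- names(config$demes)
  warnings <- character()
  if (config$burn_in < 10 * max(config$demes)) {
    warnings <- c(warnings, sprintf(
      "burn_in %d < 10 x max deme size %d; equilibrium not guaranteed",
      config$burn_in, max(config$demes)))
  }
  active0 <- dn %in% config$initial_demes
  samp <- stats::setNames(integer(length(dn)), dn)
  samp[names(config$sample_sizes)] <- as.integer(config$sample_sizes)
  ngen <- config$burn_in + config$post_burn

  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  per_chrom <- lapply(chroms, function(cc) {
    .wf_sim_cpp(config$seq_length, config$mu, config$rec,
                as.integer(config$demes), active0, config$migration,
                as.integer(ngen), .encode_events(config), samp,
                purge_interval = 25L)
  })

  sampled_demes <- dn[samp > 0]
  sample_ids <- unlist(lapply(sampled_demes, function(g) {
    sprintf("%s_%02d", g, seq_len(samp[[g]]))
  }))
  n_hap <- 2 * sum(samp)

  chrom <- character(0); pos <- integer(0)
  haps <- matrix(integer(0), 0, n_hap)
  for (i in seq_along(chroms)) {
    res <- per_chrom[[i]]
    chrom <- c(chrom, rep(chroms[i], length(res$positions)))
    pos <- c(pos, res$positions)
    haps <- rbind(haps, res$haplotypes)
  }
  colnames(haps) <- as.vector(rbind(paste0(sample_ids, "_1"),
                                    paste0(sample_ids, "_2")))
  odd <- seq(1, n_hap, by = 2)
  dos <- haps[, odd, drop = FALSE] + haps[, odd + 1, drop = FALSE]
  colnames(dos) <- sample_ids

  gm <- genotype_matrix(
    samples = sample_ids, chrom = chrom, pos = pos,
    ref = rep("A", length(pos)),
    alt = rep(list("T"), length(pos)),
    qual = rep(60, length(pos)), dosages = dos,
    chrom_lengths = stats::setNames(rep(config$seq_length,
                                        config$n_chrom), chroms),
    haplotypes = haps)
  pm <- pop_map(stats::setNames(
    rep(sampled_demes, times = samp[sampled_demes]), sample_ids))
  truth <- structure(list(
    theta_per_site = 4 * config$demes * config$mu,
    migration = config$migration, sweep_interval = NULL,
    admixture_fraction = NULL, founder_count = NULL,
    expected_d_sign = NULL, config = config, warnings = warnings),
    class = "sim_truth")
  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  list(gm = gm, pm = pm, truth = truth)
}

#' Inject a selective-sweep signature into a deme
#'
#' Emulates the footprint of a hard sweep: inside `interval`, every target
#' haplotype is replaced by one of `founder_count` founder haplotypes drawn
#' from the deme, so local diversity collapses (to zero when
#' `founder_count = 1`) while flanking regions and other demes are
#' untouched.  Requires the phased haplotypes the simulator attaches.  The
#' degenerate case `founder_count == 2 * length(deme_samples)` uses the
#' identity assignment and returns the matrix unchanged.
#'
#' @param gm a [genotype_matrix()] with haplotypes.
#' @param deme_samples sample IDs of the swept deme.
#' @param interval `list(chrom =, start =, end =)`, 1-based inclusive.
#' @param founder_count number of founder haplotypes kept (>= 1).
#' @param seed optional integer seed for founder draws.
#' @return the modified `genotype_matrix`.
#' @export
inject_sweep <- function(gm, deme_samples, interval, founder_count,
                         seed = NULL) {
  if (is.null(gm$haplotypes)) stop("genotype matrix carries no haplotypes")
  stopifnot(founder_count >= 1,
            founder_count <= 2 * length(deme_samples))
  if (!interval$chrom %in% names(gm$chrom_lengths) ||
      interval$start < 1 ||
      interval$end > gm$chrom_lengths[[interval$chrom]] ||
      interval$start > interval$end) {
    stop("sweep interval outside chromosome bounds")
  }
  j <- match(deme_samples, gm$samples)
  if (anyNA(j)) stop("deme_samples not all present in matrix")
  hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
  rows <- which(gm$chrom == interval$chrom & gm$pos >= interval$start &
                gm$pos <= interval$end)
  if (!length(rows)) return(gm)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  nh <- length(hcols)
  if (founder_count == nh) {
    assignment <- seq_len(nh)            # identity: matrix unchanged
  } else {
    founders <- sample(nh, founder_count)
    assignment <- founders[sample.int(founder_count, nh, replace = TRUE)]
  }
  block <- gm$haplotypes[rows, hcols, drop = FALSE]
  gm$haplotypes[rows, hcols] <- block[, assignment, drop = FALSE]
  h1 <- gm$haplotypes[rows, hcols[seq(1, nh, 2)], drop = FALSE]
  h2 <- gm$haplotypes[rows, hcols[seq(2, nh, 2)], drop = FALSE]
  gm$dosages[rows, j] <- h1 + h2
  gm
}

#' Two-deme island-model configuration targeting Wright's FST
#'
#' Symmetric two-deme model parameterised by the effective migrant number
#' `Nm`, so that equilibrium FST approximates Wright's `1 / (1 + 4 Nm)`.
#' For two demes the pairwise FST that a two-population estimator measures
#' is, in coalescent terms, `(T_between - T_within) / T_between =
#' 1 / (1 + 8 N m_raw)` (within-deme coalescence time `4N`, between-deme
#' excess `1 / (2 m_raw)`); the raw per-gamete rate is therefore set to
#' `m_raw = Nm / (2 N)` so the realized FST targets `1 / (1 + 4 Nm)`.
#'
#' @param Nm effective migrants per generation.
#' @param N diploid size of each deme.
#' @param seq_length,mu,rec,n_chrom,seed,sample_sizes passed to
#'   [sim_config()].
#' @return a `sim_config`.
#' @export
island_pair_config <- function(Nm, N = 100, seq_length = 5e5, mu = 1e-5,
                               rec = 1e-5, n_chrom = 1, seed = 1,
                               sample_sizes = NULL) {
  m <- Nm / (2 * N)
  if (m > 0.5) stop("migration rate exceeds 0.5; lower Nm or raise N")
  mig <- matrix(c(0, m, m, 0), 2, 2)
  # structured equilibrium relaxes on the between-deme timescale
  # T_b = 4N + 1/(2m); allow ~6 relaxation times
  burn <- max(10 * N, ceiling(6 * (4 * N + 1 / (2 * m))))
  sim_config(seq_length = seq_length, mu = mu, rec = rec,
             demes = c(deme1 = N, deme2 = N), migration = mig,
             burn_in = burn, n_chrom = n_chrom, seed = seed,
             sample_sizes = sample_sizes)
}

#' Wild/domesticated pair with bottleneck and optional sweep truth
#'
#' Splits a domesticated deme off a wild deme, applies a domestication
#' bottleneck, and lets both drift without migration.  The sweep itself is
#' injected post hoc with [inject_sweep()]; this constructor only records
#' the scenario.
#'
#' The defaults emulate a mild perennial domestication: a 20% bottleneck
#' (`bottleneck_frac = 0.8`) held for `split_gens = 10` generations loses
#' roughly `1 - exp(-split_gens / (2 N_dom))`, about 10%, of the
#' domesticated deme's diversity, and background FST stays well below the
#' sweep-caller thresholds so injected sweeps are the only strong signal.
#'
#' @param N diploid size of the wild deme.
#' @param bottleneck_frac domesticated deme size as a fraction of `N`.
#' @param split_gens generations of divergence after the split.
#' @param seq_length,mu,rec,n_chrom,seed passed to [sim_config()].
#' @return a `sim_config` with demes `wild` and `dom`.
#' @export
domestication_config <- function(N = 50, bottleneck_frac = 0.8,
                                 split_gens = 10, seq_length = 2.4e6,
                                 mu = 1e-5, rec = 1e-5, n_chrom = 1,
                                 seed = 1) {
  Nd <- max(2L, as.integer(round(N * bottleneck_frac)))
  sim_config(seq_length = seq_length, mu = mu, rec = rec,
             demes = c(wild = N, dom = Nd),
             events = list(list(gen = 0, type = "split", deme = "dom",
                                source = "wild", size = Nd)),
             post_burn = split_gens, n_chrom = n_chrom, seed = seed)
}

#' Single-deme configuration for LD-decay experiments
#'
#' LD statistics depend on the population-scaled rates `4 N rec` and
#' `4 N mu`, so a target per-bp recombination rate for a large natural
#' population can be emulated at desk scale by simulating `N` diploids
#' with `rec * ne_scale`, where `ne_scale = Ne_target / N`.  With the
#' defaults (`N = 100`, `ne_scale = 20`) a target `rec` of 1e-8 to 1e-7
#' yields half-decay distances of roughly 1-12 kb, the scale the 100-bp
#' decay-curve bins are designed to resolve.
#'
#' @param rec target per-bp recombination rate (before scaling).
#' @param ne_scale effective-size scaling factor applied to `rec`.
#' @param N diploid deme size.
#' @param bottleneck_frac if `< 1`, a second deme `bottleneck` is split
#'   off and held at `N * bottleneck_frac` diploids for `bottleneck_gens`
#'   generations before sampling, for wild-vs-bottlenecked LD contrasts.
#' @param bottleneck_gens see `bottleneck_frac`.
#' @param seq_length,mu,seed passed to [sim_config()].
#' @return a `sim_config`.
#' @export
ld_scenario_config <- function(rec, ne_scale = 20, N = 100,
                               bottleneck_frac = 1, bottleneck_gens = 40,
                               seq_length = 2e5, mu = 1e-5, seed = 1) {
  rs <- rec * ne_scale
  if (bottleneck_frac >= 1) {
    return(sim_config(seq_length = seq_length, mu = mu, rec = rs,
                      demes = c(pop = N), seed = seed))
  }
  Nb <- max(2L, as.integer(round(N * bottleneck_frac)))
  sim_config(seq_length = seq_length, mu = mu, rec = rs,
             demes = c(ancestral = N, bottleneck = Nb),
             events = list(list(gen = 0, type = "split",
                                deme = "bottleneck", source = "ancestral",
                                size = Nb)),
             post_burn = bottleneck_gens, seed = seed)
}

#' Simulate a four-population quartet for D-statistic testing
#'
#' Topology `(((W,X),Y),Z)` built by forward-in-time splits (Z deepest),
#' with an optional admixture pulse from Y into X shortly before sampling.
#' With `f = 0`, W and X are exchangeable with respect to Y, the null of the
#' ABBA-BABA test.  With `f > 0`, X and Y share excess derived alleles, so
#' the D statistic for the quartet ordered (W, X, Y, Z) is expected
#' negative ("gene flow between W and Z or X and Y" in the sign convention
#' of [interpret_sign()]); the truth records `expected_d_sign = -1`.
#'
#' @param f admixture fraction from Y into X, in `[0, 1)`.
#' @param N diploid size of every deme.
#' @param seq_length,mu,rec,n_chrom,seed passed to [sim_config()].
#' @param split_gens generations between successive splits.
#' @param sample_size diploids sampled per deme.
#' @return as [simulate_wf()], with admixture fields of the truth filled in.
#' @export
simulate_four_pop <- function(f = 0, N = 50, seq_length = 5e5, mu = 1.2e-5,
                              rec = 1e-5, split_gens = 40, n_chrom = 1,
                              sample_size = 20, seed = 1) {
  stopifnot(f >= 0, f < 1)
  events <- list(
    list(gen = 0, type = "split", deme = "Z", source = "W", size = N),
    list(gen = split_gens, type = "split", deme = "Y", source = "W",
         size = N),
    list(gen = 2 * split_gens, type = "split", deme = "X", source = "W",
         size = N))
  post <- 3 * split_gens
  if (f > 0) {
    events <- c(events, list(list(gen = post - 5, type = "admixture",
                                  deme = "X", source = "Y", fraction = f)))
  }
  cfg <- sim_config(seq_length = seq_length, mu = mu, rec = rec,
                    demes = c(W = N, X = N, Y = N, Z = N),
                    events = events, post_burn = post,
                    sample_sizes = c(W = sample_size, X = sample_size,
                                     Y = sample_size, Z = sample_size),
                    n_chrom = n_chrom, seed = seed)
  out <- simulate_wf(cfg)
  out$truth$admixture_fraction <- f
  out$truth$expected_d_sign <- if (f > 0) -1L else 0L
  out
}
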