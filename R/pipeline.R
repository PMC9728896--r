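#' Build a pipeline run configuration
#'
#' Defaults are the printed analysis parameters: site filters QUAL > 30,
#' MR < 0.25, MAF > 0.05; diversity windows 10 kb / 5 kb; scan windows
#' 100 kb / 10 kb; sweep criteria FST > 0.15, top 10% of FST, ROD > 0.2;
#' LD pairs within 200 kb; |Z| > 3 significance for D statistics.
#'
#' @param vcf path to the input VCF.
#' @param popmap path to the two-column population map TSV.
#' @param annotation optional BED/GFF3 gene annotation for sweep regions.
#' @param wild,dom group label sets for the selection scan.
#' @param quartets optional list of 4-label character vectors (W, X, Y, Z)
#'   for D tests.
#' @param ld_groups groups for LD decay curves (default: all groups).
#' @param tree logical: build the p-distance NJ tree.
#' @param outgroup optional sample ID used to root the tree.
#' @param qual_min,mr_max,maf_min site-filter thresholds.
#' @param div_window,div_step diversity window size/step (bp).
#' @param scan_window,scan_step scan window size/step (bp).
#' @param fst_abs,fst_quantile,rod_min sweep-caller thresholds.
#' @param ld_max_dist,ld_bin_width LD decay settings (bp).
#' @param dstat_block_size jackknife block span (bp); NULL = span / 20.
#' @param seed integer seed used for any subsampling.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, popmap, annotation = NULL, wild = NULL,
                       dom = NULL, quartets = NULL, ld_groups = NULL,
                       tree = TRUE, outgroup = NULL, qual_min = 30,
                       mr_max = 0.25, maf_min = 0.05, div_window = 1e4,
                       div_step = 5e3, scan_window = 1e5, scan_step = 1e4,
                       fst_abs = 0.15, fst_quantile = 0.90, rod_min = 0.2,
                       ld_max_dist = 2e5, ld_bin_width = 100,
                       dstat_block_size = NULL, seed = 1,
                       out_dir = "popgensweep_out") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$quartets)) {
    if (is.matrix(raw$quartets)) {
      raw$quartets <- lapply(seq_len(nrow(raw$quartets)),
                             function(i) raw$quartets[i, ])
    } else if (!is.list(raw$quartets)) {
      raw$quartets <- list(raw$quartets)
    }
  }
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' filter -> per-group windowed diversity -> FST/ROD scan + sweep calling
#' (when `wild` and `dom` are set) -> LD decay per group -> D statistics
#' (when quartets are given) -> p-distance NJ tree.  All outputs land in
#' `config$out_dir` along with `manifest.json` recording the configuration,
#' its md5 hash, the package version and the seed; identical config + seed
#' reproduce every output byte-identically.
#'
#' @param config a [run_config()].
#' @param gm optional pre-loaded [genotype_matrix()] (skips VCF reading;
#'   used by the simulate subcommand and tests).
#' @param pm optional pre-loaded [pop_map()].
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config, gm = NULL, pm = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  if (is.null(gm)) gm <- stage("read_vcf", read_vcf(config$vcf))
  if (is.null(pm)) pm <- stage("read_popmap", read_pop_map(config$popmap))

  filt <- stage("filter", apply_site_filters(
    gm, qual_min = config$qual_min, mr_max = config$mr_max,
    maf_min = config$maf_min))
  gmf <- filt$gm
  paths$filter_report <- file.path(config$out_dir, "filter_report.json")
  jsonlite::write_json(unclass(filt$report), paths$filter_report,
                       auto_unbox = TRUE, pretty = TRUE)

  groups <- intersect(pm$groups, unique(pm$assignment[gmf$samples]))
  div_spec <- window_spec(config$div_window, config$div_step)
  diversity <- list()
  for (g in groups) {
    w <- stage(paste0("diversity:", g),
               window_diversity(gmf, pm, g, div_spec))
    p <- file.path(config$out_dir, sprintf("diversity_%s.tsv", g))
    utils::write.table(w, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("diversity_", g)]] <- p
    diversity[[g]] <- w
  }

  scan <- sweeps <- NULL
  if (!is.null(config$wild) && !is.null(config$dom)) {
    scan <- stage("scan", window_scan(
      gmf, pm, config$wild, config$dom,
      window_spec(config$scan_window, config$scan_step)))
    paths$scan <- file.path(config$out_dir, "scan_windows.tsv")
    utils::write.table(scan, paths$scan, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sweeps <- stage("call_sweeps", call_sweeps(
      scan, fst_abs = config$fst_abs, fst_quantile = config$fst_quantile,
      rod_min = config$rod_min))
    if (!is.null(config$annotation)) {
      sweeps <- stage("annotate", annotate_regions(
        sweeps, config$annotation, gmf$chrom_lengths))
    }
    paths$sweeps_tsv <- file.path(config$out_dir, "sweep_regions.tsv")
    paths$sweeps_bed <- file.path(config$out_dir, "sweep_regions.bed")
    write_sweep_regions(sweeps, bed_path = paths$sweeps_bed,
                        tsv_path = paths$sweeps_tsv)
    summ <- list(n_regions = nrow(sweeps),
                 total_mb = attr(sweeps, "total_bp") / 1e6,
                 fst_cutoff = attr(sweeps, "fst_cutoff"),
                 n_genes = if ("genes" %in% names(sweeps)) {
                   length(unique(unlist(sweeps$genes)))
                 } else NA)
    paths$sweep_summary <- file.path(config$out_dir, "sweep_summary.json")
    jsonlite::write_json(summ, paths$sweep_summary, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  ld <- list()
  ld_groups <- if (is.null(config$ld_groups)) groups else config$ld_groups
  for (g in ld_groups) {
    curve <- stage(paste0("ld:", g), decay_curve(
      gmf, pm, g, max_dist = config$ld_max_dist,
      bin_width = config$ld_bin_width, seed = config$seed))
    p <- file.path(config$out_dir, sprintf("ld_%s.tsv", g))
    utils::write.table(curve$bins, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(group = g, mean_r2 = curve$mean_r2, max_r2 = curve$max_r2,
           half_distance_bp = curve$half_distance_bp,
           n_pairs_total = curve$n_pairs_total,
           subsampled = curve$subsampled, seed = curve$seed),
      file.path(config$out_dir, sprintf("ld_%s_summary.json", g)),
      auto_unbox = TRUE, pretty = TRUE)
    paths[[paste0("ld_", g)]] <- p
    ld[[g]] <- curve
  }

  dstats <- NULL
  if (!is.null(config$quartets) && length(config$quartets)) {
    rows <- lapply(config$quartets, function(q) {
      r <- stage("dstat", d_test(gmf, pm, q,
                                 block_size = config$dstat_block_size))
      data.table::data.table(W = q[1], X = q[2], Y = q[3], Z = q[4],
                             d = r$d, z_score = r$z_score,
                             n_blocks = r$n_blocks, n_sites = r$n_sites,
                             significant = r$significant,
                             direction = r$direction)
    })
    dstats <- data.table::rbindlist(rows)
    paths$dstat <- file.path(config$out_dir, "dstat.tsv")
    utils::write.table(dstats, paths$dstat, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  tree <- NULL
  if (isTRUE(config$tree) && n_samples(gmf) >= 3) {
    dm <- stage("p_distance", p_distance(gmf))
    tree <- stage("nj", neighbor_joining(dm))
    if (!is.null(config$outgroup)) {
      tree <- stage("root", root_with_outgroup(tree, config$outgroup))
    }
    paths$distances <- file.path(config$out_dir, "distances.tsv")
    write_distance_matrix(dm, paths$distances)
    paths$tree <- file.path(config$out_dir, "tree.nwk")
    ape::write.tree(tree, paths$tree)
  }

  cfg_plain <- unclass(config)
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  manifest <- list(
    package = "popgensweep",
    version = as.character(utils::packageVersion("popgensweep")),
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    outputs = paths)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(gm = gmf, report = filt$report, diversity = diversity,
                 scan = scan, sweeps = sweeps, ld = ld, dstats = dstats,
                 tree = tree, paths = paths,
                 manifest = file.path(config$out_dir, "manifest.json")))
}
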