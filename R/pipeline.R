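#' Load and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or equivalent list) with blocks
#' `data` (either a `sim` sub-block or `vcf`/`bed` input paths — exactly one
#' of the two), and optional `filter`, `polarize`, `clock`, `date`, `place`
#' and `scenario` blocks plus a top-level `seed` (mandatory when
#' simulating) and `outdir`.
#'
#' @param config path to a YAML file, or a list.
#' @return the validated configuration list, class `run_config`.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or YAML path", call. = FALSE)
  data <- cfg$data %||% stop("config needs a `data` block", call. = FALSE)
  has_sim <- !is.null(data$sim)
  has_vcf <- !is.null(data$vcf)
  if (has_sim == has_vcf) {
    stop("`data` must contain exactly one of a `sim` block or a `vcf` path",
         call. = FALSE)
  }
  if (has_sim && is.null(cfg$seed)) {
    stop("a top-level `seed` is mandatory when simulating", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

resolve_clade <- function(x, clades) {
  if (length(x) == 1L && !is.null(clades) && x %in% names(clades)) {
    return(clades[[x]])
  }
  as.character(unlist(x))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate/read -> filter -> polarize -> calibrate -> date
#' (-> place -> scenario) and writes every stage artifact plus a manifest
#' (`manifest.json`) listing the files with MD5 checksums, the seed and the
#' package version. Reruns with the same configuration and seed are
#' byte-identical for all seeded stages.
#'
#' @param config a [run_config()], YAML path, or list.
#' @param outdir output directory; overrides `config$outdir`.
#' @return the manifest, invisibly (a list; see `manifest.json`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- run_config(config)
  outdir <- outdir %||% cfg$outdir %||% stop("no output directory given",
                                             call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  note <- function(...) artifacts <<- unique(c(artifacts, ...))
  clock <- if (is.null(cfg$clock)) clock_params() else do.call(clock_params, cfg$clock)

  ## -- data stage ---------------------------------------------------------
  if (!is.null(cfg$data$sim)) {
    sim <- cfg$data$sim
    tree <- build_truth_tree(sim$newick %||% sim$nodes,
                             multipliers = unlist(sim$multipliers))
    model <- if (is.null(sim$coverage)) coverage_model() else
      do.call(coverage_model, sim$coverage)
    ds <- sim_dataset(tree, clock = clock,
                      region_length = sim$region_length %||% 1e7,
                      model = model,
                      recurrence_prob = sim$recurrence_prob %||% 0.002,
                      seed = cfg$seed,
                      n_invariant = sim$n_invariant %||% 0L)
    gm <- ds$gm
    vcf_path <- file.path(outdir, "simulated.vcf")
    write_vcf(gm, vcf_path)
    note(vcf_path, write_truth(ds$tree, ds$mutations, outdir))
  } else {
    gm <- read_genotypes(cfg$data$vcf, bed = cfg$data$bed,
                         callable_length = cfg$data$callable_length %||% NA_real_)
  }

  ## -- filter stage -------------------------------------------------------
  if (isTRUE(cfg$filter$enabled %||% TRUE)) {
    fp <- if (is.null(cfg$filter$params)) filter_params() else
      do.call(filter_params, cfg$filter$params)
    fc <- filter_calls(gm, fp)
    fs <- filter_sites(fc$gm, fp)
    gm <- fs$gm
    report <- rbind(fc$report, fs$report)
    if (isTRUE(cfg$filter$remove_duplicates)) {
      dups <- detect_duplicates(gm, cfg$filter$max_mismatch_rate %||% 0.01)
      rd <- remove_duplicates(gm, dups)
      gm <- rd$gm
      report <- rbind(report, data.frame(rule = "duplicate_samples_removed",
                                         count = length(rd$removed)))
    }
    rpt_path <- file.path(outdir, "filter_report.tsv")
    write_filter_report(report, rpt_path)
    flt_path <- file.path(outdir, "filtered.vcf")
    write_vcf(gm, flt_path)
    note(rpt_path, flt_path)
  }

  ## -- polarize + calibrate ----------------------------------------------
  counts <- NULL
  amap <- NULL
  if (!is.null(cfg$polarize)) {
    og <- as.character(unlist(cfg$polarize$outgroup))
    amap <- assign_ancestral(gm, og,
                             min_outgroup_calls =
                               cfg$polarize$min_outgroup_calls %||% length(og))
    amap_path <- file.path(outdir, "ancestral_map.tsv")
    write_tsv_table(amap, amap_path)
    counts <- calibration_alpha(
      derived_root_counts(gm, amap, clock = clock,
                          samples = setdiff(gm$samples, og)))
    counts_path <- file.path(outdir, "root_counts.tsv")
    write_tsv_table(counts, counts_path)
    note(amap_path, counts_path)
  }

  ## -- date stage ----------------------------------------------------------
  clades <- if (!is.null(cfg$clades)) read_clades(cfg$clades) else NULL
  if (!is.null(cfg$date)) {
    if (is.null(amap)) stop("`date` stage requires a `polarize` block", call. = FALSE)
    estimates <- lapply(cfg$date$nodes, function(nd) {
      node_split_time(gm, amap,
                      cladeA = resolve_clade(nd$clade_a, clades),
                      cladeB = resolve_clade(nd$clade_b, clades),
                      counts = counts, clock = clock,
                      denominator = cfg$date$denominator %||% "called_ancestral_sites",
                      label = nd$name %||% "node")
    })
    dates_path <- file.path(outdir, "dates.tsv")
    write_split_estimates(estimates, dates_path)
    json_path <- file.path(outdir, "dates.json")
    jsonlite::write_json(lapply(estimates, function(e) list(
      node = e$label, point = round_years(e$point),
      ci_low = unname(e$ci[1]), ci_high = unname(e$ci[2]),
      n_pairs = e$n_pairs, calibrated = e$calibrated)),
      json_path, auto_unbox = TRUE, digits = NA)
    note(dates_path, sub("\\.tsv$", "_pairs.tsv", dates_path), json_path)
  }

  ## -- place stage ---------------------------------------------------------
  if (!is.null(cfg$place)) {
    if (is.null(amap)) stop("`place` stage requires a `polarize` block", call. = FALSE)
    refs <- cfg$place$references
    refs <- if (is.character(refs)) read_clades(refs) else
      lapply(refs, function(x) as.character(unlist(x)))
    prof <- sharing_profile(gm, amap, resolve_clade(cfg$place$query, clades), refs)
    plc <- place_lineage(prof, cfg$place$recurrence_threshold %||% 1L)
    place_path <- file.path(outdir, "placement.json")
    jsonlite::write_json(list(
      counts = as.list(prof$counts), status = plc$status, clade = plc$clade,
      support = plc$support, recurrent_sites = plc$recurrent_sites),
      place_path, auto_unbox = TRUE, digits = NA)
    note(place_path)
  }

  ## -- scenario stage ------------------------------------------------------
  if (!is.null(cfg$scenario)) {
    tab <- if (is.null(cfg$scenario$lineages)) lineage_table() else
      read_lineage_table(cfg$scenario$lineages)
    sc <- scenario_windows(tab)
    rep_obj <- list(scenarios = lapply(sc$scenarios, function(s) list(
      id = s$id, exit = as.list(s$exit),
      migrants = s$migrants,
      back_migrations = lapply(s$back_migrations, function(b)
        list(lineages = b$lineages, interval = as.list(b$interval))))),
      e_m35_exit = as.list(sc$e_m35_exit))
    if (!is.null(cfg$scenario$speedup)) {
      rep_obj$rescaled_exits <- lapply(sc$scenarios, function(s)
        as.list(rescale_times(s$exit, cfg$scenario$speedup)))
    }
    if (!is.null(cfg$scenario$fossil)) {
      sp <- scenario_params(cfg$scenario$generation_time %||% 29)
      aw <- admixture_window(cfg$scenario$fossil[[1]], cfg$scenario$fossil[[2]],
                             cfg$scenario$generations[[1]],
                             cfg$scenario$generations[[2]], params = sp)
      rep_obj$admixture_window <- as.list(aw)
    }
    sc_path <- file.path(outdir, "scenarios.json")
    jsonlite::write_json(rep_obj, sc_path, auto_unbox = TRUE, digits = NA)
    note(sc_path)
  }

  ## -- manifest ------------------------------------------------------------
  files <- artifacts[file.exists(artifacts)]
  manifest <- list(
    package = "ychron",
    version = as.character(utils::packageVersion("ychron")),
    seed = cfg$seed,
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
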