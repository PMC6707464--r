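#' Quality-control filter parameters
#'
#' Thresholds for the call-level and site-level filters applied to jointly
#' called haploid genotypes. Defaults mirror standard practice for
#' short-read Y-chromosome call sets: individual calls need DP >= 5,
#' GQ >= 30 and a supporting-read fraction strictly > 0.8; sites are dropped
#' when their total depth across samples falls outside 0.5x-3x the dataset
#' mean total depth or when more than 20% of samples are missing after
#' call-level filtering.
#'
#' Depth bounds are relative (factors times the dataset mean total site
#' depth) so they adapt to cohort size and coverage; absolute bounds can be
#' supplied instead via `site_depth_low_abs` / `site_depth_high_abs`.
#'
#' @param site_depth_low_factor,site_depth_high_factor multiples of the mean
#'   total site depth defining the depth window.
#' @param site_depth_low_abs,site_depth_high_abs optional absolute total
#'   depth bounds that override the relative factors.
#' @param max_site_missingness maximum tolerated missing fraction per site.
#' @param min_call_dp,min_call_gq minimum per-call depth / genotype quality
#'   (calls failing `DP < min_call_dp` or `GQ < min_call_gq` are masked;
#'   equality passes).
#' @param min_allele_fraction supporting-read fraction that a call must
#'   strictly exceed.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(site_depth_low_factor = 0.5,
                          site_depth_high_factor = 3.0,
                          site_depth_low_abs = NULL,
                          site_depth_high_abs = NULL,
                          max_site_missingness = 0.20,
                          min_call_dp = 5,
                          min_call_gq = 30,
                          min_allele_fraction = 0.8) {
  stopifnot(site_depth_low_factor > 0,
            site_depth_low_factor < site_depth_high_factor,
            max_site_missingness >= 0, max_site_missingness <= 1,
            min_call_dp >= 0, min_call_gq >= 0,
            min_allele_fraction >= 0, min_allele_fraction <= 1)
  structure(list(site_depth_low_factor = site_depth_low_factor,
                 site_depth_high_factor = site_depth_high_factor,
                 site_depth_low_abs = site_depth_low_abs,
                 site_depth_high_abs = site_depth_high_abs,
                 max_site_missingness = max_site_missingness,
                 min_call_dp = min_call_dp,
                 min_call_gq = min_call_gq,
                 min_allele_fraction = min_allele_fraction),
            class = "filter_params")
}

#' Mask low-quality individual calls
#'
#' Sets calls to missing when `DP < min_call_dp`, `GQ < min_call_gq`, or the
#' supporting-read fraction is not strictly greater than
#' `min_allele_fraction`. A call with an absent annotation fails the
#' corresponding rule. Depth/quality matrices are retained (the site filter
#' uses total depth over all samples, masked or not).
#'
#' @param gm a [genotype_matrix()].
#' @param params a [filter_params()].
#' @return list with elements `gm` (filtered matrix) and `report`
#'   (data.frame of per-rule masked-call counts; rules overlap, `total` is
#'   the union).
#' @export
filter_calls <- function(gm, params = filter_params()) {
  called <- !is.na(gm$calls)
  fail_of <- function(m, f) {
    if (is.null(m)) matrix(TRUE, nrow(gm$calls), ncol(gm$calls)) else f(m)
  }
  fail_dp <- fail_of(gm$dp, function(m) is.na(m) | m < params$min_call_dp)
  fail_gq <- fail_of(gm$gq, function(m) is.na(m) | m < params$min_call_gq)
  fail_af <- fail_of(gm$af, function(m) is.na(m) | m <= params$min_allele_fraction)
  fail <- called & (fail_dp | fail_gq | fail_af)
  out <- gm
  out$calls[fail] <- NA_integer_
  report <- data.frame(
    rule = c("call_dp", "call_gq", "call_allele_fraction", "calls_masked_total"),
    count = c(sum(called & fail_dp), sum(called & fail_gq),
              sum(called & fail_af), sum(fail)),
    stringsAsFactors = FALSE)
  list(gm = out, report = report)
}

#' Remove sites failing depth or missingness rules
#'
#' Drops sites whose total read depth across all samples lies outside the
#' window `[low_factor, high_factor] * mean total depth` (or the absolute
#' bounds when given), and sites missing in more than `max_site_missingness`
#' of samples. Missingness is evaluated on the matrix as passed, so apply
#' [filter_calls()] first to reproduce the usual order of operations.
#'
#' @param gm a [genotype_matrix()] (call-level filtering already applied).
#' @param params a [filter_params()].
#' @param mean_total_dp optional precomputed dataset mean total site depth;
#'   by default the mean over sites of summed DP is used.
#' @return list with `gm` (surviving sites), `report` (per-rule removal
#'   counts plus survivors), and `bounds` (the realized absolute depth
#'   window).
#' @export
filter_sites <- function(gm, params = filter_params(), mean_total_dp = NULL) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix", call. = FALSE)
  total_dp <- if (is.null(gm$dp)) rep(NA_real_, n_sites(gm)) else
    rowSums(gm$dp, na.rm = TRUE)
  if (is.null(mean_total_dp)) mean_total_dp <- mean(total_dp, na.rm = TRUE)
  low <- params$site_depth_low_abs %||% (params$site_depth_low_factor * mean_total_dp)
  high <- params$site_depth_high_abs %||% (params$site_depth_high_factor * mean_total_dp)
  fail_low <- !is.na(total_dp) & total_dp < low
  fail_high <- !is.na(total_dp) & total_dp > high
  miss_frac <- rowMeans(is.na(gm$calls))
  fail_miss <- miss_frac > params$max_site_missingness
  drop <- fail_low | fail_high | fail_miss
  report <- data.frame(
    rule = c("site_depth_low", "site_depth_high", "site_missingness",
             "sites_removed", "sites_surviving"),
    count = c(sum(fail_low), sum(fail_high), sum(fail_miss),
              sum(drop), sum(!drop)),
    stringsAsFactors = FALSE)
  list(gm = gm[!drop, ], report = report, bounds = c(low = low, high = high))
}

#' Detect likely duplicate samples
#'
#' Computes the pairwise genotype mismatch rate over sites called in both
#' samples for every unordered sample pair, and reports pairs at or below
#' `max_mismatch_rate` (likely duplicates), sorted by ascending rate. Pairs
#' with no co-called sites are excluded with a warning.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @param max_mismatch_rate mismatch-rate threshold for flagging.
#' @return data.frame with columns `sample1`, `sample2`, `n_compared`,
#'   `n_mismatch`, `rate`.
#' @export
detect_duplicates <- function(gm, max_mismatch_rate = 0.01) {
  if (n_samples(gm) < 2L) stop("need at least two samples", call. = FALSE)
  pairs <- utils::combn(gm$samples, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- gm$calls[, pairs[1, p]]
    b <- gm$calls[, pairs[2, p]]
    both <- !is.na(a) & !is.na(b)
    if (!any(both)) {
      warning(sprintf("samples %s/%s share no co-called sites; pair skipped",
                      pairs[1, p], pairs[2, p]), call. = FALSE)
      return(NULL)
    }
    mism <- sum(a[both] != b[both])
    data.frame(sample1 = pairs[1, p], sample2 = pairs[2, p],
               n_compared = sum(both), n_mismatch = mism,
               rate = mism / sum(both), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(sample1 = character(), sample2 = character(),
                      n_compared = integer(), n_mismatch = integer(),
                      rate = numeric(), stringsAsFactors = FALSE)
  }
  out <- res[res$rate <= max_mismatch_rate, , drop = FALSE]
  out <- out[order(out$rate, out$sample1, out$sample2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove one sample of each duplicate pair
#'
#' For each flagged pair the sample with more missing calls is removed;
#' ties keep the lexicographically first sample id.
#'
#' @param gm a [genotype_matrix()].
#' @param dup_pairs output of [detect_duplicates()].
#' @return list with `gm` (samples removed) and `removed` (character ids).
#' @export
remove_duplicates <- function(gm, dup_pairs) {
  removed <- character()
  for (p in seq_len(nrow(dup_pairs))) {
    a <- dup_pairs$sample1[p]
    b <- dup_pairs$sample2[p]
    if (a %in% removed || b %in% removed) next
    miss_a <- sum(is.na(gm$calls[, a]))
    miss_b <- sum(is.na(gm$calls[, b]))
    drop <- if (miss_a > miss_b) a else if (miss_b > miss_a) b else
      sort(c(a, b))[2]
    removed <- c(removed, drop)
  }
  keep <- setdiff(gm$samples, removed)
  list(gm = gm[, keep], removed = removed)
}

#' Write a filter report as TSV or JSON
#'
#' @param report a report data.frame from [filter_calls()]/[filter_sites()]
#'   (or their row-bound combination).
#' @param path output path; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(stats::setNames(as.list(report$count), report$rule),
                         path, auto_unbox = TRUE)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
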