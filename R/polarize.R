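#' Assign ancestral alleles from outgroup samples
#'
#' A site's ancestral allele is the allele carried by the designated
#' outgroup samples when they are monomorphic there (the rule is
#' monomorphism, not reference identity: an outgroup unanimously carrying
#' the ALT allele makes ALT ancestral). Sites where fewer than
#' `min_outgroup_calls` outgroup samples are called, or where the outgroup
#' is polymorphic, remain unassigned with a reason code.
#'
#' @param gm a [genotype_matrix()].
#' @param outgroup_ids character vector of outgroup sample ids (e.g. the
#'   A/B-haplogroup samples).
#' @param min_outgroup_calls minimum number of called outgroup samples for a
#'   site to be assignable; defaults to all of them.
#' @return an `ancestral_map` data.frame, one row per site, with columns
#'   `chrom`, `pos`, `allele_idx` (allele index into the site's alleles, or
#'   `NA`), `allele` (character), `reason`
#'   (`assigned` / `polymorphic` / `insufficient_calls`).
#' @export
assign_ancestral <- function(gm, outgroup_ids,
                             min_outgroup_calls = length(outgroup_ids)) {
  outgroup_ids <- as.character(outgroup_ids)
  if (length(outgroup_ids) == 0L) stop("outgroup is empty", call. = FALSE)
  if (!all(outgroup_ids %in% gm$samples)) {
    stop("outgroup ids not in matrix: ",
         paste(setdiff(outgroup_ids, gm$samples), collapse = ", "), call. = FALSE)
  }
  stopifnot(min_outgroup_calls >= 1)
  og <- gm$calls[, outgroup_ids, drop = FALSE]
  ns <- n_sites(gm)
  idx <- rep(NA_integer_, ns)
  reason <- character(ns)
  for (s in seq_len(ns)) {
    calls <- og[s, ]
    calls <- calls[!is.na(calls)]
    if (length(calls) < min_outgroup_calls) {
      reason[s] <- "insufficient_calls"
    } else if (length(unique(calls)) > 1L) {
      reason[s] <- "polymorphic"
    } else {
      idx[s] <- calls[1]
      reason[s] <- "assigned"
    }
  }
  allele <- vapply(seq_len(ns), function(s) {
    if (is.na(idx[s])) NA_character_ else site_alleles(gm, s)[idx[s] + 1L]
  }, character(1))
  structure(
    data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
               allele_idx = idx, allele = allele, reason = reason,
               stringsAsFactors = FALSE),
    class = c("ancestral_map", "data.frame"))
}

# check an ancestral map matches a matrix site-for-site
check_amap <- function(gm, amap) {
  if (nrow(amap) != n_sites(gm) ||
      !all(amap$pos == gm$sites$pos & amap$chrom == gm$sites$chrom)) {
    stop("ancestral map does not match the genotype matrix sites", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-sample derived-mutation counts from the root
#'
#' Counts, for every sample, the number of assigned sites where its call
#' differs from the ancestral allele, and normalizes the count to mutations
#' per `norm_length` bp (default 10 Mb). The per-sample denominator is the
#' physical callable length scaled by the fraction of assigned sites that
#' are actually called in that sample, so missing data deflate neither the
#' count nor its normalization. Sites where a sample is missing contribute
#' nothing for that sample.
#'
#' @param gm a [genotype_matrix()].
#' @param amap an [assign_ancestral()] map built from the same matrix.
#' @param callable_length physical callable length in bp; defaults to the
#'   matrix's `callable_length`.
#' @param clock [clock_params()] supplying `norm_length`.
#' @param samples samples to count; defaults to all. Exclude the outgroup
#'   samples used for polarization: by construction they carry the ancestral
#'   allele at every assigned site, so their root counts are zero.
#' @return a `root_count_table` data.frame with columns `sample`, `raw`,
#'   `effective_length`, `normalized`, `alpha` (initialized `NA`, see
#'   [calibration_alpha()]); the dataset mean normalized count is attached
#'   as attribute `"mean_normalized"`.
#' @export
derived_root_counts <- function(gm, amap, callable_length = NULL,
                                clock = clock_params(), samples = gm$samples) {
  clock <- as_clock_params(clock)
  check_amap(gm, amap)
  samples <- as.character(samples)
  stopifnot(all(samples %in% gm$samples))
  callable_length <- callable_length %||% gm$callable_length
  if (is.null(callable_length) || is.na(callable_length) || callable_length <= 0) {
    stop("`callable_length` must be a positive length in bp", call. = FALSE)
  }
  assigned <- !is.na(amap$allele_idx)
  n_assigned <- sum(assigned)
  if (n_assigned == 0L) stop("no sites with assigned ancestral allele", call. = FALSE)
  anc <- amap$allele_idx[assigned]
  sub <- gm$calls[assigned, samples, drop = FALSE]
  raw <- integer(length(samples))
  eff <- numeric(length(samples))
  for (k in seq_along(samples)) {
    called <- !is.na(sub[, k])
    if (!any(called)) {
      stop(sprintf("sample %s has no called assigned sites; cannot normalize",
                   samples[k]), call. = FALSE)
    }
    raw[k] <- sum(sub[called, k] != anc[called])
    eff[k] <- callable_length * sum(called) / n_assigned
  }
  normalized <- raw * clock$norm_length / eff
  out <- data.frame(sample = samples, raw = raw, effective_length = eff,
                    normalized = normalized, alpha = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "mean_normalized") <- mean(normalized)
  class(out) <- c("root_count_table", "data.frame")
  out
}

#' Write an ancestral map or root-count table as TSV
#' @param x an `ancestral_map` or `root_count_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
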