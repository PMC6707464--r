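#' Haploid genotype matrix
#'
#' The central container: haploid calls for samples x sites together with the
#' per-call quality annotations the QC filters act on. Calls are allele
#' indices into each site's allele vector (0 = REF, 1 = first ALT, ...), with
#' `NA` for missing. `dp`, `gq` and `af` are matrices of read depth, phred
#' genotype quality and the fraction of reads supporting the called allele.
#'
#' @param samples character vector of sample ids (column order).
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated string, or `NA` for monomorphic sites).
#' @param calls integer matrix, sites x samples, of allele indices (`NA` =
#'   missing call).
#' @param dp,gq,af optional numeric matrices of the same shape.
#' @param callable_length physical length (bp) of the callable region the
#'   calls were made over; used as the normalization denominator downstream.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, calls, dp = NULL, gq = NULL,
                            af = NULL, callable_length = NA_real_) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(samples)) {
    stop("`calls` must be sites x samples", call. = FALSE)
  }
  for (nm in c("dp", "gq", "af")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), dim(calls))) {
      stop(sprintf("`%s` must have the same shape as `calls`", nm), call. = FALSE)
    }
  }
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) {
    sites <- sites[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[o, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[o, , drop = FALSE]
    if (!is.null(af)) af <- af[o, , drop = FALSE]
  }
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("duplicated site positions", call. = FALSE)
  }
  if (!is.null(dp) && any(dp < 0, na.rm = TRUE)) stop("DP must be >= 0", call. = FALSE)
  rownames(sites) <- NULL
  dimnames(calls) <- list(NULL, samples)
  structure(
    list(samples = samples, sites = sites, calls = calls,
         dp = dp, gq = gq, af = af, callable_length = callable_length),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (callable length %s bp)\n",
              nrow(x$sites), length(x$samples),
              ifelse(is.na(x$callable_length), "unknown",
                     format(x$callable_length, big.mark = ","))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param x a [genotype_matrix()].
#' @param i site index (logical or integer).
#' @param j sample index, ids allowed.
#' @param ... ignored.
#' @return a [genotype_matrix()].
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  genotype_matrix(x$samples[j], x$sites[i, , drop = FALSE],
                  x$calls[i, j, drop = FALSE], sub(x$dp), sub(x$gq), sub(x$af),
                  callable_length = x$callable_length)
}

# allele characters of site i: c(ref, alt1, alt2, ...)
site_alleles <- function(gm, i) {
  alt <- gm$sites$alt[i]
  if (is.na(alt) || !nzchar(alt)) return(gm$sites$ref[i])
  c(gm$sites$ref[i], strsplit(alt, ",", fixed = TRUE)[[1]])
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits haploid `GT` plus `DP`, `GQ` and `AD` FORMAT fields on a single
#' contig. `AD` is reconstructed from depth and the supporting-read fraction
#' (reads not supporting the call are attributed to the first other allele).
#' Output is byte-deterministic for a given matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  contigs <- unique(gm$sites$chrom)
  clen <- if (!is.na(gm$callable_length)) gm$callable_length else max(gm$sites$pos)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ychron",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(ceiling(clen))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  ns <- nrow(gm$sites)
  body <- character(ns)
  for (s in seq_len(ns)) {
    alleles <- site_alleles(gm, s)
    nall <- length(alleles)
    cells <- vapply(seq_along(gm$samples), function(k) {
      g <- gm$calls[s, k]
      gt <- if (is.na(g)) "." else as.character(g)
      dp <- if (is.null(gm$dp)) NA else gm$dp[s, k]
      gq <- if (is.null(gm$gq)) NA else gm$gq[s, k]
      af <- if (is.null(gm$af)) NA else gm$af[s, k]
      ad <- rep(0L, nall)
      if (!is.na(dp) && !is.na(g)) {
        supp <- if (is.na(af)) dp else round(af * dp)
        ad[g + 1L] <- as.integer(supp)
        rest <- as.integer(dp - supp)
        if (rest > 0 && nall > 1L) {
          other <- if (g + 1L == 1L) 2L else 1L
          ad[other] <- rest
        } else if (rest > 0) ad[1L] <- ad[1L] + rest
      }
      paste(gt,
            ifelse(is.na(dp), ".", as.character(as.integer(dp))),
            ifelse(is.na(gq), ".", as.character(as.integer(gq))),
            paste(ad, collapse = ","), sep = ":")
    }, character(1))
    alt <- gm$sites$alt[s]
    body[s] <- paste(c(gm$sites$chrom[s], gm$sites$pos[s], ".",
                       gm$sites$ref[s],
                       ifelse(is.na(alt) | !nzchar(alt), ".", alt),
                       ".", ".", ".", "GT:DP:GQ:AD", cells), collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read haploid genotypes from a VCF, optionally restricted to a BED mask
#'
#' Parses a VCF v4.2 via the vcfR package into a [genotype_matrix()].
#' Genotypes must be haploid (`0`, `1`, ... or `.`); the supporting-read
#' fraction is derived from `AD` when present. A BED file of callable
#' intervals (0-based half-open, as standard) restricts sites and sets the
#' callable length to the total interval width.
#'
#' @param vcf path to a VCF file.
#' @param bed optional path to a BED file of callable regions.
#' @param callable_length override for the callable length (bp); defaults to
#'   the BED width when `bed` is given.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(vcf, bed = NULL, callable_length = NA_real_) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = ifelse(fix[, "ALT"] %in% c(".", ""), NA_character_,
                                   fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (any(grepl("[/|]", gt[!is.na(gt)]))) {
    stop("diploid genotypes found; expected haploid calls", call. = FALSE)
  }
  calls <- suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt),
                                   dimnames = dimnames(gt)))
  num <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    m
  }
  dp <- num("DP")
  gq <- num("GQ")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  af <- NULL
  if (!is.null(ad)) {
    af <- matrix(NA_real_, nrow = nrow(calls), ncol = ncol(calls))
    for (k in seq_len(ncol(calls))) {
      parts <- strsplit(ad[, k], ",", fixed = TRUE)
      af[, k] <- vapply(seq_along(parts), function(s) {
        g <- calls[s, k]
        p <- suppressWarnings(as.numeric(parts[[s]]))
        if (is.na(g) || anyNA(p) || sum(p) == 0) return(NA_real_)
        if (g + 1L > length(p)) return(NA_real_)
        p[g + 1L] / sum(p)
      }, numeric(1))
    }
  }
  if (!is.null(bed)) {
    iv <- read_bed(bed)
    keep <- rep(FALSE, nrow(sites))
    for (r in seq_len(nrow(iv))) {
      keep <- keep | (sites$chrom == iv$chrom[r] &
                        sites$pos >= iv$start1[r] & sites$pos <= iv$end[r])
    }
    sites <- sites[keep, , drop = FALSE]
    calls <- calls[keep, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[keep, , drop = FALSE]
    if (!is.null(af)) af <- af[keep, , drop = FALSE]
    if (is.na(callable_length)) callable_length <- sum(iv$end - iv$start1 + 1)
  }
  genotype_matrix(samples, sites, calls, dp = dp, gq = gq, af = af,
                  callable_length = callable_length)
}

# BED intervals as a data.frame with 1-based inclusive start1/end.
# Uses rtracklayer when available; falls back to reading the three standard
# columns directly (BED is 0-based half-open).
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    return(data.frame(chrom = as.character(gr$seqnames),
                      start1 = gr$start, end = gr$end,
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start1 = df[[2]] + 1L,
             end = df[[3]], stringsAsFactors = FALSE)
}
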