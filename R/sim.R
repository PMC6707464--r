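#' Coverage and error model for synthetic genotype calls
#'
#' Parameters of the noise layer applied on top of true haplotypes. Depth is
#' drawn from a negative binomial (overdispersed Poisson) with mean
#' `mean_dp` and size (dispersion) parameter `dp_size`; calls are flipped to
#' the other allele with probability `error_rate`, dropped with probability
#' `missing_rate` (or when zero reads are drawn); supporting-read counts are
#' binomial with per-read error `seq_error`; GQ is a deterministic function
#' of depth and the error draw, scaled by `gq_scale`.
#'
#' The default mean depth of 16 reads reflects typical ~16x Y-chromosome
#' coverage of modern short-read studies.
#'
#' @param mean_dp mean read depth per call.
#' @param dp_size negative-binomial size (smaller = more overdispersed).
#' @param error_rate per-call probability of a wrong allele.
#' @param missing_rate per-call probability of a missing genotype.
#' @param seq_error per-read probability of supporting the wrong allele.
#' @param gq_scale GQ units per read of depth for a correct call.
#' @return an object of class `coverage_model`.
#' @examples
#' coverage_model()                      # study-like noise
#' coverage_model(error_rate = 0, missing_rate = 0, seq_error = 0)  # noiseless
#' @export
coverage_model <- function(mean_dp = 16, dp_size = 8, error_rate = 0.002,
                           missing_rate = 0.05, seq_error = 0.02,
                           gq_scale = 6) {
  assert_scalar_num(mean_dp, "mean_dp", lower = .Machine$double.xmin)
  assert_scalar_num(dp_size, "dp_size", lower = .Machine$double.xmin)
  assert_scalar_num(error_rate, "error_rate", 0, 1)
  assert_scalar_num(missing_rate, "missing_rate", 0, 1)
  assert_scalar_num(seq_error, "seq_error", 0, 1)
  structure(list(mean_dp = mean_dp, dp_size = dp_size, error_rate = error_rate,
                 missing_rate = missing_rate, seq_error = seq_error,
                 gq_scale = gq_scale),
            class = "coverage_model")
}

#' Drop mutations onto a dated genealogy
#'
#' Simulates Poisson mutation accumulation: each branch receives a count
#' drawn from Poisson(mu * multiplier * region_length * duration), with
#' positions uniform over the callable region. Positions are unique
#' (infinite-sites) except that each mutation independently re-uses an
#' already-mutated position on a different branch with probability
#' `recurrence_prob`, producing recurrent mutations that share the same
#' ancestral and derived alleles across lineages.
#'
#' @param tree a [build_truth_tree()] genealogy.
#' @param clock [clock_params()]; only `mu_point` is used here.
#' @param region_length callable region length in bp (positions are drawn
#'   from 1..region_length).
#' @param recurrence_prob per-mutation probability of re-using an existing
#'   position (default 0.002; recurrent SNP sharing is rare but observed).
#' @param seed integer seed; required so call sets are reproducible.
#' @return a `mutation_set` data.frame with columns `pos`, `branch`,
#'   `ancestral`, `derived`, `recurrent`, sorted by position; the region
#'   length is carried as an attribute.
#' @export
drop_mutations <- function(tree, clock, region_length,
                           recurrence_prob = 0.002, seed) {
  clock <- as_clock_params(clock)
  assert_scalar_num(region_length, "region_length", lower = 1)
  assert_scalar_num(recurrence_prob, "recurrence_prob", 0, 1)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(seed)
  br <- tree_branches(tree)
  lambda <- clock$mu_point * br$mult * region_length * br$duration
  counts <- stats::rpois(nrow(br), lambda)
  n <- sum(counts)
  empty <- data.frame(pos = integer(), branch = character(),
                      ancestral = character(), derived = character(),
                      recurrent = logical(), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(empty, region_length = region_length,
                     class = c("mutation_set", "data.frame")))
  }
  branch <- rep(br$id, counts)
  ord <- sample.int(n)            # interleave branches before recurrence draws
  branch <- branch[ord]
  pos <- sample.int(region_length, n)   # unique positions
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), character(1))
  reuse <- which(stats::runif(n) < recurrence_prob & seq_len(n) > 1L)
  for (i in reuse) {
    j <- sample.int(i - 1L, 1L)
    if (branch[j] != branch[i]) {
      pos[i] <- pos[j]
      anc[i] <- anc[j]
      der[i] <- der[j]       # homoplasy: identical-by-state derived allele
    }
  }
  out <- data.frame(pos = pos, branch = branch, ancestral = anc, derived = der,
                    recurrent = pos %in% pos[duplicated(pos)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$branch), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, region_length = region_length,
            class = c("mutation_set", "data.frame"))
}

# true haplotype matrix (sites x leaves, allele index 0=ancestral/1=derived)
# for a mutation set; one row per unique position.
true_haplotypes <- function(mutations, tree) {
  inc <- branch_leaf_incidence(tree)
  upos <- sort(unique(mutations$pos))
  leaves <- colnames(inc)
  calls <- matrix(0L, nrow = length(upos), ncol = length(leaves),
                  dimnames = list(NULL, leaves))
  idx <- match(mutations$pos, upos)
  for (r in seq_len(nrow(mutations))) {
    carriers <- inc[mutations$branch[r], ]
    calls[idx[r], carriers] <- 1L
  }
  first <- !duplicated(mutations$pos)
  ord <- order(mutations$pos[first])
  list(pos = upos,
       ancestral = mutations$ancestral[first][ord],
       derived = mutations$derived[first][ord],
       calls = calls)
}

#' Synthesize noisy haploid genotype calls from a mutation set
#'
#' Converts the true haplotypes implied by a genealogy plus mutation set
#' into a [genotype_matrix()] with per-call DP, GQ and supporting-read
#' fraction drawn from a [coverage_model()]. The VCF REF allele is the true
#' ancestral allele and ALT the derived allele. Optionally a number of
#' invariant (monomorphic ancestral) sites are emitted so that downstream
#' denominators can be computed literally from the matrix.
#'
#' @param mutations a [drop_mutations()] result.
#' @param tree the genealogy the mutations were dropped on.
#' @param model a [coverage_model()].
#' @param seed integer seed.
#' @param n_invariant number of invariant ancestral sites to emit.
#' @param contig contig name for the emitted sites.
#' @return a [genotype_matrix()]; the true (noise-free) call matrix is
#'   attached as attribute `"truth"`.
#' @export
synthesize_calls <- function(mutations, tree, model = coverage_model(), seed,
                             n_invariant = 0L, contig = "Y") {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(seed)
  region_length <- attr(mutations, "region_length") %||% NA_real_
  hap <- true_haplotypes(mutations, tree)
  leaves <- colnames(hap$calls)
  pos <- hap$pos
  ref <- hap$ancestral
  alt <- hap$derived
  calls <- hap$calls
  if (n_invariant > 0L) {
    if (is.na(region_length)) stop("region length unknown; cannot place invariant sites",
                                   call. = FALSE)
    free <- setdiff(seq_len(as.integer(region_length)), pos)
    ipos <- sort(sample(free, min(n_invariant, length(free))))
    pos <- c(pos, ipos)
    ref <- c(ref, sample(c("A", "C", "G", "T"), length(ipos), replace = TRUE))
    alt <- c(alt, rep(NA_character_, length(ipos)))
    calls <- rbind(calls, matrix(0L, nrow = length(ipos), ncol = length(leaves)))
    o <- order(pos)
    pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
    calls <- calls[o, , drop = FALSE]
  }
  truth <- calls
  ncell <- length(calls)
  dp <- matrix(stats::rnbinom(ncell, mu = model$mean_dp, size = model$dp_size),
               nrow = nrow(calls))
  err <- matrix(stats::runif(ncell) < model$error_rate, nrow = nrow(calls))
  miss <- matrix(stats::runif(ncell) < model$missing_rate, nrow = nrow(calls)) |
    (dp == 0L)
  noisy <- calls
  has_alt <- !is.na(alt)
  flip <- err & matrix(has_alt, nrow = nrow(calls), ncol = ncol(calls))
  noisy[flip] <- 1L - noisy[flip]
  noisy[miss] <- NA_integer_
  supp_p <- ifelse(err, 0.55, 1 - model$seq_error)
  supp <- stats::rbinom(ncell, size = as.vector(dp), prob = as.vector(supp_p))
  af <- matrix(ifelse(dp > 0, supp / as.vector(dp), NA_real_), nrow = nrow(calls))
  gq <- matrix(pmin(99L, as.integer(round(
    model$gq_scale * as.vector(dp) * ifelse(as.vector(err), 0.3, 1)))),
    nrow = nrow(calls))
  sites <- data.frame(chrom = contig, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(leaves, sites, noisy, dp = dp, gq = gq, af = af,
                        callable_length = region_length)
  attr(gm, "truth") <- truth
  gm
}

#' Write the simulator truth files
#'
#' Writes the genealogy as newick with branch lengths in years and the
#' mutation set as a TSV (`pos`, `branch`, `ancestral`, `derived`,
#' `recurrent`).
#'
#' @param tree a [build_truth_tree()] genealogy.
#' @param mutations a [drop_mutations()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_truth <- function(tree, mutations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nwk <- file.path(dir, "truth_tree.nwk")
  tsv <- file.path(dir, "truth_mutations.tsv")
  write_truth_newick(tree, nwk)
  utils::write.table(as.data.frame(mutations), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nwk, tsv))
}

#' Simulate a complete synthetic call set
#'
#' Convenience wrapper: drops mutations on a genealogy and synthesizes a
#' genotype matrix, deriving independent sub-seeds for the two stages from
#' one master seed.
#'
#' @inheritParams drop_mutations
#' @inheritParams synthesize_calls
#' @return list with elements `gm`, `mutations`, `tree`.
#' @export
sim_dataset <- function(tree, clock = clock_params(), region_length = 1e7,
                        model = coverage_model(), recurrence_prob = 0.002,
                        seed, n_invariant = 0L) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  mut <- drop_mutations(tree, clock, region_length,
                        recurrence_prob = recurrence_prob, seed = seeds[1])
  gm <- synthesize_calls(mut, tree, model = model, seed = seeds[2],
                         n_invariant = n_invariant)
  list(gm = gm, mutations = mut, tree = tree)
}
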