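# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

noiseless <- function() {
  coverage_model(error_rate = 0, missing_rate = 0, seq_error = 0)
}

# Genealogy used for estimator recovery: two outgroup leaves attached
# directly at the root (so outgroup polarization is exact), an ingroup split
# at `split_age`, and two clades of n_a / n_b leaves coalescing at `coal`.
mk_split_tree <- function(root_age = 1e5, split_age = 71400, coal = 2500,
                          n_a = 3, n_b = 3, mult_a = 1, mult_b = 1) {
  stopifnot(coal < split_age, split_age < root_age)
  a <- paste0("a", seq_len(n_a))
  b <- paste0("b", seq_len(n_b))
  nodes <- data.frame(
    id     = c("root", "og1", "og2", "split", "ancA", "ancB", a, b),
    parent = c(NA, "root", "root", "root", "split", "split",
               rep("ancA", n_a), rep("ancB", n_b)),
    age    = c(root_age, 0, 0, split_age, coal, coal, rep(0, n_a + n_b)))
  m <- c(stats::setNames(rep(mult_a, n_a + 1), c("ancA", a)),
         stats::setNames(rep(mult_b, n_b + 1), c("ancB", b)))
  build_truth_tree(nodes, multipliers = m)
}

# Three ingroup clades A, B, C (3 leaves each) plus outgroup; rate
# heterogeneity on A (mult_a) and B (mult_b), C at 1. The dated node is the
# A-C split, so the heterogeneity of A is one-sided with respect to it.
mk_threeclade_tree <- function(mult_a = 0.8, mult_b = 1.2) {
  a <- paste0("a", 1:3); b <- paste0("b", 1:3); c3 <- paste0("c", 1:3)
  nodes <- data.frame(
    id     = c("root", "og1", "og2", "x", "y", "ancA", "ancB", "ancC", a, b, c3),
    parent = c(NA, "root", "root", "root", "x", "y", "x", "y",
               rep("ancA", 3), rep("ancB", 3), rep("ancC", 3)),
    age    = c(1e5, 0, 0, 8e4, 71400, 2500, 2500, 2500, rep(0, 9)))
  m <- c(stats::setNames(rep(mult_a, 4), c("ancA", a)),
         stats::setNames(rep(mult_b, 4), c("ancB", b)))
  build_truth_tree(nodes, multipliers = m)
}

# Hand-built haploid matrix; all sites on contig "Y" at positions 1..n,
# ref "A", alt "G" unless alt is given.
mk_gm <- function(calls, dp = NULL, gq = NULL, af = NULL,
                  callable_length = NA_real_, alt = "G", ref = "A") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  samples <- colnames(calls) %||% paste0("s", seq_len(ncol(calls)))
  sites <- data.frame(chrom = "Y", pos = seq_len(n),
                      ref = rep(ref, length.out = n),
                      alt = rep(alt, length.out = n),
                      stringsAsFactors = FALSE)
  genotype_matrix(samples, sites, calls, dp = dp, gq = gq, af = af,
                  callable_length = callable_length)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Planted perfect-phylogeny fixture: query clade Q attaches to reference
# clade D; the Q+D stem carries SNPs shared with D, the Q stem carries
# exclusive SNPs, and one recurrent mutation is planted so the derived
# allele also appears in the distant clade E.
mk_planted <- function(n_exclusive = 10, n_shared = 3, recurrent = TRUE) {
  nodes <- data.frame(
    id = c("root", "og1", "og2", "in", "qd", "ancQ", "ancD", "ancE",
           paste0("q", 1:3), paste0("d", 1:2), paste0("e", 1:2)),
    parent = c(NA, "root", "root", "root", "in", "qd", "qd", "in",
               rep("ancQ", 3), rep("ancD", 2), rep("ancE", 2)),
    age = c(9e4, 0, 0, 8e4, 73000, 2500, 2500, 2500, rep(0, 7)))
  tree <- build_truth_tree(nodes)
  mut <- data.frame(
    pos = integer(), branch = character(), ancestral = character(),
    derived = character(), recurrent = logical(), stringsAsFactors = FALSE)
  add <- function(pos, branch, rec = FALSE) {
    rbind(mut, data.frame(pos = pos, branch = branch, ancestral = "A",
                          derived = "G", recurrent = rec))
  }
  mut <- add(seq_len(n_exclusive), rep("ancQ", n_exclusive))
  mut <- add(100 + seq_len(n_shared), rep("qd", n_shared))  # shared Q+D stem
  mut <- add(200 + seq_len(4), rep("ancE", 4))  # E-private (not query-derived)
  mut <- add(300, "ancD")                       # D-private site
  if (recurrent) {
    mut <- add(400, "ancQ", rec = TRUE)
    mut <- add(400, "ancE", rec = TRUE)         # same derived allele in E
  }
  attr(mut, "region_length") <- 1e6
  class(mut) <- c("mutation_set", "data.frame")
  gm <- synthesize_calls(mut, tree, noiseless(), seed = 1)
  amap <- assign_ancestral(gm, c("og1", "og2"))
  list(tree = tree, mut = mut, gm = gm, amap = amap)
}

# full pipeline from a simulated dataset to a calibrated split estimate
estimate_split <- function(tree, cladeA, cladeB, seed, clock = clock_params(),
                           region_length = 1e7, calibrated = TRUE,
                           outgroup = c("og1", "og2")) {
  ds <- sim_dataset(tree, clock, region_length, noiseless(), seed = seed)
  amap <- assign_ancestral(ds$gm, outgroup)
  counts <- NULL
  if (calibrated) {
    counts <- calibration_alpha(derived_root_counts(
      ds$gm, amap, clock = clock, samples = setdiff(ds$gm$samples, outgroup)))
  }
  node_split_time(ds$gm, amap, cladeA, cladeB, counts = counts, clock = clock,
                  denominator = "callable_length_proxy")
}
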