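#' Derived sites shared by all called members of a clade
#'
#' Returns the sites (positions) at which every called member of the clade
#' carries a derived allele, with at least `min_called` members called.
#' These are the candidate lineage-defining SNPs of the clade.
#'
#' @param gm a [genotype_matrix()].
#' @param amap an [assign_ancestral()] map for the same matrix.
#' @param clade non-empty character vector of sample ids.
#' @param min_called minimum called clade members for a site to qualify.
#' @return integer vector of positions.
#' @export
clade_derived_sites <- function(gm, amap, clade, min_called = 1L) {
  clade <- as.character(clade)
  if (length(clade) == 0L) stop("clade is empty", call. = FALSE)
  check_amap(gm, amap)
  assigned <- !is.na(amap$allele_idx)
  anc <- amap$allele_idx
  sub <- gm$calls[, clade, drop = FALSE]
  derived <- sweep(sub, 1, anc, FUN = `!=`)
  ncalled <- rowSums(!is.na(sub))
  all_derived <- rowSums(derived & !is.na(sub), na.rm = TRUE) == ncalled
  hit <- assigned & ncalled >= min_called & all_derived & ncalled > 0
  gm$sites$pos[hit]
}

#' Profile exclusive versus shared derived SNPs of a query clade
#'
#' Partitions the query clade's derived sites by who else carries the
#' derived allele: carried by no non-query sample (`exclusive`), carried
#' additionally by members of exactly one reference clade (`shared` with
#' that clade), or carried across several reference clades or by samples
#' outside all reference clades (`multi_clade`, treated as unstable).
#' Sharing with a clade requires at least one derived member of that clade
#' and no derived carrier outside the clade and the query.
#'
#' @param gm a [genotype_matrix()].
#' @param amap an [assign_ancestral()] map.
#' @param query character vector of query sample ids.
#' @param references named list of reference clades (character vectors),
#'   disjoint from each other and from the query.
#' @param min_called passed to [clade_derived_sites()].
#' @return an object of class `sharing_profile`: `query_sites`, `exclusive`
#'   (positions), `shared` (named list of positions per reference clade),
#'   `multi_clade` (positions), and a `counts` summary.
#' @export
sharing_profile <- function(gm, amap, query, references, min_called = 1L) {
  query <- as.character(query)
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("`references` must be a named list of clades", call. = FALSE)
  }
  allref <- unlist(references, use.names = FALSE)
  if (anyDuplicated(allref) || length(intersect(allref, query)) > 0L) {
    stop("reference clades must be disjoint from each other and the query",
         call. = FALSE)
  }
  qsites <- clade_derived_sites(gm, amap, query, min_called = min_called)
  others <- setdiff(gm$samples, query)
  anc <- amap$allele_idx
  shared <- stats::setNames(vector("list", length(references)), names(references))
  for (nm in names(references)) shared[[nm]] <- integer()
  exclusive <- integer()
  multi <- integer()
  idx <- match(qsites, gm$sites$pos)
  for (t in seq_along(qsites)) {
    s <- idx[t]
    oc <- gm$calls[s, others]
    carriers <- others[!is.na(oc) & oc != anc[s]]
    if (length(carriers) == 0L) {
      exclusive <- c(exclusive, qsites[t])
      next
    }
    hit <- names(references)[vapply(references, function(r)
      any(carriers %in% r), logical(1))]
    outside <- setdiff(carriers, allref)
    if (length(hit) == 1L && length(outside) == 0L) {
      shared[[hit]] <- c(shared[[hit]], qsites[t])
    } else {
      multi <- c(multi, qsites[t])
    }
  }
  counts <- c(exclusive = length(exclusive),
              vapply(shared, length, integer(1)),
              multi_clade = length(multi))
  structure(list(query = query, query_sites = qsites, exclusive = exclusive,
                 shared = shared, multi_clade = multi, counts = counts),
            class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat("<sharing_profile>", length(x$query_sites), "query-derived sites:\n")
  print(x$counts)
  invisible(x)
}

#' Place a query lineage from its sharing profile
#'
#' Reference clades sharing no more than `recurrence_threshold` SNPs with
#' the query are interpreted as recurrent mutation in different lineages
#' and set aside (their sites flagged). Among the remaining clades the
#' largest shared count wins; a tie yields `AMBIGUOUS`, and no clade above
#' the threshold yields `BASAL` (the query attaches below all references).
#'
#' @param profile a [sharing_profile()].
#' @param recurrence_threshold maximum shared-SNP count still explained as
#'   recurrence (default 1, the single-shared-SNP rule).
#' @return an object of class `placement`: `status` (`"placed"`,
#'   `"AMBIGUOUS"` or `"BASAL"`), `clade` (when placed), `support` (shared
#'   SNP count), `recurrent_sites` (positions flagged as recurrent).
#' @export
place_lineage <- function(profile, recurrence_threshold = 1L) {
  stopifnot(inherits(profile, "sharing_profile"))
  counts <- vapply(profile$shared, length, integer(1))
  flagged <- counts > 0L & counts <= recurrence_threshold
  recurrent_sites <- sort(unique(c(unlist(profile$shared[flagged],
                                          use.names = FALSE),
                                   profile$multi_clade)))
  viable <- counts[counts > recurrence_threshold]
  if (length(viable) == 0L) {
    out <- list(status = "BASAL", clade = NA_character_, support = 0L,
                recurrent_sites = recurrent_sites)
  } else {
    top <- names(viable)[viable == max(viable)]
    if (length(top) > 1L) {
      out <- list(status = "AMBIGUOUS", clade = NA_character_,
                  support = max(viable), recurrent_sites = recurrent_sites)
    } else {
      out <- list(status = "placed", clade = top, support = unname(max(viable)),
                  recurrent_sites = recurrent_sites)
    }
  }
  structure(out, class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %s%s (support %d SNPs, %d recurrent site(s) flagged)\n",
              x$status, if (x$status == "placed") paste0(": ", x$clade) else "",
              x$support, length(x$recurrent_sites)))
  invisible(x)
}

#' Read clade definitions from a two-column TSV
#'
#' @param path TSV with columns `sample`, `clade` (header optional when the
#'   first row parses as data).
#' @return named list of character vectors, one per clade.
#' @export
read_clades <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "clade") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("sample", "clade"),
                            stringsAsFactors = FALSE)
  }
  split(df$sample, df$clade)
}
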