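#' Build a dated genealogy with per-branch rate multipliers
#'
#' Constructs a `truth_tree`: a rooted genealogy whose nodes carry absolute
#' ages in years (leaves at 0, the root oldest) and whose branches carry
#' dimensionless rate multipliers modelling haplogroup-specific
#' mutation-accumulation heterogeneity. The tree is the fixed object the
#' simulator drops mutations onto; it is user-specified, not sampled from a
#' coalescent prior, because the analysis dates a fixed estimated topology.
#'
#' @param x either a `data.frame` with columns `id`, `parent` (`NA` for the
#'   root), `age` (years), and optionally `mult`; or a newick string /
#'   `ape::phylo` object whose branch lengths are interpreted as durations in
#'   years (the tree must then be ultrametric so leaf ages are 0).
#' @param multipliers optional named numeric vector of per-branch rate
#'   multipliers; names are child-node ids (a branch is identified by the
#'   node below it). Unnamed branches default to 1.
#' @return an object of class `truth_tree` with a node table and helper
#'   accessors (see [tree_branches()], [tree_leaves()]).
#' @examples
#' build_truth_tree("((a:71400,b:71400):1800,c:73200);")
#' build_truth_tree(data.frame(
#'   id = c("r", "a", "b"), parent = c(NA, "r", "r"), age = c(70000, 0, 0)))
#' @export
build_truth_tree <- function(x, multipliers = NULL) {
  nodes <- if (is.data.frame(x)) {
    df <- x
    if (is.null(df$mult)) df$mult <- 1
    df
  } else {
    phylo_to_nodes(x)
  }
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  nodes$mult[is.na(nodes$mult)] <- 1
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers))) {
      stop("`multipliers` must be named by child-node id", call. = FALSE)
    }
    hit <- match(names(multipliers), nodes$id)
    if (anyNA(hit)) {
      stop("multiplier names not in tree: ",
           paste(names(multipliers)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    nodes$mult[hit] <- unname(multipliers)
  }
  validate_truth_tree(nodes)
}

phylo_to_nodes <- function(x) {
  ph <- if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  if (is.null(ph) || !inherits(ph, "phylo")) {
    stop("could not parse newick input", call. = FALSE)
  }
  ntip <- length(ph$tip.label)
  depth <- ape::node.depth.edgelength(ph)
  tipd <- depth[seq_len(ntip)]
  if (diff(range(tipd)) > 1e-6 * max(tipd, 1)) {
    stop("newick branch lengths are not ultrametric: leaf ages must all be 0",
         call. = FALSE)
  }
  age <- max(tipd) - depth
  nlab <- ph$node.label
  ids <- c(ph$tip.label,
           if (!is.null(nlab) && all(nzchar(nlab))) nlab
           else paste0("node", seq_len(ph$Nnode)))
  parent <- rep(NA_character_, ntip + ph$Nnode)
  parent[ph$edge[, 2]] <- ids[ph$edge[, 1]]
  data.frame(id = ids, parent = parent, age = age, mult = 1,
             stringsAsFactors = FALSE)
}

validate_truth_tree <- function(nodes) {
  need <- c("id", "parent", "age", "mult")
  if (!all(need %in% names(nodes))) {
    stop("node table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node/sample id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1L) stop("tree must have exactly one root", call. = FALSE)
  known <- nodes$parent[!is.na(nodes$parent)] %in% nodes$id
  if (!all(known)) stop("parent id not in tree", call. = FALSE)
  if (any(nodes$age < 0)) stop("node ages must be non-negative", call. = FALSE)
  if (any(nodes$mult <= 0)) stop("rate multipliers must be > 0", call. = FALSE)
  pa <- nodes$age[match(nodes$parent, nodes$id)]
  bad <- !is.na(pa) & nodes$age > pa
  if (any(bad)) {
    stop("child node older than its parent: ",
         paste(nodes$id[bad], collapse = ", "), call. = FALSE)
  }
  has_child <- nodes$id %in% nodes$parent
  if (any(!has_child & nodes$age > 0)) {
    stop("leaf ages must be 0 (found dated node without children)", call. = FALSE)
  }
  structure(list(nodes = nodes, root = root), class = "truth_tree")
}

#' Branch table of a truth tree
#'
#' One row per branch, identified by the node below it, with the branch
#' duration in years and its rate multiplier.
#'
#' @param tree a [build_truth_tree()] object.
#' @return data.frame with columns `id`, `parent`, `duration`, `mult`.
#' @export
tree_branches <- function(tree) {
  stopifnot(inherits(tree, "truth_tree"))
  n <- tree$nodes
  b <- n[!is.na(n$parent), , drop = FALSE]
  b$duration <- n$age[match(b$parent, n$id)] - b$age
  b[, c("id", "parent", "duration", "mult")]
}

#' Leaf (sample) ids of a truth tree
#' @param tree a [build_truth_tree()] object.
#' @return character vector of leaf ids, in node-table order.
#' @export
tree_leaves <- function(tree) {
  n <- tree$nodes
  n$id[!(n$id %in% n$parent)]
}

# branch ids (child-node ids) on the path root -> leaf, for every leaf
tree_paths <- function(tree) {
  n <- tree$nodes
  parent <- stats::setNames(n$parent, n$id)
  lapply(stats::setNames(tree_leaves(tree), tree_leaves(tree)), function(leaf) {
    path <- character()
    cur <- leaf
    while (!is.na(parent[[cur]])) {
      path <- c(cur, path)
      cur <- parent[[cur]]
    }
    path
  })
}

# logical matrix branches x leaves: is leaf below this branch?
branch_leaf_incidence <- function(tree) {
  paths <- tree_paths(tree)
  br <- tree_branches(tree)$id
  out <- matrix(FALSE, nrow = length(br), ncol = length(paths),
                dimnames = list(br, names(paths)))
  for (leaf in names(paths)) out[paths[[leaf]], leaf] <- TRUE
  out
}

# total expected root-to-leaf mutational path length (sum duration * mult)
tree_root_path_years <- function(tree) {
  br <- tree_branches(tree)
  w <- stats::setNames(br$duration * br$mult, br$id)
  vapply(tree_paths(tree), function(p) sum(w[p]), numeric(1))
}

#' Write a truth tree as newick with branch lengths in years
#'
#' @param tree a [build_truth_tree()] object.
#' @param path output file; when `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_truth_newick <- function(tree, path = NULL) {
  n <- tree$nodes
  kids <- split(n$id[!is.na(n$parent)], n$parent[!is.na(n$parent)])
  rec <- function(id) {
    ch <- kids[[id]]
    lab <- if (id %in% tree_leaves(tree)) id else ""
    if (is.null(ch)) return(lab)
    inner <- paste(vapply(ch, function(c2) {
      dur <- n$age[n$id == id] - n$age[n$id == c2]
      paste0(rec(c2), ":", format(dur, scientific = FALSE, trim = TRUE))
    }, character(1)), collapse = ",")
    paste0("(", inner, ")", lab)
  }
  nwk <- paste0(rec(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' @export
print.truth_tree <- function(x, ...) {
  cat(sprintf("<truth_tree> %d nodes, %d leaves, root '%s' at %s years\n",
              nrow(x$nodes), length(tree_leaves(x)), x$root,
              format(max(x$nodes$age), big.mark = ",")))
  invisible(x)
}
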