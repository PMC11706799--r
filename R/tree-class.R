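# Rooted tree data model.
#
# A `ptree` stores a rooted tree as parallel per-node vectors. Node indices
# are arbitrary positive integers (kept stable under grafting); the root has
# parent NA and no branch length. Edge i is identified with its child node i,
# so `brlen[i]` is the length of the branch above node i and `edge_num[i]`
# its jplace edge number (NA until `number_edges()` is called).

#' Construct a rooted tree object
#'
#' Low-level constructor used by the parsers and simulators. Most users
#' obtain trees from [parse_newick()], [simulate_taxon_tree()] or
#' [as_ptree()].
#'
#' @param parent integer vector; `parent[i]` is the parent node of node `i`,
#'   `NA` for the root.
#' @param brlen numeric vector of branch lengths (substitutions/site) above
#'   each node; `NA` for the root.
#' @param label character vector of node labels; leaves must carry unique,
#'   non-empty labels, internal labels may be `NA`.
#' @param edge_num optional integer vector of jplace edge numbers per branch
#'   (`NA` for the root / unnumbered trees).
#' @param validate check structural invariants (default `TRUE`).
#' @return an object of class `ptree`.
#' @export
ptree <- function(parent, brlen, label, edge_num = NULL, validate = TRUE) {
  n <- length(parent)
  stopifnot(length(brlen) == n, length(label) == n)
  if (is.null(edge_num)) edge_num <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  ord <- seq_len(n)
  for (i in ord) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  tr <- structure(
    list(parent = as.integer(parent), brlen = as.numeric(brlen),
         label = as.character(label), children = children,
         edge_num = as.integer(edge_num),
         root = which(is.na(parent))[1]),
    class = "ptree")
  if (validate) validate_ptree(tr)
  tr
}

#' @keywords internal
validate_ptree <- function(tr) {
  n <- length(tr$parent)
  roots <- which(is.na(tr$parent))
  if (length(roots) != 1L) stop_bp("tree must have exactly one root, found ", length(roots))
  if (!is.na(tr$brlen[roots])) stop_bp("root must not carry a branch length")
  nonroot <- setdiff(seq_len(n), roots)
  if (any(is.na(tr$brlen[nonroot]))) stop_bp("all non-root nodes need a branch length")
  if (any(tr$brlen[nonroot] < 0)) stop_bp("negative branch length")
  lv <- leaf_nodes(tr)
  labs <- tr$label[lv]
  if (anyNA(labs) || any(labs == "")) stop_bp("every leaf needs a non-empty label")
  if (anyDuplicated(labs)) {
    stop_bp("duplicate leaf label: ", labs[duplicated(labs)][1])
  }
  # reachability from root (no cycles, single component)
  seen <- logical(n)
  stack <- tr$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) stop_bp("cycle detected in tree")
    seen[v] <- TRUE
    stack <- c(stack, tr$children[[v]])
  }
  if (!all(seen)) stop_bp("disconnected nodes in tree")
  en <- tr$edge_num[nonroot]
  if (!all(is.na(en))) {
    if (anyNA(en)) stop_bp("edge numbers must be assigned to all branches or none")
    if (!setequal(en, seq_along(en) - 1L)) {
      stop_bp("edge numbers must be a bijection onto 0..", length(en) - 1L)
    }
  }
  invisible(tr)
}

#' @keywords internal
leaf_nodes <- function(tr) {
  which(vapply(tr$children, length, 1L) == 0L)
}

#' Leaf labels of a tree
#' @param tr a `ptree`.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tr) tr$label[leaf_nodes(tr)]

#' Number of leaves
#' @param tr a `ptree`.
#' @export
n_leaves <- function(tr) length(leaf_nodes(tr))

#' @keywords internal
node_of_label <- function(tr, label) {
  i <- match(label, tr$label)
  if (anyNA(i)) stop_bp("unknown leaf label: ", paste(label[is.na(i)], collapse = ", "))
  i
}

#' @keywords internal
is_leaf <- function(tr, v) length(tr$children[[v]]) == 0L

# postorder node sequence, children visited in stored order
#' @keywords internal
postorder_nodes <- function(tr) {
  out <- integer(0)
  walk <- function(v) {
    for (ch in tr$children[[v]]) walk(ch)
    out[[length(out) + 1L]] <<- v
  }
  walk(tr$root)
  unlist(out)
}

#' Leaf labels subtended by a node
#' @param tr a `ptree`.
#' @param node internal or leaf node index.
#' @return character vector of leaf labels below (and including) `node`.
#' @export
clade_leaves <- function(tr, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (is_leaf(tr, v)) out <- c(out, tr$label[v]) else stack <- c(stack, tr$children[[v]])
  }
  out
}

#' @export
print.ptree <- function(x, ...) {
  cat("ptree: ", n_leaves(x), " leaves, ",
      sum(!is.na(x$parent)), " branches",
      if (any(!is.na(x$edge_num))) ", jplace-numbered" else "",
      "\n", sep = "")
  invisible(x)
}

#' Convert a `ptree` to an ape `phylo`
#'
#' @param x a `ptree`.
#' @param ... unused.
#' @return an object of class `phylo` (rooted, with edge lengths).
#' @export
as.phylo.ptree <- function(x, ...) {
  lv <- leaf_nodes(x)
  ints <- which(vapply(x$children, length, 1L) > 0L)
  ntip <- length(lv)
  idx <- integer(length(x$parent))
  idx[lv] <- seq_len(ntip)
  # root must map to ntip + 1
  ints <- c(x$root, setdiff(ints, x$root))
  idx[ints] <- ntip + seq_along(ints)
  child <- which(!is.na(x$parent))
  edge <- cbind(idx[x$parent[child]], idx[child])
  ph <- list(edge = edge, tip.label = x$label[lv],
             edge.length = x$brlen[child],
             Nnode = length(ints))
  class(ph) <- "phylo"
  ph <- ape::reorder.phylo(ph, "cladewise")
  ph
}

#' Convert an ape `phylo` to a `ptree`
#'
#' The tree must be rooted with edge lengths. Children order follows the
#' order of rows in the `phylo` edge matrix.
#'
#' @param phy an ape `phylo` object.
#' @return a `ptree`.
#' @export
as_ptree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop_bp("phylo object has no edge lengths")
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n)
  brlen <- rep(NA_real_, n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  brlen[phy$edge[, 2]] <- phy$edge.length
  label <- rep(NA_character_, n)
  label[seq_len(ntip)] <- phy$tip.label
  ptree(parent, brlen, label)
}

#' Pairwise path lengths between leaves
#'
#' Patristic distance matrix with rows/columns named by leaf label.
#'
#' @param tr a `ptree`.
#' @return numeric matrix.
#' @export
leaf_path_lengths <- function(tr) {
  ph <- as.phylo.ptree(tr)
  d <- ape::cophenetic.phylo(ph)
  d[sort(rownames(d)), sort(colnames(d)), drop = FALSE]
}

# depth (distance from root) of every node
#' @keywords internal
node_depths <- function(tr) {
  depth <- numeric(length(tr$parent))
  stack <- tr$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    p <- tr$parent[v]
    depth[v] <- if (is.na(p)) 0 else depth[p] + tr$brlen[v]
    stack <- c(stack, tr$children[[v]])
  }
  depth
}

#' Tree height
#'
#' Maximum root-to-leaf path length.
#' @param tr a `ptree`.
#' @export
tree_height <- function(tr) max(node_depths(tr)[leaf_nodes(tr)])
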