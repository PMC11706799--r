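# Tree operations: edge numbering, pruning, clade queries, grafting.

#' Assign jplace edge numbers
#'
#' Numbers every branch (identified with its child node) by a depth-first
#' postorder traversal with children visited in stored order, starting at 0.
#' The numbering is deterministic: identical trees always receive identical
#' numbers, and renumbering is idempotent. The jplace standard leaves the
#' numbering tool-defined; this is the convention fixed here.
#'
#' @param tr a [ptree()].
#' @return the tree with `edge_num` filled in.
#' @examples
#' tr <- number_edges(parse_newick("((A,B),C);"))
#' @export
number_edges <- function(tr) {
  nxt <- 0L
  en <- rep(NA_integer_, length(tr$parent))
  walk <- function(v) {
    for (ch in tr$children[[v]]) walk(ch)
    if (v != tr$root) {
      en[v] <<- nxt
      nxt <<- nxt + 1L
    }
  }
  walk(tr$root)
  tr$edge_num <- en
  tr
}

#' @keywords internal
node_of_edge <- function(tr, edge_number) {
  v <- which(!is.na(tr$edge_num) & tr$edge_num == edge_number)
  if (length(v) != 1L) stop_bp("unknown edge number: ", edge_number)
  v
}

#' Drop leaves from a tree
#'
#' Removes the given leaves and suppresses the resulting unifurcations by
#' summing the two incident branch lengths, so path lengths between all
#' retained leaf pairs are unchanged. A root left with a single child is
#' collapsed onto that child. Edge numbers are invalidated (renumber with
#' [number_edges()]).
#'
#' @param tr a [ptree()].
#' @param drop character vector of leaf labels to remove.
#' @return the pruned `ptree`.
#' @examples
#' write_newick(prune_taxa(parse_newick("((A:1,B:1):1,C:2);"), "B"))
#' @export
prune_taxa <- function(tr, drop) {
  drop <- unique(as.character(drop))
  if (length(drop) == 0L) return(tr)
  dn <- node_of_label(tr, drop)
  if (any(!vapply(dn, function(v) is_leaf(tr, v), TRUE))) {
    stop_bp("can only drop leaf labels")
  }
  if (n_leaves(tr) - length(dn) < 2L) stop_bp("pruning would leave fewer than 2 leaves")

  parent <- tr$parent; brlen <- tr$brlen; label <- tr$label
  children <- tr$children
  alive <- rep(TRUE, length(parent))
  orig_leaf <- vapply(children, length, 1L) == 0L

  detach_node <- function(v) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <<- setdiff(children[[p]], v)
    alive[v] <<- FALSE
  }
  for (v in dn) detach_node(v)

  # suppress unifurcations / empty internals, bottom-up until stable
  repeat {
    deg <- vapply(children, length, 1L)
    empties <- which(alive & deg == 0L & !orig_leaf)
    if (length(empties)) {
      for (v in empties) detach_node(v)
      next
    }
    uni <- which(alive & deg == 1L)
    if (!length(uni)) break
    v <- uni[1]
    ch <- children[[v]]
    if (is.na(parent[v])) {              # root with one child: child becomes root
      parent[ch] <- NA_integer_
      brlen[ch] <- NA_real_
      alive[v] <- FALSE
      children[[v]] <- integer(0)
    } else {
      p <- children[[parent[v]]]
      p[p == v] <- ch                    # splice, preserving sibling position
      children[[parent[v]]] <- p
      parent[ch] <- parent[v]
      brlen[ch] <- brlen[ch] + brlen[v]
      alive[v] <- FALSE
      children[[v]] <- integer(0)
    }
  }

  keep <- which(alive)
  idx <- integer(length(parent)); idx[keep] <- seq_along(keep)
  ptree(parent = ifelse(is.na(parent[keep]), NA_integer_, idx[parent[keep]]),
        brlen = brlen[keep], label = label[keep])
}

#' Most recent common ancestor
#'
#' Returns the least inclusive node whose subtended leaf set contains all of
#' `taxa`. A single taxon returns the leaf itself.
#'
#' @param tr a [ptree()].
#' @param taxa non-empty character vector of leaf labels.
#' @return a node index into `tr`.
#' @export
mrca_node <- function(tr, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop_bp("taxa must be non-empty")
  nodes <- node_of_label(tr, taxa)
  v <- nodes[1]
  while (!all(taxa %in% clade_leaves(tr, v))) {
    v <- tr$parent[v]
    if (is.na(v)) stop_bp("internal error: walked past root")  # nocov
  }
  v
}

#' Sister group of a leaf
#'
#' Leaf set of the sibling subtree of `leaf`. Requires the leaf's parent to
#' be binary.
#'
#' @param tr a [ptree()].
#' @param leaf a leaf label.
#' @return character vector of leaf labels.
#' @examples
#' sister_group(parse_newick("((A,B),(C,(D,E)));"), "C")
#' @export
sister_group <- function(tr, leaf) {
  v <- node_of_label(tr, leaf)
  if (!is_leaf(tr, v)) stop_bp("'", leaf, "' is not a leaf")
  p <- tr$parent[v]
  if (is.na(p)) stop_bp("tree has a single leaf; no sister group")
  sibs <- setdiff(tr$children[[p]], v)
  if (length(sibs) != 1L) stop_bp("tree is not binary at the parent of '", leaf, "'")
  clade_leaves(tr, sibs)
}

# Graft a pendant leaf onto the path above `child`, at distance `distal`
# measured upward from `child`. Walks across nodes inserted by earlier
# grafts, so `distal` can keep referring to the original (pre-graft) edge.
#' @keywords internal
graft_above_child <- function(tr, child, distal, pendant, label, eps = 1e-12) {
  if (distal < 0 || pendant < 0) stop_bp("distal and pendant must be non-negative")
  cur <- child
  acc <- 0
  repeat {
    p <- tr$parent[cur]
    if (is.na(p)) stop_bp("distal length ", distal, " exceeds the host branch")
    top <- acc + tr$brlen[cur]
    if (distal <= top + eps) break
    acc <- top
    cur <- p
  }
  if (distal > acc + tr$brlen[cur] + eps) {
    stop_bp("distal length out of range")  # nocov
  }
  n <- length(tr$parent)
  vnew <- n + 1L; qnew <- n + 2L
  tr$parent <- c(tr$parent, tr$parent[cur], vnew)
  tr$brlen <- c(tr$brlen, max(tr$brlen[cur] - (distal - acc), 0), pendant)
  tr$label <- c(tr$label, NA_character_, label)
  tr$edge_num <- c(tr$edge_num, NA_integer_, NA_integer_)
  tr$children <- c(tr$children, list(c(cur, qnew), integer(0)))
  kids <- tr$children[[tr$parent[cur]]]
  kids[kids == cur] <- vnew
  tr$children[[tr$parent[cur]]] <- kids
  tr$parent[cur] <- vnew
  tr$brlen[cur] <- distal - acc
  tr
}

# attach a pendant leaf above the current root: a new root is created
# whose children are the old root (with branch length `stem`) and the new
# leaf (with branch length `pendant`)
#' @keywords internal
graft_at_root <- function(tr, query, stem, pendant) {
  n <- length(tr$parent)
  rnew <- n + 1L; qnew <- n + 2L
  old_root <- tr$root
  tr$parent <- c(tr$parent, NA_integer_, rnew)
  tr$parent[old_root] <- rnew
  tr$brlen <- c(tr$brlen, NA_real_, pendant)
  tr$brlen[old_root] <- stem
  tr$label <- c(tr$label, NA_character_, query)
  tr$edge_num <- c(tr$edge_num, NA_integer_, NA_integer_)
  tr$children <- c(tr$children, list(c(old_root, qnew), integer(0)))
  tr$root <- rnew
  tr
}

#' Graft a query leaf onto a numbered edge
#'
#' Splits the host branch identified by `edge_number` at distance `distal`
#' from its child (distal) end, and attaches `query` there with a pendant
#' branch of length `pendant`. Pre-existing leaf-to-leaf path lengths are
#' unchanged. Edge numbers are invalidated on the returned tree.
#'
#' @param tr a numbered [ptree()] (see [number_edges()]).
#' @param query new leaf label (must not already be present).
#' @param edge_number jplace edge number of the host branch.
#' @param distal attachment distance from the child end, in
#'   `[0, host branch length]`.
#' @param pendant branch length of the new leaf, `>= 0`.
#' @return the extended `ptree`.
#' @export
graft_query <- function(tr, query, edge_number, distal, pendant) {
  if (query %in% tree_leaves(tr)) stop_bp("query '", query, "' is already a leaf")
  v <- node_of_edge(tr, edge_number)
  if (distal > tr$brlen[v] + 1e-12) stop_bp("distal length out of range")
  tr <- graft_above_child(tr, v, distal, pendant, query)
  tr$edge_num[] <- NA_integer_
  tr
}
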