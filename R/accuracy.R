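# Placement accuracy: build the placement tree, judge each query by the
# sister-clade comparison against the reference tree, and aggregate the
# percentage-of-correct-placements metrics.

#' Build the placement tree
#'
#' Grafts every query's best placement onto the backbone, producing a tree
#' with the same species composition as the reference tree. Queries
#' assigned to one backbone edge are grafted in descending distal order,
#' ties broken lexicographically by query name, so the result is
#' order-independent and deterministic.
#'
#' @param backbone numbered backbone [ptree()].
#' @param placements list of placement results ([epa_place()] /
#'   [apples_place()] / entries of [place_batch()]`$results`).
#' @return the placement [ptree()] (edge numbers invalidated).
#' @export
build_placement_tree <- function(backbone, placements) {
  if (length(placements) == 0L) stop_bp("no placements to graft")
  qnames <- vapply(placements, function(p) p$query, character(1))
  if (anyDuplicated(qnames)) {
    stop_bp("duplicate query names: ", qnames[duplicated(qnames)][1])
  }
  best <- do.call(rbind, lapply(placements, function(p) {
    data.frame(query = p$query, edge_num = p$best$edge_num,
               distal = p$best$distal_length, pendant = p$best$pendant_length)
  }))
  # resolve edge numbers to child nodes before any graft changes indices
  best$child <- vapply(best$edge_num, function(e) node_of_edge(backbone, e), 1L)
  best <- best[order(best$edge_num, -best$distal, best$query), ]
  tr <- backbone
  for (i in seq_len(nrow(best))) {
    if (best$query[i] %in% tree_leaves(tr)) {
      stop_bp("query '", best$query[i], "' is already a leaf")
    }
    tr <- graft_above_child(tr, best$child[i], best$distal[i],
                            best$pendant[i], best$query[i])
  }
  tr$edge_num[] <- NA_integer_
  tr
}

#' Judge one placed query by the sister-clade rule
#'
#' Let S be the sister group of the query on the placement tree (other
#' grafted queries included). The reference clade C is the leaf set of the
#' MRCA, on the reference tree, of S (`sister_mrca` mode, default) or of S
#' plus the query itself (`sister_plus_query_mrca`, stricter). The
#' difference list D = (C \ S) \ {query}: the placement is correct iff no
#' member of D sits on the backbone, i.e. every difference species is
#' itself a missing species.
#'
#' @param query query species name (a leaf of both trees).
#' @param placement_tree the grafted [ptree()] from
#'   [build_placement_tree()].
#' @param reference_tree the full reference [ptree()].
#' @param backbone_taxa character vector of species retained on the
#'   backbone.
#' @param mode `"sister_mrca"` or `"sister_plus_query_mrca"`.
#' @param lwr the best candidate's likelihood weight ratio (`NA` for the
#'   distance engine), carried into the record.
#' @return a one-row data frame: `query`, `verdict` (`correct` /
#'   `incorrect`), `lwr`, `sister_group`, `difference` (both
#'   comma-collapsed).
#' @export
assess_placement <- function(query, placement_tree, reference_tree,
                             backbone_taxa,
                             mode = c("sister_mrca", "sister_plus_query_mrca"),
                             lwr = NA_real_) {
  mode <- match.arg(mode)
  if (!query %in% tree_leaves(placement_tree)) {
    stop_bp("query '", query, "' not on the placement tree")
  }
  if (!query %in% tree_leaves(reference_tree)) {
    stop_bp("query '", query, "' not on the reference tree")
  }
  S <- sister_group(placement_tree, query)
  anchor <- if (mode == "sister_mrca") S else union(S, query)
  anchor_known <- intersect(anchor, tree_leaves(reference_tree))
  if (!length(anchor_known)) stop_bp("sister group shares no species with the reference tree")
  C <- clade_leaves(reference_tree, mrca_node(reference_tree, anchor_known))
  D <- setdiff(setdiff(C, S), query)
  verdict <- if (length(intersect(D, backbone_taxa)) == 0L) "correct" else "incorrect"
  data.frame(query = query, verdict = verdict, lwr = lwr,
             sister_group = paste(sort(S), collapse = ","),
             difference = paste(sort(D), collapse = ","))
}

#' Score a whole set of placements
#'
#' Builds the placement tree and judges every placed query, carrying the
#' per-query best-candidate LWR (when the engine provides one).
#'
#' @param placements list of placement results.
#' @param backbone numbered backbone [ptree()].
#' @param reference_tree full reference [ptree()].
#' @param mode assessment mode, see [assess_placement()].
#' @return data frame of per-query records ([assess_placement()] rows).
#' @export
score_placements <- function(placements, backbone, reference_tree,
                             mode = "sister_mrca") {
  pt <- build_placement_tree(backbone, placements)
  backbone_taxa <- tree_leaves(backbone)
  do.call(rbind, lapply(placements, function(p) {
    assess_placement(p$query, pt, reference_tree, backbone_taxa,
                     mode = mode, lwr = p$best$lwr)
  }))
}

#' Aggregate accuracy records
#'
#' PCP is the percentage of placed queries judged correct; CP the
#' percentage of placed queries whose LWR strictly exceeds the confidence
#' threshold; PCP-CP the percentage correct within that confident subset.
#' CP and PCP-CP are `NA` when the engine emits no LWR, and PCP-CP is `NA`
#' (undefined, not zero) when no placement is confident.
#'
#' @param records data frame from [score_placements()] (or rbind of
#'   [assess_placement()] rows).
#' @param lwr_threshold confidence threshold (default 0.9, strict `>`).
#' @return one-row data frame: `n_placed`, `n_correct`, `n_confident`,
#'   `n_confident_correct`, `pcp`, `cp`, `pcp_cp` (percentages).
#' @export
summarize_accuracy <- function(records, lwr_threshold = 0.9) {
  if (is.null(records) || nrow(records) == 0L) stop_bp("no placement records")
  placed <- records[records$verdict %in% c("correct", "incorrect"), , drop = FALSE]
  if (nrow(placed) == 0L) stop_bp("no placed queries")
  n <- nrow(placed)
  n_correct <- sum(placed$verdict == "correct")
  has_lwr <- any(!is.na(placed$lwr))
  conf <- has_lwr & !is.na(placed$lwr) & placed$lwr > lwr_threshold
  n_conf <- if (has_lwr) sum(conf) else NA_integer_
  n_conf_corr <- if (has_lwr) sum(conf & placed$verdict == "correct") else NA_integer_
  data.frame(
    n_placed = n, n_correct = n_correct,
    n_confident = n_conf, n_confident_correct = n_conf_corr,
    pcp = 100 * n_correct / n,
    cp = if (has_lwr) 100 * n_conf / n else NA_real_,
    pcp_cp = if (has_lwr && n_conf > 0) 100 * n_conf_corr / n_conf else NA_real_)
}

#' True attachment positions of missing species
#'
#' For each query, the reference tree is pruned down to the backbone
#' leaves plus that query; the query's attachment (host backbone edge,
#' distal from the child end, pendant) is read off. Grafting every query
#' at its true position reconstructs a tree on which the sister-clade rule
#' judges every query correct.
#'
#' A query whose lineage attaches above the backbone's root (all backbone
#' species on one side of the reference root) has no host edge; it is
#' assigned to the root's first child edge at its parent end.
#'
#' @param reference_tree full reference [ptree()].
#' @param backbone numbered backbone [ptree()] (pruned reference).
#' @param queries missing species names (default: reference leaves not on
#'   the backbone).
#' @return data frame `query`, `edge_num`, `distal`, `pendant`.
#' @export
true_placements <- function(reference_tree, backbone,
                            queries = setdiff(tree_leaves(reference_tree),
                                              tree_leaves(backbone))) {
  backbone_taxa <- tree_leaves(backbone)
  # leaf sets per backbone edge, keyed for lookup
  edges <- which(!is.na(backbone$edge_num))
  clade_key <- vapply(edges, function(v) {
    paste(sort(clade_leaves(backbone, v)), collapse = "\r")
  }, character(1))
  do.call(rbind, lapply(queries, function(q) {
    tq <- prune_taxa(reference_tree, setdiff(tree_leaves(reference_tree),
                                             c(backbone_taxa, q)))
    vq <- node_of_label(tq, q)
    par <- tq$parent[vq]
    sib <- setdiff(tq$children[[par]], vq)
    if (is.na(tq$parent[par])) {
      # attaches above the backbone root: no host edge exists
      child <- backbone$children[[backbone$root]][1]
      return(data.frame(query = q, edge_num = backbone$edge_num[child],
                        distal = backbone$brlen[child], pendant = tq$brlen[vq]))
    }
    key <- paste(sort(clade_leaves(tq, sib)), collapse = "\r")
    child <- edges[match(key, clade_key)]
    if (is.na(child)) stop_bp("no backbone edge matches the attachment of '", q, "'")  # nocov
    data.frame(query = q, edge_num = backbone$edge_num[child],
               distal = tq$brlen[sib], pendant = tq$brlen[vq])
  }))
}

#' Restore all missing species at their true positions
#'
#' Sequential inverse pruning: each missing species is attached at its
#' position in the reference tree restricted to the species restored so
#' far, including above the current root when an entire root-adjacent
#' clade is missing. The result is topologically identical to the
#' reference tree (with identical path lengths), which makes it the
#' ground-truth placement tree for identity checks: every species scores
#' correct under the sister-clade rule on it.
#'
#' @param reference_tree full reference [ptree()].
#' @param backbone backbone [ptree()] (pruned reference).
#' @return the restored [ptree()].
#' @export
restore_missing <- function(reference_tree, backbone) {
  queries <- sort(setdiff(tree_leaves(reference_tree), tree_leaves(backbone)))
  tr <- backbone
  for (q in queries) {
    tq <- prune_taxa(reference_tree,
                     setdiff(tree_leaves(reference_tree),
                             c(tree_leaves(tr), q)))
    vq <- node_of_label(tq, q)
    par <- tq$parent[vq]
    sib <- setdiff(tq$children[[par]], vq)
    if (is.na(tq$parent[par])) {
      tr <- graft_at_root(tr, q, stem = tq$brlen[sib], pendant = tq$brlen[vq])
    } else {
      A <- clade_leaves(tq, sib)
      v <- mrca_node(tr, A)
      if (!setequal(clade_leaves(tr, v), A)) {
        stop_bp("internal error: attachment clade of '", q, "' not found")  # nocov
      }
      tr <- graft_above_child(tr, v, tq$brlen[sib], tq$brlen[vq], q)
    }
  }
  tr
}

#' Graft queries at their true positions
#'
#' Convenience for identity checks: returns placement-result stubs (one
#' best candidate each) at the positions found by [true_placements()],
#' suitable for [build_placement_tree()] and [score_placements()].
#'
#' @inheritParams true_placements
#' @return list of minimal placement results.
#' @export
true_placement_results <- function(reference_tree, backbone,
                                   queries = setdiff(tree_leaves(reference_tree),
                                                     tree_leaves(backbone))) {
  tp <- true_placements(reference_tree, backbone, queries)
  lapply(seq_len(nrow(tp)), function(i) {
    cand <- data.frame(edge_num = tp$edge_num[i], score = 0, lwr = 1,
                       distal_length = tp$distal[i], pendant_length = tp$pendant[i])
    list(query = tp$query[i], engine = "likelihood", candidates = cand,
         best = cand[1, ])
  })
}
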