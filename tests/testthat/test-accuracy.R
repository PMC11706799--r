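# Sister-clade correctness metric: hand-traced verdicts, the identity
# property, mode leniency, and the PCP/CP aggregation.

stub_placement <- function(query, edge_num, distal, pendant, lwr = 1) {
  cand <- data.frame(edge_num = edge_num, score = 0, lwr = lwr,
                     distal_length = distal, pendant_length = pendant)
  list(query = query, engine = "likelihood", candidates = cand, best = cand[1, ])
}

graft_sister_to <- function(backbone, query, target_leafset) {
  v <- mrca_node(backbone, target_leafset)
  stopifnot(setequal(clade_leaves(backbone, v), target_leafset))
  stub_placement(query, backbone$edge_num[v], backbone$brlen[v] / 2, 0.1)
}

test_that("a query restored next to its true sister is judged correct", {
  ref <- parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  backbone <- number_edges(prune_taxa(ref, "D"))
  pl <- list(graft_sister_to(backbone, "D", "E"))
  for (mode in c("sister_mrca", "sister_plus_query_mrca")) {
    rec <- score_placements(pl, backbone, ref, mode = mode)
    expect_identical(rec$verdict, "correct")
    expect_identical(rec$difference, "")
  }
})

test_that("a chained misplacement drags backbone species into the difference list", {
  ref <- parse_newick("(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  backbone <- number_edges(prune_taxa(ref, c("A", "D")))
  # A grafted sister to E, then D sister to the {(A,E),F} subtree
  plA <- graft_sister_to(backbone, "A", "E")
  pt1 <- build_placement_tree(backbone, list(plA))
  pt1 <- number_edges(pt1)
  vAEF <- mrca_node(pt1, c("A", "E", "F"))
  stopifnot(setequal(clade_leaves(pt1, vAEF), c("A", "E", "F")))
  # express D's graft on the original backbone edge above {E,F}'s ancestor:
  # build both by hand to control the topology exactly
  g <- graft_above_child(pt1, vAEF, pt1$brlen[vAEF], 0.1, "D")
  for (mode in c("sister_mrca", "sister_plus_query_mrca")) {
    rec <- assess_placement("D", g, ref, tree_leaves(backbone), mode = mode)
    expect_setequal(strsplit(rec$sister_group, ",")[[1]], c("A", "E", "F"))
    expect_identical(rec$verdict, "incorrect")
    expect_setequal(strsplit(rec$difference, ",")[[1]], c("B", "C"))
  }
})

test_that("the two assessment modes diverge on exact-clade sisters", {
  ref <- parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  backbone <- number_edges(prune_taxa(ref, "D"))
  pl <- list(graft_sister_to(backbone, "D", "C"))
  lenient <- score_placements(pl, backbone, ref, mode = "sister_mrca")
  expect_identical(lenient$verdict, "correct")
  strict <- score_placements(pl, backbone, ref, mode = "sister_plus_query_mrca")
  expect_identical(strict$verdict, "incorrect")
  expect_identical(strict$difference, "E")
})

test_that("grafting every missing species at its true position scores PCP 100", {
  set.seed(515)
  for (i in 1:20) {
    n <- sample(8:32, 1)
    ref <- random_ptree(n)
    n_missing <- sample(1:max(1, n %/% 3), 1)
    missing <- sample(tree_leaves(ref), n_missing)
    backbone <- number_edges(prune_taxa(ref, missing))
    restored <- restore_missing(ref, backbone)
    d0 <- leaf_path_lengths(ref)
    expect_equal(leaf_path_lengths(restored), d0, tolerance = 1e-10)
    for (mode in c("sister_mrca", "sister_plus_query_mrca")) {
      rec <- do.call(rbind, lapply(missing, function(q) {
        assess_placement(q, restored, ref, tree_leaves(backbone), mode = mode)
      }))
      expect_equal(summarize_accuracy(rec)$pcp, 100)
    }
  }
})

test_that("strict-mode correctness implies lenient-mode correctness", {
  set.seed(616)
  ref <- random_ptree(8)
  missing <- sample(tree_leaves(ref), 1)
  backbone <- number_edges(prune_taxa(ref, missing))
  edges <- backbone$edge_num[!is.na(backbone$edge_num)]
  for (e in edges) {
    v <- which(!is.na(backbone$edge_num) & backbone$edge_num == e)
    pl <- list(stub_placement(missing, e, backbone$brlen[v] / 2, 0.05))
    strict <- score_placements(pl, backbone, ref, mode = "sister_plus_query_mrca")
    lenient <- score_placements(pl, backbone, ref, mode = "sister_mrca")
    if (strict$verdict == "correct") {
      expect_identical(lenient$verdict, "correct")
    }
  }
})

test_that("verdicts ignore other queries placed on disjoint edges", {
  ref <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  backbone <- number_edges(prune_taxa(ref, c("B", "G")))
  plB <- graft_sister_to(backbone, "B", "A")
  plG <- graft_sister_to(backbone, "G", "H")
  both <- score_placements(list(plB, plG), backbone, ref,
                           mode = "sister_plus_query_mrca")
  alone <- score_placements(list(plB), backbone, ref,
                            mode = "sister_plus_query_mrca")
  expect_identical(both[both$query == "B", ]$verdict, alone$verdict)
  expect_identical(both[both$query == "B", ]$difference, alone$difference)
})

test_that("placement-tree construction is order-invariant and bookkept", {
  ref <- random_ptree(12, seed = 81)
  missing <- sort(tree_leaves(ref))[c(2, 5, 9)]
  backbone <- number_edges(prune_taxa(ref, missing))
  pl <- true_placement_results(ref, backbone)
  t1 <- build_placement_tree(backbone, pl)
  t2 <- build_placement_tree(backbone, rev(pl))
  expect_equal(n_leaves(t1), n_leaves(backbone) + 3L)
  expect_true(ape::all.equal.phylo(as.phylo.ptree(t1), as.phylo.ptree(t2)))
  expect_error(build_placement_tree(backbone, c(pl, pl[1])), "duplicate")
  # restoring everything at truth reproduces the reference topology
  expect_true(ape::all.equal.phylo(as.phylo.ptree(t1), as.phylo.ptree(ref),
                                   use.edge.length = FALSE))
})

test_that("summaries follow the strict confidence threshold", {
  rec <- function(verdict, lwr) data.frame(query = "q", verdict = verdict,
                                           lwr = lwr, sister_group = "",
                                           difference = "")
  recs <- do.call(rbind, c(
    lapply(1:7, function(i) rec("correct", 0.95)),
    lapply(1:3, function(i) rec("incorrect", 0.5))))
  s <- summarize_accuracy(recs)
  expect_equal(s$pcp, 70)
  expect_equal(s$cp, 70)
  expect_equal(s$pcp_cp, 100)
  # lwr exactly at the threshold is NOT confident
  s2 <- summarize_accuracy(rbind(recs, rec("correct", 0.9)))
  expect_equal(s2$n_confident, 7L)
  # all correct and confident
  s3 <- summarize_accuracy(do.call(rbind, lapply(1:5, function(i) rec("correct", 0.99))))
  expect_equal(c(s3$pcp, s3$cp, s3$pcp_cp), c(100, 100, 100))
  # no LWR at all (distance engine): confidence columns undefined
  s4 <- summarize_accuracy(rbind(rec("correct", NA), rec("incorrect", NA)))
  expect_true(is.na(s4$cp) && is.na(s4$pcp_cp))
  expect_equal(s4$pcp, 50)
  # zero confident placements: PCP-CP undefined, not 0
  s5 <- summarize_accuracy(rbind(rec("correct", 0.2), rec("correct", 0.3)))
  expect_true(is.na(s5$pcp_cp))
  expect_error(summarize_accuracy(recs[0, ]), "no placement")
})
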