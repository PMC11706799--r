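# Tree data model, Newick/jplace round trips, pruning and grafting.

test_that("parse_newick builds the stated structure and counts branches", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_setequal(tree_leaves(tr), c("A", "B", "C"))
  expect_length(tr$children[[tr$root]], 2L)
  expect_equal(sum(!is.na(tr$parent)), 4L)  # 2n - 2 for n = 3
  # no branch lengths at all is fine; they default to 0
  tr0 <- parse_newick("((A,B),C);")
  expect_true(all(tr0$brlen[-tr0$root] == 0))
})

test_that("parse_newick rejects malformed input, naming the offender", {
  expect_error(parse_newick("((A:1,B:1):1,C:2)"), "';'")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "unbalanced|unexpected|trailing")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate.*A")
  expect_error(parse_newick("((A:-1,B:1):1,C:2);"), "negative.*-1")
  expect_error(parse_newick("((A:1,B):1,C:2);"), "all branches or none")
  expect_error(parse_newick("((A's:1,B:1):1,C:2);"), "label")
})

test_that("write_newick round-trips topology, labels and lengths", {
  txt <- "((A:0.5,B:0.5):1,C:2);"
  expect_identical(write_newick(parse_newick(txt)), txt)
  expect_identical(write_newick(parse_newick("(A:0.5,B:0.5);")), "(A:0.5,B:0.5);")
  # 50-leaf random tree: write-parse-write is a fixed point
  tr <- random_ptree(50, seed = 31)
  s1 <- write_newick(tr)
  expect_identical(write_newick(parse_newick(s1)), s1)
  # parse-write-parse preserves the path-length matrix
  expect_equal(leaf_path_lengths(parse_newick(s1)), leaf_path_lengths(tr),
               tolerance = 1e-12)
})

test_that("edge numbering is postorder from 0, dense, idempotent", {
  tr <- number_edges(parse_newick("((A,B),C);"))
  en <- function(lab) tr$edge_num[match(lab, tr$label)]
  expect_equal(en("A"), 0L)
  expect_equal(en("B"), 1L)
  expect_equal(en("C"), 3L)
  ab <- tr$parent[match("A", tr$label)]
  expect_equal(tr$edge_num[ab], 2L)
  expect_identical(number_edges(tr)$edge_num, tr$edge_num)
  for (n in c(5, 17, 40)) {
    tr <- number_edges(random_ptree(n))
    expect_equal(max(tr$edge_num, na.rm = TRUE), 2L * n - 3L)
    expect_setequal(tr$edge_num[-tr$root], 0:(2L * n - 3L))
  }
  # numbered newick carries one {N} token per branch
  s <- write_newick(number_edges(random_ptree(12)), with_edge_numbers = TRUE)
  expect_equal(lengths(regmatches(s, gregexpr("\\{", s))), 2L * 12 - 2L)
  expect_error(write_newick(random_ptree(5), with_edge_numbers = TRUE), "unnumbered")
})

test_that("prune_taxa removes leaves and merges branch lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(write_newick(prune_taxa(tr, "C")), "(A:1,B:1);")
  expect_identical(write_newick(prune_taxa(tr, "B")), "(A:2,C:2);")
  expect_identical(write_newick(prune_taxa(tr, character(0))), write_newick(tr))
  expect_error(prune_taxa(tr, c("A", "B")), "fewer than 2")
  expect_error(prune_taxa(tr, "Z"), "unknown leaf")
})

test_that("pruning preserves retained-pair path lengths (vs ape oracle)", {
  set.seed(71)
  for (i in 1:8) {
    n <- sample(8:40, 1)
    ph <- ape::rtree(n)
    tr <- as_ptree(ph)
    drop <- sample(ph$tip.label, sample(1:(n - 3), 1))
    pruned <- prune_taxa(tr, drop)
    keep <- setdiff(ph$tip.label, drop)
    expect_equal(leaf_path_lengths(pruned),
                 leaf_path_lengths(tr)[sort(keep), sort(keep)],
                 tolerance = 1e-10)
    # independent oracle: ape's own drop.tip
    oracle <- ape::drop.tip(ph, drop)
    expect_equal(leaf_path_lengths(pruned),
                 leaf_path_lengths(as_ptree(oracle)), tolerance = 1e-10)
  }
})

test_that("mrca_node returns the least inclusive covering clade", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  expect_setequal(clade_leaves(tr, mrca_node(tr, c("D", "E"))), c("D", "E"))
  expect_setequal(clade_leaves(tr, mrca_node(tr, c("C", "E"))), c("C", "D", "E"))
  expect_identical(clade_leaves(tr, mrca_node(tr, "A")), "A")
  expect_error(mrca_node(tr, "Z"), "unknown leaf")
})

test_that("sister_group returns the sibling subtree's leaves", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  expect_setequal(sister_group(tr, "D"), "E")
  expect_setequal(sister_group(tr, "C"), c("D", "E"))
  expect_setequal(sister_group(tr, "A"), "B")
  expect_setequal(sister_group(parse_newick("(A:1,B:1);"), "A"), "B")
  expect_error(sister_group(tr, "Z"), "unknown leaf")
})

test_that("graft_query splits the host edge and preserves other paths", {
  tr <- number_edges(parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);"))
  # terminal edge of E
  eE <- tr$edge_num[match("E", tr$label)]
  g <- graft_query(tr, "Q", eE, 0.4, 0.2)
  expect_setequal(sister_group(g, "Q"), "E")
  # branch subtending clade {C,(D,E)}
  vCDE <- mrca_node(tr, c("C", "D", "E"))
  g2 <- graft_query(tr, "Q", tr$edge_num[vCDE], 0.5, 0.1)
  expect_setequal(sister_group(g2, "Q"), c("C", "D", "E"))
  d0 <- leaf_path_lengths(tr)
  d2 <- leaf_path_lengths(g2)
  expect_equal(d2[rownames(d0), colnames(d0)], d0, tolerance = 1e-12)
  expect_error(graft_query(tr, "A", eE, 0.1, 0.1), "already a leaf")
  expect_error(graft_query(tr, "Q", 999L, 0.1, 0.1), "unknown edge")
  expect_error(graft_query(tr, "Q", eE, 5, 0.1), "out of range")
})

test_that("prune then graft at the recorded position restores the tree", {
  set.seed(99)
  for (i in 1:6) {
    tr <- number_edges(random_ptree(sample(8:30, 1)))
    leaf <- sample(tree_leaves(tr), 1)
    backbone <- number_edges(prune_taxa(tr, leaf))
    tp <- true_placements(tr, backbone, leaf)
    g <- graft_query(backbone, leaf, tp$edge_num, tp$distal, tp$pendant)
    d0 <- leaf_path_lengths(tr)
    expect_equal(leaf_path_lengths(g), d0[rownames(d0), colnames(d0)],
                 tolerance = 1e-10)
  }
})

test_that("jplace documents round-trip bit-for-bit", {
  tr <- number_edges(parse_newick("((A:0.123456789012345,B:1):0.5,C:2);"))
  cand <- data.frame(edge_num = c(0L, 2L), score = c(-12.3456789012345, -15.1),
                     lwr = c(0.9437832918273645, 0.0562167081726355),
                     distal_length = c(0.0617283945, 0.25),
                     pendant_length = c(0.01, 0.2))
  pl <- list(list(query = "Q1", engine = "likelihood", candidates = cand,
                  best = cand[1, ]))
  path <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(tr, pl, path)
  rb <- read_jplace(path)
  expect_equal(rb$placements$Q1$edge_num, cand$edge_num)
  expect_identical(rb$placements$Q1$lwr, cand$lwr)
  expect_identical(rb$placements$Q1$score, cand$score)
  expect_identical(rb$placements$Q1$distal_length, cand$distal_length)
  expect_equal(sum(rb$placements$Q1$lwr), 1, tolerance = 1e-9)
  expect_identical(write_newick(rb$tree, with_edge_numbers = TRUE),
                   write_newick(tr, with_edge_numbers = TRUE))
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$version, 3)
  expect_identical(doc$fields,
                   c("edge_num", "likelihood", "like_weight_ratio",
                     "distal_length", "pendant_length"))
  # single query, single candidate, lwr 1
  c1 <- data.frame(edge_num = 1L, score = -1, lwr = 1,
                   distal_length = 0.1, pendant_length = 0.1)
  txt <- write_jplace(tr, list(list(query = "Q", engine = "likelihood",
                                    candidates = c1, best = c1)))
  expect_equal(read_jplace(txt)$placements$Q$lwr, 1)
  # unknown edge rejected on write and on read
  c999 <- transform(c1, edge_num = 999L)
  expect_error(write_jplace(tr, list(list(query = "Q", engine = "likelihood",
                                          candidates = c999, best = c999))),
               "edge")
  doc2 <- jsonlite::fromJSON(as.character(txt), simplifyVector = FALSE)
  doc2$placements[[1]]$p[[1]][[1]] <- 999L
  bad <- jsonlite::toJSON(doc2, auto_unbox = TRUE, digits = NA)
  expect_error(read_jplace(as.character(bad)), "999")
})
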