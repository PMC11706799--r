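# Placement engines: pruning likelihood vs exhaustive oracle, EPA-style
# scan with LWR, JC/ML distances and the APPLES-style least-squares fit.

test_that("two identical 1-site sequences at vanishing distance give log 1/4", {
  tr <- parse_newick("(A:0.000000001,B:0.000000001);")
  aln <- toy_aln(c(A = "A", B = "A"))
  expect_equal(tree_loglikelihood(tr, aln, jc_model(k = 1)), log(1 / 4),
               tolerance = 1e-6)
})

test_that("pruning likelihood matches exhaustive enumeration on 4-leaf trees", {
  set.seed(202)
  m <- gtr_model(c(1.5, 8, 1.2, 0.8, 14, 1), c(0.26, 0.27, 0.17, 0.30),
                 alpha = 0.45, k = 2)
  shapes <- c("((A:B1,B:B2):B3,(C:B4,D:B5):B6);",
              "(((A:B1,B:B2):B3,C:B4):B5,D:B6);")
  for (shape in shapes) {
    for (rep in 1:3) {
      bl <- round(runif(6, 0.05, 0.9), 3)
      txt <- shape
      for (i in 1:6) txt <- sub(paste0("B", i), format(bl[i]), txt, fixed = TRUE)
      tr <- parse_newick(txt)
      seqs <- stats::setNames(vapply(1:4, function(i) random_seq(3), ""),
                              c("A", "B", "C", "D"))
      st <- aln_states(toy_aln(seqs))
      expect_equal(tree_loglikelihood(tr, st, m), brute_loglik(tr, st, m),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to collapsing a zero-length branch", {
  m <- jc_model(alpha = 0.8)
  t1 <- parse_newick("(((A:0.2,B:0.3):0,C:0.4):0.1,D:0.5);")
  t2 <- parse_newick("((A:0.2,B:0.3,C:0.4):0.1,D:0.5);")
  st <- aln_states(toy_aln(c(A = "ACGTA", B = "ACGTC", C = "GCGTA", D = "TTGTA")))
  expect_equal(tree_loglikelihood(t1, st, m), tree_loglikelihood(t2, st, m),
               tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  tr <- random_ptree(12)
  seqs <- stats::setNames(vapply(1:12, function(i) random_seq(40), ""),
                          tree_leaves(tr))
  m <- gtr_model(c(1.5, 8, 1.2, 0.8, 14, 1), c(0.26, 0.27, 0.17, 0.30),
                 alpha = 0.45, k = 4)
  dat <- phangorn::phyDat(t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                                   character(40))), type = "DNA")
  fit <- phangorn::pml(as.phylo.ptree(tr), dat, bf = m$freqs, Q = m$rates,
                       shape = 0.45, k = 4)
  expect_equal(tree_loglikelihood(tr, aln_states(toy_aln(seqs)), m),
               fit$logLik, tolerance = 1e-6)
})

test_that("per-edge scan log-likelihoods match grafting plus full pruning", {
  b <- small_bundle()
  coi <- b$partitions[[1]]
  sp <- sort(tree_leaves(b$tree))
  q <- sp[7]
  backbone <- number_edges(prune_taxa(b$tree, q))
  qrow <- coi_query_rows(b$alignment, q)
  res <- epa_place(qrow, backbone, b$alignment, coi$model, rate = coi$rate)
  sites <- which(query_states(qrow) >= 0L)
  for (i in c(1, 5, 12)) {
    cand <- res$candidates[i, ]
    g <- graft_query(backbone, q, cand$edge_num, cand$distal_length,
                     cand$pendant_length)
    states <- aln_states(b$alignment, sites)
    ll <- tree_loglikelihood(g, states, coi$model, rate = coi$rate)
    expect_equal(cand$score, ll, tolerance = 1e-8)
  }
})

test_that("a query identical to a backbone leaf lands on that leaf's edge", {
  b <- small_bundle()
  coi <- b$partitions[[1]]
  backbone <- number_edges(prune_taxa(b$tree, sort(tree_leaves(b$tree))[1]))
  leaf <- sort(tree_leaves(backbone))[10]
  qrow <- coi_query_rows(b$alignment, leaf)
  names(qrow) <- "copycat"
  res <- epa_place(qrow, backbone, b$alignment, coi$model, rate = coi$rate)
  expect_equal(res$best$edge_num,
               backbone$edge_num[match(leaf, backbone$label)])
  expect_equal(sum(res$candidates$lwr), 1, tolerance = 1e-9)
})

test_that("mirror-symmetric backbones give symmetric LWR", {
  bb <- number_edges(parse_newick("((A:0.2,B:0.4):0.3,(C:0.2,D:0.4):0.3);"))
  seqs <- c(A = "ACGTACGTAA", B = "ACGTCCGTAT", C = "ACGTACGTAA",
            D = "ACGTCCGTAT", Q = "ACGTACGTAT")
  aln <- toy_aln(seqs[1:4])
  res <- epa_place(seqs["Q"], bb, aln, jc_model(alpha = 0.8), rate = 1)
  cand <- res$candidates
  lwr_of <- function(leaf) cand$lwr[cand$edge_num ==
                                      bb$edge_num[match(leaf, bb$label)]]
  expect_equal(lwr_of("A"), lwr_of("C"), tolerance = 1e-6)
  expect_equal(lwr_of("B"), lwr_of("D"), tolerance = 1e-6)
})

test_that("best-edge LWR concentrates as the query gains signal", {
  b <- small_bundle()
  coi <- b$partitions[[1]]
  sp <- sort(tree_leaves(b$tree))
  q <- sp[12]
  backbone <- number_edges(prune_taxa(b$tree, q))
  full <- coi_query_rows(b$alignment, q)
  r <- partition_range(b$alignment, "COI")
  lwrs <- vapply(c(60L, 150L, 300L), function(len) {
    chars <- strsplit(full, "")[[1]]
    keep <- seq.int(r[1], r[1] + len - 1L)
    chars[setdiff(seq_along(chars), keep)] <- "-"
    qrow <- stats::setNames(paste(chars, collapse = ""), names(full))
    epa_place(qrow, backbone, b$alignment, coi$model, rate = coi$rate)$best$lwr
  }, numeric(1))
  expect_true(all(diff(lwrs) >= -1e-9))
})

test_that("jc_distance follows the closed form and its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.3), -0.75 * log(0.6))
  expect_error(jc_distance(0.75), "0.75")
  expect_error(jc_distance(-0.1), "0.75|proportion")
})

test_that("two-leaf least squares solves the hand algebra", {
  bb <- number_edges(parse_newick("(A:0.5,B:0.5);"))
  geom <- apples_context(bb)
  sol <- apples_solve(geom, c(A = 0.6, B = 0.8), "ols")
  i <- which(geom$edge_num == geom$edge_num[order(sol$Q)][1])
  # attachment 0.4 from A along the A-B path, pendant (0.6+0.8-1)/2 = 0.2
  onA <- which(bb$label[geom$edges] == "A")
  expect_equal(sol$x[onA], 0.4, tolerance = 1e-9)
  expect_equal(sol$t[onA], 0.2, tolerance = 1e-9)
  expect_equal(sol$Q[onA], 0, tolerance = 1e-9)
})

test_that("fm and ols agree when all distances are equal", {
  bb <- number_edges(random_ptree(8, seed = 61))
  geom <- apples_context(bb)
  delta <- stats::setNames(rep(1.3, 8), tree_leaves(bb))
  fm <- apples_solve(geom, delta, "fm")
  ols <- apples_solve(geom, delta, "ols")
  expect_equal(fm$x, ols$x, tolerance = 1e-9)
  expect_equal(fm$t, ols$t, tolerance = 1e-9)
})

test_that("noise-free additive distances recover the true edge exactly", {
  set.seed(404)
  for (i in 1:8) {
    tr <- number_edges(random_ptree(30))
    E <- sum(!is.na(tr$edge_num))
    e <- sample(0:(E - 1), 1)
    v <- which(!is.na(tr$edge_num) & tr$edge_num == e)
    distal <- runif(1, 0.05, 0.95) * tr$brlen[v]
    g <- graft_query(tr, "QQ", e, distal, runif(1, 0.05, 0.5))
    d <- leaf_path_lengths(g)
    delta <- d["QQ", setdiff(colnames(d), "QQ")]
    sol <- apples_solve(apples_context(tr), delta, "fm")
    best <- order(sol$Q, apples_context(tr)$edge_num)[1]
    expect_equal(apples_context(tr)$edge_num[best], e)
    expect_lt(sol$Q[best], 1e-9)
  }
})

test_that("ml pairwise distances recover simulated divergences", {
  m <- gtr_model(c(1.5, 8, 1.2, 0.8, 14, 1), c(0.26, 0.27, 0.17, 0.30),
                 alpha = 0.45, k = 4)
  t_true <- c(0.1, 0.45, 1.1)
  for (tt in t_true) {
    tr <- ptree(parent = c(3L, 3L, NA), brlen = c(tt / 2, tt / 2, NA),
                label = c("A", "B", NA))
    aln <- evolve_alignment(tr, list(list(name = "COI", length = 4000L,
                                          rate = 1, model = m)), seed = 77)
    st <- aln_states(aln)
    d <- ml_pairwise_distances(st["A", , drop = FALSE], st["B", , drop = FALSE], m)
    expect_equal(drop(d), tt, tolerance = 0.12)
  }
})

test_that("unplaceable queries are skipped with a report entry", {
  b <- small_bundle()
  backbone <- number_edges(prune_taxa(b$tree, sort(tree_leaves(b$tree))[1:2]))
  w <- nchar(b$alignment$seqs[1])
  good <- coi_query_rows(b$alignment, sort(tree_leaves(b$tree))[1])
  blank <- stats::setNames(strrep("-", w), "void_query")
  expect_warning(
    batch <- place_batch(c(good, blank), backbone, b$alignment,
                         engine = "distance"),
    "skipped")
  expect_equal(batch$report$status[batch$report$query == "void_query"], "skipped")
  expect_equal(names(batch$results), names(good))
})

test_that("batch placement is order-independent and one jplace entry per query", {
  b <- small_bundle()
  coi <- b$partitions[[1]]
  sp <- sort(tree_leaves(b$tree))
  missing <- sp[c(3, 9, 15)]
  backbone <- number_edges(prune_taxa(b$tree, missing))
  queries <- coi_query_rows(b$alignment, missing)
  for (engine in c("likelihood", "distance")) {
    b1 <- place_batch(queries, backbone, b$alignment, engine,
                      model = coi$model, rate = coi$rate)
    b2 <- place_batch(rev(queries), backbone, b$alignment, engine,
                      model = coi$model, rate = coi$rate)
    for (q in names(queries)) {
      expect_identical(b1$results[[q]]$candidates, b2$results[[q]]$candidates)
    }
    doc <- jsonlite::fromJSON(as.character(b1$jplace), simplifyVector = FALSE)
    expect_equal(length(doc$placements), 3L)
  }
  expect_error(place_batch(character(0), backbone, b$alignment, "distance"),
               "empty")
  clash <- stats::setNames(queries[[1]], sp[1])
  expect_error(place_batch(clash, backbone, b$alignment, "distance"),
               "already on the backbone")
})
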