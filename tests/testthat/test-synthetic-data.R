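# Family-structured tree simulation, sequence evolution, gene masks and
# planted artifacts.

test_that("simulate_taxon_tree respects counts, monophyly and the seed", {
  sim <- simulate_taxon_tree(3, c(3, 2, 5), seed = 7)
  expect_equal(n_leaves(sim$tree), 10L)
  expect_equal(nrow(sim$taxonomy), 10L)
  for (f in unique(sim$taxonomy$family)) {
    members <- sim$taxonomy$species[sim$taxonomy$family == f]
    expect_setequal(clade_leaves(sim$tree, mrca_node(sim$tree, members)),
                    members)
  }
  expect_true(all(sim$tree$brlen[-sim$tree$root] > 0))
  sim2 <- simulate_taxon_tree(3, c(3, 2, 5), seed = 7)
  expect_identical(write_newick(sim$tree), write_newick(sim2$tree))
  expect_error(simulate_taxon_tree(3, c(3, 0, 5), seed = 1), "at least 1")
  expect_error(simulate_taxon_tree(3, c(3, 2, 5), birth_rate = 1,
                                   death_rate = 2, seed = 1), "death_rate")
})

test_that("realized family sizes follow the supplied sampler", {
  # spec sampler: 1 + Poisson(9); compare realized counts against the
  # sampler distribution over many draws (chi-square on pooled bins)
  sampler <- function(n) 1L + stats::rpois(n, 9)
  set.seed(55)
  realized <- unlist(lapply(1:25, function(i) {
    sim <- simulate_taxon_tree(20, sampler, seed = 1000L + i)
    as.integer(table(sim$taxonomy$family))
  }))
  breaks <- c(-Inf, 6, 8, 10, 12, 14, Inf)
  obs <- table(cut(realized, breaks))
  probs <- diff(c(0, stats::ppois(c(5, 7, 9, 11, 13), 9), 1))
  pval <- stats::chisq.test(obs, p = probs)$p.value
  expect_gt(pval, 1e-4)
})

test_that("evolve_alignment limits: zero branch lengths and zero rate", {
  tr <- ptree(parent = c(3L, 3L, NA), brlen = c(0, 0, NA),
              label = c("A", "B", NA))
  parts <- list(list(name = "COI", length = 50L, rate = 1, model = jc_model()),
                list(name = "g2", length = 30L, rate = 0, model = jc_model()))
  aln <- evolve_alignment(tr, parts, seed = 3)
  expect_identical(aln$seqs[["A"]], aln$seqs[["B"]])
  # rate-0 partition is invariant even on a deep tree
  tr2 <- random_ptree(8, seed = 5)
  aln2 <- evolve_alignment(tr2, parts, seed = 4)
  g2 <- substr(aln2$seqs, 51, 80)
  expect_length(unique(g2), 1L)
  expect_identical(evolve_alignment(tr2, parts, seed = 4)$seqs, aln2$seqs)
})

test_that("simulated base composition converges to the model frequencies", {
  m <- gtr_model(c(1.5, 8, 1.2, 0.8, 14, 1), c(0.26, 0.27, 0.17, 0.30),
                 alpha = Inf, k = 1)
  star <- ptree(parent = c(5L, 5L, 5L, 5L, NA), brlen = c(8, 8, 8, 8, NA),
                label = c("A", "B", "C", "D", NA))
  aln <- evolve_alignment(star, list(list(name = "COI", length = 10000L,
                                          rate = 1, model = m)), seed = 11)
  chars <- unlist(strsplit(aln$seqs, ""))
  freq <- table(factor(chars, c("A", "C", "G", "T"))) / length(chars)
  expect_true(all(abs(freq - m$freqs) < 0.02))
})

test_that("two-leaf JC simulation reproduces the closed-form p-distance", {
  t_half <- 0.15   # total path 0.3
  tr <- ptree(parent = c(3L, 3L, NA), brlen = c(t_half, t_half, NA),
              label = c("A", "B", NA))
  L <- 6000L
  aln <- evolve_alignment(tr, list(list(name = "COI", length = L, rate = 1,
                                        model = jc_model())), seed = 21)
  p_obs <- mean(strsplit(aln$seqs[["A"]], "")[[1]] !=
                  strsplit(aln$seqs[["B"]], "")[[1]])
  p_exp <- 3 / 4 * (1 - exp(-4 * 2 * t_half / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 4 * se)
})

test_that("gene masks keep min_genes and COI, and match the sampler rate", {
  b <- small_bundle()
  pres <- gene_presence(b$alignment)
  expect_true(all(rowSums(pres) >= 3))
  expect_true(all(pres[, "COI"]))
  # min_genes equal to the partition count leaves the alignment untouched
  aln <- evolve_alignment(random_ptree(6, seed = 8),
                          list(list(name = "COI", length = 60L, rate = 1,
                                    model = jc_model()),
                               list(name = "g2", length = 40L, rate = 1,
                                    model = jc_model())), seed = 9)
  expect_identical(apply_gene_mask(aln, min_genes = 2L, seed = 10)$seqs,
                   aln$seqs)
  # blanked fraction tracks the sampler's own acceptance-adjusted rate
  sampler <- presence_sampler(0.5)
  set.seed(12)
  sim_rate <- mean(replicate(3000, {
    pres <- sampler(c("COI", "a", "b", "c", "d"), "COI", 3L)
    mean(!pres[-1])
  }))
  tr <- random_ptree(200, seed = 13)
  parts <- lapply(c(COI = 30, a = 30, b = 30, c = 30, d = 30), function(l) {
    list(name = "x", length = l, rate = 1, model = jc_model())
  })
  for (nm in names(parts)) parts[[match(nm, names(parts))]]$name <- nm
  aln2 <- evolve_alignment(tr, unname(parts), seed = 14)
  masked <- apply_gene_mask(aln2, min_genes = 3L,
                            gene_presence_sampler = sampler, seed = 15)
  obs_rate <- mean(!gene_presence(masked)[, -1])
  se <- sqrt(sim_rate * (1 - sim_rate) / (200 * 4))
  expect_lt(abs(obs_rate - sim_rate), 4 * se)
})

test_that("inject_artifacts plants exactly the requested violations", {
  b <- small_bundle()
  ia0 <- inject_artifacts(b$alignment, 0L, 0L, seed = 1)
  expect_identical(ia0$alignment$seqs, b$alignment$seqs)
  expect_equal(nrow(ia0$manifest), 0L)
  ia <- inject_artifacts(b$alignment, 4L, 3L, seed = 2)
  expect_equal(nrow(ia$manifest), 7L)
  expect_equal(sum(ia$manifest$rule == "long_gap"), 4L)
  for (i in seq_len(nrow(ia$manifest))) {
    cell <- aln_cell(ia$alignment, ia$manifest$species[i], ia$manifest$gene[i])
    if (ia$manifest$rule[i] == "long_gap") {
      runs <- nchar(regmatches(cell, gregexpr("-+", sub("^-+", "", sub("-+$", "", cell))))[[1]])
      expect_gt(max(runs), 150)
    } else {
      expect_lt(nchar(gsub("-", "", cell)), 100)
    }
  }
  expect_identical(inject_artifacts(b$alignment, 4L, 3L, seed = 2)$manifest,
                   ia$manifest)
  # partitions shorter than the gap cannot host one
  small <- toy_multigene(c("s1", "s2", "s3", "s4"), c(COI = 60, g2 = 60))
  expect_error(inject_artifacts(small, n_long_gap = 1L, seed = 3), "too short")
})

test_that("truth bundles are internally consistent and reproducible", {
  b <- small_bundle()
  expect_setequal(tree_leaves(b$tree), aln_species(b$alignment))
  expect_setequal(tree_leaves(b$tree), b$taxonomy$species)
  expect_equal(n_leaves(b$tree), 36L)
  b2 <- truth_bundle(n_families = 6L, total_species = 36L,
                     partitions = b$partitions, seed = 404L)
  expect_identical(b2$alignment$seqs, b$alignment$seqs)
  expect_identical(write_newick(b2$tree), write_newick(b$tree))
})
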