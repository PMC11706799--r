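# Shared fixtures and independent oracles for the test suite.

# a random rooted binary tree with uniform branch lengths, as a ptree
random_ptree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_ptree(ape::rtree(n))
}

# single-partition alignment from named sequence strings
toy_aln <- function(seqs, coi_len = NULL) {
  w <- nchar(seqs[1])
  mg_alignment(seqs, data.frame(name = "COI", start = 1, end = w), coi = "COI")
}

# multi-partition alignment builder: parts = named lengths, filled with a
# repeated base unless overridden
toy_multigene <- function(species, parts, fill = "A") {
  w <- sum(parts)
  seqs <- stats::setNames(rep(strrep(fill, w), length(species)), species)
  ends <- cumsum(parts)
  mg_alignment(seqs,
               data.frame(name = names(parts),
                          start = c(1, utils::head(ends, -1) + 1), end = ends),
               coi = names(parts)[1])
}

# brute-force tree likelihood: enumerate all internal-node state
# assignments (independent of the pruning implementation)
brute_loglik <- function(tr, states, model, rate = 1) {
  n <- length(tr$parent)
  ints <- which(vapply(tr$children, length, 1L) > 0L)
  lv <- which(vapply(tr$children, length, 1L) == 0L)
  k <- length(model$cat_rates)
  total <- 0
  for (s in seq_len(ncol(states))) {
    site <- 0
    for (cc in seq_len(k)) {
      P <- lapply(seq_len(n), function(v) {
        if (is.na(tr$parent[v])) NULL
        else transition_matrix(model, tr$brlen[v] * rate * model$cat_rates[cc])
      })
      grid <- expand.grid(rep(list(1:4), length(ints)))
      lik <- 0
      for (gi in seq_len(nrow(grid))) {
        asn <- integer(n)
        asn[ints] <- unlist(grid[gi, ])
        asn[lv] <- states[tr$label[lv], s]
        pr <- model$freqs[asn[tr$root]]
        ok <- TRUE
        for (v in seq_len(n)) {
          if (is.na(tr$parent[v])) next
          a <- asn[tr$parent[v]]; b <- asn[v]
          if (is.na(b)) { ok <- FALSE; break }  # no missing data here
          pr <- pr * P[[v]][a, b]
        }
        if (ok) lik <- lik + pr
      }
      site <- site + lik / k
    }
    total <- total + log(site)
  }
  total
}

# random nucleotide string
random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

# a small masked truth bundle shared by slower tests (memoized per session)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parts <- list(
        list(name = "COI", length = 300L, rate = 1.5,
             model = default_partitions()[[1]]$model),
        list(name = "g2", length = 200L, rate = 0.8,
             model = default_partitions()[[2]]$model),
        list(name = "g3", length = 150L, rate = 1.0,
             model = default_partitions()[[2]]$model),
        list(name = "g4", length = 150L, rate = 0.6,
             model = default_partitions()[[2]]$model))
      cache <<- truth_bundle(n_families = 6L, total_species = 36L,
                             partitions = parts, seed = 404L)
    }
    cache
  }
})

# realistic fixed family-size profile used by sampling tests
fixed_counts <- c(1, 1, 2, 3, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 14, 16, 18,
                  20, 24, 26)
fixed_taxonomy <- data.frame(
  species = unlist(lapply(seq_along(fixed_counts), function(i) {
    sprintf("fam%03d_sp%03d", i, seq_len(fixed_counts[i]))
  })),
  family = rep(sprintf("fam%03d", seq_along(fixed_counts)), fixed_counts))
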