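# Synthetic data: family-structured trees, GTR+Gamma multigene alignments,
# missing-gene masks, and planted QC violations with a manifest.

#' @keywords internal
run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(as.integer(seed) %% 2147483647L)
  }
  force(expr)
}

#' Default per-family species-count sampler
#'
#' Heavy-tailed family sizes (1 + negative binomial), emulating the skew of
#' real taxonomic checklists: many species-poor families (< 5 species)
#' alongside a few species-rich ones.
#'
#' @param n_families number of families to draw.
#' @param mean_size target mean family size.
#' @return integer vector of counts (all >= 1).
#' @export
sample_family_counts <- function(n_families, mean_size = 10) {
  1L + stats::rnbinom(n_families, size = 0.9, mu = mean_size - 1)
}

#' Simulate a family-structured species tree
#'
#' A birth-death backbone over families, each family tip expanded into its
#' own birth-death subtree, so every family is monophyletic by
#' construction. The tree is rescaled to the requested root-to-tip height
#' (in expected substitutions per site at unit rate).
#'
#' @param n_families number of families (>= 2).
#' @param species_counts integer vector of per-family species counts (all
#'   >= 1), or a function `f(n_families)` returning one; default
#'   [sample_family_counts()].
#' @param birth_rate,death_rate birth-death rates (`death_rate <
#'   birth_rate`).
#' @param seed RNG seed (integer); `NULL` uses the current RNG state.
#' @param height target maximum root-to-leaf path length.
#' @return a list with `tree` (a [ptree()]) and `taxonomy` (data frame
#'   `species`, `family`).
#' @export
simulate_taxon_tree <- function(n_families, species_counts = sample_family_counts,
                                birth_rate = 1, death_rate = 0, seed = NULL,
                                height = 0.5) {
  if (n_families < 2L) stop_bp("need at least 2 families")
  if (death_rate >= birth_rate) stop_bp("death_rate must be below birth_rate")
  run_seeded(seed, {
    counts <- if (is.function(species_counts)) species_counts(n_families)
              else as.integer(species_counts)
    if (length(counts) != n_families) stop_bp("need one species count per family")
    if (any(counts < 1L)) stop_bp("every family needs at least 1 species")
    fams <- sprintf("fam%03d", seq_len(n_families))

    backbone <- ape::rphylo(n_families, birth = birth_rate, death = death_rate)
    backbone$tip.label <- fams
    nwk <- ape::write.tree(backbone)
    for (i in seq_len(n_families)) {
      core <- if (counts[i] == 1L) {
        sprintf("%s_sp001", fams[i])
      } else if (counts[i] == 2L) {
        # rphylo needs n >= 3; a two-species family is a simple cherry
        sprintf("(%1$s_sp001:%2$.6f,%1$s_sp002:%2$.6f)", fams[i],
                stats::rexp(1, rate = birth_rate * counts[i]))
      } else {
        sub <- ape::rphylo(counts[i], birth = birth_rate, death = death_rate)
        sub$tip.label <- sprintf("%s_sp%03d", fams[i], seq_len(counts[i]))
        sub("\\);$", ")", ape::write.tree(sub))
      }
      nwk <- sub(paste0(fams[i], ":"), paste0(core, ":"), nwk, fixed = TRUE)
    }
    tr <- parse_newick(nwk)
    sc <- height / tree_height(tr)
    tr$brlen <- tr$brlen * sc
    species <- sort(tree_leaves(tr))
    list(tree = tr,
         taxonomy = data.frame(species = species,
                               family = sub("_sp[0-9]+$", "", species)))
  })
}

#' Default partition scheme
#'
#' Five markers: a 660-column COI barcode partition evolving faster than
#' the four nuclear-style partitions, each with its own GTR+Gamma model.
#'
#' @return a list of partition specs (`name`, `length`, `rate`, `model`)
#'   consumed by [evolve_alignment()].
#' @export
default_partitions <- function() {
  coi <- gtr_model(c(1.5, 8, 1.2, 0.8, 14, 1),
                   c(0.26, 0.27, 0.17, 0.30), alpha = 0.45)
  nuc <- gtr_model(c(1.2, 3, 1, 1, 3.5, 1),
                   c(0.27, 0.23, 0.24, 0.26), alpha = 0.8)
  list(
    list(name = "COI", length = 660L, rate = 1.5, model = coi),
    list(name = "rag1", length = 1200L, rate = 0.5, model = nuc),
    list(name = "myh6", length = 800L, rate = 0.7, model = nuc),
    list(name = "zic1", length = 600L, rate = 0.8, model = nuc),
    list(name = "rho", length = 400L, rate = 1.0, model = nuc)
  )
}

#' Evolve a multigene alignment along a tree
#'
#' Simulates sequences under per-partition GTR+Gamma models: root states
#' are drawn from the stationary frequencies and evolved along each branch
#' with transition matrices `exp(Q * r_c * m_p * t)`, where `r_c` is the
#' discrete-Gamma rate of the site's category (assigned once per site,
#' shared across the whole tree) and `m_p` the partition rate multiplier.
#' No indels are simulated: gaps only arise later from masks or planted
#' artifacts.
#'
#' @param tr a [ptree()] with at least 2 leaves.
#' @param partitions list of specs `list(name, length, rate, model)`;
#'   default [default_partitions()].
#' @param seed RNG seed.
#' @return an [mg_alignment()] (COI partition taken from the spec named
#'   `COI`, else the first partition).
#' @export
evolve_alignment <- function(tr, partitions = default_partitions(), seed = NULL) {
  if (n_leaves(tr) < 2L) stop_bp("tree needs at least 2 leaves")
  lens <- vapply(partitions, function(p) as.integer(p$length), 1L)
  if (any(lens < 1L)) stop_bp("partition lengths must be >= 1")
  run_seeded(seed, {
    n <- length(tr$parent)
    ord <- rev(postorder_nodes(tr))   # preorder: parents before children
    blocks <- lapply(partitions, function(p) {
      m <- p$model
      ncat <- length(m$cat_rates)
      cats <- sample.int(ncat, p$length, replace = TRUE)
      states <- matrix(NA_integer_, n, p$length)
      states[tr$root, ] <- sample.int(4L, p$length, replace = TRUE,
                                      prob = m$freqs)
      for (v in ord) {
        if (v == tr$root) next
        pa <- tr$parent[v]
        for (cc in seq_len(ncat)) {
          idx <- which(cats == cc)
          if (!length(idx)) next
          t_eff <- tr$brlen[v] * p$rate * m$cat_rates[cc]
          if (t_eff == 0) {
            states[v, idx] <- states[pa, idx]
          } else {
            P <- transition_matrix(m, t_eff)
            for (a in 1:4) {
              ai <- idx[states[pa, idx] == a]
              if (length(ai)) {
                states[v, ai] <- sample.int(4L, length(ai), replace = TRUE,
                                            prob = P[a, ])
              }
            }
          }
        }
      }
      states[leaf_nodes(tr), , drop = FALSE]
    })
    lv <- leaf_nodes(tr)
    chars <- do.call(cbind, blocks)
    seqs <- apply(chars, 1, function(row) paste(DNA_STATES[row], collapse = ""))
    names(seqs) <- tr$label[lv]
    ends <- cumsum(lens)
    parts <- data.frame(name = vapply(partitions, `[[`, "", "name"),
                        start = c(1L, utils::head(ends, -1) + 1L), end = ends)
    coi <- if ("COI" %in% parts$name) "COI" else parts$name[1]
    mg_alignment(seqs, parts, coi = coi)
  })
}

#' Default gene-presence sampler
#'
#' Each non-COI gene is present independently with probability `p`; COI is
#' always present. Draws with fewer than `min_genes` total genes are
#' rejected and resampled.
#'
#' @param p per-gene presence probability.
#' @return a sampler function `f(genes, coi, min_genes)` returning a
#'   logical presence vector named by gene.
#' @export
presence_sampler <- function(p = 0.55) {
  function(genes, coi, min_genes) {
    repeat {
      pres <- stats::runif(length(genes)) < p
      names(pres) <- genes
      pres[genes == coi] <- TRUE
      if (sum(pres) >= min_genes) return(pres)
    }
  }
}

#' Mask whole genes per species
#'
#' Blanks a random subset of gene cells per species to missing (`-`),
#' emulating patchy multigene matrices, while guaranteeing that every
#' species keeps at least `min_genes` genes and (when `coi_required`)
#' always keeps COI.
#'
#' @param aln an [mg_alignment()].
#' @param min_genes minimum genes retained per species (default 3).
#' @param coi_required never blank the COI partition (default `TRUE`).
#' @param gene_presence_sampler sampler as built by [presence_sampler()].
#' @param seed RNG seed.
#' @return the masked [mg_alignment()].
#' @export
apply_gene_mask <- function(aln, min_genes = 3L, coi_required = TRUE,
                            gene_presence_sampler = presence_sampler(),
                            seed = NULL) {
  genes <- aln$partitions$name
  if (min_genes > length(genes)) stop_bp("min_genes exceeds the number of partitions")
  if (min_genes == length(genes)) return(aln)
  run_seeded(seed, {
    for (sp in aln_species(aln)) {
      pres <- gene_presence_sampler(genes, aln$coi, min_genes)
      if (sum(pres) < min_genes) {
        stop_bp("gene_presence_sampler returned fewer than min_genes genes")
      }
      if (coi_required) pres[genes == aln$coi] <- TRUE
      for (g in genes[!pres]) aln <- blank_cell(aln, sp, g)
    }
    aln
  })
}

#' Plant quality-control violations
#'
#' Injects exactly `n_long_gap` internal gap runs longer than
#' `gap_threshold` columns and truncates exactly `n_short_gene` cells below
#' `short_threshold` non-gap characters, into distinct randomly chosen
#' non-missing species x gene cells. Used to exercise the QC filters
#' against a known ground truth.
#'
#' @param aln an [mg_alignment()].
#' @param n_long_gap,n_short_gene number of cells to corrupt.
#' @param seed RNG seed.
#' @param gap_threshold,short_threshold QC rule thresholds (defaults 150
#'   and 100, matching the filter defaults).
#' @return list with `alignment` (corrupted) and `manifest` (data frame
#'   `species`, `gene`, `rule`).
#' @export
inject_artifacts <- function(aln, n_long_gap = 0L, n_short_gene = 0L,
                             seed = NULL, gap_threshold = 150L,
                             short_threshold = 100L) {
  pres <- gene_presence(aln)
  cells <- which(pres, arr.ind = TRUE)
  genes <- aln$partitions$name
  lens <- aln$partitions$end - aln$partitions$start + 1L
  names(lens) <- genes
  run_seeded(seed, {
    if (n_long_gap + n_short_gene == 0L) {
      return(list(alignment = aln,
                  manifest = data.frame(species = character(0),
                                        gene = character(0),
                                        rule = character(0))))
    }
    nongap <- matrix(0L, nrow(pres), ncol(pres), dimnames = dimnames(pres))
    for (g in genes) {
      r <- partition_range(aln, g)
      nongap[, g] <- nchar(gsub("-", "", substr(aln$seqs, r[1], r[2])))
    }
    # a gap plant must leave >= short_threshold residues so one cell never
    # trips both rules (the manifest stays one rule per cell)
    gap_ok <- pres & matrix(lens[genes] >= gap_threshold + 1L + short_threshold,
                            nrow(pres), ncol(pres), byrow = TRUE)
    short_ok <- pres & nongap >= short_threshold
    if (n_long_gap > 0L && !any(gap_ok)) {
      stop_bp("every partition is too short for a planted gap > ", gap_threshold)
    }
    gap_cells <- which(gap_ok, arr.ind = TRUE)
    if (n_long_gap > nrow(gap_cells)) {
      stop_bp("more long-gap artifacts requested than eligible cells")
    }
    pick_gap <- gap_cells[sample.int(nrow(gap_cells), n_long_gap), , drop = FALSE]
    # short-gene cells must be distinct from the gap cells
    taken <- paste(pick_gap[, 1], pick_gap[, 2])
    short_cells <- which(short_ok, arr.ind = TRUE)
    short_cells <- short_cells[!paste(short_cells[, 1], short_cells[, 2]) %in% taken, ,
                               drop = FALSE]
    if (n_short_gene > nrow(short_cells)) {
      stop_bp("more short-gene artifacts requested than eligible cells")
    }
    pick_short <- short_cells[sample.int(nrow(short_cells), n_short_gene), ,
                              drop = FALSE]
    pick <- rbind(pick_gap, pick_short)
    rule <- rep(c("long_gap", "short_gene"), c(n_long_gap, n_short_gene))
    manifest <- data.frame(species = rownames(pres)[pick[, 1]],
                           gene = genes[pick[, 2]], rule = rule)
    for (i in seq_len(nrow(manifest))) {
      sp <- manifest$species[i]; g <- manifest$gene[i]
      cell <- aln_cell(aln, sp, g)
      len <- lens[[g]]
      if (manifest$rule[i] == "long_gap") {
        run <- sample(seq.int(gap_threshold + 1L,
                              min(gap_threshold + 50L, len - short_threshold)), 1)
        start <- sample(seq.int(2L, len - run), 1)
        substr(cell, start, start + run - 1L) <- strrep("-", run)
      } else {
        keep <- sample(seq.int(max(1L, short_threshold - 50L),
                               short_threshold - 1L), 1)
        # keep the first `keep` non-gap characters, blank the rest
        chars <- strsplit(cell, "")[[1]]
        nong <- which(chars != "-")
        if (length(nong) > keep) chars[nong[-seq_len(keep)]] <- "-"
        cell <- paste(chars, collapse = "")
      }
      aln <- set_cell(aln, sp, g, cell)
    }
    list(alignment = aln, manifest = manifest)
  })
}

#' Simulate a complete truth bundle
#'
#' Convenience wrapper producing the default study system: a
#' family-structured true tree (which doubles as the reference tree), a
#' masked multigene alignment with a COI partition, and the taxonomy.
#'
#' @param n_families number of families.
#' @param total_species total species count; the default sampler's counts
#'   are adjusted (on the largest family) to hit it exactly. `NULL` leaves
#'   sampled counts untouched.
#' @param species_counts explicit per-family counts (overrides
#'   `total_species`).
#' @param partitions partition specs, see [evolve_alignment()].
#' @param birth_rate,death_rate,height tree simulation parameters, see
#'   [simulate_taxon_tree()].
#' @param min_genes,presence_p gene mask parameters.
#' @param seed RNG seed (required for reproducible bundles).
#' @return an object of class `truth_bundle`: list with `tree`,
#'   `alignment`, `taxonomy`, `partitions`, `seed`.
#' @export
truth_bundle <- function(n_families = 20L, total_species = 200L,
                         species_counts = NULL,
                         partitions = default_partitions(),
                         birth_rate = 1, death_rate = 0, height = 0.5,
                         min_genes = 3L, presence_p = 0.55, seed = 1L) {
  counts <- if (!is.null(species_counts)) {
    as.integer(species_counts)
  } else {
    run_seeded(derive_seed(seed, 1L), {
      mean_size <- if (is.null(total_species)) 10 else total_species / n_families
      cnt <- sample_family_counts(n_families, mean_size = mean_size)
      if (!is.null(total_species)) {
        diff <- total_species - sum(cnt)
        i <- which.max(cnt)
        if (cnt[i] + diff < 1L) stop_bp("total_species too small for ", n_families, " families")
        cnt[i] <- cnt[i] + diff
      }
      cnt
    })
  }
  sim <- simulate_taxon_tree(n_families, counts, birth_rate, death_rate,
                             seed = derive_seed(seed, 2L), height = height)
  aln <- evolve_alignment(sim$tree, partitions, seed = derive_seed(seed, 3L))
  aln <- apply_gene_mask(aln, min_genes = min_genes,
                         gene_presence_sampler = presence_sampler(presence_p),
                         seed = derive_seed(seed, 4L))
  structure(list(tree = sim$tree, alignment = aln, taxonomy = sim$taxonomy,
                 partitions = partitions, seed = seed),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("truth_bundle: ", n_leaves(x$tree), " species, ",
      length(unique(x$taxonomy$family)), " families, ",
      nchar(x$alignment$seqs[1]), " columns, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
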