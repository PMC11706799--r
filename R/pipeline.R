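# Experiment orchestration: simulate -> subsample -> place -> score, over
# replicates x strategies x completeness levels x engines, with
# deterministic per-stage seeds derived from one master seed.

#' Default experiment configuration
#'
#' Desk-scale defaults: 200 species in 20 families, five partitions
#' (COI 660 bp), nested levels 99/80/60/40/20%, random + stratified
#' sampling, both engines, 3 replicates.
#'
#' @param ... overrides for any configuration entry.
#' @return a named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_families = 20L, total_species = 200L,
    partitions = default_partitions(),
    birth_rate = 1, death_rate = 0, height = 0.5,
    min_genes = 3L, presence_p = 0.55,
    strategies = c("random", "stratified"),
    levels = c(99, 80, 60, 40, 20),
    engines = c("likelihood", "distance"),
    replicates = 3L,
    modes = c("sister_plus_query_mrca", "sister_mrca"),
    lwr_threshold = 0.9,
    optimize = TRUE,
    weighting = "fm",
    distance_model = "ml",
    seed = 1L,
    run_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @keywords internal
pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Extract COI-only query rows
#'
#' Full-width alignment rows for the given species with every non-COI
#' column blanked to `-` — the query format both placement engines
#' consume (a barcode-only sequence in the reference coordinate system).
#'
#' @param aln an [mg_alignment()].
#' @param species species names to extract.
#' @return named character vector of query rows.
#' @export
coi_query_rows <- function(aln, species) {
  r <- partition_range(aln, aln$coi)
  vapply(species, function(sp) {
    row <- aln$seqs[[sp]]
    paste0(strrep("-", r[1] - 1L), substr(row, r[1], r[2]),
           strrep("-", nchar(row) - r[2]))
  }, character(1))
}

#' Run a full placement-accuracy experiment
#'
#' Simulates a truth bundle (or uses a supplied one), then for every
#' replicate x strategy x completeness level: prunes the reference tree to
#' the backbone, places all missing species from their COI sequences with
#' each engine, scores them by the sister-clade rule, and summarizes
#' PCP/CP/PCP-CP. Every stage draws its seed deterministically from the
#' master seed, so reruns are bit-identical.
#'
#' @param config list from [default_config()].
#' @param bundle optional pre-built [truth_bundle()] (skips simulation).
#' @return list with `summary` (one row per cell: replicate, strategy,
#'   level, engine, assessment mode, accuracy columns), `records`
#'   (per-query verdicts),
#'   `bundle`, and `config`. When `config$run_dir` is set, trees, jplace
#'   documents, TSV tables and a timestamped log are written there.
#' @export
run_experiment <- function(config = default_config(), bundle = NULL) {
  cfg <- config
  seed <- cfg$seed
  run_dir <- cfg$run_dir
  con <- NULL
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(run_dir, "run.log"), open = "wt")
    on.exit(close(con))
  }
  t0 <- Sys.time()
  pipeline_log(con, "simulate: seed ", seed)
  if (is.null(bundle)) {
    bundle <- truth_bundle(
      n_families = cfg$n_families, total_species = cfg$total_species,
      partitions = cfg$partitions, birth_rate = cfg$birth_rate,
      death_rate = cfg$death_rate, height = cfg$height,
      min_genes = cfg$min_genes, presence_p = cfg$presence_p,
      seed = derive_seed(seed, 1L))
  }
  ref_tree <- bundle$tree
  species <- tree_leaves(ref_tree)
  coi_spec <- Filter(function(p) p$name == bundle$alignment$coi, bundle$partitions)[[1]]

  if (!is.null(run_dir)) {
    writeLines(write_newick(ref_tree), file.path(run_dir, "reference_tree.nwk"))
    write_aln_fasta(bundle$alignment, file.path(run_dir, "alignment.fasta"))
    write_partition_file(bundle$alignment, file.path(run_dir, "partitions.txt"))
    write_taxonomy_tsv(bundle$taxonomy, file.path(run_dir, "taxonomy.tsv"))
  }

  summary_rows <- list()
  record_rows <- list()
  counter <- 100L
  for (r in seq_len(cfg$replicates)) {
    for (strat in cfg$strategies) {
      counter <- counter + 1L
      s_seed <- derive_seed(seed, counter)
      series <- switch(strat,
        random = random_series(species, cfg$levels, seed = s_seed, replicate = r),
        stratified = stratified_series(species, bundle$taxonomy, cfg$levels,
                                       seed = s_seed, replicate = r),
        biased = biased_series(species, bundle$taxonomy, cfg$missing_fractions,
                               seed = s_seed, replicate = r),
        stop_bp("unknown strategy: ", strat))
      for (li in seq_along(series$levels)) {
        lev <- series$levels[li]
        retained <- series$retained[[li]]
        missing <- setdiff(species, retained)
        pipeline_log(con, sprintf("replicate %d %s level %.3g: %d backbone, %d queries",
                                  r, strat, lev, length(retained), length(missing)))
        backbone <- number_edges(prune_taxa(ref_tree, missing))
        queries <- coi_query_rows(bundle$alignment, missing)
        for (engine in cfg$engines) {
          batch <- place_batch(queries, backbone, bundle$alignment,
                               engine = engine, model = coi_spec$model,
                               rate = coi_spec$rate,
                               optimize = isTRUE(cfg$optimize),
                               weighting = cfg$weighting,
                               distance_model = cfg$distance_model %||% "jc")
          if (!length(batch$results)) {
            stop_bp("stage placement: no query could be placed (replicate ",
                    r, ", ", strat, ", level ", lev, ", ", engine, ")")
          }
          for (mode in cfg$modes) {
            recs <- score_placements(batch$results, backbone, ref_tree,
                                     mode = mode)
            summ <- summarize_accuracy(recs, cfg$lwr_threshold)
            cell <- data.frame(replicate = r, strategy = strat, level = lev,
                               engine = engine, mode = mode)
            summary_rows[[length(summary_rows) + 1L]] <- cbind(cell, summ)
            record_rows[[length(record_rows) + 1L]] <- cbind(cell, recs)
          }
          if (!is.null(run_dir)) {
            base <- sprintf("rep%02d_%s_%03.0f_%s", r, strat, lev, engine)
            writeLines(batch$jplace, file.path(run_dir, paste0(base, ".jplace")))
          }
        }
        if (!is.null(run_dir)) {
          writeLines(write_newick(backbone, with_edge_numbers = TRUE),
                     file.path(run_dir, sprintf("rep%02d_%s_%03.0f_backbone.nwk",
                                                r, strat, lev)))
        }
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  records <- do.call(rbind, record_rows)
  rownames(summary) <- rownames(records) <- NULL
  if (!is.null(run_dir)) {
    utils::write.table(summary, file.path(run_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(records, file.path(run_dir, "records.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  pipeline_log(con, sprintf("done in %.1f s",
                            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  list(summary = summary, records = records, bundle = bundle, config = cfg)
}

#' Format an experiment summary as a report table
#'
#' One row per (level, strategy, engine) with each metric shown as the
#' replicate mean (rounded to integer percent) and its min-max range, e.g.
#' `"70 (69-71)"`. Confidence columns are omitted for the distance engine,
#' which has no likelihood weight ratio.
#'
#' @param summary the `summary` data frame from [run_experiment()].
#' @param mode assessment mode to report when the summary carries several
#'   (default: the first present).
#' @return data frame with formatted `pcp`, `cp`, `pcp_cp` columns.
#' @export
report_table <- function(summary, mode = NULL) {
  if ("mode" %in% names(summary)) {
    summary <- summary[summary$mode == (mode %||% summary$mode[1]), , drop = FALSE]
  }
  fmt <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    sprintf("%d (%d-%d)", round_half_up(mean(x)),
            round_half_up(min(x)), round_half_up(max(x)))
  }
  cells <- unique(summary[, c("strategy", "level", "engine")])
  cells <- cells[order(cells$engine, cells$strategy, -cells$level), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- merge(summary, cells[i, , drop = FALSE])
    row <- data.frame(level = cells$level[i], strategy = cells$strategy[i],
                      engine = cells$engine[i],
                      replicates = nrow(sub),
                      pcp = fmt(sub$pcp))
    if (cells$engine[i] == "likelihood") {
      row$cp <- fmt(sub$cp)
      row$pcp_cp <- fmt(sub$pcp_cp)
    } else {
      row$cp <- NA_character_
      row$pcp_cp <- NA_character_
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Build the ART design table from an experiment summary
#'
#' Extracts one engine's metric into the `replicate`/`level`/`strategy`/
#' `value` layout consumed by [art_anova()] and [art_contrasts()].
#'
#' @param summary the `summary` data frame from [run_experiment()].
#' @param engine engine to keep.
#' @param metric `"pcp"`, `"cp"` or `"pcp_cp"`.
#' @param mode assessment mode to keep when the summary carries several
#'   (default: the first present).
#' @return a design table data frame.
#' @export
design_table <- function(summary, engine = "likelihood", metric = "pcp",
                         mode = NULL) {
  if ("mode" %in% names(summary)) {
    summary <- summary[summary$mode == (mode %||% summary$mode[1]), , drop = FALSE]
  }
  sub <- summary[summary$engine == engine, , drop = FALSE]
  data.frame(replicate = sub$replicate, level = sub$level,
             strategy = sub$strategy, value = sub[[metric]])
}
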