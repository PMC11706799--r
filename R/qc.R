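# Quality-control filters for multigene alignments: gappy cells, short
# cells, and the minimum-gene / COI-required species rule.

empty_report <- function() {
  data.frame(species = character(0), gene = character(0),
             rule = character(0), detail = character(0))
}

# longest run of '-' within the aligned span of a cell; terminal runs
# (leading/trailing) are by default treated as incompleteness, not gaps
#' @keywords internal
max_gap_run <- function(cell, include_terminal = FALSE) {
  if (!include_terminal) {
    cell <- sub("^-+", "", sub("-+$", "", cell))
  }
  runs <- regmatches(cell, gregexpr("-+", cell))[[1]]
  if (!length(runs)) 0L else max(nchar(runs))
}

#' Blank gene cells containing large gaps
#'
#' Any species x gene cell whose aligned sequence contains a gap run
#' strictly longer than `threshold` columns is blanked to missing. By
#' default only internal runs count; set `include_terminal = TRUE` to also
#' count leading/trailing runs.
#'
#' @param aln an [mg_alignment()].
#' @param threshold maximum tolerated gap run (default 150; the rule is
#'   strict, so a run of exactly 150 is retained).
#' @param include_terminal count terminal gap runs too (default `FALSE`).
#' @return list with `alignment` and a `report` data frame
#'   (`species`, `gene`, `rule`, `detail`).
#' @export
strip_long_gap_genes <- function(aln, threshold = 150L, include_terminal = FALSE) {
  stopifnot(threshold >= 1L)
  report <- empty_report()
  pres <- gene_presence(aln)
  for (sp in rownames(pres)) {
    for (g in colnames(pres)[pres[sp, ]]) {
      run <- max_gap_run(aln_cell(aln, sp, g), include_terminal)
      if (run > threshold) {
        aln <- blank_cell(aln, sp, g)
        report <- rbind(report, data.frame(
          species = sp, gene = g, rule = "long_gap",
          detail = sprintf("gap run %d > %d", run, threshold)))
      }
    }
  }
  list(alignment = aln, report = report)
}

#' Blank short gene cells
#'
#' Cells with fewer than `min_len` non-gap characters are blanked to
#' missing. Already-missing (all-gap) cells are untouched and unreported.
#'
#' @param aln an [mg_alignment()].
#' @param min_len minimum non-gap length (default 100; strict, so exactly
#'   100 characters are retained).
#' @return list with `alignment` and `report`.
#' @export
strip_short_genes <- function(aln, min_len = 100L) {
  stopifnot(min_len >= 1L)
  report <- empty_report()
  pres <- gene_presence(aln)
  for (sp in rownames(pres)) {
    for (g in colnames(pres)[pres[sp, ]]) {
      len <- nchar(gsub("-", "", aln_cell(aln, sp, g)))
      if (len < min_len) {
        aln <- blank_cell(aln, sp, g)
        report <- rbind(report, data.frame(
          species = sp, gene = g, rule = "short_gene",
          detail = sprintf("%d non-gap characters < %d", len, min_len)))
      }
    }
  }
  list(alignment = aln, report = report)
}

#' Drop species with too few genes or without COI
#'
#' Species retaining fewer than `min_genes` non-blank partitions, or
#' lacking the COI partition when `require_coi`, are removed entirely.
#' Intended to run after [strip_long_gap_genes()] and
#' [strip_short_genes()].
#'
#' @param aln an [mg_alignment()].
#' @param min_genes minimum genes per species (default 3).
#' @param require_coi require a non-blank COI cell (default `TRUE`).
#' @return list with `alignment` and `report` (rule `min_genes` or
#'   `no_coi`).
#' @export
enforce_min_genes <- function(aln, min_genes = 3L, require_coi = TRUE) {
  pres <- gene_presence(aln)
  n_genes <- rowSums(pres)
  has_coi <- pres[, aln$coi]
  drop_sp <- names(aln$seqs)[n_genes < min_genes | (require_coi & !has_coi)]
  report <- empty_report()
  for (sp in drop_sp) {
    rule <- if (require_coi && !has_coi[sp]) "no_coi" else "min_genes"
    report <- rbind(report, data.frame(
      species = sp, gene = NA_character_, rule = rule,
      detail = sprintf("%d genes, COI %s", n_genes[sp],
                       if (has_coi[sp]) "present" else "absent")))
  }
  keep <- setdiff(names(aln$seqs), drop_sp)
  if (length(keep) < 4L) stop_bp("fewer than 4 species survive the gene filter")
  aln$seqs <- aln$seqs[keep]
  list(alignment = aln, report = report)
}

#' Run the full QC filter chain
#'
#' Large-gap strip, short-cell strip, then the species-level minimum-gene
#' rule, with a combined report.
#'
#' @inheritParams strip_long_gap_genes
#' @inheritParams enforce_min_genes
#' @param min_len minimum non-gap cell length.
#' @return list with `alignment` and combined `report`.
#' @export
qc_filter <- function(aln, threshold = 150L, min_len = 100L, min_genes = 3L,
                      require_coi = TRUE, include_terminal = FALSE) {
  a <- strip_long_gap_genes(aln, threshold, include_terminal)
  b <- strip_short_genes(a$alignment, min_len)
  c_ <- enforce_min_genes(b$alignment, min_genes, require_coi)
  list(alignment = c_$alignment,
       report = rbind(a$report, b$report, c_$report))
}

#' Write a filter report as TSV
#' @param report a QC report data frame.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
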