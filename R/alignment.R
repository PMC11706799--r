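# Multigene alignment container and standard-format I/O.
#
# Sequences are stored as equal-length strings over {A,C,G,T,-}; '-'
# encodes both alignment gaps and whole missing genes. Partitions are
# 1-based inclusive column ranges that tile the alignment.

#' Construct a multigene alignment
#'
#' @param seqs named character vector (names = species) of equal-length
#'   sequences over `A`, `C`, `G`, `T`, `-`.
#' @param partitions data frame with columns `name`, `start`, `end`
#'   (1-based inclusive, non-overlapping, covering all columns).
#' @param coi name of the partition holding the COI barcode marker.
#' @return an object of class `mg_alignment`.
#' @export
mg_alignment <- function(seqs, partitions, coi = "COI") {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop_bp("all rows must have equal length")
  partitions <- as.data.frame(partitions)
  stopifnot(all(c("name", "start", "end") %in% names(partitions)))
  o <- order(partitions$start)
  partitions <- partitions[o, , drop = FALSE]
  rownames(partitions) <- NULL
  if (partitions$start[1] != 1L || partitions$end[nrow(partitions)] != widths[1] ||
      (nrow(partitions) > 1 &&
       any(partitions$start[-1] != partitions$end[-nrow(partitions)] + 1L))) {
    stop_bp("partitions must be non-overlapping and cover every column")
  }
  if (anyDuplicated(partitions$name)) stop_bp("duplicate partition names")
  if (!coi %in% partitions$name) stop_bp("COI partition '", coi, "' not found")
  if (any(grepl("[^ACGT-]", seqs))) stop_bp("sequences restricted to A,C,G,T,-")
  structure(list(seqs = seqs, partitions = partitions, coi = coi),
            class = "mg_alignment")
}

#' @export
print.mg_alignment <- function(x, ...) {
  cat("mg_alignment: ", length(x$seqs), " species x ", nchar(x$seqs[1]),
      " columns; partitions: ",
      paste0(x$partitions$name, collapse = ", "),
      " (COI = ", x$coi, ")\n", sep = "")
  invisible(x)
}

#' Species of an alignment
#' @param aln an [mg_alignment()].
#' @export
aln_species <- function(aln) names(aln$seqs)

#' @keywords internal
partition_range <- function(aln, gene) {
  i <- match(gene, aln$partitions$name)
  if (is.na(i)) stop_bp("unknown partition: ", gene)
  c(aln$partitions$start[i], aln$partitions$end[i])
}

#' Extract one species x gene cell
#' @param aln an [mg_alignment()].
#' @param species species name.
#' @param gene partition name.
#' @return the cell's aligned sequence string.
#' @export
aln_cell <- function(aln, species, gene) {
  r <- partition_range(aln, gene)
  if (!species %in% names(aln$seqs)) stop_bp("unknown species: ", species)
  substr(aln$seqs[[species]], r[1], r[2])
}

#' @keywords internal
set_cell <- function(aln, species, gene, value) {
  r <- partition_range(aln, gene)
  stopifnot(nchar(value) == r[2] - r[1] + 1L)
  substr(aln$seqs[[species]], r[1], r[2]) <- value
  aln
}

#' @keywords internal
blank_cell <- function(aln, species, gene) {
  r <- partition_range(aln, gene)
  set_cell(aln, species, gene, strrep("-", r[2] - r[1] + 1L))
}

#' Gene presence matrix
#'
#' Logical matrix (species x partition): does the cell contain at least one
#' non-gap character?
#'
#' @param aln an [mg_alignment()].
#' @export
gene_presence <- function(aln) {
  genes <- aln$partitions$name
  out <- sapply(genes, function(g) {
    r <- partition_range(aln, g)
    grepl("[ACGT]", substr(aln$seqs, r[1], r[2]))
  })
  rownames(out) <- names(aln$seqs)
  out
}

# integer state matrix (species x columns), 1..4 for A,C,G,T, NA for '-'
#' @keywords internal
aln_states <- function(aln, cols = NULL) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  s <- match(m, DNA_STATES)
  dim(s) <- dim(m)
  dimnames(s) <- dimnames(m)
  s
}

#' Write an alignment to FASTA
#'
#' @param aln an [mg_alignment()].
#' @param path output file.
#' @export
write_aln_fasta <- function(aln, path) {
  bin <- ape::as.DNAbin(strsplit(tolower(aln$seqs), ""))
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Read an alignment from FASTA plus a partition file
#'
#' @param fasta path to an aligned FASTA file.
#' @param partition_file path to a RAxML-style partition file
#'   (`DNA, NAME = start-end` per line).
#' @param coi COI partition name.
#' @return an [mg_alignment()].
#' @export
read_aln_fasta <- function(fasta, partition_file, coi = "COI") {
  bin <- ape::read.FASTA(fasta)
  seqs <- toupper(vapply(as.character(bin), paste, character(1), collapse = ""))
  mg_alignment(seqs, read_partition_file(partition_file), coi = coi)
}

#' Write a RAxML-style partition file
#' @param aln an [mg_alignment()].
#' @param path output file.
#' @export
write_partition_file <- function(aln, path) {
  writeLines(sprintf("DNA, %s = %d-%d", aln$partitions$name,
                     aln$partitions$start, aln$partitions$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#' @param path input file with `DNA, NAME = start-end` lines.
#' @return data frame with `name`, `start`, `end`.
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*DNA\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop_bp("malformed partition line: ", lines[bad][1])
  data.frame(name = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)))
}

#' Write a species-to-family taxonomy TSV
#' @param taxonomy data frame with `species` and `family` columns.
#' @param path output file.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("species", "family")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species-to-family taxonomy TSV
#' @param path input TSV with `species` and `family` columns.
#' @export
read_taxonomy_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
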