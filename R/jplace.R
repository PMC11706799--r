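# jplace v3 reading and writing (Matsen et al. placement exchange format).

jplace_fields <- function(engine) {
  switch(engine,
    likelihood = c("edge_num", "likelihood", "like_weight_ratio",
                   "distal_length", "pendant_length"),
    distance = c("edge_num", "least_squares", "distal_length",
                 "pendant_length"),
    stop_bp("unknown engine: ", engine))
}

#' Write placements to a jplace v3 document
#'
#' Serializes per-query placement candidates against a numbered backbone
#' tree. The likelihood engine emits fields
#' `edge_num, likelihood, like_weight_ratio, distal_length, pendant_length`;
#' the distance engine replaces the likelihood columns by its least-squares
#' error and emits no weight ratio (distance placement carries no
#' confidence estimate).
#'
#' @param tr numbered backbone [ptree()].
#' @param placements list of placement results as returned by [epa_place()]
#'   or [apples_place()].
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return the JSON text, invisibly when written to `path`.
#' @export
write_jplace <- function(tr, placements, path = NULL) {
  if (anyNA(tr$edge_num[-tr$root])) stop_bp("backbone tree must be numbered")
  if (length(placements) == 0L) stop_bp("no placements to write")
  engines <- unique(vapply(placements, function(p) p$engine, character(1)))
  if (length(engines) != 1L) stop_bp("mixed engines in one jplace document")
  fields <- jplace_fields(engines)
  valid_edges <- tr$edge_num[!is.na(tr$edge_num)]

  score_col <- if (engines == "likelihood") "likelihood" else "least_squares"
  pl <- lapply(placements, function(p) {
    cand <- p$candidates
    if (!all(cand$edge_num %in% valid_edges)) {
      stop_bp("placement for '", p$query, "' references an edge not in the tree")
    }
    cols <- list(edge_num = cand$edge_num)
    cols[[score_col]] <- cand$score
    if ("like_weight_ratio" %in% fields) cols$like_weight_ratio <- cand$lwr
    cols$distal_length <- cand$distal_length
    cols$pendant_length <- cand$pendant_length
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      lapply(cols, function(x) jsonlite::unbox(x[i]))
    })
    list(p = lapply(rows, unname), n = list(p$query))
  })

  doc <- list(
    version = jsonlite::unbox(3L),
    tree = jsonlite::unbox(write_newick(tr, with_edge_numbers = TRUE)),
    placements = unname(pl),
    fields = fields,
    metadata = list(invocation = jsonlite::unbox("barcodeplace"))
  )
  # digits = I(17): serialize numerics at 17 significant digits so decimal
  # re-serialization round-trips doubles exactly
  txt <- jsonlite::toJSON(doc, auto_unbox = FALSE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a jplace v3 document
#'
#' @param path path to a jplace file (or a JSON string).
#' @return a list with `tree` (a numbered [ptree()]) and `placements`, a
#'   named list of per-query data frames with columns `edge_num`, `score`,
#'   `lwr` (`NA` when the document has no `like_weight_ratio` field),
#'   `distal_length`, `pendant_length`.
#' @export
read_jplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("version", "tree", "placements", "fields")) {
    if (is.null(doc[[key]])) stop_bp("jplace document missing '", key, "'")
  }
  if (as.integer(doc$version) != 3L) stop_bp("unsupported jplace version: ", doc$version)
  fields <- unlist(doc$fields)
  need <- c("edge_num", "distal_length", "pendant_length")
  if (!all(need %in% fields)) {
    stop_bp("jplace fields must include ", paste(need, collapse = ", "))
  }
  tr <- parse_newick(doc$tree)
  if (anyNA(tr$edge_num[-tr$root])) stop_bp("jplace tree has unnumbered edges")
  valid_edges <- tr$edge_num[!is.na(tr$edge_num)]

  score_field <- intersect(c("likelihood", "least_squares"), fields)[1]
  placements <- list()
  for (p in doc$placements) {
    name <- unlist(p$n %||% p$nm)[1]
    if (is.null(name)) stop_bp("jplace placement without a query name")
    rows <- do.call(rbind, lapply(p$p, function(r) as.numeric(unlist(r))))
    colnames(rows) <- fields
    if (!all(rows[, "edge_num"] %in% valid_edges)) {
      stop_bp("jplace placement for '", name, "' references edge ",
              setdiff(rows[, "edge_num"], valid_edges)[1], " not present in the tree")
    }
    placements[[name]] <- data.frame(
      edge_num = as.integer(rows[, "edge_num"]),
      score = if (!is.na(score_field)) rows[, score_field] else NA_real_,
      lwr = if ("like_weight_ratio" %in% fields) rows[, "like_weight_ratio"] else NA_real_,
      distal_length = rows[, "distal_length"],
      pendant_length = rows[, "pendant_length"])
  }
  list(tree = tr, placements = placements)
}
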