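# Batch placement: every query placed independently against the same
# backbone, results serialized as jplace v3.

#' Place a batch of query sequences
#'
#' Runs one placement engine over a set of queries. Queries are placed
#' independently (no query ever sees another's placement). Shared
#' per-backbone work (conditional likelihood vectors or edge geometry) is
#' computed once.
#'
#' @param queries named character vector of full-width alignment rows.
#' @param backbone numbered backbone [ptree()].
#' @param ref_aln reference [mg_alignment()] covering the backbone leaves.
#' @param engine `"likelihood"` ([epa_place()]) or `"distance"`
#'   ([apples_place()]).
#' @param model a [gtr_model()] (likelihood engine).
#' @param rate rate multiplier (likelihood engine), see [epa_place()].
#' @param optimize likelihood engine: jointly optimize the attachment
#'   point along each branch as well as the pendant length (see
#'   [epa_place()]).
#' @param weighting distance-engine weighting, see [apples_place()].
#' @param distance_model distance-engine distance correction (`"jc"` or
#'   `"ml"`), see [apples_place()]; `"ml"` uses `model`/`rate`.
#' @param jplace_path optional path to write the jplace document to.
#' @return list with `results` (per-query placement results, skipped
#'   queries omitted), `report` (data frame `query`, `status`), and
#'   `jplace` (JSON text).
#' @export
place_batch <- function(queries, backbone, ref_aln,
                        engine = c("likelihood", "distance"),
                        model = NULL, rate = 1, optimize = FALSE,
                        weighting = "fm", distance_model = "jc",
                        jplace_path = NULL) {
  engine <- match.arg(engine)
  if (length(queries) == 0L) stop_bp("empty query set")
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop_bp("queries must be named")
  }
  clash <- intersect(names(queries), tree_leaves(backbone))
  if (length(clash)) {
    stop_bp("queries already on the backbone: ", paste(clash, collapse = ", "))
  }
  if (anyNA(backbone$edge_num[-backbone$root])) stop_bp("backbone must be numbered")

  results <- list()
  status <- character(length(queries))
  names(status) <- names(queries)

  if (engine == "likelihood") {
    if (is.null(model)) stop_bp("likelihood engine needs a model")
    qmat <- do.call(rbind, lapply(queries, query_states))
    sites <- which(apply(qmat >= 0L, 2, any))
    if (!length(sites)) stop_bp("no query carries data")
    states <- aln_states(ref_aln, sites)[tree_leaves(backbone), , drop = FALSE]
    contexts <- edge_contexts(backbone, states, model, rate,
                              keep_partials = optimize)
    for (q in names(queries)) {
      res <- epa_place(queries[q], backbone, ref_aln, model, rate = rate,
                       optimize = optimize, contexts = contexts, sites = sites)
      results[[q]] <- res
      status[q] <- "placed"
    }
  } else {
    cols <- seq.int(partition_range(ref_aln, ref_aln$coi)[1],
                    partition_range(ref_aln, ref_aln$coi)[2])
    geom <- apples_context(backbone)
    ref_states <- aln_states(ref_aln, cols)[tree_leaves(backbone), , drop = FALSE]
    qmat <- do.call(rbind, lapply(queries, function(q) {
      match(strsplit(toupper(q), "")[[1]], DNA_STATES)[cols]
    }))
    rownames(qmat) <- names(queries)
    D <- if (distance_model == "ml") {
      if (is.null(model)) stop_bp("distance_model = 'ml' needs a model")
      ml_pairwise_distances(qmat, ref_states, model, rate)
    } else {
      t(vapply(names(queries), function(q) {
        query_leaf_distances(qmat[q, ], ref_states)
      }, numeric(nrow(ref_states))))
    }
    for (q in names(queries)) {
      delta <- D[q, ]
      if (sum(!is.na(delta)) < 4L) {
        warning("query '", q, "' has defined distances to fewer than 4 leaves; skipped",
                call. = FALSE)
        status[q] <- "skipped"
      } else {
        results[[q]] <- apples_result_from_delta(q, geom, delta, weighting)
        status[q] <- "placed"
      }
    }
  }

  report <- data.frame(query = names(queries), status = unname(status))
  jp <- if (length(results)) write_jplace(backbone, results, jplace_path) else NULL
  list(results = results, report = report, jplace = jp)
}
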