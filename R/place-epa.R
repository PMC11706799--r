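# Likelihood-based (EPA-style) phylogenetic placement.

#' @keywords internal
query_states <- function(query_seq) {
  q <- match(strsplit(toupper(query_seq), "")[[1]], DNA_STATES)
  ifelse(is.na(q), -1L, q - 1L)   # 0-based for the scan kernel
}

#' @keywords internal
lwr_from_loglik <- function(loglik) {
  w <- exp(loglik - max(loglik))
  w / sum(w)
}

#' Place a query sequence by maximum likelihood
#'
#' Every backbone edge is evaluated: the query is attached at the midpoint
#' of the branch and its pendant branch length optimized by golden-section
#' search on the attachment log-likelihood. With `optimize = TRUE`
#' (recommended, and the experiment pipeline's default) the `refine_top`
#' best-scoring edges are then re-optimized jointly over the attachment
#' point along the branch and the pendant length. Likelihood weight
#' ratios (LWR) are the per-edge likelihoods normalized over all edges;
#' the best edge is the LWR maximum with ties broken by the lowest edge
#' number.
#'
#' Only alignment columns where the query carries data enter the scan:
#' columns where the query is missing contribute the same factor to every
#' edge and cancel in the weight ratios, so the reported likelihoods are
#' log-likelihoods over the query's informative columns. Every reported
#' log-likelihood is exact for its recorded attachment (grafting the
#' query at the recorded distal/pendant and running full pruning on the
#' same columns reproduces it).
#'
#' @param query_seq single named character string: the query's full-width
#'   alignment row (typically COI columns observed, everything else `-`).
#' @param backbone numbered backbone [ptree()] (see [number_edges()]).
#' @param ref_aln reference [mg_alignment()] covering all backbone leaves.
#' @param model a [gtr_model()].
#' @param rate rate multiplier applied to backbone branch lengths and the
#'   pendant (use the COI partition's rate multiplier when placing COI
#'   queries simulated with one).
#' @param optimize refine the attachment point along the branch for the
#'   top candidates (default `FALSE`: midpoint attachment everywhere).
#' @param refine_top number of best edges refined when `optimize`.
#' @param tol pendant-length optimization tolerance.
#' @param contexts pre-computed [edge_contexts()] (used by
#'   [place_batch()] to share work across queries); when supplied,
#'   `sites` must give the columns the contexts were built on.
#' @param sites column indices the contexts were built on.
#' @return a placement result: list with `query`, `engine =
#'   "likelihood"`, `best` (row 1 of `candidates`) and `candidates`, a
#'   data frame over all edges, best first, with columns `edge_num`,
#'   `score` (log-likelihood), `lwr`, `distal_length`, `pendant_length`.
#' @export
epa_place <- function(query_seq, backbone, ref_aln, model, rate = 1,
                      optimize = FALSE, refine_top = 10L, tol = 1e-6,
                      contexts = NULL, sites = NULL) {
  qname <- names(query_seq)
  if (is.null(qname) || !nzchar(qname)) stop_bp("query sequence must be named")
  if (qname %in% tree_leaves(backbone)) {
    stop_bp("query name '", qname, "' collides with a backbone leaf")
  }
  if (anyNA(backbone$edge_num[-backbone$root])) stop_bp("backbone must be numbered")
  qs_full <- query_states(query_seq)
  if (is.null(contexts)) {
    if (nchar(query_seq) != nchar(ref_aln$seqs[1])) {
      stop_bp("query row width must equal the reference alignment width")
    }
    sites <- which(qs_full >= 0L)
    if (!length(sites)) stop_bp("query carries no data")
    states <- aln_states(ref_aln, sites)[tree_leaves(backbone), , drop = FALSE]
    contexts <- edge_contexts(backbone, states, model, rate,
                              keep_partials = optimize)
  }
  if (optimize && is.null(contexts$Dpack)) {
    stop_bp("optimize = TRUE needs contexts built with keep_partials")
  }
  qs <- qs_full[sites]
  pend_max <- max(2 * tree_height(backbone), 0.1)
  res <- .scan_place_cpp(contexts$pack, contexts$mx,
                         contexts$Dpack %||% numeric(0),
                         contexts$Upack %||% numeric(0),
                         contexts$brlen, qs,
                         model$eig_left, model$eig_right, model$eig_values,
                         model$freqs, model$cat_rates, rate, pend_max, tol,
                         if (optimize) as.integer(refine_top) else 0L)
  loglik <- res[, 1]
  lwr <- lwr_from_loglik(loglik)
  ord <- order(-lwr, contexts$edge_num)
  cand <- data.frame(edge_num = contexts$edge_num[ord], score = loglik[ord],
                     lwr = lwr[ord], distal_length = res[ord, 3],
                     pendant_length = res[ord, 2])
  list(query = qname, engine = "likelihood", candidates = cand,
       best = cand[1, ])
}
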