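# Distance-based (APPLES-style) placement: weighted least-squares fit of
# the query's corrected sequence distances to the backbone's path lengths,
# solved in closed form per edge with box constraints.

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for a mismatch proportion `p` over shared
#' non-gap sites.
#'
#' @param p mismatch proportion(s) in `[0, 0.75)`.
#' @return corrected distance(s); errors when `p >= 0.75` (saturated,
#'   undefined under the model).
#' @export
jc_distance <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 0.75)) {
    stop_bp("mismatch proportion must lie in [0, 0.75)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# per-leaf JC distances of a query against reference rows; NA where
# saturated or no shared sites
#' @keywords internal
query_leaf_distances <- function(qstates, ref_states) {
  shared <- sweep(!is.na(ref_states), 2, !is.na(qstates), "&")
  n_shared <- rowSums(shared)
  mism <- shared & sweep(ref_states, 2, qstates, "!=")
  p <- ifelse(n_shared > 0, rowSums(mism, na.rm = TRUE) / n_shared, NA)
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  d[ok] <- jc_distance(p[ok])
  names(d) <- rownames(ref_states)
  d
}

#' Pairwise maximum-likelihood distances under GTR+Gamma
#'
#' Estimates, for every (query, reference) pair, the branch length
#' maximizing the likelihood of the pair's site pattern counts under the
#' given model. Evaluated on a shared log-spaced grid (vectorized across
#' all pairs) with a quadratic refinement around the grid optimum.
#'
#' @param qstates integer state matrix (queries x sites; `NA` = missing).
#' @param ref_states integer state matrix (references x sites).
#' @param model a [gtr_model()].
#' @param rate rate multiplier (distances come out in tree units when the
#'   sequences evolved at `rate` times the tree's branch lengths).
#' @param t_max upper bound on the estimated distance.
#' @param n_grid grid resolution.
#' @return numeric matrix (queries x references); `NA` where a pair shares
#'   no sites.
#' @export
ml_pairwise_distances <- function(qstates, ref_states, model, rate = 1,
                                  t_max = 10, n_grid = 160L) {
  if (is.null(dim(qstates))) qstates <- matrix(qstates, nrow = 1)
  nq <- nrow(qstates); nl <- nrow(ref_states)
  # pattern counts N[pair, a*4+b] via indicator cross-products
  Qa <- lapply(1:4, function(a) (qstates == a) * 1)
  Rb <- lapply(1:4, function(b) (ref_states == b) * 1)
  for (a in 1:4) Qa[[a]][is.na(Qa[[a]])] <- 0
  for (b in 1:4) Rb[[b]][is.na(Rb[[b]])] <- 0
  N <- matrix(0, nq * nl, 16)
  for (a in 1:4) for (b in 1:4) {
    N[, (a - 1) * 4 + b] <- as.vector(t(Qa[[a]] %*% t(Rb[[b]])))
  }
  # rows: pair (l fastest) -> reshape later; as.vector(t(M)) flattens
  # query-major with reference fastest
  shared <- rowSums(N)
  grid <- exp(seq(log(1e-5), log(t_max), length.out = n_grid))
  k <- length(model$cat_rates)
  LL <- matrix(-Inf, nq * nl, n_grid)
  for (gi in seq_len(n_grid)) {
    P <- Reduce(`+`, lapply(model$cat_rates, function(r) {
      transition_matrix(model, grid[gi] * r * rate)
    })) / k
    # log(pi_a * P_ab), unrolled to the 16-vector matching N's columns
    lp <- as.vector(t(log(pmax(model$freqs * P, 1e-300))))
    LL[, gi] <- N %*% lp
  }
  best <- max.col(LL, ties.method = "first")
  # quadratic (log-scale) refinement around the grid maximum
  d <- grid[best]
  inner <- best > 1L & best < n_grid
  if (any(inner)) {
    i <- which(inner)
    x0 <- log(grid[best[i] - 1L]); x1 <- log(grid[best[i]]); x2 <- log(grid[best[i] + 1L])
    idx <- cbind(i, best[i])
    y0 <- LL[cbind(i, best[i] - 1L)]; y1 <- LL[idx]; y2 <- LL[cbind(i, best[i] + 1L)]
    denom <- (y0 - 2 * y1 + y2)
    shift <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
    shift <- pmin(pmax(shift, -1), 1)
    d[i] <- exp(x1 + shift * (x1 - x0))
  }
  d[shared == 0] <- NA_real_
  out <- matrix(d, nq, nl, byrow = TRUE)
  dimnames(out) <- list(rownames(qstates), rownames(ref_states))
  out
}

# Edge geometry of a numbered backbone: for every edge (ordered by edge
# number) the distances from its child and parent endpoints to every leaf,
# and which leaves sit below the edge.
#' @keywords internal
apples_context <- function(tr) {
  edges <- order(tr$edge_num)
  edges <- edges[!is.na(tr$edge_num[edges])]
  lv <- leaf_nodes(tr)
  labs <- tr$label[lv]
  n <- length(tr$parent)
  depth <- node_depths(tr)
  below <- matrix(FALSE, n, length(lv), dimnames = list(NULL, labs))
  for (v in postorder_nodes(tr)) {
    if (is_leaf(tr, v)) {
      below[v, match(tr$label[v], labs)] <- TRUE
    } else {
      for (ch in tr$children[[v]]) below[v, ] <- below[v, ] | below[ch, ]
    }
  }
  # dist(node, leaf) = depth(node) + depth(leaf) - 2 * depth(mrca); for a
  # leaf below the node the mrca is the node itself
  ndist <- matrix(0, n, length(lv), dimnames = list(NULL, labs))
  order_pre <- rev(postorder_nodes(tr))
  leafdepth <- depth[lv]
  ndist[tr$root, ] <- leafdepth
  for (v in order_pre) {
    if (v == tr$root) next
    p <- tr$parent[v]
    ndist[v, ] <- ndist[p, ] + ifelse(below[v, ], -tr$brlen[v], tr$brlen[v])
  }
  list(edges = edges, edge_num = tr$edge_num[edges], brlen = tr$brlen[edges],
       leaves = labs,
       below = below[edges, , drop = FALSE],
       d_child = ndist[edges, , drop = FALSE],
       d_parent = ndist[tr$parent[edges], , drop = FALSE])
}

# closed-form weighted LS for all edges at once. delta: named leaf
# distances (NA = unusable); returns per-edge x (distal from child end),
# t (pendant), and the weighted residual Q.
#' @keywords internal
apples_solve <- function(ctx, delta, weighting = c("fm", "ols")) {
  weighting <- match.arg(weighting)
  delta <- delta[ctx$leaves]
  use <- !is.na(delta)
  w <- numeric(length(delta))
  w[use] <- if (weighting == "fm") 1 / pmax(delta[use], 1e-8)^2 else 1
  dl <- ifelse(use, delta, 0)

  B <- ctx$below; Dc <- ctx$d_child; Du <- ctx$d_parent; b <- ctx$brlen
  # c0 = B*Dc + (1-B)*(b + Du); g = 2B - 1
  Sw <- sum(w)
  Swg <- 2 * drop(B %*% w) - Sw
  Swd <- sum(w * dl)
  Swgd <- 2 * drop(B %*% (w * dl)) - Swd
  M0 <- B * Dc + (1 - B) * Du
  notB_w <- drop((1 - B) %*% w)
  Swc <- drop(M0 %*% w) + b * notB_w
  Swgc <- drop((B * Dc - (1 - B) * Du) %*% w) - b * notB_w
  M2 <- B * Dc^2 + (1 - B) * Du^2
  Swc2 <- drop(M2 %*% w) + 2 * b * drop(((1 - B) * Du) %*% w) + b^2 * notB_w
  Swdc <- drop((B * Dc) %*% (w * dl)) + drop(((1 - B) * Du) %*% (w * dl)) +
    b * drop((1 - B) %*% (w * dl))

  Swy <- Swd - Swc                # y = delta - c0
  Swgy <- Swgd - Swgc
  Swy2 <- sum(w * dl^2) - 2 * Swdc + Swc2

  qval <- function(t, x) {
    Sw * t^2 + Sw * x^2 + 2 * t * x * Swg - 2 * t * Swy - 2 * x * Swgy + Swy2
  }
  det <- Sw^2 - Swg^2
  xu <- ifelse(det > 0, (Sw * Swgy - Swg * Swy) / det, 0)
  tu <- ifelse(det > 0, (Sw * Swy - Swg * Swgy) / det, Swy / Sw)
  cand_x <- cbind(xu, 0, b, pmin(pmax(Swgy / Sw, 0), b))
  cand_t <- cbind(tu,
                  pmax(0, Swy / Sw),
                  pmax(0, (Swy - Swg * b) / Sw),
                  0)
  feasible <- cbind(xu >= 0 & xu <= b & tu >= 0, TRUE, TRUE, TRUE)
  qs <- matrix(Inf, length(b), 4)
  for (j in 1:4) {
    qs[, j] <- ifelse(feasible[, j], qval(cand_t[, j], cand_x[, j]), Inf)
  }
  pick <- max.col(-qs, ties.method = "first")
  idx <- cbind(seq_along(b), pick)
  list(x = cand_x[idx], t = cand_t[idx], Q = qs[idx])
}

#' Place a query sequence by least-squares distances
#'
#' Computes Jukes-Cantor-corrected distances from the query's COI columns
#' to every backbone leaf, then for every edge solves the closed-form
#' box-constrained weighted least-squares problem for the attachment point
#' (distal) and pendant length. The best edge minimizes the weighted
#' residual; ties break to the lowest edge number. No likelihood weight
#' ratio is produced: distance placement carries no confidence estimate.
#'
#' @param query_seq single named character string, same width as
#'   `ref_aln` (only the COI partition columns are used).
#' @param backbone numbered backbone [ptree()].
#' @param ref_aln reference [mg_alignment()]; distances use its COI
#'   partition.
#' @param weighting `"fm"` (Fitch-Margoliash, `w = 1/d^2`, default) or
#'   `"ols"` (unit weights).
#' @param distance_model `"jc"` (Jukes-Cantor correction, default) or
#'   `"ml"` (maximum-likelihood pairwise distances under a supplied
#'   GTR+Gamma model via [ml_pairwise_distances()]).
#' @param model,rate [gtr_model()] and rate multiplier for
#'   `distance_model = "ml"`.
#' @param min_leaves minimum number of leaves with defined distances
#'   (default 4); queries below this are unplaceable and return `NULL`
#'   with a warning.
#' @param context pre-computed [apples_context()] and COI state matrix
#'   (from [place_batch()]).
#' @return a placement result like [epa_place()]'s, with engine
#'   `"distance"`, `score` the least-squares residual and `lwr` `NA`; or
#'   `NULL` when the query is unplaceable.
#' @export
apples_place <- function(query_seq, backbone, ref_aln, weighting = "fm",
                         distance_model = c("jc", "ml"), model = NULL,
                         rate = 1, min_leaves = 4L, context = NULL) {
  distance_model <- match.arg(distance_model)
  qname <- names(query_seq)
  if (is.null(qname) || !nzchar(qname)) stop_bp("query sequence must be named")
  if (qname %in% tree_leaves(backbone)) {
    stop_bp("query name '", qname, "' collides with a backbone leaf")
  }
  if (is.null(context)) {
    cols <- seq.int(partition_range(ref_aln, ref_aln$coi)[1],
                    partition_range(ref_aln, ref_aln$coi)[2])
    context <- list(geom = apples_context(backbone),
                    ref_states = aln_states(ref_aln, cols)[tree_leaves(backbone), ,
                                                           drop = FALSE],
                    cols = cols)
  }
  qs <- match(strsplit(toupper(query_seq), "")[[1]], DNA_STATES)[context$cols]
  delta <- if (distance_model == "ml") {
    if (is.null(model)) stop_bp("distance_model = 'ml' needs a model")
    drop(ml_pairwise_distances(matrix(qs, 1), context$ref_states, model, rate))
  } else {
    query_leaf_distances(qs, context$ref_states)
  }
  if (sum(!is.na(delta)) < min_leaves) {
    warning("query '", qname, "' has defined distances to fewer than ",
            min_leaves, " leaves; skipped", call. = FALSE)
    return(NULL)
  }
  apples_result_from_delta(qname, context$geom, delta, weighting)
}

#' @keywords internal
apples_result_from_delta <- function(qname, geom, delta, weighting) {
  sol <- apples_solve(geom, delta, weighting)
  ord <- order(sol$Q, geom$edge_num)
  cand <- data.frame(edge_num = geom$edge_num[ord],
                     score = sol$Q[ord], lwr = NA_real_,
                     distal_length = sol$x[ord], pendant_length = sol$t[ord])
  list(query = qname, engine = "distance", candidates = cand, best = cand[1, ])
}
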