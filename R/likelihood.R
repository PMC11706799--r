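# Felsenstein pruning likelihood under GTR+Gamma, with the two-pass
# (down/up) conditional vectors used by the placement engine. Partials are
# rescaled per node and site to avoid underflow on large trees.

# indicator partial for a tip: unit column for an observed state, ones for
# missing data
tip_partial <- function(states_row) {
  S <- length(states_row)
  L <- matrix(1, 4, S)
  obs <- which(!is.na(states_row))
  if (length(obs)) {
    L[, obs] <- 0
    L[cbind(states_row[obs], obs)] <- 1
  }
  L
}

# down-pass conditionals for one gamma category.
# returns list(D = per-node 4xS partials, logsc = per-node length-S log
# scalers, P = per-node transition matrices)
#' @keywords internal
down_pass <- function(tr, states, cat_rate, model, rate) {
  n <- length(tr$parent)
  S <- ncol(states)
  D <- vector("list", n); logsc <- vector("list", n); P <- vector("list", n)
  for (v in postorder_nodes(tr)) {
    if (v != tr$root) {
      P[[v]] <- transition_matrix(model, tr$brlen[v] * rate * cat_rate)
    }
    if (is_leaf(tr, v)) {
      D[[v]] <- tip_partial(states[tr$label[v], ])
      logsc[[v]] <- numeric(S)
    } else {
      M <- matrix(1, 4, S); sc <- numeric(S)
      for (ch in tr$children[[v]]) {
        M <- M * (P[[ch]] %*% D[[ch]])
        sc <- sc + logsc[[ch]]
      }
      mx <- apply(M, 2, max)
      mx[mx == 0] <- 1
      D[[v]] <- sweep(M, 2, mx, "/")
      logsc[[v]] <- sc + log(mx)
    }
  }
  list(D = D, logsc = logsc, P = P)
}

# up-pass: for each non-root node v, the conditional likelihood of all data
# outside subtree(v), as a function of the state at v's parent end of its
# branch. Uses reversibility (stationary start) so transitions can be read
# in either direction.
#' @keywords internal
up_pass <- function(tr, dp) {
  n <- length(tr$parent)
  S <- ncol(dp$D[[tr$root]])
  U <- vector("list", n); logscU <- vector("list", n)
  for (v in rev(postorder_nodes(tr))) {   # preorder
    if (v == tr$root) next
    p <- tr$parent[v]
    M <- matrix(1, 4, S); sc <- numeric(S)
    if (p != tr$root) {
      M <- dp$P[[p]] %*% U[[p]]
      sc <- logscU[[p]]
    }
    for (s in setdiff(tr$children[[p]], v)) {
      M <- M * (dp$P[[s]] %*% dp$D[[s]])
      sc <- sc + dp$logsc[[s]]
    }
    mx <- apply(M, 2, max)
    mx[mx == 0] <- 1
    U[[v]] <- sweep(M, 2, mx, "/")
    logscU[[v]] <- sc + log(mx)
  }
  list(U = U, logsc = logscU)
}

#' Tree log-likelihood under GTR+Gamma
#'
#' Felsenstein pruning, with gamma site categories averaged with equal
#' weights and `-` treated as missing data.
#'
#' @param tr a [ptree()] whose leaves are all present in `aln`.
#' @param aln an [mg_alignment()] (or a named integer state matrix).
#' @param model a [gtr_model()].
#' @param rate overall rate multiplier applied to all branch lengths.
#' @param cols optional column subset.
#' @return the log-likelihood (a scalar).
#' @export
tree_loglikelihood <- function(tr, aln, model, rate = 1, cols = NULL) {
  states <- if (inherits(aln, "mg_alignment")) aln_states(aln, cols) else aln
  if (is.null(dim(states)) || ncol(states) == 0L) stop_bp("zero-length alignment")
  miss <- setdiff(tree_leaves(tr), rownames(states))
  if (length(miss)) stop_bp("alignment missing leaves: ", paste(miss, collapse = ", "))
  k <- length(model$cat_rates)
  S <- ncol(states)
  site_log <- matrix(NA_real_, k, S)
  for (cc in seq_len(k)) {
    dp <- down_pass(tr, states, model$cat_rates[cc], model, rate)
    lik <- colSums(model$freqs * dp$D[[tr$root]])
    site_log[cc, ] <- log(lik) + dp$logsc[[tr$root]]
  }
  mx <- apply(site_log, 2, max)
  sum(log(colMeans(exp(sweep(site_log, 2, mx, "-")))) + mx)
}

# Per-edge attachment contexts for the placement scan: for edge e (child
# v) at attachment distance `distal` from the child end, the vector
# ctx[x, s] = pi_x * (P(distal) D_v)[x, s] * (P(b - distal) U_v)[x, s],
# with per-site log scalers. Summing ctx over states and multiplying in a
# pendant message of ones recovers the backbone likelihood, which is the
# identity the scan relies on.
#' @keywords internal
edge_contexts <- function(tr, states, model, rate = 1, distal_frac = 0.5,
                          keep_partials = FALSE) {
  edges <- order(tr$edge_num)                # node indices sorted by edge number
  edges <- edges[!is.na(tr$edge_num[edges])]
  k <- length(model$cat_rates)
  S <- ncol(states)
  E <- length(edges)
  ctx <- array(0, c(4, S, k, E))
  sc <- array(0, c(S, k, E))
  Dv <- if (keep_partials) array(0, c(4, S, k, E))
  Uv <- if (keep_partials) array(0, c(4, S, k, E))
  for (cc in seq_len(k)) {
    dp <- down_pass(tr, states, model$cat_rates[cc], model, rate)
    up <- up_pass(tr, dp)
    for (j in seq_len(E)) {
      v <- edges[j]
      a <- tr$brlen[v] * distal_frac
      Pa <- transition_matrix(model, a * rate * model$cat_rates[cc])
      Pb <- transition_matrix(model, (tr$brlen[v] - a) * rate * model$cat_rates[cc])
      ctx[, , cc, j] <- model$freqs * ((Pa %*% dp$D[[v]]) * (Pb %*% up$U[[v]]))
      sc[, cc, j] <- dp$logsc[[v]] + up$logsc[[v]]
      if (keep_partials) {
        Dv[, , cc, j] <- dp$D[[v]]
        Uv[, , cc, j] <- up$U[[v]]
      }
    }
  }
  # pre-weighted, site-major packing for the scan kernel: fold the
  # per-site category weights exp(sc - max)/k into the context (and the
  # down conditionals), so the per-query hot loop reads contiguous memory
  # and never recomputes scalers
  mx <- apply(sc, c(1, 3), max)                       # S x E
  mxk <- aperm(array(mx, c(S, E, k)), c(1, 3, 2))     # S x k x E
  w <- exp(sc - mxk) / k
  wx <- aperm(array(rep(w, each = 4), c(4, S, k, E)), c(1, 3, 2, 4))
  pack <- aperm(ctx, c(1, 3, 2, 4)) * wx
  dim(pack) <- c(4 * k, S, E)
  Dpack <- NULL
  if (keep_partials) {
    Dpack <- aperm(Dv, c(1, 3, 2, 4)) * wx
    dim(Dpack) <- c(4 * k, S, E)
    Uv <- aperm(Uv, c(1, 3, 2, 4))
    dim(Uv) <- c(4 * k, S, E)
  }
  list(ctx = ctx, logsc = sc, pack = pack, mx = mx,
       Dpack = Dpack, Upack = if (keep_partials) Uv else NULL,
       edges = edges,
       edge_num = tr$edge_num[edges], brlen = tr$brlen[edges])
}
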