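# GTR+Gamma substitution model.
#
# States are ordered A, C, G, T. Exchangeability rates follow the usual
# (AC, AG, AT, CG, CT, GT) order and are normalized so GT = 1. The rate
# matrix is rescaled so one unit of branch length equals one expected
# substitution per site at stationarity; discrete-Gamma category rates
# (equal-probability categories, mean-of-interval rates) have mean 1.

DNA_STATES <- c("A", "C", "G", "T")

#' Construct a GTR+Gamma model
#'
#' @param rates six positive exchangeability rates in (AC, AG, AT, CG, CT,
#'   GT) order; internally normalized so the last equals 1.
#' @param freqs four positive stationary base frequencies (A, C, G, T),
#'   summing to 1.
#' @param alpha gamma shape for among-site rate heterogeneity (`Inf` for
#'   rate homogeneity).
#' @param k number of discrete gamma categories (default 4).
#' @return an object of class `gtr_model` carrying the scaled rate matrix
#'   `Q`, its symmetric eigendecomposition, and the `k` category rates.
#' @examples
#' m <- gtr_model(c(1, 4, 1, 1, 8, 1), rep(0.25, 4), alpha = 0.5)
#' @export
gtr_model <- function(rates, freqs, alpha = Inf, k = 4L) {
  if (length(rates) != 6L || any(rates <= 0)) {
    stop_bp("rates must be 6 positive exchangeabilities")
  }
  if (length(freqs) != 4L || any(freqs <= 0)) {
    stop_bp("freqs must be 4 positive base frequencies")
  }
  if (abs(sum(freqs) - 1) > 1e-8) stop_bp("base frequencies must sum to 1")
  if (alpha <= 0) stop_bp("alpha must be positive")
  rates <- rates / rates[6]
  freqs <- freqs / sum(freqs)

  R <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  # lower.tri fill order is (2,1),(3,1),(4,1),(3,2),(4,2),(4,3) =
  # (CA, GA, TA, GC, TC, TG), i.e. exactly (AC, AG, AT, CG, CT, GT)
  R[lower.tri(R)] <- rates
  R <- R + t(R)
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale

  # symmetric decomposition: B = D^{1/2} Q D^{-1/2}
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)

  cat_rates <- if (is.finite(alpha)) discrete_gamma_rates(alpha, k) else rep(1, k)
  structure(
    list(rates = rates, freqs = freqs, alpha = alpha, k = as.integer(k),
         Q = Q, eig_values = eig$values,
         eig_left = diag(1 / s) %*% eig$vectors,     # P(t) = L exp(vt) R
         eig_right = t(eig$vectors) %*% diag(s),
         cat_rates = cat_rates),
    class = "gtr_model")
}

#' Discrete gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretization for among-site rate
#' heterogeneity.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @return numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for the model's scaled generator.
#'
#' @param model a [gtr_model()].
#' @param t branch length (expected substitutions per site, >= 0).
#' @return a 4x4 stochastic matrix over A, C, G, T.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop_bp("branch length must be non-negative")
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Jukes-Cantor model shortcut
#'
#' @param alpha gamma shape (default `Inf`: homogeneous rates).
#' @param k gamma categories.
#' @return a [gtr_model()] with equal rates and frequencies.
#' @export
jc_model <- function(alpha = Inf, k = 4L) {
  gtr_model(rep(1, 6), rep(0.25, 4), alpha = alpha, k = k)
}
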