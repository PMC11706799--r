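# Aligned rank transform (ART) factorial analysis for the accuracy
# metrics: align the response for one effect at a time (remove every other
# estimated effect), mid-rank the aligned values, then run a standard
# fixed-effects ANOVA on the ranks and report only the aligned effect.
# The repeated-measures structure of the design (the same replicate's
# nested subsamples across completeness levels) is approximated by an
# additive replicate block term.

art_effects <- function(table) {
  effs <- c("level", "strategy")
  effs <- effs[vapply(effs, function(e) length(unique(table[[e]])) > 1L, TRUE)]
  if (length(effs) == 2L) c(effs, "level:strategy") else effs
}

check_design <- function(table) {
  need <- c("replicate", "level", "strategy", "value")
  if (!all(need %in% names(table))) {
    stop_bp("design table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(table$value))) stop_bp("metric values must be finite")
  table$replicate <- factor(table$replicate)
  table$level <- factor(table$level)
  table$strategy <- factor(table$strategy)
  table
}

# effect estimates from cell/marginal means; replicate enters as an
# additive block
art_components <- function(table) {
  y <- table$value
  grand <- mean(y)
  m_level <- tapply(y, table$level, mean)
  m_strat <- tapply(y, table$strategy, mean)
  m_cell <- tapply(y, list(table$level, table$strategy), mean)
  m_rep <- tapply(y, table$replicate, mean)
  a <- m_level[table$level] - grand
  b <- m_strat[table$strategy] - grand
  cell <- m_cell[cbind(table$level, table$strategy)]
  ab <- cell - grand - a - b
  blk <- m_rep[table$replicate] - grand
  resid <- y - cell - blk
  list(grand = grand, a = unname(a), b = unname(b), ab = unname(ab),
       blk = unname(blk), resid = unname(resid))
}

#' Align and rank a design table for one effect
#'
#' Subtracts every estimated effect except the effect of interest from
#' each observation (leaving residual + that effect's estimate), then
#' mid-ranks the aligned values ascending from 1. Aligned values sum to
#' zero by construction.
#'
#' @param table data frame with columns `replicate`, `level`, `strategy`,
#'   `value` (the metric, in percent).
#' @param effect `"level"`, `"strategy"`, or `"level:strategy"`.
#' @return the table with columns `aligned` and `rank` appended.
#' @export
align_and_rank <- function(table, effect = c("level", "strategy",
                                             "level:strategy")) {
  effect <- match.arg(effect)
  table <- check_design(table)
  for (f in c("level", "strategy")) {
    if (length(unique(table[[f]])) < 2L && grepl(f, effect, fixed = TRUE)) {
      stop_bp("effect '", effect, "' needs at least 2 levels of ", f)
    }
  }
  cellcount <- table(table$level, table$strategy)
  if (any(cellcount < 2L)) stop_bp("every design cell needs at least 2 observations")
  comp <- art_components(table)
  est <- switch(effect, level = comp$a, strategy = comp$b,
                `level:strategy` = comp$ab)
  table$aligned <- comp$resid + est
  table$rank <- rank(table$aligned, ties.method = "average")
  table
}

#' ART factorial ANOVA
#'
#' For each estimable effect (completeness level, sampling strategy, and
#' their interaction), the response is aligned and ranked for that effect
#' and a fixed-effects ANOVA (`rank ~ level * strategy` plus an optional
#' replicate block) is fitted; only the matching effect's F and p are
#' reported.
#'
#' @param table design table, see [align_and_rank()].
#' @param block include the additive replicate block term (default
#'   `TRUE`).
#' @param alpha significance level recorded on the result (default 0.05).
#' @return data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`, `alpha`.
#' @export
art_anova <- function(table, block = TRUE, alpha = 0.05) {
  table <- check_design(table)
  effs <- art_effects(table)
  if (!length(effs)) stop_bp("no effect has 2 or more levels")
  out <- lapply(effs, function(e) {
    tab <- align_and_rank(table, e)
    rhs <- paste(setdiff(unique(c(sub(":.*", "", effs), effs)), ""), collapse = " + ")
    form <- stats::as.formula(paste("rank ~", rhs,
                                    if (block && nlevels(tab$replicate) > 1L)
                                      "+ replicate" else ""))
    fit <- stats::lm(form, data = tab)
    if (any(is.na(stats::coef(fit)))) {
      stop_bp("rank-deficient design: aliased term in '", e, "'")
    }
    an <- stats::anova(fit)
    row <- match(gsub(" ", "", e), gsub(" ", "", rownames(an)))
    data.frame(effect = e, df1 = an$Df[row], df2 = an$Df[nrow(an)],
               F = an$`F value`[row], p = an$`Pr(>F)`[row], alpha = alpha)
  })
  do.call(rbind, out)
}

#' ART pairwise contrasts (ART-C style)
#'
#' Aligns and ranks for the chosen effect (optionally within one level of
#' the other factor), fits the linear rank model used by [art_anova()],
#' and tests all pairwise differences of the effect's level means with
#' pooled-variance t statistics (`SE = sqrt(MSE * (1/n1 + 1/n2))`,
#' residual degrees of freedom). P-values are Holm-adjusted by default.
#'
#' @param table design table.
#' @param effect `"level"` or `"strategy"`.
#' @param within optional single level of the other factor to condition
#'   on.
#' @param adjust `"holm"` (default) or `"none"`.
#' @param block include the replicate block term.
#' @return data frame: `group1`, `group2`, `estimate` (rank-mean
#'   difference), `t`, `df`, `p`, `p_adj`.
#' @export
art_contrasts <- function(table, effect = c("level", "strategy"),
                          within = NULL, adjust = c("holm", "none"),
                          block = TRUE) {
  effect <- match.arg(effect)
  adjust <- match.arg(adjust)
  table <- check_design(table)
  other <- setdiff(c("level", "strategy"), effect)
  if (!is.null(within)) {
    table <- table[table[[other]] == within, , drop = FALSE]
    if (nrow(table) == 0L) stop_bp("no rows with ", other, " == ", within)
    table <- check_design(table)   # refresh factor levels
    table[] <- lapply(table, function(x) if (is.factor(x)) droplevels(x) else x)
  }
  grp <- table[[effect]]
  if (nlevels(grp) < 2L) stop_bp("effect needs at least 2 levels")
  if (any(table(grp) < 2L)) stop_bp("every level needs at least 2 observations")

  tab <- if (nlevels(factor(table[[other]])) > 1L) {
    align_and_rank(table, effect)
  } else {
    # single-factor slice: alignment for the effect reduces to removing
    # the block effect
    t2 <- table
    comp_blk <- tapply(t2$value, t2$replicate, mean) - mean(t2$value)
    t2$aligned <- t2$value - unname(comp_blk[t2$replicate])
    t2$aligned <- t2$aligned - mean(t2$aligned)
    t2$rank <- rank(t2$aligned, ties.method = "average")
    t2
  }
  rhs <- c(effect, if (nlevels(factor(tab[[other]])) > 1L) c(other, paste0(effect, ":", other)),
           if (block && nlevels(tab$replicate) > 1L) "replicate")
  fit <- stats::lm(stats::as.formula(paste("rank ~", paste(rhs, collapse = " + "))),
                   data = tab)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  dfres <- stats::df.residual(fit)
  means <- tapply(tab$rank, tab[[effect]], mean)
  ns <- table(tab[[effect]])
  lv <- names(means)
  pairs <- utils::combn(lv, 2)
  est <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(tstat), dfres)
  p[se == 0] <- 1
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             estimate = unname(est), t = unname(tstat), df = dfres,
             p = unname(p),
             p_adj = stats::p.adjust(unname(p), method = adjust))
}
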