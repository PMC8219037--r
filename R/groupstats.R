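# Stage-wise descriptor comparison: Kruskal-Wallis one-way ANOVA on ranks
# (tie-corrected, chi-square p with df = g - 1) followed by Dunn's
# all-pairs post hoc on the pooled ranks, plus per-stage summary tables.
# The chi-square approximation is advisory for group sizes n >= 5.

#' Kruskal-Wallis one-way ANOVA on ranks
#'
#' Tie-corrected H statistic with mid-ranks and chi-square p-value
#' (df = g - 1). Degenerate input with all values identical returns
#' H = 0, p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, total N >= 3)
#' @return list with `H`, `df`, `p_value`
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 1L))) stop("each group needs n >= 1")
  pooled <- unlist(groups)
  if (length(pooled) < 3) stop("total N must be >= 3")
  if (length(unique(pooled)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn's all-pairs post hoc comparison of mean ranks
#'
#' For groups i, j:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with the tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tie
#' groups of size t. Two-sided normal p-values are reported unadjusted and
#' Bonferroni-adjusted (the conservative, reproducible choice; both
#' columns are emitted since reference software rarely documents which it
#' applies).
#'
#' @param groups list of numeric samples (named or numbered)
#' @param alpha significance level for the flag column (default 0.05)
#' @return data.frame with one row per pair: `group_i`, `group_j`, `z`,
#'   `p_unadjusted`, `p_bonferroni`, `significant`
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 2) stop("need at least 2 groups")
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_len(g))
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  pooled <- unlist(groups)
  rk <- rank(pooled)  # mid-ranks
  idx <- rep(seq_len(g), n)
  rbar <- tapply(rk, idx, mean)
  tie_sizes <- table(pooled)
  Tcorr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - Tcorr
  rows <- list()
  for (i in seq_len(g - 1)) {
    for (j in seq((i + 1), g)) {
      se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
      z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
      p <- 2 * pnorm(-abs(z))
      rows[[length(rows) + 1]] <- data.frame(
        group_i = nms[i], group_j = nms[j], z = z, p_unadjusted = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_unadjusted * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}

#' Stage-wise descriptor summaries with significance flags
#'
#' Per stage and descriptor: n, mean, sd, median, quartiles and 1.5 IQR
#' whisker bounds; plus, per descriptor, the all-pairs Dunn table (gated
#' on a Kruskal-Wallis omnibus) across stages.
#'
#' @param records data.frame of per-cell descriptor records
#' @param stage name of the grouping column (default `"stage"`)
#' @param descriptors descriptor columns to summarize; default = all
#'   numeric columns except the stage and label columns
#' @param alpha significance level
#' @return list with `summary` (data.frame) and `pairwise` (data.frame)
#' @export
summarize_stages <- function(records, stage = "stage", descriptors = NULL,
                             alpha = 0.05) {
  if (!stage %in% names(records)) stop("no column '", stage, "' in records")
  stages <- unique(records[[stage]])
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                           c(stage, "label"))
  }
  summ <- list()
  pair <- list()
  for (d in descriptors) {
    for (st in stages) {
      v <- records[[d]][records[[stage]] == st]
      v <- v[is.finite(v)]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      summ[[length(summ) + 1]] <- data.frame(
        stage = st, descriptor = d, n = length(v),
        mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
        median = q[2], q25 = q[1], q75 = q[3],
        whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
    }
    if (length(stages) >= 2) {
      glist <- split(records[[d]], records[[stage]])
      glist <- lapply(glist, function(v) v[is.finite(v)])
      if (all(vapply(glist, length, 1L) >= 1) &&
          length(unique(unlist(glist))) > 1) {
        dn <- dunn_posthoc(glist, alpha = alpha)
        dn$descriptor <- d
        pair[[length(pair) + 1]] <- dn
      }
    }
  }
  list(summary = do.call(rbind, summ),
       pairwise = if (length(pair)) do.call(rbind, pair) else
         data.frame(group_i = character(0), group_j = character(0),
                    z = numeric(0), p_unadjusted = numeric(0),
                    p_bonferroni = numeric(0), significant = logical(0),
                    descriptor = character(0)))
}
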