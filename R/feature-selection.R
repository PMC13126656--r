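#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (delegated to [stats::t.test()]).
#' Degenerate inputs are resolved deterministically: two constant groups
#' with equal means give `t = 0, p = 1`; with unequal means,
#' `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2, `NA`s
#'   dropped.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  check_that(length(a) >= 2, "group_a", "needs >= 2 finite values")
  check_that(length(b) >= 2, "group_b", "needs >= 2 finite values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Screen and de-correlate features
#'
#' Ranks features by the two-sided Welch p-value of their class contrast
#' (pairwise-complete observations), keeps those significant at
#' `alpha`, and greedily accepts them in order of ascending p (ties broken
#' by feature name) provided the absolute Pearson correlation with every
#' already-accepted feature stays below `corr_threshold`, stopping at `k`.
#' No multiple-testing correction is applied: the screen reports raw Welch
#' p-values.
#'
#' @param table data.frame with numeric feature columns and a `label`
#'   column with two levels (reference level first).
#' @param k maximum number of features to retain.
#' @param corr_threshold absolute-correlation acceptance bound in
#'   `(0, 1]`.
#' @param alpha screening significance level.
#' @return An object of class `selection_result`: `stats` (per-feature
#'   data.frame `feature`, `t`, `df`, `p`), `correlation` (matrix over
#'   screened features), `selected` (character). Fewer than `k`
#'   acceptable features triggers a warning, an empty screen returns an
#'   empty selection with a warning.
#' @export
select_features <- function(table, k = 5, corr_threshold = 0.5,
                            alpha = 0.05) {
  check_that(is.data.frame(table) && "label" %in% names(table), "table",
             "must be a data.frame with a `label` column")
  check_scalar_num(k, "k", lower = 1)
  check_scalar_num(corr_threshold, "corr_threshold", lower = 1e-12, upper = 1)
  check_scalar_num(alpha, "alpha", lower = 1e-12, upper = 1)
  lab <- as.factor(table$label)
  check_that(nlevels(lab) == 2, "label", "must have exactly two levels")
  feats <- setdiff(names(table), "label")
  feats <- feats[vapply(table[feats], is.numeric, logical(1))]
  check_that(length(feats) >= 1, "table", "needs at least one numeric feature")

  stats_df <- do.call(rbind, lapply(feats, function(f) {
    x <- table[[f]]
    a <- x[lab == levels(lab)[1L]]
    b <- x[lab == levels(lab)[2L]]
    if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2)
      return(data.frame(feature = f, t = NA_real_, df = NA_real_,
                        p = NA_real_))
    w <- welch_t(a, b)
    data.frame(feature = f, t = w$t, df = w$df, p = w$p)
  }))

  cmat <- suppressWarnings(
    cor(as.matrix(table[feats]), use = "pairwise.complete.obs"))
  cand <- stats_df[!is.na(stats_df$p) & stats_df$p < alpha, , drop = FALSE]
  cand <- cand[order(cand$p, cand$feature), , drop = FALSE]

  selected <- character(0)
  for (f in cand$feature) {
    if (length(selected) >= k) break
    r <- abs(cmat[f, selected])
    r[is.na(r)] <- 0  # no overlapping observations: treat as uncorrelated
    if (all(r < corr_threshold)) selected <- c(selected, f)
  }
  if (length(selected) == 0L)
    warning("no feature passed screening; selection is empty")
  else if (length(selected) < k)
    warning(sprintf("only %d of %d requested features selected",
                    length(selected), k))
  structure(list(stats = stats_df, correlation = cmat, selected = selected,
                 k = k, corr_threshold = corr_threshold, alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features selected (|r| < %g):\n",
              length(x$selected), x$k, x$corr_threshold))
  if (length(x$selected)) {
    s <- x$stats[match(x$selected, x$stats$feature), ]
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-36s t = %7.3f  p = %.3g\n",
                  s$feature[i], s$t[i], s$p[i]))
  }
  invisible(x)
}
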