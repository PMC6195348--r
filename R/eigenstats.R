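#' Fit the control behavioral space ("eigenbehaviors")
#'
#' Z-scores the control group's metrics by the controls' own mean and
#' standard deviation, then performs PCA (singular value decomposition of
#' the centered z-scored matrix). The resulting components — linear
#' combinations of behavioral metrics fitted on control animals — define the
#' basis onto which experimental groups are projected. Loadings are
#' sign-fixed so each component's largest-magnitude loading is positive.
#'
#' @param controls a [metric_matrix()] (or plain data frame) of control mice.
#' @param metrics metric subset to analyze; default every metric column.
#'   Mice with any missing value in the subset must be removed beforehand
#'   (missing values are an error here).
#' @return an object of class `eigen_space`: `metrics`, `center`, `scale`
#'   (control mean/SD per metric), `loadings` (p x p orthonormal matrix,
#'   columns PC1..PCp ordered by descending control variance), `var`
#'   (control variance per component), `n_controls`.
#' @export
fit_control_space <- function(controls, metrics = NULL) {
  if (is.null(metrics))
    metrics <- attr(controls, "metrics") %||%
      setdiff(names(controls), c("mouse", "group"))
  X <- as.matrix(as.data.frame(controls)[metrics])
  if (anyNA(X))
    stop2("controls contain missing values in the requested metric subset; ",
          "drop incomplete mice first")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L)
    stop2("need at least ", p + 1L, " control mice for ", p, " metrics")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (any(scl == 0))
    stop2("zero-variance metric(s) in controls: ",
          paste(metrics[scl == 0], collapse = ", "))
  Z <- scale(X, center = ctr, scale = scl)
  sv <- svd(Z)
  loadings <- sv$v
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(p)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  dimnames(loadings) <- list(metrics, paste0("PC", seq_len(p)))
  structure(list(metrics = metrics, center = ctr, scale = scl,
                 loadings = loadings, var = sv$d^2 / (n - 1L),
                 n_controls = n),
            class = "eigen_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eigen_space <- function(x, ...) {
  cat("Control behavioral space:", length(x$metrics), "metrics,",
      x$n_controls, "control mice\n")
  vf <- x$var / sum(x$var)
  cat("  control variance fractions:",
      paste0(names(vf) <- NULL, sprintf("%.2f", vf[seq_len(min(5, length(vf)))]),
             collapse = " "), if (length(vf) > 5) "...", "\n")
  invisible(x)
}

#' @export
plot.eigen_space <- function(x, ...) {
  barplot(x$var / sum(x$var), names.arg = colnames(x$loadings),
          ylab = "control variance fraction", las = 2, ...)
  invisible(x)
}

#' Project a group onto the control behavioral space
#'
#' Group metrics are z-scored with the CONTROL mean and SD, then multiplied
#' by the control loadings. Per component, the projection reports the
#' group's variance fraction (variance of group scores on that component
#' over total group score variance across all components) and the mean
#' difference from controls (control scores have mean zero by construction).
#'
#' @param group a [metric_matrix()] or data frame of one group's mice.
#' @param space an `eigen_space` from [fit_control_space()]; the group must
#'   contain the same metrics.
#' @return an object of class `group_projection`: `scores` (mice x
#'   components), `var_fraction`, `mean_diff`, `n`.
#' @export
project_group <- function(group, space) {
  df <- as.data.frame(group)
  if (!all(space$metrics %in% names(df)))
    stop2("group lacks metrics: ",
          paste(setdiff(space$metrics, names(df)), collapse = ", "))
  X <- as.matrix(df[space$metrics])
  if (anyNA(X)) stop2("group contains missing values; drop incomplete mice")
  Z <- scale(X, center = space$center, scale = space$scale)
  scores <- Z %*% space$loadings
  v <- apply(scores, 2L, var)
  structure(list(scores = scores, var_fraction = v / sum(v),
                 mean_diff = colMeans(scores), n = nrow(scores)),
            class = "group_projection")
}

#' @export
print.group_projection <- function(x, ...) {
  cat("Group projection:", x$n, "mice on", ncol(x$scores), "components\n")
  print(round(rbind(mean_diff = x$mean_diff,
                    var_fraction = x$var_fraction), 3L))
  invisible(x)
}

#' Select high-contribution components
#'
#' A component is a high-contribution component for a group when it meets
#' all three criteria: the group's mean score differs from the controls' by
#' at least `mean_thresh` (in component-score units, i.e. units of the
#' control-normalized data), the component accounts for at least
#' `var_thresh` of the group's total behavioral variance, and a two-sample
#' two-tailed t-test of group versus control scores reaches `p < alpha`.
#'
#' @param gp a [group_projection()] of the experimental group.
#' @param control_scores control score matrix, e.g.
#'   `project_group(controls, space)$scores`.
#' @param mean_thresh minimum absolute mean difference (score units).
#' @param var_thresh minimum group variance fraction.
#' @param alpha t-test significance level.
#' @return data frame, one row per component: `component`, `mean_diff`,
#'   `var_fraction`, `p`, `selected`.
#' @export
high_contribution_pcs <- function(gp, control_scores, mean_thresh = 0.01,
                                  var_thresh = 0.10, alpha = 0.05) {
  if (gp$n < 2L || nrow(control_scores) < 2L)
    stop2("need at least 2 mice per group")
  p <- ncol(gp$scores)
  pv <- vapply(seq_len(p), function(k)
    t.test(gp$scores[, k], control_scores[, k],
           alternative = "two.sided")$p.value, numeric(1L))
  out <- data.frame(component = colnames(gp$scores) %||% paste0("PC", 1:p),
                    mean_diff = unname(gp$mean_diff),
                    var_fraction = unname(gp$var_fraction), p = pv,
                    stringsAsFactors = FALSE)
  out$selected <- abs(out$mean_diff) >= mean_thresh &
    out$var_fraction >= var_thresh & out$p < alpha
  out
}

#' Variance-ratio (F) test of a group against controls
#'
#' `F = s2_group / s2_control` with `(n_g - 1, n_c - 1)` degrees of freedom
#' and a two-sided p-value from the F distribution.
#'
#' @param group,control numeric vectors (n >= 2 each).
#' @return list with `F`, `df` and `p`.
#' @export
variance_ratio_test <- function(group, control) {
  group <- group[!is.na(group)]; control <- control[!is.na(control)]
  if (length(group) < 2L || length(control) < 2L)
    stop2("need n >= 2 per sample")
  if (var(control) == 0) stop2("control variance is zero")
  f <- var(group) / var(control)
  df <- c(length(group) - 1L, length(control) - 1L)
  p <- 2 * min(pf(f, df[1L], df[2L]), 1 - pf(f, df[1L], df[2L]))
  list(F = f, df = df, p = min(p, 1))
}

#' Cohen's d effect size with pooled SD
#'
#' `(mean_A - mean_B) / s_pooled`, the pooled standard deviation computed
#' with `n_A + n_B - 2` degrees of freedom.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return the effect size in pooled-SD units; `NA` when the pooled SD is
#'   zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop2("need n >= 2 per sample")
  sp2 <- ((length(a) - 1L) * var(a) + (length(b) - 1L) * var(b)) /
    (length(a) + length(b) - 2L)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

# All permutations of 1..n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman correlation with permutation p-value
#'
#' Spearman's rank correlation with a two-sided permutation p-value: exact
#' enumeration over all `n!` rank orders when `n <= exact_n_max`, otherwise
#' Monte-Carlo permutation with `n_mc` draws (p = (1 + k) / (1 + n_mc)).
#' Because the rank marginals are fixed under permutation, the permutation
#' distribution of rho is computed from the cross-products of ranks.
#'
#' @param x,y numeric vectors of equal length (n >= 4 complete pairs).
#' @param n_mc Monte-Carlo permutation count.
#' @param exact_n_max largest n for exhaustive enumeration.
#' @return list with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"monte-carlo"`).
#' @export
spearman_perm <- function(x, y, n_mc = 1e5, exact_n_max = 9L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop2("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop2("constant input: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  # |rho| is monotone in |sum(rx * ry_perm) - n * mean(rx) * mean(ry)|
  cross <- function(perm_mat) perm_mat %*% rx
  center <- n * mean(rx) * mean(ry)
  obs <- abs(sum(rx * ry) - center)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    stat <- abs(matrix(ry[perms], nrow(perms), n) %*% rx - center)
    p <- mean(stat >= obs - 1e-9)
    method <- "exact"
  } else {
    stat <- vapply(seq_len(n_mc), function(i)
      abs(sum(rx * ry[sample.int(n)]) - center), numeric(1L))
    p <- (1 + sum(stat >= obs - 1e-9)) / (1 + n_mc)
    method <- "monte-carlo"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Spearman correlation with t-test p-value
#'
#' The large-sample alternative: `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' against a t distribution with `n - 2` df, two-sided.
#'
#' @inheritParams spearman_perm
#' @return list with `rho`, `p`, `n`, `method = "t-test"`.
#' @export
spearman_ttest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop2("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop2("constant input: correlation undefined")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else
    2 * pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2, lower.tail = FALSE)
  list(rho = rho, p = p, n = n, method = "t-test")
}

#' Pairwise Spearman correlation network over a metric matrix
#'
#' Computes the Spearman correlation for every metric pair on
#' pairwise-complete observations, with permutation p-values (default) or
#' t-test p-values, and retains edges below the significance level.
#' Pairs with fewer than 4 complete observations, or with a constant metric,
#' are skipped and reported.
#'
#' @param m a [metric_matrix()] (or data frame with metric columns).
#' @param alpha edge significance level.
#' @param method `"permutation"` (exact for n <= 9, Monte-Carlo otherwise)
#'   or `"ttest"`.
#' @param n_mc Monte-Carlo permutation count.
#' @return data frame of all computed pairs (`metric_a, metric_b, rho, p, n,
#'   significant`) with attribute `skipped` (data frame of skipped pairs and
#'   reasons).
#' @export
correlation_network <- function(m, alpha = 0.01,
                                method = c("permutation", "ttest"),
                                n_mc = 1e5) {
  method <- match.arg(method)
  metrics <- attr(m, "metrics") %||% setdiff(names(m), c("mouse", "group"))
  df <- as.data.frame(m)
  pairs <- combn(metrics, 2L)
  rows <- list(); skipped <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ok <- complete.cases(df[[a]], df[[b]])
    if (sum(ok) < 4L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(metric_a = a, metric_b = b, reason = "fewer than 4 pairs")
      next
    }
    if (sd(df[[a]][ok]) == 0 || sd(df[[b]][ok]) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(metric_a = a, metric_b = b, reason = "constant metric")
      next
    }
    r <- if (method == "permutation")
      spearman_perm(df[[a]][ok], df[[b]][ok], n_mc = n_mc)
    else spearman_ttest(df[[a]][ok], df[[b]][ok])
    rows[[length(rows) + 1L]] <-
      data.frame(metric_a = a, metric_b = b, rho = r$rho, p = r$p, n = r$n,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metric_a = character(0), metric_b = character(0),
               rho = numeric(0), p = numeric(0), n = integer(0))
  out$significant <- out$p < alpha
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  if (length(skipped))
    message(length(skipped), " metric pair(s) skipped (constant or too few ",
            "complete observations)")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Wrapper around [stats::ks.test()] returning the D statistic and p-value
#' (exact when sample sizes permit).
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop2("need n >= 2 per sample")
  kt <- suppressWarnings(ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}
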