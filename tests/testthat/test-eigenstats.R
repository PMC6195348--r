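ctrl_matrix <- function(seed = 1, n = 30, metrics = paste0("m", 1:4)) {
  synth_metric_groups(synth_config(seed), metrics = metrics, n_control = n)
}

test_that("control space: centering, variance conservation, degenerate toys", {
  ctrl <- ctrl_matrix()
  es <- fit_control_space(ctrl)
  cs <- project_group(ctrl, es)$scores
  expect_equal(colMeans(cs), setNames(rep(0, 4), colnames(cs)),
               tolerance = 1e-12)
  # PCA conserves total z-scored variance (p metrics, unit variance each)
  expect_equal(sum(es$var), 4)
  expect_equal(crossprod(es$loadings), diag(4), ignore_attr = TRUE)
  expect_true(all(diff(es$var) <= 1e-12))
  # two perfectly correlated metrics: PC1 carries all control variance
  x <- rnorm(20)
  toy <- metric_matrix(data.frame(mouse = 1:20, group = "control",
                                  a = x, b = 2 * x + 5))
  es2 <- fit_control_space(toy)
  expect_equal(es2$var[1] / sum(es2$var), 1, ignore_attr = TRUE)
})

test_that("control space rejects bad inputs with named errors", {
  df <- data.frame(mouse = 1:10, group = "control", a = rnorm(10), b = 1)
  expect_error(fit_control_space(metric_matrix(df)), "b")
  df2 <- data.frame(mouse = 1:10, group = "control", a = rnorm(10),
                    b = c(NA, rnorm(9)))
  expect_error(fit_control_space(metric_matrix(df2)), "missing")
  small <- data.frame(mouse = 1:3, group = "control", a = rnorm(3),
                      b = rnorm(3), c = rnorm(3))
  expect_error(fit_control_space(metric_matrix(small)), "at least")
})

test_that("projection is exact on shifted controls and preserves variance", {
  ctrl <- ctrl_matrix(2)
  es <- fit_control_space(ctrl)
  # projecting the controls reproduces the control variance ratios
  gp0 <- project_group(ctrl, es)
  expect_equal(as.numeric(gp0$var_fraction), as.numeric(es$var / sum(es$var)))
  # shifting along component k's loading moves only component k's mean
  k <- 2; s <- 1.7
  shifted <- ctrl
  shift_raw <- s * es$scale * es$loadings[, k]
  for (m in es$metrics) shifted[[m]] <- shifted[[m]] + shift_raw[m]
  gp <- project_group(shifted, es)
  expect_equal(unname(gp$mean_diff[k]), s, tolerance = 1e-10)
  expect_equal(unname(gp$mean_diff[-k]), rep(0, 3), tolerance = 1e-10)
  # isometry: total score variance equals total z-scored variance
  Z <- scale(as.matrix(as.data.frame(ctrl)[es$metrics]),
             center = es$center, scale = es$scale)
  expect_equal(sum(apply(gp0$scores, 2, var)), sum(apply(Z, 2, var)))
  expect_error(project_group(ctrl[, 1:3], es), "lacks")
})

test_that("planted variance inflation raises that component's fraction", {
  ctrl <- ctrl_matrix(3, n = 60)
  es <- fit_control_space(ctrl)
  k <- 1
  infl <- ctrl
  cs <- project_group(ctrl, es)$scores
  cs[, k] <- cs[, k] * 2                      # inflate along component k
  back <- cs %*% t(es$loadings)               # rotate back to z space
  for (j in seq_along(es$metrics))
    infl[[es$metrics[j]]] <- back[, j] * es$scale[j] + es$center[j]
  gp <- project_group(infl, es)
  expect_gt(gp$var_fraction[k], project_group(ctrl, es)$var_fraction[k])
})

test_that("high-contribution selection needs all three criteria", {
  ctrl <- ctrl_matrix(4, n = 30)
  es <- fit_control_space(ctrl)
  cs <- project_group(ctrl, es)$scores
  # a group identical to the controls selects nothing
  hc0 <- high_contribution_pcs(project_group(ctrl, es), cs)
  expect_false(any(hc0$selected))
  # a strong shift along PC1 is selected
  shifted <- ctrl
  shift_raw <- 3 * sqrt(es$var[1]) * es$scale * es$loadings[, 1]
  for (m in es$metrics) shifted[[m]] <- shifted[[m]] + shift_raw[m]
  hc1 <- high_contribution_pcs(project_group(shifted, es), cs)
  expect_true(hc1$selected[1])
  # large variance fraction with zero mean difference is not selected
  expect_false(any(hc0$var_fraction >= 0.10 & hc0$selected))
})

test_that("selection is invariant under loading sign flips", {
  ctrl <- ctrl_matrix(5)
  es <- fit_control_space(ctrl)
  grp <- ctrl_matrix(6, n = 12)
  es_flip <- es
  es_flip$loadings[, 2] <- -es_flip$loadings[, 2]
  cs <- project_group(ctrl, es)$scores
  cs_f <- project_group(ctrl, es_flip)$scores
  h1 <- high_contribution_pcs(project_group(grp, es), cs)
  h2 <- high_contribution_pcs(project_group(grp, es_flip), cs_f)
  expect_identical(h1$selected, h2$selected)
})

test_that("variance-ratio test matches hand computation and var.test", {
  eq <- variance_ratio_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 1)
  vr <- variance_ratio_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(vr$F, 1 / 4)    # s2 = 1 vs 4
  for (s in 1:10) {
    set.seed(s)
    g <- rnorm(8); ctl <- rnorm(12)
    ours <- variance_ratio_test(g, ctl)
    ref <- var.test(g, ctl)
    expect_equal(ours$F, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
  expect_error(variance_ratio_test(rnorm(5), c(1, 1, 1)), "zero")
})

test_that("Cohen's d uses the pooled SD and flags degenerate input", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(cohens_d(c(0, 0), c(1, 1))))
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -1 / sqrt(0.5))
  set.seed(1)
  a <- rnorm(4000, 1); b <- rnorm(4000, 0)
  expect_lt(abs(cohens_d(a, b) - 1), 0.06)
})

test_that("exact permutation Spearman p matches a brute-force oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 4, 3)
  r <- spearman_perm(x, y)
  expect_identical(r$method, "exact")
  expect_equal(r$rho, 0.8)
  expect_equal(r$p, brute_spearman_p(x, y))
  x2 <- c(5, 1, 4, 2, 3); y2 <- c(2, 1, 4, 5, 3)
  r2 <- spearman_perm(x2, y2)
  expect_equal(r2$p, brute_spearman_p(x2, y2))
  mono <- spearman_perm(1:6, (1:6)^3)
  expect_equal(mono$rho, 1)
  expect_equal(mono$p, 2 / factorial(6))  # only the two extreme orders
})

test_that("correlation network: edges, skips and pairwise-complete support", {
  set.seed(10)
  n <- 12
  base <- rnorm(n)
  df <- data.frame(mouse = 1:n, group = "g",
                   a = base, b = base + rnorm(n, 0, 0.01),
                   c = rnorm(n), k = rep(1, n))
  df$c[1:2] <- NA
  m <- metric_matrix(df)
  expect_message(net <- correlation_network(m, alpha = 0.01, n_mc = 2000),
                 "skipped")
  ab <- net[net$metric_a == "a" & net$metric_b == "b", ]
  expect_true(ab$significant)
  expect_gt(ab$rho, 0.95)
  expect_identical(net[net$metric_a == "a" & net$metric_b == "c", "n"], 10L)
  skipped <- attr(net, "skipped")
  expect_true(all(skipped$metric_b == "k" | skipped$metric_a == "k"))
})

test_that("KS comparison equals exact enumeration on a tiny fixture", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(10, 11, 12))$D, 1)
  set.seed(2)
  a <- rnorm(4); b <- rnorm(4) + 0.4
  got <- ks_compare(a, b)
  pool <- c(a, b)
  splits <- combn(8, 4)
  Ds <- apply(splits, 2, function(ix) {
    fa <- stats::ecdf(pool[ix]); fb <- stats::ecdf(pool[-ix])
    max(abs(fa(sort(pool)) - fb(sort(pool))))
  })
  expect_equal(got$p, mean(Ds >= got$D - 1e-12))
})
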