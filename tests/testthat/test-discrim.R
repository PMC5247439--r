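test_that("scatter criteria collapse to 1 for coincident class means", {
  set.seed(40)
  X <- matrix(rnorm(200 * 2), ncol = 2)
  X <- rbind(X, X)                                  # same cloud, both labels
  fm <- fm_from_matrix(X, rep(c("LA", "HA"), each = 200))
  sc <- scatter_criteria(fm)
  expect_equal(max(abs(sc$S_b)), 0, tolerance = 1e-12)
  expect_equal(sc$J1, 1, tolerance = 1e-12)
  expect_equal(sc$J2, 1, tolerance = 1e-12)
})

test_that("scatter criteria match an independent covariance decomposition", {
  set.seed(41)
  X <- rbind(matrix(rnorm(500 * 2, 0), ncol = 2),
             matrix(rnorm(500 * 2, mean = rep(c(10, 0), each = 500)), ncol = 2))
  y <- rep(c("LA", "HA"), each = 500)
  fm <- fm_from_matrix(X, y)
  sc <- scatter_criteria(fm)

  # oracle: population covariances via stats::cov, weighted by class share
  n <- nrow(X)
  Sw_o <- matrix(0, 2, 2)
  mu <- colMeans(X)
  Sb_o <- matrix(0, 2, 2)
  for (cls in c("LA", "HA")) {
    Xc <- X[y == cls, ]
    nc <- nrow(Xc)
    Sw_o <- Sw_o + (nc / n) * cov(Xc) * (nc - 1) / nc
    Sb_o <- Sb_o + (nc / n) * tcrossprod(colMeans(Xc) - mu)
  }
  Sm_o <- cov(X) * (n - 1) / n
  expect_equal(unname(sc$S_w), Sw_o, tolerance = 1e-9)
  expect_equal(unname(sc$S_b), Sb_o, tolerance = 1e-9)
  expect_equal(unname(sc$S_m), Sm_o, tolerance = 1e-9)
  expect_equal(sc$J1, sum(diag(Sm_o)) / sum(diag(Sw_o)), tolerance = 1e-9)
  expect_equal(sc$J2, det(Sm_o) / det(Sw_o), tolerance = 1e-9)
  expect_gt(sc$J1, 1)
})

test_that("scatter additivity, positivity and invariances hold on random data", {
  set.seed(42)
  for (rep in 1:10) {
    d <- sample(1:5, 1)
    n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
    X <- matrix(rnorm((n1 + n0) * d, sd = runif(1, 0.5, 3)), ncol = d)
    y <- rep(c("LA", "HA"), c(n1, n0))
    sc <- scatter_criteria(fm_from_matrix(X, y))
    expect_equal(sc$S_m, sc$S_w + sc$S_b, tolerance = 1e-9)
    expect_true(isSymmetric(sc$S_w, tol = 1e-9))
    expect_gte(min(eigen(sc$S_b, only.values = TRUE)$values), -1e-9)
    expect_gte(sc$J1, 1)

    # rotation invariance of J1 and J2
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    sc_rot <- scatter_criteria(fm_from_matrix(X %*% Q, y))
    expect_equal(sc_rot$J1, sc$J1, tolerance = 1e-8)
    if (!is.na(sc$J2)) expect_equal(sc_rot$J2, sc$J2, tolerance = 1e-6)
    # global scaling invariance of J1
    sc_scaled <- scatter_criteria(fm_from_matrix(5 * X, y))
    expect_equal(sc_scaled$J1, sc$J1, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis wrapper matches manual midrank computation", {
  identical_groups <- replicate(6, c(1, 2, 3), simplify = FALSE)
  res <- kruskal_wallis_check(identical_groups)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.999)

  g <- list(c(1.2, 3.4, 2.2), c(5.1, 4.4, 6.0))
  res2 <- kruskal_wallis_check(g)
  expect_equal(res2$statistic, kw_manual_h(g), tolerance = 1e-12)

  set.seed(50)
  for (rep in 1:20) {
    g <- lapply(sample(2:4, sample(2:4, 1), replace = TRUE),
                function(n) round(rnorm(n), 1))
    expect_equal(kruskal_wallis_check(g)$statistic, kw_manual_h(g),
                 tolerance = 1e-10)
  }

  shifted <- c(lapply(1:3, function(i) rnorm(10, 0)),
               lapply(1:3, function(i) rnorm(10, 5)))
  expect_lt(kruskal_wallis_check(shifted)$p_value, 0.05)

  expect_error(kruskal_wallis_check(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis_check(list(1:3, numeric(0))), "non-empty")
})

test_that("feature subsampling harness separates a strong group effect", {
  fm <- tiny_feature_matrix(n_subj = 3, trials = 34, seed = 51,
                            evoked_amp_la = 3, evoked_amp_ha = 12)
  res <- kw_feature_samples(fm, feature = "Fz.A4.Er", seed = 1)
  expect_length(res$group_sizes, 6)
  expect_lt(res$p_value, 0.05)
  expect_identical(kw_feature_samples(fm, feature = "Fz.A4.Er", seed = 1)$p_value,
                   res$p_value)
})

test_that("content-effect t-test handles ceilings, separation and the null", {
  expect_equal(content_effect_ttest(rep(100, 30), rep(100, 30))$p_value, 1)
  expect_true(isTRUE(attr(content_effect_ttest(rep(100, 30), rep(100, 30)),
                          "degenerate")))

  set.seed(60)
  lo <- 0.5 + rnorm(30, 0, 0.01)
  hi <- 0.9 + rnorm(30, 0, 0.01)
  expect_lt(content_effect_ttest(hi, lo)$p_value, 0.001)

  # p-values uniform under the null (pooled t, equal variances)
  ps <- replicate(1000, content_effect_ttest(rnorm(15), rnorm(15))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # agreement with stats::t.test in the regular case
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(content_effect_ttest(a, b)$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(content_effect_ttest(a, b, var_equal = FALSE)$p_value,
               t.test(a, b)$p.value)
  expect_error(content_effect_ttest(1, 1:5), "length >= 2")
})
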