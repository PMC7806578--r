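test_that("percent response normalizes rows to 100 and is scale invariant", {
  m <- rbind(c(1, 1, 2), c(10, 10, 20))
  pr <- percent_response(m)
  expect_equal(pr[1, ], c(25, 25, 50))
  expect_equal(pr[1, ], pr[2, ])  # scaling a run leaves % response alone
  expect_equal(unname(rowSums(pr)), c(100, 100))
  bad <- rbind(c(1, 2), c(0, 0))
  rownames(bad) <- c("good_run", "bad_run")
  expect_error(percent_response(bad), "bad_run")
})

test_that("PCA matches the eigen-decomposition oracle and separates clouds", {
  set.seed(40)
  x <- matrix(rnorm(60), 10, 6)
  p <- pca_features(x, n_components = 4)
  ev <- eigen(stats::cov(x))
  expect_equal(p$explained[1:4], 100 * ev$values[1:4] / sum(ev$values))
  for (k in 1:4) {
    expect_equal(abs(sum(p$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)

  # two clouds separated along one direction: PC1 dominates and splits them
  cl <- rbind(matrix(rnorm(40, 0, 0.1), 8), matrix(rnorm(40, 3, 0.1), 8))
  pc <- pca_features(cl)
  expect_gt(pc$explained[1], 90)
  s1 <- pc$scores[1:8, 1]; s2 <- pc$scores[9:16, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))

  # duplicated feature columns load identically up to sign
  dup <- cbind(cl[, 1], cl[, 1], rnorm(16, 0, 0.1))
  pd <- pca_features(dup)
  expect_equal(abs(pd$loadings[1, 1]), abs(pd$loadings[2, 1]),
               tolerance = 1e-8)
})

test_that("two-group KW selection matches the closed-form rank statistic", {
  set.seed(41)
  g <- rep(c("MHO", "MUO"), c(6, 8))
  x <- matrix(rnorm(14 * 50), 14)
  x[, 1:5] <- x[, 1:5] + outer(as.numeric(g == "MUO"), rep(2, 5))
  res <- kw_dunn_bonferroni(x, g, alpha = 0.05)
  for (j in c(1, 7, 23, 50)) {
    expect_equal(res$kw_p[j], kw_closed_form_p(x[, j], g))
    expect_equal(res$p_adj[j], res$kw_p[j])  # k = 2: KW p gates directly
  }
  # disjoint group supports are always selected
  y <- c(rnorm(8), rnorm(8) + 100)
  res2 <- kw_dunn_bonferroni(cbind(f = y), rep(c("a", "b"), each = 8))
  expect_true(res2$selected)
  expect_error(kw_dunn_bonferroni(x, rep("one", 14)), ">= 2 groups")
  expect_error(kw_dunn_bonferroni(x[1:7, ], c("a", rep("b", 6))), ">= 2 runs")
})

test_that("Dunn post hoc with Bonferroni gates three-group comparisons", {
  set.seed(42)
  g <- rep(c("QC", "MHO", "MUO"), each = 6)
  x <- cbind(matrix(rnorm(18 * 30), 18,
                    dimnames = list(NULL, paste0("null", 1:30))),
             hit = c(rnorm(6), rnorm(6), rnorm(6) + 4))
  res <- kw_dunn_bonferroni(x, g, alpha = 0.05)
  expect_true(res$selected[res$feature == "hit"])
  # null features are selected at most rarely
  expect_lte(mean(res$selected[res$feature != "hit"]), 0.2)
  # hand-computed Dunn z for the MUO pair on the hit feature
  r <- rank(x[, "hit"])
  z <- (mean(r[g == "MUO"]) - mean(r[g == "MHO"])) /
    sqrt(18 * 19 / 12 * (1 / 6 + 1 / 6))
  p_hand <- min(3 * 2 * pnorm(-abs(z)), 1)
  expect_lte(res$p_adj[res$feature == "hit"], p_hand + 1e-12)
  # optional across-feature Bonferroni only tightens
  res_b <- kw_dunn_bonferroni(x, g, p_adjust_features = "bonferroni")
  expect_true(all(res_b$p_adj >= res$p_adj - 1e-12))
})

test_that("VIP satisfies its algebraic identity and ranks constructed signal first", {
  set.seed(43)
  n <- 16; p <- 12
  g <- rep(c("MHO", "MUO"), each = 8)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 3] <- x[, 3] + ifelse(g == "MUO", 4, -4)
  fit <- plsda_vip(x, g)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
  expect_identical(names(which.max(fit$vip)), "f3")
  expect_gte(fit$vip["f3"], 1)
  expect_error(plsda_vip(x, rep("MUO", n)), "2 classes")

  # permuted labels destroy the feature's prominence
  hits <- 0
  for (i in 1:20) {
    vp <- plsda_vip(x, sample(g))$vip
    hits <- hits + (names(which.max(vp)) == "f3")
  }
  expect_lt(hits, 10)
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(44)
  x <- matrix(rnorm(20 * 8), 20, dimnames = list(NULL, paste0("f", 1:8)))
  g <- rep(c("A", "B"), each = 10)
  x[, 1] <- x[, 1] + ifelse(g == "A", 1, -1)
  ours <- plsda_vip(x, g, n_components = 2)$vip
  fit <- mixOmics::plsda(x, factor(g), ncomp = 2, scale = TRUE)
  theirs <- mixOmics::vip(fit)[, 2]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("channel regression reproduces closed-form OLS quantities", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- channel_regression(x, x)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(channel_regression(x, rep(2, 5))$r_squared, 0)
  set.seed(45)
  a <- rnorm(30); b <- 0.4 * a + rnorm(30, 0, 0.5)
  r <- channel_regression(a, b)
  expect_equal(r$r_squared, cor(a, b)^2, tolerance = 1e-12)
  expect_equal(r$slope, cov(a, b) / var(a), tolerance = 1e-12)
  expect_error(channel_regression(rep(1, 5), x), "zero variance")
  expect_error(channel_regression(1:2, 1:2), ">= 3")
})

test_that("RSD is the percent ratio of SD to mean", {
  expect_equal(rsd(rep(7, 10)), 0)
  expect_equal(rsd(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(rsd(c(90, 110)), 14.14214, tolerance = 1e-6)
  set.seed(46)
  v <- runif(20, 1, 2)
  expect_equal(rsd(3.7 * v), rsd(v))
  expect_error(rsd(c(-1, 1)), "zero-mean")
})
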