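test_that("lambda only enters through shared branch lengths", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  set.seed(61)
  y <- rnorm(8); names(y) <- star$tip.label
  ll <- vapply(c(0, 0.3, 0.7, 1), function(l) bm_gls_loglik(star, y, l)$logL,
               numeric(1))
  expect_true(all(abs(ll - ll[1]) < 1e-9))
})

test_that("the GLS likelihood matches a direct matrix-algebra evaluation", {
  set.seed(62)
  tree <- simulate_tree(4)
  y <- simulate_bm_traits(tree, 1, 2)
  for (lam in c(0, 0.4, 1)) {
    got <- bm_gls_loglik(tree, y, lam)
    ## independent evaluation: explicit inverse and determinant
    C <- ape::vcv(tree); Cl <- C * lam; diag(Cl) <- diag(C)
    Ci <- solve(Cl); one <- rep(1, 4)
    mu <- drop((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
    s2 <- drop(t(y - mu) %*% Ci %*% (y - mu)) / 4
    ll <- -0.5 * (4 * log(2 * pi * s2) + log(det(Cl)) + 4)
    expect_equal(got$logL, ll, tolerance = 1e-10)
    expect_equal(got$mu_hat, mu, tolerance = 1e-10)
    expect_equal(got$sigma2_hat, s2, tolerance = 1e-10)
  }
  ## lambda = 0 is the independent-tips normal likelihood with tip-depth variances
  got0 <- bm_gls_loglik(tree, y, 0)
  depths <- diag(ape::vcv(tree))
  wm <- sum(y / depths) / sum(1 / depths)
  s2 <- mean((y - wm)^2 / depths)
  ll0 <- sum(dnorm(y, wm, sqrt(s2 * depths), log = TRUE))
  expect_equal(got0$logL, ll0, tolerance = 1e-10)
})

test_that("lambda ML recovers simulated signal and agrees with phytools", {
  skip_if_not_installed("phytools")
  set.seed(63)
  tree <- simulate_tree(60)
  y <- simulate_bm_traits(tree, 1, 1)
  fit <- fit_pagel_lambda(tree, y)
  ph <- phytools::phylosig(tree, y, method = "lambda", test = TRUE)
  expect_equal(fit$lambda_hat, ph$lambda, tolerance = 1e-4)
  ## both maximize the same likelihood to their own optimizer tolerances
  expect_gte(fit$logL, ph$logL - 1e-6)
  expect_equal(fit$logL, ph$logL, tolerance = 1e-4)
  expect_equal(fit$p, ph$P, tolerance = 1e-3)
})

test_that("lambda estimation separates real from destroyed signal", {
  set.seed(64)
  lh <- lh_shuf <- numeric(15)
  for (i in 1:15) {
    tree <- simulate_tree(100)
    y <- simulate_bm_traits(tree, 1, 1)
    lh[i] <- fit_pagel_lambda(tree, y)$lambda_hat
    ys <- setNames(sample(y), names(y))  # tip shuffle kills the signal
    lh_shuf[i] <- fit_pagel_lambda(tree, ys)$lambda_hat
  }
  expect_gte(mean(lh), 0.9)
  expect_lte(mean(lh_shuf), 0.2)
  expect_error(fit_pagel_lambda(simulate_tree(10, seed = 1),
                                rep(1, 10)), "degenerate")
})

test_that("PGLS with identity covariance reproduces OLS exactly", {
  star <- ape::stree(12, "star"); star$edge.length <- rep(1, 12)
  set.seed(65)
  x <- rnorm(12); y <- 2 + 0.5 * x + rnorm(12, 0, 0.3)
  names(y) <- star$tip.label
  fit <- pgls(star, y, x, lambda = 1)  # C = identity on a unit-depth star
  ols <- lm(y ~ x)
  sm <- summary(ols)$coefficients
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$se), unname(sm[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$p), unname(sm[, 4]), tolerance = 1e-8)
  ## exact linear response: zero residual variance, exact slope
  yy <- 1 + 3 * x; names(yy) <- star$tip.label
  fit2 <- pgls(star, yy, x)
  expect_equal(unname(fit2$coefficients$estimate[2]), 3, tolerance = 1e-10)
  expect_lt(fit2$sigma2, 1e-20)
  expect_error(pgls(star, y, cbind(x, x)), "rank")
})

test_that("PGLS slope recovery on BM-correlated traits stays within 2 SE", {
  set.seed(66)
  hits <- 0; n_rep <- 25
  for (i in 1:n_rep) {
    tree <- simulate_tree(50)
    x <- simulate_bm_traits(tree, 1, 1)
    y <- 1.5 * x + simulate_bm_traits(tree, 1, 0.5)
    fit <- pgls(tree, y, x)
    co <- fit$coefficients["x", ]
    hits <- hits + (abs(co$estimate - 1.5) <= 2 * co$se)
  }
  expect_gte(hits, ceiling(0.85 * n_rep))
})

test_that("phylogenetic t-test matches the classical t-test under identity covariance", {
  star <- ape::stree(14, "star"); star$edge.length <- rep(1, 14)
  set.seed(67)
  y <- rnorm(14); names(y) <- star$tip.label
  grp <- rep(c(0, 1), each = 7)
  got <- phylo_ttest(star, y, grp)
  ref <- t.test(y[grp == 1], y[grp == 0], var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  expect_equal(got$df, unname(ref$parameter))
  expect_error(phylo_ttest(star, y, rep(1, 14)), "single level")
  expect_error(phylo_ttest(star, rep(2, 14), grp), "degenerate")
})

test_that("t-test p-values are uniform under the matching BM null", {
  set.seed(68)
  tree <- simulate_tree(30)
  grp <- as.numeric(seq_len(30) %% 2)
  p <- replicate(400, {
    y <- simulate_bm_traits(tree, 1, 1)
    phylo_ttest(tree, y, grp)$p
  })
  D <- suppressWarnings(ks.test(p, "punif")$statistic)
  expect_lt(unname(D), 0.09)  # 5% critical value at n=400 is ~0.068
})
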