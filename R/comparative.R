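## Phylogenetic comparative methods on log-transformed repeat traits:
## Brownian-motion GLS likelihood with Pagel's lambda, maximum-likelihood
## lambda estimation with a likelihood-ratio test, PGLS regression, and the
## phylogenetic t-test.

#' Phylogenetic covariance with Pagel's lambda
#'
#' Shared-path-length (Brownian motion) tip covariance of a rooted tree with
#' off-diagonal entries multiplied by `lambda`.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return The scaled covariance matrix, tips in `tree$tip.label` order.
#' @export
lambda_cov <- function(tree, lambda = 1) {
  C <- ape::vcv(tree)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Log-likelihood of a trait under Brownian motion with Pagel's lambda
#'
#' Profile log-likelihood: for covariance `C(lambda)` the mean and rate are
#' replaced by their GLS estimates
#' `mu = (1' C^-1 1)^-1 1' C^-1 y` and `sigma2 = (y - mu)' C^-1 (y - mu) / n`,
#' and the multivariate normal log density is evaluated there.
#'
#' @param tree An `ape::phylo`.
#' @param y Named trait vector (names matched to tip labels) or unnamed in tip
#'   order.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return List `logL`, `mu_hat`, `sigma2_hat`.
#' @export
bm_gls_loglik <- function(tree, y, lambda) {
  y <- align_trait(tree, y)
  n <- length(y)
  Cl <- lambda_cov(tree, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) stop("singular covariance C(lambda)"))
  logdet <- 2 * sum(log(diag(ch)))
  ones <- rep(1, n)
  Ci1 <- backsolve(ch, forwardsolve(t(ch), ones))
  Ciy <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- sum(Ci1 * y) / sum(Ci1 * ones)
  resid <- y - mu
  Cir <- backsolve(ch, forwardsolve(t(ch), resid))
  sigma2 <- sum(resid * Cir) / n
  if (sigma2 <= 0) stop("degenerate trait: zero variance")
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logL = logL, mu_hat = mu, sigma2_hat = sigma2)
}

align_trait <- function(tree, y) {
  if (!is.null(names(y))) {
    missing <- setdiff(tree$tip.label, names(y))
    if (length(missing)) stop("trait missing for tips: ", paste(missing, collapse = ", "))
    y <- y[tree$tip.label]
  } else if (length(y) != length(tree$tip.label)) {
    stop("trait length does not match number of tips")
  }
  if (any(!is.finite(y))) stop("trait values must be finite")
  as.numeric(y)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes [bm_gls_loglik()] over `lambda` in `[0, 1]` by bounded scalar
#' optimization (tolerance 1e-6, endpoints checked), and tests phylogenetic
#' signal against `lambda = 0` with a likelihood-ratio statistic referred to
#' the chi-square distribution with 1 df.
#'
#' @param tree An `ape::phylo`.
#' @param y Named trait vector.
#' @return List `lambda_hat`, `sigma2_hat`, `mu_hat`, `logL`, `logL0`, `LR`,
#'   `p`.
#' @export
fit_pagel_lambda <- function(tree, y) {
  y <- align_trait(tree, y)
  if (var(y) == 0) stop("degenerate trait: zero variance")
  f <- function(l) bm_gls_loglik(tree, y, l)$logL
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  lambda_hat <- cand[best]
  fit <- bm_gls_loglik(tree, y, lambda_hat)
  logL0 <- ll[2]
  LR <- max(0, 2 * (fit$logL - logL0))
  list(lambda_hat = lambda_hat, sigma2_hat = fit$sigma2_hat,
       mu_hat = fit$mu_hat, logL = fit$logL, logL0 = logL0, LR = LR,
       p = pchisq(LR, df = 1, lower.tail = FALSE))
}

#' Phylogenetic generalized least squares
#'
#' GLS regression of `y` on `X` with covariance `C(lambda)` among tips;
#' coefficient tests use t statistics with `n - p` degrees of freedom. With an
#' identity covariance (e.g. `lambda = 0` on a unit-depth star tree) the fit
#' reduces exactly to ordinary least squares.
#'
#' @param tree An `ape::phylo`.
#' @param y Response, named by tip or in tip order.
#' @param X Design matrix (an intercept column is added when absent) or a
#'   vector for a single predictor.
#' @param lambda Pagel's lambda for the covariance (default 1, Brownian
#'   motion).
#' @return List with `coefficients` (data frame: estimate, se, t, p),
#'   `sigma2` (residual variance, `rss / (n - p)`), `df_residual`, `logL`.
#' @export
pgls <- function(tree, y, X, lambda = 1) {
  y <- align_trait(tree, y)
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  Cl <- lambda_cov(tree, lambda)
  ch <- chol(Cl)
  ## whiten: solve t(ch) %*% z = v
  wy <- forwardsolve(t(ch), y)
  wX <- forwardsolve(t(ch), X)
  fit <- qr(wX)
  beta <- qr.coef(fit, wy)
  resid <- wy - wX %*% beta
  rss <- sum(resid^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(fit))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  logdet <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * (n * log(2 * pi * rss / n) + logdet + n)
  list(coefficients = data.frame(estimate = beta, se = se, t = tval, p = pval,
                                 row.names = colnames(X)),
       sigma2 = sigma2, df_residual = df_res, logL = logL)
}

#' Phylogenetic t-test
#'
#' Tests whether a trait differs between two groups of taxa while accounting
#' for phylogenetic covariance: a PGLS of `y` on the group indicator; `t` is
#' the indicator coefficient over its standard error. With identity
#' covariance this is the classical pooled-variance two-sample t-test.
#'
#' @param tree An `ape::phylo`.
#' @param y Trait, named by tip or in tip order.
#' @param group Binary indicator (0/1 or logical), named by tip or in tip
#'   order.
#' @param lambda Covariance scaling (default 1, Brownian motion).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"` for
#'   the group-1 effect.
#' @return List `t`, `df`, `p`, `estimate` (group effect).
#' @export
phylo_ttest <- function(tree, y, group, lambda = 1,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  g <- align_trait(tree, as.numeric(group))
  if (length(unique(g)) < 2) stop("group indicator has a single level")
  if (var(align_trait(tree, y)) == 0) stop("degenerate trait: zero variance")
  fit <- pgls(tree, y, matrix(g, ncol = 1, dimnames = list(NULL, "group")),
              lambda = lambda)
  co <- fit$coefficients["group", ]
  p <- switch(alternative,
              two.sided = co$p,
              greater = pt(co$t, fit$df_residual, lower.tail = FALSE),
              less = pt(co$t, fit$df_residual, lower.tail = TRUE))
  list(t = co$t, df = fit$df_residual, p = p, estimate = co$estimate)
}
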