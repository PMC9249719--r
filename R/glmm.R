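# Random-intercept model helpers shared by the prevalence (logistic) and
# calorie (linear) fits: per-cluster marginal log-likelihoods, a cluster-robust
# sandwich covariance built on them, and population-averaged wave estimates.
#
# Clusters (schools) are independent under the random-intercept model, so the
# marginal log-likelihood is a sum of per-school terms; the sandwich estimator
# uses numerically differentiated per-school scores at the fitted parameters.
# The logistic marginal likelihood integrates the random intercept with
# Gauss-Hermite quadrature; the linear one is available in closed form
# (compound-symmetric Gaussian).

GH_NODES <- 15

gh_rule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussHermite(GH_NODES)
    cache
  }
})

# Per-cluster marginal log-likelihoods of a random-intercept logistic model,
# by adaptive Gauss-Hermite quadrature: nodes are centered on each cluster's
# posterior mode of the random intercept and scaled by the local curvature,
# so large clusters (whose integrand is much narrower than the prior) are
# integrated accurately. params = c(beta, log_sigma).
logit_cluster_loglik <- function(params, X, y, cluster) {
  k <- ncol(X)
  beta <- params[seq_len(k)]
  sigma <- max(exp(params[k + 1]), 1e-8)
  gh <- gh_rule()
  eta <- drop(X %*% beta)
  sgn <- 2 * y - 1
  cluster <- as.factor(cluster)
  G <- nlevels(cluster)

  # Newton iterations for the per-cluster posterior mode of b
  b <- numeric(G)
  for (it in 1:25) {
    p <- stats::plogis(eta + b[cluster])
    grad <- drop(rowsum(y - p, cluster)) - b / sigma^2
    hess <- -drop(rowsum(p * (1 - p), cluster)) - 1 / sigma^2
    step <- grad / hess
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- stats::plogis(eta + b[cluster])
  s <- 1 / sqrt(drop(rowsum(p * (1 - p), cluster)) + 1 / sigma^2)

  # log integrand at the adapted nodes: G x q
  nodes <- outer(b, rep(1, length(gh$x))) + sqrt(2) * s %o% gh$x
  Z <- matrix(0, G, length(gh$x))
  for (q in seq_along(gh$x)) {
    Z[, q] <- drop(rowsum(-log1p(exp(-sgn * (eta + nodes[cluster, q]))),
                          cluster)) +
      stats::dnorm(nodes[, q], 0, sigma, log = TRUE)
  }
  lw <- log(gh$w) + gh$x^2
  M <- sweep(Z, 2, lw, "+")
  m <- apply(M, 1, max)
  log(sqrt(2) * s) + m + log(rowSums(exp(M - m)))
}

# Per-cluster marginal log-likelihoods of a random-intercept linear model.
# params = c(beta, log_sigma_e, log_tau); y_s ~ N(X_s beta, sig^2 I + tau^2 J).
linear_cluster_loglik <- function(params, X, y, cluster) {
  k <- ncol(X)
  beta <- params[seq_len(k)]
  sig2 <- exp(2 * params[k + 1])
  tau2 <- exp(2 * params[k + 2])
  r <- y - drop(X %*% beta)
  vapply(split(seq_along(y), cluster), function(idx) {
    n <- length(idx)
    ri <- r[idx]
    s <- sum(ri)
    # Woodbury: (sig2 I + tau2 J)^-1 = I/sig2 - (tau2/(sig2*(sig2+n*tau2))) J
    quad <- sum(ri^2) / sig2 - tau2 * s^2 / (sig2 * (sig2 + n * tau2))
    logdet <- n * log(sig2) + log1p(n * tau2 / sig2)
    -0.5 * (n * log(2 * pi) + logdet + quad)
  }, 0)
}

# Cluster-robust (sandwich) covariance of the parameter vector, built from
# numerical per-cluster scores and the numerical Hessian of the total marginal
# log-likelihood, with a G/(G-1) small-sample factor.
cluster_robust_vcov <- function(params, cluster_loglik_fn) {
  G <- length(cluster_loglik_fn(params))
  total <- function(p) sum(cluster_loglik_fn(p))
  H <- pracma::hessian(total, params)
  scores <- numeric_jacobian(cluster_loglik_fn, params)  # G x npar
  meat <- crossprod(scores) * G / (G - 1)
  Hinv <- solve(-H)
  Hinv %*% meat %*% Hinv
}

numeric_jacobian <- function(fn, x, h = 1e-5) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    step <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + step
    xm <- x; xm[j] <- xm[j] - step
    J[, j] <- (fn(xp) - fn(xm)) / (2 * step)
  }
  J
}

# Population-averaged probability for each row of X under a random-intercept
# logistic model: E_b[ plogis(eta + b) ], b ~ N(0, sigma^2), by quadrature.
pa_probability <- function(eta, sigma) {
  gh <- gh_rule()
  b <- sqrt(2) * sigma * gh$x
  w <- gh$w / sqrt(pi)
  p <- vapply(b, function(bk) stats::plogis(eta + bk), numeric(length(eta)))
  drop(if (is.matrix(p)) p %*% w else sum(p * w))
}
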