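# Independent oracles for the random-intercept machinery, shared between the
# unit and acceptance suites.

# independent oracle: per-cluster marginal likelihood by stats::integrate
oracle_logit_loglik <- function(beta, sigma, X, y, cluster) {
  eta <- drop(X %*% beta)
  vapply(split(seq_along(y), cluster), function(idx) {
    f <- function(b) {
      vapply(b, function(bi) {
        p <- plogis(eta[idx] + bi)
        exp(sum(ifelse(y[idx] == 1, log(p), log1p(-p)))) *
          dnorm(bi, 0, sigma)
      }, 0)
    }
    log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }, 0)
}

make_glmm_fixture <- function(seed = 14, n_per_cell = 10) {
  set.seed(seed)
  df <- expand.grid(i = seq_len(n_per_cell), wave = c("A", "B"),
                    school_id = c("s1", "s2"), stringsAsFactors = FALSE)
  b <- c(s1 = 0.4, s2 = -0.4)
  eta <- -0.2 + 0.6 * (df$wave == "B") + b[df$school_id]
  df$daily_consumer <- rbinom(nrow(df), 1, plogis(eta)) == 1
  df
}

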