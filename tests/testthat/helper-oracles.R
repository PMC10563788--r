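# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's log-space shortcuts: densities are combined in natural
# scale, searches are naive loops.

# direct per-window density sum, no log-sum-exp
bf_loglik <- function(params, X, Y) {
  X <- as.matrix(X)
  total <- 0
  for (i in seq_len(nrow(X))) {
    eta <- params$intercept + sum(params$slopes * X[i, ])
    p <- 1 / (1 + exp(-eta))
    dens <- p * dnorm(Y[i], params$mu1, params$sigma1) +
      (1 - p) * dnorm(Y[i], params$mu0, params$sigma0)
    total <- total + log(dens)
  }
  total
}

# direct ratio of unlogged densities
bf_responsibility <- function(params, X, Y) {
  X <- as.matrix(X)
  sapply(seq_len(nrow(X)), function(i) {
    eta <- params$intercept + sum(params$slopes * X[i, ])
    p <- 1 / (1 + exp(-eta))
    f1 <- p * dnorm(Y[i], params$mu1, params$sigma1)
    f0 <- (1 - p) * dnorm(Y[i], params$mu0, params$sigma0)
    f1 / (f1 + f0)
  })
}

# random valid parameter set on k covariates
random_params <- function(k) {
  mu0 <- rnorm(1)
  mdr_params(intercept = rnorm(1, sd = 1.5), slopes = rnorm(k),
             mu0 = mu0, sigma0 = runif(1, 0.3, 2),
             mu1 = mu0 + runif(1, 0.2, 3), sigma1 = runif(1, 0.3, 2))
}

# sort-and-accumulate threshold oracle for non-overlapping scored intervals
bf_threshold <- function(intervals, genome_length, target) {
  sc <- sort(unique(intervals$score), decreasing = TRUE)
  tot <- 0
  best <- Inf
  for (t in sc) {
    tot <- tot + sum(intervals$end[intervals$score == t] -
                       intervals$start[intervals$score == t])
    if (tot <= target * genome_length) best <- t else break
  }
  best
}

fast_config <- function(seed = 1L, restarts = 2L) {
  mdr_fit_config(restarts = restarts, seed = seed)
}

quiet_fit <- function(...) {
  withCallingHandlers(fit_mdr(...),
                      warning = function(w) invokeRestart("muffleWarning"))
}
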