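# Core likelihood machinery of the two-component Gaussian mixture density
# regression: the response Y of each gene window follows
#   P(y) = p * N(y | mu1, sigma1) + (1 - p) * N(y | mu0, sigma0)
# with a covariate-dependent mixing probability p = sigmoid(a + x . b).
# All density work is done in log space so far-tail observations never
# underflow.

check_design <- function(params, X, Y = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  k <- length(params$slopes)
  if (ncol(X) != k) {
    stop(sprintf("covariate dimension mismatch: params have %d slope(s), X has %d column(s)",
                 k, ncol(X)), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  if (!is.null(Y)) {
    if (length(Y) != nrow(X)) {
      stop(sprintf("Y has length %d but X has %d row(s)", length(Y), nrow(X)),
           call. = FALSE)
    }
    if (nrow(X) == 0L) stop("empty dataset: X has zero rows", call. = FALSE)
    if (!all(is.finite(Y))) stop("Y contains non-finite values", call. = FALSE)
  }
  X
}

#' Selection-enriched component probability
#'
#' Computes p = sigmoid(a + sum_i b_i x_i), the probability that a gene window
#' belongs to the selection-enriched mixture component given its genomic
#' covariates. Evaluated through `plogis` so it is numerically stable for
#' linear predictors far beyond +/-700 and always strictly inside (0, 1) on
#' the log scale used by the likelihood.
#'
#' @param params An [mdr_params()] object.
#' @param x A covariate vector (one window) or a matrix with one row per
#'   window and one column per slope.
#' @return Probabilities in (0, 1), one per window.
#' @examples
#' p <- mdr_params(1, c(2, -1), 0, 1, 1, 1)
#' mixing_probability(p, c(0.5, 1))  # sigmoid(1) = 0.731...
#' @export
mixing_probability <- function(params, x) {
  X <- check_design(params, x)
  eta <- drop(X %*% params$slopes) + params$intercept
  stats::plogis(eta)
}

# log p and log(1 - p) without forming p; stable for any finite eta
log_mixing <- function(params, X) {
  eta <- drop(X %*% params$slopes) + params$intercept
  list(logp = stats::plogis(eta, log.p = TRUE),
       log1mp = stats::plogis(-eta, log.p = TRUE))
}

# per-window log mixture density and component log-joints, shared by the
# log likelihood, the responsibilities and the gradient
mixture_logdens <- function(params, X, Y) {
  lm <- log_mixing(params, X)
  la <- lm$logp + stats::dnorm(Y, params$mu1, params$sigma1, log = TRUE)
  lb <- lm$log1mp + stats::dnorm(Y, params$mu0, params$sigma0, log = TRUE)
  m <- pmax(la, lb)
  ll <- m + log(exp(la - m) + exp(lb - m))
  list(ll = ll, la = la, lb = lb, logp = lm$logp)
}

#' Log likelihood of the mixture density regression
#'
#' Sums log P(y) over windows, where P(y) is the two-component Gaussian
#' mixture density with covariate-dependent mixing probability. Computed via
#' log-sum-exp so observations deep in one component's tail do not underflow.
#'
#' @inheritParams mixing_probability
#' @param X Design matrix, one row per window.
#' @param Y Response vector (log-transformed, z-scored window mean |iHS|).
#' @return A single finite number.
#' @export
mdr_loglik <- function(params, X, Y) {
  X <- check_design(params, X, Y)
  sum(mixture_logdens(params, X, Y)$ll)
}

#' Posterior component responsibilities
#'
#' Probability, per window, that the observation was generated by the
#' selection-enriched component given both the covariates and the observed
#' response: r = p f1(y) / [p f1(y) + (1 - p) f0(y)]. Used for reporting and
#' diagnostics; computed in log space so it is never NaN even when both
#' densities underflow in natural scale.
#'
#' @inheritParams mdr_loglik
#' @return Responsibilities in (0, 1), one per window.
#' @export
responsibilities <- function(params, X, Y) {
  X <- check_design(params, X, Y)
  d <- mixture_logdens(params, X, Y)
  exp(d$la - d$ll)
}

## ---- unconstrained parameterization used by the optimizer ----------------
## theta = (a, b[1..k], mu0, log sigma0, delta, log sigma1),
## with mu1 = mu0 + exp(delta): sigma0, sigma1 > 0 and mu1 > mu0 by
## construction, so L-BFGS-B runs without box constraints and label switching
## cannot occur.

theta_pack <- function(params) {
  c(params$intercept, params$slopes, params$mu0, log(params$sigma0),
    log(params$mu1 - params$mu0), log(params$sigma1))
}

theta_unpack <- function(theta, covariate_names) {
  k <- length(covariate_names)
  slopes <- theta[seq_len(k) + 1L]
  names(slopes) <- covariate_names
  mu0 <- theta[k + 2L]
  list(intercept = theta[1L], slopes = slopes, mu0 = mu0,
       sigma0 = exp(theta[k + 3L]), mu1 = mu0 + exp(theta[k + 4L]),
       sigma1 = exp(theta[k + 5L]))
}

# negative log likelihood on the unconstrained scale
nll_theta <- function(theta, X, Y, covariate_names) {
  p <- theta_unpack(theta, covariate_names)
  d <- mixture_logdens(p, X, Y)
  v <- -sum(d$ll)
  if (!is.finite(v)) v <- .Machine$double.xmax / 2
  v
}

# analytic gradient of the negative log likelihood on the unconstrained
# scale; r is the selection-enriched responsibility and (r - p) drives the
# logistic-gating part, exactly as in a mixture-of-experts model
nll_grad_theta <- function(theta, X, Y, covariate_names) {
  p <- theta_unpack(theta, covariate_names)
  d <- mixture_logdens(p, X, Y)
  r <- exp(d$la - d$ll)
  pr <- exp(d$logp)
  rmp <- r - pr
  z1 <- (Y - p$mu1) / p$sigma1
  z0 <- (Y - p$mu0) / p$sigma0
  g_a <- sum(rmp)
  g_b <- drop(crossprod(X, rmp))
  d_mu1 <- sum(r * z1) / p$sigma1
  d_mu0 <- sum((1 - r) * z0) / p$sigma0
  g_mu0 <- d_mu0 + d_mu1                 # mu1 = mu0 + exp(delta) rides on mu0
  g_logs0 <- sum((1 - r) * (z0^2 - 1))
  g_delta <- (p$mu1 - p$mu0) * d_mu1
  g_logs1 <- sum(r * (z1^2 - 1))
  -c(g_a, g_b, g_mu0, g_logs0, g_delta, g_logs1)
}
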