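#' Mixture density regression parameters
#'
#' Bundles the parameters of the two-component Gaussian mixture density
#' regression: a logit-scale intercept `a`, one slope per covariate acting on
#' the mixing probability of the selection-enriched component, and the means
#' and standard deviations of the two Gaussian components. The
#' selection-enriched component (`mu1`, `sigma1`) is constrained to have the
#' higher mean, which resolves label switching.
#'
#' @param intercept Logit-scale baseline of the selection-enriched component
#'   probability when all covariates are zero.
#' @param slopes Numeric vector of covariate slopes on the logit scale; names
#'   are kept and used as covariate labels.
#' @param mu0,sigma0 Mean and standard deviation of the background (drift)
#'   component, on the response scale.
#' @param mu1,sigma1 Mean and standard deviation of the selection-enriched
#'   component; `mu1` must exceed `mu0`.
#'
#' @return An object of class `mdr_params`.
#' @examples
#' mdr_params(intercept = -1.4, slopes = c(recomb = -2.4, gc = 0.55),
#'            mu0 = -0.4, sigma0 = 0.8, mu1 = 0.8, sigma1 = 1.1)
#' @export
mdr_params <- function(intercept, slopes, mu0, sigma0, mu1, sigma1) {
  slopes <- as.numeric2(slopes)
  stopifnot(length(intercept) == 1L, length(mu0) == 1L, length(sigma0) == 1L,
            length(mu1) == 1L, length(sigma1) == 1L)
  vals <- c(intercept, slopes, mu0, sigma0, mu1, sigma1)
  if (!all(is.finite(vals))) {
    stop("all mdr_params fields must be finite", call. = FALSE)
  }
  if (sigma0 <= 0 || sigma1 <= 0) {
    stop("sigma0 and sigma1 must be positive", call. = FALSE)
  }
  if (mu1 <= mu0) {
    stop("mu1 must exceed mu0 (the selection-enriched component has the higher mean)",
         call. = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept), slopes = slopes,
         mu0 = as.numeric(mu0), sigma0 = as.numeric(sigma0),
         mu1 = as.numeric(mu1), sigma1 = as.numeric(sigma1)),
    class = "mdr_params"
  )
}

# keep names, coerce to double
as.numeric2 <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

#' @export
print.mdr_params <- function(x, ...) {
  cat("Mixture density regression parameters\n")
  cat(sprintf("  components : N(%.4g, %.4g) | N(%.4g, %.4g) [selection-enriched]\n",
              x$mu0, x$sigma0, x$mu1, x$sigma1))
  cat(sprintf("  intercept  : %.4g (baseline p = %.3f)\n",
              x$intercept, stats::plogis(x$intercept)))
  cat(sprintf("  slopes     : %d covariate(s)\n", length(x$slopes)))
  if (length(x$slopes)) {
    print(round(x$slopes, 4))
  }
  invisible(x)
}

#' Fitting configuration for the mixture density regression
#'
#' @param restarts Number of optimizer starts: the first uses the
#'   quantile-based initialization, the rest jitter it with a seeded RNG. The
#'   best log likelihood wins; ties go to the earliest start.
#' @param seed Integer seed driving the restart jitter (and nothing else).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param tol_loglik Relative log-likelihood convergence tolerance.
#' @param tol_grad Projected-gradient convergence tolerance.
#' @param init_jitter_sd Standard deviation of the Gaussian jitter applied to
#'   the starting point on the unconstrained scale for restarts beyond the
#'   first.
#' @return A list of class `mdr_fit_config`.
#' @export
mdr_fit_config <- function(restarts = 5L, seed = 1L, maxit = 2000L,
                           tol_loglik = 1e-9, tol_grad = 1e-6,
                           init_jitter_sd = 0.3) {
  stopifnot(restarts >= 1L, maxit >= 1L, tol_loglik > 0, tol_grad > 0,
            init_jitter_sd >= 0)
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 maxit = as.integer(maxit), tol_loglik = tol_loglik,
                 tol_grad = tol_grad, init_jitter_sd = init_jitter_sd),
            class = "mdr_fit_config")
}

#' Read a fit configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file whose keys
#'   are arguments of [mdr_fit_config()].
#' @return A `mdr_fit_config` list.
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(mdr_fit_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown fit-config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  do.call(mdr_fit_config, raw)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

logit <- function(p) log(p / (1 - p))
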