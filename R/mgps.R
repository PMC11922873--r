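# Multi-item gamma-Poisson shrinker. The observed count a of a drug-event
# pair is modelled Poisson(lambda * E) with the relative reporting rate
# lambda drawn from a two-component gamma mixture prior
#   lambda ~ P * Gamma(alpha1, beta1) + (1 - P) * Gamma(alpha2, beta2)
# (shape/rate). Marginally a is a mixture of negative binomials
#   nb(a; alpha, beta, E) = C(alpha + a - 1, a) (beta/(beta+E))^alpha
#                           (E/(beta+E))^a,
# i.e. dnbinom(a, size = alpha, prob = beta/(beta+E)). The five
# hyperparameters are fitted by maximizing the marginal likelihood over all
# observed pairs; the posterior of lambda given a is again a two-component
# gamma mixture, from which EBGM = 2^E[log2 lambda] and the posterior
# percentiles EB05/EB95 follow.

MGPS_START <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0, beta2 = 4.0,
                p_mix = 1 / 3)

mgps_negloglik <- function(par, a, E) {
  l1 <- dnbinom(a, size = par[1], prob = par[2] / (par[2] + E), log = TRUE)
  l2 <- dnbinom(a, size = par[3], prob = par[4] / (par[4] + E), log = TRUE)
  m <- pmax(l1, l2)
  ll <- m + log(par[5] * exp(l1 - m) + (1 - par[5]) * exp(l2 - m))
  -sum(ll)
}

#' Fit the MGPS gamma-mixture prior by marginal maximum likelihood
#'
#' Box-constrained quasi-Newton (L-BFGS-B) from the classic start point
#' (0.2, 0.1, 2.0, 4.0, 1/3), with shapes and rates bounded in
#' `[1e-6, 50]` and the mixing weight in `[1e-6, 1 - 1e-6]`. On
#' non-convergence (or a degenerate input with no nonzero counts) the start
#' point is returned with `converged = FALSE` and a warning.
#'
#' @param tables the observed pairs: either a data frame with columns `a`
#'   (observed count) and `E` (expected count under independence), or a
#'   list of [contingency_table()] objects
#' @param start optional start point, a named vector like `MGPS_START`
#' @return an `mgps_prior` object: `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `p_mix`, `loglik`, `converged`, `n_tables`
#' @export
fit_mgps_prior <- function(tables, start = MGPS_START) {
  if (is.data.frame(tables)) {
    a <- tables$a; E <- tables$E
  } else {
    a <- vapply(tables, `[[`, numeric(1), "a")
    E <- vapply(tables, function(t) {
      n <- t$a + t$b + t$c + t$d
      (t$a + t$b) * (t$a + t$c) / n
    }, numeric(1))
  }
  keep <- !is.na(a) & !is.na(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < 2L) {
    stop("fit_mgps_prior: need at least 2 pairs with positive E",
         call. = FALSE)
  }
  start_prior <- structure(c(as.list(start),
                             list(loglik = NA_real_, converged = FALSE,
                                  n_tables = length(a))),
                           class = "mgps_prior")
  if (all(a == 0)) {
    warning("fit_mgps_prior: all observed counts are zero; ",
            "returning the start-point prior (non-converged)",
            call. = FALSE)
    return(start_prior)
  }
  lower <- c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6)
  upper <- c(50, 50, 50, 50, 1 - 1e-6)
  fit <- tryCatch(
    stats::optim(start, mgps_negloglik, a = a, E = E, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    warning("fit_mgps_prior: optimizer did not converge; ",
            "returning the start-point prior", call. = FALSE)
    out <- start_prior
    if (!is.null(fit)) out$loglik <- -fit$value
    return(out)
  }
  p <- fit$par
  structure(list(alpha1 = p[[1]], beta1 = p[[2]], alpha2 = p[[3]],
                 beta2 = p[[4]], p_mix = p[[5]], loglik = -fit$value,
                 converged = TRUE, n_tables = length(a)),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> alpha1=%.4g beta1=%.4g alpha2=%.4g ",
                     "beta2=%.4g P=%.4g (%s, %d pairs)\n"),
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix,
              if (x$converged) "converged" else "NOT converged",
              x$n_tables))
  invisible(x)
}

#' Prior mean relative reporting rate
#'
#' `P * alpha1/beta1 + (1 - P) * alpha2/beta2`.
#'
#' @param prior an `mgps_prior`
#' @return numeric prior mean of lambda
#' @export
mgps_prior_mean <- function(prior) {
  prior$p_mix * prior$alpha1 / prior$beta1 +
    (1 - prior$p_mix) * prior$alpha2 / prior$beta2
}

# posterior mixture weight Q of the first component given observed a, E
mgps_posterior_weight <- function(a, E, prior) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + E), log = TRUE) +
    log(prior$p_mix)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + E), log = TRUE) +
    log(1 - prior$p_mix)
  m <- pmax(l1, l2)
  exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
}

#' Posterior CDF of the relative reporting rate
#'
#' The posterior of lambda given (a, E) is
#' `Q Gamma(alpha1 + a, beta1 + E) + (1 - Q) Gamma(alpha2 + a, beta2 + E)`.
#'
#' @param x quantile(s)
#' @param a observed count
#' @param E expected count
#' @param prior an `mgps_prior`
#' @return posterior CDF evaluated at `x`
#' @export
mgps_posterior_cdf <- function(x, a, E, prior) {
  q <- mgps_posterior_weight(a, E, prior)
  q * pgamma(x, shape = prior$alpha1 + a, rate = prior$beta1 + E) +
    (1 - q) * pgamma(x, shape = prior$alpha2 + a, rate = prior$beta2 + E)
}

mgps_posterior_quantile <- function(p, a, E, prior, tol = 1e-10) {
  q <- mgps_posterior_weight(a, E, prior)
  q1 <- qgamma(p, shape = prior$alpha1 + a, rate = prior$beta1 + E)
  q2 <- qgamma(p, shape = prior$alpha2 + a, rate = prior$beta2 + E)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (hi - lo < tol) return((lo + hi) / 2)
  f <- function(x) mgps_posterior_cdf(x, a, E, prior) - p
  uniroot(f, lower = lo, upper = hi, tol = tol,
          extendInt = "upX")$root
}

#' Empirical Bayes geometric mean with posterior percentiles
#'
#' EBGM = 2^E[log2 lambda] under the posterior gamma mixture, computed in
#' closed form via the digamma function:
#' `E[ln lambda] = Q (psi(alpha1 + a) - ln(beta1 + E)) + (1 - Q)
#' (psi(alpha2 + a) - ln(beta2 + E))`. EB05 and EB95 solve the posterior
#' CDF = 0.05 / 0.95 by bracketed root finding.
#'
#' @param t a [contingency_table()]
#' @param prior an `mgps_prior` from [fit_mgps_prior()]
#' @return list with `ebgm`, `eb05`, `eb95`, `posterior_weight`
#' @export
ebgm <- function(t, prior) {
  stopifnot(inherits(t, "contingency_table"), inherits(prior, "mgps_prior"))
  n <- t$a + t$b + t$c + t$d
  E <- (t$a + t$b) * (t$a + t$c) / n
  if (E <= 0) stop("ebgm: expected count E must be positive", call. = FALSE)
  a <- t$a
  q <- mgps_posterior_weight(a, E, prior)
  eln <- q * (digamma(prior$alpha1 + a) - log(prior$beta1 + E)) +
    (1 - q) * (digamma(prior$alpha2 + a) - log(prior$beta2 + E))
  structure(list(ebgm = exp(eln),
                 eb05 = mgps_posterior_quantile(0.05, a, E, prior),
                 eb95 = mgps_posterior_quantile(0.95, a, E, prior),
                 posterior_weight = q),
            class = "ebgm_result")
}
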