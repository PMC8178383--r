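#' Log-likelihood of the heteroscedastic Gaussian mixture
#'
#' Projected QTL peaks are modelled as
#' `x_i ~ sum_k pi_k * Normal(mu_k, s_i^2)` where the per-QTL standard
#' deviation `s_i` is fixed, derived from the QTL's projected 95% CI
#' (`s_i = ci95 / 3.92`), and only the component means `mu_k` and mixing
#' proportions `pi_k` are free.
#'
#' @param positions numeric vector of projected peak positions (cM).
#' @param sds per-QTL standard deviations (cM), all `> 0`.
#' @param means component means `mu_k`.
#' @param weights mixing proportions `pi_k` (must sum to 1).
#' @return the log-likelihood `sum_i log sum_k pi_k phi(x_i; mu_k, s_i^2)`.
#' @export
mixture_loglik <- function(positions, sds, means, weights) {
  stopifnot(length(positions) == length(sds), length(means) == length(weights))
  if (any(sds <= 0)) abort("all per-QTL standard deviations must be > 0")
  lp <- log_component_matrix(positions, sds, means, weights)
  sum(apply(lp, 1L, log_sum_exp))
}

# n x k matrix of log(pi_k) + log phi(x_i; mu_k, s_i)
log_component_matrix <- function(x, s, mu, pi) {
  k <- length(mu)
  matrix(vapply(seq_len(k),
                function(j) dnorm(x, mu[j], s, log = TRUE) + log(pi[j]),
                numeric(length(x))),
         nrow = length(x), ncol = k)
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Fit the heteroscedastic mixture by EM for a fixed number of components
#'
#' EM with per-observation fixed variances: the E-step computes
#' responsibilities `r_ik` proportional to `pi_k phi(x_i; mu_k, s_i^2)`;
#' the M-step sets `mu_k` to the responsibility- and inverse-variance-
#' weighted mean of the positions and `pi_k` to the mean responsibility.
#' Iterations stop when the log-likelihood improves by less than `tol`
#' (or after `max_iter` iterations). The best of `restarts` deterministic
#' seeded initializations is kept; initial means are empirical quantiles
#' of the positions (evenly spaced probabilities for the first restart,
#' seeded random probabilities afterwards).
#'
#' Model-choice criteria are attached with free-parameter count
#' `p = 2k - 1` (k means and k - 1 independent weights; the per-QTL
#' variances are data, not parameters):
#' `AIC = -2 lnL + 2p`, `AICc = AIC + 2p(p+1)/(n-p-1)` (`Inf` when
#' `n - p - 1 <= 0`), `BIC = -2 lnL + p ln n`,
#' `AWE = -2 lnL + 2p(3/2 + ln n)`.
#'
#' If any two fitted means come within `1e-6` cM the restart is recorded
#' as non-identifiable; a fit is returned with `identifiable = FALSE` only
#' when every restart collapses.
#'
#' @inheritParams mixture_loglik
#' @param k number of components, `1 <= k <= n`.
#' @param restarts number of seeded initializations (default 10).
#' @param seed integer seed making the restarts deterministic.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 1000).
#' @return object of class `mqtl_mixture`: list with `k`, `means`,
#'   `weights`, `loglik`, `loglik_trace`, `responsibilities` (n x k),
#'   `n_params`, `aic`, `aicc`, `bic`, `awe`, `identifiable`, `n`.
#' @export
fit_mixture <- function(positions, sds, k, restarts = 10, seed = 42,
                        tol = 1e-8, max_iter = 1000) {
  n <- length(positions)
  stopifnot(length(sds) == n)
  if (any(sds <= 0)) abort("all per-QTL standard deviations must be > 0")
  if (k < 1 || k > n) abort("k must satisfy 1 <= k <= n")
  if (k == 1) restarts <- 1L

  best <- NULL
  for (r in seq_len(restarts)) {
    probs <- if (r == 1) {
      (seq_len(k) - 0.5) / k
    } else {
      sort(seeded_runif(k, seed = seed + 1000L * r))
    }
    mu0 <- unname(quantile(positions, probs, type = 7))
    mu0 <- spread_degenerate(mu0, positions)
    fit <- em_run(positions, sds, mu0, rep(1 / k, k), tol, max_iter)
    if (is.null(best) ||
        (fit$identifiable && !best$identifiable) ||
        (fit$identifiable == best$identifiable && fit$loglik > best$loglik))
      best <- fit
  }

  crit <- information_criteria(best$loglik, k, n)
  structure(c(list(
    k = k, means = best$means, weights = best$weights,
    loglik = best$loglik, loglik_trace = best$trace,
    responsibilities = best$resp, n = n),
    as.list(crit),
    list(identifiable = best$identifiable,
         positions = positions, sds = sds)),
    class = "mqtl_mixture")
}

#' Model-choice criteria for a mixture fit
#'
#' Free-parameter count is `p = 2k - 1` (k means and k - 1 independent
#' weights; the per-QTL variances are data, not parameters). The four
#' criteria are `AIC = -2 lnL + 2p`,
#' `AICc = AIC + 2p(p + 1)/(n - p - 1)` (`Inf` when `n - p - 1 <= 0`),
#' `BIC = -2 lnL + p ln n` and `AWE = -2 lnL + 2p(3/2 + ln n)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of mixture components.
#' @param n number of observations.
#' @return one-row tibble `n_params`, `aic`, `aicc`, `bic`, `awe`.
#' @export
#' @examples
#' information_criteria(-100, k = 2, n = 10)  # p = 3
information_criteria <- function(loglik, k, n) {
  p <- 2 * k - 1
  m2ll <- -2 * loglik
  tibble::tibble(
    n_params = p,
    aic = m2ll + 2 * p,
    aicc = if (n - p - 1 > 0) m2ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
           else Inf,
    bic = m2ll + p * log(n),
    awe = m2ll + 2 * p * (3 / 2 + log(n)))
}

# single EM run from a given initialization
em_run <- function(x, s, mu, pi, tol, max_iter) {
  n <- length(x); k <- length(mu)
  trace <- numeric(0)
  ll_old <- -Inf
  resp <- matrix(1, n, k)
  for (it in seq_len(max_iter)) {
    lp <- log_component_matrix(x, s, mu, pi)
    row_lse <- apply(lp, 1L, log_sum_exp)
    ll <- sum(row_lse)
    resp <- exp(lp - row_lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- 1 / s^2
    denom <- colSums(resp * w)
    mu_new <- colSums(resp * w * x) / denom
    # a component losing all responsibility mass keeps its mean
    mu <- ifelse(is.finite(mu_new), mu_new, mu)
    pi <- pmax(colMeans(resp), 1e-300)
    pi <- pi / sum(pi)
  }
  identifiable <- k == 1 || min(diff(sort(mu))) > 1e-6
  list(means = mu, weights = pi, loglik = trace[length(trace)],
       trace = trace, resp = resp, identifiable = identifiable)
}

# deterministic uniforms that do not disturb the caller's RNG stream
seeded_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  runif(n)
}

# nudge coincident initial means apart so EM can separate components
spread_degenerate <- function(mu, x) {
  rng <- diff(range(x))
  if (rng == 0) rng <- 1
  eps <- 1e-3 * rng
  for (i in seq_along(mu)[-1]) {
    if (mu[i] - mu[i - 1] < eps) mu[i] <- mu[i - 1] + eps
  }
  mu
}

#' Choose the number of components by criterion vote
#'
#' The chosen `k` is the one attaining the minimum of at least three of
#' the four criteria (AIC, AICc, BIC, AWE). When no `k` collects three
#' votes, the smallest `k` among those with the most votes is taken, with
#' the BIC winner as final fallback. Non-identifiable fits (collapsed
#' means) are excluded from the vote.
#'
#' @param fits list of `mqtl_mixture` objects, one per candidate `k`.
#' @return the chosen `mqtl_mixture` fit.
#' @export
select_best_k <- function(fits) {
  if (!length(fits)) abort("no fits supplied")
  fits <- fits[order(purrr::map_dbl(fits, "k"))]
  usable <- purrr::map_lgl(fits, "identifiable")
  if (!any(usable)) usable <- rep(TRUE, length(fits))
  cand <- fits[usable]
  ks <- purrr::map_dbl(cand, "k")
  votes <- setNames(rep(0L, length(cand)), ks)
  for (crit in c("aic", "aicc", "bic", "awe")) {
    vals <- purrr::map_dbl(cand, crit)
    win <- which.min(vals)  # first (smallest-k) minimum
    votes[win] <- votes[win] + 1L
  }
  if (max(votes) >= 3) return(cand[[which(votes == max(votes))[1]]])
  top <- which(votes == max(votes))
  if (length(top)) {
    # smallest k among the most-voted; fall back to BIC winner on a
    # 4-way scatter (every k with exactly one vote)
    if (max(votes) >= 2) return(cand[[top[1]]])
  }
  cand[[which.min(purrr::map_dbl(cand, "bic"))]]
}

#' @export
print.mqtl_mixture <- function(x, ...) {
  cat("Gaussian mixture with fixed per-QTL variances\n")
  cat(sprintf("  n = %d QTL, k = %d component(s), logLik = %.4f\n",
              x$n, x$k, x$loglik))
  cat(sprintf("  AIC %.3f | AICc %.3f | BIC %.3f | AWE %.3f\n",
              x$aic, x$aicc, x$bic, x$awe))
  if (!x$identifiable) cat("  (non-identifiable: collapsed means)\n")
  invisible(x)
}

#' @method tidy mqtl_mixture
#' @export
tidy.mqtl_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), mean = x$means,
                 weight = x$weights,
                 n_members = colSums(
                   outer(max.col(x$responsibilities), seq_len(x$k), "==")))
}

#' @method glance mqtl_mixture
#' @export
glance.mqtl_mixture <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik,
                 n_params = x$n_params, aic = x$aic, aicc = x$aicc,
                 bic = x$bic, awe = x$awe, identifiable = x$identifiable)
}
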