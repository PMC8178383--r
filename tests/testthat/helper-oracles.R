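# Independent oracles used to cross-check the EM mixture core and the
# interval queries. These deliberately avoid the package's own code paths.

# direct log-likelihood of the heteroscedastic mixture (plain loop)
oracle_loglik <- function(x, s, mu, pi) {
  tot <- 0
  for (i in seq_along(x)) {
    dens <- 0
    for (j in seq_along(mu)) dens <- dens + pi[j] * dnorm(x[i], mu[j], s[i])
    tot <- tot + log(dens)
  }
  tot
}

# maximized log-likelihood by dense grid search with local refinement,
# for k = 1 or 2 components (practical for n <= 4)
oracle_grid_max <- function(x, s, k, n_mu = 61, n_pi = 49, refine = 3) {
  lo <- min(x) - 2 * max(s); hi <- max(x) + 2 * max(s)
  mu_grid <- seq(lo, hi, length.out = n_mu)
  if (k == 1) {
    best <- c(mu = mu_grid[1], ll = -Inf)
    for (r in seq_len(refine)) {
      ll <- vapply(mu_grid, function(m) oracle_loglik(x, s, m, 1),
                   numeric(1))
      i <- which.max(ll)
      best <- c(mu = mu_grid[i], ll = ll[i])
      step <- diff(mu_grid[1:2])
      mu_grid <- seq(best[["mu"]] - step, best[["mu"]] + step,
                     length.out = n_mu)
    }
    return(best[["ll"]])
  }
  stopifnot(k == 2)
  pi_grid <- seq(0.01, 0.99, length.out = n_pi)
  best <- list(mu1 = mu_grid[1], mu2 = mu_grid[2], pi = 0.5, ll = -Inf)
  g1 <- g2 <- mu_grid
  for (r in seq_len(refine)) {
    # n x g density matrices per component position
    P1 <- vapply(g1, function(m) dnorm(x, m, s), numeric(length(x)))
    P2 <- vapply(g2, function(m) dnorm(x, m, s), numeric(length(x)))
    for (p in pi_grid) {
      # sum_i log(p * P1[i, a] + (1 - p) * P2[i, b]) over all (a, b)
      ll <- matrix(0, length(g1), length(g2))
      for (i in seq_along(x))
        ll <- ll + log(outer(p * P1[i, ], (1 - p) * P2[i, ], "+"))
      m <- which(ll == max(ll), arr.ind = TRUE)[1, ]
      if (ll[m[1], m[2]] > best$ll)
        best <- list(mu1 = g1[m[1]], mu2 = g2[m[2]], pi = p,
                     ll = ll[m[1], m[2]])
    }
    s1 <- diff(g1[1:2]); s2 <- diff(g2[1:2])
    g1 <- seq(best$mu1 - s1, best$mu1 + s1, length.out = 31)
    g2 <- seq(best$mu2 - s2, best$mu2 + s2, length.out = 31)
  }
  best$ll
}

# brute-force interval query used against genes_in_interval
oracle_genes_in_interval <- function(genes, chromosome, lo, hi,
                                     exclude_te = TRUE) {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    keep[i] <- g$chromosome == chromosome && g$start <= hi && g$end >= lo &&
      (!exclude_te || !g$is_te)
  }
  genes$gene_id[keep]
}
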