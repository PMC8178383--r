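test_that("mixture log-likelihood matches closed-form normal densities", {
  # one QTL sitting on its component mean, sd 1: standard normal at 0
  expect_equal(mixture_loglik(5, 1, 5, 1), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # K = 1: two observations from N(15, 2^2)
  expect_equal(mixture_loglik(c(10, 20), c(2, 2), 15, 1),
               sum(dnorm(c(10, 20), 15, 2, log = TRUE)))
  # equal-mean two-component mixture collapses to K = 1
  expect_equal(mixture_loglik(c(10, 20), c(2, 2), c(15, 15), c(0.5, 0.5)),
               mixture_loglik(c(10, 20), c(2, 2), 15, 1))
  # agrees with the plain-loop oracle on a random instance
  set.seed(3)
  x <- runif(6, 0, 50); s <- runif(6, 0.5, 3)
  expect_equal(mixture_loglik(x, s, c(10, 35), c(0.3, 0.7)),
               oracle_loglik(x, s, c(10, 35), c(0.3, 0.7)))
  expect_error(mixture_loglik(1, 0, 1, 1), "standard deviations")
})

test_that("K = 1 EM recovers the inverse-variance weighted mean", {
  f <- fit_mixture(c(10, 20), c(2, 2), k = 1)
  expect_equal(f$means, 15)
  expect_equal(f$weights, 1)
  f2 <- fit_mixture(c(0, 30), c(1, 3), k = 1)
  expect_equal(f2$means, (0 * 1 + 30 / 9) / (1 + 1 / 9), tolerance = 1e-9)
  expect_equal(f2$means, 3, tolerance = 1e-9)
})

test_that("information criteria match their hand-computed values", {
  crit <- information_criteria(-100, k = 2, n = 10)  # p = 3
  expect_equal(crit$n_params, 3)
  expect_equal(crit$aic, 206)
  expect_equal(crit$aicc, 210)
  expect_equal(crit$bic, 206.908, tolerance = 1e-3)
  expect_equal(crit$awe, 222.816, tolerance = 1e-3)
  # AICc degenerates to +Inf when n - p - 1 <= 0
  expect_equal(information_criteria(-10, k = 2, n = 4)$aicc, Inf)
})

test_that("EM log-likelihood is non-decreasing and normalizations hold", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 100)
    s <- runif(n, 0.5, 5)
    k <- sample(1:min(3, n), 1)
    f <- fit_mixture(x, s, k, restarts = 3, seed = i)
    expect_true(all(diff(f$loglik_trace) >= -1e-8))
    expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    expect_equal(rowSums(f$responsibilities), rep(1, n), tolerance = 1e-9)
    # reported likelihood is reproducible from the reported parameters
    expect_equal(f$loglik, mixture_loglik(x, s, f$means, f$weights),
                 tolerance = 1e-6)
  }
})

test_that("EM attains the grid-search optimum for tiny problems", {
  set.seed(8)
  for (i in 1:12) {
    n <- sample(2:4, 1)
    x <- runif(n, 0, 20)
    s <- runif(n, 0.5, 3)
    for (k in 1:min(2, n)) {
      em <- fit_mixture(x, s, k, restarts = 10, seed = i)$loglik
      grid <- oracle_grid_max(x, s, k)
      expect_equal(em, grid, tolerance = 1e-3)
    }
  }
})

test_that("EM separates well-resolved components (external cross-check)", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(5)
  x <- c(rnorm(25, 20, 1), rnorm(25, 60, 1))
  s <- rep(1, 50)
  f <- fit_mixture(x, s, k = 2, restarts = 5, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(sort(f$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.2)
})

fake_fit <- function(k, aic, aicc, bic, awe) {
  structure(list(k = k, aic = aic, aicc = aicc, bic = bic, awe = awe,
                 identifiable = TRUE), class = "mqtl_mixture")
}

test_that("model choice follows the three-of-four vote rule", {
  # k = 2 minimizes AIC, BIC, AWE; k = 3 minimizes AICc -> k = 2
  fits <- list(fake_fit(1, 10, 10, 10, 10),
               fake_fit(2, 5, 6, 5, 5),
               fake_fit(3, 6, 5, 6, 6))
  expect_equal(select_best_k(fits)$k, 2)
  # unanimous k = 1
  fits <- list(fake_fit(1, 1, 1, 1, 1), fake_fit(2, 2, 2, 2, 2))
  expect_equal(select_best_k(fits)$k, 1)
  # 2-2 split between k = 2 and k = 4 -> smallest k among most voted
  fits <- list(fake_fit(1, 9, 9, 9, 9),
               fake_fit(2, 1, 1, 5, 5),
               fake_fit(3, 8, 8, 8, 8),
               fake_fit(4, 2, 2, 4, 4))
  expect_equal(select_best_k(fits)$k, 2)
  # non-identifiable fits are excluded from the vote
  fits <- list(fake_fit(1, 9, 9, 9, 9), fake_fit(2, 1, 1, 1, 1))
  fits[[2]]$identifiable <- FALSE
  expect_equal(select_best_k(fits)$k, 1)
})

test_that("degenerate inputs are guarded", {
  expect_error(fit_mixture(c(1, 2), c(1, 1), k = 3), "1 <= k <= n")
  expect_error(fit_mixture(c(1, 2), c(1, 0), k = 1), "standard deviations")
  # coincident positions: k = 2 collapses and is flagged non-identifiable
  f <- fit_mixture(rep(10, 4), rep(1, 4), k = 2, restarts = 3)
  expect_false(f$identifiable)
})

test_that("tidy and glance expose components and criteria", {
  f <- fit_mixture(c(1, 2, 30, 31), rep(1, 4), k = 2, seed = 2)
  td <- tidy(f)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$n_members), 4)
  gl <- glance(f)
  expect_equal(gl$k, 2)
  expect_equal(gl$aic, f$aic)
})
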