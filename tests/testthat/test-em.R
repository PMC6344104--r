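no_hidden_regression <- function() {
  dbn_structure(
    tibble::tibble(name = c("x", "y"), kind = "continuous"),
    tibble::tibble(from = c("x", "x"), to = c("x", "y"), lag = 1L)
  )
}

test_that("without hidden nodes EM reduces to ordinary least squares", {
  set.seed(1)
  n <- 80
  x <- rnorm(n)
  y <- 0.7 + 1.3 * c(0, head(x, -1)) + rnorm(n, sd = 0.5)
  dat <- toy_table(cbind(x = x, y = y))
  fit <- fit_em(no_hidden_regression(), dat, em_config(seed = 2))
  ols <- lm(y[-1] ~ x[-n])
  expect_equal(fit$params$y$mu, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit$params$y$w[1, 1], unname(coef(ols)[2]), tolerance = 1e-8)
  s2 <- sum(residuals(ols)^2) / (n - 1)
  expect_equal(fit$params$y$sigma2, s2, tolerance = 1e-8)
  # and it converges immediately: a single-iteration fixed point
  trace <- attr(fit, "trace")
  expect_lte(max(trace$iteration), 2)
})

test_that("the log-likelihood trace is monotone on every run", {
  for (s in 1:3) {
    spec <- synthetic_spec(
      n_years = 24, n_climate = 2, n_physio = 2, n_biota = 3, seed = s
    )
    truth <- generate_structure(spec)
    sim <- simulate_table(truth)
    fit <- fit_em(
      truth$structure, sim$data,
      em_config(n_inits = 3, max_iterations = 40, seed = 100 + s)
    )
    trace <- attr(fit, "trace")
    for (i in unique(trace$init)) {
      lls <- trace$loglik[trace$init == i]
      expect_gte(min(diff(lls)), -1e-8)
    }
  }
})

test_that("the M-step is a fixed point of exact model statistics", {
  # build sufficient statistics from the model's own analytic moments
  # (infinite-data limit of a no-hidden AR regression): the M-step must
  # return exactly the generating parameters
  st <- no_hidden_regression()
  mu_y <- 0.4
  w_y <- 0.8
  s2 <- 0.25
  # x ~ AR(0.5) stationary: var = 1 / (1 - 0.25) with unit innovations
  vx <- 1 / (1 - 0.25)
  n <- 1000
  stats <- list(
    node = list(
      x = list(list(
        S_zz = n * matrix(c(1, 0, 0, vx), 2, 2),
        S_zy = n * c(0, 0.5 * vx),
        S_yy = n * vx, n = n
      )),
      y = list(list(
        S_zz = n * matrix(c(1, 0, 0, vx), 2, 2),
        S_zy = n * c(mu_y, w_y * vx),
        S_yy = n * (mu_y^2 + w_y^2 * vx + s2), n = n
      ))
    ),
    chain = list()
  )
  fit <- m_step(stats, st)
  expect_equal(fit$params$y$mu, mu_y, tolerance = 1e-9)
  expect_equal(fit$params$y$w[1, 1], w_y, tolerance = 1e-9)
  expect_equal(fit$params$y$sigma2, s2, tolerance = 1e-9)
  expect_equal(fit$params$x$w[1, 1], 0.5, tolerance = 1e-9)
})

test_that("a converged EM solution is a fixed point of one more cycle", {
  spec <- synthetic_spec(n_years = 30, n_climate = 2, n_physio = 1, n_biota = 2, seed = 5)
  truth <- generate_structure(spec)
  sim <- simulate_table(truth)
  fit <- fit_em(
    truth$structure, sim$data,
    em_config(n_inits = 2, max_iterations = 300, rel_tolerance = 1e-12, seed = 6)
  )
  es <- e_step(fit, sim$data)
  fit2 <- m_step(es$stats, truth$structure, prev = fit)
  for (v in names(fit$params)) {
    expect_equal(fit2$params[[v]]$mu, fit$params[[v]]$mu, tolerance = 1e-5)
    expect_equal(fit2$params[[v]]$sigma2, fit$params[[v]]$sigma2, tolerance = 1e-5)
  }
  for (h in names(fit$chains)) {
    expect_equal(fit2$chains[[h]]$A, fit$chains[[h]]$A, tolerance = 1e-5)
  }
})

test_that("parameters of a two-state model are recovered from long series", {
  spec <- synthetic_spec(
    n_years = 500, n_climate = 2, n_physio = 1, n_biota = 2,
    hidden_persistence = 0.9, regime_shift = 2, noise_sd = 0.4, seed = 7
  )
  truth <- generate_structure(spec)
  sim <- simulate_dbn(truth$model, 500, seed = 8)
  fit <- fit_em(
    truth$structure, sim$data,
    em_config(n_inits = 3, max_iterations = 100, seed = 9)
  )
  # canonical ordering aligns states (ascending first-child mean);
  # the generator plants ascending means already
  expect_lt(max(abs(diag(fit$chains$H_regime$A) - 0.9)), 0.05)
  expect_lt(max(abs(fit$params$clim1$mu - c(-1, 1))), 0.1)
  w_true <- truth$model$params$biota1$w
  expect_lt(max(abs(fit$params$biota1$w - w_true)), 0.1)
})

test_that("an empty state falls back to pseudocounts and previous parameters", {
  st <- dbn_structure(
    tibble::tibble(name = c("H", "x"), kind = c("hidden", "continuous")),
    tibble::tibble(from = c("H", "H"), to = c("H", "x"), lag = c(1L, 0L))
  )
  T_ <- 5
  gamma <- matrix(c(1, 0), T_, 2, byrow = TRUE) # all mass on state 1
  xi <- matrix(c(T_ - 1, 0, 0, 0), 2, 2)
  dat <- toy_table(cbind(x = c(0.1, -0.2, 0.3, 0, 0.2)))
  prev <- dbn_model(
    st,
    params = list(x = clg_params(mu = c(9, -9), sigma2 = c(4, 4))),
    chains = list(H = list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2)))
  )
  stats <- ecodbn:::suffstats_from_posterior(
    st, dat, gamma, xi,
    S = cbind(H = 1:2)
  )
  fit <- m_step(stats, st, prev = prev)
  # state 1 re-estimated from data, state 2 kept from prev
  expect_equal(fit$params$x$mu[2], -9)
  expect_equal(fit$params$x$mu[1], mean(dat$x), tolerance = 1e-8)
  # transition rows renormalize from pseudocounts; row 2 has no counts
  expect_equal(fit$chains$H$A[2, ], c(0.5, 0.5), tolerance = 1e-9)
  expect_gt(fit$chains$H$A[1, 1], 0.99)
})

test_that("estimation error shrinks with series length", {
  err_at <- function(n_years) {
    errs <- vapply(1:6, function(s) {
      spec <- synthetic_spec(
        n_years = max(n_years, 10), n_climate = 2, n_physio = 1, n_biota = 1,
        hidden_persistence = 0.85, regime_shift = 2, noise_sd = 0.4, seed = s
      )
      truth <- generate_structure(spec)
      sim <- simulate_dbn(truth$model, n_years, seed = 50 + s)
      fit <- fit_em(
        truth$structure, sim$data,
        em_config(n_inits = 2, max_iterations = 60, seed = 60 + s)
      )
      abs(fit$chains$H_regime$A[1, 1] - 0.85)
    }, numeric(1))
    median(errs)
  }
  e100 <- err_at(100)
  e1000 <- err_at(1000)
  expect_lt(e1000, e100 + 1e-9)
})
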