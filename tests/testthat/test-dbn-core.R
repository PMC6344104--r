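test_that("conditional linear Gaussian density matches the normal formula", {
  p0 <- clg_params(mu = 0, sigma2 = 1)
  expect_equal(clg_logdensity(0, params = p0), -0.5 * log(2 * pi), tolerance = 1e-10)

  p1 <- clg_params(mu = 1, w = matrix(2, 1, 1), sigma2 = 1)
  expect_equal(clg_logdensity(2, x = 0.5, params = p1), -0.5 * log(2 * pi), tolerance = 1e-10)

  # arbitrary cases against the explicit formula
  set.seed(7)
  for (i in 1:20) {
    mu <- rnorm(2)
    w <- matrix(rnorm(6), 2, 3)
    s2 <- rexp(2) + 0.1
    p <- clg_params(mu, w, s2)
    x <- rnorm(3)
    y <- rnorm(1)
    q <- sample(1:2, 1)
    m <- mu[q] + sum(w[q, ] * x)
    expect_equal(
      clg_logdensity(y, x, q, p),
      -0.5 * log(2 * pi * s2[q]) - (y - m)^2 / (2 * s2[q]),
      tolerance = 1e-12
    )
  }
  expect_error(clg_logdensity(0, x = 1, params = p0), "parent value length")
  expect_error(clg_logdensity(0, q = 3, params = p0), "out of range")
})

test_that("structure invariants are enforced", {
  nodes <- tibble::tibble(name = c("H", "x"), kind = c("hidden", "continuous"))
  expect_error(
    dbn_structure(nodes, tibble::tibble(from = "x", to = "x", lag = 0L)),
    "self-loop"
  )
  expect_error(
    dbn_structure(
      tibble::tibble(name = c("H", "G"), kind = "hidden"),
      tibble::tibble(from = "H", to = "G", lag = 0L)
    ),
    "hidden-to-hidden"
  )
  expect_error(
    dbn_structure(nodes, tibble::tibble(from = "x", to = "H", lag = 0L)),
    "continuous parents"
  )
  expect_error(
    dbn_structure(
      tibble::tibble(name = c("a", "b"), kind = "continuous"),
      tibble::tibble(from = c("a", "b"), to = c("b", "a"), lag = 0L)
    ),
    "cycle"
  )
  # lag-1 two-cycles are legitimate (they unroll forward in time)
  st <- dbn_structure(
    tibble::tibble(name = c("a", "b"), kind = "continuous"),
    tibble::tibble(from = c("a", "b"), to = c("b", "a"), lag = 1L)
  )
  expect_s3_class(st, "dbn_structure")
})

test_that("complete-data log-likelihood agrees with hand arithmetic", {
  # degenerate: single node, no parents, no hidden
  st <- dbn_structure(
    tibble::tibble(name = "x", kind = "continuous"),
    tibble::tibble(from = character(), to = character(), lag = integer())
  )
  fit <- dbn_model(st, params = list(x = clg_params(mu = 0.3, sigma2 = 2)))
  dat <- toy_table(cbind(x = c(-1, 0.5, 2)))
  expect_equal(
    joint_loglik_complete(fit, dat, list()),
    sum(dnorm(dat$x, 0.3, sqrt(2), log = TRUE)),
    tolerance = 1e-12
  )

  # 2-year toy with hidden chain, hand-computed
  fit2 <- toy_hmm(p_stay = 0.8, pi1 = 0.6)
  dat2 <- toy_table(cbind(x = c(0.2, -0.4), y = c(1.0, 0.1)))
  path <- list(H = c(1L, 2L))
  # chain: log pi_1 + log A[1,2]
  expected <- log(0.6) + log(0.2) +
    # year 1: y | H=1 only; x has a lag-1 parent, so its first-year
    # emission is omitted (conditional AR likelihood)
    dnorm(1.0, 0.5, sqrt(1.2), log = TRUE) +
    # year 2: x | H=2 with AR on x_1, y | H=2
    dnorm(-0.4, 1 + 0.3 * 0.2, sqrt(0.8), log = TRUE) +
    dnorm(0.1, -0.5, sqrt(0.9), log = TRUE)
  expect_equal(joint_loglik_complete(fit2, dat2, path), expected, tolerance = 1e-10)

  # zero-probability transition gives -Inf
  fit3 <- toy_hmm(p_stay = 1, pi1 = 0.6)
  expect_identical(joint_loglik_complete(fit3, dat2, path), -Inf)
})

test_that("forward filter equals brute-force path enumeration", {
  fit <- toy_hmm()
  for (T_ in c(3, 5, 8)) {
    set.seed(T_)
    dat <- toy_table(cbind(x = rnorm(T_), y = rnorm(T_)))
    ff <- forward_filter(fit, dat)
    expect_equal(ff$loglik, enum_loglik(fit, dat), tolerance = 1e-8)
  }
  # with a missing cell marginalized
  dat <- toy_table(cbind(x = c(0.3, NA, -0.2), y = c(NA, 0.8, 0.1)))
  expect_equal(forward_filter(fit, dat)$loglik, enum_loglik(fit, dat), tolerance = 1e-8)
})

test_that("uninformative emissions leave the prior untouched", {
  st <- dbn_structure(
    tibble::tibble(name = c("H", "x"), kind = c("hidden", "continuous")),
    tibble::tibble(from = c("H", "H"), to = c("H", "x"), lag = c(1L, 0L))
  )
  fit <- dbn_model(
    st,
    params = list(x = clg_params(mu = c(0.4, 0.4), sigma2 = c(1, 1))),
    chains = list(H = list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2)))
  )
  dat <- toy_table(cbind(x = c(1, -2, 0.5)))
  ff <- forward_filter(fit, dat)
  expect_equal(unique(round(ff$marginals$prob, 12)), 0.5)
})

test_that("fully missing evidence yields zero log-likelihood and the prior chain", {
  fit <- toy_hmm(p_stay = 0.7, pi1 = 0.9)
  dat <- toy_table(cbind(x = rep(NA_real_, 4), y = rep(NA_real_, 4)))
  ff <- forward_filter(fit, dat)
  expect_equal(ff$loglik, 0)
  m <- ff$marginals
  # prior chain: p_t = p_{t-1} A
  p <- c(0.9, 0.1)
  for (t in 1:4) {
    if (t > 1) p <- as.vector(p %*% fit$chains$H$A)
    expect_equal(m$prob[m$year == t & m$state == 1], p[1], tolerance = 1e-12)
  }
})

test_that("smoothing matches enumeration and filtering at the last year", {
  fit <- toy_hmm()
  set.seed(11)
  dat <- toy_table(cbind(x = rnorm(4), y = rnorm(4)))
  sm <- infer_hidden(fit, dat)
  for (t in 1:4) {
    expect_equal(
      sm$prob[sm$year == t & sm$state == 2],
      enum_posterior(fit, dat, "H", t, 2),
      tolerance = 1e-8
    )
  }
  # proper distributions
  sums <- tapply(sm$prob, sm$year, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # smoothed == filtered at final year
  ff <- forward_filter(fit, dat)
  expect_equal(
    sm$prob[sm$year == 4],
    ff$marginals$prob[ff$marginals$year == 4],
    tolerance = 1e-12
  )
})

test_that("a deterministic chain forces its path", {
  fit <- toy_hmm(p_stay = 1, pi1 = 1)
  set.seed(3)
  dat <- toy_table(cbind(x = rnorm(3), y = rnorm(3)))
  sm <- infer_hidden(fit, dat)
  expect_equal(sm$prob[sm$state == 1], rep(1, 3), tolerance = 1e-12)
})

test_that("one-step prediction is exact in the pure linear case", {
  fit <- linear_chain_model(w_sa = 0.8, w_ab = 0.5, sigma2 = 0.3)
  pr <- predict_one_step(fit, c(sst = 1.5, a = -0.4, b = 2))
  expect_equal(pr$mean[pr$variable == "sst"], 0.5 * 1.5, tolerance = 1e-12)
  expect_equal(pr$mean[pr$variable == "a"], 0.8 * 1.5, tolerance = 1e-12)
  expect_equal(pr$mean[pr$variable == "b"], 0.5 * -0.4, tolerance = 1e-12)
  expect_equal(pr$var[match(c("a", "b"), pr$variable)], c(0.3, 0.3), tolerance = 1e-12)
})

test_that("symmetric two-state mixture gives mean 0 and inflated variance", {
  st <- dbn_structure(
    tibble::tibble(name = c("H", "x"), kind = c("hidden", "continuous")),
    tibble::tibble(from = c("H", "H"), to = c("H", "x"), lag = c(1L, 0L))
  )
  fit <- dbn_model(
    st,
    params = list(x = clg_params(mu = c(-1, 1), sigma2 = c(0.7, 0.7))),
    chains = list(H = list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2)))
  )
  pr <- predict_one_step(fit, c(x = 0), hidden_prior = list(H = c(0.5, 0.5)))
  expect_equal(pr$mean, 0, tolerance = 1e-12)
  expect_equal(pr$var, 0.7 + 1, tolerance = 1e-12)
})

test_that("prediction matches a Monte-Carlo forward sample", {
  fit <- toy_hmm(p_stay = 0.75, pi1 = 0.5)
  prior <- list(H = c(0.3, 0.7))
  evidence <- c(x = 0.6, y = -0.2)
  pr <- predict_one_step(fit, evidence, prior)
  n <- 2e5
  set.seed(99)
  h_prev <- sample(1:2, n, replace = TRUE, prob = prior$H)
  h_t <- ifelse(runif(n) < fit$chains$H$A[cbind(h_prev, 1)], 1L, 2L)
  px <- fit$params$x
  x_t <- rnorm(n, px$mu[h_t] + px$w[h_t, 1] * evidence[["x"]], sqrt(px$sigma2[h_t]))
  se <- sd(x_t) / sqrt(n)
  expect_lt(abs(mean(x_t) - pr$mean[pr$variable == "x"]), 3 * se)
  expect_equal(var(x_t), pr$var[pr$variable == "x"], tolerance = 0.02)
})

test_that("sampling is reproducible and follows the law of large numbers", {
  fit <- toy_hmm()
  s1 <- simulate_dbn(fit, 20, seed = 5)
  s2 <- simulate_dbn(fit, 20, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_dbn(fit, 20, seed = 6)
  expect_false(identical(s1$data, s3$data))

  # no-parent node y: mean over many draws ~ weighted mixture of mu
  big <- simulate_dbn(toy_hmm(p_stay = 0.5, pi1 = 0.5), 2e4, seed = 8)
  # stationary distribution uniform: E[y] = 0.5 * 0.5 + 0.5 * (-0.5) = 0
  se <- sd(big$data$y) / sqrt(2e4)
  expect_lt(abs(mean(big$data$y) - 0), 3 * se)

  # identity transitions freeze the hidden state
  frozen <- simulate_dbn(toy_hmm(p_stay = 1, pi1 = 0.5), 50, seed = 9)
  expect_equal(length(unique(frozen$hidden$state)), 1L)
})
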