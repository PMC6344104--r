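test_that("sse is the plain sum of squared differences", {
  expect_equal(sse(c(1, 2), c(1, 2)), 0)
  expect_equal(sse(c(1, 2), c(0, 0)), 5)
  expect_error(sse(1:3, 1:2), "length mismatch")
  set.seed(1)
  p <- rnorm(50)
  a <- rnorm(50)
  ref <- 0
  for (i in 1:50) ref <- ref + (p[i] - a[i])^2
  expect_equal(sse(p, a), ref, tolerance = 1e-12)
  # pairwise-complete on missing actuals
  a[c(3, 7)] <- NA
  expect_equal(sse(p, a), sum((p[-c(3, 7)] - a[-c(3, 7)])^2), tolerance = 1e-12)
})

test_that("bootstrap splits are reproducible out-of-bag partitions", {
  s1 <- bootstrap_split(32, seed = 4)
  s2 <- bootstrap_split(32, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1$train, 32)
  expect_length(intersect(unique(s1$train), s1$test), 0)
  expect_gt(length(s1$test), 0)
  expect_true(all(sort(union(unique(s1$train), s1$test)) == 1:32))
})

test_that("expected out-of-bag fraction matches the analytic value", {
  # E[|oob|]/n = (1 - 1/n)^n ~= 0.362 at n = 32; quick check at 2000 seeds
  # (the acceptance suite uses 10^4)
  fr <- vapply(1:2000, function(s) {
    length(bootstrap_split(32, seed = s)$test) / 32
  }, numeric(1))
  expect_lt(abs(mean(fr) - (1 - 1 / 32)^32), 0.015)
})

test_that("a noiseless linear system is predicted with near-zero error", {
  fit <- linear_chain_model(w_sa = 0.8, w_ab = 0.5, sigma2 = 1e-4)
  sim <- simulate_dbn(fit, 30, seed = 2)
  ev <- evaluate_model(sim$data, fit$structure,
    n_boot = 8, seed = 3,
    predicted = c("a", "b")
  )
  expect_lt(max(ev$sse$sse), 0.05)
  expect_equal(ev$n_failed, 0)
})

test_that("evaluation is deterministic and n_boot = 1 is a single split", {
  fit <- linear_chain_model(sigma2 = 0.2)
  sim <- simulate_dbn(fit, 20, seed = 5)
  e1 <- evaluate_model(sim$data, fit$structure, n_boot = 3, seed = 7)
  e2 <- evaluate_model(sim$data, fit$structure, n_boot = 3, seed = 7)
  expect_equal(e1$sse, e2$sse)
  expect_equal(e1$predictions, e2$predictions)

  single <- evaluate_model(sim$data, fit$structure, n_boot = 1, seed = 7)
  # with one iteration the mean equals the per-iteration SSE and the
  # bootstrap sd is degenerate
  expect_equal(single$sse$sse, single$sse$sse_total)
  expect_true(all(single$predictions$boot_sd == 0))
  # and it matches a by-hand single train/test evaluation
  split <- bootstrap_split(20, seed = (7 + 49999L) %% .Machine$integer.max)
  w <- tabulate(split$train, nbins = 20)
  cfg <- em_config(n_inits = 2, max_iterations = 100, rel_tolerance = 1e-5,
                   seed = (7 + 49999L) %% .Machine$integer.max)
  refit <- fit_em(fit$structure, sim$data, config = cfg, weights = w)
  obs <- as.matrix(sim$data[, c("sst", "a", "b")])
  manual <- vapply(c(sst = "sst", a = "a", b = "b"), function(v) {
    tot <- 0
    for (t in split$test) {
      if (t < 2) next
      pr <- predict_one_step(refit, obs[t - 1, ])
      tot <- tot + (pr$mean[pr$variable == v] - obs[t, v])^2
    }
    tot
  }, numeric(1))
  expect_equal(single$sse$sse, unname(manual[single$sse$variable]), tolerance = 1e-10)
})

test_that("per-variable SSE ignores the order of bootstrap iterations", {
  # averaging commutes: evaluating with the same seed must give the mean of
  # the per-iteration errors regardless of accumulation order, so two
  # models sharing seeds see identical splits
  fit <- linear_chain_model(sigma2 = 0.3)
  sim <- simulate_dbn(fit, 18, seed = 11)
  e <- evaluate_model(sim$data, fit$structure, n_boot = 4, seed = 13)
  expect_equal(e$sse$sse, e$sse$sse_total / 4, tolerance = 1e-12)
})

test_that("structures with planted cross-links outpredict the blind ARHMM", {
  wins <- 0
  for (s in 1:5) {
    spec <- synthetic_spec(
      n_years = 32, n_climate = 2, n_physio = 2, n_biota = 4,
      weight_range = c(0.6, 0.9), noise_sd = 0.3, seed = 40 + s
    )
    truth <- generate_structure(spec)
    sim <- simulate_table(truth)
    predicted <- truth$descriptors$name[truth$descriptors$predicted]
    em <- em_config(n_inits = 2, max_iterations = 60, rel_tolerance = 1e-5)
    ev_true <- evaluate_model(sim$data, truth$structure,
      n_boot = 10, em = em, seed = 70 + s, predicted = predicted
    )
    ev_arhmm <- evaluate_model(sim$data, build_arhmm(truth$descriptors),
      n_boot = 10, em = em, seed = 70 + s, predicted = predicted
    )
    if (sum(ev_true$sse$sse) < sum(ev_arhmm$sse$sse)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("model comparison marks the per-variable minimum with simpler-model ties", {
  spec <- synthetic_spec(
    n_years = 28, n_climate = 2, n_physio = 2, n_biota = 3,
    weight_range = c(0.6, 0.9), noise_sd = 0.4, seed = 90
  )
  truth <- generate_structure(spec)
  sim <- simulate_table(truth)
  fit <- fit_em(
    build_arhmm(truth$descriptors), sim$data,
    em_config(n_inits = 2, max_iterations = 50, rel_tolerance = 1e-5, seed = 91)
  )
  post <- infer_hidden(fit, sim$data)
  hv <- post$prob[post$hidden == "H" & post$state == 2]
  conf <- edge_confidence(
    sim$data,
    hill_climb_config(window_length = 14, window_stride = 7, n_restarts = 2, seed = 92),
    hidden = hv
  )
  cmp <- compare_models(sim$data, conf, truth$descriptors,
    n_boot = 4, seed = 93,
    em = em_config(n_inits = 1, max_iterations = 40, rel_tolerance = 1e-4)
  )
  expect_s3_class(cmp, "dbn_comparison")
  expect_setequal(cmp$variable, truth$descriptors$name[truth$descriptors$predicted])
  mat <- as.matrix(cmp[, c("ARHMM", "ARDBN", "DDDBN")])
  expect_equal(cmp$best, c("ARHMM", "ARDBN", "DDDBN")[apply(mat, 1, which.min)])
  expect_true(all(mat >= 0))
})

test_that("bootstrap spread shrinks with the generator's noise level", {
  spread_at <- function(noise_sd) {
    st <- dbn_structure(
      tibble::tibble(name = c("x", "y"), kind = "continuous"),
      tibble::tibble(from = c("x", "x"), to = c("x", "y"), lag = 1L)
    )
    gen <- dbn_model(st, params = list(
      x = clg_params(mu = 0, w = matrix(0.6, 1, 1), sigma2 = 0.5),
      y = clg_params(mu = 0, w = matrix(0.8, 1, 1), sigma2 = noise_sd^2)
    ))
    sim <- simulate_dbn(gen, 24, seed = 21)
    ev <- evaluate_model(sim$data, st, n_boot = 8, seed = 22, predicted = "y")
    median(ev$predictions$boot_sd[ev$predictions$variable == "y"])
  }
  expect_lt(spread_at(0.1), spread_at(0.8))
})

test_that("without parents predictions collapse to the fitted mean", {
  # a single isolated node: the one-step prediction is its intercept, so
  # out-of-bag SSE approaches the test years' sum of squares around the
  # (weighted) training mean
  st <- dbn_structure(
    tibble::tibble(name = "x", kind = "continuous"),
    tibble::tibble(from = character(), to = character(), lag = integer())
  )
  gen <- dbn_model(st, params = list(x = clg_params(mu = 0, sigma2 = 1)))
  sim <- simulate_dbn(gen, 40, seed = 31)
  ev <- evaluate_model(sim$data, st, n_boot = 6, seed = 32)
  x <- sim$data$x
  # crude reference: centered sum of squares over an average-sized test set
  ref <- mean((x - mean(x))^2) * 40 * (1 - 1 / 40)^40
  expect_equal(ev$sse$sse, ref, tolerance = 0.35)
})
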