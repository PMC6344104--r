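# shared fixtures: tiny hand-parameterized models and a brute-force
# hidden-path enumeration oracle, all built in code

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# brute-force marginal log-likelihood: enumerate every hidden path of every
# chain and log-sum-exp the complete-data log-likelihoods
enum_loglik <- function(fit, data) {
  hid <- names(fit$chains)
  T_ <- nrow(data)
  if (!length(hid)) {
    return(joint_loglik_complete(fit, data, list()))
  }
  n_slots <- length(hid) * T_
  grid <- do.call(expand.grid, rep(list(1:2), n_slots))
  lls <- apply(grid, 1, function(row) {
    path <- list()
    for (i in seq_along(hid)) {
      path[[hid[i]]] <- as.integer(row[((i - 1) * T_ + 1):(i * T_)])
    }
    joint_loglik_complete(fit, data, path)
  })
  logsumexp(lls)
}

# enumeration-based smoothed posterior P(H_t = s | x) for one chain
enum_posterior <- function(fit, data, chain, t, s) {
  hid <- names(fit$chains)
  T_ <- nrow(data)
  grid <- do.call(expand.grid, rep(list(1:2), length(hid) * T_))
  lls <- apply(grid, 1, function(row) {
    path <- list()
    for (i in seq_along(hid)) {
      path[[hid[i]]] <- as.integer(row[((i - 1) * T_ + 1):(i * T_)])
    }
    joint_loglik_complete(fit, data, path)
  })
  ci <- match(chain, hid)
  sel <- grid[[(ci - 1) * T_ + t]] == s
  exp(logsumexp(lls[sel]) - logsumexp(lls))
}

# one binary hidden chain, two observed nodes (one autoregressive), fixed
# hand-set parameters
toy_hmm <- function(p_stay = 0.8, pi1 = 0.6) {
  st <- dbn_structure(
    nodes = tibble::tibble(
      name = c("H", "x", "y"),
      kind = c("hidden", "continuous", "continuous")
    ),
    edges = tibble::tibble(
      from = c("H", "H", "H", "x"),
      to = c("H", "x", "y", "x"),
      lag = c(1L, 0L, 0L, 1L)
    )
  )
  dbn_model(
    st,
    params = list(
      x = clg_params(mu = c(-1, 1), w = matrix(c(0.5, 0.3), 2, 1), sigma2 = c(0.6, 0.8)),
      y = clg_params(mu = c(0.5, -0.5), sigma2 = c(1.2, 0.9))
    ),
    chains = list(H = list(
      pi = c(pi1, 1 - pi1),
      A = matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2, byrow = TRUE)
    ))
  )
}

# purely linear chain sst -> a -> b with no hidden nodes; the driver keeps
# a real innovation variance so downstream regressions have signal
linear_chain_model <- function(w_sa = 0.8, w_ab = 0.5, sigma2 = 1e-4,
                               driver_sigma2 = 0.5) {
  st <- dbn_structure(
    nodes = tibble::tibble(
      name = c("sst", "a", "b"),
      kind = "continuous"
    ),
    edges = tibble::tibble(
      from = c("sst", "sst", "a"),
      to = c("sst", "a", "b"),
      lag = 1L
    )
  )
  dbn_model(
    st,
    params = list(
      sst = clg_params(mu = 0, w = matrix(0.5, 1, 1), sigma2 = driver_sigma2),
      a = clg_params(mu = 0, w = matrix(w_sa, 1, 1), sigma2 = sigma2),
      b = clg_params(mu = 0, w = matrix(w_ab, 1, 1), sigma2 = sigma2)
    )
  )
}

# Full structure-recovery protocol on planted synthetic data: fit the ARHMM,
# feed its smoothed hidden state into the sliding-window hill-climb, and
# report the fraction of planted biota-parent edges whose confidence exceeds
# every spurious edge. Spurious = a non-planted parent of a biota or
# physiochemical child (children whose complete parent sets are observed);
# climate-climate dependence is real marginally over the hidden regime, and
# edges touching the hidden column are search plumbing, so neither counts.
planted_edge_ranking <- function(seed) {
  spec <- synthetic_spec(
    n_years = 300, n_climate = 2, n_physio = 3, n_biota = 8,
    weight_range = c(0.5, 0.9), noise_sd = 0.3, max_parents = 2, seed = seed
  )
  truth <- generate_structure(spec)
  sim <- simulate_table(truth)
  fit <- fit_em(
    build_arhmm(truth$descriptors), sim$data,
    em_config(n_inits = 2, max_iterations = 60, rel_tolerance = 1e-5, seed = seed)
  )
  post <- infer_hidden(fit, sim$data)
  hv <- post$prob[post$hidden == "H" & post$state == 2]
  conf <- edge_confidence(
    sim$data,
    hill_climb_config(window_length = 100, window_stride = 50, n_restarts = 3, seed = seed + 10),
    hidden = hv
  )
  te <- truth$structure$edges
  te <- te[te$lag == 1L, ]
  true_keys <- paste(te$from, te$to)
  conf_keys <- paste(conf$from, conf$to)
  planted_cross <- true_keys[te$from != te$to]
  checked_children <- truth$descriptors$name[
    truth$descriptors$category != "climate"
  ]
  spurious <- !conf_keys %in% true_keys &
    conf$to %in% checked_children &
    conf$from != "HV" & conf$to != "HV"
  spurious_max <- max(c(0, conf$confidence[spurious]))
  planted_conf <- conf$confidence[match(planted_cross, conf_keys)]
  planted_conf[is.na(planted_conf)] <- 0
  mean(planted_conf > spurious_max)
}

toy_table <- function(values) {
  tibble::tibble(year = seq_len(nrow(values))) %>%
    dplyr::bind_cols(tibble::as_tibble(values))
}
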