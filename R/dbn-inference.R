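#' Log-density of a conditional linear Gaussian node
#'
#' Evaluates `log N(y; mu[q] + w[q, ] %*% x, sigma2[q])`: the observed node's
#' density given its continuous parents' values `x` and its discrete-parent
#' configuration `q`.
#'
#' @param y Observed scalar value.
#' @param x Numeric vector of continuous-parent values (length must match
#'   the weight columns; may be empty).
#' @param q Configuration index (1-based).
#' @param params A [clg_params()] object.
#' @return Log-density (scalar).
#' @export
clg_logdensity <- function(y, x = numeric(0), q = 1L, params) {
  if (q < 1 || q > length(params$mu)) abort("configuration index out of range")
  if (length(x) != ncol(params$w)) abort("parent value length does not match weights")
  s2 <- params$sigma2[q]
  if (s2 <= 0) abort("sigma2 must be positive")
  m <- params$mu[q] + if (length(x)) sum(params$w[q, ] * x) else 0
  stats::dnorm(y, mean = m, sd = sqrt(s2), log = TRUE)
}

# Per-node emission log-densities over all years and joint hidden states.
# Conventions: a node with lag-1 continuous parents contributes no emission
# in the first year (conditional AR likelihood); a year is skipped for a node
# whenever its value or any required parent value is missing (exact
# marginalization of the missing emission factor).
# Returns T x n_joint matrix of summed log-densities, plus per-node pieces
# used by the EM sufficient statistics.
emission_pieces <- function(fit, data) {
  structure_ <- fit$structure
  cont <- continuous_node_names(structure_)
  S <- joint_state_matrix(fit)
  n_joint <- nrow(S)
  T_ <- nrow(data)
  X <- as.matrix(data[, cont, drop = FALSE])
  E <- matrix(0, T_, n_joint)
  pieces <- vector("list", length(cont))
  names(pieces) <- cont
  for (v in cont) {
    fam <- node_family(structure_, v)
    p <- fit$params[[v]]
    ncfg <- length(p$mu)
    y <- X[, v]
    # design: one column per continuous parent, aligned to response year t
    np <- nrow(fam$cparents)
    Z <- matrix(NA_real_, T_, np)
    if (np) {
      for (j in seq_len(np)) {
        pv <- X[, fam$cparents$name[j]]
        Z[, j] <- if (fam$cparents$lag[j] == 1L) c(NA_real_, pv[-T_]) else pv
      }
    }
    ok <- !is.na(y)
    if (np) ok <- ok & !rowSums(is.na(Z))
    # node-config log-density matrix over valid years
    ld <- matrix(0, T_, ncfg)
    for (cfg in seq_len(ncfg)) {
      m <- p$mu[cfg] + if (np) as.vector(Z %*% p$w[cfg, ]) else 0
      ld[, cfg] <- stats::dnorm(y, mean = m, sd = sqrt(p$sigma2[cfg]), log = TRUE)
    }
    ld[!ok, ] <- 0
    cfg_of <- node_config_of_joint(S, fam$dparents)
    E <- E + ld[, cfg_of, drop = FALSE]
    pieces[[v]] <- list(Z = Z, y = y, ok = ok, ld = ld, n_config = ncfg, fam = fam)
  }
  list(E = E, S = S, pieces = pieces)
}

#' Forward filtering and observed-data log-likelihood
#'
#' Runs the exact forward recursion over the joint space of all hidden
#' chains (2 states each), returning filtered posteriors
#' `P(H_t | x_1..x_t)` and the marginal log-likelihood `log P(x | theta)`.
#' Missing observations are marginalized exactly (their emission factor is
#' omitted). `weights` optionally scales each year's emission log-density
#' (used for bootstrap-weighted training; weight 0 masks a year's evidence).
#'
#' @param fit A [dbn_model()] or [fit_em()] result.
#' @param data Ecosystem table with a `year` column covering the model's
#'   observed nodes.
#' @param weights Optional nonnegative per-year emission weights.
#' @return List with `loglik`, `filtered` (years x joint-states matrix),
#'   `states` (joint state matrix), and `marginals`, a tibble of per-chain
#'   filtered state probabilities (`year`, `hidden`, `state`, `prob`).
#' @export
forward_filter <- function(fit, data, weights = NULL) {
  ep <- emission_logmat_checked(fit, data, weights)
  fwd <- forward_pass(fit, ep$E, ep$S)
  list(
    loglik = fwd$loglik, filtered = fwd$alpha, states = ep$S,
    marginals = chain_marginals(data$year, fwd$alpha, ep$S)
  )
}

emission_logmat_checked <- function(fit, data, weights = NULL) {
  validate_ecosystem_table(data, min_years = 1L)
  cont <- continuous_node_names(fit$structure)
  missing_cols <- setdiff(cont, names(data))
  if (length(missing_cols)) {
    abort(paste0("data lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  ep <- emission_pieces(fit, data)
  if (!is.null(weights)) {
    if (length(weights) != nrow(data) || any(weights < 0)) {
      abort("weights must be nonnegative, one per year")
    }
    ep$E <- ep$E * weights
  }
  ep
}

forward_pass <- function(fit, E, S) {
  T_ <- nrow(E)
  n <- nrow(S)
  alpha <- matrix(0, T_, n)
  init <- joint_initial(fit, S)
  P <- joint_transition(fit, S)
  loglik <- 0
  prev <- init
  for (t in seq_len(T_)) {
    if (t > 1) prev <- as.vector(prev %*% P)
    m <- max(E[t, ])
    v <- prev * exp(E[t, ] - m)
    c_t <- sum(v)
    if (c_t <= 0 || !is.finite(c_t)) {
      return(list(loglik = -Inf, alpha = alpha, scale = NULL, P = P, init = init))
    }
    alpha[t, ] <- v / c_t
    loglik <- loglik + log(c_t) + m
    prev <- alpha[t, ]
  }
  list(loglik = loglik, alpha = alpha, P = P, init = init)
}

chain_marginals <- function(years, gamma, S) {
  if (!ncol(S)) {
    return(tibble(year = numeric(), hidden = character(), state = integer(), prob = numeric()))
  }
  purrr::map_dfr(colnames(S), function(h) {
    purrr::map_dfr(1:2, function(s) {
      tibble(
        year = years, hidden = h, state = s,
        prob = rowSums(gamma[, S[, h] == s, drop = FALSE])
      )
    })
  }) %>% arrange(.data$year, .data$hidden, .data$state)
}

#' Smoothed posteriors over hidden states
#'
#' Forward-backward smoothing: `P(H_t | x_1..x_T)` for every year and hidden
#' chain. At the final year the smoothed and filtered posteriors coincide.
#'
#' @inheritParams forward_filter
#' @return Tibble with columns `year`, `hidden`, `state`, `prob`, carrying
#'   the observed-data log-likelihood as attribute `"loglik"`.
#' @export
infer_hidden <- function(fit, data, weights = NULL) {
  ep <- emission_logmat_checked(fit, data, weights)
  fb <- forward_backward_pass(fit, ep$E, ep$S)
  out <- chain_marginals(data$year, fb$gamma, ep$S)
  attr(out, "loglik") <- fb$loglik
  out
}

# full forward-backward with pairwise transition expectations (for EM)
forward_backward_pass <- function(fit, E, S) {
  fwd <- forward_pass(fit, E, S)
  if (!is.finite(fwd$loglik)) abort("zero-probability evidence during forward pass")
  T_ <- nrow(E)
  n <- nrow(S)
  alpha <- fwd$alpha
  P <- fwd$P
  gamma <- matrix(0, T_, n)
  xi <- matrix(0, n, n)
  beta <- rep(1, n)
  gamma[T_, ] <- alpha[T_, ]
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      m <- max(E[t + 1, ])
      b_em <- beta * exp(E[t + 1, ] - m)
      # pairwise expectation at (t -> t+1)
      x_t <- (alpha[t, ] * P) * matrix(b_em, n, n, byrow = TRUE)
      sx <- sum(x_t)
      if (sx > 0) xi <- xi + x_t / sx
      beta <- as.vector(P %*% b_em)
      beta <- beta / sum(beta)
      g <- alpha[t, ] * beta
      gamma[t, ] <- g / sum(g)
    }
  }
  list(loglik = fwd$loglik, gamma = gamma, xi = xi, alpha = alpha)
}

#' Complete-data log-likelihood along a stated hidden path
#'
#' Sums the hidden chains' initial/transition log-probabilities along the
#' given state path with every observed node's conditional log-density at
#' the stated configurations. Returns `-Inf` for a path using a
#' zero-probability transition. This is the enumerand of the marginal
#' likelihood: summing its exponential over all paths reproduces
#' [forward_filter()]'s log-likelihood.
#'
#' @inheritParams forward_filter
#' @param hidden_path Named list, one integer vector of states (1 or 2) per
#'   hidden node, each of length `nrow(data)`.
#' @return Scalar log-likelihood.
#' @export
joint_loglik_complete <- function(fit, data, hidden_path) {
  ep <- emission_logmat_checked(fit, data)
  S <- ep$S
  T_ <- nrow(data)
  hid <- colnames(S)
  if (length(hid) && !setequal(names(hidden_path), hid)) {
    abort("hidden_path must name every hidden node")
  }
  ll <- 0
  for (h in hid) {
    path <- hidden_path[[h]]
    if (length(path) != T_) abort("hidden_path length must equal the number of years")
    if (any(!path %in% 1:2)) abort("hidden state out of range")
    ch <- fit$chains[[h]]
    ll <- ll + log(ch$pi[path[1]])
    if (T_ > 1) ll <- ll + sum(log(ch$A[cbind(path[-T_], path[-1])]))
  }
  # joint-state index per year
  if (length(hid)) {
    idx <- rep(1L, T_)
    mult <- 1L
    for (h in hid) {
      idx <- idx + (hidden_path[[h]] - 1L) * mult
      mult <- mult * 2L
    }
  } else {
    idx <- rep(1L, T_)
  }
  ll + sum(ep$E[cbind(seq_len(T_), idx)])
}

#' One-step-ahead prediction from last year's evidence
#'
#' Propagates the hidden-state distribution one step through each chain's
#' transition matrix and returns, for every observed node, the mixture mean
#' and variance of its conditional linear Gaussian distribution given the
#' evidence observed at the previous year. Intra-slice continuous parents
#' are resolved in topological order using their predicted means; a missing
#' lag-1 parent value is marginalized at the standardized stationary mean
#' (zero contribution).
#'
#' @param fit A fitted model.
#' @param evidence_prev Named numeric vector of observed values at year
#'   t-1 (NA allowed).
#' @param hidden_prior Named list, one length-2 distribution per hidden
#'   node, giving `P(H_{t-1})`; defaults to each chain's initial
#'   distribution.
#' @return Tibble with columns `variable`, `mean`, `var`.
#' @export
predict_one_step <- function(fit, evidence_prev, hidden_prior = NULL) {
  structure_ <- fit$structure
  hid <- hidden_node_names(structure_)
  if (is.null(hidden_prior)) {
    hidden_prior <- purrr::map(stats::setNames(hid, hid), ~ fit$chains[[.x]]$pi)
  }
  S <- joint_state_matrix(fit)
  # P(H_t) = P(H_{t-1}) %*% A, per chain, then product over chains
  p_joint <- rep(1, nrow(S))
  for (h in hid) {
    p_h <- as.vector(hidden_prior[[h]] %*% fit$chains[[h]]$A)
    p_joint <- p_joint * p_h[S[, h]]
  }
  topo <- intra_topo_order(structure_)
  means <- vars <- stats::setNames(numeric(length(topo)), topo)
  for (v in topo) {
    fam <- node_family(structure_, v)
    p <- fit$params[[v]]
    ncfg <- length(p$mu)
    # parent values: lag-1 from evidence, lag-0 from already-predicted means
    np <- nrow(fam$cparents)
    xv <- numeric(np)
    if (np) {
      for (j in seq_len(np)) {
        nm <- fam$cparents$name[j]
        xv[j] <- if (fam$cparents$lag[j] == 1L) {
          val <- evidence_prev[[nm]]
          if (is.null(val) || is.na(val)) 0 else val
        } else {
          means[[nm]]
        }
      }
    }
    cfg_means <- p$mu + if (np) as.vector(p$w %*% xv) else 0
    # node-config distribution from the joint hidden distribution
    cfg_of <- node_config_of_joint(S, fam$dparents)
    p_cfg <- vapply(seq_len(ncfg), function(cfg) sum(p_joint[cfg_of == cfg]), numeric(1))
    m <- sum(p_cfg * cfg_means)
    v2 <- sum(p_cfg * (p$sigma2 + cfg_means^2)) - m^2
    means[[v]] <- m
    vars[[v]] <- max(v2, 0)
  }
  ord <- continuous_node_names(structure_)
  tibble(variable = ord, mean = unname(means[ord]), var = unname(vars[ord]))
}

#' Sample a synthetic series from a model
#'
#' Ancestral sampling over the unrolled network: hidden chains first, then
#' observed nodes in intra-slice topological order; lag-1 parent
#' contributions in the first year are taken at the standardized stationary
#' mean (zero). Reproducible given `seed`.
#'
#' @param fit A fitted or hand-built model.
#' @param n_years Number of years to draw.
#' @param seed Integer seed.
#' @return List with `data` (tibble: `year` plus one column per observed
#'   node) and `hidden` (tibble: `year`, `hidden`, `state`).
#' @export
simulate_dbn <- function(fit, n_years, seed = 1L) {
  if (n_years < 1) abort("n_years must be >= 1")
  with_local_seed(seed, {
    structure_ <- fit$structure
    hid <- hidden_node_names(structure_)
    topo <- intra_topo_order(structure_)
    H <- matrix(1L, n_years, length(hid), dimnames = list(NULL, hid))
    for (h in hid) {
      ch <- fit$chains[[h]]
      H[1, h] <- sample.int(2L, 1, prob = ch$pi)
      if (n_years > 1) {
        for (t in 2:n_years) H[t, h] <- sample.int(2L, 1, prob = ch$A[H[t - 1, h], ])
      }
    }
    X <- matrix(NA_real_, n_years, length(topo), dimnames = list(NULL, topo))
    fams <- purrr::map(stats::setNames(topo, topo), ~ node_family(structure_, .x))
    for (t in seq_len(n_years)) {
      for (v in topo) {
        fam <- fams[[v]]
        p <- fit$params[[v]]
        cfg <- 1L
        if (length(fam$dparents)) {
          mult <- 1L
          for (dp in fam$dparents) {
            cfg <- cfg + (H[t, dp] - 1L) * mult
            mult <- mult * 2L
          }
        }
        m <- p$mu[cfg]
        np <- nrow(fam$cparents)
        if (np) {
          for (j in seq_len(np)) {
            nm <- fam$cparents$name[j]
            pv <- if (fam$cparents$lag[j] == 1L) {
              if (t == 1) 0 else X[t - 1, nm]
            } else {
              X[t, nm]
            }
            m <- m + p$w[cfg, j] * pv
          }
        }
        X[t, v] <- stats::rnorm(1, m, sqrt(p$sigma2[cfg]))
      }
    }
    hidden <- if (length(hid)) {
      purrr::map_dfr(hid, ~ tibble(year = seq_len(n_years), hidden = .x, state = H[, .x]))
    } else {
      tibble(year = integer(), hidden = character(), state = integer())
    }
    list(
      data = dplyr::bind_cols(tibble(year = seq_len(n_years)), as_tibble(X)),
      hidden = hidden
    )
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
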