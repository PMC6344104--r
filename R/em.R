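#' Expectation-Maximization configuration
#'
#' @param max_iterations Maximum EM iterations per initialization.
#' @param rel_tolerance Relative log-likelihood change declaring
#'   convergence.
#' @param n_inits Number of random initializations; the best final
#'   log-likelihood wins.
#' @param seed Integer seed for the initializations.
#' @param variance_floor Lower bound on every node variance (standardized
#'   units squared), preventing degenerate likelihoods.
#' @return List of class `em_config`.
#' @export
em_config <- function(max_iterations = 200L, rel_tolerance = 1e-6,
                      n_inits = 5L, seed = 1L, variance_floor = 1e-6) {
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  if (rel_tolerance <= 0) abort("rel_tolerance must be positive")
  structure(
    list(
      max_iterations = as.integer(max_iterations), rel_tolerance = rel_tolerance,
      n_inits = as.integer(n_inits), seed = as.integer(seed),
      variance_floor = variance_floor
    ),
    class = "em_config"
  )
}

# design pieces that depend only on structure + data (not parameters)
design_pieces <- function(structure_, data) {
  cont <- continuous_node_names(structure_)
  T_ <- nrow(data)
  X <- as.matrix(data[, cont, drop = FALSE])
  purrr::map(stats::setNames(cont, cont), function(v) {
    fam <- node_family(structure_, v)
    y <- X[, v]
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
    list(fam = fam, y = y, Z = Z, ok = ok, n_config = 2^length(fam$dparents))
  })
}

# Precomputed quantities reused across EM iterations: per-node design
# matrices with missing rows masked, node-config maps into the joint state
# space, and the per-year emission weights.
em_cache <- function(structure_, data, weights = NULL) {
  hid <- hidden_node_names(structure_)
  S <- if (length(hid)) {
    as.matrix(do.call(expand.grid, stats::setNames(rep(list(1:2), length(hid)), hid)))
  } else {
    matrix(integer(), 1, 0)
  }
  pieces <- design_pieces(structure_, data)
  T_ <- nrow(data)
  w_t <- if (is.null(weights)) rep(1, T_) else weights
  nodes <- purrr::map(pieces, function(piece) {
    y0 <- piece$y
    y0[!piece$ok] <- 0
    Z0 <- piece$Z
    Z0[is.na(Z0)] <- 0
    list(
      piece = piece,
      cfg_of = node_config_of_joint(S, piece$fam$dparents),
      Zf = cbind(1, Z0), y0 = y0
    )
  })
  list(S = S, nodes = nodes, w_t = w_t, T_ = T_)
}

# emission log-density matrix (T x joint states) from cached designs
cached_emission <- function(fit, cache) {
  E <- matrix(0, cache$T_, nrow(cache$S))
  for (v in names(cache$nodes)) {
    nd <- cache$nodes[[v]]
    piece <- nd$piece
    p <- fit$params[[v]]
    ncfg <- piece$n_config
    ld <- matrix(0, cache$T_, ncfg)
    np <- ncol(piece$Z)
    for (cfg in seq_len(ncfg)) {
      m <- p$mu[cfg] + if (np) as.vector(piece$Z %*% p$w[cfg, ]) else 0
      ld[, cfg] <- stats::dnorm(piece$y, mean = m, sd = sqrt(p$sigma2[cfg]), log = TRUE)
    }
    ld[!piece$ok, ] <- 0
    E <- E + ld[, nd$cfg_of, drop = FALSE]
  }
  E * cache$w_t
}

cached_suffstats <- function(cache, gamma, xi) {
  S <- cache$S
  node_stats <- purrr::map(cache$nodes, function(nd) {
    ncfg <- nd$piece$n_config
    out <- vector("list", ncfg)
    for (cfg in seq_len(ncfg)) {
      r <- rowSums(gamma[, nd$cfg_of == cfg, drop = FALSE]) * cache$w_t
      r[!nd$piece$ok] <- 0
      out[[cfg]] <- list(
        S_zz = crossprod(nd$Zf, r * nd$Zf),
        S_zy = as.vector(crossprod(nd$Zf, r * nd$y0)),
        S_yy = sum(r * nd$y0^2),
        n = sum(r)
      )
    }
    out
  })
  chain_stats <- list()
  if (ncol(S)) {
    for (h in colnames(S)) {
      init <- vapply(1:2, function(s) sum(gamma[1, S[, h] == s]), numeric(1))
      trans <- matrix(0, 2, 2)
      for (a in 1:2) {
        for (b in 1:2) {
          trans[a, b] <- sum(xi[S[, h] == a, S[, h] == b, drop = FALSE])
        }
      }
      chain_stats[[h]] <- list(init = init, trans = trans)
    }
  }
  list(node = node_stats, chain = chain_stats)
}

# expected sufficient statistics given per-year joint-state responsibilities
suffstats_from_posterior <- function(structure_, data, gamma, xi, S, weights = NULL,
                                     pieces = NULL) {
  dp <- if (is.null(pieces)) design_pieces(structure_, data) else pieces
  T_ <- nrow(data)
  w_t <- if (is.null(weights)) rep(1, T_) else weights
  node_stats <- purrr::map(dp, function(piece) {
    ncfg <- piece$n_config
    cfg_of <- node_config_of_joint(S, piece$fam$dparents)
    R <- matrix(0, T_, ncfg)
    for (cfg in seq_len(ncfg)) {
      R[, cfg] <- rowSums(gamma[, cfg_of == cfg, drop = FALSE]) * w_t
    }
    R[!piece$ok, ] <- 0
    y <- piece$y
    y[!piece$ok] <- 0
    Z <- piece$Z
    Z[is.na(Z)] <- 0
    Zf <- cbind(1, Z)
    purrr::map(seq_len(ncfg), function(cfg) {
      r <- R[, cfg]
      list(
        S_zz = crossprod(Zf, r * Zf),
        S_zy = as.vector(crossprod(Zf, r * y)),
        S_yy = sum(r * y^2),
        n = sum(r)
      )
    })
  })
  chain_stats <- list()
  if (ncol(S)) {
    for (h in colnames(S)) {
      init <- vapply(1:2, function(s) sum(gamma[1, S[, h] == s]), numeric(1))
      trans <- matrix(0, 2, 2)
      for (a in 1:2) {
        for (b in 1:2) {
          trans[a, b] <- sum(xi[S[, h] == a, S[, h] == b, drop = FALSE])
        }
      }
      chain_stats[[h]] <- list(init = init, trans = trans)
    }
  }
  list(node = node_stats, chain = chain_stats)
}

#' E-step: expected sufficient statistics under the current parameters
#'
#' Runs forward-backward smoothing over the joint hidden chains and
#' accumulates, per observed node and discrete configuration, the
#' responsibility-weighted cross-products needed by the M-step, plus
#' expected initial-state and transition counts per chain.
#'
#' @inheritParams forward_filter
#' @return List with `stats` (node and chain sufficient statistics),
#'   `loglik`, and the smoothed `gamma` matrix.
#' @export
e_step <- function(fit, data, weights = NULL) {
  ep <- emission_logmat_checked(fit, data, weights)
  fb <- forward_backward_pass(fit, ep$E, ep$S)
  stats <- suffstats_from_posterior(
    fit$structure, data, fb$gamma, fb$xi, ep$S, weights,
    pieces = ep$pieces
  )
  list(stats = stats, loglik = fb$loglik, gamma = fb$gamma, states = ep$S)
}

#' M-step: maximize the expected complete-data log-likelihood
#'
#' Per observed node and configuration, solves the responsibility-weighted
#' least-squares normal equations for intercept and weights; the variance is
#' the weighted residual variance, floored at `config$variance_floor`.
#' Singular normal equations receive a 1e-8 ridge. Transition rows are
#' expected counts with a 1e-3 pseudocount, normalized; the initial
#' distribution is the expected first-year marginal. A configuration with
#' (near-)zero responsibility mass keeps its previous parameters.
#'
#' @param stats Sufficient statistics from [e_step()].
#' @param structure A [dbn_structure()].
#' @param config An [em_config()].
#' @param prev Optional previous `dbn_fit` supplying fallback parameters
#'   for empty configurations.
#' @return A `dbn_fit`.
#' @export
m_step <- function(stats, structure, config = em_config(), prev = NULL) {
  cont <- continuous_node_names(structure)
  params <- lapply(stats::setNames(cont, cont), function(v) {
    st <- stats$node[[v]]
    ncfg <- length(st)
    k <- length(st[[1]]$S_zy)
    mu <- numeric(ncfg)
    w <- matrix(0, ncfg, k - 1)
    sigma2 <- rep(1, ncfg)
    for (cfg in seq_len(ncfg)) {
      s <- st[[cfg]]
      if (s$n < 1e-8) {
        if (!is.null(prev)) {
          p0 <- prev$params[[v]]
          mu[cfg] <- p0$mu[cfg]
          if (k > 1) w[cfg, ] <- p0$w[cfg, ]
          sigma2[cfg] <- p0$sigma2[cfg]
        }
        next
      }
      beta <- tryCatch(
        solve(s$S_zz, s$S_zy),
        error = function(e) solve(s$S_zz + diag(1e-8, k), s$S_zy)
      )
      rss <- s$S_yy - 2 * sum(beta * s$S_zy) + as.numeric(crossprod(beta, s$S_zz %*% beta))
      mu[cfg] <- beta[1]
      if (k > 1) w[cfg, ] <- beta[-1]
      sigma2[cfg] <- max(rss / s$n, config$variance_floor)
    }
    structure(list(mu = mu, w = w, sigma2 = sigma2), class = "clg_params")
  })
  chains <- lapply(stats$chain, function(cs) {
    A <- cs$trans + 1e-3
    A <- A / rowSums(A)
    pi <- cs$init / sum(cs$init)
    list(pi = pi, A = A)
  })
  # parameters produced here are internally consistent by construction;
  # skip dbn_model()'s re-validation on the hot path
  structure(list(structure = structure, params = params, chains = chains),
    class = "dbn_fit"
  )
}

#' Fit a dynamic Bayesian network by Expectation-Maximization
#'
#' Alternates [e_step()] and [m_step()] from random initializations until
#' the relative log-likelihood change drops below `config$rel_tolerance` or
#' `config$max_iterations` is reached, and returns the initialization with
#' the highest final observed-data log-likelihood. The first start places
#' initial responsibilities along a k-means clustering (k = 2) of each
#' chain's observed children; the remaining starts use random sticky state
#' paths (soft assignment 0.7, stay probability 0.85). Both give each
#' start a temporally coherent regime hypothesis. Hidden states are put in
#' canonical order (ascending mean of the first observed child) so that
#' repeated fits are comparable.
#'
#' @param structure A [dbn_structure()].
#' @param data Ecosystem table (standardized).
#' @param config An [em_config()].
#' @param weights Optional per-year emission weights (bootstrap
#'   multiplicities); years with weight 0 contribute no evidence.
#' @return A `dbn_fit` with attribute `"trace"`: a tibble
#'   (`init`, `iteration`, `loglik`) plus `"converged"`, `"best_init"` and
#'   `"loglik"` attributes.
#' @export
fit_em <- function(structure, data, config = em_config(), weights = NULL) {
  validate_ecosystem_table(data)
  if (nrow(data) < 3) abort("need at least 3 years")
  hid <- hidden_node_names(structure)
  n_joint <- 2^length(hid)
  T_ <- nrow(data)
  cache <- em_cache(structure, data, weights)
  S <- cache$S
  best <- NULL
  traces <- list()
  n_inits <- if (length(hid)) config$n_inits else 1L
  for (i in seq_len(n_inits)) {
    # The first start clusters each chain's children by k-means (the
    # standard data-driven initialization for Gaussian regime models);
    # later starts use random sticky state paths. Both give temporally
    # coherent responsibilities: i.i.d. per-year random responsibilities
    # average out over time and collapse onto a regime-free optimum.
    gamma0 <- with_local_seed(config$seed + i - 1L, {
      path <- if (i == 1L && length(hid)) {
        kmeans_joint_path(structure, data, S)
      } else {
        sticky_random_path(T_, n_joint)
      }
      g <- matrix((1 - 0.7) / max(n_joint - 1, 1), T_, n_joint)
      g[cbind(seq_len(T_), path)] <- 0.7
      if (n_joint == 1) g[] <- 1
      g / rowSums(g)
    })
    xi0 <- if (T_ > 1) crossprod(gamma0[-T_, , drop = FALSE], gamma0[-1, , drop = FALSE]) else
      matrix(0, n_joint, n_joint)
    stats0 <- cached_suffstats(cache, gamma0, xi0)
    fit <- m_step(stats0, structure, config)
    ll_prev <- -Inf
    lls <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(config$max_iterations)) {
      E <- cached_emission(fit, cache)
      fb <- forward_backward_pass(fit, E, S)
      lls <- c(lls, fb$loglik)
      if (is.finite(ll_prev) &&
        abs(fb$loglik - ll_prev) / (1 + abs(fb$loglik)) < config$rel_tolerance) {
        converged <- TRUE
        break
      }
      ll_prev <- fb$loglik
      fit <- m_step(cached_suffstats(cache, fb$gamma, fb$xi), structure, config, prev = fit)
    }
    traces[[i]] <- tibble(init = i, iteration = seq_along(lls), loglik = lls)
    final_ll <- lls[length(lls)]
    if (is.null(best) || final_ll > best$loglik) {
      best <- list(fit = fit, loglik = final_ll, init = i, converged = converged)
    }
  }
  fit <- canonicalize_states(best$fit)
  attr(fit, "trace") <- dplyr::bind_rows(traces)
  attr(fit, "loglik") <- best$loglik
  attr(fit, "best_init") <- best$init
  attr(fit, "converged") <- best$converged
  fit
}

sticky_random_path <- function(T_, n_states, stay = 0.85) {
  path <- integer(T_)
  path[1] <- sample.int(n_states, 1)
  if (T_ > 1) {
    for (t in 2:T_) {
      path[t] <- if (stats::runif(1) < stay) path[t - 1] else sample.int(n_states, 1)
    }
  }
  path
}

# data-driven joint-state path: per chain, 2-means clustering of the years
# in the space of the chain's observed children (missing values at the
# column mean); chains without children fall back to a sticky random path
kmeans_joint_path <- function(structure_, data, S) {
  hid <- colnames(S)
  T_ <- nrow(data)
  cont <- continuous_node_names(structure_)
  chain_paths <- matrix(1L, T_, length(hid), dimnames = list(NULL, hid))
  for (h in hid) {
    children <- purrr::keep(cont, ~ h %in% node_family(structure_, .x)$dparents)
    if (!length(children)) {
      chain_paths[, h] <- sticky_random_path(T_, 2L)
      next
    }
    X <- as.matrix(data[, children, drop = FALSE])
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
    cl <- tryCatch(
      stats::kmeans(X, centers = 2, nstart = 3)$cluster,
      error = function(e) sticky_random_path(T_, 2L)
    )
    chain_paths[, h] <- as.integer(cl)
  }
  # joint index consistent with the expand.grid state order
  idx <- rep(1L, T_)
  mult <- 1L
  for (h in hid) {
    idx <- idx + (chain_paths[, h] - 1L) * mult
    mult <- mult * 2L
  }
  idx
}

# relabel each hidden chain so that state 1 has the smaller mean for the
# chain's first observed child (label-switching guard)
canonicalize_states <- function(fit) {
  structure_ <- fit$structure
  cont <- continuous_node_names(structure_)
  for (h in hidden_node_names(structure_)) {
    children <- purrr::keep(cont, ~ h %in% node_family(structure_, .x)$dparents)
    if (!length(children)) next
    c1 <- children[[1]]
    fam <- node_family(structure_, c1)
    pos <- match(h, fam$dparents)
    cfgs <- seq_len(2^length(fam$dparents)) - 1L
    bit <- bitwAnd(cfgs %/% 2^(pos - 1L), 1L)
    mu1 <- mean(fit$params[[c1]]$mu[bit == 0L])
    mu2 <- mean(fit$params[[c1]]$mu[bit == 1L])
    if (mu1 <= mu2) next
    # swap the two states of chain h everywhere
    ch <- fit$chains[[h]]
    fit$chains[[h]] <- list(pi = rev(ch$pi), A = ch$A[2:1, 2:1])
    for (v in cont) {
      famv <- node_family(structure_, v)
      posv <- match(h, famv$dparents)
      if (is.na(posv)) next
      cfgv <- seq_len(2^length(famv$dparents)) - 1L
      perm <- bitwXor(cfgv, 2L^(posv - 1L)) + 1L
      p <- fit$params[[v]]
      fit$params[[v]] <- clg_params(
        mu = p$mu[perm],
        w = p$w[perm, , drop = FALSE],
        sigma2 = p$sigma2[perm]
      )
    }
  }
  fit
}
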