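#' Hill-climb configuration
#'
#' Settings for the sliding-window hill-climb with random restarts that
#' estimates edge confidences. Defaults: 10-year windows, stride 1, 10
#' restarts per window, at most 3 parents per node — on a 32-year series
#' this gives 23 windows x 10 restarts = 230 runs, enough for stable
#' confidence estimates.
#'
#' @param window_length Window length in years.
#' @param window_stride Stride between consecutive window starts.
#' @param n_restarts Random restarts per window.
#' @param max_parents Maximum parents per child during the search.
#' @param seed Integer seed.
#' @return List of class `hill_climb_config`.
#' @export
hill_climb_config <- function(window_length = 10L, window_stride = 1L,
                              n_restarts = 10L, max_parents = 3L, seed = 1L) {
  if (max_parents < 1) abort("max_parents must be >= 1")
  if (n_restarts < 1) abort("n_restarts must be >= 1")
  structure(
    list(
      window_length = as.integer(window_length),
      window_stride = as.integer(window_stride),
      n_restarts = as.integer(n_restarts),
      max_parents = as.integer(max_parents),
      seed = as.integer(seed)
    ),
    class = "hill_climb_config"
  )
}

# Gaussian family BIC of child `v` regressed on the lag-1 values of
# `parents` (character; may include v itself = autoregressive link).
# X: years x variables numeric matrix. Higher is better; -Inf when there
# are fewer complete effective rows than parameters.
family_bic <- function(X, v, parents) {
  T_ <- nrow(X)
  y <- X[2:T_, v]
  Z <- cbind(1, X[1:(T_ - 1), parents, drop = FALSE])
  ok <- !is.na(y) & !rowSums(is.na(Z))
  n <- sum(ok)
  k <- ncol(Z) + 1 # intercept + weights + variance
  if (n < k) return(-Inf)
  fit <- stats::.lm.fit(Z[ok, , drop = FALSE], y[ok])
  rss <- sum(fit$residuals^2)
  s2 <- max(rss / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  ll - k / 2 * log(n)
}

#' Score a lag-1 network structure by node-wise Gaussian BIC
#'
#' Each observed node's family score is the maximized Gaussian
#' log-likelihood of its regression on its parents' previous-year values,
#' penalized by half the parameter count times `log(n)`. The total score is
#' the sum over nodes (decomposable); higher is better.
#'
#' @param structure A [dbn_structure()] whose continuous nodes' parents are
#'   columns of `data` (lag-1 edges).
#' @param data Ecosystem table.
#' @return Scalar score; `-Inf` when any family has fewer effective rows
#'   than parameters.
#' @export
score_structure <- function(structure, data) {
  validate_ecosystem_table(data)
  cont <- continuous_node_names(structure)
  X <- as.matrix(data[, setdiff(names(data), "year"), drop = FALSE])
  total <- 0
  for (v in cont) {
    fam <- node_family(structure, v)
    parents <- fam$cparents$name
    if (!all(c(v, parents) %in% colnames(X))) {
      abort(paste0("data lacks columns for family of '", v, "'"))
    }
    total <- total + family_bic(X, v, parents)
  }
  total
}

# reachability in the off-diagonal projected graph: TRUE if `to` is
# reachable from `from` (used to veto cycle-creating additions)
reaches <- function(adj, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(adj)
  seen <- logical(p)
  stack <- from
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[u]) next
    seen[u] <- TRUE
    if (u == to) return(TRUE)
    nxt <- which(adj[u, ] & !seen)
    nxt <- nxt[nxt != u]
    stack <- c(stack, nxt)
  }
  seen[to]
}

#' Greedy hill-climb over lag-1 dependency structures
#'
#' Searches the space of lag-1 parent sets (including autoregressive
#' self-links) by single-edge additions, deletions and reversals from a
#' random initial structure, maximizing the node-wise Gaussian BIC.
#' The projection of the learned graph onto the variables (ignoring the
#' lag) is kept acyclic, mirroring static Bayesian-network semantics, and
#' no child may exceed `config$max_parents` parents. Deterministic given
#' `seed`.
#'
#' @param data Ecosystem table (a window of years).
#' @param config A [hill_climb_config()].
#' @param seed Seed for the random restart (defaults to `config$seed`).
#' @return A [dbn_structure()] over the data's variables with the learned
#'   lag-1 edges; attribute `"score"` holds the final BIC.
#' @export
hill_climb <- function(data, config = hill_climb_config(), seed = config$seed) {
  validate_ecosystem_table(data)
  vars <- table_variables(data)
  X <- as.matrix(data[, vars, drop = FALSE])
  p <- length(vars)
  adj <- with_local_seed(seed, random_initial_adj(p, config$max_parents))
  max_parents <- config$max_parents

  cur <- numeric(p)
  addS <- delS <- matrix(NA_real_, p, p)
  recompute_child <- function(v) {
    parents <- which(adj[, v])
    cur[v] <<- family_bic(X, v, parents)
    for (u in seq_len(p)) {
      if (adj[u, v]) {
        delS[u, v] <<- family_bic(X, v, setdiff(parents, u))
        addS[u, v] <<- NA_real_
      } else {
        addS[u, v] <<- family_bic(X, v, c(parents, u))
        delS[u, v] <<- NA_real_
      }
    }
  }
  for (v in seq_len(p)) recompute_child(v)

  repeat {
    closure <- transitive_closure(adj)
    n_par <- colSums(adj)
    # addition deltas: invalid where edge exists, child is full, or cycle
    addD <- sweep(addS, 2, cur, "-")
    addD[adj] <- -Inf
    addD[, n_par >= max_parents] <- -Inf
    cyc <- t(closure) # cyc[u, v] TRUE when v reaches u
    diag(cyc) <- FALSE # self-links are lag-1, never cyclic
    addD[cyc] <- -Inf
    addD[is.na(addD)] <- -Inf
    # deletion deltas
    delD <- sweep(delS, 2, cur, "-")
    delD[is.na(delD)] <- -Inf
    # reversal deltas: del(u -> v) + add(v -> u); off-diagonal edges only
    revD <- delD + t(sweep(addS, 2, cur, "-"))
    revD[!adj] <- -Inf
    diag(revD) <- -Inf
    revD[is.na(revD)] <- -Inf
    revD[n_par >= max_parents, ] <- -Inf # u would exceed max parents

    improved <- FALSE
    repeat {
      m_add <- max(addD)
      m_del <- max(delD)
      m_rev <- max(revD)
      m_best <- max(m_add, m_del, m_rev)
      if (m_best <= 1e-9) break
      if (m_best == m_rev && m_rev >= m_add && m_rev >= m_del) {
        ij <- which(revD == m_rev, arr.ind = TRUE)[1, ]
        u <- ij[1]
        v <- ij[2]
        adj2 <- adj
        adj2[u, v] <- FALSE
        if (reaches(adj2, u, v)) { # another path u ~> v: reversal cycles
          revD[u, v] <- -Inf
          next
        }
        adj[u, v] <- FALSE
        adj[v, u] <- TRUE
        recompute_child(v)
        recompute_child(u)
      } else if (m_best == m_add && m_add >= m_del) {
        ij <- which(addD == m_add, arr.ind = TRUE)[1, ]
        adj[ij[1], ij[2]] <- TRUE
        recompute_child(ij[2])
      } else {
        ij <- which(delD == m_del, arr.ind = TRUE)[1, ]
        adj[ij[1], ij[2]] <- FALSE
        recompute_child(ij[2])
      }
      improved <- TRUE
      break
    }
    if (!improved) break
  }
  edges <- which(adj, arr.ind = TRUE)
  structure_out <- dbn_structure(
    nodes = tibble(name = vars, kind = "continuous"),
    edges = tibble(from = vars[edges[, 1]], to = vars[edges[, 2]], lag = 1L)
  )
  attr(structure_out, "score") <- sum(cur)
  structure_out
}

# boolean reachability matrix of the off-diagonal projected graph
transitive_closure <- function(adj) {
  R <- adj
  diag(R) <- FALSE
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

which_parents <- function(adj, v) which(adj[, v])

random_initial_adj <- function(p, max_parents) {
  adj <- matrix(FALSE, p, p)
  n_try <- stats::rbinom(1, p, 0.5)
  if (n_try > 0) {
    cand <- cbind(sample.int(p, n_try, replace = TRUE), sample.int(p, n_try, replace = TRUE))
    for (i in seq_len(nrow(cand))) {
      u <- cand[i, 1]
      v <- cand[i, 2]
      if (adj[u, v] || sum(adj[, v]) >= max_parents) next
      if (u != v && reaches(adj, v, u)) next
      adj[u, v] <- TRUE
    }
  }
  adj
}

#' Edge confidence from sliding-window hill-climbs
#'
#' Runs [hill_climb()] on every window x restart combination and reports,
#' for every directed edge, the fraction of runs whose locally optimal
#' structure contains it. When `hidden` is supplied (the smoothed posterior
#' probability of the ARHMM's hidden state), it enters the data matrix as a
#' continuous column named `hidden_name`, so hidden-to-observed
#' dependencies can be learned alongside observed ones.
#'
#' @param data Ecosystem table.
#' @param config A [hill_climb_config()].
#' @param hidden Optional numeric vector (one per year): smoothed
#'   P(hidden state = 2) from an ARHMM fit.
#' @param hidden_name Column name for the hidden series.
#' @return Tibble (`from`, `to`, `confidence`) sorted by descending
#'   confidence, with attribute `"n_runs"`.
#' @export
edge_confidence <- function(data, config = hill_climb_config(), hidden = NULL,
                            hidden_name = "HV") {
  validate_ecosystem_table(data)
  if (!is.null(hidden)) {
    if (length(hidden) != nrow(data)) abort("hidden must have one value per year")
    data[[hidden_name]] <- hidden
  }
  T_ <- nrow(data)
  L <- config$window_length
  if (L > T_) abort("window_length exceeds series length")
  starts <- seq(1L, T_ - L + 1L, by = config$window_stride)
  counts <- NULL
  n_runs <- 0L
  for (wi in seq_along(starts)) {
    window <- data[starts[wi] + 0:(L - 1L), , drop = FALSE]
    for (r in seq_len(config$n_restarts)) {
      seed_run <- (config$seed + 7919L * wi + 104729L * r) %% .Machine$integer.max
      st <- hill_climb(window, config, seed = seed_run)
      n_runs <- n_runs + 1L
      e <- st$edges
      if (nrow(e)) {
        key <- paste(e$from, e$to, sep = "\r")
        counts <- c(counts, key)
      }
    }
  }
  if (is.null(counts)) {
    out <- tibble(from = character(), to = character(), confidence = numeric())
  } else {
    tab <- table(counts)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- tibble(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      confidence = as.numeric(tab) / n_runs
    ) %>% arrange(dplyr::desc(.data$confidence), .data$from, .data$to)
  }
  attr(out, "n_runs") <- n_runs
  out
}
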