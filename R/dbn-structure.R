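#' Define a two-slice dynamic Bayesian network structure
#'
#' A structure couples two kinds of nodes: observed continuous (scalar,
#' conditional linear Gaussian) and hidden discrete (binary regime chains).
#' Edges are either intra-slice (`lag = 0`, within a year) or inter-slice
#' (`lag = 1`, from year t-1 to year t). Hidden-to-hidden edges may only be
#' lag-1 self-links, so each hidden node is a first-order Markov chain; the
#' intra-slice graph must be acyclic, which makes the unrolled network
#' acyclic as well.
#'
#' @param nodes Tibble/data frame with columns `name` and `kind`
#'   (`"continuous"` or `"hidden"`). Hidden nodes are binary.
#' @param edges Tibble/data frame with columns `from`, `to`, `lag` (0 or 1).
#'   Duplicate edges are an error; lag-0 self-loops are an error.
#' @return An object of class `dbn_structure`.
#' @export
#' @examples
#' dbn_structure(
#'   nodes = tibble::tibble(name = c("H", "x"), kind = c("hidden", "continuous")),
#'   edges = tibble::tibble(from = c("H", "H", "x"), to = c("H", "x", "x"), lag = c(1, 0, 1))
#' )
dbn_structure <- function(nodes, edges) {
  nodes <- as_tibble(nodes)[, c("name", "kind")]
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), lag = integer())
  }
  edges <- as_tibble(edges)[, c("from", "to", "lag")]
  edges$lag <- as.integer(edges$lag)
  if (anyDuplicated(nodes$name)) abort("duplicate node name")
  if (!all(nodes$kind %in% c("continuous", "hidden"))) {
    abort("node kind must be 'continuous' or 'hidden'")
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(unknown)) abort(paste0("edge references unknown node: ", unknown[1]))
  if (!all(edges$lag %in% c(0L, 1L))) abort("edge lag must be 0 or 1")
  if (anyDuplicated(edges[, c("from", "to", "lag")])) abort("duplicate edge")
  if (any(edges$lag == 0L & edges$from == edges$to)) abort("intra-slice self-loop")
  kind <- stats::setNames(nodes$kind, nodes$name)
  hh <- edges$lag == 1L & kind[edges$from] == "hidden" & kind[edges$to] == "hidden"
  if (any(kind[edges$from] == "hidden" & kind[edges$to] == "hidden" & !(hh & edges$from == edges$to))) {
    abort("hidden-to-hidden edges must be lag-1 self-links")
  }
  if (any(kind[edges$from] == "continuous" & kind[edges$to] == "hidden")) {
    abort("hidden nodes cannot have continuous parents")
  }
  intra <- edges[edges$lag == 0L, ]
  if (nrow(intra)) {
    g <- igraph::graph_from_data_frame(intra[, c("from", "to")],
      vertices = nodes$name, directed = TRUE
    )
    if (!igraph::is_dag(g)) abort("intra-slice graph has a cycle")
  }
  structure(list(nodes = nodes, edges = edges), class = "dbn_structure")
}

#' @export
print.dbn_structure <- function(x, ...) {
  nh <- sum(x$nodes$kind == "hidden")
  cat(
    "<dbn_structure> ", sum(x$nodes$kind == "continuous"), " observed node(s), ",
    nh, " hidden chain(s), ", nrow(x$edges), " edge(s)\n",
    sep = ""
  )
  invisible(x)
}

hidden_node_names <- function(structure) {
  structure$nodes$name[structure$nodes$kind == "hidden"]
}

continuous_node_names <- function(structure) {
  structure$nodes$name[structure$nodes$kind == "continuous"]
}

node_kind <- function(structure, name) {
  structure$nodes$kind[match(name, structure$nodes$name)]
}

# parents of a continuous node, split into hidden (always intra-slice) and
# continuous (tibble name/lag); hidden parents sorted for stable config order
node_family <- function(structure, name) {
  e <- structure$edges[structure$edges$to == name, , drop = FALSE]
  kinds <- node_kind(structure, e$from)
  list(
    dparents = sort(e$from[kinds == "hidden"]),
    cparents = tibble(name = e$from[kinds == "continuous"], lag = e$lag[kinds == "continuous"])
  )
}

# topological order of continuous nodes under intra-slice continuous edges
intra_topo_order <- function(structure) {
  cont <- continuous_node_names(structure)
  kind <- stats::setNames(structure$nodes$kind, structure$nodes$name)
  e <- structure$edges[structure$edges$lag == 0L &
    kind[structure$edges$from] == "continuous" &
    kind[structure$edges$to] == "continuous", , drop = FALSE]
  if (!nrow(e)) return(cont)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], vertices = cont, directed = TRUE)
  names(igraph::topo_sort(g, mode = "out"))
}

max_parent_count <- function(structure) {
  if (!nrow(structure$edges)) return(0L)
  cont <- continuous_node_names(structure)
  e <- structure$edges[structure$edges$to %in% cont, , drop = FALSE]
  if (!nrow(e)) return(0L)
  max(table(e$to))
}

#' Conditional linear Gaussian node parameters
#'
#' Parameters of one observed node: per discrete-parent configuration `i`,
#' an intercept `mu[i]`, a row of regression weights `w[i, ]` over the
#' node's continuous parents, and a variance `sigma2[i]`.
#'
#' @param mu Numeric vector, one intercept per configuration.
#' @param w Numeric matrix (configurations x continuous parents); may have
#'   zero columns for nodes without continuous parents.
#' @param sigma2 Positive numeric vector, one variance per configuration.
#' @return A list of class `clg_params`.
#' @export
clg_params <- function(mu, w = matrix(0, length(mu), 0), sigma2) {
  mu <- as.numeric(mu)
  sigma2 <- as.numeric(sigma2)
  w <- as.matrix(w)
  if (length(sigma2) != length(mu) || nrow(w) != length(mu)) {
    abort("mu, w rows and sigma2 must share the number of configurations")
  }
  if (any(sigma2 <= 0)) abort("sigma2 must be positive")
  structure(list(mu = mu, w = w, sigma2 = sigma2), class = "clg_params")
}

#' Assemble a fitted (or hand-parameterized) dynamic Bayesian network
#'
#' @param structure A [dbn_structure()].
#' @param params Named list of [clg_params()], one per continuous node. The
#'   number of configurations must be `2^(number of hidden parents)` and the
#'   weight columns must match the node's continuous parents (in the order
#'   given by the structure's edge list).
#' @param chains Named list, one per hidden node, each
#'   `list(pi = length-2 initial distribution, A = 2x2 transition matrix)`.
#' @return Object of class `dbn_fit`.
#' @export
dbn_model <- function(structure, params, chains = list()) {
  cont <- continuous_node_names(structure)
  hid <- hidden_node_names(structure)
  if (!setequal(names(params), cont)) abort("params must cover exactly the continuous nodes")
  if (!setequal(names(chains), hid)) abort("chains must cover exactly the hidden nodes")
  for (v in cont) {
    fam <- node_family(structure, v)
    p <- params[[v]]
    if (length(p$mu) != 2^length(fam$dparents)) {
      abort(paste0("node '", v, "': expected ", 2^length(fam$dparents), " configurations"))
    }
    if (ncol(p$w) != nrow(fam$cparents)) {
      abort(paste0("node '", v, "': weight columns must match continuous parents"))
    }
  }
  for (h in hid) {
    ch <- chains[[h]]
    if (abs(sum(ch$pi) - 1) > 1e-8 || any(ch$pi < 0)) abort("pi must be a distribution")
    if (any(abs(rowSums(ch$A) - 1) > 1e-8) || any(ch$A < 0)) abort("A rows must be distributions")
  }
  structure(list(structure = structure, params = params, chains = chains),
    class = "dbn_fit"
  )
}

#' @export
print.dbn_fit <- function(x, ...) {
  print(x$structure)
  cat("fitted parameters for", length(x$params), "observed node(s)\n")
  invisible(x)
}

# --- joint hidden state machinery ---------------------------------------

# matrix of joint states (rows: joint configurations, cols: chains, values 1/2)
joint_state_matrix <- function(fit) {
  hid <- hidden_node_names(fit$structure)
  if (!length(hid)) {
    return(matrix(integer(), nrow = 1, ncol = 0, dimnames = list(NULL, NULL)))
  }
  g <- do.call(expand.grid, stats::setNames(rep(list(1:2), length(hid)), hid))
  as.matrix(g)
}

joint_initial <- function(fit, S) {
  p <- rep(1, nrow(S))
  for (h in colnames(S)) p <- p * fit$chains[[h]]$pi[S[, h]]
  p
}

joint_transition <- function(fit, S) {
  n <- nrow(S)
  P <- matrix(1, n, n)
  for (h in colnames(S)) {
    A <- fit$chains[[h]]$A
    P <- P * A[cbind(S[rep(seq_len(n), times = n), h], S[rep(seq_len(n), each = n), h])]
  }
  # row r (state at t-1) -> column c (state at t)
  matrix(P, n, n, byrow = FALSE)
}

# map joint states to a node's local configuration index (first parent fastest)
node_config_of_joint <- function(S, dparents) {
  if (!length(dparents)) return(rep(1L, nrow(S)))
  idx <- rep(1L, nrow(S))
  mult <- 1L
  for (dp in dparents) {
    idx <- idx + (S[, dp] - 1L) * mult
    mult <- mult * 2L
  }
  idx
}
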