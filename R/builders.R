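#' Build the autoregressive hidden Markov model structure
#'
#' The simplest competing structure: one binary hidden regime chain `H`
#' (lag-1 self-link) influencing every observed component within the year,
#' and a lag-1 autoregressive self-link on every observed component. No
#' other edges.
#'
#' @param descriptors Variable descriptor tibble from
#'   [variable_descriptors()].
#' @param hidden_name Name of the hidden chain node.
#' @return A [dbn_structure()].
#' @export
build_arhmm <- function(descriptors, hidden_name = "H") {
  vars <- descriptors$name
  if (!length(vars)) abort("need at least one observed variable")
  nodes <- tibble(
    name = c(hidden_name, vars),
    kind = c("hidden", rep("continuous", length(vars)))
  )
  edges <- dplyr::bind_rows(
    tibble(from = hidden_name, to = hidden_name, lag = 1L),
    tibble(from = hidden_name, to = vars, lag = 0L),
    tibble(from = vars, to = vars, lag = 1L)
  )
  dbn_structure(nodes, edges)
}

# shared scaffolding for the two learned-structure builders: the two hidden
# regime chains, their mandated links to the climate indices, and (optionally)
# autoregressive self-links
hidden_scaffold <- function(descriptors, ar_vars, hv_amo = "HV_AMO", hv_sst = "HV_SST") {
  amo_vars <- descriptors$name[descriptors$category == "climate" & !descriptors$sst_region]
  sst_vars <- descriptors$name[descriptors$sst_region]
  edges <- dplyr::bind_rows(
    tibble(from = c(hv_amo, hv_sst), to = c(hv_amo, hv_sst), lag = 1L),
    if (length(amo_vars)) tibble(from = hv_amo, to = amo_vars, lag = 0L),
    if (length(sst_vars)) tibble(from = hv_sst, to = sst_vars, lag = 0L),
    if (length(ar_vars)) tibble(from = ar_vars, to = ar_vars, lag = 1L)
  )
  nodes <- tibble(
    name = c(hv_amo, hv_sst, descriptors$name),
    kind = c("hidden", "hidden", rep("continuous", nrow(descriptors)))
  )
  list(nodes = nodes, edges = edges, hv_amo = hv_amo, hv_sst = hv_sst, amo_vars = amo_vars)
}

# candidate learned parents of `child`, best first: by descending confidence,
# ties broken lexicographically by parent name; self-links excluded
ranked_candidates <- function(confidence, child) {
  cand <- confidence[confidence$to == child & confidence$from != child, , drop = FALSE]
  cand[order(-cand$confidence, cand$from), , drop = FALSE]
}

# map an edge out of the learned hidden column onto one of the two regime
# chains: the AMO chain for the AMO node, the SST chain otherwise
resolve_hidden_parent <- function(parent, child, scaffold, hidden_name) {
  if (parent != hidden_name) return(parent)
  if (child %in% scaffold$amo_vars) scaffold$hv_amo else scaffold$hv_sst
}

#' Build the autoregressive dynamic Bayesian network structure
#'
#' The moderate-complexity structure: two binary hidden regime chains
#' (`HV_AMO` linked to the non-SST climate index, `HV_SST` to every
#' regional SST series), an autoregressive lag-1 self-link on every
#' observed component, and, for each predicted component, exactly its
#' single highest-confidence learned parent from the hill-climb. A learned
#' parent that is the hidden-state column is allocated to one of the two
#' regime chains (the AMO chain for the AMO node, the SST chain otherwise).
#'
#' @param confidence Edge-confidence tibble from [edge_confidence()].
#' @param descriptors Variable descriptor tibble.
#' @param hidden_name Name of the learned hidden column inside
#'   `confidence`.
#' @return A [dbn_structure()].
#' @export
build_ardbn <- function(confidence, descriptors, hidden_name = "HV") {
  sc <- hidden_scaffold(descriptors, ar_vars = descriptors$name)
  predicted <- descriptors$name[descriptors$predicted]
  orphans <- character()
  extra <- list()
  for (child in predicted) {
    cand <- ranked_candidates(confidence, child)
    if (!nrow(cand)) {
      orphans <- c(orphans, child)
      next
    }
    parent <- resolve_hidden_parent(cand$from[1], child, sc, hidden_name)
    lag <- if (parent %in% c(sc$hv_amo, sc$hv_sst)) 0L else 1L
    extra[[child]] <- tibble(from = parent, to = child, lag = lag)
  }
  if (length(orphans)) {
    abort(paste0("no scored candidate parent for: ", paste(orphans, collapse = ", ")))
  }
  edges <- dplyr::distinct(dplyr::bind_rows(sc$edges, dplyr::bind_rows(extra)))
  dbn_structure(sc$nodes, edges)
}

#' Build the data-driven dynamic Bayesian network structure
#'
#' The most complex structure: the two hidden regime chains keep their
#' lag-1 self-links, autoregressive self-links are retained only for
#' climate and physiochemical drivers, and each predicted component
#' receives its top-confidence learned parents — those at or above
#' `threshold`, best first — up to three parents in total. When no
#' candidate reaches the threshold, the child falls back to its single
#' best-scored parent so that every predicted component stays predictable.
#' Any edge that would close a cycle in the unrolled network is skipped.
#'
#' @inheritParams build_ardbn
#' @param threshold Minimum confidence for a candidate edge.
#' @param max_parents Cap on each child's total parent count.
#' @return A [dbn_structure()].
#' @export
build_dddbn <- function(confidence, descriptors, hidden_name = "HV",
                        threshold = 0.5, max_parents = 3L) {
  driver_vars <- descriptors$name[descriptors$category %in% c("climate", "physiochemical")]
  sc <- hidden_scaffold(descriptors, ar_vars = driver_vars)
  predicted <- descriptors$name[descriptors$predicted]
  edges <- sc$edges
  orphans <- character()
  for (child in predicted) {
    cand <- ranked_candidates(confidence, child)
    if (!nrow(cand)) {
      orphans <- c(orphans, child)
      next
    }
    keep <- cand[cand$confidence >= threshold, , drop = FALSE]
    if (!nrow(keep)) keep <- cand[1, , drop = FALSE]
    n_parents <- sum(edges$to == child)
    for (i in seq_len(nrow(keep))) {
      if (n_parents >= max_parents) break
      parent <- resolve_hidden_parent(keep$from[i], child, sc, hidden_name)
      lag <- if (parent %in% c(sc$hv_amo, sc$hv_sst)) 0L else 1L
      cand_edge <- tibble(from = parent, to = child, lag = lag)
      if (nrow(dplyr::semi_join(cand_edge, edges, by = c("from", "to", "lag")))) next
      trial <- dplyr::bind_rows(edges, cand_edge)
      ok <- tryCatch(
        {
          dbn_structure(sc$nodes, trial)
          TRUE
        },
        error = function(e) FALSE
      )
      if (!ok) next
      edges <- trial
      n_parents <- n_parents + 1L
    }
  }
  if (length(orphans)) {
    abort(paste0("no scored candidate parent for: ", paste(orphans, collapse = ", ")))
  }
  dbn_structure(sc$nodes, edges)
}
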