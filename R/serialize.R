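#' Export a structure as Graphviz DOT
#'
#' Hidden nodes are drawn as boxes; lag-1 edges are dashed and labelled.
#'
#' @param structure A [dbn_structure()].
#' @return A single DOT string (also usable with `cat()`).
#' @export
structure_to_dot <- function(structure) {
  nd <- structure$nodes
  shapes <- ifelse(nd$kind == "hidden", "box", "ellipse")
  node_lines <- sprintf("  \"%s\" [shape=%s];", nd$name, shapes)
  e <- structure$edges
  edge_lines <- if (nrow(e)) {
    sprintf(
      "  \"%s\" -> \"%s\"%s;", e$from, e$to,
      ifelse(e$lag == 1L, " [style=dashed, label=\"t-1\"]", "")
    )
  } else {
    character()
  }
  paste(c("digraph dbn {", node_lines, edge_lines, "}"), collapse = "\n")
}

#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON document holding the structure, every node's
#' conditional linear Gaussian parameters, and the hidden chains. Requires
#' the `jsonlite` package.
#'
#' @param fit A `dbn_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dbn_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_dbn_json requires the 'jsonlite' package")
  }
  doc <- list(
    format = "ecodbn-model", version = 1L,
    nodes = fit$structure$nodes,
    edges = fit$structure$edges,
    params = purrr::map(fit$params, function(p) {
      list(mu = p$mu, w = unclass(p$w), sigma2 = p$sigma2)
    }),
    chains = purrr::map(fit$chains, function(ch) list(pi = ch$pi, A = unclass(ch$A)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path A file written by [write_dbn_json()].
#' @return A `dbn_fit`.
#' @export
read_dbn_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("read_dbn_json requires the 'jsonlite' package")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ecodbn-model")) abort("not an ecodbn model document")
  structure_ <- dbn_structure(as_tibble(doc$nodes), as_tibble(doc$edges))
  params <- purrr::map(doc$params, function(p) {
    w <- p$w
    if (is.null(w) || !length(w) || (is.list(w) && all(lengths(w) == 0))) {
      w <- matrix(0, length(p$mu), 0)
    }
    clg_params(mu = as.numeric(p$mu), w = matrix(unlist(w), nrow = length(p$mu)),
               sigma2 = as.numeric(p$sigma2))
  })
  chains <- purrr::map(doc$chains, function(ch) {
    A <- ch$A
    # the document stores A row-major; guard against list-of-rows parses
    if (!is.matrix(A)) A <- matrix(unlist(A), 2, 2, byrow = TRUE)
    list(pi = as.numeric(ch$pi), A = A)
  })
  dbn_model(structure_, params, chains)
}
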