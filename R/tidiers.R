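#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted dynamic Bayesian network
#'
#' One row per node, discrete-parent configuration and term: intercepts,
#' regression weights (named `<parent>.lag<k>`) and variances, plus the
#' hidden chains' initial and transition probabilities.
#'
#' @param x A `dbn_fit`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `config`, `term`, `estimate`.
#' @method tidy dbn_fit
#' @export
tidy.dbn_fit <- function(x, ...) {
  cont_rows <- purrr::map_dfr(names(x$params), function(v) {
    p <- x$params[[v]]
    fam <- node_family(x$structure, v)
    terms <- c(
      "(Intercept)",
      if (nrow(fam$cparents)) paste0(fam$cparents$name, ".lag", fam$cparents$lag),
      "sigma2"
    )
    purrr::map_dfr(seq_along(p$mu), function(cfg) {
      tibble(
        node = v, config = cfg, term = terms,
        estimate = c(p$mu[cfg], if (ncol(p$w)) p$w[cfg, ], p$sigma2[cfg])
      )
    })
  })
  chain_rows <- purrr::map_dfr(names(x$chains), function(h) {
    ch <- x$chains[[h]]
    tibble(
      node = h, config = NA_integer_,
      term = c("pi[1]", "pi[2]", "A[1,1]", "A[1,2]", "A[2,1]", "A[2,2]"),
      estimate = c(ch$pi, ch$A[1, 1], ch$A[1, 2], ch$A[2, 1], ch$A[2, 2])
    )
  })
  dplyr::bind_rows(cont_rows, chain_rows)
}

#' One-line fit summary
#'
#' @param x A `dbn_fit` returned by [fit_em()].
#' @param ... Unused.
#' @return Tibble with `loglik`, `n_params`, `n_iterations`, `converged`,
#'   `best_init`.
#' @method glance dbn_fit
#' @export
glance.dbn_fit <- function(x, ...) {
  n_params <- sum(purrr::map_int(x$params, function(p) {
    length(p$mu) * (2L + ncol(p$w))
  })) + 3L * length(x$chains)
  trace <- attr(x, "trace")
  tibble(
    loglik = attr(x, "loglik") %||% NA_real_,
    n_params = n_params,
    n_iterations = if (is.null(trace)) NA_integer_ else max(trace$iteration),
    converged = attr(x, "converged") %||% NA,
    best_init = attr(x, "best_init") %||% NA_integer_
  )
}

#' @method tidy dbn_eval
#' @export
tidy.dbn_eval <- function(x, ...) x$predictions

#' @method glance dbn_eval
#' @export
glance.dbn_eval <- function(x, ...) {
  tibble(
    total_sse = sum(x$sse$sse), n_variables = nrow(x$sse),
    n_boot = x$n_boot, n_failed = x$n_failed
  )
}

#' @method tidy dbn_comparison
#' @export
tidy.dbn_comparison <- function(x, ...) {
  models <- intersect(c("ARHMM", "ARDBN", "DDDBN"), names(x))
  tidyr::pivot_longer(
    as_tibble(x)[, c("variable", models)],
    cols = dplyr::all_of(models), names_to = "model", values_to = "sse"
  )
}

#' @method tidy dbn_scenario
#' @export
tidy.dbn_scenario <- function(x, ...) x$series

#' @method glance dbn_scenario
#' @export
glance.dbn_scenario <- function(x, ...) {
  tibble(
    label = x$spec$label, delta_celsius = x$spec$delta_celsius,
    mean_abs_diff = mean(abs(x$summary$mean_diff)), n_boot = x$n_boot
  )
}
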