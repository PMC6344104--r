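#' Sum of squared prediction errors
#'
#' @param predicted,actual Equal-length numeric vectors; pairs with a
#'   missing actual (or prediction) are excluded.
#' @return Sum over complete pairs of `(predicted - actual)^2`.
#' @export
sse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort("length mismatch")
  ok <- !is.na(predicted) & !is.na(actual)
  sum((predicted[ok] - actual[ok])^2)
}

#' Non-parametric bootstrap split of the years
#'
#' Draws `n_years` year indices uniformly with replacement as the training
#' multiset; the out-of-bag years (never drawn) form the test set. A draw
#' leaving no out-of-bag year is redrawn.
#'
#' @param n_years Number of years (>= 3).
#' @param seed Integer seed; the split is reproducible.
#' @return List with `train` (integer multiset, length `n_years`) and
#'   `test` (sorted out-of-bag year indices).
#' @export
bootstrap_split <- function(n_years, seed = 1L) {
  if (n_years < 3) abort("n_years must be >= 3")
  with_local_seed(seed, {
    repeat {
      train <- sample.int(n_years, n_years, replace = TRUE)
      test <- setdiff(seq_len(n_years), unique(train))
      if (length(test)) break
    }
    list(train = train, test = sort(test))
  })
}

#' Bootstrap one-step-ahead evaluation of a network structure
#'
#' For each bootstrap iteration the model parameters are re-estimated by EM
#' with the training years' bootstrap multiplicities as emission weights
#' (out-of-bag years contribute no evidence), then every out-of-bag year t
#' with an observed predecessor is predicted one step ahead from the
#' observed evidence at t-1 and the filtered hidden-state posterior at t-1.
#' Per-variable SSE is the per-iteration sum over test years, averaged
#' across iterations; per-year bootstrap means and standard deviations give
#' the 95% intervals (mean +- 1.96 sd).
#'
#' @param data Standardized ecosystem table.
#' @param structure A [dbn_structure()].
#' @param n_boot Bootstrap iterations (the full protocol uses 250).
#' @param em Control object from [em_config()].
#' @param seed Integer seed driving all splits and EM initializations.
#' @param predicted Character vector of variables to score; defaults to all
#'   observed nodes.
#' @return Object of class `dbn_eval`: list with `sse` (tibble `variable`,
#'   `sse`, `sse_total`), `predictions` (tibble `variable`, `year`,
#'   `observed`, `boot_mean`, `boot_sd`, `lo95`, `hi95`), `n_boot`,
#'   `n_failed`.
#' @export
evaluate_model <- function(data, structure, n_boot = 250L,
                           em = em_config(n_inits = 2L, max_iterations = 100L,
                                          rel_tolerance = 1e-5),
                           seed = 1L, predicted = NULL) {
  validate_ecosystem_table(data)
  cont <- continuous_node_names(structure)
  if (is.null(predicted)) predicted <- cont
  T_ <- nrow(data)
  obs <- as.matrix(data[, cont, drop = FALSE])
  sse_rows <- list()
  pred_rows <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    seed_b <- (seed + 49999L * b) %% .Machine$integer.max
    split <- bootstrap_split(T_, seed = seed_b)
    weights <- tabulate(split$train, nbins = T_)
    res <- tryCatch(
      boot_iteration(data, structure, weights, split$test, em, seed_b, obs, cont),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      if (n_failed > max(1L, ceiling(0.1 * n_boot))) {
        abort(paste0("EM failed in ", n_failed, " bootstrap iterations; aborting"))
      }
      next
    }
    res$iteration <- b
    pred_rows[[length(pred_rows) + 1L]] <- res
    err <- res %>%
      filter(.data$variable %in% predicted) %>%
      group_by(.data$variable) %>%
      summarise(sse = sum((.data$mean - .data$observed)^2, na.rm = TRUE), .groups = "drop")
    sse_rows[[length(sse_rows) + 1L]] <- err
  }
  n_ok <- n_boot - n_failed
  if (!n_ok) abort("all bootstrap iterations failed")
  preds <- dplyr::bind_rows(pred_rows)
  sse_tab <- dplyr::bind_rows(sse_rows) %>%
    group_by(.data$variable) %>%
    summarise(
      sse_total = sum(.data$sse),
      sse = mean(.data$sse),
      .groups = "drop"
    ) %>%
    select("variable", "sse", "sse_total") %>%
    arrange(match(.data$variable, cont))
  summary_tab <- preds %>%
    group_by(.data$variable, .data$year) %>%
    summarise(
      observed = .data$observed[1],
      boot_mean = mean(.data$mean),
      boot_sd = if (dplyr::n() > 1) stats::sd(.data$mean) else 0,
      .groups = "drop"
    ) %>%
    mutate(
      lo95 = .data$boot_mean - 1.96 * .data$boot_sd,
      hi95 = .data$boot_mean + 1.96 * .data$boot_sd
    ) %>%
    arrange(match(.data$variable, cont), .data$year)
  structure(
    list(
      sse = sse_tab, predictions = summary_tab,
      n_boot = n_boot, n_failed = n_failed, predicted = predicted
    ),
    class = "dbn_eval"
  )
}

# one bootstrap iteration: weighted EM refit, filtered hidden priors, and
# one-step predictions at the out-of-bag years
boot_iteration <- function(data, structure, weights, test_years, em, seed_b, obs, cont) {
  em_b <- em
  em_b$seed <- seed_b
  fit <- fit_em(structure, data, config = em_b, weights = weights)
  ff <- forward_filter(fit, data)
  S <- ff$states
  hid <- colnames(S)
  rows <- list()
  for (t in test_years) {
    if (t < 2) next
    evidence <- obs[t - 1, ]
    if (all(is.na(evidence))) next
    prior <- NULL
    if (length(hid)) {
      prior <- purrr::map(stats::setNames(hid, hid), function(h) {
        vapply(1:2, function(s) sum(ff$filtered[t - 1, S[, h] == s]), numeric(1))
      })
    }
    pr <- predict_one_step(fit, evidence, prior)
    pr$year <- data$year[t]
    pr$observed <- obs[t, pr$variable]
    rows[[length(rows) + 1L]] <- pr
  }
  dplyr::bind_rows(rows)
}

#' @export
print.dbn_eval <- function(x, ...) {
  cat(
    "<dbn_eval> ", x$n_boot, " bootstrap iterations (", x$n_failed, " failed), ",
    length(unique(x$sse$variable)), " scored variable(s)\n",
    sep = ""
  )
  print(x$sse, n = 10)
  invisible(x)
}

#' Compare the three competing structures by bootstrap predictive error
#'
#' Builds the ARHMM, ARDBN and DDDBN structures, evaluates each with
#' [evaluate_model()] under a shared seed (identical bootstrap splits), and
#' marks the per-variable minimum SSE. Ties go to the simpler model
#' (ARHMM before ARDBN before DDDBN).
#'
#' @param data Standardized ecosystem table.
#' @param confidence Edge-confidence tibble from [edge_confidence()].
#' @param descriptors Variable descriptor tibble.
#' @param n_boot Bootstrap iterations per model.
#' @param em [em_config()] used for every refit.
#' @param seed Integer seed.
#' @param hidden_name Name of the learned hidden column in `confidence`.
#' @return Object of class `dbn_comparison`: tibble (`variable`, `ARHMM`,
#'   `ARDBN`, `DDDBN`, `best`) with the three [evaluate_model()] results in
#'   attribute `"evaluations"`.
#' @export
compare_models <- function(data, confidence, descriptors, n_boot = 250L,
                           em = em_config(n_inits = 2L, max_iterations = 100L,
                                          rel_tolerance = 1e-5),
                           seed = 1L, hidden_name = "HV") {
  predicted <- descriptors$name[descriptors$predicted]
  structures <- list(
    ARHMM = build_arhmm(descriptors),
    ARDBN = build_ardbn(confidence, descriptors, hidden_name),
    DDDBN = build_dddbn(confidence, descriptors, hidden_name)
  )
  evals <- purrr::map(structures, function(st) {
    evaluate_model(data, st, n_boot = n_boot, em = em, seed = seed, predicted = predicted)
  })
  tab <- tibble(variable = predicted)
  for (m in names(evals)) {
    tab[[m]] <- evals[[m]]$sse$sse[match(predicted, evals[[m]]$sse$variable)]
  }
  models <- names(structures)
  tab$best <- models[apply(as.matrix(tab[, models]), 1, which.min)]
  structure(tab, class = c("dbn_comparison", class(tab)), evaluations = evals)
}
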