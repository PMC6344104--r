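#' Specify a sea-surface-temperature press perturbation
#'
#' A press is a sustained increase of `delta_celsius` degrees applied to
#' the regional SST series, expressed in physical units and converted to
#' the model's standardized scale with each series' own original standard
#' deviation.
#'
#' @param delta_celsius Nonnegative temperature increase in degrees
#'   Celsius.
#' @param targets Character vector of SST variable names to perturb.
#' @param label Scenario label; defaults to `"+<delta>C"`.
#' @param scale `"raw"` (delta in degrees Celsius, converted by each
#'   series' original sd) or `"standardized"` (delta applied directly on
#'   the standardized scale).
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(delta_celsius, targets, label = NULL, scale = c("raw", "standardized")) {
  if (delta_celsius < 0) abort("delta_celsius must be >= 0")
  scale <- match.arg(scale)
  structure(
    list(
      delta_celsius = delta_celsius,
      targets = as.character(targets),
      label = label %||% sprintf("+%.1fC", delta_celsius),
      scale = scale
    ),
    class = "scenario_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an SST press to a standardized table
#'
#' Each target column is shifted by `delta_celsius / sd_original`, i.e. a
#' sustained +delta degrees Celsius in physical units; every other column
#' is untouched. A zero delta returns the table unchanged.
#'
#' @param data Standardized ecosystem table.
#' @param params Standardization parameters (tibble `variable`, `mean`,
#'   `sd`) covering the targets; unused when the spec's scale is
#'   `"standardized"`.
#' @param spec A [scenario_spec()].
#' @return The perturbed table.
#' @export
perturb_sst <- function(data, params, spec) {
  validate_ecosystem_table(data)
  missing_cols <- setdiff(spec$targets, names(data))
  if (length(missing_cols)) {
    abort(paste0("targets absent from data: ", paste(missing_cols, collapse = ", ")))
  }
  out <- data
  for (v in spec$targets) {
    shift <- if (spec$scale == "standardized") {
      spec$delta_celsius
    } else {
      i <- match(v, params$variable)
      if (is.na(i)) abort(paste0("no standardization params for target '", v, "'"))
      spec$delta_celsius / params$sd[i]
    }
    out[[v]] <- data[[v]] + shift
  }
  out
}

#' Run a press-perturbation scenario through a fitted network
#'
#' Training is untouched: parameters are (re-)estimated on the original
#' data only, under the same bootstrap protocol as model evaluation. For
#' every bootstrap refit, each year from the second onward is predicted
#' one step ahead twice — once from the original evidence (baseline) and
#' once under the press. In the press pass the SST columns of the evidence
#' carry the sustained shift (hidden-state filtering also sees the
#' perturbed SST, so the SST regime chain responds), and press-induced
#' prediction shifts are propagated recursively: the shift a downstream
#' variable acquires at year t feeds its children's evidence at year t+1.
#' This realizes multi-hop responses along directed SST paths (their
#' magnitude is the product of the path weights in a linear model), while
#' all non-SST *data* stay untouched. The scenario response per variable
#' is the mean over years of (scenario - baseline) bootstrap-mean
#' predictions, on the standardized scale.
#'
#' @param data Standardized ecosystem table (original, unperturbed).
#' @param structure A [dbn_structure()].
#' @param params Standardization parameters for the unit conversion.
#' @param spec A [scenario_spec()].
#' @param n_boot Bootstrap refits.
#' @param em [em_config()] for the refits.
#' @param seed Integer seed (shared splits with the baseline).
#' @param predicted Variables to report; defaults to all observed nodes.
#' @return Object of class `dbn_scenario`: list with `series` (tibble
#'   `variable`, `year`, `baseline`, `scenario`, `diff`, `boot_sd`),
#'   `summary` (tibble `variable`, `mean_diff`), and the spec.
#' @export
run_scenario <- function(data, structure, params, spec, n_boot = 50L,
                         em = em_config(n_inits = 2L, max_iterations = 100L,
                                        rel_tolerance = 1e-5),
                         seed = 1L, predicted = NULL) {
  validate_ecosystem_table(data)
  cont <- continuous_node_names(structure)
  if (is.null(predicted)) predicted <- cont
  data_press <- perturb_sst(data, params, spec)
  T_ <- nrow(data)
  obs <- as.matrix(data[, cont, drop = FALSE])
  rows <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    seed_b <- (seed + 49999L * b) %% .Machine$integer.max
    split <- bootstrap_split(T_, seed = seed_b)
    weights <- tabulate(split$train, nbins = T_)
    res <- tryCatch(
      {
        em_b <- em
        em_b$seed <- seed_b
        fit <- fit_em(structure, data, config = em_b, weights = weights)
        press_predictions(fit, data, data_press, obs, spec$targets)
      },
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      if (n_failed > max(1L, ceiling(0.1 * n_boot))) {
        abort("too many failed bootstrap refits in scenario run")
      }
      next
    }
    res$iteration <- b
    rows[[length(rows) + 1L]] <- res
  }
  all_rows <- dplyr::bind_rows(rows) %>% filter(.data$variable %in% predicted)
  series <- all_rows %>%
    group_by(.data$variable, .data$year) %>%
    summarise(
      baseline = mean(.data$baseline),
      scenario = mean(.data$scenario),
      boot_sd = if (dplyr::n() > 1) stats::sd(.data$scenario - .data$baseline) else 0,
      .groups = "drop"
    ) %>%
    mutate(diff = .data$scenario - .data$baseline) %>%
    arrange(match(.data$variable, cont), .data$year)
  summary_tab <- series %>%
    group_by(.data$variable) %>%
    summarise(mean_diff = mean(.data$diff), .groups = "drop") %>%
    arrange(match(.data$variable, cont))
  structure(
    list(series = series, summary = summary_tab, spec = spec, n_boot = n_boot),
    class = "dbn_scenario"
  )
}

# paired baseline/press one-step predictions for every year from the second
# onward. The baseline pass filters and predicts on the original evidence.
# The press pass filters on the perturbed table (pressed SST only) and
# predicts from evidence shifted by the press: target columns by the fixed
# press, downstream columns by their own press-induced prediction shift
# from the previous year (recursive propagation along directed paths).
press_predictions <- function(fit, data, data_press, obs, targets) {
  cont <- continuous_node_names(fit$structure)
  ff_b <- forward_filter(fit, data)
  ff_s <- forward_filter(fit, data_press)
  S <- ff_b$states
  hid <- colnames(S)
  press_fixed <- as.matrix(data_press[, cont, drop = FALSE]) - obs
  press_fixed[is.na(press_fixed)] <- 0
  shift <- stats::setNames(numeric(length(cont)), cont)
  rows <- vector("list", nrow(data) - 1L)
  for (t in 2:nrow(data)) {
    shift[targets] <- press_fixed[t - 1, targets]
    prior_b <- prior_s <- NULL
    if (length(hid)) {
      prior_b <- purrr::map(stats::setNames(hid, hid), function(h) {
        vapply(1:2, function(s) sum(ff_b$filtered[t - 1, S[, h] == s]), numeric(1))
      })
      prior_s <- purrr::map(stats::setNames(hid, hid), function(h) {
        vapply(1:2, function(s) sum(ff_s$filtered[t - 1, S[, h] == s]), numeric(1))
      })
    }
    ev_b <- obs[t - 1, ]
    ev_s <- ev_b + shift
    pr_b <- predict_one_step(fit, ev_b, prior_b)
    pr_s <- predict_one_step(fit, ev_s, prior_s)
    out <- tibble(
      variable = pr_b$variable, year = data$year[t],
      baseline = pr_b$mean, scenario = pr_s$mean
    )
    rows[[t - 1L]] <- out
    diff_t <- pr_s$mean - pr_b$mean
    names(diff_t) <- pr_b$variable
    shift[setdiff(cont, targets)] <- diff_t[setdiff(cont, targets)]
  }
  dplyr::bind_rows(rows)
}

# one-step predictions for every year from the second onward, filtering the
# hidden chains on the supplied evidence
predict_all_years <- function(fit, data, obs) {
  ff <- forward_filter(fit, data)
  S <- ff$states
  hid <- colnames(S)
  rows <- vector("list", nrow(data) - 1L)
  for (t in 2:nrow(data)) {
    prior <- NULL
    if (length(hid)) {
      prior <- purrr::map(stats::setNames(hid, hid), function(h) {
        vapply(1:2, function(s) sum(ff$filtered[t - 1, S[, h] == s]), numeric(1))
      })
    }
    pr <- predict_one_step(fit, obs[t - 1, ], prior)
    pr$year <- data$year[t]
    rows[[t - 1L]] <- pr
  }
  dplyr::bind_rows(rows)
}

#' @export
print.dbn_scenario <- function(x, ...) {
  cat("<dbn_scenario> ", x$spec$label, ", ", x$n_boot, " bootstrap refits\n", sep = "")
  print(x$summary, n = 10)
  invisible(x)
}

#' Mean scenario-minus-baseline difference per variable
#'
#' @param baseline,scenario Tibbles with columns `variable`, `year`,
#'   `mean` (one-step predicted means) over the same variable-year grid.
#' @return Tibble (`variable`, `mean_diff`): the per-variable average over
#'   years of `scenario - baseline`.
#' @export
mean_difference <- function(baseline, scenario) {
  j <- dplyr::full_join(
    dplyr::rename(baseline[, c("variable", "year", "mean")], base = "mean"),
    dplyr::rename(scenario[, c("variable", "year", "mean")], scen = "mean"),
    by = c("variable", "year")
  )
  if (anyNA(j$base) || anyNA(j$scen)) abort("baseline and scenario years are misaligned")
  j %>%
    group_by(.data$variable) %>%
    summarise(mean_diff = mean(.data$scen - .data$base), .groups = "drop")
}

#' Variables reachable from the SST nodes
#'
#' Directed closure of the structure from the given source variables; in a
#' purely linear model only reachable variables can respond to an SST
#' press.
#'
#' @param structure A [dbn_structure()].
#' @param sources Character vector of source node names.
#' @return Character vector of reachable node names (sources excluded).
#' @export
sst_reachable <- function(structure, sources) {
  g <- igraph::graph_from_data_frame(
    structure$edges[, c("from", "to")],
    vertices = structure$nodes$name, directed = TRUE
  )
  out <- unique(unlist(purrr::map(sources, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
  setdiff(out, sources)
}
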