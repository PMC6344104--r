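#' Specify a synthetic ecosystem-like generating model
#'
#' Describes a ground-truth system shaped like an annual ecosystem
#' monitoring table: a small set
#' of climate driver series switched between two regimes by a persistent
#' binary hidden chain, autoregressive physiochemical drivers, and biota
#' series driven by a planted sparse set of lag-1 parents. Defaults give
#' 32 years of 4 climate, 6 physiochemical and 18 biota series.
#'
#' @param n_years Years to simulate (>= 10).
#' @param n_climate,n_physio,n_biota Series counts per class (each >= 1).
#' @param hidden_persistence Diagonal of the hidden transition matrix, in
#'   (0.5, 1): the probability of staying in the current regime.
#' @param regime_shift Difference between the climate-series means of the
#'   two hidden regimes (standardized units).
#' @param weight_range Length-2 positive interval for planted lag-1 weight
#'   magnitudes (biota weights get random signs).
#' @param noise_sd Observation noise standard deviation.
#' @param max_parents Maximum planted parents per biota node (<= 3).
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_years = 32L, n_climate = 4L, n_physio = 6L, n_biota = 18L,
                           hidden_persistence = 0.9, regime_shift = 1.5,
                           weight_range = c(0.4, 0.8), noise_sd = 0.5,
                           max_parents = 3L, seed = 1L) {
  if (n_years < 10) abort("n_years must be >= 10")
  if (min(n_climate, n_physio, n_biota) < 1) abort("all series counts must be >= 1")
  if (hidden_persistence <= 0.5 || hidden_persistence >= 1) {
    abort("hidden_persistence must be in (0.5, 1)")
  }
  if (max_parents < 1 || max_parents > 3) abort("max_parents must be in 1..3")
  if (length(weight_range) != 2 || any(weight_range <= 0) || diff(weight_range) < 0) {
    abort("weight_range must be a positive nondecreasing interval")
  }
  structure(
    list(
      n_years = as.integer(n_years), n_climate = as.integer(n_climate),
      n_physio = as.integer(n_physio), n_biota = as.integer(n_biota),
      hidden_persistence = hidden_persistence, regime_shift = regime_shift,
      weight_range = weight_range, noise_sd = noise_sd,
      max_parents = as.integer(max_parents), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Draw a planted structure with true parameters
#'
#' Builds the generating network: a binary hidden regime chain influencing
#' every climate series within the year (regime means +-`regime_shift`/2),
#' autoregressive self-links on climate and physiochemical series, and for
#' each biota series 1 to `max_parents` lag-1 parents drawn from the
#' climate, physiochemical and earlier biota series (never biota to
#' climate; the projected graph stays acyclic). Reproducible given the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `structure` (a [dbn_structure()]), `model` (a
#'   `dbn_fit` holding the true parameters), `descriptors` (a
#'   [variable_descriptors()] tibble treating climate series 2..4 as SST
#'   regions), and `spec`.
#' @export
generate_structure <- function(spec) {
  with_local_seed(spec$seed, {
    clim <- paste0("clim", seq_len(spec$n_climate))
    phys <- paste0("phys", seq_len(spec$n_physio))
    biota <- paste0("biota", seq_len(spec$n_biota))
    hidden <- "H_regime"
    drivers <- c(clim, phys)
    nodes <- tibble(
      name = c(hidden, clim, phys, biota),
      kind = c("hidden", rep("continuous", length(c(clim, phys, biota))))
    )
    edges <- dplyr::bind_rows(
      tibble(from = hidden, to = hidden, lag = 1L),
      tibble(from = hidden, to = clim, lag = 0L),
      tibble(from = drivers, to = drivers, lag = 1L)
    )
    draw_weight <- function(n, signed = TRUE) {
      w <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
      if (signed) w <- w * sample(c(-1, 1), n, replace = TRUE)
      w
    }
    params <- list()
    for (v in clim) {
      params[[v]] <- clg_params(
        mu = c(-spec$regime_shift / 2, spec$regime_shift / 2),
        w = matrix(draw_weight(1, signed = FALSE), 2, 1),
        sigma2 = rep(spec$noise_sd^2, 2)
      )
    }
    for (v in phys) {
      params[[v]] <- clg_params(
        mu = 0,
        w = matrix(draw_weight(1, signed = FALSE), 1, 1),
        sigma2 = spec$noise_sd^2
      )
    }
    for (i in seq_along(biota)) {
      v <- biota[i]
      pool <- c(drivers, biota[seq_len(i - 1L)]) # earlier biota only: acyclic
      k <- sample.int(spec$max_parents, 1)
      parents <- sample(pool, min(k, length(pool)))
      edges <- dplyr::bind_rows(edges, tibble(from = parents, to = v, lag = 1L))
      params[[v]] <- clg_params(
        mu = 0,
        w = matrix(draw_weight(length(parents)), 1, length(parents)),
        sigma2 = spec$noise_sd^2
      )
    }
    structure_ <- dbn_structure(nodes, edges)
    # weight columns must follow the structure's edge order per node
    for (v in c(clim, phys, biota)) {
      fam <- node_family(structure_, v)
      colnames(params[[v]]$w) <- fam$cparents$name
    }
    chains <- list(H_regime = list(
      pi = c(0.5, 0.5),
      A = matrix(c(
        spec$hidden_persistence, 1 - spec$hidden_persistence,
        1 - spec$hidden_persistence, spec$hidden_persistence
      ), 2, 2, byrow = TRUE)
    ))
    model <- dbn_model(structure_, params, chains)
    descriptors <- variable_descriptors(
      name = c(clim, phys, biota),
      category = c(
        rep("climate", length(clim)), rep("physiochemical", length(phys)),
        rep("population_estimate", length(biota))
      ),
      sst_region = c(FALSE, rep(TRUE, length(clim) - 1L),
                     rep(FALSE, length(phys) + length(biota))),
      predicted = c(rep(FALSE, length(clim) + length(phys)), rep(TRUE, length(biota)))
    )
    list(structure = structure_, model = model, descriptors = descriptors, spec = spec)
  })
}

#' Simulate a standardized table from a planted model
#'
#' Draws a series from the true model by ancestral sampling, standardizes
#' it column-wise (as the pipeline requires), and returns the table
#' together with the hidden regime path and the ground truth.
#'
#' @param truth Result of [generate_structure()].
#' @param seed Seed for the draw; defaults to the spec's seed plus one so
#'   structure and noise are independently reproducible.
#' @return List with `data` (standardized tibble carrying standardization
#'   params), `raw` (unstandardized tibble), `hidden` (tibble `year`,
#'   `hidden`, `state`), and `truth`.
#' @export
simulate_table <- function(truth, seed = truth$spec$seed + 1L) {
  sim <- simulate_dbn(truth$model, truth$spec$n_years, seed = seed)
  std <- standardize_table(sim$data)
  list(data = std, raw = sim$data, hidden = sim$hidden, truth = truth)
}

# planted lag-1 cross edges (excluding self-links), used by recovery tests
planted_cross_edges <- function(truth) {
  e <- truth$structure$edges
  kind <- stats::setNames(truth$structure$nodes$kind, truth$structure$nodes$name)
  e[e$lag == 1L & e$from != e$to & kind[e$from] == "continuous", c("from", "to")]
}
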