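#' Run a seeded structure-to-correlation experiment
#'
#' Orchestrates the pipeline generate -> theory (-> spectrum) (-> ring
#' analytics) (-> simulate -> estimate) over several network realisations
#' and aggregates the results with means and standard errors.  Every stage
#' seed is derived deterministically from the master seed, and the returned
#' object carries a provenance block (config, hash, seeds, package version).
#'
#' @param config A nested list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{generator}{`list(model = "random"|"ring"|"hub"|"patchy",
#'       params = list(...))` — `params` are passed to the matching
#'       `make_*_network()` generator (profiles may be given as
#'       `list(half_width=, height=)`).}
#'     \item{n_seeds}{Number of network realisations (default 1).}
#'     \item{theory}{`list(y0 = 1, max_order = 8)` motif/correlation controls.}
#'     \item{spectrum}{`TRUE` to attach eigenvalue summaries (default `FALSE`).}
#'     \item{simulate}{`NULL`, or `list(bin_s = 0.5, <sim_config fields>)` to
#'       also simulate each realisation and estimate rates/counts.}
#'   }
#' @param seed Master seed; expands to per-stage child seeds by a fixed
#'   counter scheme (`(seed + 10007 * stage + 101 * rep) mod 2^31 - 1`, with
#'   stages numbered in pipeline order), so runs are reproducible stage by
#'   stage.
#' @return An object of class `hawkes_experiment`: list with `summary`
#'   (per-realisation tibble), `contributions` (per-order averages per
#'   realisation), `aggregate` and `contributions_aggregate` (means and
#'   SEs), `sim` (per-neuron predicted vs estimated rates, or `NULL`), and
#'   `provenance`.
#' @export
run_experiment <- function(config, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$generator))
  gen <- config$generator
  n_seeds <- config$n_seeds %||% 1L
  theory_cfg <- modifyList(list(y0 = 1, max_order = 8), config$theory %||% list())
  sim_cfg <- config$simulate

  make_net <- function(rep) {
    params <- gen$params
    for (nm in intersect(names(params), c("profile_exc", "profile_inh"))) {
      if (!inherits(params[[nm]], "ring_profile")) {
        params[[nm]] <- ring_profile(params[[nm]]$half_width, params[[nm]]$height)
      }
    }
    fn <- switch(gen$model,
      random = make_random_network,
      ring = make_ring_network,
      hub = make_hub_network,
      patchy = make_patchy_network,
      abort(sprintf("Unknown generator model '%s'.", gen$model),
        class = "hawkesnet_parameter_error"
      )
    )
    do.call(fn, c(params, list(seed = child_seed(seed, 1L, rep))))
  }

  run_one <- function(rep) {
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(
          sprintf("Stage '%s' failed for realisation %d: %s", name, rep, conditionMessage(e)),
          class = "hawkesnet_stage_error", parent = e
        )
      })
    }
    net <- stage("generate", make_net(rep))
    rates <- stage("theory", equilibrium_rates(net, y0 = theory_cfg$y0))
    c_bar <- stage("theory", average_correlation(net, y0 = theory_cfg$y0))
    contribs <- stage("theory", {
      average_contributions(
        motif_terms(net, y0 = theory_cfg$y0, max_order = theory_cfg$max_order)
      )
    })
    row <- tibble(
      rep = rep, seed = child_seed(seed, 1L, rep),
      n_nodes = net$n, n_edges = length(net$G@x),
      mean_rate = mean(rates), avg_correlation = c_bar
    )
    if (isTRUE(config$spectrum)) {
      sp <- stage("spectrum", spectrum_report(net))
      row$spectral_radius <- sp$spectral_radius
      row$max_real_part <- sp$max_real_part
      row$predicted_bulk_radius <- sp$predicted_bulk_radius
    }
    sim_tbl <- NULL
    if (!is.null(sim_cfg)) {
      bin_s <- sim_cfg$bin_s %||% 0.5
      cfg_fields <- sim_cfg[setdiff(names(sim_cfg), "bin_s")]
      cfg <- stage("simulate", do.call(sim_config, cfg_fields))
      sp_trains <- stage("simulate", simulate_hawkes(net, cfg, seed = child_seed(seed, 4L, rep)))
      est <- stage("estimate", estimate_counts(sp_trains, bin_s = bin_s))
      sim_tbl <- tibble(
        rep = rep, neuron = seq_len(net$n),
        rate_pred = rates * cfg$y0_rate / theory_cfg$y0,
        rate_hat = est$rates_hat, cv = est$cv
      )
      row$mean_rate_hat <- mean(est$rates_hat)
      row$mean_cv <- mean(est$cv, na.rm = TRUE)
      row$pop_var_hat <- est$pop_var_hat
    }
    list(summary = row, contributions = dplyr::mutate(contribs, rep = rep), sim = sim_tbl)
  }

  runs <- lapply(seq_len(n_seeds), run_one)
  summary <- purrr::map_dfr(runs, "summary")
  contributions <- purrr::map_dfr(runs, "contributions")
  num_cols <- names(summary)[vapply(summary, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("rep", "seed"))
  aggregate <- summary |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(num_cols),
      list(mean = mean, se = ~ sd(.x) / sqrt(dplyr::n()))
    ))
  contributions_aggregate <- contributions |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(
      dplyr::across(
        c("chain", "common_input", "total"),
        list(mean = mean, se = ~ sd(.x) / sqrt(dplyr::n()))
      ),
      .groups = "drop"
    )
  structure(
    list(
      summary = summary,
      contributions = contributions,
      aggregate = aggregate,
      contributions_aggregate = contributions_aggregate,
      sim = if (is.null(sim_cfg)) NULL else purrr::map_dfr(runs, "sim"),
      provenance = list(
        config = config, master_seed = seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("hawkesnet")),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "hawkes_experiment"
  )
}

#' @export
print.hawkes_experiment <- function(x, ...) {
  cat(sprintf(
    "<hawkes_experiment> %s model, %d realisation(s), master seed %s (config %s)\n",
    x$provenance$config$generator$model, nrow(x$summary),
    x$provenance$master_seed, substr(x$provenance$config_hash, 1, 8)
  ))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_experiment Per-realisation summary tibble.
#' @param x A `hawkes_experiment`.
#' @param ... Unused.
#' @export
tidy.hawkes_experiment <- function(x, ...) x$summary

#' @describeIn run_experiment One-row aggregate tibble (means and SEs).
#' @export
glance.hawkes_experiment <- function(x, ...) x$aggregate
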