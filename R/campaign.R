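#' Campaign configuration
#'
#' Everything a sequential formulation-optimization campaign needs: the
#' design space and constraint windows, the number of uniform initialization
#' points, the acquisition settings, surrogate fitting controls and the seed
#' of the campaign random number stream.
#'
#' @param space A [design_space()].
#' @param n_init Uniformly sampled (feasibility-rejected) initialization
#'   points.
#' @param acquisition An [acquisition_config()].
#' @param objectives Objective column names, all maximized.
#' @param restarts Surrogate MLE restarts.
#' @param seed Campaign seed.
#' @param init_retry_cap Rejection cap while sampling initialization points.
#' @return A list of class `formubo_campaign_config`.
#' @export
campaign_config <- function(space = design_space(), n_init = 13,
                            acquisition = acquisition_config(),
                            objectives = c("tm_C", "kd_mL_per_g", "rm_pct"),
                            restarts = 10, seed = 1,
                            init_retry_cap = 1000) {
  structure(list(space = space, n_init = n_init, acquisition = acquisition,
                 objectives = objectives, restarts = restarts, seed = seed,
                 init_retry_cap = init_retry_cap),
            class = "formubo_campaign_config")
}

#' Initialize a campaign
#'
#' Draws uniform points on the unit design cube, rejection-samples them to
#' feasibility until `n_init` are accepted, decodes them into formulations
#' and (when a measurement source is supplied) measures them. The accepted
#' points form iteration 0 with route label `"init"`. Seeds the campaign
#' random number stream.
#'
#' @param config A [campaign_config()].
#' @param lab Optional measurement source (e.g. [virtual_lab()]); when
#'   `NULL` the initialization formulations are recorded unmeasured, to be
#'   completed via [record_observations()].
#' @return A `formubo_campaign` state.
#' @export
initialize_campaign <- function(config = campaign_config(), lab = NULL) {
  set.seed(config$seed)
  feas <- unit_cube_feasible(config$space)
  pts <- matrix(NA_real_, 0, 6)
  drawn <- 0L
  while (nrow(pts) < config$n_init) {
    U <- matrix(runif(config$n_init * 6), config$n_init, 6)
    ok <- feas(U)
    pts <- rbind(pts, U[ok, , drop = FALSE])
    drawn <- drawn + config$n_init
    if (drawn > config$init_retry_cap * config$n_init) {
      abort("initialization rejection cap exceeded: constraint window too tight",
            class = "formubo_config_error")
    }
  }
  pts <- pts[seq_len(config$n_init), , drop = FALSE]
  forms <- decode_points(pts, config$space)
  if (!is.null(lab)) forms <- lab(forms)
  ledger <- dplyr::bind_cols(
    tibble::tibble(iteration = 0L, route = "init"), forms
  )
  state <- structure(list(config = config, ledger = ledger, models = NULL),
                     class = "formubo_campaign")
  state$rng <- .Random.seed
  state
}

# Fit the three objective surrogates on the measured ledger rows.
fit_surrogates <- function(state) {
  ledger <- measured_rows(state$ledger, state$config$objectives)
  X <- as.matrix(ledger[u_cols(ledger)])
  models <- lapply(state$config$objectives, function(obj) {
    fit_objective_model(X, ledger[[obj]], objective = obj,
                        restarts = state$config$restarts)
  })
  names(models) <- state$config$objectives
  models
}

measured_rows <- function(ledger, objectives) {
  ok <- rowSums(is.na(as.matrix(ledger[intersect(objectives,
                                                 names(ledger))]))) == 0
  if (!all(objectives %in% names(ledger)) || !any(ok)) {
    abort("ledger has no measured observations",
          class = "formubo_config_error")
  }
  ledger[ok, ]
}

#' Run one campaign iteration
#'
#' Fits the three Gaussian-process surrogates on the current ledger,
#' proposes a Kriging-believer batch via the exploit/explore acquisition
#' rule, obtains measurements from the lab and appends the new observations
#' with an incremented iteration index. The campaign RNG stream is restored
#' from, and saved back to, the state, so a campaign is reproducible
#' end to end from its seed.
#'
#' @param state A `formubo_campaign`.
#' @param lab Measurement source: function mapping a decoded formulation
#'   tibble to the same tibble with objective columns appended.
#' @return The updated `formubo_campaign`.
#' @export
run_iteration <- function(state, lab) {
  if (nrow(measured_rows(state$ledger, state$config$objectives)) < 2L) {
    abort("need at least 2 measured observations",
          class = "formubo_config_error")
  }
  assign(".Random.seed", state$rng, envir = globalenv())
  models <- fit_surrogates(state)
  history <- measured_rows(state$ledger, state$config$objectives)
  batch <- propose_batch(models, history, config = state$config$acquisition,
                         feasibility = unit_cube_feasible(state$config$space))
  forms <- decode_points(as.matrix(batch[u_cols(batch)]), state$config$space)
  forms <- lab(forms)
  new_rows <- dplyr::bind_cols(
    tibble::tibble(iteration = max(state$ledger$iteration) + 1L,
                   route = batch$route),
    forms
  )
  state$ledger <- dplyr::bind_rows(state$ledger, new_rows)
  state$models <- models
  state$rng <- .Random.seed
  state
}

#' Run a full closed-loop campaign on a measurement source
#'
#' Initialization followed by `iterations` batched iterations. With the
#' defaults (13 initialization points, 4 iterations of 5 suggestions) the
#' ledger holds 33 observations.
#'
#' @param config A [campaign_config()].
#' @param lab Measurement source, e.g. [virtual_lab()].
#' @param iterations Number of batched iterations after initialization.
#' @return A `formubo_campaign`.
#' @examples
#' \donttest{
#' cfg <- campaign_config(acquisition = acquisition_config(pop = 20,
#'   gens = 10), restarts = 2, seed = 7)
#' st <- simulate_campaign(cfg, virtual_lab(), iterations = 1)
#' nrow(st$ledger)
#' }
#' @export
simulate_campaign <- function(config = campaign_config(),
                              lab = virtual_lab(), iterations = 4) {
  state <- initialize_campaign(config, lab)
  for (i in seq_len(iterations)) state <- run_iteration(state, lab)
  state
}

#' @export
print.formubo_campaign <- function(x, ...) {
  led <- x$ledger
  cat("<formubo campaign>\n")
  cat(sprintf("  %d observations over %d iteration(s) (+init)\n",
              nrow(led), max(led$iteration)))
  if (all(x$config$objectives %in% names(led))) {
    for (obj in x$config$objectives) {
      cat(sprintf("  best %s: %.3g\n", obj, max(led[[obj]], na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @method tidy formubo_campaign
#' @export
tidy.formubo_campaign <- function(x, ...) {
  x$ledger
}

#' @method glance formubo_campaign
#' @export
glance.formubo_campaign <- function(x, ...) {
  led <- measured_rows(x$ledger, x$config$objectives)
  hv <- hypervolume_trace(x)
  tibble::tibble(
    n_obs = nrow(led),
    iterations = max(led$iteration),
    best_tm_C = max(led$tm_C),
    best_kd_mL_per_g = max(led$kd_mL_per_g),
    best_rm_pct = max(led$rm_pct),
    hypervolume = hv$hypervolume[nrow(hv)]
  )
}

# Standardized objective matrix + reference point shared by the
# hypervolume reports: objectives standardized over the full measured
# ledger, reference = per-objective minimum minus 0.5.
standardized_objectives <- function(ledger, objectives) {
  Y <- as.matrix(ledger[objectives])
  mu <- colMeans(Y)
  sdv <- apply(Y, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Ys <- sweep(sweep(Y, 2L, mu), 2L, sdv, `/`)
  list(Y = Ys, ref = apply(Ys, 2L, min) - 0.5)
}

#' Hypervolume convergence trace
#'
#' The dominated hypervolume of all observations up to and including each
#' iteration, computed on objectives standardized over the full ledger with
#' a fixed reference point (the per-objective standardized minimum minus
#' 0.5). With the reference fixed across the trace, the trace is
#' non-decreasing by construction.
#'
#' @param state A `formubo_campaign` (or a ledger tibble).
#' @return A tibble with columns `iteration`, `n_observations`,
#'   `hypervolume`.
#' @export
hypervolume_trace <- function(state) {
  ledger <- if (inherits(state, "formubo_campaign")) state$ledger else state
  objectives <- if (inherits(state, "formubo_campaign")) {
    state$config$objectives
  } else {
    c("tm_C", "kd_mL_per_g", "rm_pct")
  }
  ledger <- measured_rows(ledger, objectives)
  so <- standardized_objectives(ledger, objectives)
  its <- sort(unique(ledger$iteration))
  purrr::map_dfr(its, function(t) {
    i <- ledger$iteration <= t
    tibble::tibble(iteration = t, n_observations = sum(i),
                   hypervolume = hypervolume(so$Y[i, , drop = FALSE],
                                             so$ref))
  })
}

#' Per-formulation hypervolume
#'
#' The individual dominated box of every observation against the shared
#' standardized reference point, a per-formulation quality score that lets
#' single formulations be compared across iterations.
#'
#' @param state A `formubo_campaign` (or a ledger tibble).
#' @return The measured ledger with a `point_hv` column appended.
#' @export
per_formulation_hypervolume <- function(state) {
  ledger <- if (inherits(state, "formubo_campaign")) state$ledger else state
  objectives <- if (inherits(state, "formubo_campaign")) {
    state$config$objectives
  } else {
    c("tm_C", "kd_mL_per_g", "rm_pct")
  }
  ledger <- measured_rows(ledger, objectives)
  so <- standardized_objectives(ledger, objectives)
  ledger$point_hv <- vapply(seq_len(nrow(ledger)), function(i) {
    point_hypervolume(so$Y[i, ], so$ref)
  }, numeric(1))
  ledger
}

#' Out-of-sample prediction error trace
#'
#' How well the surrogates predicted each iteration before it was measured:
#' for every iteration `t >= 1`, surrogates are fitted on the observations
#' of iterations `< t` only and the mean absolute error of their posterior
#' means against iteration `t`'s measured objectives is reported in raw
#' units. Surrogate refits are seeded from the campaign seed so the trace
#' is reproducible; the global RNG stream is left untouched.
#'
#' @param state A `formubo_campaign`.
#' @return A tibble with columns `iteration`, `objective`, `mae`.
#' @export
prediction_mae_trace <- function(state) {
  ledger <- measured_rows(state$ledger, state$config$objectives)
  its <- sort(unique(ledger$iteration))
  its <- its[its >= 1]
  if (length(its) == 0L) {
    abort("need at least one post-initialization iteration",
          class = "formubo_config_error")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  purrr::map_dfr(its, function(t) {
    train <- ledger[ledger$iteration < t, ]
    test <- ledger[ledger$iteration == t, ]
    X <- as.matrix(train[u_cols(train)])
    Xt <- as.matrix(test[u_cols(test)])
    set.seed(state$config$seed + t)
    purrr::map_dfr(state$config$objectives, function(obj) {
      m <- fit_objective_model(X, train[[obj]], objective = obj,
                               restarts = state$config$restarts)
      tibble::tibble(iteration = t, objective = obj,
                     mae = mean(abs(predict(m, Xt)$.mean - test[[obj]])))
    })
  })
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Returns `NA` with a warning when either variable has zero rank variance.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Rank correlation in `[-1, 1]`, or `NA`.
#' @examples
#' spearman_rank(1:5, c(2, 4, 6, 8, 10)) # 1
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3",
          class = "formubo_config_error")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Excipient-objective Spearman correlation table
#'
#' Rank correlations between every design variable and every measured
#' objective over the campaign ledger, the standard screen for which
#' excipients drive which stability readout.
#'
#' @param state A `formubo_campaign` (or a measured ledger tibble).
#' @param variables Design-variable columns to correlate.
#' @return A tibble with columns `variable`, `objective`, `rho`.
#' @export
spearman_table <- function(state,
                           variables = c("sorbitol_mM", "arginine_mM", "pH",
                                         "f_asp", "f_glu", "f_hcl",
                                         "f_acetic")) {
  ledger <- if (inherits(state, "formubo_campaign")) state$ledger else state
  objectives <- if (inherits(state, "formubo_campaign")) {
    state$config$objectives
  } else {
    c("tm_C", "kd_mL_per_g", "rm_pct")
  }
  ledger <- measured_rows(ledger, objectives)
  tidyr::expand_grid(variable = variables, objective = objectives) |>
    dplyr::mutate(rho = purrr::map2_dbl(.data$variable, .data$objective,
                                        function(v, o) {
                                          spearman_rank(ledger[[v]],
                                                        ledger[[o]])
                                        }))
}

#' Write / read the campaign ledger CSV
#'
#' The ledger is the authoritative record of a campaign: one row per
#' observation with iteration index, route label, unit-cube coordinates,
#' the decoded formulation columns and the measured objectives.
#'
#' @param state A `formubo_campaign` (or ledger tibble).
#' @param path CSV path.
#' @return `write_ledger` the path, invisibly; `read_ledger` a ledger
#'   tibble.
#' @export
write_ledger <- function(state, path) {
  ledger <- if (inherits(state, "formubo_campaign")) state$ledger else state
  ledger <- ledger[setdiff(names(ledger), c("raw", "violations"))]
  readr::write_csv(ledger, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(route = "c", reason = "c"))
}

#' Rebuild a campaign state from a ledger
#'
#' @param ledger A ledger tibble (e.g. from [read_ledger()]).
#' @param config A [campaign_config()].
#' @return A `formubo_campaign` whose RNG stream is seeded from the config
#'   seed plus the number of observations, so resumed campaigns do not
#'   replay the original stream.
#' @export
campaign_from_ledger <- function(ledger, config = campaign_config()) {
  state <- structure(list(config = config,
                          ledger = tibble::as_tibble(ledger),
                          models = NULL),
                     class = "formubo_campaign")
  set.seed(config$seed + nrow(ledger))
  state$rng <- .Random.seed
  state
}

#' Record measured observations into a campaign
#'
#' Completes pending (unmeasured) ledger rows with measured objective
#' values, matching rows by their unit-cube coordinates, or appends new
#' measured rows when no pending match exists. This is how wet-lab results
#' enter a campaign driven through suggestion files.
#'
#' @param state A `formubo_campaign`.
#' @param measurements Tibble with the unit-cube columns `u1...u6` and the
#'   objective columns; unmatched rows must also carry the decoded
#'   formulation columns.
#' @param iteration Iteration index for appended rows (default: current
#'   maximum + 1).
#' @param route Route label for appended rows.
#' @return The updated `formubo_campaign`.
#' @export
record_observations <- function(state, measurements, iteration = NULL,
                                route = "manual") {
  objectives <- state$config$objectives
  led <- state$ledger
  for (obj in objectives) {
    if (is.null(led[[obj]])) led[[obj]] <- NA_real_
  }
  uc <- u_cols(led)
  U <- as.matrix(led[uc])
  appended <- NULL
  for (i in seq_len(nrow(measurements))) {
    x <- as.numeric(measurements[i, uc])
    d <- sqrt(rowSums(sweep(U, 2L, x)^2))
    j <- which(d < 1e-9 & is.na(led[[objectives[1]]]))
    if (length(j) > 0L) {
      for (obj in objectives) led[j[1], obj] <- measurements[i, obj]
    } else {
      row <- dplyr::bind_cols(
        tibble::tibble(
          iteration = iteration %||% (max(led$iteration) + 1L),
          route = if ("route" %in% names(measurements)) {
            measurements$route[i]
          } else {
            route
          }
        ),
        measurements[i, setdiff(names(measurements), c("iteration", "route"))]
      )
      appended <- dplyr::bind_rows(appended, row)
    }
  }
  state$ledger <- dplyr::bind_rows(led, appended)
  state
}
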