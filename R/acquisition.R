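#' Acquisition configuration
#'
#' Settings of the exploit/explore acquisition rule: the probability of the
#' exploitation route, the greedy (Kriging-believer) batch size, the number
#' of random restarts of the exploration search, and the weight that blends
#' objective-space and variable-space distances in the exploitation pick.
#'
#' @param p_exploit Probability of the exploitation route per suggestion.
#' @param batch_size Suggestions per iteration.
#' @param explore_starts Random starting points of the exploration search.
#' @param distance_weight Weight `w` on the objective-space distance in the
#'   exploitation score `w * d_obj + (1 - w) * d_var`.
#' @param retry_cap Rejection-sampling cap for constrained moves.
#' @param pop,gens NSGA-II generation size and number of generations used by
#'   the exploitation route.
#' @param explore_maxit Simplex-search iterations per exploration start.
#' @return A list of class `formubo_acquisition`.
#' @export
acquisition_config <- function(p_exploit = 0.75, batch_size = 5,
                               explore_starts = 20, distance_weight = 0.5,
                               retry_cap = 1000, pop = 100, gens = 100,
                               explore_maxit = 200) {
  stopifnot(p_exploit >= 0, p_exploit <= 1, batch_size >= 1,
            explore_starts >= 1, distance_weight >= 0, distance_weight <= 1)
  structure(list(p_exploit = p_exploit, batch_size = batch_size,
                 explore_starts = explore_starts,
                 distance_weight = distance_weight, retry_cap = retry_cap,
                 pop = pop, gens = gens, explore_maxit = explore_maxit),
            class = "formubo_acquisition")
}

#' Draw acquisition routes
#'
#' Bernoulli draws from the current random number stream: each suggestion
#' independently takes the exploitation route with probability `p_exploit`,
#' otherwise the exploration route.
#'
#' @param n Number of draws.
#' @param p_exploit Exploitation probability.
#' @return Character vector of `"exploit"` / `"explore"` labels.
#' @examples
#' set.seed(1)
#' table(choose_route(1000))
#' @export
choose_route <- function(n = 1, p_exploit = 0.75) {
  ifelse(runif(n) < p_exploit, "exploit", "explore")
}

# Columns of a tibble that hold unit-cube coordinates.
u_cols <- function(x) grep("^u[0-9]+$", names(x), value = TRUE)

#' Exploitation pick from a Pareto front
#'
#' Scores every candidate of the surrogate Pareto front by its minimum
#' Euclidean distance to the existing observations, measured both in the
#' normalized variable space and in the standardized objective space
#' (candidates use predicted means, observations their measured values,
#' both standardized by the observation mean/sd). The two distances are
#' each divided by their maximum over the front and combined linearly with
#' weight `w`; the candidate with the maximum combined score is returned,
#' ties broken by the lowest candidate index.
#'
#' @param front Tibble from [nsga2_front()]: unit-cube columns plus one
#'   predicted column per objective.
#' @param history Tibble of observations with the same unit-cube columns and
#'   objective columns.
#' @param w Weight on the objective-space distance.
#' @param objectives Objective column names; defaults to the non-coordinate
#'   columns of `front`.
#' @return The selected one-row tibble with scoring columns `.d_var`,
#'   `.d_obj`, `.score`; the selected index is in attribute `"index"`.
#' @export
exploit_candidate <- function(front, history, w = 0.5, objectives = NULL) {
  if (nrow(front) == 0L) {
    abort("empty Pareto front: fall back to exploration",
          class = "formubo_search_error")
  }
  if (nrow(history) == 0L) {
    abort("exploitation needs at least one observation",
          class = "formubo_config_error")
  }
  uc <- u_cols(front)
  objectives <- objectives %||% setdiff(names(front), uc)
  Uf <- as.matrix(front[uc])
  Uh <- as.matrix(history[uc])
  Yh <- as.matrix(history[objectives])
  mu <- colMeans(Yh)
  sdv <- apply(Yh, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  std <- function(Y) sweep(sweep(Y, 2L, mu), 2L, sdv, `/`)
  Yf <- std(as.matrix(front[objectives]))
  Yh <- std(Yh)
  min_dist <- function(A, B) {
    # rows of A vs rows of B
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(apply(d2, 1L, min), 0))
  }
  d_var <- min_dist(Uf, Uh)
  d_obj <- min_dist(Yf, Yh)
  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  score <- w * norm1(d_obj) + (1 - w) * norm1(d_var)
  i <- which.max(score)  # which.max takes the first (lowest-index) maximum
  out <- front[i, ]
  out$.d_var <- d_var[i]
  out$.d_obj <- d_obj[i]
  out$.score <- score[i]
  attr(out, "index") <- i
  out
}

#' Steinerberger proximity sum
#'
#' The low-discrepancy energy functional
#' `S(x) = sum_p prod_d (1 - log(2 sin(pi |x_d - p_d|)))` over the explored
#' points `p`. Larger values mean `x` is closer to explored territory;
#' exploration proposes points by minimizing it. The kernel is singular
#' where any coordinate coincides with (or is exactly one away from) an
#' explored point's coordinate; such evaluations return the `sentinel`.
#'
#' @param x A point in the unit cube (vector) or a matrix of points (rows).
#' @param history_points Matrix of explored unit-cube points (rows).
#' @param sentinel Value returned at kernel singularities.
#' @return Numeric vector of proximity scores.
#' @examples
#' steinerberger_sum(0.5, matrix(c(0.25, 0.75), ncol = 1))
#' @export
steinerberger_sum <- function(x, history_points, sentinel = 1e18) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  P <- as.matrix(history_points)
  vapply(seq_len(nrow(X)), function(i) {
    delta <- abs(sweep(P, 2L, X[i, ]))           # n_hist x d
    f <- 1 - log(2 * sin(pi * delta))
    s <- sum(apply(f, 1L, prod))
    if (!is.finite(s) || s > sentinel) sentinel else s
  }, numeric(1))
}

#' Exploration pick by Steinerberger-sum minimization
#'
#' Runs a derivative-free bounded simplex (Nelder-Mead) search of the
#' Steinerberger sum from several random feasible starting points; iterates
#' outside the cube or violating the constraints receive the sentinel score,
#' which is equivalent to rejection. The feasible minimizer with the lowest
#' score over all starts is returned.
#'
#' @param history_points Matrix of explored unit-cube points (rows).
#' @param feasibility Predicate on point matrices, or `NULL`.
#' @param n_starts Number of random starts.
#' @param maxit Simplex iterations per start.
#' @param retry_cap Maximum rejected uniform draws while sampling starts.
#' @param sentinel Singularity/infeasibility score.
#' @return A unit-cube point (numeric vector).
#' @export
explore_candidate <- function(history_points, feasibility = NULL,
                              n_starts = 20, maxit = 200, retry_cap = 1000,
                              sentinel = 1e18) {
  P <- as.matrix(history_points)
  d <- ncol(P)
  feas <- feasibility %||% function(U) rep(TRUE, nrow(U))
  starts <- matrix(NA_real_, 0, d)
  draws <- 0L
  while (nrow(starts) < n_starts) {
    U <- matrix(runif(n_starts * d), n_starts, d)
    ok <- feas(U)
    starts <- rbind(starts, U[ok, , drop = FALSE])
    draws <- draws + n_starts
    if (draws > retry_cap * n_starts) {
      abort("no feasible exploration start found",
            class = "formubo_search_error")
    }
  }
  starts <- starts[seq_len(n_starts), , drop = FALSE]

  objective <- function(x) {
    if (any(x < 0) || any(x > 1)) return(sentinel)
    if (!feas(matrix(x, nrow = 1L))) return(sentinel)
    steinerberger_sum(x, P, sentinel)
  }
  best <- NULL
  best_val <- Inf
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      if (d == 1L) {
        optim(starts[i, ], objective, method = "Brent", lower = 0,
              upper = 1, control = list(maxit = maxit))
      } else {
        optim(starts[i, ], objective, method = "Nelder-Mead",
              control = list(maxit = maxit))
      },
      error = function(e) NULL
    )
    cand <- if (is.null(res) || objective(res$par) >= sentinel) {
      starts[i, ]
    } else {
      res$par
    }
    val <- objective(cand)
    if (val < best_val) {
      best <- cand
      best_val <- val
    }
  }
  as.numeric(best)
}

#' Propose a batch of formulations (Kriging believer)
#'
#' Greedy batch acquisition: for each of `batch_size` suggestions, a route
#' is drawn (`exploit` with probability `p_exploit`); the exploitation route
#' evolves the surrogate Pareto front with NSGA-II and applies the combined
#' distance rule, the exploration route minimizes the Steinerberger sum.
#' After every pick each surrogate is augmented with its own posterior mean
#' at the picked point and refitted (the "believer" step), and the pick
#' joins the fantasy history, so later suggestions spread away from earlier
#' ones.
#'
#' @param models Named list of fitted `formubo_gp` surrogates; names are the
#'   objective columns of `history`.
#' @param history Tibble of observations: unit-cube columns `u1...` plus one
#'   column per objective.
#' @param config An [acquisition_config()].
#' @param feasibility Predicate on unit-cube point matrices, or `NULL`.
#' @return A tibble with `batch_size` rows: unit-cube coordinates, `route`,
#'   and fantasy predicted means (one column per objective).
#' @export
propose_batch <- function(models, history, config = acquisition_config(),
                          feasibility = NULL) {
  uc <- u_cols(history)
  d <- length(uc)
  objectives <- names(models)
  fantasy <- history[c(uc, objectives)]
  picks <- vector("list", config$batch_size)

  for (b in seq_len(config$batch_size)) {
    route <- choose_route(1, config$p_exploit)
    x <- if (route == "exploit") {
      front <- nsga2_front(models, feasibility, pop = config$pop,
                           gens = config$gens, retry_cap = config$retry_cap)
      sel <- exploit_candidate(front, fantasy, w = config$distance_weight,
                               objectives = objectives)
      as.numeric(sel[1, uc])
    } else {
      explore_candidate(as.matrix(fantasy[uc]), feasibility,
                        n_starts = config$explore_starts,
                        maxit = config$explore_maxit,
                        retry_cap = config$retry_cap)
    }
    # duplicate guard: perturb once, then error
    dup <- function(x) {
      U <- as.matrix(fantasy[uc])
      any(sqrt(rowSums(sweep(U, 2L, x)^2)) < 1e-9)
    }
    if (dup(x)) {
      x <- pmin(pmax(x + runif(d, -1e-3, 1e-3), 0), 1)
      if (dup(x)) {
        abort("duplicate batch selection after perturbation",
              class = "formubo_search_error")
      }
    }
    xm <- matrix(x, nrow = 1L)
    mu <- vapply(models, function(m) predict(m, xm)$.mean, numeric(1))
    models <- lapply(models, augment_with_fantasy, x = x)
    row <- tibble::as_tibble(as.data.frame(xm))
    names(row) <- uc
    row$route <- route
    for (nm in objectives) row[[nm]] <- mu[[nm]]
    fantasy <- dplyr::bind_rows(fantasy, row[c(uc, objectives)])
    picks[[b]] <- row
  }
  dplyr::bind_rows(picks)
}
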