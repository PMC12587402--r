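# All objectives are maximized throughout this module. Any conversion to a
# minimization convention stays internal to the functions below.

#' Pareto domination between two objective vectors
#'
#' `a` dominates `b` when it is at least as good in every objective and
#' strictly better in at least one (all objectives maximized). A vector
#' never dominates itself.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @examples
#' dominates(c(71, 48, 95), c(70, 40, 90))
#' @export
dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

# Pairwise domination matrix: D[i, j] TRUE iff row i dominates row j.
domination_matrix <- function(Y) {
  n <- nrow(Y)
  geq <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(Y))) {
    geq <- geq & outer(Y[, k], Y[, k], `>=`)
    gt <- gt | outer(Y[, k], Y[, k], `>`)
  }
  geq & gt
}

#' Non-dominated subset of a set of objective vectors
#'
#' @param Y Matrix or data frame, one objective vector per row (all
#'   maximized).
#' @return Integer indices (in original order) of the rows not dominated by
#'   any other row.
#' @examples
#' non_dominated_filter(rbind(c(3, 1), c(1, 3), c(2, 2), c(1, 1)))
#' @export
non_dominated_filter <- function(Y) {
  Y <- as.matrix(as.data.frame(Y))
  if (nrow(Y) == 0L) return(integer(0))
  unname(which(colSums(domination_matrix(Y)) == 0L))
}

# Fast-ish non-dominated sorting: front rank (1 = non-dominated) per row.
nds_ranks <- function(Y) {
  n <- nrow(Y)
  D <- domination_matrix(Y)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    dominated_count <- colSums(D[remaining, remaining, drop = FALSE])
    front <- which(remaining)[dominated_count == 0L]
    rank[front] <- r
    remaining[front] <- FALSE
  }
  rank
}

# NSGA-II crowding distance within one front.
crowding_distance <- function(Y) {
  n <- nrow(Y)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(Y))) {
    o <- order(Y[, k])
    span <- Y[o[n], k] - Y[o[1], k]
    cd[o[c(1, n)]] <- Inf
    if (span > 0) {
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (Y[o[3:n], k] - Y[o[1:(n - 2)], k]) / span
    }
  }
  cd
}

# Simulated binary crossover (SBX) of two parent matrices, row-wise.
sbx_crossover <- function(P1, P2, eta = 15, p_cross = 0.9) {
  n <- nrow(P1); d <- ncol(P1)
  u <- matrix(runif(n * d), n, d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  do_cross <- matrix(runif(n * d) < 0.5, n, d) &
    matrix(runif(n) < p_cross, n, d)
  beta[!do_cross] <- 1
  C <- 0.5 * ((1 + beta) * P1 + (1 - beta) * P2)
  pmin(pmax(C, 0), 1)
}

# Polynomial mutation, per-gene probability p_mut.
poly_mutate <- function(P, eta = 20, p_mut = 1 / ncol(P)) {
  n <- nrow(P); d <- ncol(P)
  u <- matrix(runif(n * d), n, d)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  mutate <- matrix(runif(n * d) < p_mut, n, d)
  P[mutate] <- P[mutate] + delta[mutate]
  pmin(pmax(P, 0), 1)
}

# Predicted objective matrix (raw units) of unit-cube points under a list of
# fitted surrogates.
predict_objectives <- function(models, U) {
  out <- vapply(models, function(m) predict(m, U)$.mean, numeric(nrow(U)))
  matrix(out, nrow = nrow(U), ncol = length(models))
}

#' NSGA-II Pareto front over fitted surrogates
#'
#' Evolves a population on the unit cube, maximizing the posterior means of
#' the fitted surrogates, with the canonical NSGA-II operators (binary
#' tournament on rank and crowding, simulated binary crossover, polynomial
#' mutation). Constraints are handled strictly by rejection: a genetic move
#' that produces an infeasible child is discarded and attempted again, so
#' the population never contains infeasible points.
#'
#' @param models List of fitted `formubo_gp` surrogates (one per objective,
#'   all maximized).
#' @param feasibility Predicate: takes an n x d matrix of unit-cube points,
#'   returns a logical vector. `NULL` means unconstrained.
#' @param pop Generation size.
#' @param gens Number of generations.
#' @param eta_cross,p_cross SBX distribution index and probability.
#' @param eta_mut Polynomial-mutation distribution index; per-gene mutation
#'   probability is `1/d`.
#' @param retry_cap Maximum rejected attempts per offspring slot before a
#'   search error is raised.
#' @return A tibble of mutually non-dominated feasible candidates: unit-cube
#'   coordinates `u1...ud` plus one predicted-mean column per objective,
#'   named after the surrogates.
#' @export
nsga2_front <- function(models, feasibility = NULL, pop = 100, gens = 100,
                        eta_cross = 15, p_cross = 0.9, eta_mut = 20,
                        retry_cap = 1000) {
  d <- ncol(models[[1]]$X)
  feas <- feasibility %||% function(U) rep(TRUE, nrow(U))

  sample_feasible <- function(n) {
    out <- matrix(NA_real_, 0, d)
    attempts <- 0L
    while (nrow(out) < n) {
      U <- matrix(runif(n * d), n, d)
      ok <- feas(U)
      out <- rbind(out, U[ok, , drop = FALSE])
      attempts <- attempts + n
      if (attempts > retry_cap * n) {
        abort("could not sample feasible points: constraint window too tight",
              class = "formubo_search_error")
      }
    }
    out[seq_len(n), , drop = FALSE]
  }

  P <- sample_feasible(pop)
  Y <- predict_objectives(models, P)

  for (g in seq_len(gens)) {
    rank <- nds_ranks(Y)
    cd <- numeric(length(rank))
    for (r in unique(rank)) {
      i <- rank == r
      cd[i] <- crowding_distance(Y[i, , drop = FALSE])
    }
    tournament <- function(n) {
      i <- sample.int(pop, n, replace = TRUE)
      j <- sample.int(pop, n, replace = TRUE)
      better <- rank[i] < rank[j] | (rank[i] == rank[j] & cd[i] >= cd[j])
      ifelse(better, i, j)
    }
    # offspring with discard-and-retry on constraint violation
    need <- seq_len(pop)
    Q <- matrix(NA_real_, pop, d)
    tries <- 0L
    while (length(need) > 0L) {
      m <- length(need)
      C <- sbx_crossover(P[tournament(m), , drop = FALSE],
                         P[tournament(m), , drop = FALSE],
                         eta = eta_cross, p_cross = p_cross)
      C <- poly_mutate(C, eta = eta_mut, p_mut = 1 / d)
      ok <- feas(C)
      Q[need[ok], ] <- C[ok, , drop = FALSE]
      need <- need[!ok]
      tries <- tries + 1L
      if (tries > retry_cap) {
        abort("offspring rejection cap exceeded",
              class = "formubo_search_error")
      }
    }
    YQ <- predict_objectives(models, Q)
    R <- rbind(P, Q)
    YR <- rbind(Y, YQ)
    # environmental selection
    rr <- nds_ranks(YR)
    keep <- integer(0)
    for (r in sort(unique(rr))) {
      front <- which(rr == r)
      if (length(keep) + length(front) <= pop) {
        keep <- c(keep, front)
      } else {
        cdf <- crowding_distance(YR[front, , drop = FALSE])
        keep <- c(keep, front[order(cdf, decreasing = TRUE)][
          seq_len(pop - length(keep))])
        break
      }
    }
    P <- R[keep, , drop = FALSE]
    Y <- YR[keep, , drop = FALSE]
  }

  idx <- non_dominated_filter(Y)
  out <- tibble::as_tibble(as.data.frame(P[idx, , drop = FALSE]))
  names(out) <- paste0("u", seq_len(d))
  preds <- as.data.frame(Y[idx, , drop = FALSE])
  names(preds) <- vapply(models, `[[`, character(1), "objective")
  dplyr::bind_cols(out, tibble::as_tibble(preds))
}

#' Dominated hypervolume of a point set
#'
#' Lebesgue measure of the region dominated by the points and bounded below
#' by the reference point, under the maximization convention. Exact sweep
#' algorithms are used (dimension at most 3); points that do not strictly
#' dominate the reference contribute nothing.
#'
#' @param Y Matrix or data frame of objective vectors (rows), 1 to 3
#'   columns.
#' @param ref Reference point (numeric vector matching `ncol(Y)`).
#' @return Non-negative scalar volume.
#' @examples
#' hypervolume(rbind(c(3, 1), c(1, 3)), ref = c(0, 0)) # 5
#' @export
hypervolume <- function(Y, ref) {
  Y <- as.matrix(as.data.frame(Y))
  ref <- unname(as.numeric(ref))
  d <- length(ref)
  if (ncol(Y) != d) abort("ref dimension mismatch",
                          class = "formubo_config_error")
  if (d > 3L) abort("exact hypervolume implemented for <= 3 objectives",
                    class = "formubo_config_error")
  keep <- rowSums(sweep(Y, 2L, ref, `>`)) == d
  Y <- Y[keep, , drop = FALSE]
  dimnames(Y) <- NULL
  if (nrow(Y) == 0L) return(0)
  if (d == 1L) return(max(Y[, 1]) - ref[1])
  if (d == 2L) return(hv2d(Y, ref))
  # 3D: sweep slices downward in z; each slice contributes the 2D
  # hypervolume of the points whose z reaches it.
  o <- order(Y[, 3], decreasing = TRUE)
  Y <- Y[o, , drop = FALSE]
  z <- c(Y[, 3], ref[3])
  vol <- 0
  for (k in seq_len(nrow(Y))) {
    dz <- z[k] - z[k + 1]
    if (dz > 0) {
      vol <- vol + dz * hv2d(Y[seq_len(k), 1:2, drop = FALSE], ref[1:2])
    }
  }
  vol
}

# 2D hypervolume (maximization), points already strictly above ref.
hv2d <- function(Y, ref) {
  o <- order(Y[, 1], decreasing = TRUE)
  area <- 0
  best_y <- ref[2]
  for (i in o) {
    if (Y[i, 2] > best_y) {
      area <- area + (Y[i, 1] - ref[1]) * (Y[i, 2] - best_y)
      best_y <- Y[i, 2]
    }
  }
  area
}

#' Hypervolume contribution of a single point
#'
#' The volume of the axis-aligned box between the reference point and `y`:
#' `prod(pmax(0, y - ref))`. Used for per-formulation hypervolume reports.
#'
#' @param y Objective vector.
#' @param ref Reference point.
#' @return Non-negative scalar.
#' @examples
#' point_hypervolume(c(2, 3, 4), c(0, 0, 0)) # 24
#' @export
point_hypervolume <- function(y, ref) {
  prod(pmax(0, as.numeric(y) - as.numeric(ref)))
}
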