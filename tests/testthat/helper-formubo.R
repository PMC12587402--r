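# Shared fixtures. Everything is generated in code; the seeded reference
# campaign is expensive (a full closed-loop run) and is memoized so several
# test files can interrogate the same ledger.

.formubo_test_cache <- new.env(parent = emptyenv())

# Reference closed-loop campaign on the virtual lab: 13 initialization
# points + 4 iterations x batch 5 = 33 observations, at reduced NSGA-II
# settings (generation size 40, 40 generations).
reference_campaign <- function() {
  if (is.null(.formubo_test_cache$campaign)) {
    cfg <- campaign_config(
      acquisition = acquisition_config(pop = 40, gens = 40),
      seed = 1
    )
    .formubo_test_cache$campaign <-
      simulate_campaign(cfg, virtual_lab(), iterations = 4)
  }
  .formubo_test_cache$campaign
}

# Two 1D surrogates whose predicted objectives realize the analytic
# trade-off front (maximize x and maximize 1 - x on [0, 1]).
toy_tradeoff_models <- function() {
  if (is.null(.formubo_test_cache$toy_models)) {
    set.seed(99)
    Xg <- matrix(seq(0, 1, length.out = 15), ncol = 1)
    .formubo_test_cache$toy_models <- list(
      fit_objective_model(Xg, Xg[, 1], objective = "obj_x", restarts = 3),
      fit_objective_model(Xg, 1 - Xg[, 1], objective = "obj_1mx",
                          restarts = 3)
    )
  }
  .formubo_test_cache$toy_models
}

# Random feasible unit-cube points for the default design space.
sample_feasible_points <- function(n, space = design_space()) {
  feas <- formubo:::unit_cube_feasible(space)
  out <- matrix(NA_real_, 0, 6)
  while (nrow(out) < n) {
    U <- matrix(runif(10 * n * 6), ncol = 6)
    out <- rbind(out, U[feas(U), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Independent Matern 5/2 covariance, written from the closed form (not via
# package internals), for GP oracles.
oracle_matern52_cov <- function(X1, X2, lengthscales, output_var) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1))) {
    for (j in seq_len(nrow(X2))) {
      r <- sqrt(sum(((X1[i, ] - X2[j, ]) / lengthscales)^2))
      K[i, j] <- output_var * (1 + sqrt(5) * r + 5 * r^2 / 3) *
        exp(-sqrt(5) * r)
    }
  }
  K
}

# Inclusion-exclusion hypervolume oracle for up to 3 points (maximization).
oracle_hv_incl_excl <- function(Y, ref) {
  Y <- as.matrix(Y)
  box <- function(rows) {
    lo <- apply(Y[rows, , drop = FALSE], 2L, min)
    prod(pmax(0, lo - ref))
  }
  n <- nrow(Y)
  single <- sum(vapply(seq_len(n), function(i) box(i), numeric(1)))
  pairs <- if (n >= 2) {
    sum(apply(utils::combn(n, 2), 2L, box))
  } else 0
  triples <- if (n >= 3) {
    sum(apply(utils::combn(n, 3), 2L, box))
  } else 0
  single - pairs + triples
}

# Brute-force non-dominated indices via pairwise dominates().
oracle_non_dominated <- function(Y) {
  Y <- as.matrix(Y)
  keep <- logical(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    keep[i] <- !any(vapply(seq_len(nrow(Y)), function(j) {
      j != i && dominates(Y[j, ], Y[i, ])
    }, logical(1)))
  }
  which(keep)
}

# Measurement source that returns the noise-free ground truth directly;
# used where only campaign bookkeeping (not the assay pipeline) is under
# test, to keep loops over many campaigns fast.
truth_lab <- function() {
  function(formulation) {
    dplyr::bind_cols(formulation, true_surfaces(formulation))
  }
}
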