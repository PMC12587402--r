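test_that("route draws follow the exploit probability", {
  set.seed(51)
  expect_true(all(choose_route(100, p_exploit = 1) == "exploit"))
  expect_true(all(choose_route(100, p_exploit = 0) == "explore"))
  n <- 20000
  frac <- mean(choose_route(n, p_exploit = 0.75) == "exploit")
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("exploitation picks the candidate farthest from observations", {
  # single candidate is returned regardless of score
  front1 <- tibble::tibble(u1 = 0.5, u2 = 0.5, y = 1)
  hist1 <- tibble::tibble(u1 = 0.1, u2 = 0.2, y = 0.4)
  expect_equal(attr(exploit_candidate(front1, hist1), "index"), 1L)

  # a candidate coinciding with an observation scores zero
  front2 <- tibble::tibble(u1 = c(0.1, 0.9), u2 = c(0.2, 0.9),
                           y = c(0.4, 2))
  sel <- exploit_candidate(front2, hist1)
  expect_equal(attr(sel, "index"), 2L)
  expect_equal(exploit_candidate(front2[1, ], hist1)$.score, 0)

  expect_error(exploit_candidate(front1[0, ], hist1),
               class = "formubo_search_error")
})

test_that("exploitation scoring matches an exhaustive oracle", {
  set.seed(52)
  front <- tibble::as_tibble(as.data.frame(matrix(runif(5 * 6), 5)))
  names(front) <- paste0("u", 1:6)
  front$tm <- runif(5, 60, 75)
  front$kd <- runif(5, -20, 50)
  front$rm <- runif(5, 70, 100)
  history <- tibble::as_tibble(as.data.frame(matrix(runif(3 * 6), 3)))
  names(history) <- paste0("u", 1:6)
  history$tm <- runif(3, 60, 75)
  history$kd <- runif(3, -20, 50)
  history$rm <- runif(3, 70, 100)

  # independent exhaustive scoring
  objs <- c("tm", "kd", "rm")
  mu <- colMeans(as.matrix(history[objs]))
  sdv <- apply(as.matrix(history[objs]), 2L, sd)
  dv <- dob <- numeric(5)
  for (i in 1:5) {
    dv[i] <- min(vapply(1:3, function(j) {
      sqrt(sum((as.numeric(front[i, 1:6]) -
                  as.numeric(history[j, 1:6]))^2))
    }, numeric(1)))
    dob[i] <- min(vapply(1:3, function(j) {
      sqrt(sum((((as.numeric(front[i, objs]) - mu) / sdv) -
                  ((as.numeric(history[j, objs]) - mu) / sdv))^2))
    }, numeric(1)))
  }
  score <- 0.5 * dob / max(dob) + 0.5 * dv / max(dv)
  sel <- exploit_candidate(front, history, w = 0.5)
  expect_equal(attr(sel, "index"), which.max(score))
  expect_equal(sel$.score, max(score))
})

test_that("the Steinerberger sum penalizes proximity to explored points", {
  P <- matrix(c(0.25, 0.75), ncol = 1)
  expect_lt(steinerberger_sum(0.5, P), steinerberger_sum(0.26, P))
  # grid confirmation: closer to a history point means a larger sum
  xs <- seq(0.26, 0.49, by = 1e-3)
  s <- steinerberger_sum(matrix(xs, ncol = 1), P)
  expect_true(all(diff(s) < 0))  # decreasing while moving away from 0.25
  # singular exactly at an explored point -> sentinel
  expect_equal(steinerberger_sum(0.25, P), 1e18)
  # reflection symmetry of the kernel
  P2 <- matrix(c(0.3, 0.6), ncol = 1)
  expect_equal(steinerberger_sum(0.2, P2),
               steinerberger_sum(0.8, 1 - P2))
})

test_that("exploration minimizes the Steinerberger sum under constraints", {
  P <- matrix(0.5, ncol = 1)
  set.seed(53)
  x <- explore_candidate(P, n_starts = 10, maxit = 100)
  # the single-history 1D landscape is minimized at the boundary
  expect_lt(min(x, 1 - x), 0.05)
  expect_lt(steinerberger_sum(x, P), steinerberger_sum(0.4, P))

  feas <- function(U) U[, 1] >= 0.5
  set.seed(54)
  x2 <- explore_candidate(matrix(c(0.6, 0.8), ncol = 1), feas,
                          n_starts = 8, maxit = 60)
  expect_gte(x2, 0.5)

  set.seed(55)
  a <- explore_candidate(P, n_starts = 6, maxit = 60)
  set.seed(55)
  b <- explore_candidate(P, n_starts = 6, maxit = 60)
  expect_identical(a, b)

  expect_error(
    explore_candidate(P, function(U) rep(FALSE, nrow(U)), n_starts = 4,
                      retry_cap = 3),
    class = "formubo_search_error"
  )
})

test_that("batch proposal returns distinct feasible points with route labels", {
  set.seed(56)
  sp <- design_space()
  U <- sample_feasible_points(8, sp)
  hist <- decode_points(U, sp)
  hist <- dplyr::bind_cols(hist, true_surfaces(hist))
  X <- as.matrix(hist[paste0("u", 1:6)])
  models <- lapply(c("tm_C", "kd_mL_per_g", "rm_pct"), function(o) {
    fit_objective_model(X, hist[[o]], objective = o, restarts = 2)
  })
  names(models) <- c("tm_C", "kd_mL_per_g", "rm_pct")
  cfg <- acquisition_config(batch_size = 5, pop = 12, gens = 6,
                            explore_starts = 5, explore_maxit = 50)
  feas <- formubo:::unit_cube_feasible(sp)

  set.seed(57)
  batch <- propose_batch(models, hist, cfg, feas)
  expect_equal(nrow(batch), 5L)
  expect_true(all(batch$route %in% c("exploit", "explore")))
  Ub <- as.matrix(batch[paste0("u", 1:6)])
  expect_true(all(feas(Ub)))
  expect_gt(min(stats::dist(Ub)), 0)
  # determinism under a fixed seed
  set.seed(57)
  batch2 <- propose_batch(models, hist, cfg, feas)
  expect_identical(batch, batch2)

  # pure exploration never consults the surrogate front
  set.seed(58)
  b0 <- propose_batch(models, hist,
                      acquisition_config(p_exploit = 0, batch_size = 3,
                                         explore_starts = 5,
                                         explore_maxit = 50), feas)
  expect_true(all(b0$route == "explore"))
})

test_that("Kriging-believer picks spread along the toy trade-off front", {
  models <- toy_tradeoff_models()
  names(models) <- c("obj_x", "obj_1mx")
  hist <- tibble::tibble(u1 = c(0.4, 0.6),
                         obj_x = c(0.4, 0.6), obj_1mx = c(0.6, 0.4))
  cfg <- acquisition_config(p_exploit = 1, batch_size = 5, pop = 16,
                            gens = 8)
  set.seed(59)
  batch <- propose_batch(models, hist, cfg)
  u <- batch$u1
  expect_true(all(batch$route == "exploit"))
  expect_gt(min(stats::dist(u)), 0)
  # the five picks are not clustered within 0.05 of each other
  expect_gt(max(stats::dist(u)), 0.05)
})
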