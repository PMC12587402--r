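small_campaign_config <- function(seed = 81, n_init = 4, batch_size = 2) {
  campaign_config(
    n_init = n_init,
    acquisition = acquisition_config(batch_size = batch_size, pop = 10,
                                     gens = 4, explore_starts = 4,
                                     explore_maxit = 40),
    restarts = 2, seed = seed
  )
}

test_that("initialization draws the configured number of feasible points", {
  st <- initialize_campaign(campaign_config(seed = 3))
  expect_equal(nrow(st$ledger), 13L)
  expect_true(all(st$ledger$feasible))
  expect_true(all(st$ledger$iteration == 0L))
  expect_true(all(st$ledger$route == "init"))
  st2 <- initialize_campaign(campaign_config(seed = 3))
  expect_equal(st$ledger, st2$ledger)
  one <- initialize_campaign(campaign_config(n_init = 1, seed = 4))
  expect_equal(nrow(one$ledger), 1L)
  # an unreachable constraint window aborts cleanly
  tight <- design_space(osmolality = c(599.99, 600))
  expect_error(
    initialize_campaign(campaign_config(space = tight, init_retry_cap = 2)),
    class = "formubo_config_error"
  )
})

test_that("the ledger grows by exactly batch_size per iteration", {
  lab <- truth_lab()
  st <- initialize_campaign(small_campaign_config(), lab)
  st <- run_iteration(st, lab)
  st <- run_iteration(st, lab)
  expect_equal(nrow(st$ledger), 4L + 2L * 2L)
  expect_equal(as.integer(table(st$ledger$iteration)), c(4L, 2L, 2L))
  expect_true(all(st$ledger$feasible))
  expect_true(all(st$ledger$route[st$ledger$iteration > 0] %in%
                    c("exploit", "explore")))

  one <- initialize_campaign(small_campaign_config(seed = 82,
                                                   batch_size = 1), lab)
  one <- run_iteration(one, lab)
  expect_equal(nrow(one$ledger), 5L)
})

test_that("a fixed seed yields a byte-identical ledger CSV", {
  cfg <- small_campaign_config(seed = 83)
  lab <- virtual_lab()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ledger(simulate_campaign(cfg, lab, iterations = 1), f1)
  write_ledger(simulate_campaign(cfg, lab, iterations = 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the ledger round-trips through CSV
  led <- read_ledger(f1)
  expect_equal(nrow(led), 6L)
  st <- campaign_from_ledger(led, cfg)
  expect_s3_class(st, "formubo_campaign")
  expect_equal(glance(st)$n_obs, 6L)
})

test_that("hypervolume traces are monotone and match hand computations", {
  # single observation: trace equals the point hypervolume at the shared
  # reference (-0.5 per standardized objective)
  led1 <- tibble::tibble(iteration = 0L, u1 = 0.5, tm_C = 70,
                         kd_mL_per_g = 10, rm_pct = 95)
  tr1 <- hypervolume_trace(led1)
  expect_equal(tr1$hypervolume, 0.5^3)
  expect_equal(per_formulation_hypervolume(led1)$point_hv, 0.5^3)

  # three printed points over two iterations vs inclusion-exclusion
  led3 <- tibble::tibble(
    iteration = c(0L, 0L, 1L), u1 = c(0.1, 0.5, 0.9),
    tm_C = c(68, 70, 71), kd_mL_per_g = c(30, 10, 25),
    rm_pct = c(95, 90, 99)
  )
  Y <- as.matrix(led3[c("tm_C", "kd_mL_per_g", "rm_pct")])
  Ys <- scale(Y)[, ]
  ref <- apply(Ys, 2L, min) - 0.5
  expected <- c(oracle_hv_incl_excl(Ys[1:2, ], ref),
                oracle_hv_incl_excl(Ys, ref))
  tr3 <- hypervolume_trace(led3)
  expect_equal(tr3$hypervolume, expected)
  expect_equal(tr3$n_observations, c(2L, 3L))

  # monotone on the reference campaign
  trc <- hypervolume_trace(reference_campaign())
  expect_equal(trc$iteration, 0:4)
  expect_true(all(diff(trc$hypervolume) >= -1e-12))
})

test_that("prediction error traces are exact for perfectly learnable labs", {
  lab_const <- function(f) {
    dplyr::bind_cols(f, tibble::tibble(tm_C = rep(70, nrow(f)),
                                       kd_mL_per_g = rep(20, nrow(f)),
                                       rm_pct = rep(95, nrow(f))))
  }
  cfg <- small_campaign_config(seed = 84)
  st <- suppressWarnings(simulate_campaign(cfg, lab_const, iterations = 1))
  mae <- suppressWarnings(prediction_mae_trace(st))
  expect_equal(mae$mae, rep(0, 3), tolerance = 1e-8)
  expect_equal(sort(unique(mae$objective)), sort(cfg$objectives))
})

test_that("surrogate prediction error improves over the reference campaign", {
  mae <- prediction_mae_trace(reference_campaign())
  tm <- mae[mae$objective == "tm_C", ]
  expect_equal(tm$iteration, 1:4)
  expect_true(all(mae$mae >= 0))
  # by the final iteration the thermal-stability model predicts the next
  # batch better than it did at the start (seeded regression)
  expect_lt(tm$mae[4], tm$mae[1])
})

test_that("Spearman correlation equals the mid-rank Pearson oracle", {
  expect_equal(spearman_rank(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rank(1:5, 5:1), -1)
  # hand mid-rank computation for a tied case:
  # ranks of x=(1,2,2,3) are (1, 2.5, 2.5, 4); of y=(1,3,2,4) are
  # (1,3,2,4); Pearson of those is 4.5/sqrt(4.5*5)
  expect_equal(spearman_rank(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               4.5 / sqrt(4.5 * 5))
  expect_equal(spearman_rank(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               cor(c(1, 2, 2, 3), c(1, 3, 2, 4), method = "spearman"))
  expect_warning(out <- spearman_rank(c(1, 1, 1), 1:3), "zero rank")
  expect_true(is.na(out))
  expect_error(spearman_rank(1:2, 1:2), class = "formubo_config_error")
})

test_that("route labels over many campaigns match the exploit probability", {
  lab <- truth_lab()
  set.seed(85)
  seeds <- sample.int(1e6, 100)
  routes <- unlist(lapply(seeds, function(s) {
    st <- initialize_campaign(small_campaign_config(seed = s,
                                                    n_init = 3), lab)
    st <- run_iteration(st, lab)
    st$ledger$route[st$ledger$iteration == 1L]
  }))
  n <- length(routes)
  expect_equal(n, 200L)
  frac <- mean(routes == "exploit")
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("the reference campaign improves on its initialization", {
  st <- reference_campaign()
  led <- st$ledger
  expect_gt(max(led$kd_mL_per_g[led$iteration > 0]),
            max(led$kd_mL_per_g[led$iteration == 0]))
  # final non-dominated set reaches the constructed optima region
  nd <- led[non_dominated_filter(led[c("tm_C", "kd_mL_per_g", "rm_pct")]), ]
  expect_gt(max(nd$kd_mL_per_g), 40)
  expect_gt(max(nd$tm_C), 70)
})

test_that("excipient-objective correlation tables cover all pairs", {
  tab <- spearman_table(reference_campaign())
  expect_equal(nrow(tab), 7L * 3L)
  rho_arg_kd <- tab$rho[tab$variable == "arginine_mM" &
                          tab$objective == "kd_mL_per_g"]
  expect_lt(rho_arg_kd, 0)
})

test_that("pending suggestions can be completed with recorded measurements", {
  st <- initialize_campaign(campaign_config(n_init = 3, seed = 86))
  expect_false("tm_C" %in% names(st$ledger))
  meas <- dplyr::bind_cols(st$ledger[-(1:2)],
                           true_surfaces(st$ledger[-(1:2)]))
  st2 <- record_observations(st, meas)
  expect_equal(nrow(st2$ledger), 3L)
  expect_false(any(is.na(st2$ledger$tm_C)))
  # unmatched measured rows are appended as a new iteration
  extra <- meas[1, ]
  extra$u1 <- 1 - extra$u1
  st3 <- record_observations(st2, extra)
  expect_equal(nrow(st3$ledger), 4L)
  expect_equal(st3$ledger$iteration[4], 1L)
})

test_that("campaign plots and summaries are well-formed", {
  st <- reference_campaign()
  expect_s3_class(autoplot(st, "hypervolume"), "ggplot")
  expect_s3_class(autoplot(st, "objectives"), "ggplot")
  expect_s3_class(tidy(st), "tbl_df")
  gl <- glance(st)
  expect_equal(gl$n_obs, 33L)
  models <- formubo:::fit_surrogates(st)
  set.seed(87)
  front <- nsga2_front(models,
                       formubo:::unit_cube_feasible(st$config$space),
                       pop = 16, gens = 6)
  expect_s3_class(plot_pareto_front(front), "ggplot")
  tc <- seq(25, 90, by = 0.5)
  expect_s3_class(
    plot_melt_curve(melt_curve(tc, 0.8 + 0.3 * stats::plogis((tc - 70) / 2))),
    "ggplot"
  )
})
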