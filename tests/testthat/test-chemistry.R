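test_that("forward pH solver reproduces limiting cases", {
  # strong acid: 1 mM HCl, autoionization negligible
  expect_equal(solve_mixture_ph(list(hcl = 1)), 3.00, tolerance = 0.01)
  # pure water: Kw symmetry
  expect_equal(solve_mixture_ph(list()), 7.00, tolerance = 1e-6)
  # 10 mM weak acid, pKa 4.76: closed-form quadratic ignoring
  # autoionization gives [H+] = (-Ka + sqrt(Ka^2 + 4 Ka C)) / 2
  ka <- 10^-4.76
  h <- (-ka + sqrt(ka^2 + 4 * ka * 0.01)) / 2
  expect_equal(solve_mixture_ph(list(acetic = 10)), -log10(h),
               tolerance = 0.005)
  expect_error(solve_mixture_ph(list(unobtainium = 5)),
               class = "formubo_config_error")
})

test_that("species tables conserve mass and balance charge at the solved pH", {
  set.seed(41)
  db <- species_db()
  for (i in 1:20) {
    comp <- list(his = runif(1, 0, 20), arg = runif(1, 0, 100),
                 asp = runif(1, 0, 30), glu = runif(1, 0, 30),
                 acetic = runif(1, 0, 30), hcl = runif(1, 0, 30))
    ph <- solve_mixture_ph(comp)
    tab <- species_table(comp, ph, db)
    # per-component mass conservation
    sums <- tapply(tab$conc_mM, tab$component, sum)
    for (nm in names(comp)) {
      expect_equal(unname(sums[nm]), comp[[nm]], tolerance = 1e-9)
    }
    # electroneutrality in M at the solved pH
    residual <- sum(tab$charge * tab$conc_mM) / 1000
    expect_lt(abs(residual), 1e-10)
  }
})

test_that("pH decreases strictly as any acid total increases", {
  for (acid in c("asp", "glu", "acetic", "hcl")) {
    comp <- tibble::tibble(his = 10, arg = 0, asp = 0, glu = 0, acetic = 0,
                           hcl = 0, sorbitol = 0)[rep(1, 10), ]
    comp[[acid]] <- seq(1, 50, length.out = 10)
    ph <- solve_mixture_ph(comp)
    expect_true(all(diff(ph) < 0))
  }
})

test_that("inverse acid solve hits the target pH and flags infeasible targets", {
  # forward/inverse round trip on random feasible points
  set.seed(42)
  U <- sample_feasible_points(100)
  f <- decode_points(U, design_space())
  expect_true(all(f$feasible))
  ph_back <- solve_mixture_ph(formubo:::composition_of(f))
  expect_lt(max(abs(ph_back - f$pH)), 1e-4)

  # acetic acid alone cannot raise pH above neutrality
  expect_error(
    acid_totals_for_target_ph(7.5, f_acetic = 1, histidine = 0),
    class = "formubo_infeasible_error"
  )
  # cap on total acid
  expect_error(
    acid_totals_for_target_ph(4.5, f_acetic = 1, histidine = 10,
                              arginine = 250, acid_cap_mM = 10),
    class = "formubo_infeasible_error"
  )
})

test_that("inverse acid solve matches the brute-force 1 uM grid oracle", {
  set.seed(43)
  db <- species_db()
  grid <- seq(0, 60, by = 1e-3)  # mM, 1 uM steps
  for (case in 1:20) {
    f <- runif(4)
    f <- f / sum(f)
    arg <- runif(1, 0, 15)
    target <- runif(1, 5, 7)
    sol <- acid_totals_for_target_ph(target, f_asp = f[1], f_glu = f[2],
                                     f_hcl = f[3], f_acetic = f[4],
                                     histidine = 10, arginine = arg)
    expect_true(sol$feasible)
    expect_lt(sol$total_mM, 59)  # oracle grid must cover the solution
    comp <- tibble::tibble(his = 10, arg = arg, asp = grid * f[1],
                           glu = grid * f[2], hcl = grid * f[3],
                           acetic = grid * f[4], sorbitol = 0)
    ph <- solve_mixture_ph(comp, db)
    c_oracle <- grid[which.min(abs(ph - target))]
    expect_lt(abs(sol$total_mM - c_oracle), 2e-3)
  }
})

test_that("unit-cube decoding maps bounds, midpoints and the fraction simplex", {
  sp <- design_space()
  f <- decode_points(rbind(rep(0, 6), rep(0.5, 6)), sp)
  expect_equal(f$sorbitol_mM, c(0, 275))
  expect_equal(f$arginine_mM, c(0, 125))
  expect_equal(f$pH, c(4.5, 6.0))
  expect_equal(f$f_acetic[1], 1)

  # fraction coordinates (0.6, 0.5, 0.3) sum to 1.4: simplex violated
  bad <- decode_points(matrix(c(0.5, 0.5, 0.5, 0.6, 0.5, 0.3), 1), sp)
  expect_false(bad$feasible)
  expect_match(bad$reason, "fraction simplex")
  expect_error(decode_points(matrix(2, 1, 6), sp),
               class = "formubo_config_error")
})

test_that("osmolality is the ideal particle sum and is linear in sorbitol", {
  base <- tibble::tibble(sorbitol_mM = 300, histidine_mM = 10,
                         arginine_mM = 0, asp_mM = 0, glu_mM = 0,
                         acetic_mM = 0, hcl_mM = 5)
  expect_equal(estimate_osmolality(base), 315)
  expect_equal(estimate_osmolality(dplyr::mutate(base, sorbitol_mM = 0,
                                                 hcl_mM = 0)), 10)
  plus50 <- dplyr::mutate(base, sorbitol_mM = sorbitol_mM + 50)
  expect_equal(estimate_osmolality(plus50) - estimate_osmolality(base), 50)
})

test_that("feasibility reports name the violated constraints", {
  sp <- design_space()
  # minimal-acid point: pH 7.5, no sorbitol/arginine -> osmolality below 100
  low <- decode_points(matrix(c(0, 0, 1, 0, 0, 1), 1), sp)
  expect_false(low$feasible)
  expect_match(low$reason, "osmolality")
  expect_lt(low$hcl_mM + low$histidine_mM, 100)

  # 300 mM sorbitol, pH 6, HCl only: inside the window
  ok <- decode_points(matrix(c(300 / 550, 0, 0.5, 0, 0, 1), 1), sp)
  expect_true(ok$feasible)

  rep <- check_feasibility(dplyr::mutate(ok, f_asp = 0.7, f_glu = 0.5), sp)
  expect_false(rep$feasible)
  expect_true("fraction simplex violated" %in% rep$violations[[1]])
})

test_that("fast feasibility predicate agrees with full decoding", {
  set.seed(44)
  sp <- design_space()
  feas <- formubo:::unit_cube_feasible(sp)
  U <- matrix(runif(500 * 6), ncol = 6)
  expect_equal(feas(U), decode_points(U, sp)$feasible)
})
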