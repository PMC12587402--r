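#' Virtual laboratory configuration
#'
#' Noise model and replicate settings of the synthetic measurement source.
#' The defaults emulate plausible instrument scatter for triplicate nanoDSF,
#' DLS and agitation-stress measurements of a monoclonal antibody.
#'
#' @param tm_noise_C Replicate sd of the unfolding midpoint, degrees C.
#' @param kd_noise Replicate sd of the diffusion interaction parameter,
#'   mL/g.
#' @param rm_noise_pct Replicate sd of retained monomer, percentage points.
#' @param dls_noise_rel Relative (multiplicative) sd of individual diffusion
#'   coefficient readings.
#' @param replicates Replicate measurements per formulation.
#' @param melt_grid Temperature grid of simulated melt curves, degrees C.
#' @param dls_conc DLS dilution series concentrations, mg/mL.
#' @param keep_raw Keep the simulated raw assay data as a list column.
#' @return A list of class `formubo_lab_config`.
#' @export
lab_config <- function(tm_noise_C = 0.2, kd_noise = 1.5, rm_noise_pct = 2,
                       dls_noise_rel = 0.005, replicates = 3,
                       melt_grid = seq(25, 90, by = 0.5),
                       dls_conc = c(2, 3.25, 4.5, 5.75, 7),
                       keep_raw = FALSE) {
  stopifnot(tm_noise_C >= 0, kd_noise >= 0, rm_noise_pct >= 0,
            dls_noise_rel >= 0, replicates >= 1)
  structure(list(tm_noise_C = tm_noise_C, kd_noise = kd_noise,
                 rm_noise_pct = rm_noise_pct, dls_noise_rel = dls_noise_rel,
                 replicates = replicates, melt_grid = melt_grid,
                 dls_conc = dls_conc, keep_raw = keep_raw),
            class = "formubo_lab_config")
}

#' Ground-truth response surfaces of the virtual lab
#'
#' Deterministic, noise-free objective values of a feasible formulation.
#' The surfaces are synthetic test fixtures, not fitted to any experimental
#' data; their shape encodes the qualitative structure expected for an
#' antibody formulation problem: higher pH raises thermal stability (Tm)
#' while lower pH raises colloidal stability (kD), sorbitol helps up to an
#' intermediate concentration (~300 mM), arginine is mildly detrimental to
#' Tm and strongly detrimental to kD, and retained monomer saturates in a
#' 90-100% plateau. With `s` = sorbitol mM, `a` = arginine mM:
#' \deqn{Tm = 66 + 1.2 (pH - 4.5) + 3 s/(s + 150) - 2 a/250}
#' \deqn{kD = -25 + 18 (7.5 - pH) + 15 (2 r - r^2) - 0.2 a, \quad r = s/324}
#' \deqn{RM = \min(100, 70 + 28 \,\mathrm{logistic}(0.01 s - 0.03 a + 1))}
#'
#' @param formulation Decoded formulation tibble (see [decode_points()]);
#'   all rows must be feasible.
#' @param config A [lab_config()] (unused by the deterministic surfaces,
#'   accepted for interface symmetry).
#' @return A tibble with columns `tm_C`, `kd_mL_per_g`, `rm_pct`.
#' @examples
#' f <- decode_points(matrix(c(324 / 550, 0, 0, 0, 0, 1), 1), design_space())
#' true_surfaces(f)
#' @export
true_surfaces <- function(formulation, config = lab_config()) {
  if (!all(formulation[["feasible"]] %||% TRUE)) {
    abort("true_surfaces requires feasible formulations",
          class = "formubo_config_error")
  }
  s <- formulation$sorbitol_mM
  a <- formulation$arginine_mM
  ph <- formulation$pH
  r <- s / 324
  tibble::tibble(
    tm_C = 66 + 1.2 * (ph - 4.5) + 3 * s / (s + 150) - 2 * a / 250,
    kd_mL_per_g = -25 + 18 * (7.5 - ph) + 15 * (2 * r - r^2) - 0.2 * a,
    rm_pct = pmin(100, 70 + 28 * stats::plogis(0.01 * s - 0.03 * a + 1))
  )
}

# Simulate raw assay data for one formulation and push it through the assay
# pipeline. Returns list(objectives = tibble row, raw = list).
simulate_one_measurement <- function(truth, config) {
  reps <- seq_len(config$replicates)

  # nanoDSF: logistic 350/330 ratio, replicate-shifted center
  centers <- truth$tm_C + rnorm(config$replicates, 0, config$tm_noise_C)
  melt <- lapply(centers, function(ctr) {
    melt_curve(config$melt_grid,
               0.8 + 0.3 * stats::plogis((config$melt_grid - ctr) / 2))
  })
  tm <- mean(vapply(melt, tm_from_curve, numeric(1)))

  # DLS dilution series: D0 = 1 (arbitrary units), slope from the true kD
  kd_rep <- truth$kd_mL_per_g + rnorm(config$replicates, 0, config$kd_noise)
  dls <- dplyr::bind_rows(lapply(reps, function(i) {
    D <- (1 + kd_rep[i] / 1000 * config$dls_conc) *
      (1 + rnorm(length(config$dls_conc), 0, config$dls_noise_rel))
    dls_series(config$dls_conc, D, replicate = i)
  }))
  kd_fit <- fit_kd(dls)

  # agitation stress: reference 1 mg/mL, shaken supernatant implies RM
  c_ref <- 1
  rm_rep <- truth$rm_pct + rnorm(config$replicates, 0, config$rm_noise_pct)
  c_shaken <- pmax(rm_rep / 100 * c_ref, 0)
  rm <- mean(retained_monomer(rep(c_ref, config$replicates), c_shaken))

  list(
    objectives = tibble::tibble(tm_C = tm, kd_mL_per_g = kd_fit$kD_mL_per_g,
                                rm_pct = rm),
    raw = list(melt = melt, dls = dls,
               agitation = tibble::tibble(replicate = reps, c_ref = c_ref,
                                          c_shaken = c_shaken))
  )
}

#' Simulate measurements of formulations
#'
#' For every (feasible) formulation row, simulates raw instrument data from
#' the ground-truth surfaces — replicate melt curves, DLS dilution series
#' and agitation supernatant concentrations — with seeded Gaussian noise,
#' then runs the full assay pipeline ([tm_from_curve()], [fit_kd()],
#' [retained_monomer()]) and averages replicates. The assay code path is
#' therefore exercised end to end, never bypassed.
#'
#' @param formulation Decoded formulation tibble; feasible rows only.
#' @param config A [lab_config()].
#' @return The input tibble with measured `tm_C`, `kd_mL_per_g`, `rm_pct`
#'   columns appended (and a `raw` list column when `keep_raw = TRUE`).
#' @export
measure_formulations <- function(formulation, config = lab_config()) {
  truths <- true_surfaces(formulation, config)
  res <- lapply(seq_len(nrow(formulation)), function(i) {
    simulate_one_measurement(truths[i, ], config)
  })
  out <- dplyr::bind_cols(
    formulation,
    dplyr::bind_rows(lapply(res, `[[`, "objectives"))
  )
  if (isTRUE(config$keep_raw)) out$raw <- lapply(res, `[[`, "raw")
  out
}

#' A virtual-lab measurement source
#'
#' Wraps [measure_formulations()] into the measurement-source interface the
#' campaign loop consumes: a function that maps a formulation tibble to the
#' same tibble with measured objectives appended.
#'
#' @param config A [lab_config()].
#' @return A function of class `formubo_lab`.
#' @export
virtual_lab <- function(config = lab_config()) {
  structure(function(formulation) measure_formulations(formulation, config),
            class = c("formubo_lab", "function"), config = config)
}
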