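#' DLS dilution series
#'
#' Builds/validates a dilution-series table for the diffusion interaction
#' parameter fit: protein concentration in mg/mL against measured diffusion
#' coefficient, optionally with a replicate id.
#'
#' @param conc_mg_mL Protein concentrations (default instrument series
#'   2, 3.25, 4.5, 5.75, 7 mg/mL).
#' @param D Diffusion coefficients (any consistent units).
#' @param replicate Optional replicate labels.
#' @return A tibble with columns `conc_mg_mL`, `D`, `replicate`.
#' @export
dls_series <- function(conc_mg_mL = c(2, 3.25, 4.5, 5.75, 7), D,
                       replicate = 1L) {
  out <- tibble::tibble(conc_mg_mL = conc_mg_mL, D = D,
                        replicate = replicate)
  if (any(out$conc_mg_mL <= 0)) {
    abort("concentrations must be positive", class = "formubo_config_error")
  }
  if (length(unique(out$conc_mg_mL)) < 2L) {
    abort("need at least 2 distinct concentrations",
          class = "formubo_config_error")
  }
  out
}

#' Diffusion interaction parameter from a dilution series
#'
#' Fits the linear concentration dependence of the diffusion coefficient,
#' `D = D0 (1 + kD c)`, by ordinary least squares of `D` on `c`. The
#' intercept is `D0` and `kD` is the slope/intercept ratio; with `c` in
#' mg/mL that ratio is in mL/mg and is multiplied by 1000 to report the
#' conventional mL/g. Positive `kD` indicates net repulsive protein-protein
#' interactions (colloidal stability), negative net attraction. When a
#' `replicate` column distinguishes replicate series, each replicate is
#' fitted separately and the estimates are averaged.
#'
#' @param series A data frame with columns `conc_mg_mL` and `D` (and
#'   optionally `replicate`), e.g. from [dls_series()].
#' @return A one-row tibble: `D0`, `kD_mL_per_g`, `r_squared`,
#'   `n_replicates`. `r_squared` is 0 by convention for a flat series.
#' @examples
#' s <- dls_series(D = 1 * (1 + 0.02 * c(2, 3.25, 4.5, 5.75, 7)))
#' fit_kd(s) # kD = 20 mL/g
#' @export
fit_kd <- function(series) {
  if (!all(c("conc_mg_mL", "D") %in% names(series))) {
    abort("series needs columns conc_mg_mL and D",
          class = "formubo_config_error")
  }
  if (any(series$conc_mg_mL <= 0)) {
    abort("concentrations must be positive", class = "formubo_config_error")
  }
  series$replicate <- series$replicate %||% 1L
  one <- function(df) {
    if (nrow(df) < 2L || length(unique(df$conc_mg_mL)) < 2L) {
      abort("need at least 2 distinct concentrations",
            class = "formubo_config_error")
    }
    fit <- lm(D ~ conc_mg_mL, data = df)
    d0 <- unname(coef(fit)[1])
    slope <- unname(coef(fit)[2])
    if (d0 <= 0) {
      abort("non-positive intercept D0: kD undefined",
            class = "formubo_assay_error")
    }
    ss_tot <- sum((df$D - mean(df$D))^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 0
    tibble::tibble(D0 = d0, kD_mL_per_g = slope / d0 * 1000, r_squared = r2)
  }
  per_rep <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(~ one(.x)) |>
    dplyr::bind_rows()
  tibble::tibble(
    D0 = mean(per_rep$D0),
    kD_mL_per_g = mean(per_rep$kD_mL_per_g),
    r_squared = mean(per_rep$r_squared),
    n_replicates = nrow(per_rep)
  )
}

#' Retained monomer after agitation stress
#'
#' `RM [%] = 100 - (c_ref - c_shaken) / c_ref * 100`: the percentage of
#' protein remaining in the supernatant of the shaken sample relative to the
#' unshaken reference. Values above 100 (shaken concentration exceeding the
#' reference) are returned as-is; inspect them upstream.
#'
#' @param c_ref Reference (unshaken) concentration, mg/mL; must be > 0.
#' @param c_shaken Concentration after shaking and centrifugation, mg/mL.
#' @return RM in percent (vectorized).
#' @examples
#' retained_monomer(1.0, 0.9) # 90
#' @export
retained_monomer <- function(c_ref, c_shaken) {
  if (any(c_ref <= 0)) {
    abort("c_ref must be positive", class = "formubo_assay_error")
  }
  if (any(c_shaken < 0)) {
    abort("c_shaken must be non-negative", class = "formubo_assay_error")
  }
  100 - (c_ref - c_shaken) / c_ref * 100
}

#' Melt curve container
#'
#' @param temperature_C Strictly increasing temperature grid, degrees C.
#' @param ratio Intrinsic fluorescence 350/330 nm ratio at each temperature.
#' @return A tibble with columns `temperature_C`, `ratio`.
#' @export
melt_curve <- function(temperature_C, ratio) {
  if (length(temperature_C) != length(ratio)) {
    abort("temperature and ratio lengths differ",
          class = "formubo_config_error")
  }
  if (any(diff(temperature_C) <= 0)) {
    abort("temperatures must be strictly increasing",
          class = "formubo_config_error")
  }
  tibble::tibble(temperature_C = temperature_C, ratio = ratio)
}

#' Melting temperature from a fluorescence-ratio melt curve
#'
#' Smooths the 350/330 nm ratio with a Savitzky-Golay filter, takes the
#' central-difference first derivative, and returns the temperature of the
#' global derivative maximum, refined by a local quadratic (three-point
#' parabola) interpolation. A curve whose maximum derivative stays below
#' `min_slope` has no detectable unfolding transition and raises an error.
#'
#' @param curve A data frame with columns `temperature_C` and `ratio`, e.g.
#'   from [melt_curve()].
#' @param window Savitzky-Golay window length (odd number of points).
#' @param poly_order Savitzky-Golay polynomial order.
#' @param min_slope Minimum derivative (ratio units per degree C) for a
#'   transition to count.
#' @return Tm in degrees C.
#' @examples
#' tc <- seq(25, 90, by = 0.5)
#' tm_from_curve(melt_curve(tc, 0.8 + 0.3 * plogis((tc - 70) / 2)))
#' @export
tm_from_curve <- function(curve, window = 9, poly_order = 3,
                          min_slope = 1e-3) {
  tc <- curve$temperature_C
  y <- curve$ratio
  if (length(tc) < 7L) {
    abort("need at least 7 grid points", class = "formubo_config_error")
  }
  if (length(y) > window) {
    y <- signal::sgolayfilt(y, p = poly_order, n = window)
  }
  n <- length(y)
  # central differences on the interior grid
  dy <- (y[3:n] - y[1:(n - 2)]) / (tc[3:n] - tc[1:(n - 2)])
  tmid <- tc[2:(n - 1)]
  i <- which.max(dy)
  if (dy[i] < min_slope) {
    abort("no unfolding transition detected (flat derivative)",
          class = "formubo_assay_error")
  }
  if (i == 1L || i == length(dy)) return(tmid[i])
  # quadratic refinement around the discrete maximum
  d1 <- dy[i - 1]; d2 <- dy[i]; d3 <- dy[i + 1]
  denom <- d1 - 2 * d2 + d3
  offset <- if (denom < 0) 0.5 * (d1 - d3) / denom else 0
  h <- tmid[i + 1] - tmid[i]
  tmid[i] + offset * h
}

#' Read a DLS dilution series from CSV
#'
#' Expects columns `conc_mg_mL`, `D` and optionally `replicate`.
#'
#' @param path CSV file path.
#' @return A validated dilution-series tibble.
#' @export
read_dls_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  dls_series(conc_mg_mL = df$conc_mg_mL, D = df$D,
             replicate = df$replicate %||% 1L)
}

#' Read a melt curve from CSV
#'
#' Expects columns `T_C` (or `temperature_C`) and `ratio`.
#'
#' @param path CSV file path.
#' @return A melt-curve tibble.
#' @export
read_melt_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  melt_curve(df$T_C %||% df$temperature_C, df$ratio)
}
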