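#' Formulation design space
#'
#' Bounds of the six independent design variables (sorbitol, arginine, pH and
#' the three free acid fractions), the fixed histidine buffer concentration,
#' and the osmolality constraint window. The acetic acid fraction is not
#' independent: it is derived as `1 - (f_asp + f_glu + f_hcl)` and must stay
#' non-negative, which together with the osmolality window defines the
#' feasible region.
#'
#' @param sorbitol,arginine Concentration ranges in mM.
#' @param ph pH range.
#' @param fractions Range shared by the three independent acid fractions.
#' @param histidine Fixed histidine buffer concentration in mM.
#' @param osmolality Allowed osmolality window in mOsm/kg.
#' @param acid_cap_mM Maximum admissible total acid concentration for the
#'   inverse pH solve, in mM.
#' @return An object of class `formubo_space`.
#' @examples
#' design_space()
#' @export
design_space <- function(sorbitol = c(0, 550), arginine = c(0, 250),
                         ph = c(4.5, 7.5), fractions = c(0, 1),
                         histidine = 10, osmolality = c(100, 600),
                         acid_cap_mM = 2000) {
  stopifnot(
    sorbitol[1] <= sorbitol[2], arginine[1] <= arginine[2], ph[1] <= ph[2],
    fractions[1] <= fractions[2], fractions[1] >= 0, fractions[2] <= 1,
    histidine > 0, osmolality[1] <= osmolality[2], acid_cap_mM > 0
  )
  structure(
    list(sorbitol = sorbitol, arginine = arginine, ph = ph,
         fractions = fractions, histidine = histidine,
         osmolality = osmolality, acid_cap_mM = acid_cap_mM),
    class = "formubo_space"
  )
}

#' @export
print.formubo_space <- function(x, ...) {
  cat("<formubo design space>\n")
  cat(sprintf("  sorbitol   %g-%g mM\n", x$sorbitol[1], x$sorbitol[2]))
  cat(sprintf("  arginine   %g-%g mM\n", x$arginine[1], x$arginine[2]))
  cat(sprintf("  pH         %g-%g\n", x$ph[1], x$ph[2]))
  cat(sprintf("  fractions  %g-%g (f_asp, f_glu, f_hcl; f_acetic derived)\n",
              x$fractions[1], x$fractions[2]))
  cat(sprintf("  histidine  %g mM (fixed)\n", x$histidine))
  cat(sprintf("  osmolality %g-%g mOsm/kg\n", x$osmolality[1],
              x$osmolality[2]))
  invisible(x)
}

# Charge-balance residual (M) of compositions at the given pH values.
# `comp` is a data frame with columns his, arg, asp, glu, acetic, hcl (mM),
# recycled against `ph`. Strictly decreasing in pH.
charge_balance_residual <- function(ph, comp, db = species_db()) {
  h <- 10^(-ph)
  res <- h - 1e-14 / h
  for (i in seq_len(nrow(db))) {
    nm <- db$component[i]
    if (is.null(comp[[nm]])) next
    c_m <- comp[[nm]] / 1000
    if (all(c_m == 0)) next
    res <- res + c_m * average_charge(db$pkas[[i]], db$z_max[i], ph,
                                      db$strong[i])
  }
  res
}

#' Solve the pH of a buffer mixture
#'
#' Finds the pH in `[0, 14]` at which the charge balance of the mixture
#' (all ionic species from the pKa ladders, plus H+ and OH- with
#' Kw = 1e-14) is zero. The residual is strictly decreasing in pH, so a
#' vectorized bisection converges unconditionally; 60 halvings shrink the
#' bracket to ~1e-17 pH units, far below the 1e-10 M residual tolerance.
#'
#' @param composition Named list (single mixture) or data frame (one row per
#'   mixture) of analytical concentrations in mM; recognized names are the
#'   components of [species_db()].
#' @param db Species database.
#' @return Numeric vector of pH values.
#' @examples
#' solve_mixture_ph(list(hcl = 1))        # strong acid, pH 3
#' solve_mixture_ph(list(acetic = 10))    # weak acid, pH ~3.39
#' solve_mixture_ph(list())               # pure water, pH 7
#' @export
solve_mixture_ph <- function(composition, db = species_db()) {
  comp <- if (is.data.frame(composition)) {
    missing <- setdiff(db$component, names(composition))
    unknown <- setdiff(names(composition), db$component)
    if (length(unknown) > 0) {
      abort(paste0("unknown component(s): ", paste(unknown, collapse = ", ")),
            class = "formubo_config_error")
    }
    out <- composition
    for (nm in missing) out[[nm]] <- 0
    if (any(vapply(out, function(x) any(x < 0), logical(1)))) {
      abort("negative concentration(s)", class = "formubo_config_error")
    }
    out
  } else {
    tibble::as_tibble(normalize_composition(composition, db))
  }
  n <- max(nrow(comp), 1L)
  lo <- rep(0, n); hi <- rep(14, n)
  r_lo <- charge_balance_residual(lo, comp, db)
  r_hi <- charge_balance_residual(hi, comp, db)
  if (any(r_lo < 0) || any(r_hi > 0)) {
    abort("charge balance has no root in [0, 14]",
          class = "formubo_solver_error")
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    pos <- charge_balance_residual(mid, comp, db) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  (lo + hi) / 2
}

#' Total acid concentration that hits a target pH
#'
#' The acids are dosed as a fixed blend `(f_asp, f_glu, f_hcl, f_acetic)`
#' summing to one; the total blend concentration C that brings the histidine
#' (+ arginine) base mixture to the target pH follows in closed form: at
#' fixed pH the speciation alpha-fractions, and hence the average charge of
#' every component, are constants, so the charge-balance residual is linear
#' in C. The solution is exact (no iteration); infeasibility arises when the
#' required C is negative (target pH above the acid-free mixture's pH) or
#' exceeds the configured cap.
#'
#' @param target_ph Target pH value(s).
#' @param f_asp,f_glu,f_hcl,f_acetic Acid blend fractions, summing to 1.
#' @param histidine,arginine Base concentrations in mM.
#' @param db Species database.
#' @param acid_cap_mM Maximum admissible total acid in mM.
#' @param strict If `TRUE` (default), signal a `formubo_infeasible_error`
#'   when any target is unreachable; if `FALSE`, mark the affected rows
#'   infeasible instead.
#' @return A tibble with columns `total_mM`, `asp_mM`, `glu_mM`,
#'   `acetic_mM`, `hcl_mM`, `feasible`, `reason`.
#' @examples
#' acid_totals_for_target_ph(6, f_hcl = 1, histidine = 10)
#' @export
acid_totals_for_target_ph <- function(target_ph, f_asp = 0, f_glu = 0,
                                      f_hcl = 0, f_acetic = 0,
                                      histidine = 10, arginine = 0,
                                      db = species_db(), acid_cap_mM = 2000,
                                      strict = TRUE) {
  n <- max(lengths(list(target_ph, f_asp, f_glu, f_hcl, f_acetic,
                        histidine, arginine)))
  rec <- function(x) rep_len(x, n)
  target_ph <- rec(target_ph); f_asp <- rec(f_asp); f_glu <- rec(f_glu)
  f_hcl <- rec(f_hcl); f_acetic <- rec(f_acetic)
  histidine <- rec(histidine); arginine <- rec(arginine)
  fsum <- f_asp + f_glu + f_hcl + f_acetic
  if (any(abs(fsum - 1) > 1e-8) || any(c(f_asp, f_glu, f_hcl, f_acetic) < 0)) {
    abort("acid fractions must be non-negative and sum to 1",
          class = "formubo_config_error")
  }
  zc <- function(nm) {
    i <- match(nm, db$component)
    average_charge(db$pkas[[i]], db$z_max[i], target_ph, db$strong[i])
  }
  h <- 10^(-target_ph)
  base <- h - 1e-14 / h +
    histidine / 1000 * zc("his") + arginine / 1000 * zc("arg")
  slope <- f_asp * zc("asp") + f_glu * zc("glu") + f_acetic * zc("acetic") +
    f_hcl * zc("hcl")
  total <- -base / slope * 1000  # mM
  reason <- rep(NA_character_, n)
  reason[total < 0] <- "target pH above acid-free mixture pH"
  reason[total > acid_cap_mM] <- "total acid exceeds cap"
  feasible <- is.na(reason)
  if (strict && !all(feasible)) {
    abort(paste0("infeasible target pH: ", reason[!feasible][1]),
          class = "formubo_infeasible_error")
  }
  total[!feasible] <- NA_real_
  tibble::tibble(
    total_mM = total,
    asp_mM = total * f_asp, glu_mM = total * f_glu,
    acetic_mM = total * f_acetic, hcl_mM = total * f_hcl,
    feasible = feasible, reason = reason
  )
}

#' Ideal-solution osmolality of a formulation
#'
#' Sums analytical solute particles: sorbitol, histidine, arginine, each weak
#' acid counted once per analytical particle, and the chloride delivered by
#' HCl. No osmotic coefficients; molar and molal scales are identified. The
#' model is deliberately simple and isolated here so it can be swapped.
#'
#' @param formulation Data frame with columns `sorbitol_mM`, `histidine_mM`,
#'   `arginine_mM`, `asp_mM`, `glu_mM`, `acetic_mM`, `hcl_mM`.
#' @return Osmolality in mOsm/kg (numeric vector).
#' @examples
#' estimate_osmolality(data.frame(sorbitol_mM = 300, histidine_mM = 10,
#'   arginine_mM = 0, asp_mM = 0, glu_mM = 0, acetic_mM = 0, hcl_mM = 5))
#' @export
estimate_osmolality <- function(formulation) {
  with(formulation,
       sorbitol_mM + histidine_mM + arginine_mM +
         asp_mM + glu_mM + acetic_mM + hcl_mM)
}

#' Decode unit-hypercube points into formulations
#'
#' Maps points of the normalized 6-dimensional design cube affinely onto
#' (sorbitol, arginine, pH, f_asp, f_glu, f_hcl), derives the acetic acid
#' fraction, solves for the per-acid concentrations that realize the target
#' pH, estimates osmolality and flags feasibility. Infeasible points are
#' returned marked, never dropped and never raised as errors, so the decoder
#' can sit inside rejection loops.
#'
#' @param points Data frame with columns `u1` ... `u6` (or any 6 numeric
#'   columns, taken in order), or a numeric matrix with 6 columns; all
#'   entries in `[0, 1]`.
#' @param space A [design_space()].
#' @param db Species database.
#' @return A tibble with the unit-cube coordinates, the decoded formulation
#'   (`sorbitol_mM`, `arginine_mM`, `pH`, the four fractions, per-acid mM,
#'   `histidine_mM`, `osmolality_mOsm_kg`) and `feasible`/`reason` columns.
#' @examples
#' decode_points(matrix(0.5, 1, 6), design_space())
#' @export
decode_points <- function(points, space = design_space(), db = species_db()) {
  u <- as.matrix(as.data.frame(points))
  if (ncol(u) != 6L) abort("points must have 6 coordinates",
                           class = "formubo_config_error")
  if (any(u < -1e-12) || any(u > 1 + 1e-12)) {
    abort("unit-cube coordinates must lie in [0, 1]",
          class = "formubo_config_error")
  }
  u <- pmin(pmax(u, 0), 1)
  colnames(u) <- paste0("u", 1:6)
  aff <- function(x, r) unname(r[1] + x * (r[2] - r[1]))
  fr <- space$fractions
  out <- tibble::as_tibble(u)
  out$sorbitol_mM <- aff(u[, 1], space$sorbitol)
  out$arginine_mM <- aff(u[, 2], space$arginine)
  out$pH <- aff(u[, 3], space$ph)
  out$f_asp <- aff(u[, 4], fr)
  out$f_glu <- aff(u[, 5], fr)
  out$f_hcl <- aff(u[, 6], fr)
  out$f_acetic <- 1 - (out$f_asp + out$f_glu + out$f_hcl)
  simplex_ok <- out$f_acetic >= -1e-12
  out$f_acetic <- pmax(out$f_acetic, 0)

  tot <- tibble::tibble(total_mM = NA_real_, asp_mM = NA_real_,
                        glu_mM = NA_real_, acetic_mM = NA_real_,
                        hcl_mM = NA_real_, feasible = FALSE,
                        reason = NA_character_)[rep(1, nrow(out)), ]
  if (any(simplex_ok)) {
    i <- which(simplex_ok)
    tot[i, ] <- acid_totals_for_target_ph(
      out$pH[i], out$f_asp[i], out$f_glu[i], out$f_hcl[i], out$f_acetic[i],
      histidine = space$histidine, arginine = out$arginine_mM[i],
      db = db, acid_cap_mM = space$acid_cap_mM, strict = FALSE
    )
  }
  out$asp_mM <- tot$asp_mM
  out$glu_mM <- tot$glu_mM
  out$acetic_mM <- tot$acetic_mM
  out$hcl_mM <- tot$hcl_mM
  out$histidine_mM <- space$histidine
  out$osmolality_mOsm_kg <- ifelse(tot$feasible,
                                   estimate_osmolality(out), NA_real_)
  reason <- character(nrow(out))
  reason[!simplex_ok] <- "fraction simplex violated"
  solver_bad <- simplex_ok & !tot$feasible
  reason[solver_bad] <- paste0("inverse pH solve: ", tot$reason[solver_bad])
  osmo_bad <- tot$feasible & (out$osmolality_mOsm_kg < space$osmolality[1] |
                                out$osmolality_mOsm_kg > space$osmolality[2])
  reason[osmo_bad] <- "osmolality outside window"
  out$feasible <- reason == ""
  out$reason <- ifelse(out$feasible, NA_character_, reason)
  out
}

#' Feasibility report for decoded formulations
#'
#' Re-checks the three constraints that define the feasible region: the acid
#' fraction simplex (`f_asp + f_glu + f_hcl <= 1`), the osmolality window,
#' and success of the inverse pH solve (non-NA acid totals).
#'
#' @param formulation A tibble as returned by [decode_points()].
#' @param space A [design_space()].
#' @return The input with `feasible` recomputed plus a `violations` list
#'   column naming each violated constraint.
#' @export
check_feasibility <- function(formulation, space = design_space()) {
  fsum <- formulation$f_asp + formulation$f_glu + formulation$f_hcl
  solver_ok <- !is.na(formulation$hcl_mM)
  osmo <- formulation$osmolality_mOsm_kg
  viol <- purrr::pmap(
    list(fsum > 1 + 1e-12, !solver_ok,
         solver_ok & !is.na(osmo) &
           (osmo < space$osmolality[1] | osmo > space$osmolality[2])),
    function(f, s, o) {
      c(if (f) "fraction simplex violated",
        if (s) "inverse pH solve failed",
        if (o) "osmolality outside window")
    }
  )
  formulation$feasible <- lengths(viol) == 0L
  formulation$violations <- viol
  formulation
}

# Feasibility predicate on the unit cube: U (n x 6 matrix) -> logical n.
# Pure vector math (no tibble allocation): this predicate sits in the inner
# loop of every rejection-sampled genetic move and simplex iterate, so it is
# the hottest path in the package. Kept numerically identical to
# decode_points() + the constraint checks (a property test asserts this).
unit_cube_feasible <- function(space = design_space(), db = species_db()) {
  zc_at <- function(nm, ph) {
    i <- match(nm, db$component)
    average_charge(db$pkas[[i]], db$z_max[i], ph, db$strong[i])
  }
  function(U) {
    if (is.null(dim(U))) U <- matrix(U, nrow = 1L)
    aff <- function(x, r) r[1] + x * (r[2] - r[1])
    s <- aff(U[, 1], space$sorbitol)
    a <- aff(U[, 2], space$arginine)
    ph <- aff(U[, 3], space$ph)
    fr <- space$fractions
    f_asp <- aff(U[, 4], fr); f_glu <- aff(U[, 5], fr)
    f_hcl <- aff(U[, 6], fr)
    f_acetic <- 1 - (f_asp + f_glu + f_hcl)
    ok <- f_acetic >= -1e-12
    f_acetic <- pmax(f_acetic, 0)
    h <- 10^(-ph)
    base <- h - 1e-14 / h + space$histidine / 1000 * zc_at("his", ph) +
      a / 1000 * zc_at("arg", ph)
    slope <- f_asp * zc_at("asp", ph) + f_glu * zc_at("glu", ph) +
      f_acetic * zc_at("acetic", ph) - f_hcl
    total <- -base / slope * 1000
    ok <- ok & total >= 0 & total <= space$acid_cap_mM
    osmo <- s + space$histidine + a + total
    ok & !is.na(osmo) & osmo >= space$osmolality[1] &
      osmo <= space$osmolality[2]
  }
}

# Composition list (mM) of one decoded formulation row, for forward checks.
composition_of <- function(formulation) {
  tibble::tibble(
    his = formulation$histidine_mM, arg = formulation$arginine_mM,
    asp = formulation$asp_mM, glu = formulation$glu_mM,
    acetic = formulation$acetic_mM, hcl = formulation$hcl_mM,
    sorbitol = formulation$sorbitol_mM
  )
}
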