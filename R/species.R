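#' Acid-base species database
#'
#' The speciation tables used to reconstruct buffer compositions. Each row is
#' one titratable component with its pKa ladder and the charge of the fully
#' protonated form (`z_max`). Average charge at a given pH follows from the
#' alpha fractions of the successive deprotonation states. Values are
#' standard biochemistry-handbook pKas at 25 degrees C; the table is an
#' ordinary tibble, so alternative pKa sets can be supplied to any chemistry
#' function that accepts a `db` argument.
#'
#' Components:
#' * `his` L-histidine (pKa 1.82, 6.04, 9.17; +2 fully protonated)
#' * `arg` L-arginine (pKa 2.03, 9.00, 12.10; +2)
#' * `asp` L-aspartic acid (pKa 1.99, 3.90, 9.90; +1)
#' * `glu` L-glutamic acid (pKa 2.10, 4.07, 9.47; +1)
#' * `acetic` acetic acid (pKa 4.76; 0)
#' * `hcl` hydrochloric acid, fully dissociated (charge -1 contribution)
#' * `sorbitol` non-ionizable
#'
#' @return A tibble with columns `component`, `pkas` (list of numeric
#'   vectors), `z_max`, and `strong` (TRUE for fully dissociated acids).
#' @examples
#' species_db()
#' @export
species_db <- function() {
  tibble::tibble(
    component = c("his", "arg", "asp", "glu", "acetic", "hcl", "sorbitol"),
    pkas = list(
      c(1.82, 6.04, 9.17),
      c(2.03, 9.00, 12.10),
      c(1.99, 3.90, 9.90),
      c(2.10, 4.07, 9.47),
      4.76,
      numeric(0),
      numeric(0)
    ),
    z_max = c(2, 2, 1, 1, 0, -1, 0),
    strong = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Alpha fractions of a polyprotic component
#'
#' Fraction of each protonation state at the given pH values, from the pKa
#' ladder. State `j` has lost `j` protons relative to the fully protonated
#' form; weights are accumulated on the log10 scale for numerical stability.
#'
#' @param pkas Numeric vector of successive pKa values (may be empty).
#' @param ph Numeric vector of pH values.
#' @return A matrix with `length(ph)` rows and `length(pkas) + 1` columns;
#'   rows sum to one.
#' @export
alpha_fractions <- function(pkas, ph) {
  k <- length(pkas)
  if (k == 0L) return(matrix(1, nrow = length(ph), ncol = 1L))
  # log10 unnormalized weight of state j: sum_{i<=j} (ph - pKa_i)
  cs <- outer(ph, pkas, `-`)
  if (k > 1L) for (j in 2:k) cs[, j] <- cs[, j - 1L] + cs[, j]
  lw <- cbind(0, cs)
  m <- lw[, 1L]
  for (j in 2:ncol(lw)) m <- pmax(m, lw[, j])
  w <- 10^(lw - m)
  w / rowSums(w)
}

# Average (concentration-weighted) charge of a component at the given pH.
# Vectorized over ph; strong acids contribute their fixed counter-ion
# charge. Equivalent to weighting the charge ladder by alpha_fractions(),
# written without the intermediate matrices: this sits inside the bisection
# loop of the pH solver.
average_charge <- function(pkas, z_max, ph, strong = FALSE) {
  if (strong || length(pkas) == 0L) return(rep(z_max, length(ph)))
  w <- rep(1, length(ph))
  den <- w
  num <- z_max * w
  for (j in seq_along(pkas)) {
    w <- w * 10^(ph - pkas[j])
    den <- den + w
    num <- num + (z_max - j) * w
  }
  num / den
}

#' Speciation table of a buffer composition
#'
#' Expands a composition into individual charge-state species at a given pH,
#' including H+ and OH- from water autoionization (Kw = 1e-14). Species
#' concentrations of each component sum to its analytical concentration, and
#' at the solved pH of the mixture the signed charges balance.
#'
#' @param composition Named list or one-row data frame of analytical
#'   concentrations in mM. Recognized names are the components of
#'   [species_db()]; missing names default to 0.
#' @param ph pH at which to speciate.
#' @param db Species database, see [species_db()].
#' @return A tibble with columns `component`, `charge`, `conc_mM`.
#' @examples
#' species_table(list(his = 10, hcl = 5), ph = 6)
#' @export
species_table <- function(composition, ph, db = species_db()) {
  comp <- normalize_composition(composition, db)
  rows <- purrr::pmap(db, function(component, pkas, z_max, strong, ...) {
    c_mm <- comp[[component]]
    if (c_mm <= 0) return(NULL)
    if (strong || length(pkas) == 0L) {
      return(tibble::tibble(component = component, charge = z_max,
                            conc_mM = c_mm))
    }
    a <- drop(alpha_fractions(pkas, ph))
    tibble::tibble(component = component,
                   charge = z_max - seq(0, length(pkas)),
                   conc_mM = c_mm * a)
  })
  water <- tibble::tibble(
    component = c("H+", "OH-"),
    charge = c(1, -1),
    conc_mM = c(10^(-ph), 1e-14 / 10^(-ph)) * 1000
  )
  dplyr::bind_rows(rows, water)
}

# Fill a composition list with zeros for absent components; reject unknowns
# and negative concentrations.
normalize_composition <- function(composition, db = species_db()) {
  comp <- as.list(composition)
  unknown <- setdiff(names(comp), db$component)
  if (length(unknown) > 0) {
    abort(paste0("unknown component(s): ", paste(unknown, collapse = ", ")),
          class = "formubo_config_error")
  }
  out <- setNames(as.list(rep(0, nrow(db))), db$component)
  for (nm in names(comp)) out[[nm]] <- comp[[nm]]
  bad <- vapply(out, function(x) any(x < 0), logical(1))
  if (any(bad)) {
    abort("negative concentration(s) in composition",
          class = "formubo_config_error")
  }
  out
}
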