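#' Define a chemical substance
#'
#' A lightweight record of a substance's name and molar mass, used to turn
#' weighed masses into mole fractions.
#'
#' @param name Character name of the substance.
#' @param molar_mass Molar mass in g/mol; must be strictly positive.
#'
#' @return An object of class `"substance"`.
#' @examples
#' substance("emtricitabine", 247.24)
#' @export
substance <- function(name, molar_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0) {
    stop("'molar_mass' must be a single positive number (g/mol)", call. = FALSE)
  }
  structure(list(name = name, molar_mass = as.numeric(molar_mass)),
            class = "substance")
}

#' @export
print.substance <- function(x, ...) {
  cat(sprintf("<substance> %s (M = %g g/mol)\n", x$name, x$molar_mass))
  invisible(x)
}

#' Mole-fraction solubility from weighed masses
#'
#' Converts the masses of dissolved solute and solvent(s) in a saturated
#' solution into the mole-fraction solubility of the solute,
#' \deqn{x_e = \frac{m_1/M_1}{m_1/M_1 + m_2/M_2 + m_3/M_3},}
#' where subscript 1 is the solute, 2 the cosolvent and 3 the antisolvent
#' (water).  With `m3 = 0` (or `antisolvent = NULL`) this reduces to the
#' binary two-component form.
#'
#' @param m1,m2,m3 Masses in g of solute, cosolvent and antisolvent.  `m1`
#'   must be positive and at least one of `m2`, `m3` positive.
#' @param solute,cosolvent,antisolvent [substance()] objects supplying the
#'   molar masses.  `antisolvent` may be `NULL` for a binary system.
#'
#' @return The mole fraction of the solute, a number in (0, 1).
#' @examples
#' ect <- substance("emtricitabine", 247.24)
#' peg <- substance("PEG-400", 400)
#' h2o <- substance("water", 18.07)
#' mole_fraction(2.4724, 4.0, 0, ect, peg)           # one mole each -> 0.5
#' mole_fraction(1, 2, 3, ect, peg, h2o)
#' @export
mole_fraction <- function(m1, m2, m3 = 0, solute, cosolvent,
                          antisolvent = NULL) {
  for (nm in c("m1", "m2", "m3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  if (m1 <= 0) stop("solute mass 'm1' must be positive", call. = FALSE)
  if (m2 < 0 || m3 < 0) stop("solvent masses must be non-negative", call. = FALSE)
  if (m2 + m3 <= 0) stop("at least one solvent mass must be positive", call. = FALSE)
  if (m3 > 0 && is.null(antisolvent)) {
    stop("'antisolvent' substance required when m3 > 0", call. = FALSE)
  }
  stopifnot(inherits(solute, "substance"), inherits(cosolvent, "substance"))
  n1 <- m1 / solute$molar_mass
  n2 <- m2 / cosolvent$molar_mass
  n3 <- if (m3 > 0) m3 / antisolvent$molar_mass else 0
  n1 / (n1 + n2 + n3)
}
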