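#' Mean harmonic temperature
#'
#' The reference temperature for apparent dissolution thermodynamics,
#' \eqn{T_{hm} = n / \sum_i 1/T_i}.
#'
#' @param temperature Non-empty vector of positive absolute temperatures (K).
#' @return The harmonic mean, K.
#' @examples
#' harmonic_mean_temperature(c(298.2, 303.2, 308.2, 313.2, 318.2))  # 308.03
#' @export
harmonic_mean_temperature <- function(temperature) {
  if (length(temperature) == 0L) stop("empty temperature list", call. = FALSE)
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperatures must be positive (K)", call. = FALSE)
  }
  length(temperature) / sum(1 / temperature)
}

#' Apparent dissolution thermodynamics for one composition
#'
#' Fits the modified van't Hoff regression of \eqn{\ln x_e} on
#' \eqn{(1/T - 1/T_{hm})} by ordinary least squares and extracts the
#' apparent standard thermodynamic functions of dissolution:
#' \deqn{\Delta_{sol}H^0 = -R\,\mathrm{slope},\qquad
#'       \Delta_{sol}G^0 = -R\,T_{hm}\,\mathrm{intercept},\qquad
#'       \Delta_{sol}S^0 = (\Delta_{sol}H^0 - \Delta_{sol}G^0)/T_{hm}.}
#' Centring the inverse temperature on the harmonic mean makes the intercept
#' equal \eqn{\ln x_e} at \eqn{T_{hm}}, so enthalpy and Gibbs energy are
#' estimated with minimal correlation.
#'
#' @param x Mole-fraction solubilities at one composition, all in (0, 1).
#' @param temperature Matching absolute temperatures (K), at least 3
#'   distinct values.
#' @param t_hm Mean harmonic temperature (K); defaults to the harmonic mean
#'   of `temperature`.
#' @param R Gas constant, J/mol/K.
#' @param m Optional composition label stored in the result.
#'
#' @return An object of class `"thermo_result"`: list with `m`, `dsol_h`
#'   (kJ/mol), `dsol_g` (kJ/mol), `dsol_s` (J/mol/K), `r_squared`, `slope`
#'   (K), `intercept`, `t_hm` (K).
#' @examples
#' ect <- ect_solubility()
#' vant_hoff_thermo(ect$x["0.0", ], ect$temperature)
#' @export
vant_hoff_thermo <- function(x, temperature,
                             t_hm = harmonic_mean_temperature(temperature),
                             R = 8.314, m = NA_real_) {
  if (length(x) != length(temperature)) {
    stop("'x' and 'temperature' must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("at least 3 temperature points are required", call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) stop("solubilities must lie in (0, 1)", call. = FALSE)
  if (length(unique(temperature)) < 2L) {
    stop("degenerate design: no temperature variation", call. = FALSE)
  }
  z <- 1 / temperature - 1 / t_hm
  fit <- stats::lm(log(x) ~ z)
  cf <- stats::coef(fit)
  dsol_h <- -R * cf[[2L]] / 1000            # kJ/mol
  dsol_g <- -R * t_hm * cf[[1L]] / 1000     # kJ/mol
  dsol_s <- (dsol_h - dsol_g) / t_hm * 1000 # J/mol/K
  structure(list(m = m, dsol_h = dsol_h, dsol_g = dsol_g, dsol_s = dsol_s,
                 r_squared = stats::cor(log(x), stats::fitted(fit))^2,
                 slope = cf[[2L]], intercept = cf[[1L]], t_hm = t_hm),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "dissolution thermodynamics%s at T_hm = %.2f K\n  dH = %.2f kJ/mol, dG = %.2f kJ/mol, dS = %.2f J/mol/K (R2 = %.4f)\n",
    if (is.na(x$m)) "" else sprintf(" (m = %g)", x$m), x$t_hm,
    x$dsol_h, x$dsol_g, x$dsol_s, x$r_squared))
  invisible(x)
}

#' Dissolution thermodynamics across a solubility table
#'
#' Applies [vant_hoff_thermo()] to every composition of a solubility table,
#' using one common mean harmonic temperature computed from the table's
#' temperature grid.
#'
#' @param table A [solubility_table()] with at least 3 temperatures.
#' @param R Gas constant, J/mol/K.
#'
#' @return A data frame of class `"dissolution_thermo"` with columns `m`,
#'   `dsol_h` (kJ/mol), `dsol_g` (kJ/mol), `dsol_s` (J/mol/K), `r_squared`,
#'   `slope`, `intercept`; attribute `t_hm` carries the unrounded harmonic
#'   mean temperature.
#' @examples
#' thermo_profile(ect_solubility())
#' @export
thermo_profile <- function(table, R = 8.314) {
  stopifnot(inherits(table, "solubility_table"))
  t_hm <- harmonic_mean_temperature(table$temperature)
  rows <- lapply(seq_along(table$m), function(i) {
    r <- vant_hoff_thermo(table$x[i, ], table$temperature, t_hm = t_hm,
                          R = R, m = table$m[i])
    data.frame(m = r$m, dsol_h = r$dsol_h, dsol_g = r$dsol_g,
               dsol_s = r$dsol_s, r_squared = r$r_squared,
               slope = r$slope, intercept = r$intercept)
  })
  out <- do.call(rbind, rows)
  attr(out, "t_hm") <- t_hm
  attr(out, "R") <- R
  class(out) <- c("dissolution_thermo", "data.frame")
  out
}

#' @export
print.dissolution_thermo <- function(x, ...) {
  cat(sprintf("Apparent dissolution thermodynamics at T_hm = %.2f K\n",
              attr(x, "t_hm")))
  df <- data.frame(m = x$m,
                   `dH (kJ/mol)` = sprintf("%.2f", x$dsol_h),
                   `dG (kJ/mol)` = sprintf("%.2f", x$dsol_g),
                   `dS (J/mol/K)` = sprintf("%.2f", x$dsol_s),
                   R2 = sprintf("%.4f", x$r_squared),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enthalpy-entropy compensation analysis
#'
#' Collects the (\eqn{\Delta_{sol}G^0}, \eqn{\Delta_{sol}H^0}) pairs across
#' solvent compositions and fits an ordinary least-squares line through them.
#' A positive slope is conventionally read as enthalpy-driven solvation.
#' With fewer than two distinct points the slope is undefined and returned
#' as `NA`.
#'
#' @param thermo A `"dissolution_thermo"` data frame from [thermo_profile()],
#'   with at least 2 rows.
#'
#' @return An object of class `"compensation_series"`: list with `points`
#'   (data frame `m`, `dsol_g`, `dsol_h`, ordered by `m`), `slope`,
#'   `intercept`, `pearson_r` and `driving_force`
#'   (`"enthalpy"`, `"entropy"` or `NA`).
#' @examples
#' compensation_analysis(thermo_profile(ect_solubility()))
#' @export
compensation_analysis <- function(thermo) {
  stopifnot(inherits(thermo, "dissolution_thermo") ||
              (is.data.frame(thermo) && all(c("m", "dsol_g", "dsol_h") %in% names(thermo))))
  if (nrow(thermo) < 2L) stop("at least 2 compositions are required", call. = FALSE)
  pts <- thermo[order(thermo$m), c("m", "dsol_g", "dsol_h")]
  degenerate <- stats::var(pts$dsol_g) == 0
  if (degenerate) {
    slope <- NA_real_; intercept <- NA_real_; r <- NA_real_
  } else {
    fit <- stats::lm(dsol_h ~ dsol_g, data = pts)
    slope <- stats::coef(fit)[[2L]]
    intercept <- stats::coef(fit)[[1L]]
    r <- stats::cor(pts$dsol_g, pts$dsol_h)
  }
  structure(list(points = pts, slope = slope, intercept = intercept,
                 pearson_r = r,
                 driving_force = if (is.na(slope)) NA_character_
                                 else if (slope > 0) "enthalpy" else "entropy"),
            class = "compensation_series")
}

#' @export
print.compensation_series <- function(x, ...) {
  cat(sprintf(
    "Enthalpy-entropy compensation: %d points, OLS slope = %s (r = %s)\n",
    nrow(x$points),
    if (is.na(x$slope)) "undefined" else sprintf("%.3f", x$slope),
    if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r)))
  if (!is.na(x$driving_force)) {
    cat(sprintf("  classified as %s-driven solvation\n", x$driving_force))
  }
  invisible(x)
}

#' @export
plot.compensation_series <- function(x, ...) {
  graphics::plot(x$points$dsol_g, x$points$dsol_h,
                 xlab = expression(Delta[sol] * G^0 ~ "(kJ/mol)"),
                 ylab = expression(Delta[sol] * H^0 ~ "(kJ/mol)"),
                 main = "Enthalpy-entropy compensation", ...)
  if (!is.na(x$slope)) graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
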