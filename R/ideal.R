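#' Fusion properties of a crystalline solute
#'
#' Bundles the calorimetric quantities needed for the ideal-solubility
#' expression: fusion temperature, molar fusion enthalpy, and the difference
#' between the liquid- and solid-state molar heat capacities.
#'
#' @param t_fus Fusion (melting) temperature, K.
#' @param dh_fus Molar fusion enthalpy, J/mol.
#' @param dcp Heat-capacity difference, J/mol/K (default 0, which recovers
#'   the classical van't Hoff ideal-solubility form).
#' @param name Optional solute name.
#'
#' @return An object of class `"fusion_properties"`.
#' @examples
#' ect_fusion()
#' fusion_properties(427.80, 32370, 75.66, "emtricitabine")
#' @export
fusion_properties <- function(t_fus, dh_fus, dcp = 0, name = NULL) {
  if (!is.numeric(t_fus) || t_fus <= 0) stop("'t_fus' must be positive (K)", call. = FALSE)
  if (!is.numeric(dh_fus) || dh_fus <= 0) stop("'dh_fus' must be positive (J/mol)", call. = FALSE)
  if (!is.numeric(dcp) || dcp < 0) stop("'dcp' must be non-negative (J/mol/K)", call. = FALSE)
  structure(list(t_fus = as.numeric(t_fus), dh_fus = as.numeric(dh_fus),
                 dcp = as.numeric(dcp), name = name),
            class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf("<fusion_properties>%s T_fus = %.2f K, dH_fus = %.4g kJ/mol, dCp = %.4g J/mol/K\n",
              if (is.null(x$name)) "" else paste0(" ", x$name, ":"),
              x$t_fus, x$dh_fus / 1000, x$dcp))
  invisible(x)
}

#' @rdname fusion_properties
#' @details `ect_fusion()` returns the thermal-analysis values for
#'   emtricitabine: 427.80 K, 32.37 kJ/mol, 75.66 J/mol/K.
#' @export
ect_fusion <- function() {
  fusion_properties(427.80, 32370, 75.66, name = "emtricitabine")
}

#' Read fusion properties from a configuration file
#'
#' YAML or JSON with fields `t_fus` (K), `dh_fus` (kJ/mol, converted to
#' J/mol internally), `dcp` (J/mol/K) and optional `name`.
#'
#' @param path Path to the config file.
#' @return A [fusion_properties()] object.
#' @export
read_fusion_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fusion_properties(cfg$t_fus, cfg$dh_fus * 1000,
                    if (is.null(cfg$dcp)) 0 else cfg$dcp, cfg$name)
}

#' Ideal mole-fraction solubility from fusion properties
#'
#' Solubility of the crystalline solute predicted from its fusion
#' thermodynamics alone (activity coefficient 1):
#' \deqn{\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
#'   + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
#'   + \ln\frac{T}{T_{fus}}\right].}
#' At `T = t_fus` both terms vanish and the ideal solubility is exactly 1.
#'
#' @param temperature Absolute temperature(s) in K, each in (0, `t_fus`\].
#' @param fp A [fusion_properties()] object.
#' @param R Gas constant, J/mol/K.
#'
#' @return Ideal mole-fraction solubility, same length as `temperature`.
#' @examples
#' ideal_solubility(298.2, ect_fusion())   # 3.74e-2
#' @export
ideal_solubility <- function(temperature, fp, R = 8.314) {
  stopifnot(inherits(fp, "fusion_properties"))
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (any(temperature > fp$t_fus)) {
    stop("temperature above the fusion point: the solid phase no longer exists",
         call. = FALSE)
  }
  tf <- fp$t_fus
  lnx <- -fp$dh_fus * (tf - temperature) / (R * tf * temperature) +
    (fp$dcp / R) * ((tf - temperature) / temperature + log(temperature / tf))
  exp(lnx)
}

#' Activity coefficients from experimental and ideal solubility
#'
#' The activity coefficient of the solute in each solvent composition,
#' \eqn{\gamma_i = x^{idl}/x_e}, quantifying the departure from ideal
#' solution behaviour: values below 1 indicate solute-solvent interactions
#' stronger than in the ideal solution.
#'
#' @param table A [solubility_table()].
#' @param fp A [fusion_properties()] object for the solute.
#' @param R Gas constant, J/mol/K.
#'
#' @return An object of class `"activity_table"`: list with `m`,
#'   `temperature`, `gamma` (matrix aligned with the input grid) and
#'   `x_ideal` (the ideal-solubility row over temperature).
#' @examples
#' act <- activity_coefficients(ect_solubility(), ect_fusion())
#' round(act$gamma["0.0", ], 2)
#' @export
activity_coefficients <- function(table, fp, R = 8.314) {
  stopifnot(inherits(table, "solubility_table"))
  xidl <- ideal_solubility(table$temperature, fp, R = R)
  gamma <- sweep(1 / table$x, 2L, xidl, "*")
  structure(list(m = table$m, temperature = table$temperature,
                 gamma = gamma, x_ideal = xidl),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Activity coefficients (x_ideal / x_e)\n")
  print(round(x$gamma, 2))
  cat("x_ideal:", sprintf("%.3g", x$x_ideal), "\n")
  invisible(x)
}
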