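#' Run the full cosolvency analysis pipeline
#'
#' Composes every stage of the analysis on one solubility table: echo of the
#' data, ideal solubility and activity coefficients (if fusion properties
#' are supplied), the Hansen blend profile (if solvent parameters are
#' supplied), apparent dissolution thermodynamics with enthalpy-entropy
#' compensation, and the five-model cosolvency comparison.  Stage failures
#' are caught, recorded under `$errors` by stage name, and the remaining
#' sections are still produced.
#'
#' @param table A [solubility_table()].
#' @param fusion Optional [fusion_properties()]; enables the ideal
#'   solubility and activity sections.
#' @param hsp Optional named numeric with `delta_cosolvent` and
#'   `delta_antisolvent` (MPa^0.5); enables the Hansen blend section.
#' @param n_terms Interaction terms for the Jouyban-Acree family.
#' @param R Gas constant, J/mol/K.
#'
#' @return An object of class `"cosolv_report"`: list with sections
#'   `table`, `ideal`, `activity`, `hsp`, `thermo`, `compensation`,
#'   `comparison`, `errors` (named character), and `provenance`.
#' @examples
#' rep <- run_full_analysis(ect_solubility(), ect_fusion(),
#'                          hsp = c(delta_cosolvent = 18.90,
#'                                  delta_antisolvent = 47.80))
#' rep$thermo
#' @export
run_full_analysis <- function(table, fusion = NULL, hsp = NULL,
                              n_terms = 1L, R = 8.314) {
  stopifnot(inherits(table, "solubility_table"))
  errors <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  ideal <- activity <- NULL
  if (!is.null(fusion)) {
    ideal <- stage("ideal", {
      data.frame(temperature = table$temperature,
                 x_ideal = ideal_solubility(table$temperature, fusion, R = R))
    })
    activity <- stage("activity", activity_coefficients(table, fusion, R = R))
  } else {
    errors[["ideal"]] <- errors[["activity"]] <-
      "unavailable: no fusion properties supplied"
  }
  hsp_profile_out <- if (!is.null(hsp)) {
    stage("hsp", hansen_profile(table$m, hsp[["delta_cosolvent"]],
                                hsp[["delta_antisolvent"]]))
  } else NULL
  thermo <- stage("thermo", thermo_profile(table, R = R))
  compensation <- if (!is.null(thermo)) {
    stage("compensation", compensation_analysis(thermo))
  } else NULL
  comparison <- stage("models", compare_models(table, n_terms = n_terms))
  structure(list(
    table = table, ideal = ideal, activity = activity,
    hsp = hsp_profile_out, thermo = thermo, compensation = compensation,
    comparison = comparison, errors = errors,
    provenance = list(
      package = "cosolvency",
      version = as.character(utils::packageVersion("cosolvency")),
      gas_constant = R, n_terms = n_terms,
      n_compositions = length(table$m),
      n_temperatures = length(table$temperature),
      fusion = if (is.null(fusion)) NULL else
        fusion[c("t_fus", "dh_fus", "dcp")],
      hsp = if (is.null(hsp)) NULL else as.list(hsp))),
    class = "cosolv_report")
}

#' @export
print.cosolv_report <- function(x, ...) {
  cat("== Cosolvency analysis report ==\n\n")
  cat("-- Solubility data --\n"); print(x$table); cat("\n")
  if (!is.null(x$ideal)) {
    cat("-- Ideal solubility --\n")
    print(data.frame(temperature = x$ideal$temperature,
                     x_ideal = sprintf("%.3g", x$ideal$x_ideal)),
          row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$activity)) { cat("-- Activity coefficients --\n"); print(x$activity); cat("\n") }
  if (!is.null(x$hsp)) { cat("-- Hansen blend profile --\n"); print(x$hsp); cat("\n") }
  if (!is.null(x$thermo)) { cat("-- Dissolution thermodynamics --\n"); print(x$thermo); cat("\n") }
  if (!is.null(x$compensation)) { print(x$compensation); cat("\n") }
  if (!is.null(x$comparison)) { print(x$comparison); cat("\n") }
  if (length(x$errors)) {
    cat("-- Skipped/failed sections --\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serialises a [run_full_analysis()] report: full-precision JSON for
#' machine use and/or a fixed-format text rendering for side-by-side
#' reading.  Output contains no timestamps, so regeneration from identical
#' inputs is byte-identical.
#'
#' @param report A `"cosolv_report"`.
#' @param json,text Optional output paths.
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json = NULL, text = NULL) {
  stopifnot(inherits(report, "cosolv_report"))
  if (!is.null(json)) {
    payload <- list(
      solubility = list(m = report$table$m,
                        temperature = report$table$temperature,
                        x = as.vector(t(report$table$x))),
      ideal = report$ideal,
      activity = if (is.null(report$activity)) NULL else
        list(gamma = as.vector(t(report$activity$gamma)),
             x_ideal = report$activity$x_ideal),
      hsp = if (is.null(report$hsp)) NULL else as.data.frame(report$hsp),
      thermo = if (is.null(report$thermo)) NULL else
        c(as.list(as.data.frame(report$thermo)),
          list(t_hm = attr(report$thermo, "t_hm"))),
      compensation = if (is.null(report$compensation)) NULL else
        report$compensation[c("points", "slope", "pearson_r")],
      models = if (is.null(report$comparison)) NULL else
        lapply(attr(report$comparison, "fits"), function(f)
          list(params = f$params, per_m = f$per_m,
               overall_rmsd = f$overall_rmsd)),
      errors = as.list(report$errors),
      provenance = report$provenance)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(text)) {
    con <- file(text, open = "wt")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  }
  invisible(report)
}
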