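#' Construct a solubility table
#'
#' The central data container: a complete grid of equilibrium mole-fraction
#' solubilities `x` of one solute, indexed by cosolvent mass fraction `m`
#' (rows) and absolute temperature in kelvin (columns).
#'
#' Rows and columns are canonicalised to strictly increasing `m` and
#' temperature; the matrix is permuted consistently.  All cells must be
#' present and lie strictly inside (0, 1).
#'
#' @param m Numeric vector of cosolvent mass fractions in \[0, 1\], no
#'   duplicates.
#' @param temperature Numeric vector of absolute temperatures (K), positive,
#'   no duplicates.
#' @param x Numeric matrix of mole-fraction solubilities,
#'   `length(m)` x `length(temperature)`, all values in (0, 1).
#' @param solute,cosolvent,antisolvent Optional [substance()] metadata.
#'
#' @return An object of class `"solubility_table"`: a list with elements
#'   `m`, `temperature`, `x` and the three substances.
#' @examples
#' solubility_table(c(0, 1), c(298.2, 318.2),
#'                  matrix(c(0.008, 0.011, 0.106, 0.145), nrow = 2, byrow = TRUE))
#' @export
solubility_table <- function(m, temperature, x, solute = NULL,
                             cosolvent = NULL, antisolvent = NULL) {
  m <- as.numeric(m)
  temperature <- as.numeric(temperature)
  x <- as.matrix(x)
  if (anyNA(m) || anyNA(temperature)) {
    stop("'m' and 'temperature' must not contain missing values", call. = FALSE)
  }
  if (any(m < 0 | m > 1)) stop("mass fractions must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(m)) stop("duplicate mass fractions", call. = FALSE)
  if (any(temperature <= 0)) stop("temperatures must be positive (kelvin)", call. = FALSE)
  if (anyDuplicated(temperature)) stop("duplicate temperatures", call. = FALSE)
  if (nrow(x) != length(m) || ncol(x) != length(temperature)) {
    stop(sprintf("solubility matrix must be %d x %d, got %d x %d",
                 length(m), length(temperature), nrow(x), ncol(x)),
         call. = FALSE)
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing solubility at m = %g, T = %g K",
                 m[bad[1L]], temperature[bad[2L]]), call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) {
    bad <- which(x <= 0 | x >= 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("solubility out of (0, 1) at m = %g, T = %g K",
                 m[bad[1L]], temperature[bad[2L]]), call. = FALSE)
  }
  ord_m <- order(m)
  ord_t <- order(temperature)
  obj <- list(m = m[ord_m], temperature = temperature[ord_t],
              x = x[ord_m, ord_t, drop = FALSE],
              solute = solute, cosolvent = cosolvent, antisolvent = antisolvent)
  dimnames(obj$x) <- list(format(obj$m), format(obj$temperature))
  class(obj) <- "solubility_table"
  obj
}

#' @export
print.solubility_table <- function(x, digits = 3, ...) {
  cat(sprintf("<solubility_table> %d compositions x %d temperatures\n",
              length(x$m), length(x$temperature)))
  if (!is.null(x$solute)) {
    cat(sprintf("  solute: %s", x$solute$name))
    if (!is.null(x$cosolvent)) cat(sprintf("; cosolvent: %s", x$cosolvent$name))
    if (!is.null(x$antisolvent)) cat(sprintf("; antisolvent: %s", x$antisolvent$name))
    cat("\n")
  }
  print(signif(x$x, digits), ...)
  invisible(x)
}

#' @export
as.data.frame.solubility_table <- function(x, ...) {
  data.frame(m = rep(x$m, times = length(x$temperature)),
             temperature = rep(x$temperature, each = length(x$m)),
             x = as.vector(x$x))
}

#' @rdname solubility_table
#' @param table A `solubility_table`.
#' @export
is_complete_grid <- function(table) {
  inherits(table, "solubility_table") && !anyNA(table$x)
}

# pull one composition row; m matched exactly
solubility_column <- function(table, m) {
  i <- match(m, table$m)
  if (is.na(i)) stop(sprintf("composition m = %g not in table", m), call. = FALSE)
  table$x[i, ]
}

#' Emtricitabine in PEG-400 + water: packaged solubility data
#'
#' Loads the packaged equilibrium mole-fraction solubility grid of
#' emtricitabine in polyethylene glycol 400 + water mixtures: 11 cosolvent
#' mass fractions (0 to 1 in steps of 0.1) by 5 temperatures (298.2 to
#' 318.2 K in steps of 5 K), measured at ambient pressure by the isothermal
#' shake-flask method with HPLC quantification.  Values are as published, to
#' three significant figures; all downstream fits in this package treat them
#' as exact.
#'
#' @return A [solubility_table()] with substance metadata (emtricitabine
#'   247.24 g/mol, PEG-400 400 g/mol, water 18.07 g/mol).
#' @examples
#' ect <- ect_solubility()
#' ect$x["0.0", "298.2"]   # 7.95e-3, pure water at 298.2 K
#' @export
ect_solubility <- function() {
  path <- system.file("extdata", "ect_peg400_water.csv",
                      package = "cosolvency", mustWork = TRUE)
  tab <- read_solubility_table(path)
  # transcription integrity: dimensions and strict monotonicity in m and T
  if (length(tab$m) != 11L || length(tab$temperature) != 5L) {
    stop("packaged emtricitabine fixture is corrupted: wrong dimensions",
         call. = FALSE)
  }
  if (any(apply(tab$x, 1L, diff) <= 0) || any(apply(tab$x, 2L, diff) <= 0)) {
    stop("packaged emtricitabine fixture is corrupted: monotonicity violated",
         call. = FALSE)
  }
  tab
}

#' Read and write solubility tables
#'
#' Delimited-text and JSON serialisation of [solubility_table()] objects.
#' The delimited layout has one header row (`m` followed by the
#' temperatures in kelvin), one composition per row, and optional
#' `#`-prefixed metadata lines of the form
#' `# solute: <name>, <molar mass g/mol>` (likewise `cosolvent`,
#' `antisolvent`).  A `.json` path round-trips the same schema through JSON.
#' Values survive a write/read round trip at full double precision.
#'
#' @param path File path.  Extension `.json` selects JSON; otherwise
#'   delimited text.
#' @param sep Field separator for delimited text; `NULL` (default) sniffs
#'   comma vs tab from the header line.
#' @param table A `solubility_table` to write.
#'
#' @return `read_solubility_table()` returns a [solubility_table()];
#'   `write_solubility_table()` returns `path` invisibly.
#' @export
read_solubility_table <- function(path, sep = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    subs <- lapply(j$substances, function(s)
      if (is.null(s)) NULL else substance(s$name, s$molar_mass))
    return(solubility_table(j$m, j$temperature,
                            matrix(j$x, nrow = length(j$m), byrow = TRUE),
                            solute = subs$solute, cosolvent = subs$cosolvent,
                            antisolvent = subs$antisolvent))
  }
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no tabular body found in ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", body[[1L]])) "\t" else ","
  split_row <- function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1L]])
  header <- split_row(body[[1L]])
  if (tolower(header[[1L]]) != "m") {
    stop("first header field must be 'm', got '", header[[1L]], "'", call. = FALSE)
  }
  temps <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(temps)) {
    stop("non-numeric temperature in header column ",
         which(is.na(temps))[1L] + 1L, call. = FALSE)
  }
  rows <- lapply(body[-1L], split_row)
  nfield <- length(header)
  m <- numeric(length(rows))
  xmat <- matrix(NA_real_, nrow = length(rows), ncol = length(temps))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != nfield) {
      stop(sprintf("row %d is ragged: expected %d fields, got %d",
                   i, nfield, length(r)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(r))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop(sprintf("non-numeric cell at row %d (m column %d): '%s'",
                   i, j, r[[j]]), call. = FALSE)
    }
    m[i] <- vals[1L]
    xmat[i, ] <- vals[-1L]
  }
  if (anyDuplicated(m)) {
    stop("duplicate composition key m = ", m[anyDuplicated(m)], call. = FALSE)
  }
  subs <- parse_substance_meta(meta)
  solubility_table(m, temps, xmat, solute = subs$solute,
                   cosolvent = subs$cosolvent, antisolvent = subs$antisolvent)
}

parse_substance_meta <- function(meta) {
  out <- list(solute = NULL, cosolvent = NULL, antisolvent = NULL)
  for (line in meta) {
    mt <- regmatches(line, regexec(
      "^\\s*#\\s*(solute|cosolvent|antisolvent)\\s*:\\s*([^,]+),\\s*([0-9.eE+-]+)",
      line))[[1L]]
    if (length(mt) == 4L) {
      out[[mt[[2L]]]] <- substance(trimws(mt[[3L]]), as.numeric(mt[[4L]]))
    }
  }
  out
}

#' @rdname read_solubility_table
#' @export
write_solubility_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "solubility_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- list(m = table$m, temperature = table$temperature,
              x = as.vector(t(table$x)),
              substances = lapply(
                table[c("solute", "cosolvent", "antisolvent")],
                function(s) if (is.null(s)) NULL else
                  list(name = s$name, molar_mass = s$molar_mass)))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  fmt <- function(v) sprintf("%.17g", v)
  lines <- character(0)
  for (role in c("solute", "cosolvent", "antisolvent")) {
    s <- table[[role]]
    if (!is.null(s)) {
      lines <- c(lines, sprintf("# %s: %s, %g", role, s$name, s$molar_mass))
    }
  }
  lines <- c(lines, paste(c("m", fmt(table$temperature)), collapse = sep))
  for (i in seq_along(table$m)) {
    lines <- c(lines,
               paste(c(fmt(table$m[i]), fmt(table$x[i, ])), collapse = sep))
  }
  writeLines(lines, path)
  invisible(path)
}
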