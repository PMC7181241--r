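#' Total Hansen solubility parameter from its components
#'
#' Combines the dispersion, polar and hydrogen-bonding Hansen components into
#' the total solubility parameter
#' \deqn{\delta = \sqrt{\delta_d^2 + \delta_p^2 + \delta_h^2}.}
#' All quantities are in MPa^0.5.
#'
#' @param dispersion,polar,hydrogen Non-negative component parameters
#'   (MPa^0.5); vectors are combined elementwise.
#'
#' @return Total Hansen parameter(s), MPa^0.5.
#' @examples
#' hansen_total(3, 4, 0)  # 5
#' @export
hansen_total <- function(dispersion, polar, hydrogen) {
  comps <- cbind(dispersion, polar, hydrogen)
  if (any(!is.finite(comps)) || any(comps < 0)) {
    stop("Hansen components must be finite and non-negative", call. = FALSE)
  }
  sqrt(dispersion^2 + polar^2 + hydrogen^2)
}

#' Hansen parameter of a binary solvent blend
#'
#' Linear blending rule for the total Hansen parameter of a cosolvent +
#' antisolvent mixture,
#' \deqn{\delta_{mix} = \alpha\,\delta_1 + (1 - \alpha)\,\delta_2,}
#' with blend weight `fraction` on the cosolvent parameter `delta1`.  The
#' weight is used exactly as supplied; for the packaged emtricitabine system
#' the published blend grid is reproduced with the cosolvent *mass* fraction
#' as the weight.
#'
#' @param fraction Blend weight(s) of the cosolvent, in \[0, 1\].
#' @param delta1 Total Hansen parameter of the cosolvent (MPa^0.5).
#' @param delta2 Total Hansen parameter of the antisolvent (MPa^0.5).
#'
#' @return Blend parameter(s), MPa^0.5.
#' @examples
#' hansen_mix(0.1, 18.90, 47.80)  # 44.91
#' @export
hansen_mix <- function(fraction, delta1, delta2) {
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("blend fraction must lie in [0, 1]", call. = FALSE)
  }
  fraction * delta1 + (1 - fraction) * delta2
}

#' Hansen blend profile over a composition grid
#'
#' Evaluates [hansen_mix()] over a vector of blend fractions.
#'
#' @inheritParams hansen_mix
#' @param fractions Vector of blend weights in \[0, 1\] (may be empty).
#'
#' @return A data frame of class `"hsp_profile"` with columns `fraction` and
#'   `delta_mix`, and attributes `delta1`, `delta2`.
#' @examples
#' hansen_profile(seq(0.1, 0.9, 0.1), 18.90, 47.80)
#' @export
hansen_profile <- function(fractions, delta1, delta2) {
  out <- data.frame(fraction = as.numeric(fractions),
                    delta_mix = if (length(fractions))
                      hansen_mix(fractions, delta1, delta2) else numeric(0))
  attr(out, "delta1") <- delta1
  attr(out, "delta2") <- delta2
  class(out) <- c("hsp_profile", "data.frame")
  out
}

#' @export
print.hsp_profile <- function(x, ...) {
  cat(sprintf("Hansen blend profile (delta1 = %.2f, delta2 = %.2f MPa^0.5)\n",
              attr(x, "delta1"), attr(x, "delta2")))
  df <- data.frame(fraction = x$fraction, delta_mix = sprintf("%.2f", x$delta_mix))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a Hansen parameter configuration
#'
#' Reads a YAML or JSON mapping of substance name to either a scalar total
#' parameter (`delta`) or a component triplet (`dispersion`, `polar`,
#' `hydrogen`), returning total parameters via [hansen_total()] where needed.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named numeric vector of total Hansen parameters (MPa^0.5).
#' @export
read_hsp_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vapply(cfg, function(entry) {
    if (is.list(entry) && all(c("dispersion", "polar", "hydrogen") %in% names(entry))) {
      hansen_total(entry$dispersion, entry$polar, entry$hydrogen)
    } else if (is.numeric(entry) && length(entry) == 1L) {
      as.numeric(entry)
    } else if (is.list(entry) && "delta" %in% names(entry)) {
      as.numeric(entry$delta)
    } else {
      stop("Hansen config entry must be a total delta or a component triplet",
           call. = FALSE)
    }
  }, numeric(1))
}
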