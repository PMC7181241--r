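#' Specify a synthetic solubility surface
#'
#' Defines the generating model for simulated solubility data: a
#' Jouyban-Acree-van't Hoff surface
#' \deqn{\ln x_{m,T} = m_1(a_1 + b_1/T) + m_2(a_2 + b_2/T)
#'   + \frac{m_1 m_2}{T}\sum_i J_i (m_1 - m_2)^i}
#' with multiplicative lognormal measurement noise: independent Gaussian
#' perturbations of standard deviation `log(1 + noise_cv)` added on the
#' ln x scale.
#'
#' The defaults reproduce the emtricitabine / PEG-400 / water study
#' conditions: the published pure-solvent van't Hoff parameters and
#' interaction coefficient, the 11 x 5 (m, T) grid, and a 1.1% relative
#' measurement uncertainty (`noise_cv = 0.011`).
#'
#' @param vanthoff_cosolvent,vanthoff_antisolvent Named numeric `c(a=, b=)`
#'   van't Hoff parameters of the pure cosolvent / antisolvent columns
#'   (`b` in K).
#' @param j Numeric vector of interaction coefficients `J_i` (K), up to 3.
#' @param mass_fractions Composition grid in \[0, 1\].
#' @param temperatures Temperature grid, K.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives exact model values).
#' @param seed Optional integer seed stored with the spec.
#'
#' @return An object of class `"synthetic_spec"`.
#' @examples
#' generate_surface(synthetic_spec(noise_cv = 0, seed = 1))
#' @export
synthetic_spec <- function(vanthoff_cosolvent = c(a = 2.50, b = -1412.30),
                           vanthoff_antisolvent = c(a = 0.94, b = -1724.70),
                           j = 21.32,
                           mass_fractions = seq(0, 1, by = 0.1),
                           temperatures = c(298.2, 303.2, 308.2, 313.2, 318.2),
                           noise_cv = 0.011,
                           seed = NULL) {
  stopifnot(all(c("a", "b") %in% names(vanthoff_cosolvent)),
            all(c("a", "b") %in% names(vanthoff_antisolvent)))
  if (length(j) < 1L || length(j) > 3L) stop("'j' must have 1 to 3 coefficients", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (length(mass_fractions) == 0L || length(temperatures) == 0L) {
    stop("composition and temperature grids must be non-empty", call. = FALSE)
  }
  structure(list(vanthoff_cosolvent = vanthoff_cosolvent,
                 vanthoff_antisolvent = vanthoff_antisolvent,
                 j = as.numeric(j),
                 mass_fractions = sort(as.numeric(mass_fractions)),
                 temperatures = sort(as.numeric(temperatures)),
                 noise_cv = noise_cv, seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d x %d grid, J = (%s), noise_cv = %g%s\n",
              length(x$mass_fractions), length(x$temperatures),
              paste(x$j, collapse = ", "), x$noise_cv,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Generate a synthetic solubility table
#'
#' Draws one solubility surface from the generating model of a
#' [synthetic_spec()].  Deterministic under a fixed seed; with
#' `noise_cv = 0` the returned values are the exact model surface.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec` (may be
#'   `NULL`, in which case the current RNG state is used).
#'
#' @return A [solubility_table()].
#' @export
generate_surface <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- list(a1 = spec$vanthoff_cosolvent[["a"]],
                 b1 = spec$vanthoff_cosolvent[["b"]],
                 a2 = spec$vanthoff_antisolvent[["a"]],
                 b2 = spec$vanthoff_antisolvent[["b"]],
                 j = spec$j)
  xmat <- predict_javh_matrix(spec$mass_fractions, spec$temperatures, params)
  if (spec$noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- matrix(stats::rnorm(length(xmat), sd = log1p(spec$noise_cv)),
                    nrow = nrow(xmat))
    xmat <- xmat * exp(noise)
  }
  bad <- which(xmat >= 1 | xmat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("generated solubility out of (0, 1) at m = %g, T = %g K",
                 spec$mass_fractions[bad[1L, 1L]],
                 spec$temperatures[bad[1L, 2L]]), call. = FALSE)
  }
  solubility_table(spec$mass_fractions, spec$temperatures, xmat)
}

#' Parameter-recovery experiment on synthetic surfaces
#'
#' Repeatedly generates surfaces from a [synthetic_spec()], refits the
#' chosen cosolvency model, and summarises how well each generating
#' parameter is recovered: bias (mean estimate minus truth) and root mean
#' square error across replicates.  Fit failures are caught and counted,
#' not raised.
#'
#' For the per-composition `"vanthoff"` and `"apelblat"` models the true
#' column parameters are derived from the generating surface, which is
#' exactly linear in 1/T at every fixed composition with
#' \eqn{a(m) = m_1 a_1 + m_2 a_2} and
#' \eqn{b(m) = m_1 b_1 + m_2 b_2 + m_1 m_2 \sum_i J_i (m_1-m_2)^i}
#' (for Apelblat, C(m) = 0); their summaries report one row per composition
#' and parameter.
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicates Number of simulated datasets (>= 1).
#' @param model Model name as in [fit_cosolvency()].
#' @param n_terms Interaction terms for the Jouyban-Acree family.
#' @param seed Integer seed for the replicate stream; defaults to the
#'   spec's seed.
#'
#' @return A data frame of class `"recovery_summary"` with columns
#'   `parameter`, `true`, `mean`, `bias`, `rmse`; attribute `n_failed`
#'   counts failed fits.
#' @examples
#' spec <- synthetic_spec(noise_cv = 0.011, seed = 7)
#' recovery_experiment(spec, n_replicates = 5, model = "javh")
#' @export
recovery_experiment <- function(spec, n_replicates, model = "javh",
                                n_terms = length(spec$j), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1L)
  truth <- true_parameters(spec, model, n_terms)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  est <- matrix(NA_real_, n_replicates, length(truth),
                dimnames = list(NULL, names(truth)))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    got <- tryCatch({
      tab <- generate_surface(spec, seed = rep_seeds[r])
      fit <- fit_cosolvency(tab, model, n_terms = n_terms)
      flatten_parameters(fit)
    }, error = function(e) NULL)
    if (is.null(got)) n_failed <- n_failed + 1L else est[r, names(got)] <- got
  }
  ok <- stats::complete.cases(est)
  out <- data.frame(parameter = names(truth), true = unname(truth),
                    mean = colMeans(est[ok, , drop = FALSE]))
  out$bias <- out$mean - out$true
  out$rmse <- sqrt(colMeans((est[ok, , drop = FALSE] -
                               rep(truth, each = sum(ok)))^2))
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("recovery_summary", "data.frame")
  out
}

true_parameters <- function(spec, model, n_terms) {
  a1 <- spec$vanthoff_cosolvent[["a"]]; b1 <- spec$vanthoff_cosolvent[["b"]]
  a2 <- spec$vanthoff_antisolvent[["a"]]; b2 <- spec$vanthoff_antisolvent[["b"]]
  jj <- spec$j
  m1 <- spec$mass_fractions; m2 <- 1 - m1
  mixb <- m1 * m2 * drop(outer(m1 - m2, seq_along(jj) - 1L, `^`) %*% jj)
  a_m <- m1 * a1 + m2 * a2
  b_m <- m1 * b1 + m2 * b2 + mixb
  pad_j <- function(k) c(jj, rep(0, k))[seq_len(max(k, length(jj)))]
  switch(model,
    vanthoff = stats::setNames(c(rbind(a_m, b_m)),
                               c(rbind(sprintf("a[m=%g]", m1), sprintf("b[m=%g]", m1)))),
    apelblat = stats::setNames(c(rbind(a_m, b_m, 0 * m1)),
                               c(rbind(sprintf("A[m=%g]", m1), sprintf("B[m=%g]", m1),
                                       sprintf("C[m=%g]", m1)))),
    yalkowsky = stop("the Yalkowsky-Roseman rule has no fitted parameters", call. = FALSE),
    jouyban = stats::setNames(c(jj, rep(0, n_terms))[seq_len(n_terms)],
                              paste0("j", seq_len(n_terms) - 1L)),
    javh = stats::setNames(c(a1, b1, a2, b2,
                             c(jj, rep(0, n_terms))[seq_len(n_terms)]),
                           c("a1", "b1", "a2", "b2",
                             paste0("j", seq_len(n_terms) - 1L))),
    stop("unknown model '", model, "'", call. = FALSE))
}

flatten_parameters <- function(fit) {
  p <- fit$params
  switch(fit$model,
    vanthoff = stats::setNames(c(rbind(p$a, p$b)),
                               c(rbind(sprintf("a[m=%g]", p$m), sprintf("b[m=%g]", p$m)))),
    apelblat = stats::setNames(c(rbind(p$A, p$B, p$C)),
                               c(rbind(sprintf("A[m=%g]", p$m), sprintf("B[m=%g]", p$m),
                                       sprintf("C[m=%g]", p$m)))),
    jouyban = stats::setNames(p$j, paste0("j", seq_along(p$j) - 1L)),
    javh = stats::setNames(c(p$a1, p$b1, p$a2, p$b2, p$j),
                           c("a1", "b1", "a2", "b2",
                             paste0("j", seq_along(p$j) - 1L))))
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed fits)\n",
              attr(x, "n_replicates"), attr(x, "n_failed")))
  print(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
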