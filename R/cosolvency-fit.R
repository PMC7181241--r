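#' Percent root-mean-square relative deviation
#'
#' The model-validation metric used throughout: the root mean square of the
#' relative deviations between observed and predicted mole-fraction
#' solubilities, expressed in percent,
#' \deqn{\%RMSD = 100\sqrt{\frac{1}{N}\sum_i
#'   \left(\frac{x_i^{obs}-x_i^{pred}}{x_i^{obs}}\right)^2}.}
#'
#' @param observed Observed mole fractions, all strictly positive.
#' @param predicted Predicted mole fractions, same length.
#' @return The percent RMSD, a non-negative scalar.
#' @examples
#' rmsd_percent(c(0.01, 0.02), c(0.011, 0.022))  # uniform +10% error -> 10
#' @export
rmsd_percent <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(observed <= 0)) stop("observed solubilities must be positive", call. = FALSE)
  100 * sqrt(mean(((observed - predicted) / observed)^2))
}

#' Fit a cosolvency solubility model
#'
#' Fits one of five correlation models for mole-fraction solubility over a
#' (composition, temperature) grid.  Writing `m1` for the cosolvent mass
#' fraction, `m2 = 1 - m1`, `x1`/`x2` for the pure-cosolvent/pure-water
#' solubility columns and `T` for absolute temperature:
#'
#' * `"vanthoff"` — per composition, \eqn{\ln x = a + b/T} (OLS of ln x on
#'   1/T; 2 parameters per composition).
#' * `"apelblat"` — per composition, \eqn{\ln x = A + B/T + C\ln T} (linear
#'   least squares; 3 parameters per composition).
#' * `"yalkowsky"` — the parameter-free log-linear mixing rule
#'   \eqn{\log_{10} x = m_1\log_{10} x_1 + m_2\log_{10} x_2}, anchored on the
#'   observed pure-solvent columns and evaluated at the intermediate
#'   compositions.
#' * `"jouyban"` — the Jouyban-Acree model
#'   \eqn{\ln x_{m,T} = m_1\ln x_1 + m_2\ln x_2 +
#'     \frac{m_1 m_2}{T}\sum_{i=0}^{k-1} J_i (m_1-m_2)^i}, with the `J_i`
#'   obtained by no-intercept least squares pooled over all intermediate
#'   cells.
#' * `"javh"` — the Jouyban-Acree-van't Hoff model, replacing the observed
#'   pure columns by their van't Hoff fits:
#'   \eqn{\ln x_{m,T} = m_1(A_1 + B_1/T) + m_2(A_2 + B_2/T) +
#'     \frac{m_1 m_2}{T}\sum_i J_i (m_1-m_2)^i}.  Fitted in two stages:
#'   \eqn{(A_1,B_1)}, \eqn{(A_2,B_2)} from the pure columns, then the `J_i`
#'   by no-intercept least squares on the residual.
#'
#' Every fit is validated by the per-composition percent RMSD of
#' [rmsd_percent()]; the overall figure is the unweighted mean of the
#' per-composition values (over the intermediate compositions for
#' `"yalkowsky"`, which does not predict the anchors; over all compositions
#' otherwise).
#'
#' @param table A [solubility_table()].  The mixing models (`"yalkowsky"`,
#'   `"jouyban"`, `"javh"`) require both pure-solvent rows `m = 0` and
#'   `m = 1`.
#' @param model One of `"vanthoff"`, `"apelblat"`, `"yalkowsky"`,
#'   `"jouyban"`, `"javh"`.
#' @param n_terms Number of interaction coefficients `J_i` (1 to 3) for the
#'   Jouyban-Acree family.  Default 1.
#'
#' @return An object of class `c("cosolv_fit_<model>", "cosolv_fit")`, a
#'   list with elements `model`, `params`, `n_params`, `predicted` (matrix
#'   of predicted mole fractions aligned with `table$x`), `per_m` (data
#'   frame of per-composition `rmsd` and, where defined, `r_squared`),
#'   `overall_rmsd`, and the input `table`.
#' @seealso [compare_models()], [predict.cosolv_fit()]
#' @examples
#' fit <- fit_cosolvency(ect_solubility(), "jouyban")
#' coef(fit)
#' fit$overall_rmsd
#' @export
fit_cosolvency <- function(table,
                           model = c("vanthoff", "apelblat", "yalkowsky",
                                     "jouyban", "javh"),
                           n_terms = 1L) {
  stopifnot(inherits(table, "solubility_table"))
  model <- match.arg(model)
  fitter <- switch(model,
                   vanthoff = fit_vanthoff_table,
                   apelblat = fit_apelblat_table,
                   yalkowsky = fit_yalkowsky_table,
                   jouyban = function(tab) fit_jouyban_table(tab, n_terms),
                   javh = function(tab) fit_javh_table(tab, n_terms))
  out <- fitter(table)
  out$model <- model
  out$table <- table
  # per-composition %RMSD on the rows the model predicts
  keep <- !is.na(out$predicted[, 1L])
  rmsd <- rep(NA_real_, length(table$m))
  rmsd[keep] <- vapply(which(keep), function(i)
    rmsd_percent(table$x[i, ], out$predicted[i, ]), numeric(1))
  out$per_m <- data.frame(m = table$m, rmsd = rmsd,
                          r_squared = if (is.null(out$r_squared))
                            NA_real_ else out$r_squared)
  out$r_squared <- NULL
  out$overall_rmsd <- mean(rmsd[keep])
  class(out) <- c(paste0("cosolv_fit_", model), "cosolv_fit")
  out
}

# ---- per-model fitters (internal) -----------------------------------------

# single-column OLS of ln x on 1/T; returns intercept a, slope b, R2 (ln scale)
vanthoff_column <- function(x, temperature) {
  if (length(x) < 3L) stop("at least 3 temperature points are required", call. = FALSE)
  fit <- stats::lm(log(x) ~ I(1 / temperature))
  c(a = stats::coef(fit)[[1L]], b = stats::coef(fit)[[2L]],
    r2 = stats::cor(log(x), stats::fitted(fit))^2)
}

fit_vanthoff_table <- function(table) {
  cf <- t(vapply(seq_along(table$m), function(i)
    vanthoff_column(table$x[i, ], table$temperature), numeric(3)))
  pred <- exp(outer(cf[, "a"], rep(1, length(table$temperature))) +
                outer(cf[, "b"], 1 / table$temperature))
  list(params = data.frame(m = table$m, a = cf[, "a"], b = cf[, "b"]),
       n_params = 2L * length(table$m),
       predicted = pred, r_squared = cf[, "r2"])
}

fit_apelblat_table <- function(table) {
  tv <- table$temperature
  if (length(tv) < 4L) {
    stop("Apelblat model needs at least 4 temperature points", call. = FALSE)
  }
  X <- cbind(1, 1 / tv, log(tv))
  # narrow temperature spans make 1/T and ln T nearly collinear
  if (kappa(qr.R(qr(scale(X[, -1L])))) > 1e3) {
    warning("near-singular Apelblat design: 1/T and ln(T) are almost collinear over this temperature range",
            call. = FALSE)
  }
  cf <- t(vapply(seq_along(table$m), function(i) {
    fit <- stats::lm.fit(X, log(table$x[i, ]))
    if (fit$rank < 3L) stop("singular Apelblat design", call. = FALSE)
    r2 <- stats::cor(log(table$x[i, ]), X %*% fit$coefficients)^2
    c(fit$coefficients, r2)
  }, numeric(4)))
  pred <- exp(cf[, 1:3, drop = FALSE] %*% t(X))
  list(params = data.frame(m = table$m, A = cf[, 1L], B = cf[, 2L], C = cf[, 3L]),
       n_params = 3L * length(table$m),
       predicted = pred, r_squared = cf[, 4L])
}

require_pure_columns <- function(table) {
  if (!all(c(0, 1) %in% table$m)) {
    stop("mixing models require both pure-solvent rows (m = 0 and m = 1)",
         call. = FALSE)
  }
  list(x1 = solubility_column(table, 1),   # pure cosolvent
       x2 = solubility_column(table, 0))   # pure antisolvent (water)
}

fit_yalkowsky_table <- function(table) {
  pure <- require_pure_columns(table)
  pred <- matrix(NA_real_, length(table$m), length(table$temperature),
                 dimnames = dimnames(table$x))
  mid <- table$m > 0 & table$m < 1
  for (i in which(mid)) {
    pred[i, ] <- 10^(table$m[i] * log10(pure$x1) +
                       (1 - table$m[i]) * log10(pure$x2))
  }
  list(params = NULL, n_params = 0L, predicted = pred, r_squared = NULL)
}

# mixing regressors m1*m2*(m1-m2)^i / T for i = 0..n_terms-1
jouyban_design <- function(m1, temperature, n_terms) {
  m2 <- 1 - m1
  Z <- matrix(0, length(m1), n_terms)
  for (i in seq_len(n_terms)) Z[, i] <- m1 * m2 * (m1 - m2)^(i - 1L) / temperature
  Z
}

check_n_terms <- function(table, n_terms) {
  if (!is.numeric(n_terms) || n_terms < 1L || n_terms > 3L) {
    stop("'n_terms' must be 1, 2 or 3", call. = FALSE)
  }
  n_mid <- sum(table$m > 0 & table$m < 1)
  if (n_mid < n_terms) {
    stop(sprintf("insufficient data: %d interaction terms but only %d intermediate compositions",
                 n_terms, n_mid), call. = FALSE)
  }
  as.integer(n_terms)
}

fit_jouyban_table <- function(table, n_terms = 1L) {
  n_terms <- check_n_terms(table, n_terms)
  pure <- require_pure_columns(table)
  mid <- which(table$m > 0 & table$m < 1)
  grid <- expand.grid(i = mid, j = seq_along(table$temperature))
  m1 <- table$m[grid$i]
  tv <- table$temperature[grid$j]
  base <- m1 * log(pure$x1[grid$j]) + (1 - m1) * log(pure$x2[grid$j])
  resid <- log(table$x[cbind(grid$i, grid$j)]) - base
  Z <- jouyban_design(m1, tv, n_terms)
  j_coef <- drop(solve(crossprod(Z), crossprod(Z, resid)))
  pred <- predict_jouyban(table$m, table$temperature, pure, j_coef)
  list(params = list(j = j_coef), n_params = n_terms,
       predicted = pred, r_squared = NULL)
}

predict_jouyban <- function(m, temperature, pure, j_coef) {
  lnp <- matrix(NA_real_, length(m), length(temperature))
  for (i in seq_along(m)) {
    m1 <- m[i]; m2 <- 1 - m1
    mix <- m1 * m2 / temperature *
      drop(outer((m1 - m2), seq_along(j_coef) - 1L, `^`) %*% j_coef)
    lnp[i, ] <- m1 * log(pure$x1) + m2 * log(pure$x2) + mix
  }
  exp(lnp)
}

fit_javh_table <- function(table, n_terms = 1L) {
  n_terms <- check_n_terms(table, n_terms)
  require_pure_columns(table)
  tv <- table$temperature
  vh1 <- vanthoff_column(solubility_column(table, 1), tv)  # pure cosolvent
  vh2 <- vanthoff_column(solubility_column(table, 0), tv)  # pure water
  mid <- which(table$m > 0 & table$m < 1)
  grid <- expand.grid(i = mid, j = seq_along(tv))
  m1 <- table$m[grid$i]
  tg <- tv[grid$j]
  base <- m1 * (vh1[["a"]] + vh1[["b"]] / tg) +
    (1 - m1) * (vh2[["a"]] + vh2[["b"]] / tg)
  resid <- log(table$x[cbind(grid$i, grid$j)]) - base
  Z <- jouyban_design(m1, tg, n_terms)
  j_coef <- drop(solve(crossprod(Z), crossprod(Z, resid)))
  params <- list(a1 = vh1[["a"]], b1 = vh1[["b"]],
                 a2 = vh2[["a"]], b2 = vh2[["b"]], j = j_coef)
  pred <- predict_javh_matrix(table$m, tv, params)
  list(params = params, n_params = 4L + n_terms,
       predicted = pred, r_squared = NULL)
}

predict_javh_matrix <- function(m, temperature, params) {
  lnp <- matrix(NA_real_, length(m), length(temperature))
  for (i in seq_along(m)) {
    m1 <- m[i]; m2 <- 1 - m1
    mix <- m1 * m2 / temperature *
      drop(outer((m1 - m2), seq_along(params$j) - 1L, `^`) %*% params$j)
    lnp[i, ] <- m1 * (params$a1 + params$b1 / temperature) +
      m2 * (params$a2 + params$b2 / temperature) + mix
  }
  exp(lnp)
}

# ---- methods --------------------------------------------------------------

#' @export
print.cosolv_fit <- function(x, ...) {
  label <- c(vanthoff = "van't Hoff", apelblat = "Apelblat",
             yalkowsky = "Yalkowsky-Roseman", jouyban = "Jouyban-Acree",
             javh = "Jouyban-Acree-van't Hoff")[[x$model]]
  cat(sprintf("%s cosolvency fit (%d parameter%s)\n", label, x$n_params,
              if (x$n_params == 1L) "" else "s"))
  cat(sprintf("  overall %%RMSD: %.2f over %d compositions\n",
              x$overall_rmsd, sum(!is.na(x$per_m$rmsd))))
  if (!is.null(x$params)) {
    cat("  parameters:\n")
    if (is.data.frame(x$params)) {
      print(format(x$params, digits = 4), row.names = FALSE)
    } else {
      utils::str(x$params, give.attr = FALSE, digits.d = 6)
    }
  }
  invisible(x)
}

#' @export
coef.cosolv_fit <- function(object, ...) object$params

#' @export
fitted.cosolv_fit <- function(object, ...) object$predicted

#' Residuals of a cosolvency fit
#'
#' Log-scale residuals \eqn{\ln x^{obs} - \ln x^{pred}}, the scale on which
#' every model in the family is linear.
#'
#' @param object A `cosolv_fit`.
#' @param ... Unused.
#' @export
residuals.cosolv_fit <- function(object, ...) {
  log(object$table$x) - log(object$predicted)
}

#' Predict solubility from a fitted cosolvency model
#'
#' @param object A `cosolv_fit` from [fit_cosolvency()].
#' @param m Cosolvent mass fraction(s).  The per-composition models
#'   (`vanthoff`, `apelblat`) only predict at fitted compositions; the
#'   mixing models accept any `m` in \[0, 1\].
#' @param temperature Absolute temperature(s), K.  Models anchored on the
#'   observed pure columns (`yalkowsky`, `jouyban`) only predict at the
#'   fitted temperatures; `vanthoff`, `apelblat` and `javh` are parametric
#'   in T.
#' @param ... Unused.
#'
#' @return Matrix of predicted mole fractions, `length(m)` rows by
#'   `length(temperature)` columns.
#' @export
predict.cosolv_fit <- function(object, m = object$table$m,
                               temperature = object$table$temperature, ...) {
  tab <- object$table
  p <- object$params
  switch(object$model,
    vanthoff = {
      idx <- match_m(m, p$m)
      exp(outer(p$a[idx], rep(1, length(temperature))) +
            outer(p$b[idx], 1 / temperature))
    },
    apelblat = {
      idx <- match_m(m, p$m)
      exp(cbind(p$A[idx], p$B[idx], p$C[idx]) %*%
            rbind(1, 1 / temperature, log(temperature)))
    },
    yalkowsky = {
      jdx <- match_temperature(temperature, tab$temperature)
      pure <- require_pure_columns(tab)
      lnp <- outer(m, log(pure$x1[jdx])) + outer(1 - m, log(pure$x2[jdx]))
      exp(lnp)
    },
    jouyban = {
      jdx <- match_temperature(temperature, tab$temperature)
      pure <- require_pure_columns(tab)
      pure$x1 <- pure$x1[jdx]; pure$x2 <- pure$x2[jdx]
      predict_jouyban(m, temperature, pure, p$j)
    },
    javh = predict_javh_matrix(m, temperature, p))
}

match_m <- function(m, fitted_m) {
  idx <- match(m, fitted_m)
  if (anyNA(idx)) {
    stop("this per-composition model only predicts at fitted compositions; ",
         "unknown m = ", paste(m[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

match_temperature <- function(temperature, fitted_t) {
  jdx <- match(temperature, fitted_t)
  if (anyNA(jdx)) {
    stop("this model is anchored on observed pure-solvent columns and only ",
         "predicts at fitted temperatures", call. = FALSE)
  }
  jdx
}

#' @export
summary.cosolv_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cosolv_fit")
}

#' @export
print.summary.cosolv_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-composition %RMSD:\n")
  df <- x$fit$per_m
  df$rmsd <- sprintf("%.2f", df$rmsd)
  df$r_squared <- ifelse(is.na(x$fit$per_m$r_squared), "",
                         sprintf("%.4f", x$fit$per_m$r_squared))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cosolv_fit <- function(x, ...) {
  tab <- x$table
  invT <- 1 / tab$temperature
  graphics::matplot(invT, t(log(tab$x)), pch = 1, col = seq_along(tab$m),
                    xlab = "1/T (1/K)", ylab = "ln x",
                    main = sprintf("%s fit", x$model), ...)
  ok <- which(!is.na(x$predicted[, 1L]))
  graphics::matlines(invT, t(log(x$predicted[ok, , drop = FALSE])),
                     lty = 1, col = ok)
  invisible(x)
}

#' Rank the five cosolvency models on one dataset
#'
#' Fits all five models of [fit_cosolvency()] to the same table and ranks
#' them by overall percent RMSD.
#'
#' @param table A [solubility_table()] with both pure-solvent rows.
#' @param n_terms Interaction terms for the Jouyban-Acree family.
#'
#' @return A data frame of class `"cosolv_comparison"` with columns `model`,
#'   `n_params`, `overall_rmsd`, ordered best first; the fitted objects are
#'   attached as attribute `fits`.
#' @examples
#' compare_models(ect_solubility())
#' @export
compare_models <- function(table, n_terms = 1L) {
  models <- c("vanthoff", "apelblat", "yalkowsky", "jouyban", "javh")
  fits <- lapply(models, function(mm) fit_cosolvency(table, mm, n_terms = n_terms))
  out <- data.frame(model = models,
                    n_params = vapply(fits, `[[`, integer(1), "n_params"),
                    overall_rmsd = vapply(fits, `[[`, numeric(1), "overall_rmsd"))
  out <- out[order(out$overall_rmsd), ]
  rownames(out) <- NULL
  attr(out, "fits") <- stats::setNames(fits, models)
  class(out) <- c("cosolv_comparison", "data.frame")
  out
}

#' @export
print.cosolv_comparison <- function(x, ...) {
  cat("Cosolvency model comparison (best first)\n")
  df <- data.frame(model = x$model, n_params = x$n_params,
                   `overall %RMSD` = sprintf("%.2f", x$overall_rmsd),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
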