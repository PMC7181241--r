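test_that("percent RMSD is the root mean square relative deviation", {
  expect_equal(rmsd_percent(c(0.01, 0.02, 0.3), c(0.01, 0.02, 0.3)), 0)
  # uniform +10% error -> exactly 10
  expect_equal(rmsd_percent(c(0.01, 0.02), c(0.011, 0.022)), 10,
               tolerance = 1e-12)
  expect_error(rmsd_percent(c(0.1, 0.2), 0.1), "equal length")
  expect_error(rmsd_percent(c(0, 0.2), c(0.1, 0.2)), "positive")
})

test_that("van't Hoff fits recover exact log-linear data", {
  temps <- ect_temps
  tab <- make_table(c(0.2, 0.8), temps,
                    function(m, T) exp((2.50 - m) + (-1412.30 + 100 * m) / T))
  fit <- fit_cosolvency(tab, "vanthoff")
  expect_equal(fit$params$a, c(2.30, 1.70), tolerance = 1e-9)
  expect_equal(fit$params$b, c(-1392.30, -1332.30), tolerance = 1e-7)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-9)
  expect_equal(unname(fit$per_m$r_squared), c(1, 1), tolerance = 1e-9)
  expect_error(fit_cosolvency(make_table(0.5, c(300, 310),
                                         function(m, T) 0.01 + 0 * T),
                              "vanthoff"),
               "at least 3")
})

test_that("Apelblat fits recover exact three-parameter data", {
  temps <- ect_temps
  A <- -81.15; B <- 2029.00; C <- 12.20
  tab <- make_table(0, temps, function(m, T) exp(A + B / T + C * log(T)))
  fit <- fit_cosolvency(tab, "apelblat")
  expect_equal(fit$params$A, A, tolerance = 1e-6)
  expect_equal(fit$params$B, B, tolerance = 1e-6)
  expect_equal(fit$params$C, C, tolerance = 1e-6)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-6)

  # a very narrow temperature span makes 1/T and ln T collinear
  narrow <- make_table(0, c(300, 300.5, 301, 301.5),
                       function(m, T) exp(1 - 1500 / T))
  expect_warning(fit_cosolvency(narrow, "apelblat"), "collinear")
})

test_that("every least-squares fit agrees with a normal-equations oracle", {
  ect <- ect_solubility()
  temps <- ect$temperature

  # van't Hoff, each composition
  vh <- fit_cosolvency(ect, "vanthoff")
  for (i in seq_along(ect$m)) {
    oracle <- ols_normal_equations(cbind(1, 1 / temps), log(ect$x[i, ]))
    expect_equal(unname(c(vh$params$a[i], vh$params$b[i])), unname(oracle),
                 tolerance = 1e-9)
  }

  # Apelblat, each composition.  The 1/T-lnT design is ill-conditioned, so
  # the explicit normal-equations solve is itself the precision bottleneck:
  # coefficients agree to ~1e-6 while the fitted surfaces agree to 1e-10.
  ap <- fit_cosolvency(ect, "apelblat")
  X <- cbind(1, 1 / temps, log(temps))
  for (i in seq_along(ect$m)) {
    oracle <- ols_normal_equations(X, log(ect$x[i, ]))
    expect_equal(unname(unlist(ap$params[i, c("A", "B", "C")])),
                 unname(oracle), tolerance = 1e-6)
    expect_equal(unname(log(ap$predicted[i, ])), unname(drop(X %*% oracle)),
                 tolerance = 1e-10)
  }

  # Jouyban-Acree pooled no-intercept design over intermediate cells
  ja <- fit_cosolvency(ect, "jouyban", n_terms = 2)
  mid <- which(ect$m > 0 & ect$m < 1)
  grid <- expand.grid(i = mid, j = seq_along(temps))
  m1 <- ect$m[grid$i]; tg <- temps[grid$j]
  y <- log(ect$x[cbind(grid$i, grid$j)]) -
    m1 * log(ect$x[11, grid$j]) - (1 - m1) * log(ect$x[1, grid$j])
  Z <- cbind(m1 * (1 - m1) / tg, m1 * (1 - m1) * (2 * m1 - 1) / tg)
  expect_equal(unname(ja$params$j), unname(ols_normal_equations(Z, y)),
               tolerance = 1e-9)
})

test_that("Yalkowsky-Roseman mixing rule anchors on the pure columns", {
  ect <- ect_solubility()
  fit <- fit_cosolvency(ect, "yalkowsky")
  expect_equal(fit$n_params, 0L)
  # pure compositions are not scored but predict() returns them exactly
  expect_true(all(is.na(fit$per_m$rmsd[c(1, 11)])))
  expect_equal(unname(predict(fit, m = 1)[1, ]), unname(ect$x["1.0", ]),
               tolerance = 1e-12)
  expect_equal(unname(predict(fit, m = 0)[1, ]), unname(ect$x["0.0", ]),
               tolerance = 1e-12)
  # published mixing row at m = 0.9, log10 scale, printed to 2 decimals
  expect_equal(unname(log10(fit$predicted["0.9", ])),
               c(-1.08, -1.04, -1.01, -0.98, -0.94), tolerance = 0.011)
  # pure columns required
  no_pure <- solubility_table(c(0.2, 0.5, 0.8), ect$temperature,
                              ect$x[c(3, 6, 9), ])
  expect_error(fit_cosolvency(no_pure, "yalkowsky"), "pure-solvent")
})

test_that("Jouyban-Acree model nests the Yalkowsky-Roseman rule at J = 0", {
  ect <- ect_solubility()
  yal <- fit_cosolvency(ect, "yalkowsky")
  pure <- list(x1 = ect$x["1.0", ], x2 = ect$x["0.0", ])
  ja_zero <- cosolvency:::predict_jouyban(ect$m, ect$temperature, pure, 0)
  mid <- 2:10
  expect_equal(unname(ja_zero[mid, ]), unname(yal$predicted[mid, ]),
               tolerance = 1e-12)
  # and data generated by the mixing rule alone is fitted with J ~ 0
  gen <- solubility_table(ect$m, ect$temperature, ja_zero)
  refit <- fit_cosolvency(gen, "jouyban")
  expect_equal(unname(refit$params$j), 0, tolerance = 1e-9)
  expect_equal(refit$overall_rmsd, 0, tolerance = 1e-9)
})

test_that("Jouyban-Acree recovers a known interaction coefficient exactly", {
  spec <- synthetic_spec(j = 50, noise_cv = 0)
  tab <- generate_surface(spec)
  fit <- fit_cosolvency(tab, "jouyban")
  expect_equal(unname(fit$params$j), 50, tolerance = 1e-9)
  expect_error(fit_cosolvency(tab, "jouyban", n_terms = 5), "'n_terms'")
  two_mid <- solubility_table(c(0, 0.4, 1), tab$temperature, tab$x[c(1, 5, 11), ])
  expect_error(fit_cosolvency(two_mid, "jouyban", n_terms = 3),
               "insufficient data")
})

test_that("JAVH is exact on its own surface and nests van't Hoff when pure", {
  spec <- synthetic_spec(noise_cv = 0)
  tab <- generate_surface(spec)
  fit <- fit_cosolvency(tab, "javh")
  expect_equal(fit$params$a1, 2.50, tolerance = 1e-6)
  expect_equal(fit$params$b1, -1412.30, tolerance = 1e-6)
  expect_equal(fit$params$a2, 0.94, tolerance = 1e-6)
  expect_equal(fit$params$b2, -1724.70, tolerance = 1e-6)
  expect_equal(unname(fit$params$j), 21.32, tolerance = 1e-6)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-8)

  # at the pure compositions JAVH equals the van't Hoff fit of that column
  ect <- ect_solubility()
  javh <- fit_cosolvency(ect, "javh")
  vh <- fit_cosolvency(ect, "vanthoff")
  expect_equal(unname(javh$predicted[c(1, 11), ]),
               unname(vh$predicted[c(1, 11), ]), tolerance = 1e-12)
})

test_that("model comparison ranks all five models", {
  cmp <- compare_models(ect_solubility())
  expect_equal(nrow(cmp), 5L)
  expect_setequal(cmp$model,
                  c("vanthoff", "apelblat", "yalkowsky", "jouyban", "javh"))
  expect_false(is.unsorted(cmp$overall_rmsd))
  expect_equal(cmp$n_params[cmp$model == "javh"], 5L)

  # on a noiseless van't Hoff surface (no interaction) the van't Hoff
  # family fits perfectly
  tab <- generate_surface(synthetic_spec(j = 0, noise_cv = 0))
  cmp0 <- compare_models(tab)
  rm0 <- with(cmp0, setNames(overall_rmsd, model))
  expect_lt(rm0[["vanthoff"]], 1e-9)
  expect_lt(rm0[["javh"]], 1e-9)
  expect_lt(rm0[["apelblat"]], 1e-6)
})

test_that("predict() works on new grids and guards its domain", {
  ect <- ect_solubility()
  javh <- fit_cosolvency(ect, "javh")
  p <- predict(javh, m = c(0.25, 0.75), temperature = c(300, 325))
  expect_equal(dim(p), c(2L, 2L))
  expect_true(all(p > 0 & p < 1))
  vh <- fit_cosolvency(ect, "vanthoff")
  expect_error(predict(vh, m = 0.33), "fitted compositions")
  ja <- fit_cosolvency(ect, "jouyban")
  expect_error(predict(ja, temperature = 299), "fitted temperatures")
  expect_equal(unname(predict(ja)), unname(ja$predicted), tolerance = 1e-12)
})
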