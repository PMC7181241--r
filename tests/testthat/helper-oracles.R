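# independent least-squares oracle: explicit normal-equations solve,
# deliberately distinct from the lm/lm.fit path used by the package
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# small helper: build a table from a function of (m, T) on a given grid
make_table <- function(m, temperature, fn) {
  x <- outer(m, temperature, fn)
  solubility_table(m, temperature, x)
}

ect_m <- seq(0, 1, by = 0.1)
ect_temps <- c(298.2, 303.2, 308.2, 313.2, 318.2)
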