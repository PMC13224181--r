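# Shared fixtures built in code.

# small thermodynamic table with realistic energetics, generated from a
# seed; logS computed through the parametrized model when coef given,
# otherwise through the cycle
make_thermo_table <- function(n = 44, seed = 1, coef = NULL, noise_sd = 0) {
  set.seed(seed)
  d <- data.frame(
    dG_solv = rnorm(n, -40, 12),
    dH_sub = rnorm(n, 100, 20),
    dS_sub = rnorm(n, 180, 40),
    V_m = exp(rnorm(n, log(0.15), 0.3))
  )
  d$logS <- if (is.null(coef)) {
    logS_from_cycle(d$dG_solv, d$dH_sub, d$dS_sub, d$V_m)
  } else {
    thermo_model_predict(coef, d$dG_solv, d$dH_sub, d$dS_sub, d$V_m)
  }
  d$logS <- d$logS + rnorm(n, 0, noise_sd)
  d
}

# a small feature matrix with named columns and target
make_fm <- function(n = 40, p = 5, seed = 1, target = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%02d", seq_len(p))))
  if (is.null(target)) target <- rnorm(n)
  feature_matrix(X, target = target)
}

# write a compound csv and return its path
write_compound_csv <- function(df, dir = tempdir()) {
  path <- tempfile("compounds", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
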