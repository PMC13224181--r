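## Thermodynamic cycle of dissolution.
##
## Solubility is modeled through the cycle crystal -> gas -> solution:
## dG_sol = dG_sub + dG_solv, with dG_sub = dH_sub - T * dS_sub, and the
## free energy of solution related to the intrinsic solubility S0 by
## dG_sol = -ln(10) R T log10(S0 * V_m).  The sublimation enthalpy is
## obtained from the per-molecule lattice energy through the empirical
## offset dH_sub = -U_latt - 2RT, and the sublimation entropy from
## dS_sub = dS_vib - (dS_trans + dS_rot).

#' Per-molecule lattice energy from crystal and molecular energies
#'
#' The cohesive (lattice) energy is the total energy of the periodic
#' crystal unit cell minus the sum of the energies of its Z isolated
#' molecules, normalized by Z.
#'
#' @param E_cryst total energy of the unit cell (any energy unit, per cell).
#' @param E_mol numeric vector of isolated-molecule energies, one per
#'   molecule in the unit cell (same unit as `E_cryst`).
#' @param Z number of molecules per unit cell; must equal `length(E_mol)`.
#' @return Per-molecule lattice energy, `(E_cryst - sum(E_mol)) / Z`.
#'   Negative for bound crystals.
#' @examples
#' lattice_energy(-10, rep(-2.4, 4), Z = 4)
#' @export
lattice_energy <- function(E_cryst, E_mol, Z = length(E_mol)) {
  stopifnot(is.numeric(E_cryst), length(E_cryst) == 1L, is.numeric(E_mol))
  if (length(E_mol) != Z || Z < 1L) {
    stop("`E_mol` must contain exactly Z >= 1 molecular energies (got ",
         length(E_mol), " for Z = ", Z, ")", call. = FALSE)
  }
  (E_cryst - sum(E_mol)) / Z
}

#' Sublimation enthalpy from the lattice energy
#'
#' dH_sub = -U_latt - 2RT.  The -2RT term is the standard empirical
#' correction converting a static per-molecule cohesive energy into a
#' finite-temperature sublimation enthalpy.
#'
#' @param U_latt per-molecule lattice energy in kJ/mol (negative for a
#'   bound crystal).
#' @param T_K temperature in kelvin (>= 0).
#' @return Sublimation enthalpy in kJ/mol.
#' @examples
#' dH_sub_from_Ulatt(-100)  # 95.042 kJ/mol at 298.15 K
#' @export
dH_sub_from_Ulatt <- function(U_latt, T_K = ROOM_TEMPERATURE_K) {
  stopifnot(is.numeric(U_latt), is.numeric(T_K))
  if (any(T_K < 0)) stop("temperature must be >= 0 K", call. = FALSE)
  -U_latt - 2 * GAS_CONSTANT_KJ * T_K
}

#' Sublimation entropy from its vibrational / translational / rotational parts
#'
#' dS_sub = dS_vib - (dS_trans + dS_rot): the crystal loses vibrational
#' entropy and the gas gains translational and rotational entropy.
#'
#' @param dS_vib,dS_trans,dS_rot entropies in J/(mol K).
#' @return dS_sub in J/(mol K).
#' @export
dS_sub_compose <- function(dS_vib, dS_trans, dS_rot) {
  dS_vib - (dS_trans + dS_rot)
}

#' logS from the thermodynamic cycle
#'
#' Composes dG_sub = dH_sub - T dS_sub and dG_sol = dG_sub + dG_solv,
#' then converts the free energy of solution to a base-10 log solubility:
#' logS = -dG_sol / (ln(10) R T) - log10(V_m).
#'
#' @param dG_solv solvation free energy, kJ/mol.
#' @param dH_sub sublimation enthalpy, kJ/mol.
#' @param dS_sub sublimation entropy, J/(mol K).
#' @param V_m molar volume of the solid, L/mol (> 0).
#' @param T_K temperature in kelvin (> 0).
#' @return logS, the base-10 logarithm of intrinsic solubility in mol/L.
#' @seealso [dG_sol_from_logS()] for the inverse conversion.
#' @export
logS_from_cycle <- function(dG_solv, dH_sub, dS_sub, V_m,
                            T_K = ROOM_TEMPERATURE_K) {
  if (any(V_m <= 0)) stop("molar volume V_m must be > 0", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  dG_sub <- dH_sub - T_K * dS_sub / 1000   # J -> kJ
  dG_sol <- dG_sub + dG_solv
  -dG_sol / (log(10) * GAS_CONSTANT_KJ * T_K) - log10(V_m)
}

#' Free energy of solution from logS (inverse of the cycle conversion)
#'
#' @param logS base-10 log solubility, mol/L.
#' @param V_m molar volume, L/mol (> 0).
#' @param T_K temperature, kelvin (> 0).
#' @return dG_sol in kJ/mol.
#' @export
dG_sol_from_logS <- function(logS, V_m, T_K = ROOM_TEMPERATURE_K) {
  if (any(V_m <= 0)) stop("molar volume V_m must be > 0", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  -(logS + log10(V_m)) * log(10) * GAS_CONSTANT_KJ * T_K
}

#' Coefficients of the parametrized thermodynamic solubility model
#'
#' Container for the four coefficients of the linear-in-coefficients
#' model logS = alpha dG_solv - beta (dH_sub - dS_sub T) - gamma
#' log10(V_m) - delta, tagged with the unit system they were fit in.
#'
#' @param alpha,beta,gamma,delta finite numerics.
#' @param unit_system `"kJ"` or `"kcal"`.
#' @return An object of class `thermo_coefficients`.
#' @export
thermo_coefficients <- function(alpha, beta, gamma, delta,
                                unit_system = "kJ") {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (!all(is.finite(vals))) stop("coefficients must be finite", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 unit_system = check_unit_system(unit_system)),
            class = "thermo_coefficients")
}

#' @export
print.thermo_coefficients <- function(x, ...) {
  cat(sprintf(
    "thermo model coefficients [%s]: alpha=%.6g beta=%.6g gamma=%.6g delta=%.6g\n",
    x$unit_system, x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' The published optimized thermodynamic-model coefficients
#'
#' alpha = 0.38075, beta = 0.107058, gamma = 0.057, delta = 0.540,
#' in the internal kJ/mol unit system.
#'
#' @return A [thermo_coefficients()] object.
#' @export
published_thermo_coefficients <- function() {
  thermo_coefficients(alpha = 0.38075, beta = 0.107058,
                      gamma = 0.057, delta = 0.540, unit_system = "kJ")
}

#' Predict logS with the parametrized thermodynamic model
#'
#' logS = alpha dG_solv - beta (dH_sub - dS_sub T) - gamma log10(V_m) - delta.
#' The log is base 10, fixed by the ln(10) R T prefactor of the underlying
#' free-energy conversion.
#'
#' @param coef a [thermo_coefficients()] object.
#' @param dG_solv solvation free energy, kJ/mol.
#' @param dH_sub sublimation enthalpy, kJ/mol.
#' @param dS_sub sublimation entropy, J/(mol K).
#' @param V_m molar volume, L/mol (> 0).
#' @param T_K temperature, kelvin.
#' @param unit_system unit system of the inputs; must match the
#'   coefficient tag.
#' @return Predicted logS (vectorized over the inputs).
#' @export
thermo_model_predict <- function(coef, dG_solv, dH_sub, dS_sub, V_m,
                                 T_K = ROOM_TEMPERATURE_K,
                                 unit_system = "kJ") {
  stopifnot(inherits(coef, "thermo_coefficients"))
  if (check_unit_system(unit_system) != coef$unit_system) {
    stop("unit mismatch: inputs are in ", unit_system,
         " but coefficients were fit in ", coef$unit_system, call. = FALSE)
  }
  if (any(V_m <= 0)) stop("molar volume V_m must be > 0", call. = FALSE)
  coef$alpha * dG_solv -
    coef$beta * (dH_sub - dS_sub * T_K / 1000) -
    coef$gamma * log10(V_m) -
    coef$delta
}

#' Fit the thermodynamic-model coefficients by quasi-Newton optimization
#'
#' Minimizes the mean squared error of [thermo_model_predict()] against
#' the measured logS with L-BFGS-B.  Because the model is linear in
#' (alpha, beta, gamma, delta) the optimum coincides with ordinary least
#' squares and is initialization-independent; the regressor columns are
#' standardized internally for conditioning and the coefficients mapped
#' back exactly.
#'
#' @param data a data.frame with columns `dG_solv`, `dH_sub`, `dS_sub`,
#'   `V_m` and the target column `logS` (>= 5 rows).
#' @param T_K temperature in kelvin.
#' @param init optional [thermo_coefficients()] starting point
#'   (default all-zeros).
#' @param tol convergence tolerance passed to the optimizer (`factr`
#'   scale; smaller is tighter).
#' @param unit_system unit system of `data`.
#' @return A list of class `thermo_fit` with elements `coefficients`
#'   (a `thermo_coefficients`), `r_squared`, `rmse`, `converged`,
#'   `iterations` and `fitted`.
#' @export
fit_thermo_model <- function(data, T_K = ROOM_TEMPERATURE_K, init = NULL,
                             tol = 1e-2, unit_system = "kJ") {
  req <- c("dG_solv", "dH_sub", "dS_sub", "V_m", "logS")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 5L) stop("need at least 5 rows to fit", call. = FALSE)
  if (any(data$V_m <= 0)) stop("molar volume V_m must be > 0", call. = FALSE)
  check_unit_system(unit_system)

  y <- data$logS
  ## regressors for (alpha, beta, gamma, delta); model is y = A %*% theta
  A <- cbind(alpha = data$dG_solv,
             beta  = -(data$dH_sub - data$dS_sub * T_K / 1000),
             gamma = -log10(data$V_m),
             delta = -1)
  ## standardize the non-constant columns for conditioning
  mu <- colMeans(A[, 1:3, drop = FALSE])
  sc <- apply(A[, 1:3, drop = FALSE], 2, stats::sd)
  sc[sc == 0] <- 1
  As <- cbind(sweep(sweep(A[, 1:3, drop = FALSE], 2, mu), 2, sc, "/"),
              delta = -1)

  n <- length(y)
  fn <- function(th) mean((As %*% th - y)^2)
  gr <- function(th) as.numeric(2 * crossprod(As, As %*% th - y)) / n

  th0 <- if (is.null(init)) {
    rep(0, 4)
  } else {
    stopifnot(inherits(init, "thermo_coefficients"))
    ## map a raw-scale start into the standardized parametrization
    raw <- c(init$alpha, init$beta, init$gamma, init$delta)
    c(raw[1:3] * sc, raw[4] - sum(raw[1:3] * mu))
  }
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 500L, factr = tol,
                                     pgtol = 1e-15))
  ## warm-restart polish: a quadratic objective converges to machine
  ## precision in a handful of further iterations
  opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                       control = list(maxit = 200L, factr = tol,
                                      pgtol = 1e-15))
  if (opt2$value <= opt$value) {
    opt2$counts <- opt$counts + opt2$counts
    opt <- opt2
  }
  ## at machine precision the line search may abort (convergence code
  ## 52) with a vanishing gradient; treat that as converged
  converged <- opt$convergence == 0L ||
    max(abs(gr(opt$par))) < 1e-8 * (1 + abs(opt$value))
  if (!converged) {
    warning("thermo-model fit did not fully converge (code ",
            opt$convergence, "); returning best iterate", call. = FALSE)
  }
  ths <- opt$par
  ## undo the standardization: y = sum_j ths_j (a_j - mu_j)/sc_j - ths_4
  ## = sum_j (ths_j/sc_j) a_j - (ths_4 + sum_j ths_j mu_j / sc_j)
  raw <- unname(c(ths[1:3] / sc, ths[4] + sum(ths[1:3] * mu / sc)))
  coefs <- thermo_coefficients(raw[1], raw[2], raw[3], raw[4],
                               unit_system = unit_system)
  fitted <- as.numeric(A %*% raw)
  structure(list(
    coefficients = coefs,
    r_squared = if (stats::var(y) > 0) r2(y, fitted) else 0,
    rmse = rmse(y, fitted),
    converged = converged,
    iterations = unname(opt$counts[["function"]]),
    fitted = fitted
  ), class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("  training R^2 = %.4f, RMSE = %.4f logS units (%s, %d fn evals)\n",
              x$r_squared, x$rmse,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
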