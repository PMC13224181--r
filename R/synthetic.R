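## Synthetic data with the statistical structure of the study.
##
## The generator emulates a small curated solubility data set: a
## few-dozen-row matrix of correlated continuous descriptors, a planted
## sparse algebraic law for logS with additive Gaussian noise, and a
## corrupted "entropy" channel whose correlation with the truth can be
## tuned down to the near-zero level seen for computed sublimation
## entropies.  Everything is reproducible from the seed, and ground
## truth (law, coefficients, noise ceiling) is returned alongside the
## data.

#' Specification of a synthetic descriptor data set
#'
#' @param n_compounds number of rows (default 44, the study scale;
#'   >= 8).
#' @param n_descriptors number of primary descriptor columns.
#' @param rho exchangeable latent correlation between descriptors
#'   (ignored when `correlation` is given).
#' @param correlation optional full correlation matrix
#'   (positive semi-definite, checked).
#' @param planted_law list with `terms` (list of
#'   `list(coefficient =, expression =)`), and `intercept`; the default
#'   mirrors the shape of the published model: three product terms plus
#'   an intercept over five of the descriptors.
#' @param noise_sd additive Gaussian noise on logS (>= 0), in logS
#'   units.
#' @param entropy_corruption optional `c(a =, b =, s =)` for the
#'   corrupted entropy channel `a * dS_true + b + N(0, s^2)`.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 44L, n_descriptors = 8L,
                           rho = 0.15, correlation = NULL,
                           planted_law = default_planted_law(),
                           noise_sd = 0.2,
                           entropy_corruption = NULL, seed = 1L) {
  if (n_compounds < 8L) stop("need n_compounds >= 8", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(correlation)) {
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("spec error: correlation matrix is not positive semi-definite",
           call. = FALSE)
    }
    if (nrow(correlation) != n_descriptors) {
      stop("spec error: correlation matrix dimension != n_descriptors",
           call. = FALSE)
    }
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors), rho = rho,
                 correlation = correlation, planted_law = planted_law,
                 noise_sd = noise_sd,
                 entropy_corruption = entropy_corruption,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The default planted law
#'
#' Three product terms plus an intercept, the complexity class of the
#' published model (products of descriptors and descriptor
#' differences, with descriptors reused across terms):
#' logS = 1.0 d01 (d03 - d04) - 0.8 d02 (d01 - d03) - 0.5 d04 (d02 - d03)
#' + 1.55.  The three terms interlock over four descriptors with six
#' distinct descriptor-pair products and well-separated coefficients,
#' so the law is identifiable from few samples while exercising the
#' same expression class as the published model.
#'
#' @return A list with `terms` and `intercept`.
#' @export
default_planted_law <- function() {
  list(terms = list(
    list(coefficient = 1.0,
         expression = ex_op("*", "d01", ex_op("-", "d03", "d04"))),
    list(coefficient = -0.8,
         expression = ex_op("*", "d02", ex_op("-", "d01", "d03"))),
    list(coefficient = -0.5,
         expression = ex_op("*", "d04", ex_op("-", "d02", "d03")))),
    intercept = 1.55)
}

.law_signal <- function(law, X) {
  sig <- rep(law$intercept, nrow(X))
  for (t in law$terms) {
    sig <- sig + t$coefficient * eval_expression(t$expression, X)
  }
  sig
}

.law_model <- function(law, unit_system = "kJ") {
  symbolic_model(terms = law$terms, intercept = law$intercept,
                 config = list(source = "planted"),
                 unit_system = unit_system)
}

## latent correlated normals -> descriptor marginals: odd-indexed
## columns stay normal (signed descriptors, e.g. autocorrelations or
## solvation energies), even-indexed get a skewed lognormal shape
## (magnitude-like descriptors, e.g. walk counts or surface areas).
## Every column has its own nonzero location, as real descriptor
## catalogues do -- columns differ in scale and are far from centered.
.descriptor_means <- function(p) {
  base <- c(2.0, 1.2, 0.6, 1.6, 2.4, 0.8, 1.4, 1.0, 2.2, 0.9, 1.8, 1.1)
  rep_len(base, p) + 0.05 * (seq_len(p) - 1L)
}

.descriptor_transform <- function(Z) {
  X <- Z
  even <- seq(2L, ncol(Z), by = 2L)
  ## centered, rescaled lognormal: skewed but comparable in spread
  X[, even] <- 2.8 * (exp(0.35 * Z[, even]) - exp(0.35^2 / 2))
  X <- sweep(X, 2L, .descriptor_means(ncol(Z)), "+")
  colnames(X) <- sprintf("d%02d", seq_len(ncol(Z)))
  X
}

.draw_descriptors <- function(n, spec) {
  p <- spec$n_descriptors
  Sigma <- spec$correlation %||%
    (matrix(spec$rho, p, p) + diag(1 - spec$rho, p))
  L <- chol(Sigma + diag(1e-12, p))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  .descriptor_transform(Z)
}

#' Population signal variance and noise ceiling of a spec
#'
#' Monte-Carlo estimate (large fixed sample) of the variance of the
#' planted signal under the spec's descriptor distribution, and the
#' corresponding ceiling R^2 = V / (V + noise_sd^2) -- the best R^2 any
#' model can reach on average given the noise.
#'
#' @param spec a [synthetic_spec()].
#' @param n_mc Monte-Carlo sample size.
#' @return List with `signal_var` and `ceiling_r2`.
#' @export
noise_ceiling <- function(spec, n_mc = 100000L) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(spec$seed + 777L)
  X <- .draw_descriptors(n_mc, spec)
  v <- stats::var(.law_signal(spec$planted_law, X))
  list(signal_var = v,
       ceiling_r2 = v / (v + spec$noise_sd^2))
}

#' Noise level achieving a target population R^2
#'
#' Inverts the noise ceiling: sd = sqrt(V (1 - r2) / r2) with V the
#' population signal variance of the spec's planted law.
#'
#' @param spec a [synthetic_spec()].
#' @param r2_target target population R^2 in (0, 1).
#' @return Noise standard deviation in logS units.
#' @export
noise_sd_for_r2 <- function(spec, r2_target) {
  stopifnot(r2_target > 0, r2_target < 1)
  v <- noise_ceiling(spec)$signal_var
  sqrt(v * (1 - r2_target) / r2_target)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic descriptor data set with a planted law
#'
#' Draws correlated continuous descriptors (normal and lognormal
#' marginals), evaluates the planted law, adds Gaussian noise, and --
#' when requested -- attaches a corrupted entropy channel.  Byte-identical
#' for equal seeds.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `fm` (a `feature_matrix` with target) and `truth`
#'   (planted law as a `symbolic_model`, the noise-free signal, the
#'   noise draw, `signal_var`/`ceiling_r2`, and -- with corruption
#'   enabled -- `dS_true` plus the observed channel in the matrix).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  X <- .draw_descriptors(n, spec)
  signal <- .law_signal(spec$planted_law, X)
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  y <- signal + noise
  dS_true <- NULL
  if (!is.null(spec$entropy_corruption)) {
    ec <- spec$entropy_corruption
    dS_true <- stats::rnorm(n, 180, 40)   # J/(mol K), sublimation scale
    dS_obs <- corrupt_entropy(dS_true, a = ec[["a"]], b = ec[["b"]],
                              s = ec[["s"]],
                              seed = spec$seed + 1L)
    X <- cbind(X, dS_sub_obs = dS_obs)
  }
  ceiling <- noise_ceiling(spec)
  ids <- sprintf("syn%03d", seq_len(n))
  fm <- feature_matrix(X, row_ids = ids, target = y,
                       provenance = "derived", unit_system = "kJ")
  list(fm = fm,
       truth = list(law = .law_model(spec$planted_law),
                    signal = signal, noise = noise, dS_true = dS_true,
                    signal_var = ceiling$signal_var,
                    ceiling_r2 = ceiling$ceiling_r2,
                    spec = spec))
}

#' Corrupt an entropy channel with scale, bias and noise
#'
#' dS_observed = a dS_true + b + N(0, s^2), emulating the systematic
#' failure of computed sublimation entropies.  The population R^2
#' between truth and observation is a^2 V / (a^2 V + s^2) with V the
#' variance of the true channel.
#'
#' @param dS_true numeric vector, J/(mol K).
#' @param a scale; `a = 0` makes the observation independent of truth.
#' @param b bias, J/(mol K).
#' @param s noise standard deviation (>= 0), J/(mol K).
#' @param seed integer seed.
#' @return The corrupted channel.
#' @export
corrupt_entropy <- function(dS_true, a = 1, b = 0, s = 0, seed = 1L) {
  if (s < 0) stop("noise sd must be >= 0", call. = FALSE)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  a * dS_true + b + stats::rnorm(length(dS_true), 0, s)
}

#' Corruption noise achieving a target truth/observation R^2
#'
#' Closed form: s = |a| sd_true sqrt((1 - r2)/r2).
#'
#' @param r2_target target population R^2 in (0, 1).
#' @param sd_true standard deviation of the true channel.
#' @param a corruption scale.
#' @return Noise standard deviation `s`.
#' @export
entropy_noise_for_r2 <- function(r2_target, sd_true, a = 1) {
  stopifnot(r2_target > 0, r2_target < 1, sd_true > 0)
  abs(a) * sd_true * sqrt((1 - r2_target) / r2_target)
}

#' Generate thermodynamic-cycle data with true and corrupted entropy
#'
#' Draws realistic solvation/sublimation energetics (dG_solv ~ N(-40,
#' 12) kJ/mol, U_latt ~ N(-110, 20) kJ/mol with dH_sub = -U_latt - 2RT,
#' dS_sub ~ N(180, 40) J/(mol K), lognormal V_m around 0.15 L/mol),
#' computes logS through the cycle plus measurement noise, and attaches
#' a corrupted entropy channel (defaults tuned so the population R^2
#' between true and observed entropy is 0.05).
#'
#' @param n number of compounds.
#' @param seed integer seed.
#' @param noise_sd measurement noise on logS, logS units.
#' @param entropy_r2 target population R^2 of the corrupted channel.
#' @param entropy_bias additive bias of the corrupted channel,
#'   J/(mol K).
#' @param T_K temperature.
#' @return A data.frame (id, dG_solv, U_latt, dH_sub, dS_sub true
#'   channel, dS_sub_obs corrupted channel, V_m, logS) with attribute
#'   `"truth"` carrying the noise-free logS.
#' @export
generate_cycle_data <- function(n = 44L, seed = 1L, noise_sd = 0.2,
                                entropy_r2 = 0.05, entropy_bias = 60,
                                T_K = ROOM_TEMPERATURE_K) {
  set.seed(seed)
  dG_solv <- stats::rnorm(n, -40, 12)
  U_latt <- stats::rnorm(n, -110, 20)
  dH_sub <- dH_sub_from_Ulatt(U_latt, T_K)
  sd_S <- 40
  dS_sub <- stats::rnorm(n, 180, sd_S)
  V_m <- exp(stats::rnorm(n, log(0.15), 0.25))
  logS_true <- logS_from_cycle(dG_solv, dH_sub, dS_sub, V_m, T_K)
  logS <- logS_true + stats::rnorm(n, 0, noise_sd)
  s <- entropy_noise_for_r2(entropy_r2, sd_true = sd_S)
  dS_obs <- corrupt_entropy(dS_sub, a = 1, b = entropy_bias, s = s,
                            seed = seed + 1L)
  out <- data.frame(id = sprintf("cyc%03d", seq_len(n)),
                    dG_solv = dG_solv, U_latt = U_latt, dH_sub = dH_sub,
                    dS_sub = dS_sub, dS_sub_obs = dS_obs, V_m = V_m,
                    logS = logS)
  attr(out, "truth") <- list(logS_true = logS_true, noise_sd = noise_sd,
                             entropy_noise = s, entropy_r2 = entropy_r2)
  out
}

#' Synthetic voltammetric calibration fixture
#'
#' Builds calibration points along a dilution schedule with a linear
#' current response plus Gaussian noise, and the peak current of a
#' saturated sample of known solubility measured after aliquot
#' dilution.
#'
#' @param true_slope current per (mol/L).
#' @param intercept baseline current.
#' @param noise_sd current noise (>= 0).
#' @param schedule concentrations from [dilution_series()].
#' @param seed integer seed.
#' @param true_solubility known solubility of the saturated sample,
#'   mol/L.
#' @param dilution_factor aliquot dilution before the saturated-sample
#'   scan.
#' @return List with `points` (concentration, current),
#'   `saturated_current`, and the generating truth.
#' @export
make_calibration_fixture <- function(true_slope, intercept = 0,
                                     noise_sd = 0,
                                     schedule = dilution_series(2.0, 0.5, 6, 0.01),
                                     seed = 1L, true_solubility = 0.05,
                                     dilution_factor = 10) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  current <- true_slope * schedule + intercept +
    stats::rnorm(length(schedule), 0, noise_sd)
  sat <- true_slope * (true_solubility / dilution_factor) + intercept +
    stats::rnorm(1, 0, noise_sd)
  list(points = data.frame(concentration = schedule, current = current),
       saturated_current = sat,
       truth = list(slope = true_slope, intercept = intercept,
                    noise_sd = noise_sd, solubility = true_solubility,
                    dilution_factor = dilution_factor))
}
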