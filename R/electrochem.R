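# Electrode kinetics: Nernst potential, Butler-Volmer rate law and its
# numerical inverse, a lumped loss-decomposed cell voltage, polarization
# curves, and calibration of per-material exchange current densities against
# benchmark mean voltages.

#' Physical constants
#'
#' Gas constant and Faraday constant used throughout the electrochemical
#' calculations. Both can be overridden, e.g. to propagate unit conventions,
#' but must remain strictly positive.
#'
#' @param R Gas constant, J/(mol K). Default 8.314.
#' @param F Faraday constant, C/mol. Default 96485.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(R = 8.314, F = 96485) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single positive number", call. = FALSE)
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F <= 0)
    stop("'F' must be a single positive number", call. = FALSE)
  structure(list(R = R, F = F), class = "physical_constants")
}

#' Nernst electrode potential
#'
#' Concentration-corrected electrode potential
#' \deqn{E = E^0 - \frac{RT}{nF} \ln Q}
#' for a half-cell with standard potential `E0`, `n` electrons transferred
#' and reaction quotient `Q`.
#'
#' @param E0 Standard potential, V.
#' @param T Temperature, K. Must be positive.
#' @param n Electrons transferred (integer, at least 1).
#' @param Q Reaction quotient, dimensionless. Must be positive.
#' @param consts A [physical_constants()] object.
#' @return Electrode potential, V.
#' @examples
#' nernst_potential(0.5, 298.15, 4, 1)   # Q = 1 leaves E = E0
#' @export
nernst_potential <- function(E0, T, n, Q, consts = physical_constants()) {
  if (!is.finite(T) || T <= 0)
    stop("'T' must be positive (got ", T, ")", call. = FALSE)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("'n' must be an integer >= 1 (got ", n, ")", call. = FALSE)
  if (!is.finite(Q) || Q <= 0)
    stop("'Q' must be positive (got ", Q, ")", call. = FALSE)
  E0 - (consts$R * T / (n * consts$F)) * log(Q)
}

#' Butler-Volmer kinetic parameters for an anode material
#'
#' @param name Material label, e.g. `"platinum"`.
#' @param i0 Exchange current density, A/m^2 (positive).
#' @param alpha Charge-transfer coefficient, strictly between 0 and 1.
#' @param n Electrons in the rate-determining interfacial step (default 1;
#'   distinct from the 24-electron overall glucose stoichiometry, which would
#'   be pathological in the exponent).
#' @param E_eq Equilibrium anode potential, V (metadata; the lumped cell
#'   model carries the open-circuit voltage in [cell_circuit()]).
#' @return An object of class `material_kinetics`.
#' @export
material_kinetics <- function(name, i0, alpha = 0.5, n = 1, E_eq = 0) {
  if (!is.finite(i0) || i0 <= 0)
    stop("'i0' must be positive (got ", i0, ")", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1) (got ", alpha, ")", call. = FALSE)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("'n' must be an integer >= 1 (got ", n, ")", call. = FALSE)
  structure(list(name = as.character(name), i0 = i0, alpha = alpha,
                 n = n, E_eq = E_eq),
            class = "material_kinetics")
}

#' @export
print.material_kinetics <- function(x, ...) {
  cat(sprintf("<material_kinetics> %s: i0 = %.6g A/m^2, alpha = %.3g, n = %d\n",
              x$name, x$i0, x$alpha, as.integer(x$n)))
  invisible(x)
}

#' Butler-Volmer current density
#'
#' Net interfacial current density at activation overpotential `eta`:
#' \deqn{i = i_0\left[\exp\!\left(\frac{\alpha n F \eta}{RT}\right) -
#'   \exp\!\left(-\frac{(1-\alpha) n F \eta}{RT}\right)\right]}
#' The sign of the result matches the sign of `eta` (anodic positive).
#' Exponential arguments are clamped at `exp_max` (with a warning) to guard
#' against overflow for unphysically large overpotentials.
#'
#' @param mk A [material_kinetics()] object.
#' @param eta Activation overpotential, V. Vectorized.
#' @param T Temperature, K.
#' @param consts A [physical_constants()] object.
#' @param exp_max Clamp bound for the exponential arguments.
#' @return Current density, A/m^2.
#' @export
bv_current_density <- function(mk, eta, T = 303.15,
                               consts = physical_constants(),
                               exp_max = 500) {
  stopifnot(inherits(mk, "material_kinetics"))
  if (!is.finite(T) || T <= 0)
    stop("'T' must be positive (got ", T, ")", call. = FALSE)
  f <- mk$n * consts$F / (consts$R * T)
  a1 <- mk$alpha * f * eta
  a2 <- -(1 - mk$alpha) * f * eta
  if (any(abs(c(a1, a2)) > exp_max)) {
    warning("Butler-Volmer exponent clamped at +/-", exp_max, call. = FALSE)
    a1 <- pmin(pmax(a1, -exp_max), exp_max)
    a2 <- pmin(pmax(a2, -exp_max), exp_max)
  }
  mk$i0 * (exp(a1) - exp(a2))
}

#' Invert the Butler-Volmer relation for the activation overpotential
#'
#' Solves `bv_current_density(mk, eta, T) == i` for `eta` by a deterministic
#' expanding bracket followed by root polishing. The returned overpotential
#' carries the sign of `i`.
#'
#' @inheritParams bv_current_density
#' @param i Target current density, A/m^2. Vectorized.
#' @param tol Absolute tolerance on the residual current density, A/m^2.
#' @param max_expand Maximum number of bracket doublings.
#' @return Activation overpotential, V.
#' @export
bv_overpotential <- function(mk, i, T = 303.15,
                             consts = physical_constants(),
                             tol = 1e-12, max_expand = 200) {
  stopifnot(inherits(mk, "material_kinetics"))
  if (any(!is.finite(i))) stop("'i' must be finite", call. = FALSE)
  one <- function(ii) {
    if (ii == 0) return(0)
    s <- sign(ii)
    hi <- 0.05
    f <- function(e) bv_current_density(mk, e, T, consts) - ii
    k <- 0
    while (sign(f(s * hi)) == sign(f(0)) && k < max_expand) {
      hi <- hi * 2
      k <- k + 1
    }
    if (k >= max_expand)
      stop("Butler-Volmer inversion failed to bracket i = ", ii,
           " A/m^2 (bracket grew to |eta| = ", hi, " V)", call. = FALSE)
    lo <- if (s > 0) 0 else -hi
    up <- if (s > 0) hi else 0
    r <- stats::uniroot(f, c(lo, up), tol = .Machine$double.eps^0.9,
                        maxiter = 2000)
    # Newton polish with the analytic derivative: drives the current
    # residual to machine precision
    eta <- r$root
    fac <- mk$n * consts$F / (consts$R * T)
    for (it in 1:5) {
      res <- f(eta)
      if (abs(res) <= tol * max(1, abs(ii))) break
      dfde <- mk$i0 * fac * (mk$alpha * exp(mk$alpha * fac * eta) +
        (1 - mk$alpha) * exp(-(1 - mk$alpha) * fac * eta))
      eta <- eta - res / dfde
    }
    if (abs(f(eta)) > max(tol * max(1, abs(ii)), 1e-7 * abs(ii)))
      stop("Butler-Volmer inversion did not converge for i = ", ii,
           " A/m^2 (residual ", f(eta), " A/m^2 on bracket [", lo,
           ", ", up, "])", call. = FALSE)
    eta
  }
  vapply(i, one, numeric(1))
}

#' Lumped cell circuit
#'
#' Zero-current cell voltage and the ohmic / concentration loss parameters of
#' the loss-decomposed cell-voltage model. The open-circuit value is carried
#' as a single positive `E_cell0` (anode-cathode couple at zero current);
#' losses are subtracted from it.
#'
#' @param E_cell0 Zero-current cell voltage, V.
#' @param ASR Area-specific internal resistance, Ohm m^2 (non-negative).
#' @param i_L Limiting current density for the concentration loss, A/m^2.
#'   `NULL` (default) disables the concentration term.
#' @return An object of class `cell_circuit`.
#' @export
cell_circuit <- function(E_cell0 = 0.80, ASR = 0.04, i_L = NULL) {
  if (!is.finite(E_cell0))
    stop("'E_cell0' must be finite", call. = FALSE)
  if (!is.finite(ASR) || ASR < 0)
    stop("'ASR' must be non-negative (got ", ASR, ")", call. = FALSE)
  if (!is.null(i_L) && (!is.finite(i_L) || i_L <= 0))
    stop("'i_L' must be positive when given (got ", i_L, ")", call. = FALSE)
  structure(list(E_cell0 = E_cell0, ASR = ASR, i_L = i_L),
            class = "cell_circuit")
}

#' Cell voltage under load
#'
#' Loss-decomposed cell voltage
#' \deqn{V_{cell}(i) = E_{cell,0} - \eta_{act}(i) - \eta_{conc}(i) - i\,\mathrm{ASR}}
#' where the activation overpotential comes from inverting the Butler-Volmer
#' relation and the concentration overpotential uses the logarithmic
#' limiting-current form
#' \eqn{\eta_{conc} = -(RT/nF)\ln(1 - i/i_L)} (zero when `i_L` is absent).
#' Monotone non-increasing in `i`.
#'
#' @param circuit A [cell_circuit()] object.
#' @param mk A [material_kinetics()] object.
#' @param i Current density, A/m^2; must satisfy `0 <= i < i_L`. Vectorized.
#' @param T Temperature, K.
#' @param consts A [physical_constants()] object.
#' @return Cell voltage, V.
#' @export
cell_voltage <- function(circuit, mk, i, T = 303.15,
                         consts = physical_constants()) {
  stopifnot(inherits(circuit, "cell_circuit"), inherits(mk, "material_kinetics"))
  if (any(i < 0)) stop("'i' must be non-negative", call. = FALSE)
  if (!is.null(circuit$i_L) && any(i >= circuit$i_L))
    stop("current density beyond limiting current (i >= i_L = ",
         circuit$i_L, " A/m^2)", call. = FALSE)
  eta_act <- bv_overpotential(mk, i, T, consts)
  eta_conc <- if (is.null(circuit$i_L)) 0 else
    -(consts$R * T / (mk$n * consts$F)) * log(1 - i / circuit$i_L)
  circuit$E_cell0 - eta_act - eta_conc - i * circuit$ASR
}

#' Default polarization current-density grid
#'
#' 50 points uniform on [0, 10] A/m^2 — the operating envelope used for
#' preset calibration and reported mean voltages.
#' @return Numeric vector of current densities, A/m^2.
#' @export
default_current_grid <- function() seq(0, 10, length.out = 50)

#' Polarization curve for one material
#'
#' Evaluates activation overpotential and cell voltage pointwise over a
#' strictly increasing current-density grid.
#'
#' @inheritParams cell_voltage
#' @param i_grid Strictly increasing current densities, A/m^2, first entry
#'   non-negative.
#' @return A data frame of class `polarization_curve` with columns
#'   `i_A_per_m2`, `eta_V`, `v_cell_V` and attribute `material`.
#' @export
polarization_curve <- function(circuit, mk, i_grid = default_current_grid(),
                               T = 303.15, consts = physical_constants()) {
  if (length(i_grid) < 1L || any(diff(i_grid) <= 0) || i_grid[1] < 0)
    stop("'i_grid' must be strictly increasing with first entry >= 0",
         call. = FALSE)
  eta <- bv_overpotential(mk, i_grid, T, consts)
  v <- cell_voltage(circuit, mk, i_grid, T, consts)
  out <- data.frame(i_A_per_m2 = i_grid, eta_V = eta, v_cell_V = v)
  attr(out, "material") <- mk$name
  attr(out, "T_K") <- T
  class(out) <- c("polarization_curve", "data.frame")
  out
}

#' Mean cell voltage of a polarization curve
#'
#' Arithmetic mean of the cell-voltage column — the summary statistic used to
#' compare anode materials across the shared operating envelope.
#'
#' @param curve A [polarization_curve()] result.
#' @return Mean cell voltage, V.
#' @export
mean_voltage <- function(curve) {
  if (!inherits(curve, "polarization_curve"))
    stop("'curve' must be a polarization_curve", call. = FALSE)
  if (nrow(curve) == 0L) stop("empty polarization curve", call. = FALSE)
  mean(curve$v_cell_V)
}

#' Calibrate an exchange current density to a target mean voltage
#'
#' Finds `i0` such that the mean cell voltage over `i_grid` equals
#' `target_mean`. The map i0 -> mean voltage is strictly increasing (larger
#' exchange current density means smaller activation loss), so a bracketed
#' root search on log10(i0) is used.
#'
#' @param target_mean Target mean cell voltage, V.
#' @param circuit A [cell_circuit()] object.
#' @param alpha,n,E_eq Kinetic parameters held fixed during calibration.
#' @param i_grid Current-density grid, A/m^2.
#' @param T Temperature, K.
#' @param consts A [physical_constants()] object.
#' @param tol Absolute tolerance on the achieved mean voltage, V.
#' @param bracket Search bracket for `i0`, A/m^2.
#' @return Calibrated exchange current density `i0`, A/m^2.
#' @export
calibrate_i0 <- function(target_mean, circuit = cell_circuit(),
                         alpha = 0.5, n = 1, E_eq = 0,
                         i_grid = default_current_grid(), T = 303.15,
                         consts = physical_constants(), tol = 1e-4,
                         bracket = c(1e-12, 1e6)) {
  mv <- function(i0) {
    mk <- material_kinetics("probe", i0 = i0, alpha = alpha, n = n, E_eq = E_eq)
    mean_voltage(polarization_curve(circuit, mk, i_grid, T, consts))
  }
  lo <- mv(bracket[1]); hi <- mv(bracket[2])
  if (target_mean < lo || target_mean > hi)
    stop(sprintf(
      "target mean voltage %.6g V outside attainable range [%.6g, %.6g] V",
      target_mean, lo, hi), call. = FALSE)
  r <- stats::uniroot(function(l10) mv(10^l10) - target_mean,
                      log10(bracket), tol = 1e-12, maxiter = 2000)
  i0 <- 10^r$root
  if (abs(mv(i0) - target_mean) > tol)
    stop("calibration did not reach the target mean within tol", call. = FALSE)
  i0
}

#' Benchmark mean cell voltages for the five anode materials
#'
#' Reference mean voltages (V) used to calibrate the shipped kinetic presets:
#' platinum 0.375, graphene 0.36, carbon nanotube 0.342, graphite felt 0.32,
#' stainless steel 0.30. These act as the regression anchors for the
#' per-material exchange current densities.
#'
#' @return Named numeric vector, V, in decreasing order.
#' @export
reference_mean_voltages <- function() {
  c(platinum = 0.375, graphene = 0.36, carbon_nanotube = 0.342,
    graphite_felt = 0.32, stainless_steel = 0.30)
}

#' Calibrate all material presets
#'
#' Runs [calibrate_i0()] for every material in `means` under a shared
#' operating envelope and returns the preset table.
#'
#' @param means Named target mean voltages, V.
#' @inheritParams calibrate_i0
#' @return Data frame with columns `name`, `i0`, `alpha`, `n`, `E_eq` and
#'   attributes describing the calibration envelope.
#' @export
calibrate_presets <- function(means = reference_mean_voltages(),
                              circuit = cell_circuit(), alpha = 0.5, n = 1,
                              E_eq = 0, i_grid = default_current_grid(),
                              T = 303.15, consts = physical_constants(),
                              tol = 1e-4) {
  i0 <- vapply(means, calibrate_i0, numeric(1), circuit = circuit,
               alpha = alpha, n = n, E_eq = E_eq, i_grid = i_grid, T = T,
               consts = consts, tol = tol)
  out <- data.frame(name = names(means), i0 = unname(i0), alpha = alpha,
                    n = n, E_eq = E_eq, stringsAsFactors = FALSE)
  attr(out, "envelope") <- list(E_cell0 = circuit$E_cell0, ASR = circuit$ASR,
                                T_K = T, i_max = max(i_grid),
                                n_grid = length(i_grid))
  out
}

#' Load the shipped (or a user) material preset file
#'
#' @param path Preset CSV path; defaults to the versioned file shipped with
#'   the package, produced once by [calibrate_presets()].
#' @return Named list of [material_kinetics()] objects.
#' @export
load_presets <- function(path = system.file("extdata", "material_presets.csv",
                                            package = "mfcsim")) {
  if (!nzchar(path) || !file.exists(path))
    stop("preset file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "i0", "alpha", "n", "E_eq")
  if (!all(need %in% names(tab)))
    stop("preset file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(k)
    material_kinetics(tab$name[k], tab$i0[k], tab$alpha[k], tab$n[k],
                      tab$E_eq[k]))
  names(out) <- tab$name
  out
}

#' Write a preset table to CSV
#'
#' @param presets Data frame from [calibrate_presets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presets <- function(presets, path) {
  env <- attr(presets, "envelope")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(env))
    writeLines(sprintf(
      "# calibration envelope: E_cell0=%g V, ASR=%g Ohm.m2, T=%g K, grid %d pts on [0, %g] A/m2",
      env$E_cell0, env$ASR, env$T_K, env$n_grid, env$i_max), con)
  utils::write.csv(presets, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
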