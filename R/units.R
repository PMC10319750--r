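# Parameter containers, validation, the dimensionless Planck constant and the
# Zurek-style decoherence-time estimate.

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be strictly positive (got ", format(x), ")",
         call. = FALSE)
  if (nonneg && x < 0)
    stop("'", name, "' must be non-negative (got ", format(x), ")",
         call. = FALSE)
  invisible(x)
}

# CODATA 2018 exact values (SI)
.const <- list(hbar = 1.054571817e-34, kB = 1.380649e-23)

#' Quasi-classical units system and the dimensionless Planck constant
#'
#' For a double-well degree of freedom with characteristic length `R0`,
#' characteristic (barrier) energy `U0` and mass `M`, the natural momentum is
#' \eqn{P_0 = \sqrt{M U_0}} and the natural time is the traversal (tunneling)
#' time \eqn{\tau_0 = R_0 \sqrt{M/U_0}}.  Written in these units, the
#' Schr\enc{ö}{o}dinger equation contains the dimensionless ratio
#' \deqn{\tilde h = \frac{\hbar}{U_0 \tau_0} = \frac{\hbar}{P_0 R_0} =
#'   \left\{\frac{\hbar^2 / (M R_0^2)}{U_0}\right\}^{1/2}}
#' instead of Planck's constant.  \eqn{\tilde h} measures how much quantum
#' behaviour a near-macroscopic two-level system can display:
#' \eqn{\tilde h \ll 1} is the quasi-classical limit, while \eqn{\tilde h
#' \approx 1} is fully quantum.  All three algebraically equivalent forms are
#' evaluated and must agree to a relative tolerance of 1e-12.
#'
#' @param M mass, in an arbitrary mass unit (> 0).
#' @param R0 characteristic length of the potential (> 0).
#' @param U0 characteristic energy of the potential (> 0).
#' @param hbar physical action constant expressed in the same unit system
#'   (> 0); defaults to 1 so that model-level quantities stay dimensionless.
#' @return An object of class `"units_system"`: a list with the inputs plus
#'   the derived `P0`, `tau0` and `hbar_tilde`.
#' @examples
#' u <- units_system(M = 4, R0 = 1, U0 = 1)
#' hbar_tilde(u)  # 0.5
#' @export
units_system <- function(M, R0, U0, hbar = 1) {
  .check_scalar(M, "M", positive = TRUE)
  .check_scalar(R0, "R0", positive = TRUE)
  .check_scalar(U0, "U0", positive = TRUE)
  .check_scalar(hbar, "hbar", positive = TRUE)
  P0 <- sqrt(M * U0)
  tau0 <- R0 * sqrt(M / U0)
  forms <- c(hbar / (U0 * tau0),
             hbar / (P0 * R0),
             sqrt((hbar^2 / (M * R0^2)) / U0))
  if (max(abs(forms - forms[1L])) > 1e-12 * abs(forms[1L]))
    stop("internal inconsistency: the three forms of hbar_tilde disagree")
  structure(list(M = M, R0 = R0, U0 = U0, hbar = hbar,
                 P0 = P0, tau0 = tau0, hbar_tilde = forms[1L]),
            class = "units_system")
}

#' @rdname units_system
#' @param units a `"units_system"` object.
#' @export
hbar_tilde <- function(units) {
  if (!inherits(units, "units_system"))
    stop("'units' must be a units_system object")
  units$hbar_tilde
}

#' @export
print.units_system <- function(x, ...) {
  cat("Quasi-classical units system\n")
  cat(sprintf("  M = %g, R0 = %g, U0 = %g, hbar = %g\n",
              x$M, x$R0, x$U0, x$hbar))
  cat(sprintf("  derived: P0 = %g, tau0 = %g, hbar_tilde = %g\n",
              x$P0, x$tau0, x$hbar_tilde))
  invisible(x)
}

#' Initial entangled amplitudes of the DNA-mRNA pair
#'
#' The bipartite system starts in \eqn{\alpha|00\rangle + \beta|11\rangle}
#' with both reservoirs in their vacuum.  Amplitudes are taken real and
#' non-negative; complex inputs are reduced to their moduli, since every
#' observable of the model depends only on \eqn{\alpha^2}, \eqn{\beta^2} and
#' \eqn{\alpha\beta}.
#'
#' @param alpha,beta amplitudes in `[0, 1]` with `alpha^2 + beta^2 == 1`
#'   (checked to 1e-12).
#' @return An object of class `"initial_state"`.
#' @examples
#' initial_state(0.6, 0.8)
#' initial_state(cos(pi / 4), sin(pi / 4))  # maximally entangled
#' @export
initial_state <- function(alpha, beta) {
  if (is.complex(alpha)) alpha <- Mod(alpha)
  if (is.complex(beta)) beta <- Mod(beta)
  .check_scalar(alpha, "alpha", nonneg = TRUE)
  .check_scalar(beta, "beta", nonneg = TRUE)
  if (alpha > 1 || beta > 1)
    stop("'alpha' and 'beta' must lie in [0, 1]")
  nrm <- alpha^2 + beta^2
  if (abs(nrm - 1) > 1e-12)
    stop("alpha^2 + beta^2 must equal 1 (got ", format(nrm, digits = 15), ")")
  structure(list(alpha = alpha, beta = beta), class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("Initial state: %g |00> + %g |11>\n", x$alpha, x$beta))
  invisible(x)
}

#' Per-qubit channel parameters
#'
#' Each qubit couples to its own reservoir through a channel characterised by
#' a tunnel splitting `delta` (\eqn{\Delta_i = (E_{1,i} - E_{0,i})/\tilde h},
#' a dimensionless frequency) and a decay rate `gamma` (\eqn{\Gamma_i},
#' a dimensionless rate).  `delta` is always a direct input of the dynamics;
#' `gamma` may be supplied directly or computed from an Ohmic spectrum via
#' [decay_rate()].
#'
#' @param delta tunnel splitting, >= 0.
#' @param gamma decay rate, >= 0.
#' @return An object of class `"channel_params"`.
#' @examples
#' channel_params(delta = 1, gamma = 0.1)
#' @export
channel_params <- function(delta, gamma) {
  .check_scalar(delta, "delta", nonneg = TRUE)
  .check_scalar(gamma, "gamma", nonneg = TRUE)
  structure(list(delta = delta, gamma = gamma), class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf("Channel: delta = %g, gamma = %g\n", x$delta, x$gamma))
  invisible(x)
}

as_initial_state <- function(x) {
  if (inherits(x, "initial_state")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(initial_state(x[1L], x[2L]))
  stop("expected an initial_state object or a numeric (alpha, beta) pair")
}

as_channel_params <- function(x) {
  if (inherits(x, "channel_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(channel_params(x[1L], x[2L]))
  stop("expected a channel_params object or a numeric (delta, gamma) pair")
}

#' Thermal de Broglie wavelength
#'
#' The `"standard"` convention returns \eqn{\hbar / \sqrt{2 m k_B T}}, the
#' dimensionally correct length that the Zurek decoherence-time formula
#' requires.  The `"as_printed"` convention returns
#' \eqn{\hbar \sqrt{2 m k_B T}} and is retained only for fidelity with a
#' published variant of the formula; it carries units of action times
#' momentum, not length, and is documented as dimensionally anomalous.
#'
#' @param m particle mass in kg (> 0).
#' @param T temperature in K (> 0).
#' @param convention `"standard"` (default) or `"as_printed"`.
#' @param hbar,kB physical constants; default to CODATA SI values but may be
#'   overridden (e.g. set to 1 for dimensionless work).
#' @return wavelength (m under the standard convention).
#' @examples
#' thermal_de_broglie(m = 0.5, T = 1, hbar = 1, kB = 1)  # 1
#' @export
thermal_de_broglie <- function(m, T, convention = c("standard", "as_printed"),
                               hbar = .const$hbar, kB = .const$kB) {
  convention <- match.arg(convention)
  .check_scalar(m, "m", positive = TRUE)
  .check_scalar(T, "T", positive = TRUE)
  p <- sqrt(2 * m * kB * T)
  switch(convention, standard = hbar / p, as_printed = hbar * p)
}

#' Zurek-style decoherence-time estimate
#'
#' For a mass `m` held in a superposition of two positions separated by
#' `delta_x` at temperature `T`, the environment suppresses the coherence on
#' a timescale \eqn{t_D \simeq t_R \, \lambda_T / \Delta x}, where
#' \eqn{t_R} is the relaxation time and \eqn{\lambda_T} the thermal de
#' Broglie wavelength.  `decoherence_estimate()` assembles the full estimate
#' from physical inputs; `zurek_decoherence_time()` applies the ratio
#' directly when \eqn{\lambda_T} is already known.
#'
#' @param m mass in kg (> 0).
#' @param T temperature in K (> 0).
#' @param delta_x spatial separation of the superposed positions, m (> 0).
#' @param t_R relaxation time, s (> 0).
#' @param convention passed to [thermal_de_broglie()].
#' @param hbar,kB physical constants, as in [thermal_de_broglie()].
#' @return `decoherence_estimate()` returns a `"decoherence_estimate"` list
#'   with the inputs plus `lambda_T` and `t_D`; `zurek_decoherence_time()`
#'   returns the time `t_D`.
#' @examples
#' zurek_decoherence_time(t_R = 2, lambda_T = 1e-12, delta_x = 1e-10)  # 0.02 s
#' @export
decoherence_estimate <- function(m, T, delta_x, t_R,
                                 convention = c("standard", "as_printed"),
                                 hbar = .const$hbar, kB = .const$kB) {
  convention <- match.arg(convention)
  .check_scalar(delta_x, "delta_x", positive = TRUE)
  .check_scalar(t_R, "t_R", positive = TRUE)
  lambda_T <- thermal_de_broglie(m, T, convention, hbar = hbar, kB = kB)
  structure(list(m = m, T = T, delta_x = delta_x, t_R = t_R,
                 convention = convention, lambda_T = lambda_T,
                 t_D = zurek_decoherence_time(t_R, lambda_T, delta_x)),
            class = "decoherence_estimate")
}

#' @rdname decoherence_estimate
#' @param lambda_T thermal de Broglie wavelength, m (> 0).
#' @export
zurek_decoherence_time <- function(t_R, lambda_T, delta_x) {
  .check_scalar(t_R, "t_R", positive = TRUE)
  .check_scalar(lambda_T, "lambda_T", positive = TRUE)
  if (!is.numeric(delta_x) || length(delta_x) != 1L || !is.finite(delta_x))
    stop("'delta_x' must be a finite numeric scalar")
  if (delta_x == 0)
    stop("'delta_x' is zero: the decoherence-time ratio t_R * lambda_T / delta_x is undefined")
  if (delta_x < 0) stop("'delta_x' must be positive")
  t_R * lambda_T / delta_x
}

#' @export
print.decoherence_estimate <- function(x, ...) {
  cat("Zurek decoherence-time estimate\n")
  cat(sprintf("  m = %g kg, T = %g K, delta_x = %g m, t_R = %g s (%s lambda_T)\n",
              x$m, x$T, x$delta_x, x$t_R, x$convention))
  cat(sprintf("  lambda_T = %g, t_D = %g s\n", x$lambda_T, x$t_D))
  invisible(x)
}
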