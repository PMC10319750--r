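# Time evolution of the bipartite system: propagator matrix elements, parity
# selection rules, the reduced-density-matrix elements Lambda_ij and the
# survival probability of the initial entangled state.

#' Parity selection rules for the perturbative propagator
#'
#' To second order, the part of the evolution that returns the reservoir to
#' its vacuum connects only qubit levels with even `m - n`, while the part
#' that deposits one quantum in bath mode alpha connects only levels with odd
#' `m - n`.
#'
#' @param m,n qubit level indices in `{0, 1}`.
#' @param operator `"vac"` (vacuum-preserving branch) or `"alpha"`
#'   (one-quantum branch).
#' @return logical: is the matrix element allowed to be non-zero?
#' @examples
#' parity_allowed(0, 0, "vac")    # TRUE
#' parity_allowed(0, 1, "vac")    # FALSE
#' parity_allowed(0, 1, "alpha")  # TRUE
#' @export
parity_allowed <- function(m, n, operator = c("vac", "alpha")) {
  operator <- match.arg(operator)
  if (!all(c(m, n) %in% c(0L, 1L))) stop("'m' and 'n' must be 0 or 1")
  even <- (m - n) %% 2 == 0
  if (operator == "vac") even else !even
}

#' Propagator matrix elements of one system-bath channel
#'
#' Second-order perturbation theory leaves only two kinds of non-vanishing
#' matrix elements.  The vacuum-preserving branch is a pure phase on each
#' level,
#' \deqn{\langle 0|\hat u_{vac}|0\rangle = e^{-\frac{i}{\tilde h}\{t\,\delta
#'   E_0 - |f_{10}|^2 F_+(t)\}}, \qquad
#'   \langle 1|\hat u_{vac}|1\rangle = e^{-\frac{i}{\tilde h}\{t\,\delta
#'   E_1 - |f_{01}|^2 F_-(t)\}},}
#' with the principal-value shifts \eqn{F_\pm} of
#' [principal_value_shift()].  The one-quantum branch connects the two levels
#' per bath mode of frequency `omega`:
#' \deqn{\langle 0|\hat u_\alpha|1\rangle = \frac{2\pi i}{\sqrt{2\tilde h}}
#'   \bar\gamma(\omega) f_{01} \frac{1}{\pi}
#'   \frac{\sin((\omega + \Delta)t/2)}{\omega + \Delta}
#'   e^{i(\omega + \Delta)t/2},}
#' with \eqn{\langle 1|\hat u_\alpha|0\rangle} its complex conjugate.
#' Parity-forbidden elements are identically zero.  The level shifts
#' \eqn{\delta E_0, \delta E_1} have no closed form at this order and default
#' to 0; they are diagnostics only — the observable dynamics depends on phase
#' differences absorbed into `delta`.
#'
#' @param ch a [channel_params()] object.
#' @param spec an [ohmic_spectrum()] object.
#' @param t time, >= 0.
#' @param hbar_tilde dimensionless Planck constant (> 0, default 1).
#' @param delta_E0,delta_E1 level shifts (dimensionless energies, default 0).
#' @return An object of class `"propagator_elements"`: a list with complex
#'   `u_vac_00`, `u_vac_11` (unit modulus), the shifts `F_plus`, `F_minus`,
#'   the inputs, and `u_alpha_01(omega)`, a function returning the
#'   one-quantum amplitude for a bath mode of frequency `omega` (zero
#'   vector when `t = 0`).
#' @export
propagator_elements <- function(ch, spec, t, hbar_tilde = 1,
                                delta_E0 = 0, delta_E1 = 0) {
  ch <- as_channel_params(ch)
  stopifnot(inherits(spec, "ohmic_spectrum"))
  .check_scalar(t, "t", nonneg = TRUE)
  .check_scalar(hbar_tilde, "hbar_tilde", positive = TRUE)
  Fp <- principal_value_shift(spec, ch$delta, t, sign = +1L)
  Fm <- principal_value_shift(spec, ch$delta, t, sign = -1L)
  u00 <- exp(-1i / hbar_tilde * (t * delta_E0 - Mod(spec$f10)^2 * Fp))
  u11 <- exp(-1i / hbar_tilde * (t * delta_E1 - Mod(spec$f01)^2 * Fm))
  u01 <- function(omega) {
    if (t == 0) return(rep(0 + 0i, length(omega)))
    gb <- gamma_bar(spec, omega, t)
    (2i * pi / sqrt(2 * hbar_tilde)) * gb * spec$f01 / pi *
      sin((omega + ch$delta) * t / 2) / (omega + ch$delta) *
      exp(1i * (omega + ch$delta) * t / 2)
  }
  structure(list(u_vac_00 = u00, u_vac_11 = u11, u_alpha_01 = u01,
                 F_plus = Fp, F_minus = Fm,
                 delta_E0 = delta_E0, delta_E1 = delta_E1,
                 t = t, channel = ch, spectrum = spec,
                 hbar_tilde = hbar_tilde),
            class = "propagator_elements")
}

#' @export
print.propagator_elements <- function(x, ...) {
  cat(sprintf("Propagator elements at t = %g (delta = %g)\n", x$t, x$channel$delta))
  cat(sprintf("  u_vac_00 = %s (|.| = %g)\n", format(x$u_vac_00), Mod(x$u_vac_00)))
  cat(sprintf("  u_vac_11 = %s (|.| = %g)\n", format(x$u_vac_11), Mod(x$u_vac_11)))
  cat(sprintf("  F_plus = %g, F_minus = %g\n", x$F_plus, x$F_minus))
  invisible(x)
}

#' Reduced-density-matrix elements Lambda_ij
#'
#' Tracing the second-order evolved state over both reservoirs leaves an
#' X-shaped two-qubit matrix whose non-zero elements, in the product basis
#' `{|00>, |01>, |10>, |11>}`, are
#' \deqn{\Lambda_{14} = \alpha\beta\, e^{-(\Gamma_1+\Gamma_2)t/2}
#'   e^{+i(\Delta_1+\Delta_2)t}, \quad
#'   \Lambda_{22} = \beta^2 (1 - e^{-\Gamma_1 t}) e^{-\Gamma_2 t}, \quad
#'   \Lambda_{33} = \beta^2 e^{-\Gamma_1 t} (1 - e^{-\Gamma_2 t}), \quad
#'   \Lambda_{44} = \beta^2 e^{-(\Gamma_1+\Gamma_2)t},}
#' with \eqn{\Lambda_{41} = \Lambda_{14}^*} and
#' \eqn{\Lambda_{23} = \Lambda_{32} = 0}.  In `"paper"` mode
#' \eqn{\Lambda_{11} = \alpha^2} and the trace decays as population leaks out
#' of the truncated description; in `"trace_preserving"` mode the doubly
#' decayed population is fed back,
#' \eqn{\Lambda_{11} = \alpha^2 + \beta^2 (1 - e^{-\Gamma_1 t})
#' (1 - e^{-\Gamma_2 t})}, giving a unit-trace completely positive map.  The
#' concurrence is the same in both modes.
#'
#' @param state an [initial_state()] object (or `(alpha, beta)` pair).
#' @param ch1,ch2 [channel_params()] objects (or `(delta, gamma)` pairs) for
#'   the DNA and mRNA channels.
#' @param t time(s), >= 0 (vectorised).
#' @param mode `"trace_preserving"` (default) or `"paper"`.
#' @return A list of vectors `L11`, `L22`, `L33`, `L44` (real), `L14`, `L41`
#'   (complex), `L23`, `L32` (zero), one entry per time, with attribute
#'   `"mode"`.
#' @examples
#' lam <- lambda_elements(initial_state(0.6, 0.8),
#'                        channel_params(1, 0.5), channel_params(1, 0.5),
#'                        t = c(0, 1, 2))
#' lam$L44
#' @export
lambda_elements <- function(state, ch1, ch2, t,
                            mode = c("trace_preserving", "paper")) {
  state <- as_initial_state(state)
  ch1 <- as_channel_params(ch1)
  ch2 <- as_channel_params(ch2)
  mode <- match.arg(mode)
  if (any(t < 0)) stop("'t' must be non-negative")
  a2 <- state$alpha^2
  b2 <- state$beta^2
  e1 <- exp(-ch1$gamma * t)
  e2 <- exp(-ch2$gamma * t)
  L11 <- if (mode == "paper") rep(a2, length(t)) else a2 + b2 * (1 - e1) * (1 - e2)
  L14 <- state$alpha * state$beta * sqrt(e1 * e2) *
    exp(1i * (ch1$delta + ch2$delta) * t)
  zero <- rep(0, length(t))
  structure(list(L11 = L11, L14 = L14, L22 = b2 * (1 - e1) * e2,
                 L23 = zero, L32 = zero, L33 = b2 * e1 * (1 - e2),
                 L41 = Conj(L14), L44 = b2 * e1 * e2),
            mode = mode, class = "lambda_elements")
}

#' Reduced density matrix of the qubit pair
#'
#' Assembles the 4x4 X-shaped matrix from [lambda_elements()] in the ordered
#' product basis `{|00>, |01>, |10>, |11>}`.  The result is Hermitian with a
#' real non-negative diagonal; in `"trace_preserving"` mode it has unit trace
#' and non-negative eigenvalues, while in `"paper"` mode its trace equals
#' \eqn{\alpha^2 + \beta^2 (e^{-\Gamma_1 t} + e^{-\Gamma_2 t} -
#' e^{-(\Gamma_1+\Gamma_2)t})}.
#'
#' @inheritParams lambda_elements
#' @param t a single time, >= 0.
#' @return A 4x4 complex matrix of class `"two_qubit_dm"` with attribute
#'   `"mode"`.
#' @examples
#' rho <- reduced_density_matrix(initial_state(1, 0) , channel_params(1, 0.1),
#'                               channel_params(1, 0.1), t = 0)
#' Re(diag(rho))
#' @export
reduced_density_matrix <- function(state, ch1, ch2, t,
                                   mode = c("trace_preserving", "paper")) {
  .check_scalar(t, "t", nonneg = TRUE)
  mode <- match.arg(mode)
  lam <- lambda_elements(state, ch1, ch2, t, mode)
  rho <- matrix(0 + 0i, 4L, 4L)
  rho[1L, 1L] <- lam$L11
  rho[1L, 4L] <- lam$L14
  rho[2L, 2L] <- lam$L22
  rho[2L, 3L] <- lam$L23
  rho[3L, 2L] <- lam$L32
  rho[3L, 3L] <- lam$L33
  rho[4L, 1L] <- lam$L41
  rho[4L, 4L] <- lam$L44
  structure(rho, mode = mode, class = c("two_qubit_dm", "matrix"))
}

#' @export
print.two_qubit_dm <- function(x, ...) {
  cat(sprintf("Two-qubit reduced density matrix (%s mode), trace = %g\n",
              attr(x, "mode"), Re(sum(diag(x)))))
  print(unclass(x), ...)
  invisible(x)
}

#' Survival probability of the initial entangled state
#'
#' The probability of finding the pair still in
#' \eqn{\alpha|00\rangle + \beta|11\rangle} at time `t`:
#' \deqn{P(t) = \alpha^4 + \beta^4 e^{-(\Gamma_1+\Gamma_2)t}
#'   + 2\alpha^2\beta^2 e^{-(\Gamma_1+\Gamma_2)t/2}
#'   \cos((\Delta_1+\Delta_2)t).}
#' `P(0) = 1`; with both decay rates zero it oscillates with period
#' \eqn{2\pi/(\Delta_1+\Delta_2)}; as \eqn{t \to \infty} with positive rates
#' it tends to \eqn{\alpha^4}.
#'
#' @inheritParams lambda_elements
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' s <- initial_state(cos(pi / 4), sin(pi / 4))
#' survival_probability(s, channel_params(1, 0), channel_params(1, 0),
#'                      t = pi / 2)  # 0
#' @export
survival_probability <- function(state, ch1, ch2, t) {
  state <- as_initial_state(state)
  ch1 <- as_channel_params(ch1)
  ch2 <- as_channel_params(ch2)
  if (any(t < 0)) stop("'t' must be non-negative")
  a2 <- state$alpha^2
  b2 <- state$beta^2
  G <- ch1$gamma + ch2$gamma
  a2^2 + b2^2 * exp(-G * t) +
    2 * a2 * b2 * exp(-G * t / 2) * cos((ch1$delta + ch2$delta) * t)
}
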