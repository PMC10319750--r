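# The main user-facing time-series object tying the dynamics and the
# entanglement measures together.

#' Entanglement dynamics of the qubit pair over a time grid
#'
#' Evaluates, on a uniform time grid, the survival probability of the initial
#' entangled state, the closed-form concurrence, the concurrence recomputed
#' independently by the Wootters spin-flip eigenvalue procedure on the
#' reduced density matrix, the entanglement of formation, the diagonal
#' density-matrix elements and the trace.  The numeric concurrence is taken
#' on the raw (unnormalised) matrix so that it matches the closed form in
#' both density-matrix modes; in `"trace_preserving"` mode the trace is 1 and
#' the distinction vanishes.
#'
#' @param alpha,beta initial amplitudes (see [initial_state()]); an
#'   `initial_state` object may be given as `alpha` with `beta` missing.
#' @param delta1,delta2 tunnel splittings of the two channels (>= 0).
#' @param gamma1,gamma2 decay rates of the two channels (>= 0).
#' @param t_max,n_steps uniform grid `seq(0, t_max, length.out = n_steps)`
#'   (defaults 20 and 400), unless `times` is given.
#' @param times explicit time grid (optional, overrides `t_max`/`n_steps`).
#' @param mode density-matrix mode, `"trace_preserving"` (default) or
#'   `"paper"`.
#' @return An object of class `"entanglement_dynamics"`: a list with
#'   `times`, `P_survival`, `C_closed`, `C_numeric`, `EoF`, the Lambda
#'   diagonal/coherence series, `trace`, `sudden_death_time` (`NA` when no
#'   finite death time exists) and `params`.
#' @examples
#' ed <- entanglement_dynamics(0.6, 0.8, gamma1 = 1, gamma2 = 1,
#'                             t_max = 5, n_steps = 101)
#' ed$sudden_death_time  # log(4)
#' head(as.data.frame(ed))
#' @export
entanglement_dynamics <- function(alpha, beta, delta1 = 1, delta2 = 1,
                                  gamma1 = 0.1, gamma2 = 0.1,
                                  t_max = 20, n_steps = 400, times = NULL,
                                  mode = c("trace_preserving", "paper")) {
  state <- if (missing(beta)) as_initial_state(alpha) else initial_state(alpha, beta)
  ch1 <- channel_params(delta1, gamma1)
  ch2 <- channel_params(delta2, gamma2)
  mode <- match.arg(mode)
  if (is.null(times)) {
    .check_scalar(t_max, "t_max", positive = TRUE)
    if (!is.numeric(n_steps) || n_steps < 2) stop("'n_steps' must be >= 2")
    times <- seq(0, t_max, length.out = n_steps)
  }
  if (any(times < 0)) stop("'times' must be non-negative")

  lam <- lambda_elements(state, ch1, ch2, times, mode)
  P <- survival_probability(state, ch1, ch2, times)
  Cc <- concurrence_closed_form(state, ch1, ch2, times)
  Cn <- vapply(seq_along(times), function(i) {
    wootters_concurrence(reduced_density_matrix(state, ch1, ch2, times[i], mode),
                         normalize = FALSE)
  }, numeric(1))
  sdt <- if (ch1$gamma > 0 && ch2$gamma > 0 && state$beta > state$alpha)
    sudden_death_time(state, ch1, ch2, t_max = max(times, 1) * 10)
  else NA_real_

  structure(list(times = times, P_survival = P,
                 C_closed = Cc, C_numeric = Cn,
                 EoF = entanglement_of_formation(Cc),
                 Lambda_11 = lam$L11, Lambda_22 = lam$L22,
                 Lambda_33 = lam$L33, Lambda_44 = lam$L44,
                 Lambda_14 = lam$L14,
                 trace = lam$L11 + lam$L22 + lam$L33 + lam$L44,
                 sudden_death_time = sdt,
                 params = list(alpha = state$alpha, beta = state$beta,
                               delta1 = ch1$delta, delta2 = ch2$delta,
                               gamma1 = ch1$gamma, gamma2 = ch2$gamma,
                               mode = mode)),
            class = "entanglement_dynamics")
}

#' @export
print.entanglement_dynamics <- function(x, ...) {
  p <- x$params
  cat("Entanglement dynamics of a DNA-mRNA qubit pair\n")
  cat(sprintf("  alpha = %g, beta = %g; delta = (%g, %g); gamma = (%g, %g); %s mode\n",
              p$alpha, p$beta, p$delta1, p$delta2, p$gamma1, p$gamma2, p$mode))
  cat(sprintf("  %d time points on [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  C(0) = %.6g, C(t_end) = %.6g; P(t_end) = %.6g\n",
              x$C_closed[1L], x$C_closed[length(x$times)],
              x$P_survival[length(x$times)]))
  if (is.na(x$sudden_death_time))
    cat("  no entanglement sudden death (concurrence decays asymptotically)\n")
  else
    cat(sprintf("  entanglement sudden death at t* = %.6g\n", x$sudden_death_time))
  invisible(x)
}

#' @export
summary.entanglement_dynamics <- function(object, ...) {
  print(object)
  cat(sprintf("  max |C_closed - C_numeric| = %.3g\n",
              max(abs(object$C_closed - object$C_numeric))))
  cat(sprintf("  trace range: [%.6g, %.6g]\n",
              min(object$trace), max(object$trace)))
  invisible(object)
}

#' @export
as.data.frame.entanglement_dynamics <- function(x, ...) {
  data.frame(t = x$times, P_survival = x$P_survival,
             C_closed = x$C_closed, C_numeric = x$C_numeric, EoF = x$EoF,
             Lambda_11 = x$Lambda_11, Lambda_22 = x$Lambda_22,
             Lambda_33 = x$Lambda_33, Lambda_44 = x$Lambda_44,
             Re_Lambda_14 = Re(x$Lambda_14), Im_Lambda_14 = Im(x$Lambda_14),
             trace = x$trace)
}

#' @export
plot.entanglement_dynamics <- function(x, which = c("all", "P", "C", "EoF"),
                                       ...) {
  which <- match.arg(which)
  cols <- switch(which,
                 all = c("P_survival", "C_closed", "EoF"),
                 P = "P_survival", C = "C_closed", EoF = "EoF")
  y <- do.call(cbind, x[cols])
  graphics::matplot(x$times, y, type = "l", lty = 1, lwd = 2,
                    col = seq_along(cols), xlab = "t (dimensionless)",
                    ylab = "value", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, lwd = 2, bty = "n")
  if (!is.na(x$sudden_death_time))
    graphics::abline(v = x$sudden_death_time, lty = 3)
  invisible(x)
}
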