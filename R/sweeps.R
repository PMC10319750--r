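# Figure-style parameter sweeps and the random-state test fixture.

.sweep_scenarios <- c("fig2a", "fig2b", "fig2c", "fig3", "fig4")

.sweep_row <- function(scenario, curve, kappa, state, ch1, ch2, times, mode) {
  ed <- entanglement_dynamics(state, delta1 = ch1$delta, delta2 = ch2$delta,
                              gamma1 = ch1$gamma, gamma2 = ch2$gamma,
                              times = times, mode = mode)
  data.frame(scenario = scenario, curve = curve,
             alpha = state$alpha, beta = state$beta,
             delta1 = ch1$delta, delta2 = ch2$delta,
             gamma1 = ch1$gamma, gamma2 = ch2$gamma,
             kappa = kappa, t = times,
             P_survival = ed$P_survival, C = ed$C_closed, EoF = ed$EoF)
}

#' Parameter sweeps reproducing the figure-style experiments
#'
#' Runs the entanglement dynamics over documented default parameter grids
#' mirroring the published figure scenarios:
#'
#' * `"fig2a"` — survival probability for equal channels
#'   (`delta1 = delta2 = 1`) at increasing decay rates; slower decay for
#'   weaker coupling.
#' * `"fig2b"` — equal channels versus moderately asymmetric channels
#'   (`delta1 > delta2`, `gamma1 > gamma2`).
#' * `"fig2c"` — as `"fig2b"` but strongly asymmetric (`delta1 >> delta2`).
#' * `"fig3"` — concurrence on the factorial grid `kappa x delta`, with the
#'   decay rates tied to the splittings as `gamma_i = kappa * delta_i`.
#' * `"fig4"` — entanglement of formation on the same grids.
#'
#' Exact published curve parameters are not available, so the sweeps assert
#' only the qualitative claims (when `check = TRUE`): the survival-probability
#' envelope is ordered inversely to the total decay rate, and the time for
#' the concurrence to fall below 0.01 is non-increasing in `kappa`.
#'
#' @param scenario one of `"fig2a"`, `"fig2b"`, `"fig2c"`, `"fig3"`,
#'   `"fig4"`.
#' @param kappa ratio `gamma / delta` grid, > 0 (default `c(0.05, 0.1,
#'   0.3)`).
#' @param delta tunnel-splitting grid for the factorial scenarios (default
#'   `c(0.2, 1, 5)`).
#' @param alpha,beta initial amplitudes (default maximally entangled,
#'   `cos(pi/4)`, `sin(pi/4)`).
#' @param t_max,n_steps uniform time grid (defaults 20 and 400).
#' @param mode density-matrix mode (default `"trace_preserving"`).
#' @param check assert the scenario's qualitative ordering claims (default
#'   `TRUE`).
#' @return a `data.frame` with one row per (curve, time point): columns
#'   `scenario`, `curve`, `alpha`, `beta`, `delta1`, `delta2`, `gamma1`,
#'   `gamma2`, `kappa`, `t`, `P_survival`, `C`, `EoF`.
#' @examples
#' sw <- run_sweep("fig3", t_max = 10, n_steps = 50)
#' aggregate(C ~ curve, sw, function(z) z[1])  # all start at 1
#' @export
run_sweep <- function(scenario, kappa = c(0.05, 0.1, 0.3),
                      delta = c(0.2, 1, 5),
                      alpha = cos(pi / 4), beta = sin(pi / 4),
                      t_max = 20, n_steps = 400,
                      mode = c("trace_preserving", "paper"), check = TRUE) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% .sweep_scenarios)
    stop("unknown scenario; use one of: ", paste(.sweep_scenarios, collapse = ", "))
  if (length(kappa) < 1L || any(kappa <= 0)) stop("'kappa' must be positive")
  if (length(delta) < 1L || any(delta <= 0)) stop("'delta' must be positive")
  mode <- match.arg(mode)
  state <- initial_state(alpha, beta)
  times <- seq(0, t_max, length.out = n_steps)
  kappa <- sort(kappa)

  rows <- switch(scenario,
    fig2a = {
      labels <- if (length(kappa) == 3L) c("blue", "red", "green")
                else paste0("gamma=", kappa)
      lapply(seq_along(kappa), function(i)
        .sweep_row(scenario, labels[i], kappa[i], state,
                   channel_params(1, kappa[i]), channel_params(1, kappa[i]),
                   times, mode))
    },
    fig2b = ,
    fig2c = {
      k <- kappa[[ceiling(length(kappa) / 2)]]
      d_hi <- if (scenario == "fig2b") 1 else 5
      d_lo <- if (scenario == "fig2b") 0.5 else 0.2
      list(.sweep_row(scenario, "red", k, state,
                      channel_params(1, k), channel_params(1, k),
                      times, mode),
           .sweep_row(scenario, "blue", k, state,
                      channel_params(d_hi, k * d_hi),
                      channel_params(d_lo, k * d_lo), times, mode))
    },
    fig3 = ,
    fig4 = {
      grid <- expand.grid(kappa = kappa, delta = delta)
      lapply(seq_len(nrow(grid)), function(i) {
        kp <- grid$kappa[i]; dl <- grid$delta[i]
        .sweep_row(scenario, sprintf("kappa=%g delta=%g", kp, dl), kp, state,
                   channel_params(dl, kp * dl), channel_params(dl, kp * dl),
                   times, mode)
      })
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (check) .check_sweep(scenario, out, state)
  out
}

# Qualitative figure-caption claims, asserted on the sweep output.
.check_sweep <- function(scenario, out, state) {
  a2 <- state$alpha^2; b2 <- state$beta^2
  if (scenario == "fig2a") {
    curves <- split(out, out$curve)
    curves <- curves[order(vapply(curves, function(d) d$gamma1[1], numeric(1)))]
    for (i in seq_len(length(curves) - 1L)) {
      lo <- curves[[i]]; hi <- curves[[i + 1L]]
      env_lo <- a2^2 + b2^2 * exp(-2 * lo$gamma1[1] * lo$t) +
        2 * a2 * b2 * exp(-lo$gamma1[1] * lo$t)
      env_hi <- a2^2 + b2^2 * exp(-2 * hi$gamma1[1] * hi$t) +
        2 * a2 * b2 * exp(-hi$gamma1[1] * hi$t)
      if (any(env_lo < env_hi - 1e-12))
        stop("fig2a envelope ordering violated")
      pos <- cos((lo$delta1[1] + lo$delta2[1]) * lo$t) >= 0
      if (any(lo$P_survival[pos] < hi$P_survival[pos] - 1e-12))
        stop("fig2a pointwise ordering violated where the coherent term is non-negative")
    }
  }
  if (scenario %in% c("fig3", "fig4")) {
    first_below <- function(d) {
      i <- which(d$C < 0.01)
      if (length(i)) d$t[min(i)] else Inf
    }
    sp <- split(out, out$delta1)
    for (d in sp) {
      byk <- split(d, d$kappa) # split() orders by numeric value
      tt <- vapply(byk, first_below, numeric(1))
      dd <- diff(tt)
      dd[is.nan(dd)] <- 0 # both Inf: neither curve dies on the grid
      if (any(dd > 1e-9))
        stop("fig3 claim violated: concurrence does not die faster for larger kappa")
    }
  }
  invisible(TRUE)
}

#' Reproducible random two-qubit density matrices (test fixture)
#'
#' Draws `n_states` matrices as normalised \eqn{A A^\dagger} with `A` a 4x4
#' complex matrix of independent standard-normal real and imaginary parts.
#' Each draw is Hermitian, positive semidefinite and unit trace by
#' construction.  The global RNG state is restored afterwards.
#'
#' @param n_states number of matrices, > 0.
#' @param seed integer seed for reproducibility.
#' @return a list of 4x4 complex matrices.
#' @examples
#' rhos <- generate_random_states(3, seed = 42)
#' Re(sum(diag(rhos[[1]])))  # 1
#' @export
generate_random_states <- function(n_states, seed = 1L) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 1)
    stop("'n_states' must be a positive integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_states), function(i) {
    A <- matrix(complex(real = stats::rnorm(16), imaginary = stats::rnorm(16)), 4L, 4L)
    rho <- A %*% Conj(t(A))
    rho / Re(sum(diag(rho)))
  })
}
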