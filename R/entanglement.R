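# Entanglement quantification: Wootters concurrence (spin-flip eigenvalue
# procedure and the model's closed form), X-state eigenvalues, entanglement of
# formation, sudden-death detection and the biological error-basis transform.

.sigma_y2 <- matrix(c(0, 0, 0, -1,
                      0, 0, 1, 0,
                      0, 1, 0, 0,
                      -1, 0, 0, 0), 4L, 4L) # sigma_y (x) sigma_y

#' Wootters concurrence of a two-qubit density matrix
#'
#' Computes the entanglement monotone
#' \deqn{C(\rho) = \max\{0, \sqrt{\lambda_1} - \sqrt{\lambda_2} -
#'   \sqrt{\lambda_3} - \sqrt{\lambda_4}\},}
#' where \eqn{\lambda_1 \ge \dots \ge \lambda_4} are the eigenvalues of
#' \eqn{\rho (\sigma_y \otimes \sigma_y) \rho^* (\sigma_y \otimes \sigma_y)}.
#' `C` is 1 for a maximally entangled state and 0 for a separable one.
#' Eigenvalues within `-1e-12` of zero are clamped to 0 before the square
#' root.
#'
#' The square-rooted eigenvalues are evaluated as the singular values of
#' \eqn{\sqrt{\tilde\rho}\,\sqrt{\rho}} (with \eqn{\tilde\rho} the spin-flipped
#' matrix), which is the same spectrum in exact arithmetic but keeps full
#' precision when eigenvalues of the product matrix underflow toward zero.
#'
#' @param rho a 4x4 Hermitian matrix with positive trace (e.g. from
#'   [reduced_density_matrix()]).  Hermiticity is checked to `herm_tol`.
#' @param normalize if `TRUE` (default) `rho` is renormalised to unit trace
#'   before the measure is taken, as the definition presumes a density
#'   operator.  `normalize = FALSE` evaluates the raw matrix, the convention
#'   under which the model's closed form [concurrence_closed_form()] is
#'   exact even when the `"paper"`-mode trace has leaked below 1.
#' @param herm_tol tolerance for the Hermiticity check (default 1e-10).
#' @return concurrence in `[0, 1]`.
#' @examples
#' bell <- outer(c(1, 0, 0, 1) / sqrt(2), c(1, 0, 0, 1) / sqrt(2))
#' wootters_concurrence(bell)  # 1
#' wootters_concurrence(diag(c(1, 0, 0, 0)))  # 0
#' @export
wootters_concurrence <- function(rho, normalize = TRUE, herm_tol = 1e-10) {
  if (!is.matrix(rho) || !all(dim(rho) == 4L))
    stop("'rho' must be a 4x4 matrix")
  rho <- unclass(rho)
  if (max(Mod(rho - Conj(t(rho)))) > herm_tol * max(1, max(Mod(rho))))
    stop("'rho' is not Hermitian within tolerance ", herm_tol)
  tr <- Re(sum(diag(rho)))
  if (tr <= 0) stop("'rho' must have positive trace")
  if (normalize) rho <- rho / tr
  # sqrt(lambda_i) of rho %*% Y %*% Conj(rho) %*% Y, via singular values of
  # sqrt(rho_tilde) %*% sqrt(rho): identical spectrum, stable near zero
  e <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE)
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * Conj(t(e$vectors)))
  B <- .sigma_y2 %*% Conj(S) %*% .sigma_y2 %*% S
  s <- svd(B, nu = 0, nv = 0)$d # descending
  max(0, s[1L] - s[2L] - s[3L] - s[4L])
}

#' Spin-flip eigenvalues of an X-shaped density matrix
#'
#' For the X matrix of [reduced_density_matrix()] (anti-diagonal coherence
#' only in the `|00>,|11>` block, \eqn{\Lambda_{23} = \Lambda_{32} = 0}) the
#' eigenvalues of \eqn{\rho(\sigma_y\otimes\sigma_y)\rho^*
#' (\sigma_y\otimes\sigma_y)} are available in closed form:
#' \eqn{\lambda_1 = \lambda_2 = \Lambda_{22}\Lambda_{33}} and
#' \eqn{\lambda_{3,4} = (\sqrt{\Lambda_{11}\Lambda_{44}} \mp
#' |\Lambda_{14}|)^2}.  They agree with a direct numerical eigendecomposition
#' to 1e-10.
#'
#' @param lam a `"lambda_elements"` list (single time point) or any list with
#'   entries `L11`, `L22`, `L33`, `L44`, `L14`.
#' @return numeric vector `c(lambda1, lambda2, lambda3, lambda4)` (unsorted;
#'   `lambda3 <= lambda4`).
#' @export
xstate_eigenvalues <- function(lam) {
  need <- c("L11", "L22", "L33", "L44", "L14")
  if (!all(need %in% names(lam))) stop("'lam' must carry ", paste(need, collapse = ", "))
  v <- lapply(lam[need], function(x) {
    if (length(x) != 1L) stop("xstate_eigenvalues expects a single time point")
    x
  })
  d <- Re(c(v$L11, v$L22, v$L33, v$L44))
  if (any(d < -1e-12)) stop("negative diagonal Lambda element")
  d <- pmax(d, 0)
  l12 <- d[2L] * d[3L]
  root <- sqrt(d[1L] * d[4L])
  z <- Mod(v$L14)
  c(lambda1 = l12, lambda2 = l12,
    lambda3 = (root - z)^2, lambda4 = (root + z)^2)
}

#' Closed-form concurrence of the decohering entangled pair
#'
#' For the X-state dynamics of [lambda_elements()] the Wootters concurrence
#' reduces to
#' \deqn{C(t) = \max\left\{0,\; 2\alpha\beta\, e^{-(\Gamma_1+\Gamma_2)t/2}
#'   - 2\beta^2 e^{-(\Gamma_1+\Gamma_2)t/2}
#'   \sqrt{(1 - e^{-\Gamma_1 t})(1 - e^{-\Gamma_2 t})}\right\}.}
#' It is independent of the tunnel splittings (they only rotate the phase of
#' the coherence), starts at \eqn{2\alpha\beta}, and, when \eqn{\beta >
#' \alpha}, hits exactly zero at a finite time (entanglement sudden death,
#' [sudden_death_time()]) while population remains in `|11>`.
#'
#' @inheritParams lambda_elements
#' @param clamp apply the `max(0, .)` clamp required by the Wootters
#'   definition (default `TRUE`).  `clamp = FALSE` exposes the raw
#'   expression, which goes negative past the sudden-death time.
#' @return numeric vector of concurrence values.
#' @examples
#' s <- initial_state(cos(pi / 4), sin(pi / 4))
#' concurrence_closed_form(s, channel_params(1, 0.1), channel_params(1, 0.1),
#'                         t = 0)  # 1
#' @export
concurrence_closed_form <- function(state, ch1, ch2, t, clamp = TRUE) {
  state <- as_initial_state(state)
  ch1 <- as_channel_params(ch1)
  ch2 <- as_channel_params(ch2)
  if (any(t < 0)) stop("'t' must be non-negative")
  env <- exp(-(ch1$gamma + ch2$gamma) * t / 2)
  feed <- sqrt((1 - exp(-ch1$gamma * t)) * (1 - exp(-ch2$gamma * t)))
  val <- 2 * state$alpha * state$beta * env - 2 * state$beta^2 * env * feed
  if (clamp) pmax(0, val) else val
}

#' Binary (Shannon) entropy
#'
#' \eqn{h(x) = -x \log_2 x - (1 - x)\log_2(1 - x)} with the convention
#' \eqn{0 \log 0 = 0}; symmetric about 1/2.
#'
#' @param x probability vector in `[0, 1]`.
#' @return entropy in bits.
#' @examples
#' binary_entropy(c(0, 0.5, 1))  # 0 1 0
#' @export
binary_entropy <- function(x) {
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("'x' must lie in [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  term <- function(p) ifelse(p == 0, 0, -p * log2(p))
  term(x) + term(1 - x)
}

#' Entanglement of formation from concurrence
#'
#' For two qubits the entanglement of formation — the minimal average pure
#' state entanglement over all decompositions — is a closed function of the
#' concurrence:
#' \deqn{E(C) = h\!\left(\frac{1 + \sqrt{1 - C^2}}{2}\right),}
#' with `h` the [binary_entropy()].  `E` is monotone increasing on `[0, 1]`
#' with `E(0) = 0`, `E(1) = 1`.
#'
#' @param C concurrence vector in `[0, 1]`.
#' @return entanglement of formation in bits, in `[0, 1]`.
#' @examples
#' entanglement_of_formation(c(0, 0.6, 1))
#' @export
entanglement_of_formation <- function(C) {
  if (any(!is.finite(C)) || any(C < -1e-12) || any(C > 1 + 1e-12))
    stop("'C' must lie in [0, 1]")
  C <- pmin(pmax(C, 0), 1)
  binary_entropy((1 + sqrt(pmax(0, 1 - C^2))) / 2)
}

#' Entanglement sudden-death time
#'
#' When \eqn{\beta > \alpha} the clamped closed-form concurrence reaches
#' exactly zero at the unique root of
#' \eqn{\alpha\beta = \beta^2 \sqrt{(1 - e^{-\Gamma_1 t})
#' (1 - e^{-\Gamma_2 t})}}, found by bracketed root-finding to 1e-10.  For
#' \eqn{\alpha \ge \beta} the concurrence only decays asymptotically and no
#' finite root exists; `NA` is returned (also when no root lies below
#' `t_max`).
#'
#' @inheritParams lambda_elements
#' @param t_max upper end of the search bracket (default 100).
#' @return the sudden-death time, or `NA_real_` if none exists below
#'   `t_max`.
#' @examples
#' sudden_death_time(initial_state(0.6, 0.8), channel_params(1, 1),
#'                   channel_params(1, 1))  # log(4)
#' @export
sudden_death_time <- function(state, ch1, ch2, t_max = 100) {
  state <- as_initial_state(state)
  ch1 <- as_channel_params(ch1)
  ch2 <- as_channel_params(ch2)
  .check_scalar(t_max, "t_max", positive = TRUE)
  if (ch1$gamma <= 0 || ch2$gamma <= 0)
    stop("sudden-death detection requires gamma1 > 0 and gamma2 > 0")
  if (state$beta <= state$alpha) return(NA_real_)
  f <- function(t) {
    state$alpha - state$beta *
      sqrt((1 - exp(-ch1$gamma * t)) * (1 - exp(-ch2$gamma * t)))
  }
  if (f(t_max) > 0) return(NA_real_) # root beyond the searched horizon
  stats::uniroot(f, c(0, t_max), tol = 1e-10)$root
}

#' Populations in the biological error basis
#'
#' The computational levels are superpositions of the biologically legible
#' outcomes: on each factor
#' \eqn{|0\rangle = (|cor\rangle - |er\rangle)/\sqrt2},
#' \eqn{|1\rangle = (|cor\rangle + |er\rangle)/\sqrt2}, where "cor"/"er" is a
#' correct/erroneous base laid down by the corresponding polymerase (D for
#' the daughter DNA strand, R for the mRNA).  This rotates the density matrix
#' by \eqn{W \otimes W} and returns its diagonal, i.e. the joint error
#' probabilities, renormalised by the trace.  For the maximally entangled
#' initial state the two single-error outcomes have probability zero: a
#' D-error occurs exactly when an R-error does.
#'
#' @param rho a 4x4 density matrix in the computational product basis.
#' @return named numeric vector `(cor_cor, cor_er, er_cor, er_er)` summing
#'   to 1.
#' @examples
#' bell <- outer(c(1, 0, 0, 1) / sqrt(2), c(1, 0, 0, 1) / sqrt(2))
#' error_basis_populations(bell)  # (0.5, 0, 0, 0.5)
#' @export
error_basis_populations <- function(rho) {
  if (!is.matrix(rho) || !all(dim(rho) == 4L))
    stop("'rho' must be a 4x4 matrix")
  rho <- unclass(rho)
  tr <- Re(sum(diag(rho)))
  if (abs(tr) < 1e-14) stop("'rho' has zero trace")
  W <- matrix(c(1, -1, 1, 1), 2L, 2L) / sqrt(2) # columns: |0>, |1> in (cor, er) coords
  W4 <- kronecker(W, W)
  p <- Re(diag(W4 %*% rho %*% Conj(t(W4)))) / tr
  names(p) <- c("cor_cor", "cor_er", "er_cor", "er_er")
  p
}
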