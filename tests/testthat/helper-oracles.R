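# Independent brute-force oracles used to validate the quadrature engines and
# the concurrence implementation.

# composite Simpson rule on a uniform grid (n intervals, n even)
oracle_simpson <- function(f, a, b, n = 200000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

oracle_trapezoid <- function(f, a, b, n = 200000L) {
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  sum((y[-1L] + y[-length(y)]) / 2) * (b - a) / n
}

# principal value of -(1/pi) * int_0^upper J(w) sin((w - delta) t)/(w - delta)^2
# by paired sampling around the pole plus trapezoid tails
oracle_pv_minus <- function(Jf, delta, t, upper, n = 200000L) {
  g <- function(w) Jf(w) * sin((w - delta) * t) / (w - delta)^2
  h <- 0.5 * min(delta, upper - delta)
  paired <- function(u) (Jf(delta + u) - Jf(delta - u)) * sin(u * t) / u^2
  u <- seq(h / n, h, length.out = n) # paired points, pole excluded
  window <- sum((paired(u)[-1L] + paired(u)[-n]) / 2) * (h - h / n) / (n - 1L) +
    paired(h / n) * (h / n) # small residual cell, integrand -> 2 J'(delta) t
  val <- oracle_trapezoid(g, 0, delta - h, n) + window +
    oracle_trapezoid(g, delta + h, upper, n)
  -(1 / pi) * val
}

# Wootters concurrence by the direct eigendecomposition of
# rho (sy x sy) rho* (sy x sy) -- the textbook route, independent of the
# package's singular-value evaluation
oracle_wootters_eigen <- function(rho) {
  Y <- matrix(c(0, 0, 0, -1,
                0, 0, 1, 0,
                0, 1, 0, 0,
                -1, 0, 0, 0), 4L, 4L)
  rho <- unclass(rho) / Re(sum(diag(unclass(rho))))
  R <- rho %*% Y %*% Conj(rho) %*% Y
  lam <- sort(pmax(Re(eigen(R, only.values = TRUE)$values), 0),
              decreasing = TRUE)
  s <- sqrt(lam)
  max(0, s[1L] - s[2L] - s[3L] - s[4L])
}

oracle_spinflip_eigenvalues <- function(rho) {
  Y <- matrix(c(0, 0, 0, -1,
                0, 0, 1, 0,
                0, 1, 0, 0,
                -1, 0, 0, 0), 4L, 4L)
  rho <- unclass(rho)
  sort(Re(eigen(rho %*% Y %*% Conj(rho) %*% Y, only.values = TRUE)$values))
}

# total mass of the mode density: Simpson on [0, W] plus the analytic tail
# (1/(2 pi t)) int_W^Inf 2(1 - cos(wt))/w^2 dw ~ (1/(2 pi t)) (2/W + 2 sin(Wt)/(t W^2))
oracle_mode_density_mass <- function(t, W = 1000 / t, n = 200000L) {
  oracle_simpson(function(w) mode_density(w, t), 0, W, n) +
    (1 / (2 * pi * t)) * (2 / W + 2 * sin(W * t) / (t * W^2))
}

# a random normalized (alpha, beta) pair
random_state <- function() {
  th <- runif(1, 0, pi / 2)
  initial_state(cos(th), sin(th))
}
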