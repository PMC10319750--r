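bell_rho <- outer(c(1, 0, 0, 1) / sqrt(2), c(1, 0, 0, 1) / sqrt(2)) + 0i

test_that("Wootters concurrence is 1 for a Bell state and 0 for product states", {
  expect_equal(wootters_concurrence(bell_rho), 1)
  expect_equal(wootters_concurrence(diag(c(1, 0, 0, 0)) + 0i), 0)
  expect_equal(wootters_concurrence(diag(rep(0.25, 4)) + 0i), 0) # maximally mixed
})

test_that("Wootters concurrence crosses zero at the Werner-state boundary p = 1/3", {
  werner <- function(p) p * bell_rho + (1 - p) * diag(4) / 4
  # known closed form C = max(0, (3p - 1)/2), exercised through the
  # eigenvalue procedure itself just above and below the boundary
  expect_equal(wootters_concurrence(werner(1 / 3)), 0, tolerance = 1e-12)
  expect_equal(wootters_concurrence(werner(1 / 3 - 0.05)), 0)
  expect_equal(wootters_concurrence(werner(1 / 3 + 0.05)),
               (3 * (1 / 3 + 0.05) - 1) / 2, tolerance = 1e-12)
  expect_equal(wootters_concurrence(werner(0.8)), (3 * 0.8 - 1) / 2,
               tolerance = 1e-12)
})

test_that("Wootters concurrence agrees with the direct eigendecomposition route", {
  for (rho in generate_random_states(25, seed = 5)) {
    expect_equal(wootters_concurrence(rho), oracle_wootters_eigen(rho),
                 tolerance = 1e-7)
  }
  bad <- bell_rho; bad[1, 2] <- 0.3
  expect_error(wootters_concurrence(bad), "Hermitian")
})

test_that("X-state eigenvalues match a brute-force eigensolver", {
  # t = 0 pure Bell: lambda1 = lambda2 = 0 and sqrt(l4) - sqrt(l3) = 1
  lam0 <- list(L11 = 0.5, L22 = 0, L33 = 0, L44 = 0.5, L14 = 0.5 + 0i)
  ev0 <- xstate_eigenvalues(lam0)
  expect_equal(unname(ev0[c("lambda1", "lambda2")]), c(0, 0))
  expect_equal(sqrt(ev0[["lambda4"]]) - sqrt(ev0[["lambda3"]]), 1)
  # no coherence: lambda3 = lambda4 degenerate
  lamd <- list(L11 = 0.3, L22 = 0.1, L33 = 0.2, L44 = 0.4, L14 = 0 + 0i)
  evd <- xstate_eigenvalues(lamd)
  expect_equal(evd[["lambda3"]], evd[["lambda4"]])
  # random X-state draws against the direct eigensolver, ordering-insensitive
  set.seed(9)
  for (i in seq_len(50)) {
    st <- random_state()
    c1 <- channel_params(runif(1, 0, 4), runif(1, 0, 2))
    c2 <- channel_params(runif(1, 0, 4), runif(1, 0, 2))
    t0 <- runif(1, 0, 10)
    mode <- sample(c("paper", "trace_preserving"), 1)
    lam <- lambda_elements(st, c1, c2, t0, mode)
    rho <- reduced_density_matrix(st, c1, c2, t0, mode)
    expect_equal(sort(unname(xstate_eigenvalues(lam))),
                 oracle_spinflip_eigenvalues(rho), tolerance = 1e-10)
  }
  expect_error(xstate_eigenvalues(list(L11 = -0.2, L22 = 0, L33 = 0,
                                       L44 = 0.5, L14 = 0i)), "negative")
})

test_that("the closed-form concurrence matches its hand-evaluated values", {
  st <- initial_state(cos(pi / 4), sin(pi / 4))
  ch <- channel_params(1, 0.3)
  expect_equal(concurrence_closed_form(st, ch, ch, 0), 1)
  st2 <- initial_state(0.6, 0.8)
  expect_equal(concurrence_closed_form(st2, ch, ch, 0), 0.96)
  # no decoherence: constant 2 alpha beta
  ch0 <- channel_params(5, 0)
  expect_equal(concurrence_closed_form(st2, ch0, ch0, c(0, 3, 50)),
               rep(0.96, 3))
  # alpha = beta = 1/sqrt(2), Gamma = log(2), t = 1: 1/2 - 1/4 = 1/4
  chl <- channel_params(1, log(2))
  expect_equal(concurrence_closed_form(st, chl, chl, 1), 0.25)
})

test_that("the unclamped expression goes negative where Wootters returns zero", {
  st <- initial_state(0.3, sqrt(1 - 0.09)) # beta > alpha: sudden death regime
  ch <- channel_params(1, 1)
  t_late <- 5
  raw <- concurrence_closed_form(st, ch, ch, t_late, clamp = FALSE)
  expect_lt(raw, 0)
  expect_equal(concurrence_closed_form(st, ch, ch, t_late), 0)
  rho <- reduced_density_matrix(st, ch, ch, t_late)
  expect_equal(wootters_concurrence(rho), 0)
})

test_that("closed-form and eigenvalue-procedure concurrence agree on a dense grid", {
  # oracle equivalence in BOTH density-matrix modes
  alphas <- c(0.3, 0.5, 0.7, 0.9)
  gammas <- c(0.05, 0.2, 1)
  deltas <- c(0, 1, 5)
  times <- seq(0, 10, length.out = 20)
  worst <- 0
  for (a in alphas) {
    st <- initial_state(a, sqrt(1 - a^2))
    for (g1 in gammas) for (d in deltas) {
      c1 <- channel_params(d, g1)
      c2 <- channel_params(d, 0.2)
      closed <- concurrence_closed_form(st, c1, c2, times)
      for (mode in c("paper", "trace_preserving")) {
        numeric <- vapply(times, function(t0)
          wootters_concurrence(reduced_density_matrix(st, c1, c2, t0, mode),
                               normalize = FALSE), numeric(1))
        worst <- max(worst, max(abs(closed - numeric)))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("concurrence is phase-invariant and monotone under decoherence", {
  st <- initial_state(0.6, 0.8)
  times <- seq(0, 15, length.out = 40)
  base <- vapply(times, function(t0)
    wootters_concurrence(reduced_density_matrix(st, channel_params(0, 0.3),
                                                channel_params(0, 0.7), t0)),
    numeric(1))
  for (d in c(1, 5)) {
    rot <- vapply(times, function(t0)
      wootters_concurrence(reduced_density_matrix(st, channel_params(d, 0.3),
                                                  channel_params(2 * d, 0.7), t0)),
      numeric(1))
    expect_equal(rot, base, tolerance = 1e-12) # splittings only rotate the phase
  }
  expect_true(all(diff(base) <= 1e-12)) # nonincreasing under positive rates
})

test_that("binary entropy and entanglement of formation match direct evaluation", {
  expect_identical(binary_entropy(0.5), 1)
  expect_identical(binary_entropy(0), 0)
  expect_identical(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), 0.8112781244591328, tolerance = 1e-12)
  x <- seq(0, 1, by = 0.05)
  expect_equal(binary_entropy(x), binary_entropy(1 - x)) # symmetry
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")

  expect_equal(entanglement_of_formation(0), 0)
  expect_equal(entanglement_of_formation(1), 1)
  expect_equal(entanglement_of_formation(0.6), binary_entropy(0.9))
  expect_equal(entanglement_of_formation(0.6), 0.4689955935892812,
               tolerance = 1e-10)
  expect_error(entanglement_of_formation(-0.1), "\\[0, 1\\]")
  # monotone in C
  C <- sort(runif(500))
  expect_true(all(diff(entanglement_of_formation(C)) >= 0))
})

test_that("sudden-death time matches the closed-form inversion", {
  st <- initial_state(0.6, 0.8)
  ch <- channel_params(1, 1)
  # (1 - exp(-t*)) = alpha / beta = 0.75 -> t* = -log(0.25)
  expect_equal(sudden_death_time(st, ch, ch), -log(0.25), tolerance = 1e-8)
  # concurrence is exactly zero past t* while |11> population persists
  tst <- -log(0.25) + c(0.1, 1, 3)
  expect_equal(concurrence_closed_form(st, ch, ch, tst), rep(0, 3))
  expect_true(all(lambda_elements(st, ch, ch, tst)$L44 > 0))
  # alpha >= beta: asymptotic decay only
  expect_true(is.na(sudden_death_time(initial_state(cos(pi / 4), sin(pi / 4)),
                                      ch, ch)))
  expect_true(is.na(sudden_death_time(initial_state(0.8, 0.6), ch, ch)))
  # root beyond the searched horizon
  slow <- channel_params(1, 1e-4)
  expect_true(is.na(sudden_death_time(st, slow, slow, t_max = 1)))
  expect_error(sudden_death_time(st, channel_params(1, 0), ch), "gamma")
})

test_that("error-basis populations expose the correlated R-D error structure", {
  expect_equal(error_basis_populations(bell_rho),
               c(cor_cor = 0.5, cor_er = 0, er_cor = 0, er_er = 0.5))
  expect_equal(unname(error_basis_populations(diag(c(1, 0, 0, 0)) + 0i)),
               rep(0.25, 4))
  expect_equal(unname(error_basis_populations(diag(4) / 4 + 0i)), rep(0.25, 4))
  # populations sum to 1 even for a leaking (paper-mode) matrix
  st <- initial_state(0.6, 0.8)
  ch <- channel_params(1, 0.5)
  rho <- reduced_density_matrix(st, ch, ch, 2, mode = "paper")
  expect_equal(sum(error_basis_populations(rho)), 1, tolerance = 1e-12)
  expect_error(error_basis_populations(matrix(0 + 0i, 4, 4)), "zero trace")
})

test_that("the dynamics object ties the measures together consistently", {
  ed <- entanglement_dynamics(0.6, 0.8, delta1 = 2, delta2 = 1,
                              gamma1 = 0.8, gamma2 = 0.4, t_max = 8,
                              n_steps = 80)
  expect_s3_class(ed, "entanglement_dynamics")
  expect_lt(max(abs(ed$C_closed - ed$C_numeric)), 1e-8)
  expect_equal(ed$EoF, entanglement_of_formation(ed$C_closed))
  expect_true(all(ed$C_closed >= 0 & ed$C_closed <= 1))
  expect_true(all(ed$EoF >= 0 & ed$EoF <= 1))
  expect_equal(ed$trace, rep(1, 80), tolerance = 1e-12)
  expect_false(is.na(ed$sudden_death_time))
  df <- as.data.frame(ed)
  expect_named(df, c("t", "P_survival", "C_closed", "C_numeric", "EoF",
                     "Lambda_11", "Lambda_22", "Lambda_33", "Lambda_44",
                     "Re_Lambda_14", "Im_Lambda_14", "trace"))
  expect_output(print(ed), "sudden death")
  # paper and trace-preserving modes give identical concurrence
  edp <- entanglement_dynamics(0.6, 0.8, delta1 = 2, delta2 = 1,
                               gamma1 = 0.8, gamma2 = 0.4, t_max = 8,
                               n_steps = 80, mode = "paper")
  expect_equal(edp$C_numeric, ed$C_numeric, tolerance = 1e-10)
})
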